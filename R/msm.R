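#' Count microstate transitions at a lag
#'
#' Counts ordered pairs `(t, t + lag)` within each trajectory with a sliding
#' window (stride 1) by default, or with strided sampling (`t = 1, 1+lag,
#' 1+2*lag, ...`) when `sliding = FALSE`. Populations count every frame once,
#' independent of the lag.
#'
#' @param trajs a [dtrajs()] object (or a list coercible to one).
#' @param lag positive integer lag, in trajectory steps.
#' @param sliding logical; sliding window (default) or strided counting.
#' @return a list of class `count_matrix`: `counts` (n x n integer matrix),
#'   `populations`, `lag`, and `state_map` carried over from the input.
#' @examples
#' count_transitions(dtrajs(list(c(0, 1, 0, 1, 0))), lag = 1)$counts
#' @export
count_transitions <- function(trajs, lag = 1L, sliding = TRUE) {
  if (!inherits(trajs, "dtrajs")) trajs <- dtrajs(trajs)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be a positive integer")
  n <- trajs$n_states
  usable <- lengths(trajs$trajectories) > lag
  if (!any(usable))
    stop(sprintf("no transitions at this lag: all trajectories have length <= %d", lag))
  counts <- matrix(0L, n, n)
  for (tr in trajs$trajectories[usable]) {
    len <- length(tr)
    from_idx <- if (sliding) seq_len(len - lag) else seq(1L, len - lag, by = lag)
    from <- tr[from_idx] + 1L
    to <- tr[from_idx + lag] + 1L
    # accumulate via a linearized index table
    tab <- tabulate((to - 1L) * n + from, nbins = n * n)
    counts <- counts + matrix(tab, n, n)
  }
  populations <- tabulate(unlist(trajs$trajectories, use.names = FALSE) + 1L,
                          nbins = n)
  structure(
    list(counts = counts, populations = populations, lag = lag,
         state_map = trajs$state_map),
    class = "count_matrix"
  )
}

#' Restrict a count matrix to its largest strongly connected component
#'
#' Commute times to states that cannot be reached (or left) are infinite, so
#' the microstate model is built on the largest strongly connected component
#' of the directed transition-count graph. Removed states are reported via a
#' message, never silently dropped.
#'
#' @param cm a `count_matrix` from [count_transitions()].
#' @return a `count_matrix` restricted to the retained states, with
#'   `state_map` giving the original label of each retained state and
#'   `removed` listing the dropped original labels.
#' @export
trim_to_ergodic <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  n <- nrow(cm$counts)
  g <- igraph::graph_from_adjacency_matrix(cm$counts > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  largest <- which.max(tabulate(comp$membership, nbins = comp$no))
  keep <- which(comp$membership == largest)
  if (length(keep) < 2L)
    stop("degenerate chain: largest strongly connected component has < 2 states")
  keep <- sort(keep)
  removed <- setdiff(seq_len(n), keep)
  if (length(removed))
    message(sprintf("trim_to_ergodic: removed %d of %d states outside the largest strongly connected component",
                    length(removed), n))
  structure(
    list(counts = cm$counts[keep, keep, drop = FALSE],
         populations = cm$populations[keep],
         lag = cm$lag,
         state_map = cm$state_map[keep],
         removed = cm$state_map[removed]),
    class = "count_matrix"
  )
}

#' Maximum-likelihood transition matrix from counts
#'
#' `T[i, j] = counts[i, j] / rowsum_i`, with no pseudocounts by default. An
#' optional additive `prior` is added to every count before normalization;
#' `symmetrize` averages the count matrix with its transpose first, giving a
#' reversible estimate.
#'
#' @param cm a `count_matrix` (trim with [trim_to_ergodic()] first).
#' @param prior non-negative pseudocount added to every entry (default 0).
#' @param symmetrize average counts with their transpose before normalizing.
#' @return row-stochastic numeric matrix.
#' @export
transition_matrix <- function(cm, prior = 0, symmetrize = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  C <- cm$counts + 0
  if (symmetrize) C <- (C + t(C)) / 2
  if (prior > 0) C <- C + prior
  rs <- rowSums(C)
  if (any(rs == 0))
    stop("zero row sum in count matrix; apply trim_to_ergodic() first")
  C / rs
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi T = pi`, `sum(pi) = 1` by replacing one equation of the
#' singular system with the normalization constraint; the result is verified
#' as a left eigenvector to 1e-8. Requires an irreducible chain.
#'
#' @param T row-stochastic matrix.
#' @return numeric vector `pi`, strictly positive, summing to 1.
#' @export
stationary_distribution <- function(T) {
  n <- nrow(T)
  stopifnot(n == ncol(T), all(abs(rowSums(T) - 1) < 1e-8))
  g <- igraph::graph_from_adjacency_matrix(T > 0, mode = "directed")
  if (!igraph::is_connected(g, mode = "strong"))
    stop("transition matrix is not irreducible; stationary distribution is not unique")
  A <- t(diag(n) - T)        # rows: pi (I - T) = 0 transposed
  A[n, ] <- 1                # replace last equation with sum(pi) = 1
  b <- c(rep(0, n - 1L), 1)
  pi <- solve(A, b)
  pi <- pi / sum(pi)
  if (max(abs(pi %*% T - pi)) > 1e-8)
    stop("stationary distribution failed to verify (pi T != pi)")
  if (any(pi <= 0))
    stop("non-positive stationary probability; chain may be numerically degenerate")
  as.numeric(pi)
}

#' Free-energy proxy from stationary probabilities
#'
#' `E_i = -log(pi_i)` (dimensionless): a microstate with high stationary
#' probability sits in a deep basin and gets a low free energy.
#'
#' @param pi stationary distribution with all entries > 0.
#' @return numeric vector of free energies.
#' @export
free_energies <- function(pi) {
  if (any(pi <= 0)) stop("free energies undefined for pi_i <= 0")
  -log(pi)
}

#' Fit a microstate Markov model from discrete trajectories
#'
#' Convenience wrapper running [count_transitions()], [trim_to_ergodic()],
#' [transition_matrix()], [stationary_distribution()] and [free_energies()].
#'
#' @inheritParams count_transitions
#' @inheritParams transition_matrix
#' @return an object of class `msm_fit`: `T`, `pi`, `E`, `populations`
#'   (restricted to retained states), `counts`, `state_map` (original label
#'   of each retained state), `removed`, `lag`, `n_states`.
#' @examples
#' m <- fit_msm(dtrajs(list(c(0, 1, 0, 1, 1, 0, 0, 1))))
#' m$pi
#' @export
fit_msm <- function(trajs, lag = 1L, sliding = TRUE, prior = 0,
                    symmetrize = FALSE) {
  cm <- count_transitions(trajs, lag = lag, sliding = sliding)
  cm <- trim_to_ergodic(cm)
  T <- transition_matrix(cm, prior = prior, symmetrize = symmetrize)
  pi <- stationary_distribution(T)
  structure(
    list(T = T, pi = pi, E = free_energies(pi),
         populations = cm$populations, counts = cm$counts,
         state_map = cm$state_map, removed = cm$removed,
         lag = cm$lag, n_states = nrow(T)),
    class = "msm_fit"
  )
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("<msm_fit> %d microstates (lag %d)", x$n_states, x$lag))
  if (length(x$removed)) cat(sprintf(", %d trimmed", length(x$removed)))
  cat(sprintf("\n  free energy range [%.3f, %.3f]\n", min(x$E), max(x$E)))
  invisible(x)
}

#' Tidy a fitted microstate model
#'
#' @param x an `msm_fit`.
#' @param ... unused.
#' @return a tibble with one row per retained microstate: internal `state`
#'   (0-based), original `label`, `population`, stationary probability `pi`
#'   and `free_energy`.
#' @importFrom generics tidy
#' @method tidy msm_fit
#' @export
tidy.msm_fit <- function(x, ...) {
  tibble::tibble(
    state = seq_len(x$n_states) - 1L,
    label = x$state_map,
    population = x$populations,
    pi = x$pi,
    free_energy = x$E
  )
}

#' One-row model summary
#'
#' @param x an `msm_fit`.
#' @param ... unused.
#' @return a tibble with `n_states`, `n_removed`, `lag`, `total_frames`, and
#'   the free-energy range.
#' @importFrom generics glance
#' @method glance msm_fit
#' @export
glance.msm_fit <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states,
    n_removed = length(x$removed),
    lag = x$lag,
    total_frames = sum(x$populations),
    min_free_energy = min(x$E),
    max_free_energy = max(x$E)
  )
}

#' @export
generics::tidy

#' @export
generics::glance
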