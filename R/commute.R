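#' Expected hitting times to a target microstate
#'
#' For an irreducible row-stochastic `T`, the hitting time `h[i]` is the
#' expected number of steps for a walker started at `i` to first reach
#' `target`. It solves the linear system `h_i = 1 + sum_k T[i, k] h_k` over
#' `i != target` with `h[target] = 0`.
#'
#' @param T row-stochastic transition matrix.
#' @param target 1-based index of the target microstate.
#' @return numeric vector of hitting times (in lag units), 0 at the target.
#' @export
hitting_times_to <- function(T, target) {
  n <- nrow(T)
  stopifnot(target >= 1, target <= n)
  idx <- setdiff(seq_len(n), target)
  A <- diag(n - 1L) - T[idx, idx, drop = FALSE]
  h <- rep(0, n)
  sol <- tryCatch(solve(A, rep(1, n - 1L)),
                  error = function(e) stop("singular hitting-time system; chain is reducible"))
  h[idx] <- sol
  h
}

#' Commute-time distance matrix between microstates
#'
#' The commute time `D[i, j]` is the expected number of steps for a walker
#' to go from `i` to `j` and back: the sum of the two (generally asymmetric)
#' hitting times, which is symmetric. It is computed from the fundamental
#' matrix `Z = (I - T + 1 pi^T)^{-1}` via
#' `h(i -> j) = (Z[j, j] - Z[i, j]) / pi[j]`, one O(n^3) solve for the whole
#' matrix. If `Z` is badly conditioned the computation falls back to
#' per-target linear solves with a warning.
#'
#' Commute time behaves like a squared kinetic distance: it is symmetric and
#' positive off the diagonal but need not satisfy the triangle inequality.
#'
#' @param model an `msm_fit` (or a list with elements `T` and `pi`).
#' @param rcond_threshold reciprocal-condition threshold below which the
#'   fundamental-matrix route is abandoned.
#' @return an object of class `commute_dist`: symmetric matrix `D` with zero
#'   diagonal (lag units), `d_min` (smallest off-diagonal entry) and
#'   `D_star` (largest minimum-spanning-tree edge: the smallest scale at
#'   which the neighborhood graph over all states is connected), plus the
#'   model's `state_map`.
#' @examples
#' m <- list(T = matrix(c(0.9, 0.2, 0.1, 0.8), 2), pi = c(2 / 3, 1 / 3))
#' commute_distances(m)$D[1, 2]  # 1/0.1 + 1/0.2 = 15
#' @export
commute_distances <- function(model, rcond_threshold = 1e-12) {
  T <- model$T
  pi <- model$pi
  n <- nrow(T)
  if (n < 2L) stop("commute distances need at least 2 microstates")
  A <- diag(n) - T + matrix(1, n, 1) %*% matrix(pi, 1, n)
  H <- NULL
  if (rcond(A) > rcond_threshold) {
    Z <- solve(A)
    # H[i, j] = hitting time i -> j
    H <- (matrix(diag(Z), n, n, byrow = TRUE) - Z) /
      matrix(pi, n, n, byrow = TRUE)
  } else {
    warning("ill-conditioned fundamental matrix; falling back to per-target solves")
    H <- vapply(seq_len(n), function(j) hitting_times_to(T, j), numeric(n))
  }
  D <- H + t(H)
  D <- (D + t(D)) / 2   # enforce exact symmetry against round-off
  diag(D) <- 0
  if (any(D[upper.tri(D)] <= 0))
    stop("non-positive off-diagonal commute time; chain is numerically degenerate")
  bounds <- scale_bounds(D)
  structure(
    list(D = D, d_min = bounds[["d_min"]], D_star = bounds[["D_star"]],
         state_map = model$state_map %||% (seq_len(n) - 1L)),
    class = "commute_dist"
  )
}

#' @export
print.commute_dist <- function(x, ...) {
  cat(sprintf("<commute_dist> %d microstates; d_min = %.4g, D* = %.4g\n",
              nrow(x$D), x$d_min, x$D_star))
  invisible(x)
}

#' Scale-parameter bounds of a distance matrix
#'
#' Any scale below `d_min` (the smallest pairwise distance) produces only
#' singletons; any scale at or above `D_star` (the largest edge of the
#' minimum spanning tree) produces a single cluster. Useful scales live in
#' `[d_min, D_star]`.
#'
#' @param D symmetric distance matrix, `n >= 2`.
#' @return named numeric vector `c(d_min = , D_star = )`.
#' @export
scale_bounds <- function(D) {
  n <- nrow(D)
  if (is.null(n) || n < 2L) stop("scale bounds need at least 2 points")
  off <- D[upper.tri(D)]
  g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE,
                                           mode = "undirected", diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  c(d_min = min(off), D_star = max(igraph::E(mst)$weight))
}

#' Tidy a commute-distance matrix into long form
#'
#' @param x a `commute_dist`.
#' @param ... unused.
#' @return a tibble with columns `from`, `to` (original labels, upper
#'   triangle only) and `commute_time`.
#' @method tidy commute_dist
#' @export
tidy.commute_dist <- function(x, ...) {
  n <- nrow(x$D)
  idx <- which(upper.tri(x$D), arr.ind = TRUE)
  tibble::tibble(
    from = x$state_map[idx[, 1L]],
    to = x$state_map[idx[, 2L]],
    commute_time = x$D[idx]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
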