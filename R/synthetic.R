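#' Synthetic multi-well landscape specification
#'
#' A landscape is a sum of inverted Gaussian wells on a flat background over
#' the unit domain `[0, 1)^dimension`, optionally periodic (torsion-angle
#' style: both axes wrap). Together with a temperature and a discretization
#' grid it defines a stated world in which every stage of the analysis can
#' be tested against planted structure.
#'
#' @param dimension 1 or 2.
#' @param wells data frame with columns `well` (name), `depth` (> 0),
#'   `width` (> 0) and center coordinates `x` (and `y` when 2-D).
#' @param periodic logical; wrap both axes (2-D torsion-like domain).
#' @param temperature Metropolis temperature (energy units of `depth`).
#' @param grid_bins bins per axis (>= 4) for microstate discretization.
#' @param step_size default Gaussian proposal width for the Metropolis
#'   walker on this landscape.
#' @return an object of class `landscape_spec`.
#' @export
landscape_spec <- function(dimension, wells, periodic = FALSE,
                           temperature = 1, grid_bins = 20L,
                           step_size = 0.05) {
  stopifnot(dimension %in% c(1L, 2L),
            all(wells$depth > 0), all(wells$width > 0),
            grid_bins >= 4L, step_size > 0)
  if (dimension == 2L) stopifnot(!is.null(wells$y))
  structure(
    list(dimension = as.integer(dimension), wells = tibble::as_tibble(wells),
         periodic = periodic, temperature = temperature,
         grid_bins = as.integer(grid_bins), step_size = step_size),
    class = "landscape_spec")
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat(sprintf("<landscape_spec> %d-D%s, %d wells, %d bins/axis, T = %g\n",
              x$dimension, if (x$periodic) " periodic" else "",
              nrow(x$wells), x$grid_bins, x$temperature))
  invisible(x)
}

# displacement respecting periodic minimum image on the unit interval
axis_delta <- function(x, center, periodic) {
  d <- x - center
  if (periodic) d <- d - round(d)
  d
}

#' Potential energy of a landscape
#'
#' @param spec a [landscape_spec()].
#' @param x numeric vector of first-axis coordinates.
#' @param y second-axis coordinates (2-D only).
#' @return potential values (0 on the background, negative inside wells).
#' @export
landscape_potential <- function(spec, x, y = NULL) {
  U <- numeric(length(x))
  for (k in seq_len(nrow(spec$wells))) {
    w <- spec$wells[k, ]
    d2 <- axis_delta(x, w$x, spec$periodic)^2
    if (spec$dimension == 2L)
      d2 <- d2 + axis_delta(y, w$y, spec$periodic)^2
    U <- U - w$depth * exp(-d2 / (2 * w$width^2))
  }
  U
}

#' The three-basin one-dimensional test landscape
#'
#' Two deep, well-separated basins A and B and one shallow basin C sitting
#' between them but much nearer to A, with the A-C barrier lower than any
#' barrier to B. At a permissive density threshold and moderate scale C
#' merges into A, leaving two main clusters; at strict thresholds all three
#' basins are distinct.
#'
#' @return a 1-D [landscape_spec()] with 50 bins.
#' @export
make_figure1_landscape <- function() {
  landscape_spec(
    dimension = 1L,
    wells = tibble::tibble(
      well = c("A", "C", "B"),
      x = c(0.20, 0.45, 0.80),
      depth = c(8.0, 4.0, 7.5),
      width = c(0.055, 0.05, 0.055)),
    periodic = FALSE, temperature = 1, grid_bins = 50L, step_size = 0.06)
}

#' A torsion-like two-dimensional six-well test landscape
#'
#' Periodic in both axes (as a pair of backbone dihedrals would be). Four
#' prominent wells `a`-`d` of graded depth, with a low saddle between `a`
#' and `b` — lower than the core energies of the two remaining wells, so
#' `a` and `b` merge at the density level where every state is visible —
#' plus two small, shallow wells `e` and `f` placed far from the main
#' basins, emulating rare but kinetically distinct states.
#'
#' @return a 2-D periodic [landscape_spec()] with 20 bins per axis.
#' @export
make_alanine_like_landscape <- function() {
  landscape_spec(
    dimension = 2L,
    wells = tibble::tibble(
      well = c("a", "b", "c", "d", "e", "f"),
      x = c(0.300, 0.300, 0.720, 0.740, 0.025, 0.525),
      y = c(0.300, 0.625, 0.340, 0.720, 0.975, 0.025),
      depth = c(10.3, 8.8, 8.3, 6.5, 5.2, 4.35),
      width = c(0.095, 0.095, 0.085, 0.09, 0.05, 0.07)),
    periodic = TRUE, temperature = 1, grid_bins = 20L, step_size = 0.07)
}

#' Discretize continuous positions onto the microstate grid
#'
#' Uniform binning per axis over `[0, 1)`; 2-D indices are row-major
#' (`index = bin_x * grid_bins + bin_y`). On periodic domains positions are
#' wrapped; on bounded domains out-of-range positions are clamped to the
#' edge bins with a warning.
#'
#' @param spec a [landscape_spec()].
#' @param x,y coordinates (vectors; `y` for 2-D).
#' @return integer vector of 0-based microstate indices.
#' @export
discretize_grid <- function(spec, x, y = NULL) {
  b <- spec$grid_bins
  bin1 <- function(v) {
    if (spec$periodic) v <- v - floor(v)
    bins <- floor(v * b)
    if (any(bins < 0L | bins >= b)) {
      if (!spec$periodic)
        warning("positions outside the domain clamped to edge bins")
      bins <- pmin(pmax(bins, 0L), b - 1L)
    }
    as.integer(bins)
  }
  if (spec$dimension == 1L) bin1(x) else bin1(x) * b + bin1(y)
}

# potential evaluated at every bin center, as a vector over 0-based indices
bin_center_potential <- function(spec) {
  b <- spec$grid_bins
  centers <- (seq_len(b) - 0.5) / b
  if (spec$dimension == 1L) {
    landscape_potential(spec, centers)
  } else {
    i <- seq_len(b * b) - 1L   # row-major: index = bin_x * b + bin_y
    landscape_potential(spec, centers[i %/% b + 1L], centers[i %% b + 1L])
  }
}

#' Ground-truth well assignment of every microstate bin
#'
#' Each bin is mapped to a well by steepest descent on the bin-center
#' potential (8-neighborhood in 2-D, wrapping on periodic domains) until a
#' local minimum is reached, then labeled by the nearest well center. Bins
#' on the flat background whose descent terminates away from any well get
#' label `"bg"`.
#'
#' @param spec a [landscape_spec()].
#' @return a tibble with `state` (0-based bin index), `well`, and the bin
#'   center potential `U`.
#' @export
ground_truth_wells <- function(spec) {
  b <- spec$grid_bins
  n <- if (spec$dimension == 1L) b else b * b
  U <- bin_center_potential(spec)
  neighbors <- function(i) {
    if (spec$dimension == 1L) {
      nb <- c(i - 1L, i + 1L)
      if (spec$periodic) nb <- nb %% b else nb <- nb[nb >= 0L & nb < b]
      nb
    } else {
      r <- i %/% b
      c0 <- i %% b
      dr <- rep(-1:1, each = 3L)
      dc <- rep(-1:1, times = 3L)
      keep <- !(dr == 0L & dc == 0L)
      rr <- r + dr[keep]
      cc <- c0 + dc[keep]
      if (spec$periodic) {
        rr <- rr %% b
        cc <- cc %% b
      } else {
        ok <- rr >= 0L & rr < b & cc >= 0L & cc < b
        rr <- rr[ok]
        cc <- cc[ok]
      }
      rr * b + cc
    }
  }
  sink <- integer(n)
  for (i in seq_len(n) - 1L) {
    cur <- i
    repeat {
      nb <- neighbors(cur)
      best <- nb[which.min(U[nb + 1L])]
      if (U[best + 1L] >= U[cur + 1L] - 1e-12) break
      cur <- best
    }
    sink[i + 1L] <- cur
  }
  centers <- (seq_len(b) - 0.5) / b
  sink_x <- centers[(if (spec$dimension == 1L) sink else sink %/% b) + 1L]
  sink_y <- if (spec$dimension == 2L) centers[sink %% b + 1L] else NULL
  well_of_sink <- vapply(seq_len(n), function(i) {
    d2 <- axis_delta(sink_x[[i]], spec$wells$x, spec$periodic)^2
    if (spec$dimension == 2L)
      d2 <- d2 + axis_delta(sink_y[[i]], spec$wells$y, spec$periodic)^2
    k <- which.min(d2)
    # descent that stalls on the flat background is not inside any well
    if (sqrt(d2[[k]]) > 3 * spec$wells$width[[k]]) "bg"
    else spec$wells$well[[k]]
  }, character(1))
  tibble::tibble(state = seq_len(n) - 1L, well = well_of_sink, U = U)
}

#' Sample discrete trajectories with a Metropolis walker
#'
#' Independent walkers start uniformly in the domain, propose isotropic
#' Gaussian steps and accept with probability
#' `min(1, exp(-dU / temperature))`; on bounded domains proposals leaving
#' the domain are rejected, on periodic domains they wrap. Positions are
#' discretized onto the microstate grid. All walkers advance in lockstep,
#' so the sampler is vectorized over trajectories and fully reproducible
#' from the seed.
#'
#' @param spec a [landscape_spec()].
#' @param n_traj number of trajectories.
#' @param n_steps steps per trajectory (>= 2).
#' @param step_size standard deviation of the Gaussian proposal; `NULL`
#'   uses the landscape's own default.
#' @param seed integer seed.
#' @return an object of class `mpc_sim`: `dtrajs` (a [dtrajs()] whose
#'   `state_map` holds the original 0-based bin indices), `ground_truth`
#'   (from [ground_truth_wells()]), `spec`, `seed` and the overall
#'   `acceptance` rate.
#' @export
metropolis_trajectories <- function(spec, n_traj = 100L, n_steps = 2000L,
                                    step_size = NULL, seed = 1L) {
  stopifnot(n_steps >= 2L, n_traj >= 1L)
  if (is.null(step_size)) step_size <- spec$step_size
  dim <- spec$dimension
  temp <- spec$temperature
  withr::with_seed(as.integer(seed), {
    pos <- matrix(stats::runif(n_traj * dim), n_traj, dim)
    U <- landscape_potential(spec, pos[, 1L],
                             if (dim == 2L) pos[, 2L] else NULL)
    bins <- matrix(0L, n_steps, n_traj)
    bins[1L, ] <- discretize_grid(spec, pos[, 1L],
                                  if (dim == 2L) pos[, 2L] else NULL)
    accepted <- 0
    for (t in 2:n_steps) {
      prop <- pos + matrix(stats::rnorm(n_traj * dim, sd = step_size),
                           n_traj, dim)
      if (spec$periodic) {
        prop <- prop - floor(prop)
        inside <- rep(TRUE, n_traj)
      } else {
        inside <- rowSums(prop < 0 | prop >= 1) == 0L
      }
      U_prop <- U
      if (any(inside))
        U_prop[inside] <- landscape_potential(
          spec, prop[inside, 1L], if (dim == 2L) prop[inside, 2L] else NULL)
      acc <- inside &
        (stats::runif(n_traj) < exp(pmin(0, -(U_prop - U) / temp)))
      pos[acc, ] <- prop[acc, , drop = FALSE]
      U[acc] <- U_prop[acc]
      accepted <- accepted + sum(acc)
      bins[t, ] <- discretize_grid(spec, pos[, 1L],
                                   if (dim == 2L) pos[, 2L] else NULL)
    }
    rate <- accepted / (n_traj * (n_steps - 1L))
    if (rate < 0.01)
      warning(sprintf("Metropolis acceptance rate %.3f; step size too large?",
                      rate))
    trajs <- dtrajs(lapply(seq_len(n_traj), function(i) bins[, i]))
    structure(
      list(dtrajs = trajs, ground_truth = ground_truth_wells(spec),
           spec = spec, seed = as.integer(seed), acceptance = rate),
      class = "mpc_sim")
  })
}

#' @export
print.mpc_sim <- function(x, ...) {
  cat(sprintf("<mpc_sim> %d trajectories x %d steps on %d-D landscape (%d wells), acceptance %.2f\n",
              length(x$dtrajs$trajectories),
              length(x$dtrajs$trajectories[[1L]]),
              x$spec$dimension, nrow(x$spec$wells), x$acceptance))
  invisible(x)
}
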