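# Shared fixtures and independent oracles.

# random strictly positive count matrix -> irreducible chain
random_irreducible_counts <- function(n, density = 0.5) {
  C <- matrix(rpois(n * n, 2) * (runif(n * n) < density), n, n)
  # guarantee irreducibility with a ring of counts
  ring <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  C[ring] <- C[ring] + 1L
  C
}

random_transition_matrix <- function(n) {
  C <- random_irreducible_counts(n) + 0
  C / rowSums(C)
}

# power-iteration oracle for the stationary distribution
power_iteration_pi <- function(T, iters = 200000, tol = 1e-13) {
  pi <- rep(1 / nrow(T), nrow(T))
  for (i in seq_len(iters)) {
    nxt <- as.numeric(pi %*% T)
    if (max(abs(nxt - pi)) < tol) return(nxt / sum(nxt))
    pi <- nxt
  }
  pi / sum(pi)
}

# single-linkage dendrogram cut: the independent clustering oracle
single_linkage_cut <- function(members, D, epsilon) {
  if (length(members) == 1L) return(stats::setNames(1L, members))
  sub <- D[members, members, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  # cutree(h) merges all joins at height <= h
  stats::setNames(stats::cutree(hc, h = epsilon), members)
}

# same partition? compare as set-of-sets
same_partition <- function(a, b) {
  split_a <- split(seq_along(a), a)
  split_b <- split(seq_along(b), b)
  setequal(lapply(split_a, sort), lapply(split_b, sort))
}

# random symmetric distance matrix with zero diagonal
random_distance_matrix <- function(n, max_d = 10) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, max_d)
  D + t(D)
}

# build a small model from random trajectories over n states
random_small_model <- function(n, len = 400) {
  # a random walk biased to revisit low states gives uneven populations
  probs <- sort(runif(n), decreasing = TRUE)
  traj <- integer(len)
  traj[1L] <- sample.int(n, 1L) - 1L
  for (t in 2:len) {
    if (runif(1) < 0.5) {
      traj[t] <- traj[t - 1L]
    } else {
      traj[t] <- sample.int(n, 1L, prob = probs) - 1L
    }
  }
  # ensure every state occurs so the model keeps n states
  traj[seq_len(n)] <- seq_len(n) - 1L
  fit_msm(dtrajs(list(traj)))
}

# lazily computed, memoized pipeline runs shared across test files
.fixture_cache <- new.env(parent = emptyenv())

fig1_run <- function(seed = 1L) {
  key <- paste0("fig1_", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- metropolis_trajectories(make_figure1_landscape(),
                                   n_traj = 100, n_steps = 2000, seed = seed)
    res <- suppressWarnings(run_mpc(sim$dtrajs, include_rare = FALSE))
    .fixture_cache[[key]] <- list(sim = sim, res = res)
  }
  .fixture_cache[[key]]
}

alanine_run <- function(seed = 1L) {
  key <- paste0("ala_", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- metropolis_trajectories(make_alanine_like_landscape(),
                                   n_traj = 200, n_steps = 5000, seed = seed)
    t0 <- proc.time()[["elapsed"]]
    res <- suppressWarnings(run_mpc(sim$dtrajs, m = 25, q = 25))
    elapsed <- proc.time()[["elapsed"]] - t0
    .fixture_cache[[key]] <- list(sim = sim, res = res, elapsed = elapsed)
  }
  .fixture_cache[[key]]
}

# map a candidate/summary row's label to its ground-truth well
wells_of <- function(labels, ground_truth) {
  ground_truth$well[match(labels, ground_truth$state)]
}
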