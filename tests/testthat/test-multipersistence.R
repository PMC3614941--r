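# hand-built 5-state system used across grid tests: two tight pairs plus a
# far singleton; E increasing with index
toy_system <- function() {
  E <- c(0.5, 1.0, 2.0, 2.5, 4.0)
  D <- matrix(20, 5, 5)
  D[1, 2] <- D[2, 1] <- 1      # deep pair
  D[3, 4] <- D[4, 3] <- 1.5    # second pair
  D[1, 3] <- D[3, 1] <- 6      # pair-pair bridge
  diag(D) <- 0
  model <- list(E = E, populations = c(50L, 30L, 12L, 6L, 2L),
                state_map = 0:4)
  dist <- list(D = D, d_min = 1, D_star = 20)
  list(model = model, dist = dist)
}

test_that("build_grid respects bounds and spacing strategies", {
  sys <- toy_system()
  g <- build_grid(sys$model, sys$dist, m = 3, q = 4,
                  theta_spacing = "quantile", eps_spacing = "log")
  expect_equal(g$thetas, c(0.5, 2.0, 4.0))  # quantiles of E at 0/.5/1
  expect_true(all(diff(g$thetas) > 0))
  expect_equal(g$epsilons[[1L]], 1)
  expect_equal(g$epsilons[[length(g$epsilons)]], 20)

  glin <- build_grid(sys$model, sys$dist, m = 5, q = 5,
                     theta_spacing = "linear", eps_spacing = "linear")
  expect_equal(glin$thetas, seq(0.5, 4.0, length.out = 5))
  expect_equal(glin$epsilons, seq(1, 20, length.out = 5))

  # duplicated quantiles may be dropped with a warning here
  gq <- suppressWarnings(build_grid(sys$model, sys$dist, m = 4, q = 4,
                                    eps_spacing = "quantile"))
  expect_true(all(gq$epsilons >= sys$dist$d_min - 1e-12))
  expect_true(all(gq$epsilons <= sys$dist$D_star + 1e-12))

  degen <- list(E = c(1, 1, 1), populations = c(1L, 1L, 1L), state_map = 0:2)
  w <- capture_warnings(build_grid(degen, sys$dist, m = 3, q = 3))
  expect_true(any(grepl("degenerate", w)))
})

test_that("super level sets select E <= theta and nest", {
  E <- c(1, 2, 3)
  expect_equal(superlevel_set(E, 2), c(1L, 2L))
  expect_warning(expect_equal(superlevel_set(E, 0.5), integer(0)), "empty")
  expect_equal(superlevel_set(E, 3), 1:3)
  thetas <- sort(runif(6, 0, 4))
  prev <- integer(0)
  for (th in thetas) {
    cur <- suppressWarnings(superlevel_set(E, th))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("neighborhood clusters equal connected components and the single-linkage cut", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 1
  D[2, 3] <- D[3, 2] <- 5
  D[1, 3] <- D[3, 1] <- 6
  E <- c(1, 2, 3)
  expect_equal(neighborhood_clusters(1:3, D, 2, E), c(1L, 1L, 3L))
  # chaining at eps = 5 links all three through the middle point
  expect_equal(neighborhood_clusters(1:3, D, 5, E), c(1L, 1L, 1L))

  withr::with_seed(99, {
    for (i in 1:40) {
      n <- sample(3:15, 1)
      Dm <- random_distance_matrix(n)
      Em <- runif(n)
      members <- sort(sample.int(n, sample(2:n, 1)))
      eps <- runif(1, 0, 10)
      ours <- neighborhood_clusters(members, Dm, eps, Em)
      oracle <- single_linkage_cut(members, Dm, eps)
      expect_true(same_partition(ours, oracle))
      # labels are the minimum-E member of each component
      for (s in unique(ours)) {
        comp <- members[ours == s]
        expect_equal(s, comp[which.min(Em[comp])])
      }
    }
  })
})

test_that("label ties break to the lowest index", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  E <- c(2, 2)
  expect_equal(neighborhood_clusters(1:2, D, 2, E), c(1L, 1L))
  expect_equal(neighborhood_clusters(1:2, D, 0.5, E), c(1L, 2L))
})

test_that("compute_grid coarsens with scale and matches per-cell clustering", {
  sys <- toy_system()
  params <- build_grid(sys$model, sys$dist, m = 5, q = 6,
                       theta_spacing = "linear", eps_spacing = "linear")
  grid <- compute_grid(sys$model, sys$dist, params)
  m <- length(params$thetas)
  q <- length(params$epsilons)
  for (j in seq_len(m)) {
    r <- grid$rows[[j]]
    expect_equal(r$members, superlevel_set(sys$model$E, params$thetas[[j]]))
    for (l in seq_len(q)) {
      direct <- neighborhood_clusters(r$members, sys$dist$D,
                                      params$epsilons[[l]], sys$model$E)
      expect_equal(r$labels[l, ], direct)
      if (l > 1L) {
        # partitions coarsen: component count non-increasing in l
        expect_lte(length(unique(r$labels[l, ])),
                   length(unique(r$labels[l - 1L, ])))
      }
    }
    # at eps >= D_star the connected level set is one component
    expect_equal(length(unique(r$labels[q, ])), 1L)
  }
})

test_that("persistence regions track labels, sizes and merge events", {
  sys <- toy_system()
  params <- build_grid(sys$model, sys$dist, m = 5, q = 6,
                       theta_spacing = "linear", eps_spacing = "linear")
  grid <- compute_grid(sys$model, sys$dist, params)
  regions <- persistence_regions(grid)
  m <- 5L; q <- 6L
  # global-minimum-E label covers its whole sub-grid
  r1 <- regions[["1"]]
  expect_equal(r1$birth_level, 1L)
  expect_equal(nrow(r1$cells), m * q)
  # state 2 never labels: closer pair-mate 1 has lower E at every scale
  # where they are joined; it labels only while still a singleton
  expect_true(all(vapply(regions, function(r)
    all(r$cells$j >= r$birth_level), logical(1))))
  # sizes at any cell sum to the level set's population
  tidy_cells <- tidy(regions)
  sums <- tapply(tidy_cells$size, paste(tidy_cells$j, tidy_cells$l), sum)
  for (j in seq_len(m)) {
    members <- grid$rows[[j]]$members
    expect_true(all(sums[paste(j, seq_len(q))] ==
                      sum(sys$model$populations[members])))
  }
  # merge bookkeeping is symmetric: each merged_by has a matching absorbs
  for (r in regions) {
    mb <- r$merges[r$merges$event == "merged_by", ]
    for (k in seq_len(nrow(mb))) {
      other <- regions[[as.character(mb$other[[k]])]]
      ab <- other$merges
      expect_true(any(ab$event == "absorbs" & ab$j == mb$j[[k]] &
                        ab$l == mb$l[[k]] & ab$other == r$label_idx))
    }
  }
})

test_that("max_persistences counts runs in grid indices", {
  rect <- structure(list(
    label_idx = 1L, label = 0L, birth_level = 3L,
    cells = tibble::tibble(j = rep(3:5, each = 8), l = rep(2:9, times = 3),
                           size = 1, n_members = 1),
    merges = NULL), class = "mpc_region")
  expect_equal(unname(max_persistences(rect)[1:2]), c(8, 3))

  single <- structure(list(
    label_idx = 1L, label = 0L, birth_level = 2L,
    cells = tibble::tibble(j = 2L, l = 4L, size = 7, n_members = 1),
    merges = NULL), class = "mpc_region")
  expect_equal(unname(max_persistences(single)), c(1, 1, 7))

  # broken run: cells at l = 1,2,5 -> longest scale run 2
  gap <- structure(list(
    label_idx = 1L, label = 0L, birth_level = 1L,
    cells = tibble::tibble(j = 1L, l = c(1L, 2L, 5L), size = 1,
                           n_members = 1),
    merges = NULL), class = "mpc_region")
  expect_equal(unname(max_persistences(gap)[["scale_persistence"]]), 2)
})

test_that("structural theorems hold on random models and grids", {
  withr::with_seed(2024, {
    for (i in 1:25) {
      model <- random_small_model(sample(5:15, 1))
      dist <- commute_distances(model)
      params <- build_grid(model, dist, m = sample(3:6, 1),
                           q = sample(3:6, 1))
      grid <- compute_grid(model, dist, params)
      # persistence_regions hard-errors on any non-4-connected region
      regions <- persistence_regions(grid)
      summ <- summarize_persistence(regions)
      # exactly one region covers all columns at every row above its birth
      full <- summ[summ$n_cells ==
                     (length(params$thetas) - summ$birth_level + 1L) *
                     length(params$epsilons), ]
      expect_gte(nrow(full), 1L)
      argmin <- which.min(model$E)
      expect_true(argmin %in% full$label_idx)
    }
  })
})
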