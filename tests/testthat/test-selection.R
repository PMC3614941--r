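# same hand-built system as the grid tests
toy_setup <- function(m = 5, q = 6) {
  E <- c(0.5, 1.0, 2.0, 2.5, 4.0)
  D <- matrix(20, 5, 5)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1.5
  D[1, 3] <- D[3, 1] <- 6
  diag(D) <- 0
  model <- list(E = E, populations = c(50L, 30L, 12L, 6L, 2L), state_map = 0:4)
  dist <- list(D = D, d_min = 1, D_star = 20)
  params <- build_grid(model, dist, m = m, q = q,
                       theta_spacing = "linear", eps_spacing = "linear")
  grid <- compute_grid(model, dist, params)
  regions <- persistence_regions(grid)
  list(model = model, dist = dist, grid = grid, regions = regions,
       summary = summarize_persistence(regions))
}

test_that("summarize_persistence has one row per region with the right shape", {
  s <- toy_setup()
  expect_equal(nrow(s$summary), length(s$regions))
  full <- s$summary[s$summary$label_idx == 1L, ]
  expect_equal(full$birth_level, 1L)
  expect_equal(full$scale_persistence, 6L)
  expect_equal(full$density_persistence, 5L)
  expect_equal(full$max_size, sum(s$model$populations))
})

test_that("selection applies the three principles plus the rare-state guards", {
  s <- toy_setup()
  cand <- select_candidates(s$summary, min_scale = 2, min_density = 2,
                            min_size = 10, min_rare_size = 3,
                            min_rare_scale = 2)
  # whole-grid cluster always selected
  expect_true(cand$selected[cand$label_idx == 1L])
  # a label with scale persistence 1 is never selected at min_scale >= 2
  expect_false(any(cand$selected[cand$scale_persistence < 2]))
  # rare-state candidates pass scale + density but fail size, above the floor
  expect_true(all(cand$max_size[cand$rare_state] < 10))
  expect_true(all(cand$max_size[cand$rare_state] >= 3))
  expect_false(any(cand$selected & cand$rare_state))
  # nothing passing -> global minimum kept with a warning
  expect_warning(
    fallback <- select_candidates(s$summary, min_scale = 100),
    "global minimum")
  expect_equal(fallback$label_idx[fallback$selected], 1L)
})

test_that("choose_versions picks maximal non-conflicting versions, shallow first", {
  s <- toy_setup()
  v <- choose_versions(c(1L, 3L), s$grid, s$regions)
  expect_s3_class(v, "mpc_versions")
  expect_equal(v$label_idx, c(1L, 3L))  # returned sorted by ascending E
  # shallow candidate 3 claims its largest clean version {3,4}
  expect_setequal(v$members[[which(v$label_idx == 3L)]], c(3L, 4L))
  # deep candidate 1 then takes {1,2}, excluding 3's claim
  expect_setequal(v$members[[which(v$label_idx == 1L)]], c(1L, 2L))
  expect_length(intersect(v$members[[1L]], v$members[[2L]]), 0L)
})

test_that("version choice is disjoint on random systems", {
  withr::with_seed(5, {
    for (i in 1:15) {
      model <- random_small_model(sample(6:14, 1))
      dist <- commute_distances(model)
      params <- build_grid(model, dist, m = 4, q = 4)
      grid <- compute_grid(model, dist, params)
      regions <- persistence_regions(grid)
      ints <- as.integer(names(regions))
      labs <- unique(c(which.min(model$E),
                       ints[sample.int(length(ints),
                                       min(3L, length(ints)))]))
      v <- suppressWarnings(choose_versions(labs, grid, regions))
      all_members <- unlist(v$members)
      expect_equal(anyDuplicated(all_members), 0L)
    }
  })
})

test_that("full partition assigns every microstate, ties to the lower-E label", {
  s <- toy_setup()
  v <- choose_versions(c(1L, 3L), s$grid, s$regions)
  p <- full_partition(v, s$dist, s$grid, mode = "full")
  expect_equal(nrow(p), 5L)
  expect_false(anyNA(p$cluster))
  # members of a version keep their version's label
  expect_equal(p$cluster[p$state %in% c(1, 2)], c(0L, 0L))
  expect_equal(p$cluster[p$state %in% c(3, 4)], c(2L, 2L))
  # state 5 is equidistant (20) from both versions -> lower-E label wins
  expect_equal(p$cluster[p$state == 5L], 0L)
  # core mode leaves it unassigned
  pc <- full_partition(v, s$dist, s$grid, mode = "core")
  expect_true(is.na(pc$cluster[pc$state == 5L]))
  expect_equal(sum(pc$core), 4L)
})

test_that("hierarchy joins clusters at the level where a bridge state appears", {
  # two basins joined only through a high-energy bridge state
  E <- c(1.0, 2.5, 5.0)
  D <- matrix(c(0, 20, 5,
                20, 0, 5,
                5, 5, 0), 3, 3)
  model <- list(E = E, populations = c(10L, 5L, 1L), state_map = 0:2)
  dist <- list(D = D, d_min = 5, D_star = 20)
  params <- structure(list(thetas = c(1, 2, 2.5, 4, 5),
                           epsilons = c(1, 10),
                           theta_spacing = "linear", eps_spacing = "linear"),
                      class = "mpc_param_grid")
  grid <- compute_grid(model, dist, params)
  regions <- persistence_regions(grid)
  v <- choose_versions(c(1L, 2L), grid, regions)
  h <- cluster_hierarchy(v, grid, regions)
  # births 1 and 3; bridge appears at level 5 -> branch lengths 4 and 2
  expect_equal(h$reference_l, 2L)
  expect_equal(h$merges$level, 5L)
  expect_equal(sort(h$phylo$tip.label), c("cluster_0", "cluster_1"))
  bl <- setNames(h$phylo$edge.length,
                 h$phylo$tip.label[h$phylo$edge[, 2L]])
  expect_equal(unname(bl[["cluster_0"]]), 4)
  expect_equal(unname(bl[["cluster_1"]]), 2)
})

test_that("candidates that never merge join at a virtual root with a warning", {
  E <- c(1.0, 2.0)
  D <- matrix(c(0, 50, 50, 0), 2, 2)
  model <- list(E = E, populations = c(5L, 5L), state_map = 0:1)
  dist <- list(D = D, d_min = 50, D_star = 50)
  params <- structure(list(thetas = c(1, 2), epsilons = c(1, 2),
                           theta_spacing = "linear", eps_spacing = "linear"),
                      class = "mpc_param_grid")
  grid <- compute_grid(model, dist, params)
  regions <- persistence_regions(grid)
  v <- choose_versions(c(1L, 2L), grid, regions)
  expect_warning(h <- cluster_hierarchy(v, grid, regions), "virtual root")
  expect_equal(h$merges$level, 3L)   # one level above the top row
})
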