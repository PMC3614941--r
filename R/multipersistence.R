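#' Build the density x scale parameter grid
#'
#' The density axis is a strictly increasing sequence of `m` free-energy
#' thresholds `theta` (a larger index admits more microstates: super level
#' sets in density are sub level sets in free energy). The scale axis is a
#' strictly increasing sequence of `q` commute-time radii `epsilon` kept
#' inside `[d_min, D_star]`: below `d_min` every cluster is a singleton and
#' at `D_star` the whole state set is one component, so nothing is learned
#' outside those bounds.
#'
#' Spacing is controlled per axis. `theta_spacing = "linear"` (default)
#' makes the density axis evenly spaced in free energy, so birth levels
#' read directly as basin depth; `"quantile"` spaces thresholds on the
#' empirical quantiles of `E`. For the scale axis, commute times grow
#' exponentially with barrier heights and span orders of magnitude, so
#' `eps_spacing = "log"` (default) spaces the radii geometrically between
#' `d_min` and `D_star`; `"quantile"` (ranks of the off-diagonal distances
#' restricted to the bounds) and `"linear"` are also available, but rank
#' quantiles are easily dominated by the enormous commute times of rarely
#' visited microstates, which compresses the scale resolution available to
#' the well-sampled basins.
#'
#' @param model an `msm_fit`.
#' @param dist a `commute_dist` for the same model.
#' @param m,q number of density and scale values (each >= 2).
#' @param theta_spacing `"linear"` (default) or `"quantile"`.
#' @param eps_spacing `"log"` (default), `"quantile"` or `"linear"`.
#' @return an object of class `mpc_param_grid` with strictly increasing
#'   `thetas` and `epsilons` (duplicated quantiles are dropped with a
#'   warning, so the realized grid can be smaller than requested).
#' @export
build_grid <- function(model, dist, m = 25L, q = 25L,
                       theta_spacing = c("linear", "quantile"),
                       eps_spacing = c("log", "quantile", "linear")) {
  theta_spacing <- match.arg(theta_spacing)
  eps_spacing <- match.arg(eps_spacing)
  stopifnot(m >= 2L, q >= 2L)
  E <- model$E
  D <- dist$D
  if (diff(range(E)) < .Machine$double.eps^0.5) {
    warning("degenerate free energies (all equal); single density level")
    thetas <- max(E)
  } else if (theta_spacing == "quantile") {
    thetas <- unname(stats::quantile(E, probs = seq(0, 1, length.out = m)))
  } else {
    thetas <- seq(min(E), max(E), length.out = m)
  }
  epsilons <- switch(
    eps_spacing,
    log = exp(seq(log(dist$d_min), log(dist$D_star), length.out = q)),
    linear = seq(dist$d_min, dist$D_star, length.out = q),
    quantile = {
      off <- D[upper.tri(D)]
      off <- off[off >= dist$d_min & off <= dist$D_star]
      unname(stats::quantile(off, probs = seq(0, 1, length.out = q)))
    })
  dedup <- function(x, axis, want) {
    x <- unique(x)
    if (length(x) < want)
      warning(sprintf("dropped %d duplicated %s values; grid has %d",
                      want - length(x), axis, length(x)))
    x
  }
  thetas <- dedup(thetas, "theta", m)
  epsilons <- dedup(epsilons, "epsilon", q)
  structure(list(thetas = thetas, epsilons = epsilons,
                 theta_spacing = theta_spacing, eps_spacing = eps_spacing),
            class = "mpc_param_grid")
}

#' @export
print.mpc_param_grid <- function(x, ...) {
  cat(sprintf("<mpc_param_grid> %d density levels (%s) x %d scales (%s)\n",
              length(x$thetas), x$theta_spacing,
              length(x$epsilons), x$eps_spacing))
  invisible(x)
}

#' Super level set at a free-energy threshold
#'
#' Members are the microstates whose free energy does not exceed `theta`
#' (equivalently whose stationary density exceeds the matching density
#' threshold). Level sets nest as `theta` grows.
#'
#' @param E free-energy vector.
#' @param theta threshold.
#' @return integer vector of member indices (1-based into `E`), possibly
#'   empty (with a warning).
#' @export
superlevel_set <- function(E, theta) {
  members <- which(E <= theta)
  if (length(members) == 0L) warning("empty super level set")
  members
}

# Minimal union-find with path halving; used by the neighborhood clustering
# and by the incremental per-row grid sweep.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[[i]] != i) {
    parent[[i]] <- parent[[parent[[i]]]]
    i <- parent[[i]]
  }
  i
}

#' Connected components of the epsilon-neighborhood graph
#'
#' Builds the graph on `members` with an edge wherever the pairwise distance
#' is at most `epsilon` and returns its connected components. The result
#' coincides with cutting a single-linkage dendrogram at height `epsilon`.
#' Each component is labeled by its member with minimum free energy (ties
#' broken by the lowest index).
#'
#' @param members integer vector of member indices (1-based into `E`/`D`).
#' @param D full symmetric distance matrix.
#' @param epsilon scale parameter.
#' @param E free-energy vector (full length); used only for labeling.
#' @return integer vector parallel to `members`: the label (a member index)
#'   of each member's component.
#' @export
neighborhood_clusters <- function(members, D, epsilon, E) {
  nm <- length(members)
  stopifnot(nm >= 1L)
  parent <- uf_new(nm)
  if (nm > 1L) {
    sub <- D[members, members, drop = FALSE] <= epsilon
    edges <- which(sub & upper.tri(sub), arr.ind = TRUE)
    for (k in seq_len(nrow(edges))) {
      ra <- uf_find(parent, edges[[k, 1L]])
      rb <- uf_find(parent, edges[[k, 2L]])
      if (ra != rb) parent[[rb]] <- ra
    }
  }
  roots <- vapply(seq_len(nm), function(i) uf_find(parent, i), integer(1))
  label_components(roots, members, E)
}

# Given component roots (parallel to members), return per-member labels:
# the member index with minimum E in each component, ties to lowest index.
label_components <- function(roots, members, E) {
  labels <- integer(length(members))
  for (r in unique(roots)) {
    in_comp <- roots == r
    comp_members <- members[in_comp]
    # order() breaks E-ties by member index
    lab <- comp_members[order(E[comp_members], comp_members)][1L]
    labels[in_comp] <- lab
  }
  labels
}

#' Cluster every cell of the parameter grid
#'
#' For each density level `j` the super level set is clustered at every
#' scale `epsilon_l`. Within a row the scan is incremental: edges of the
#' level set are sorted by length once and merged into a union-find
#' structure as `epsilon` grows, so the partition at `epsilon_{l+1}` is a
#' coarsening of the one at `epsilon_l` by construction.
#'
#' @param model an `msm_fit`.
#' @param dist a `commute_dist`.
#' @param grid an `mpc_param_grid` from [build_grid()].
#' @return an object of class `mpc_grid`: `params`, the model's `E`,
#'   `populations` and `state_map`, and `rows`, one entry per density level
#'   holding `members` and a `q x |members|` label matrix (entry = member
#'   index labeling that member's component at that scale).
#' @export
compute_grid <- function(model, dist, grid) {
  stopifnot(inherits(grid, "mpc_param_grid"))
  E <- model$E
  D <- dist$D
  m <- length(grid$thetas)
  q <- length(grid$epsilons)
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    members <- which(E <= grid$thetas[[j]])
    nm <- length(members)
    labels <- matrix(NA_integer_, q, nm)
    if (nm > 0L) {
      parent <- uf_new(nm)
      if (nm > 1L) {
        sub <- D[members, members, drop = FALSE]
        pairs <- which(upper.tri(sub), arr.ind = TRUE)
        w <- sub[pairs]
        ord <- order(w)
        pairs <- pairs[ord, , drop = FALSE]
        w <- w[ord]
        k <- 1L
        n_edges <- length(w)
        for (l in seq_len(q)) {
          eps <- grid$epsilons[[l]]
          while (k <= n_edges && w[[k]] <= eps) {
            ra <- uf_find(parent, pairs[[k, 1L]])
            rb <- uf_find(parent, pairs[[k, 2L]])
            if (ra != rb) parent[[rb]] <- ra
            k <- k + 1L
          }
          roots <- vapply(seq_len(nm), function(i) uf_find(parent, i),
                          integer(1))
          labels[l, ] <- label_components(roots, members, E)
        }
      } else {
        labels[, 1L] <- members
      }
    }
    rows[[j]] <- list(members = members, labels = labels)
  }
  structure(
    list(params = grid, rows = rows, E = E,
         populations = model$populations,
         state_map = model$state_map %||% (seq_along(E) - 1L)),
    class = "mpc_grid"
  )
}

#' @export
print.mpc_grid <- function(x, ...) {
  cat(sprintf("<mpc_grid> %d x %d cells over %d microstates\n",
              length(x$params$thetas), length(x$params$epsilons),
              length(x$E)))
  invisible(x)
}

#' Persistence regions of every cluster label
#'
#' A cluster is tracked across the grid by its minimum-free-energy
#' microstate. Its persistence region is the set of `(density level j,
#' scale index l)` cells at which the component containing that microstate
#' is still labeled by it, i.e. has not been merged by a cluster holding a
#' lower-energy microstate. Each region is provably 4-connected; a
#' disconnected region is reported as a hard error because it can only
#' arise from an implementation defect.
#'
#' Merge events are recorded explicitly: when a label's component absorbs
#' other labels as `epsilon` or the level set grows (`event = "absorbs"`),
#' and when the label itself is merged away (`event = "merged_by"`).
#'
#' @param grid an `mpc_grid` from [compute_grid()].
#' @return an object of class `mpc_regions`: a named list of regions (one
#'   per microstate that ever labels a component), each with `label_idx`
#'   (1-based member index), `label` (original microstate label),
#'   `birth_level`, `cells` (tibble `j`, `l`, `size` in conformation
#'   counts, `n_members`) and `merges` (tibble `j`, `l`, `direction`,
#'   `event`, `other`).
#' @export
persistence_regions <- function(grid) {
  stopifnot(inherits(grid, "mpc_grid"))
  m <- length(grid$params$thetas)
  q <- length(grid$params$epsilons)
  pops <- grid$populations
  cell_blocks <- vector("list", m * q)
  merge_blocks <- vector("list", 2L * m * q)
  for (j in seq_len(m)) {
    r <- grid$rows[[j]]
    nm <- length(r$members)
    if (nm == 0L) next
    member_pops <- pops[r$members]
    members_next <- if (j < m) grid$rows[[j + 1L]]$members else NULL
    for (l in seq_len(q)) {
      labs <- r$labels[l, ]
      f <- factor(labs)
      ulabs <- as.integer(levels(f))
      cell_blocks[[(j - 1L) * q + l]] <- list(
        label_idx = ulabs, j = j, l = l,
        size = as.integer(rowsum(member_pops, f)[, 1L]),
        n_members = as.integer(rowsum(rep(1L, nm), f)[, 1L])
      )
      # scale-direction merges: label of each current label's state at l+1
      if (l < q) {
        pos <- match(ulabs, r$members)
        nxt <- r$labels[l + 1L, ][pos]
        gone <- nxt != ulabs
        if (any(gone))
          merge_blocks[[(j - 1L) * q + l]] <- list(
            j = j, l = l, direction = "scale",
            label_idx = ulabs[gone], other = nxt[gone])
      }
      # density-direction merges: label of each current label's state at j+1
      if (j < m) {
        pos <- match(ulabs, members_next)
        nxt <- grid$rows[[j + 1L]]$labels[l, ][pos]
        gone <- !is.na(nxt) & nxt != ulabs
        if (any(gone))
          merge_blocks[[m * q + (j - 1L) * q + l]] <- list(
            j = j, l = l, direction = "density",
            label_idx = ulabs[gone], other = nxt[gone])
      }
    }
  }
  cells_all <- dplyr::bind_rows(purrr::map(
    purrr::compact(cell_blocks), tibble::as_tibble))
  merges_all <- dplyr::bind_rows(purrr::map(
    purrr::compact(merge_blocks), tibble::as_tibble))
  if (nrow(merges_all) == 0L)
    merges_all <- tibble::tibble(j = integer(), l = integer(),
                                 direction = character(),
                                 label_idx = integer(), other = integer())
  # "x merged_by y" and "y absorbs x" are the two views of one event
  merged_by <- merges_all
  merged_by$event <- "merged_by"
  absorbs <- merges_all
  absorbs$event <- "absorbs"
  absorbs[c("label_idx", "other")] <- absorbs[c("other", "label_idx")]
  events <- dplyr::bind_rows(merged_by, absorbs)
  all_labels <- sort(unique(cells_all$label_idx))
  # birth level: first density row where the state enters the level set
  birth <- vapply(all_labels, function(s)
    min(which(vapply(grid$rows, function(r) s %in% r$members, logical(1)))),
    integer(1))
  cells_split <- split(cells_all[c("j", "l", "size", "n_members")],
                       cells_all$label_idx)
  events_split <- split(events[c("j", "l", "direction", "event", "other")],
                        events$label_idx)
  empty_merges <- tibble::tibble(j = integer(), l = integer(),
                                 direction = character(), event = character(),
                                 other = integer())
  regions <- purrr::map(seq_along(all_labels), function(i) {
    s <- all_labels[[i]]
    key <- as.character(s)
    mg <- events_split[[key]] %||% empty_merges
    structure(
      list(label_idx = s, label = grid$state_map[[s]],
           birth_level = birth[[i]],
           cells = tibble::as_tibble(cells_split[[key]]),
           merges = tibble::as_tibble(mg)[order(mg$j, mg$l), ]),
      class = "mpc_region")
  })
  names(regions) <- as.character(all_labels)
  for (reg in regions) {
    if (!region_is_connected(reg$cells, m, q))
      stop(sprintf("persistence region of state %d is not 4-connected: implementation bug",
                   reg$label))
  }
  structure(regions, class = "mpc_regions",
            grid_dim = c(m = m, q = q),
            state_map = grid$state_map,
            E = grid$E,
            total_frames = sum(grid$populations))
}

# 4-connectivity check on a set of (j, l) cells: flood fill on the
# occupancy matrix.
region_is_connected <- function(cells, m, q) {
  n <- nrow(cells)
  if (n <= 1L) return(TRUE)
  occ <- matrix(FALSE, m, q)
  occ[cbind(cells$j, cells$l)] <- TRUE
  seen <- matrix(FALSE, m, q)
  queue <- list(c(cells$j[[1L]], cells$l[[1L]]))
  seen[[cells$j[[1L]], cells$l[[1L]]]] <- TRUE
  count <- 1L
  while (length(queue)) {
    cur <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      a <- cur[[1L]] + d[[1L]]
      b <- cur[[2L]] + d[[2L]]
      if (a >= 1L && a <= m && b >= 1L && b <= q &&
          occ[[a, b]] && !seen[[a, b]]) {
        seen[[a, b]] <- TRUE
        count <- count + 1L
        queue[[length(queue) + 1L]] <- c(a, b)
      }
    }
  }
  count == n
}

longest_run <- function(x) {
  # length of the longest run of consecutive integers in sorted unique x
  x <- sort(unique(x))
  if (length(x) == 0L) return(0L)
  max(tabulate(cumsum(c(1L, diff(x) != 1L))))
}

#' Maximum persistence lengths of one region
#'
#' Scale persistence is the longest consecutive run of scale indices within
#' a single density row of the region; density persistence the longest run
#' of density levels within a single scale column. Both are measured in grid
#' indices. `max_size` is the largest conformation count the cluster attains
#' anywhere in its region.
#'
#' @param region an `mpc_region`.
#' @return named numeric vector `c(scale_persistence, density_persistence,
#'   max_size)`.
#' @export
max_persistences <- function(region) {
  stopifnot(inherits(region, "mpc_region"))
  cells <- region$cells
  scale_p <- max(vapply(split(cells$l, cells$j), longest_run, integer(1)))
  density_p <- max(vapply(split(cells$j, cells$l), longest_run, integer(1)))
  c(scale_persistence = scale_p, density_persistence = density_p,
    max_size = max(cells$size))
}

#' @export
print.mpc_regions <- function(x, ...) {
  dim <- attr(x, "grid_dim")
  cat(sprintf("<mpc_regions> %d persistence regions on a %d x %d grid\n",
              length(x), dim[["m"]], dim[["q"]]))
  invisible(x)
}

#' Tidy persistence regions into a cell table
#'
#' @param x an `mpc_regions` collection.
#' @param ... unused.
#' @return a tibble with one row per (label, cell): `label`, `j`, `l`,
#'   `size`, `n_members`, `birth_level`.
#' @method tidy mpc_regions
#' @export
tidy.mpc_regions <- function(x, ...) {
  dplyr::bind_rows(purrr::map(unclass(x), function(reg)
    dplyr::mutate(reg$cells, label = reg$label,
                  birth_level = reg$birth_level)))
}
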