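#' Summarize persistence diagrams
#'
#' Collapses every persistence region to one row: its maximum persistence
#' in the scale and density dimensions (in grid indices), the largest
#' conformation count it attains, and the density level at which the label
#' first enters the analysis. This is the overview plot's data: clusters in
#' the upper right of (scale, density) persistence are the reliable ones.
#'
#' @param regions an `mpc_regions` collection from [persistence_regions()].
#' @return a tibble of class `mpc_summary` with columns `label_idx`,
#'   `label`, `free_energy`, `birth_level`, `scale_persistence`,
#'   `density_persistence`, `max_size` and `n_cells`; grid dimensions and
#'   total frame count are kept as attributes.
#' @export
summarize_persistence <- function(regions) {
  stopifnot(inherits(regions, "mpc_regions"))
  E <- attr(regions, "E")
  rows <- purrr::map(unclass(regions), function(reg) {
    p <- max_persistences(reg)
    tibble::tibble(
      label_idx = reg$label_idx,
      label = reg$label,
      free_energy = E[[reg$label_idx]],
      birth_level = reg$birth_level,
      scale_persistence = as.integer(p[["scale_persistence"]]),
      density_persistence = as.integer(p[["density_persistence"]]),
      max_size = p[["max_size"]],
      n_cells = nrow(reg$cells)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        dplyr::desc(.data$scale_persistence *
                                      .data$density_persistence))
  attr(out, "grid_dim") <- attr(regions, "grid_dim")
  attr(out, "total_frames") <- attr(regions, "total_frames")
  class(out) <- c("mpc_summary", class(out))
  out
}

#' Select candidate metastable clusters
#'
#' Applies three selection principles to a persistence summary:
#' clusters must (i) persist in the scale dimension (kinetically detached
#' from the rest of the landscape), (ii) persist in the density dimension
#' *after they appear* (a late-born cluster cannot be penalized for levels
#' that predate it, so the density threshold is capped at the room left
#' above its birth level), and (iii) carry a significant number of
#' conformations. Clusters passing (i) and (ii) but failing the size rule
#' (iii) are flagged as *rare-state candidates* rather than dropped: they
#' are either genuinely rare, kinetically distinct states or under-sampled
#' regions, and the decision is the user's.
#'
#' A sparsely visited microstate has few observed transitions, hence huge
#' commute times to everything and misleadingly long scale persistence.
#' Two extra guards therefore separate rare-state candidates from such
#' sampling artifacts: a much lower size floor (`min_rare_size`), below
#' which a label is flagged neither selected nor rare (it stays visible in
#' the summary), and a stricter scale requirement (`min_rare_scale`) -- a
#' small cluster is only trusted as kinetically distinct when its scale
#' persistence is well beyond what the inflated commute times of an
#' under-sampled microstate produce. On a geometric scale grid spanning
#' `[d_min, D_star]` a state near the size floor dies by about the middle
#' of the scale range, so the default asks for survival past 60% of it.
#'
#' @param summary an `mpc_summary` from [summarize_persistence()].
#' @param min_scale minimum scale persistence (grid indices); default
#'   `ceiling(q / 3)`.
#' @param min_density minimum density persistence after birth; default
#'   `ceiling(m / 3)`, capped per label at `m - birth_level + 1` (a
#'   cluster cannot persist over levels that predate its birth).
#' @param min_size minimum conformation count; default 1% of all frames.
#' @param min_rare_size outlier floor for rare-state candidates; default
#'   `min_size / 10` (0.1% of all frames under the default `min_size`).
#' @param min_rare_scale minimum scale persistence for rare-state
#'   candidates; default `ceiling(0.6 * q)`.
#' @return the summary tibble (class `mpc_candidates`) with logical columns
#'   `selected` and `rare_state`. If nothing passes, the global-minimum-E
#'   label alone is selected, with a warning.
#' @export
select_candidates <- function(summary, min_scale = NULL, min_density = NULL,
                              min_size = NULL, min_rare_size = NULL,
                              min_rare_scale = NULL) {
  stopifnot(inherits(summary, "mpc_summary"))
  dim <- attr(summary, "grid_dim")
  m <- dim[["m"]]
  q <- dim[["q"]]
  if (is.null(min_scale)) min_scale <- ceiling(q / 3)
  if (is.null(min_density)) min_density <- ceiling(m / 3)
  if (is.null(min_size)) min_size <- 0.01 * attr(summary, "total_frames")
  if (is.null(min_rare_size)) min_rare_size <- min_size / 10
  if (is.null(min_rare_scale)) min_rare_scale <- ceiling(0.6 * q)
  pass_scale <- summary$scale_persistence >= min_scale
  pass_density <- summary$density_persistence >=
    pmin(min_density, m - summary$birth_level + 1L)
  pass_size <- summary$max_size >= min_size
  out <- summary
  out$selected <- pass_scale & pass_density & pass_size
  out$rare_state <- pass_density & !pass_size &
    summary$scale_persistence >= min_rare_scale &
    summary$max_size >= min_rare_size
  if (!any(out$selected)) {
    warning("no cluster passed the selection rules; keeping only the global minimum-free-energy cluster")
    out$selected <- out$free_energy == min(out$free_energy)
    out$rare_state <- out$rare_state & !out$selected
  }
  attr(out, "rules") <- list(min_scale = min_scale, min_density = min_density,
                             min_size = min_size,
                             min_rare_size = min_rare_size,
                             min_rare_scale = min_rare_scale)
  class(out) <- c("mpc_candidates", class(summary))
  out
}

#' Choose a concrete version of each candidate cluster
#'
#' A candidate's *version* is its member set at one particular grid cell.
#' Candidates are processed in order of descending free energy of their
#' label (shallow basins first), and each receives the largest version (by
#' conformation count) in its persistence region that contains neither
#' another candidate's label microstate nor any microstate already claimed
#' by a previously chosen version; this guarantees pairwise-disjoint cores.
#' If every cell conflicts, the candidate falls back to its smallest (birth)
#' version with a warning, minus any members that still conflict.
#'
#' @param candidates an `mpc_candidates` tibble (or integer vector of
#'   `label_idx` values).
#' @param grid the `mpc_grid` the regions were computed from.
#' @param regions the matching `mpc_regions`.
#' @param include_rare include rare-state candidates (default `TRUE`).
#' @return a tibble of class `mpc_versions`: `label_idx`, `label`,
#'   `free_energy`, cell `j`, `l`, `size`, and list-column `members`
#'   (1-based member indices), ordered by ascending free energy.
#' @export
choose_versions <- function(candidates, grid, regions, include_rare = TRUE) {
  stopifnot(inherits(grid, "mpc_grid"), inherits(regions, "mpc_regions"))
  if (inherits(candidates, "mpc_candidates")) {
    keep <- candidates$selected | (include_rare & candidates$rare_state)
    labels <- candidates$label_idx[keep]
  } else {
    labels <- as.integer(candidates)
  }
  if (length(labels) == 0L) stop("no candidate clusters to choose versions for")
  E <- grid$E
  ord <- order(-E[labels], -labels)   # descending free energy, shallow first
  labels <- labels[ord]
  claimed <- integer(0)
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    s <- labels[[i]]
    forbidden <- c(setdiff(labels, s), claimed)
    reg <- regions[[as.character(s)]]
    cells <- reg$cells[order(-reg$cells$size, reg$cells$j, reg$cells$l), ]
    version <- NULL
    for (k in seq_len(nrow(cells))) {
      j <- cells$j[[k]]
      l <- cells$l[[k]]
      r <- grid$rows[[j]]
      members <- r$members[r$labels[l, ] == s]
      if (!any(members %in% forbidden)) {
        version <- list(j = j, l = l, members = members,
                        size = cells$size[[k]])
        break
      }
    }
    if (is.null(version)) {
      warning(sprintf("all versions of cluster %d conflict; falling back to its birth cell",
                      grid$state_map[[s]]))
      k <- order(cells$size, cells$j, cells$l)[[1L]]
      r <- grid$rows[[cells$j[[k]]]]
      members <- r$members[r$labels[cells$l[[k]], ] == s]
      members <- setdiff(members, forbidden)
      version <- list(j = cells$j[[k]], l = cells$l[[k]], members = members,
                      size = sum(grid$populations[members]))
    }
    claimed <- c(claimed, version$members)
    out[[i]] <- tibble::tibble(
      label_idx = s, label = grid$state_map[[s]], free_energy = E[[s]],
      j = version$j, l = version$l, size = version$size,
      members = list(version$members))
  }
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$free_energy)
  class(res) <- c("mpc_versions", class(res))
  res
}

#' Partition microstates among the chosen clusters
#'
#' In `"core"` mode the partition is just the chosen versions: microstates
#' outside every core stay unassigned (`NA`). In `"full"` mode (default)
#' every remaining microstate is assigned to the candidate minimizing the
#' commute-time distance to the cluster, measured single-linkage style as
#' the minimum over the version's members; ties go to the candidate with
#' the lower-energy label.
#'
#' @param versions an `mpc_versions` tibble from [choose_versions()].
#' @param dist the `commute_dist` used throughout the analysis.
#' @param grid the `mpc_grid` (for free energies and state labels).
#' @param mode `"full"` (default) or `"core"`.
#' @return a tibble of class `mpc_partition`: `state` (1-based internal),
#'   `label` (original microstate label), `cluster` (original label of the
#'   assigned candidate, `NA` if unassigned in core mode) and `core`
#'   (logical: member of the chosen version).
#' @export
full_partition <- function(versions, dist, grid, mode = c("full", "core")) {
  mode <- match.arg(mode)
  stopifnot(inherits(versions, "mpc_versions"))
  n <- length(grid$E)
  assignment <- rep(NA_integer_, n)   # candidate row index per state
  for (i in seq_len(nrow(versions)))
    assignment[versions$members[[i]]] <- i
  core <- !is.na(assignment)
  if (mode == "full") {
    unclaimed <- which(is.na(assignment))
    if (length(unclaimed)) {
      # distance from each unclaimed state to each candidate's version
      dmat <- vapply(seq_len(nrow(versions)), function(i) {
        mem <- versions$members[[i]]
        apply(dist$D[unclaimed, mem, drop = FALSE], 1L, min)
      }, numeric(length(unclaimed)))
      dmat <- matrix(dmat, nrow = length(unclaimed))
      # candidates are sorted by ascending free energy, so the first
      # minimizer is the lower-energy label on ties
      assignment[unclaimed] <- apply(dmat, 1L, which.min)
    }
  }
  out <- tibble::tibble(
    state = seq_len(n),
    label = grid$state_map,
    cluster = versions$label[assignment],
    core = core
  )
  attr(out, "mode") <- mode
  class(out) <- c("mpc_partition", class(out))
  out
}

#' Hierarchy of the chosen clusters
#'
#' At one reference scale column, the density levels are scanned from the
#' strictest upward; the first level at which two (or more) candidates'
#' label microstates fall into a single neighborhood-graph component joins
#' their branches at that level index. The default reference column is the
#' smallest scale at which at least one candidate pair co-occurs in a
#' component of the most permissive level set -- the first column where the
#' merge ladder is visible, so join heights read as the density levels at
#' which basins coalesce (barrier heights).
#' Leaves sit at the candidates' birth levels, so branch lengths are
#' level-index differences and node height reflects the free-energy level
#' at which basins merge — the barrier structure of the landscape.
#' Candidates that never merge within the grid are joined at a virtual root
#' one level above the top, with a warning.
#'
#' @param versions an `mpc_versions` tibble (only `label_idx` is used).
#' @param grid the `mpc_grid`.
#' @param regions the matching `mpc_regions` (for birth levels).
#' @param reference_l reference scale column; `NULL` (default) picks the
#'   first column at which any candidate pair is merged in the most
#'   permissive level set, falling back to the median column.
#' @return an object of class `mpc_hierarchy`: `newick` string, `phylo`
#'   (an [ape::read.tree()] tree with branch lengths in level indices),
#'   `merges` tibble (`level`, `clusters` joined), and `reference_l`.
#' @export
cluster_hierarchy <- function(versions, grid, regions, reference_l = NULL) {
  stopifnot(inherits(grid, "mpc_grid"))
  labels <- if (is.data.frame(versions)) versions$label_idx
            else as.integer(versions)
  if (length(labels) < 2L) stop("hierarchy needs at least 2 candidates")
  m <- length(grid$params$thetas)
  q <- length(grid$params$epsilons)
  if (is.null(reference_l)) {
    top <- grid$rows[[m]]
    pos <- match(labels, top$members)
    merged_at <- which(vapply(seq_len(q), function(l) {
      comp <- top$labels[l, pos]
      anyDuplicated(comp[!is.na(comp)]) > 0L
    }, logical(1)))
    reference_l <- if (length(merged_at)) min(merged_at) else ceiling(q / 2)
  }
  stopifnot(reference_l >= 1L, reference_l <= q)
  birth <- vapply(labels, function(s)
    regions[[as.character(s)]]$birth_level, integer(1))
  # active node per candidate group: newick fragment + height
  nodes <- purrr::map2(labels, birth, function(s, b)
    list(newick = sprintf("cluster_%d", grid$state_map[[s]]), height = b,
         members = s))
  merges <- list()
  for (j in seq_len(m)) {
    r <- grid$rows[[j]]
    present <- labels[labels %in% r$members]
    if (length(present) < 2L) next
    comp <- r$labels[reference_l, ][match(present, r$members)]
    for (cid in unique(comp)) {
      group <- present[comp == cid]
      node_ids <- unique(vapply(seq_along(nodes), function(i)
        if (any(group %in% nodes[[i]]$members)) i else NA_integer_,
        integer(1)))
      node_ids <- node_ids[!is.na(node_ids)]
      if (length(node_ids) >= 2L) {
        children <- nodes[node_ids]
        frag <- paste(vapply(children, function(ch)
          sprintf("%s:%d", ch$newick, j - ch$height), character(1)),
          collapse = ",")
        merged <- list(newick = sprintf("(%s)", frag), height = j,
                       members = unlist(lapply(children, `[[`, "members")))
        nodes <- c(nodes[-node_ids], list(merged))
        merges[[length(merges) + 1L]] <- tibble::tibble(
          level = j,
          clusters = list(grid$state_map[merged$members]))
      }
    }
  }
  if (length(nodes) > 1L) {
    warning("some candidates never merge within the grid; joining them at a virtual root")
    root_h <- m + 1L
    frag <- paste(vapply(nodes, function(ch)
      sprintf("%s:%d", ch$newick, root_h - ch$height), character(1)),
      collapse = ",")
    nodes <- list(list(newick = sprintf("(%s)", frag), height = root_h,
                       members = unlist(lapply(nodes, `[[`, "members"))))
    merges[[length(merges) + 1L]] <- tibble::tibble(
      level = root_h, clusters = list(grid$state_map[nodes[[1L]]$members]))
  }
  newick <- paste0(nodes[[1L]]$newick, ";")
  structure(
    list(newick = newick,
         phylo = ape::read.tree(text = newick),
         merges = dplyr::bind_rows(merges),
         reference_l = reference_l),
    class = "mpc_hierarchy")
}

#' @export
print.mpc_hierarchy <- function(x, ...) {
  cat("<mpc_hierarchy>", x$newick, "\n")
  invisible(x)
}
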