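#' Run the full multi-persistent clustering pipeline
#'
#' Chains every stage: transition counting, ergodic trimming, transition
#' matrix, stationary distribution and free energies, commute-time
#' distances, the density x scale grid of clusterings, persistence regions,
#' diagram summary, candidate selection, version choice, microstate
#' partition and cluster hierarchy. Any stage failure is re-signaled with
#' the stage name in the message.
#'
#' @param trajs a [dtrajs()] object, a list of integer vectors, or a path
#'   accepted by [read_dtrajs()].
#' @param lag lag time in trajectory steps.
#' @param m,q grid sizes (density levels, scale values).
#' @param theta_spacing,eps_spacing grid spacing per axis
#'   (see [build_grid()]).
#' @param min_scale,min_density,min_size,min_rare_size,min_rare_scale
#'   selection thresholds (see [select_candidates()]); `NULL` for the
#'   defaults.
#' @param include_rare include rare-state candidates in the partition.
#' @param reference_l reference scale column for the hierarchy (`NULL`:
#'   median).
#' @param mode partition mode, `"full"` or `"core"`.
#' @param sliding,prior,symmetrize forwarded to [fit_msm()].
#' @return an object of class `mpc_result`: a list with `model`, `dist`,
#'   `grid`, `regions`, `summary`, `candidates`, `versions`, `partition`,
#'   `hierarchy` and the effective `config`.
#' @examples
#' \donttest{
#' sim <- metropolis_trajectories(make_figure1_landscape(),
#'                                n_traj = 20, n_steps = 500, seed = 7)
#' res <- run_mpc(sim$dtrajs, m = 10, q = 10)
#' res$summary
#' }
#' @export
run_mpc <- function(trajs, lag = 1L, m = 25L, q = 25L,
                    theta_spacing = c("linear", "quantile"),
                    eps_spacing = c("log", "quantile", "linear"),
                    min_scale = NULL, min_density = NULL, min_size = NULL,
                    min_rare_size = NULL, min_rare_scale = NULL,
                    include_rare = TRUE, reference_l = NULL,
                    mode = c("full", "core"),
                    sliding = TRUE, prior = 0, symmetrize = FALSE) {
  theta_spacing <- match.arg(theta_spacing)
  eps_spacing <- match.arg(eps_spacing)
  mode <- match.arg(mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (is.character(trajs)) trajs <- stage("read", read_dtrajs(trajs))
  if (!inherits(trajs, "dtrajs")) trajs <- stage("read", dtrajs(trajs))
  model <- stage("model", fit_msm(trajs, lag = lag, sliding = sliding,
                                  prior = prior, symmetrize = symmetrize))
  dist <- stage("distances", commute_distances(model))
  params <- stage("grid", build_grid(model, dist, m = m, q = q,
                                     theta_spacing = theta_spacing,
                                     eps_spacing = eps_spacing))
  grid <- stage("grid", compute_grid(model, dist, params))
  regions <- stage("regions", persistence_regions(grid))
  summary <- stage("summary", summarize_persistence(regions))
  candidates <- stage("select", select_candidates(
    summary, min_scale = min_scale, min_density = min_density,
    min_size = min_size, min_rare_size = min_rare_size,
    min_rare_scale = min_rare_scale))
  versions <- stage("versions", choose_versions(candidates, grid, regions,
                                                include_rare = include_rare))
  partition <- stage("partition", full_partition(versions, dist, grid,
                                                 mode = mode))
  hierarchy <- if (nrow(versions) >= 2L)
    stage("hierarchy", cluster_hierarchy(versions, grid, regions,
                                         reference_l = reference_l))
  else NULL
  structure(
    list(model = model, dist = dist, grid = grid, regions = regions,
         summary = summary, candidates = candidates, versions = versions,
         partition = partition, hierarchy = hierarchy,
         config = list(lag = lag, m = m, q = q,
                       theta_spacing = theta_spacing,
                       eps_spacing = eps_spacing,
                       min_scale = min_scale, min_density = min_density,
                       min_size = min_size, min_rare_size = min_rare_size,
                       min_rare_scale = min_rare_scale,
                       include_rare = include_rare,
                       reference_l = reference_l, mode = mode,
                       sliding = sliding, prior = prior,
                       symmetrize = symmetrize)),
    class = "mpc_result")
}

#' @export
print.mpc_result <- function(x, ...) {
  cat(sprintf("<mpc_result> %d microstates, %d x %d grid, %d regions\n",
              x$model$n_states, length(x$grid$params$thetas),
              length(x$grid$params$epsilons), length(x$regions)))
  cat(sprintf("  %d selected cluster(s), %d rare-state candidate(s)\n",
              sum(x$candidates$selected), sum(x$candidates$rare_state)))
  invisible(x)
}

#' Write every pipeline artifact as plain text
#'
#' Produces, under `dir`: `model/` (`T.tsv`, `pi.tsv`, `E.tsv`,
#' `populations.tsv`, `state_map.tsv`), `D.tsv` with a `bounds.json`
#' sidecar, `grid.json` (parameters plus sparse per-cell labelings),
#' `regions.json`, `summary.tsv`, `candidates.json`, `partition.tsv` (in
#' original input labels), `tree.nwk` and `config.json`.
#'
#' @param result an `mpc_result` from [run_mpc()].
#' @param dir output directory (created recursively).
#' @return `dir`, invisibly.
#' @export
write_mpc <- function(result, dir) {
  stopifnot(inherits(result, "mpc_result"))
  dir.create(file.path(dir, "model"), recursive = TRUE, showWarnings = FALSE)
  model <- result$model
  labels <- model$state_map
  write_matrix <- function(M, path) {
    colnames(M) <- labels
    utils::write.table(M, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  write_matrix(model$T, file.path(dir, "model", "T.tsv"))
  utils::write.table(
    data.frame(retained_index = seq_along(labels) - 1L,
               original_label = labels, pi = model$pi, E = model$E,
               population = model$populations),
    file.path(dir, "model", "state_map.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(model$removed))
    writeLines(as.character(model$removed),
               file.path(dir, "model", "removed_states.txt"))
  write_matrix(result$dist$D, file.path(dir, "D.tsv"))
  jsonlite::write_json(
    list(d_min = result$dist$d_min, D_star = result$dist$D_star),
    file.path(dir, "bounds.json"), auto_unbox = TRUE, digits = NA)
  grid <- result$grid
  jsonlite::write_json(
    list(thetas = grid$params$thetas, epsilons = grid$params$epsilons,
         theta_spacing = grid$params$theta_spacing,
         eps_spacing = grid$params$eps_spacing,
         rows = purrr::map(grid$rows, function(r) list(
           members = labels[r$members],
           labels = apply(r$labels, 1L, function(v) labels[v],
                          simplify = FALSE)))),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    purrr::map(unclass(result$regions), function(reg) list(
      label = reg$label, birth_level = reg$birth_level,
      cells = reg$cells, merges = reg$merges)),
    file.path(dir, "regions.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    result$summary[c("label", "scale_persistence", "density_persistence",
                     "max_size", "birth_level")],
    file.path(dir, "summary.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    purrr::map(seq_len(nrow(result$versions)), function(i) list(
      label = result$versions$label[[i]],
      j = result$versions$j[[i]], l = result$versions$l[[i]],
      size = result$versions$size[[i]],
      members = labels[result$versions$members[[i]]])),
    file.path(dir, "candidates.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(original_label = result$partition$label,
               cluster_label = result$partition$cluster,
               core = result$partition$core),
    file.path(dir, "partition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(result$hierarchy))
    writeLines(result$hierarchy$newick, file.path(dir, "tree.nwk"))
  jsonlite::write_json(result$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dense labeled matrix written by [write_mpc()]
#'
#' @param path a TSV with a header row of original microstate labels.
#' @return numeric matrix.
#' @export
read_mpc_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  as.matrix(df)
}
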