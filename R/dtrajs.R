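#' Discrete trajectories of microstate indices
#'
#' A light container for a set of discrete trajectories: ordered integer
#' sequences of microstate indices sampled at a fixed time step. Indices are
#' 0-based internally; arbitrary non-negative input labels are remapped to a
#' contiguous 0-based range and the original labels kept in `state_map`.
#'
#' @param trajectories list of integer vectors (microstate index sequences).
#' @param n_states number of microstates; defaults to `max(index) + 1` after
#'   remapping. When supplied it must cover every observed index.
#' @param state_map optional integer vector: `state_map[i + 1]` is the
#'   original label of internal state `i`. Defaults to the identity.
#' @return an object of class `dtrajs` with elements `trajectories`,
#'   `n_states` and `state_map`.
#' @examples
#' dt <- dtrajs(list(c(0L, 1L, 0L, 1L, 0L), c(1L, 2L, 2L)))
#' dt$n_states
#' @export
dtrajs <- function(trajectories, n_states = NULL, state_map = NULL) {
  if (!is.list(trajectories)) trajectories <- list(trajectories)
  if (length(trajectories) == 0L) stop("no trajectories supplied")
  trajectories <- lapply(trajectories, function(x) {
    if (length(x) == 0L) return(integer(0))
    if (!is.numeric(x) || any(x != floor(x)) || anyNA(x))
      stop("trajectories must contain integer microstate indices")
    as.integer(x)
  })
  trajectories <- trajectories[lengths(trajectories) > 0L]
  if (length(trajectories) == 0L) stop("all trajectories are empty")
  if (!any(lengths(trajectories) >= 2L))
    stop("need at least one trajectory of length >= 2 (no transitions exist)")
  all_states <- sort(unique(unlist(trajectories, use.names = FALSE)))
  if (min(all_states) < 0L) stop("microstate indices must be non-negative")
  if (is.null(state_map)) {
    if (is.null(n_states)) {
      # compact representation: remap observed labels to 0..k-1
      if (!identical(all_states, seq_along(all_states) - 1L)) {
        remap <- integer(max(all_states) + 1L)
        remap[all_states + 1L] <- seq_along(all_states) - 1L
        trajectories <- lapply(trajectories, function(x) remap[x + 1L])
        state_map <- all_states
        n_states <- length(all_states)
      } else {
        state_map <- all_states
        n_states <- length(all_states)
      }
    } else {
      n_states <- as.integer(n_states)
      if (max(all_states) >= n_states)
        stop("n_states must exceed the largest observed index")
      state_map <- seq_len(n_states) - 1L
    }
  } else {
    if (is.null(n_states)) n_states <- length(state_map)
    stopifnot(length(state_map) == n_states, max(all_states) < n_states)
  }
  structure(
    list(trajectories = trajectories, n_states = as.integer(n_states),
         state_map = as.integer(state_map)),
    class = "dtrajs"
  )
}

#' @export
print.dtrajs <- function(x, ...) {
  cat(sprintf("<dtrajs> %d trajectories, %d frames, %d microstates\n",
              length(x$trajectories), sum(lengths(x$trajectories)),
              x$n_states))
  invisible(x)
}

#' @export
length.dtrajs <- function(x) length(x$trajectories)

#' Read discrete trajectories from plain text
#'
#' Accepts either a directory (every regular file inside is one trajectory of
#' whitespace-separated integers), a character vector of file paths (one
#' trajectory per file), or a single file. A single file holding several
#' lines is read with one trajectory per line when `multi = TRUE` (the
#' default for a lone file with more than one non-empty line); with
#' `multi = FALSE` all its tokens form one trajectory.
#'
#' Labels need not be contiguous: they are remapped internally and the
#' original labels preserved in the `state_map` of the returned [dtrajs()].
#'
#' @param path directory, file, or vector of files.
#' @param multi logical; split a single file into one trajectory per line.
#'   `NULL` (default) auto-detects.
#' @return a [dtrajs()] object.
#' @export
read_dtrajs <- function(path, multi = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    path <- list.files(path, full.names = TRUE)
    path <- path[!dir.exists(path)]
    if (length(path) == 0L) stop("no trajectory files in directory")
  }
  missing <- path[!file.exists(path)]
  if (length(missing)) stop("input path does not exist: ", missing[[1L]])
  parse_tokens <- function(tokens, where) {
    tokens <- tokens[nzchar(tokens)]
    vals <- suppressWarnings(as.integer(tokens))
    if (anyNA(vals)) {
      bad <- tokens[which(is.na(vals))[1L]]
      stop(sprintf("non-integer token '%s' in %s", bad, where))
    }
    vals
  }
  trajs <- list()
  for (f in path) {
    lines <- readLines(f, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warning("empty trajectory file skipped: ", f)
      next
    }
    split_lines <- if (is.null(multi)) length(path) == 1L && length(lines) > 1L else multi
    if (split_lines) {
      for (i in seq_along(lines)) {
        trajs[[length(trajs) + 1L]] <-
          parse_tokens(strsplit(trimws(lines[[i]]), "\\s+")[[1L]],
                       sprintf("%s line %d", f, i))
      }
    } else {
      trajs[[length(trajs) + 1L]] <-
        parse_tokens(unlist(strsplit(trimws(lines), "\\s+")), f)
    }
  }
  if (length(trajs) == 0L) stop("no non-empty trajectories found")
  dtrajs(trajs)
}

#' Write discrete trajectories as plain text
#'
#' One file per trajectory (`traj_0001.txt`, ...) of space-separated
#' integers, using original (`state_map`) labels.
#'
#' @param x a [dtrajs()] object.
#' @param dir output directory, created if needed.
#' @return the paths written, invisibly.
#' @export
write_dtrajs <- function(x, dir) {
  stopifnot(inherits(x, "dtrajs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(x$trajectories))
  for (i in seq_along(x$trajectories)) {
    paths[[i]] <- file.path(dir, sprintf("traj_%04d.txt", i))
    writeLines(paste(x$state_map[x$trajectories[[i]] + 1L], collapse = " "),
               paths[[i]])
  }
  invisible(paths)
}
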