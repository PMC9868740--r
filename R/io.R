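# Plain-text I/O: one delimited matrix file per subject (filename is the
# subject id), TSV parcellation and cohort tables. Chosen for inspectability;
# no binary formats.

#' Write connectivity matrices to a directory
#'
#' One CSV file per subject, named `<subject_id>.csv`, no header or row
#' names. A `state.txt` sidecar records the shared processing state.
#'
#' @param matrices List of `connectivity_matrix` objects.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_matrices <- function(matrices, dir) {
  stopifnot(length(matrices) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  states <- unique(vapply(matrices, `[[`, "", "state"))
  if (length(states) != 1)
    stop("all matrices in one set must share a state", call. = FALSE)
  writeLines(states, file.path(dir, "state.txt"))
  paths <- vapply(matrices, function(m) {
    p <- file.path(dir, paste0(m$subject_id, ".csv"))
    utils::write.table(m$values, p, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Read connectivity matrices from a directory
#'
#' Reads every `*.csv` file in `dir` as one subject's matrix (subject id =
#' file name without extension). Validates squareness and symmetry; a
#' malformed file is reported by name.
#'
#' @param dir Directory written by [write_matrices()], or any directory of
#'   per-subject delimited matrices.
#' @param state Processing state of the stored matrices; defaults to the
#'   `state.txt` sidecar if present, else `"raw-r"`.
#' @param tol Symmetry tolerance passed to [connectivity_matrix()].
#' @return Named list of `connectivity_matrix` objects.
#' @export
read_matrices <- function(dir, state = NULL, tol = 1e-6) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no .csv matrix files in ", dir, call. = FALSE)
  if (is.null(state)) {
    sf <- file.path(dir, "state.txt")
    state <- if (file.exists(sf)) readLines(sf, n = 1L) else "raw-r"
  }
  out <- lapply(files, function(p) {
    sid <- sub("\\.csv$", "", basename(p))
    v <- tryCatch(
      as.matrix(utils::read.table(p, sep = ",", header = FALSE)),
      error = function(e) stop("malformed matrix file ", p, ": ",
                               conditionMessage(e), call. = FALSE))
    storage.mode(v) <- "double"
    dimnames(v) <- NULL
    tryCatch(connectivity_matrix(v, sid, state = state, tol = tol),
             error = function(e) stop("file ", p, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(out) <- vapply(out, `[[`, "", "subject_id")
  out
}

#' Read a parcellation from a TSV file
#'
#' Expects a header line and two columns: `roi_id`, `network`.
#'
#' @param path Path to the TSV file.
#' @return A `parcellation` object.
#' @export
read_parcellation <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character",
                         quote = "")
  need <- c("roi_id", "network")
  if (!all(need %in% names(d)))
    stop(path, ": parcellation needs columns roi_id, network", call. = FALSE)
  blank <- which(is.na(d$network) | !nzchar(trimws(d$network)))
  if (length(blank))
    stop(sprintf("%s line %d: ROI '%s' has no network label",
                 path, blank[1] + 1L, d$roi_id[blank[1]]), call. = FALSE)
  parcellation(d$roi_id, d$network)
}

#' Write a parcellation to a TSV file
#' @param parc A `parcellation` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV or JSON
#'
#' TSV needs columns `subject_id`, `group` (optionally `site`); JSON an array
#' of objects with the same fields. Group labels must be one of
#' neurotypical / neuroatypical / unlabeled and subject ids unique.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @return A `cohort_table` object.
#' @export
read_cohort <- function(path) {
  d <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, colClasses = "character",
                      quote = "")
  }
  if (!all(c("subject_id", "group") %in% names(d)))
    stop(path, ": cohort table needs columns subject_id, group",
         call. = FALSE)
  cohort_table(d$subject_id, d$group, site = d[["site"]])
}

#' Write a cohort table to TSV
#' @param cohort A `cohort_table` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
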