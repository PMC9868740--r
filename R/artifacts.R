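# Directory-level artifact writers: everything is plain text (CSV/TSV/JSON)
# so simulated cohorts and pipeline outputs can be inspected and versioned.

#' Write a simulated cohort to a directory
#'
#' Writes the raw-r matrices (one CSV per subject), `parcellation.tsv`,
#' `cohort.tsv` and `hubs.json` (the ground-truth perturbed hub ROIs).
#'
#' @param cohort The list returned by [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_cohort_dir <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrices(cohort$matrices, file.path(dir, "matrices"))
  write_parcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  write_cohort(cohort$cohort, file.path(dir, "cohort.tsv"))
  jsonlite::write_json(cohort$hubs, file.path(dir, "hubs.json"))
  invisible(dir)
}

#' Read a simulated cohort directory
#'
#' Inverse of [write_cohort_dir()].
#'
#' @param dir Directory written by [write_cohort_dir()].
#' @return List with `matrices`, `cohort`, `parcellation`, `hubs`.
#' @export
read_cohort_dir <- function(dir) {
  list(matrices = read_matrices(file.path(dir, "matrices")),
       cohort = read_cohort(file.path(dir, "cohort.tsv")),
       parcellation = read_parcellation(file.path(dir, "parcellation.tsv")),
       hubs = unlist(jsonlite::fromJSON(file.path(dir, "hubs.json"))))
}

#' Write / read a split manifest as JSON
#'
#' @param splits A `cohort_splits` object.
#' @param path Output path (JSON).
#' @return `write_splits()` invisibly returns `path`; `read_splits()` the
#'   `cohort_splits`.
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(unclass(splits), path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_splits
#' @export
read_splits <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  chr <- function(v) as.character(unlist(v))
  structure(list(cv_pool = chr(x$cv_pool),
                 folds = lapply(x$folds, chr),
                 eval_typical = chr(x$eval_typical),
                 eval_atypical = chr(x$eval_atypical),
                 validation_atypical = chr(x$validation_atypical),
                 seed = as.integer(x$seed[[1]])),
            class = "cohort_splits")
}

#' Write a centrality map as TSV
#'
#' Columns `roi_id`, `network`, `group`, `centrality` — ready for
#' downstream plotting.
#'
#' @param map A `centrality_map` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_centrality <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
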