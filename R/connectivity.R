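#' Canonical resting-state network names
#'
#' The five resting-state brain functional networks (RSBFNs) modeled by the
#' pipeline: Default Mode, Dorsal Attention, Ventral Attention,
#' Fronto-parietal, and the combined Cingulo-opercular + Salience network.
#'
#' @format Character vector of length 5.
#' @export
RSBFN_NAMES <- c("Default", "DorsalAttn", "VentralAttn", "FrontoParietal",
                 "CO+SN")

#' Construct a per-subject connectivity matrix
#'
#' A `connectivity_matrix` holds one subject's symmetric ROI-by-ROI matrix of
#' functional-connectivity values together with a state marker tracking where
#' it sits in the processing chain: `"raw-r"` (Pearson correlations),
#' `"fisher-z"` (after the variance-stabilizing transform z = atanh(r)), or
#' `"cleaned"` (after clipping and rescaling to [-1, 1]).
#'
#' @param values Square numeric matrix, symmetric to within `tol`.
#' @param subject_id Subject identifier (scalar character).
#' @param state One of `"raw-r"`, `"fisher-z"`, `"cleaned"`.
#' @param tol Absolute tolerance for the symmetry check.
#' @return An object of class `connectivity_matrix`: a list with elements
#'   `subject_id`, `n_rois`, `values` and `state`.
#' @export
connectivity_matrix <- function(values, subject_id, state = "raw-r",
                                tol = 1e-8) {
  state <- match.arg(state, c("raw-r", "fisher-z", "cleaned"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) != ncol(values))
    stop(sprintf("`values` must be square; got %d x %d",
                 nrow(values), ncol(values)), call. = FALSE)
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop(sprintf("matrix for subject '%s' is asymmetric (max |m - t(m)| = %g)",
                 subject_id, asym), call. = FALSE)
  off <- values[upper.tri(values)]
  if (state == "raw-r" && length(off) && any(abs(off) > 1))
    stop(sprintf("subject '%s': raw correlations outside [-1, 1]", subject_id),
         call. = FALSE)
  if (state == "cleaned" && any(abs(values) > 1 + 1e-12))
    stop(sprintf("subject '%s': cleaned values outside [-1, 1]", subject_id),
         call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 n_rois = nrow(values),
                 values = (values + t(values)) / 2,
                 state = state),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> subject '%s': %d ROIs, state = %s\n",
              x$subject_id, x$n_rois, x$state))
  invisible(x)
}

#' Fisher r-to-z transform of a connectivity matrix
#'
#' Applies z = atanh(r) to every off-diagonal entry. The diagonal
#' (self-connections) is set to zero by convention and never enters the
#' feature set.
#'
#' @param m A `connectivity_matrix` in state `"raw-r"`.
#' @return A `connectivity_matrix` in state `"fisher-z"`.
#' @export
fisher_transform <- function(m) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (m$state != "raw-r")
    stop(sprintf("fisher_transform expects state 'raw-r', got '%s'", m$state),
         call. = FALSE)
  v <- m$values
  bad <- which(abs(v) >= 1 & row(v) < col(v), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf(
      "subject '%s': |r| >= 1 at cell (%d, %d); atanh undefined",
      m$subject_id, bad[1, 1], bad[1, 2]), call. = FALSE)
  z <- atanh(v)
  diag(z) <- 0
  connectivity_matrix(z, m$subject_id, state = "fisher-z")
}

#' Vectorize the strict upper triangle of a connectivity matrix
#'
#' Returns the strict upper triangle (i < j) in row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). All downstream feature
#' indices — network subsetting, explanations, centrality — refer to this
#' fixed order. Length is n(n-1)/2; for the 333-parcel cortical atlas that
#' is 55,278 features.
#'
#' @param m A `connectivity_matrix`, or a symmetric numeric matrix.
#' @return Numeric vector of length `n_rois * (n_rois - 1) / 2`.
#' @export
vectorize_upper <- function(m) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else m
  if (!is.matrix(v) || nrow(v) != ncol(v))
    stop("input must be a square matrix", call. = FALSE)
  # t(v)[lower.tri(v)] enumerates the upper triangle in row-major (i < j) order
  t(v)[lower.tri(v)]
}

#' Rebuild a symmetric matrix from an upper-triangle feature vector
#'
#' Inverse of [vectorize_upper()]: places the vector back on the strict upper
#' triangle (row-major i < j order), mirrors it, and zeroes the diagonal.
#'
#' @param v Numeric vector of length `n_rois * (n_rois - 1) / 2`.
#' @param n_rois Number of ROIs of the target matrix.
#' @param subject_id Optional subject id for the returned object; if `NULL` a
#'   plain matrix is returned.
#' @param state State marker for the returned `connectivity_matrix`.
#' @return A symmetric matrix with zero diagonal (or a `connectivity_matrix`).
#' @export
devectorize <- function(v, n_rois, subject_id = NULL, state = "fisher-z") {
  expect <- n_rois * (n_rois - 1) / 2
  if (length(v) != expect)
    stop(sprintf("feature vector has length %d; n_rois = %d needs %d",
                 length(v), n_rois, expect), call. = FALSE)
  m <- matrix(0, n_rois, n_rois)
  m[lower.tri(m)] <- v       # column-major lower triangle == row-major upper
  m <- t(m)
  m <- m + t(m)
  if (is.null(subject_id)) return(m)
  connectivity_matrix(m, subject_id, state = state)
}

#' Construct a parcellation table
#'
#' Maps each ROI to exactly one resting-state network label. Labels outside
#' the five modeled networks (see [RSBFN_NAMES]) are allowed (e.g. `"other"`)
#' but are never modeled.
#'
#' @param roi_ids Character vector of ROI identifiers, in matrix row order.
#' @param networks Character vector of network labels, same length.
#' @return A data frame of class `parcellation` with columns `roi_id`,
#'   `network`.
#' @export
parcellation <- function(roi_ids, networks) {
  roi_ids <- as.character(roi_ids)
  networks <- as.character(networks)
  if (length(roi_ids) != length(networks))
    stop("`roi_ids` and `networks` must have equal length", call. = FALSE)
  if (anyDuplicated(roi_ids))
    stop("duplicate roi_id: ", roi_ids[duplicated(roi_ids)][1], call. = FALSE)
  if (anyNA(networks) || any(!nzchar(networks)))
    stop("every ROI needs a network label; missing for roi_id ",
         roi_ids[which(is.na(networks) | !nzchar(networks))[1]],
         call. = FALSE)
  structure(data.frame(roi_id = roi_ids, network = networks,
                       stringsAsFactors = FALSE),
            class = c("parcellation", "data.frame"))
}

#' Construct a cohort table
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param group Group label per subject: `"neurotypical"`, `"neuroatypical"`,
#'   or `"unlabeled"`.
#' @param site Optional acquisition-site label per subject.
#' @return A data frame of class `cohort_table`.
#' @export
cohort_table <- function(subject_id, group, site = NULL) {
  subject_id <- as.character(subject_id)
  group <- as.character(group)
  if (length(subject_id) != length(group))
    stop("`subject_id` and `group` must have equal length", call. = FALSE)
  if (anyDuplicated(subject_id))
    stop("duplicate subject_id: ", subject_id[duplicated(subject_id)][1],
         call. = FALSE)
  ok <- group %in% c("neurotypical", "neuroatypical", "unlabeled")
  if (!all(ok))
    stop("unknown group label '", group[!ok][1], "' for subject ",
         subject_id[!ok][1],
         " (expected neurotypical/neuroatypical/unlabeled)", call. = FALSE)
  d <- data.frame(subject_id = subject_id, group = group,
                  stringsAsFactors = FALSE)
  if (!is.null(site)) d$site <- as.character(site)
  structure(d, class = c("cohort_table", "data.frame"))
}
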