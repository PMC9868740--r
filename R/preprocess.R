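# Per-network feature subsetting, the clip/scale/exclusion cleaning rules,
# and the cross-validation / evaluation / validation split construction.

#' Cleaning parameters
#'
#' Fisher-z values are clipped to `[floor, ceiling]` and then mapped
#' linearly onto [-1, 1] (for the symmetric default this is x/2), matching
#' the input range of the tanh-activated models. A subject whose fraction of
#' clipped cells exceeds `exclusion_fraction` (strictly) is discarded from
#' that network's dataset.
#'
#' @param floor,ceiling Clip bounds for Fisher-z values (defaults -2, 2).
#' @param exclusion_fraction Maximum tolerated fraction of modified
#'   (clipped) cells; default 0.15.
#' @return A list of class `cleaning_params`.
#' @export
cleaning_params <- function(floor = -2, ceiling = 2,
                            exclusion_fraction = 0.15) {
  if (floor >= ceiling) stop("floor must be < ceiling", call. = FALSE)
  if (exclusion_fraction <= 0 || exclusion_fraction >= 1)
    stop("exclusion_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(floor = floor, ceiling = ceiling,
                 exclusion_fraction = exclusion_fraction),
            class = "cleaning_params")
}

#' Indices of a network's intra-network features
#'
#' Positions, in the global row-major upper-triangle order of
#' [vectorize_upper()], of the features whose two ROIs both belong to the
#' named network. A k-ROI network yields k(k-1)/2 positions.
#'
#' @param parc A `parcellation`.
#' @param network Network name present in `parc$network`.
#' @return Integer vector of feature positions (possibly empty).
#' @export
network_feature_index <- function(parc, network) {
  nets <- parc$network
  if (!network %in% nets)
    stop(sprintf("unknown network '%s'; available: %s", network,
                 paste(unique(nets), collapse = ", ")), call. = FALSE)
  n <- length(nets)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)   # row index, row-major i<j
  j <- sequence((n - 1L):1L) + i                   # column index
  which(nets[i] == network & nets[j] == network)
}

#' Subset a global feature vector to one network's features
#'
#' @param v Feature vector (or subjects-by-features matrix) in the global
#'   upper-triangle order.
#' @param parc A `parcellation`.
#' @param network Network name.
#' @return The intra-network features, in the induced order.
#' @export
subset_network <- function(v, parc, network) {
  idx <- network_feature_index(parc, network)
  if (is.matrix(v)) v[, idx, drop = FALSE] else v[idx]
}

#' Clip and rescale Fisher-z features
#'
#' Values are clipped to `[floor, ceiling]` and then mapped by the fixed
#' affine map onto [-1, 1] (x/2 for the symmetric default). The per-subject
#' fraction of cells altered by clipping is returned alongside; it feeds the
#' exclusion rule of [apply_exclusion()]. Already-cleaned data (all values
#' in [-1, 1]) is never clipped again, so re-cleaning always reports
#' fraction 0.
#'
#' @param features Subjects-by-features numeric matrix of Fisher-z values
#'   (rownames = subject ids).
#' @param params A [cleaning_params()].
#' @return List with `features` (cleaned matrix, all values in [-1, 1]) and
#'   `modified_fraction` (named numeric per subject).
#' @export
clean_features <- function(features, params = cleaning_params()) {
  stopifnot(is.matrix(features))
  if (!all(is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite feature value for subject '%s', feature %d",
                 rownames(features)[bad[1]] %||% bad[1], bad[2]),
         call. = FALSE)
  }
  clipped <- pmin(pmax(features, params$floor), params$ceiling)
  modified <- rowMeans(clipped != features)
  scaled <- 2 * (clipped - params$floor) / (params$ceiling - params$floor) - 1
  list(features = scaled, modified_fraction = modified)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply the modified-cell exclusion rule
#'
#' Subjects whose fraction of clipped cells exceeds
#' `params$exclusion_fraction` strictly are excluded; a subject exactly at
#' the limit is retained. Exclusion is per network: a subject can be dropped
#' from one network's dataset and kept in another.
#'
#' @param network Network name the features belong to.
#' @param cleaned Result of [clean_features()] on that network's features.
#' @param params A [cleaning_params()].
#' @return A `network_dataset`: list with `network`, `features` (retained
#'   subjects only), `retained_ids`, `excluded_ids`, `modified_fraction`.
#' @export
apply_exclusion <- function(network, cleaned, params = cleaning_params()) {
  frac <- cleaned$modified_fraction
  keep <- frac <= params$exclusion_fraction
  structure(list(network = network,
                 features = cleaned$features[keep, , drop = FALSE],
                 retained_ids = names(frac)[keep] %||%
                   rownames(cleaned$features)[keep],
                 excluded_ids = names(frac)[!keep] %||%
                   rownames(cleaned$features)[!keep],
                 modified_fraction = frac),
            class = "network_dataset")
}

#' @export
print.network_dataset <- function(x, ...) {
  cat(sprintf(
    "<network_dataset> %s: %d features, %d retained, %d excluded\n",
    x$network, ncol(x$features), length(x$retained_ids),
    length(x$excluded_ids)))
  invisible(x)
}

#' Build one network's cleaned dataset from Fisher-z matrices
#'
#' Convenience chain: vectorize each subject's Fisher-z matrix, subset to the
#' network's intra-network features, clip/scale, and apply the exclusion
#' rule.
#'
#' @param matrices Named list of `connectivity_matrix` in state `fisher-z`.
#' @param parc A `parcellation` matching the matrices.
#' @param network Network name.
#' @param params A [cleaning_params()].
#' @return A `network_dataset`.
#' @export
network_dataset <- function(matrices, parc, network,
                            params = cleaning_params()) {
  states <- vapply(matrices, `[[`, "", "state")
  if (any(states != "fisher-z"))
    stop("all matrices must be in state 'fisher-z'", call. = FALSE)
  feats <- t(vapply(matrices, function(m) vectorize_upper(m),
                    numeric(nrow(parc) * (nrow(parc) - 1) / 2)))
  rownames(feats) <- vapply(matrices, `[[`, "", "subject_id")
  sub <- subset_network(feats, parc, network)
  apply_exclusion(network, clean_features(sub, params), params)
}

# Seeded RNG scope: runs `expr` under `seed` and restores the caller's RNG.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Largest multiple of 5 strictly below 0.8 * n, in exact integer arithmetic:
# 5k < 4n/5  <=>  k <= floor((4n - 1) / 25).
cv_pool_size <- function(n) 5L * ((4L * as.integer(n) - 1L) %/% 25L)

#' Construct cross-validation, evaluation and validation splits
#'
#' Only neurotypical subjects are used for training. The cross-validation
#' pool is the largest multiple of 5 strictly below 80% of the retained
#' typicals (366 retained typicals give a pool of 290, hence folds of 58 and
#' 76 evaluation typicals); membership is drawn by seeded shuffle and split
#' into 5 equal folds. The remaining typicals form the evaluation set
#' together with an equally sized seeded sample of atypicals; atypicals left
#' over (e.g. 48 of 124) form the validation set used for ensemble ranking.
#'
#' @param typical_ids Retained neurotypical subject ids.
#' @param atypical_ids Retained neuroatypical subject ids.
#' @param seed Integer seed for the shuffles.
#' @return A list of class `cohort_splits` with `cv_pool`, `folds` (list of
#'   5), `eval_typical`, `eval_atypical`, `validation_atypical`, `seed`.
#' @export
make_splits <- function(typical_ids, atypical_ids, seed = 0L) {
  n <- length(typical_ids)
  if (n < 10) stop("need at least 10 retained typical subjects",
                   call. = FALSE)
  pool_n <- cv_pool_size(n)
  n_eval <- n - pool_n
  if (length(atypical_ids) < n_eval)
    stop(sprintf(paste0("cannot balance evaluation set: need %d atypicals, ",
                        "have %d"), n_eval, length(atypical_ids)),
         call. = FALSE)
  with_seed(seed, {
    typ <- sample(typical_ids)
    cv_pool <- typ[seq_len(pool_n)]
    eval_typical <- typ[(pool_n + 1L):n]
    folds <- split(cv_pool, rep(seq_len(5L), each = pool_n / 5L))
    aty <- sample(atypical_ids)
    eval_atypical <- aty[seq_len(n_eval)]
    validation_atypical <- if (length(aty) > n_eval)
      aty[(n_eval + 1L):length(aty)] else character(0)
    structure(list(cv_pool = cv_pool, folds = unname(folds),
                   eval_typical = eval_typical,
                   eval_atypical = eval_atypical,
                   validation_atypical = validation_atypical,
                   seed = as.integer(seed)),
              class = "cohort_splits")
  })
}

#' @export
print.cohort_splits <- function(x, ...) {
  cat(sprintf(paste0("<cohort_splits> cv pool %d (5 folds of %d), ",
                     "eval %d + %d, validation %d (seed %d)\n"),
              length(x$cv_pool), length(x$folds[[1]]),
              length(x$eval_typical), length(x$eval_atypical),
              length(x$validation_atypical), x$seed))
  invisible(x)
}
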