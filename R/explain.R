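# Local surrogate (LIME-style) explanations of discriminator predictions,
# and their aggregation to mean connection importance and per-ROI
# centrality, stratified by group.

#' Local surrogate explanation of one prediction
#'
#' Tabular-LIME scheme: draw Gaussian perturbations around the sample (per
#' feature, standard deviation = the model's training-data feature sd),
#' score each perturbation with the discriminator, weight perturbations by
#' an exponential kernel on Euclidean distance from the sample, and fit a
#' weighted ridge regression of scores on features. The `k_features`
#' coefficients largest in absolute value are kept as the explanation; the
#' rest are treated as zero. Positive weights mark features that raise the
#' neurotypicality score locally.
#'
#' @param model A fitted `gan_normative`.
#' @param sample Feature vector in [-1, 1] (length `model$n_features`).
#' @param n_perturbations Number of perturbed samples (default 1000).
#' @param kernel_width Kernel width; default `0.75 * sqrt(d)`.
#' @param k_features Number of features retained (default 20).
#' @param ridge Ridge penalty of the surrogate (default 1, the usual LIME
#'   choice).
#' @param seed Integer seed for the perturbation draws.
#' @param subject_id Optional id carried on the result.
#' @return Object of class `lime_explanation`: `weights` (named by feature
#'   index), `intercept`, `local_fit_quality` (weighted R^2 of the
#'   surrogate), `subject_id`, `network`.
#' @export
lime_explain <- function(model, sample, n_perturbations = 1000L,
                         kernel_width = NULL, k_features = 20L,
                         ridge = 1, seed = 0L, subject_id = NA_character_) {
  d <- model$n_features
  stopifnot(length(sample) == d)
  if (n_perturbations < 10 * k_features)
    warning("fewer than 10 perturbations per retained feature; ",
            "surrogate may be unstable")
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(d)
  sds <- model$feature_sd
  sds[sds == 0 | is.na(sds)] <- 1e-6
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_perturbations * d, mean = rep(sample, each =
                  n_perturbations), sd = rep(sds, each = n_perturbations)),
                n_perturbations, d)
    y <- predict(model, X)
    dist2 <- rowSums(sweep(X, 2, sample)^2)
    w <- exp(-dist2 / kernel_width^2)
    # weighted ridge with unpenalized intercept, via centering
    mx <- colSums(X * w) / sum(w)
    my <- sum(y * w) / sum(w)
    Xc <- sweep(X, 2, mx)
    yc <- y - my
    A <- crossprod(Xc * w, Xc) + diag(ridge, d)
    beta <- drop(solve(A, crossprod(Xc * w, yc)))
    intercept <- my - sum(mx * beta)
    fit <- drop(Xc %*% beta)
    denom <- sum(w * yc^2)
    r2 <- if (denom < 1e-12) NA_real_ else 1 - sum(w * (yc - fit)^2) / denom
    keep <- order(abs(beta), decreasing = TRUE)[seq_len(min(k_features, d))]
    weights <- beta[keep]
    names(weights) <- as.character(keep)
    structure(list(subject_id = subject_id, network = model$network,
                   weights = weights, intercept = intercept,
                   local_fit_quality = r2),
              class = "lime_explanation")
  })
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat(sprintf(
    "<lime_explanation> subject %s (%s): %d features, local R^2 %.3f\n",
    x$subject_id, x$network, length(x$weights), x$local_fit_quality))
  invisible(x)
}

#' Mean connection importance across explanations
#'
#' Averages per-feature explanation weights over subjects of one group
#' (features absent from an explanation contribute 0) and reshapes the
#' result onto the network's ROI-by-ROI grid using the package's fixed
#' upper-triangle feature order.
#'
#' @param explanations List of `lime_explanation`s from the same network.
#' @param n_rois Number of ROIs of that network (features = n(n-1)/2).
#' @return Symmetric `n_rois` x `n_rois` matrix of mean importances, zero
#'   diagonal.
#' @export
mean_connection_importance <- function(explanations, n_rois) {
  stopifnot(length(explanations) > 0)
  nets <- unique(vapply(explanations, `[[`, "", "network"))
  if (length(nets) > 1)
    stop("explanations mix networks: ", paste(nets, collapse = ", "),
         call. = FALSE)
  d <- n_rois * (n_rois - 1) / 2
  acc <- numeric(d)
  for (e in explanations) {
    idx <- as.integer(names(e$weights))
    if (any(idx > d))
      stop("explanation feature index exceeds n(n-1)/2; wrong n_rois?",
           call. = FALSE)
    acc[idx] <- acc[idx] + e$weights
  }
  devectorize(acc / length(explanations), n_rois)
}

#' ROI centrality from a connection-importance matrix
#'
#' Centrality of ROI i is the mean importance of its connections: the mean
#' of row i excluding the diagonal. Positive centrality marks ROIs whose
#' connections raised the neurotypicality score; large magnitudes mark
#' candidate local hubs.
#'
#' @param importance Symmetric k x k importance matrix.
#' @return Numeric vector of length k (named if `importance` has rownames).
#' @export
roi_centrality <- function(importance) {
  k <- nrow(importance)
  if (is.null(k) || k < 2 || k != ncol(importance))
    stop("importance must be a square matrix with k >= 2", call. = FALSE)
  (rowSums(importance) - diag(importance)) / (k - 1)
}

#' Group-stratified centrality map for one network
#'
#' Explains every requested subject with [lime_explain()] and aggregates to
#' a per-ROI centrality vector, separately per group so that group
#' differences are not confounded into the map.
#'
#' @param model The network's explaining model (highest individual
#'   accuracy).
#' @param dataset The network's `network_dataset`.
#' @param subjects_by_group Named list of subject-id vectors, e.g.
#'   `list(neurotypical = ..., neuroatypical = ...)`.
#' @param n_rois ROI count of the network.
#' @param roi_ids Optional ROI identifiers for naming the result.
#' @param seed Base seed; each subject derives its own sub-seed.
#' @param ... Passed to [lime_explain()].
#' @return Data frame of class `centrality_map` with columns `roi_id`
#'   (index or id), `network`, `group`, `centrality`.
#' @export
centrality_map <- function(model, dataset, subjects_by_group, n_rois,
                           roi_ids = NULL, seed = 0L, ...) {
  stopifnot(is.list(subjects_by_group), !is.null(names(subjects_by_group)))
  out <- do.call(rbind, lapply(names(subjects_by_group), function(g) {
    ids <- intersect(subjects_by_group[[g]], dataset$retained_ids)
    ex <- lapply(seq_along(ids), function(i)
      lime_explain(model, dataset$features[ids[i], ],
                   seed = seed * 1009L + i, subject_id = ids[i], ...))
    cen <- roi_centrality(mean_connection_importance(ex, n_rois))
    data.frame(roi_id = if (is.null(roi_ids)) as.character(seq_len(n_rois))
               else roi_ids,
               network = dataset$network, group = g, centrality = cen,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  class(out) <- c("centrality_map", "data.frame")
  out
}
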