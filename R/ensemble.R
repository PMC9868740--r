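# Fold selection per architecture, exhaustive enumeration of per-network
# ensembles, exclusion harmonization across member networks, and the two
# decision rules (mean score, majority vote).

#' Fold-out metrics for a trained model
#'
#' Computed on the held-out fifth of the model's cross-validation fold only:
#' the percentage of neurotypicality scores above the threshold and the mean
#' neurotypicality score.
#'
#' @param model A fitted `gan_normative`.
#' @param foldout Feature matrix of the fold-out (neurotypical) subjects.
#' @param threshold Score threshold (default from the model's control).
#' @return List with `pct_above` and `mean_score`.
#' @export
fold_out_metrics <- function(model, foldout,
                             threshold = model$control$score_threshold) {
  s <- predict(model, foldout)
  list(pct_above = mean(s > threshold), mean_score = mean(s))
}

#' Train one architecture across the five cross-validation folds
#'
#' For each fold, trains on the other four fifths of the cross-validation
#' pool and computes fold-out metrics on the held-out fifth. Only subjects
#' retained in the network's dataset are used. Each fold derives its own
#' sub-seed from `control$seed` so folds are independent but reproducible.
#'
#' @param dataset A `network_dataset`.
#' @param splits A `cohort_splits`.
#' @param arch A [gan_architecture()].
#' @param control A [gan_training_config()].
#' @return List of 5 `gan_normative` models, each with a `fold_metrics`
#'   element attached.
#' @export
train_folds <- function(dataset, splits, arch, control) {
  feats <- dataset$features
  lapply(seq_along(splits$folds), function(k) {
    hold <- intersect(splits$folds[[k]], rownames(feats))
    train <- intersect(unlist(splits$folds[-k]), rownames(feats))
    ctl <- control
    ctl$seed <- control$seed * 31L + k
    m <- gan_normative(feats[train, , drop = FALSE], arch, ctl,
                       network = dataset$network, fold_index = k)
    m$fold_metrics <- fold_out_metrics(m, feats[hold, , drop = FALSE])
    m
  })
}

#' Select the representative fold of one architecture
#'
#' Returns the fold model with the best fold-out performance under the
#' chosen criterion. Ties are broken by the other metric, then by the lowest
#' fold index, so selection is deterministic.
#'
#' @param models List of fold models from [train_folds()] (each carrying
#'   `fold_metrics`).
#' @param criterion `"pct_above"` (percentage of fold-out scores above the
#'   threshold) or `"mean_score"`.
#' @return The selected `gan_normative` model.
#' @export
select_fold <- function(models, criterion = c("pct_above", "mean_score")) {
  criterion <- match.arg(criterion)
  other <- setdiff(c("pct_above", "mean_score"), criterion)
  met <- lapply(models, `[[`, "fold_metrics")
  if (any(vapply(met, is.null, TRUE)))
    stop("every model needs fold_metrics; run train_folds()", call. = FALSE)
  primary <- vapply(met, `[[`, 0, criterion)
  secondary <- vapply(met, `[[`, 0, other)
  ord <- order(-primary, -secondary, seq_along(models))
  models[[ord[1]]]
}

#' Enumerate all per-network ensembles
#'
#' All combinations choosing zero or one candidate model per network,
#' excluding the empty combination: with candidate counts k_i this yields
#' prod(k_i + 1) - 1 ensembles (counts {2,2,2,3,4} give 539).
#'
#' @param candidates Named list: network name -> list of candidate models.
#' @return List of `gan_ensemble` objects (members only; eligibility is
#'   attached by [harmonize_exclusions()]).
#' @export
enumerate_ensembles <- function(candidates) {
  stopifnot(length(candidates) > 0)
  counts <- vapply(candidates, length, 0L)
  if (all(counts == 0)) stop("no candidate models", call. = FALSE)
  choices <- lapply(counts, function(k) 0:k)   # 0 = network absent
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- names(candidates)
  keep <- rowSums(grid > 0) > 0
  grid <- grid[keep, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(r) {
    members <- list()
    for (nm in names(candidates)) {
      j <- grid[r, nm]
      if (j > 0) members[[nm]] <- candidates[[nm]][[j]]
    }
    structure(list(members = members, eligible_subjects = NULL),
              class = "gan_ensemble")
  })
}

#' @export
print.gan_ensemble <- function(x, ...) {
  cat(sprintf("<gan_ensemble> %d member(s): %s\n", length(x$members),
              paste(names(x$members), collapse = ", ")))
  if (!is.null(x$eligible_subjects))
    cat(sprintf("  eligible subjects: %d\n", length(x$eligible_subjects)))
  invisible(x)
}

#' Harmonize per-network exclusions for an ensemble
#'
#' A subject excluded during preprocessing of any member network cannot be
#' scored by that member, so the ensemble's eligible set is the intersection
#' of the member networks' retained sets (equivalently, the union of their
#' exclusions is removed).
#'
#' @param ensemble A `gan_ensemble`.
#' @param datasets Named list of `network_dataset`s covering the member
#'   networks.
#' @return The ensemble with `eligible_subjects` filled in.
#' @export
harmonize_exclusions <- function(ensemble, datasets) {
  nets <- names(ensemble$members)
  missing <- setdiff(nets, names(datasets))
  if (length(missing))
    stop("no dataset for network(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  eligible <- Reduce(intersect, lapply(datasets[nets], `[[`, "retained_ids"))
  if (!length(eligible))
    stop("exclusion harmonization left no eligible subjects", call. = FALSE)
  ensemble$eligible_subjects <- eligible
  ensemble
}

# Score every eligible requested subject with every member model.
member_scores <- function(ensemble, datasets, subjects) {
  if (!is.null(ensemble$eligible_subjects)) {
    bad <- setdiff(subjects, ensemble$eligible_subjects)
    if (length(bad))
      stop("subject(s) not eligible for this ensemble: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  sc <- vapply(names(ensemble$members), function(nm) {
    predict(ensemble$members[[nm]],
            datasets[[nm]]$features[subjects, , drop = FALSE])
  }, numeric(length(subjects)))
  if (length(subjects) == 1) sc <- matrix(sc, nrow = 1,
                                          dimnames = list(subjects,
                                                          names(ensemble$members)))
  rownames(sc) <- subjects
  sc
}

#' Ensemble decision rules
#'
#' `decide_mean()` labels a subject neurotypical iff the arithmetic mean of
#' the member scores is strictly above the threshold (a mean of exactly 0.5
#' is neuroatypical). `decide_vote()` gives each member one vote —
#' neurotypical iff its score is strictly above the threshold — and the
#' majority decides, with an exact tie resolved as neuroatypical.
#'
#' @param scores Numeric vector of member neurotypicality scores.
#' @param threshold Score threshold (default 0.5).
#' @return `"neurotypical"` or `"neuroatypical"`.
#' @export
decide_mean <- function(scores, threshold = 0.5) {
  if (mean(scores) > threshold) "neurotypical" else "neuroatypical"
}

#' @rdname decide_mean
#' @export
decide_vote <- function(scores, threshold = 0.5) {
  votes_typ <- sum(scores > threshold)
  if (votes_typ > length(scores) - votes_typ) "neurotypical"
  else "neuroatypical"
}

#' Ensemble predictions
#'
#' Two decision rules. `"mean"`: a subject is neurotypical iff the
#' arithmetic mean of the member scores is strictly above the threshold.
#' `"vote"`: each member casts a neurotypical vote iff its score is strictly
#' above the threshold; the majority decides and an exact tie is resolved as
#' neuroatypical.
#'
#' @param object A `gan_ensemble` (after [harmonize_exclusions()]).
#' @param datasets Named list of `network_dataset`s for the member networks.
#' @param subjects Subject ids to predict (must be eligible).
#' @param strategy `"mean"` or `"vote"`.
#' @param threshold Score threshold (default 0.5).
#' @param ... Unused.
#' @return Data frame with one row per subject: member scores, `aggregate`
#'   (mean score or neurotypical-vote count), and `label`.
#' @export
predict.gan_ensemble <- function(object, datasets, subjects,
                                 strategy = c("mean", "vote"),
                                 threshold = 0.5, ...) {
  strategy <- match.arg(strategy)
  sc <- member_scores(object, datasets, subjects)
  if (strategy == "mean") {
    agg <- rowMeans(sc)
    label <- apply(sc, 1, decide_mean, threshold = threshold)
  } else {
    agg <- rowSums(sc > threshold)            # neurotypical votes
    label <- apply(sc, 1, decide_vote, threshold = threshold)
  }
  out <- data.frame(subject_id = subjects, sc, aggregate = unname(agg),
                    label = unname(label), row.names = NULL,
                    check.names = FALSE)
  out
}

#' Rank ensembles on the validation (all-neuroatypical) set
#'
#' Primary criterion: the fraction of eligible validation subjects the
#' ensemble labels neuroatypical (detection rate). Ties are broken by the
#' mean fold-out neurotypicality score across the ensemble's members (higher
#' first), then by the lexicographic member signature, so the order is
#' deterministic.
#'
#' @param ensembles List of harmonized `gan_ensemble`s.
#' @param datasets Named list of `network_dataset`s.
#' @param validation_ids Neuroatypical validation subject ids.
#' @param strategy `"mean"` or `"vote"`.
#' @param threshold Score threshold.
#' @return The ensembles reordered best-first, each with
#'   `validation_detection` attached.
#' @export
rank_ensembles <- function(ensembles, datasets, validation_ids,
                           strategy = c("mean", "vote"), threshold = 0.5) {
  strategy <- match.arg(strategy)
  if (!length(validation_ids)) stop("empty validation set", call. = FALSE)
  stats_tab <- lapply(ensembles, function(e) {
    ids <- intersect(validation_ids,
                     e$eligible_subjects %||% validation_ids)
    pred <- predict(e, datasets, ids, strategy = strategy,
                    threshold = threshold)
    det <- mean(pred$label == "neuroatypical")
    fo <- mean(vapply(e$members,
                      function(m) m$fold_metrics$mean_score, 0))
    sig <- paste(names(e$members),
                 vapply(e$members, function(m)
                   sprintf("%s/f%d", m$arch$name, m$fold_index), ""),
                 collapse = "|")
    list(det = det, fo = fo, sig = sig)
  })
  det <- vapply(stats_tab, `[[`, 0, "det")
  fo <- vapply(stats_tab, `[[`, 0, "fo")
  sig <- vapply(stats_tab, `[[`, "", "sig")
  ord <- order(-det, -fo, sig)
  out <- ensembles[ord]
  for (i in seq_along(out)) out[[i]]$validation_detection <- det[ord[i]]
  out
}
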