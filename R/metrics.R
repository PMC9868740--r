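# Confusion-matrix metrics and the permutation test of balanced accuracy.
# The positive (detection-target) class is neuroatypical; specificity
# therefore tracks the neurotypical class.

balanced_accuracy_of <- function(predictions, truth) {
  sens <- if (any(truth == "neuroatypical"))
    mean(predictions[truth == "neuroatypical"] == "neuroatypical") else NA_real_
  spec <- if (any(truth == "neurotypical"))
    mean(predictions[truth == "neurotypical"] == "neurotypical") else NA_real_
  (sens + spec) / 2
}

#' Classification metrics for typical/atypical predictions
#'
#' Standard contingency-table metrics with neuroatypical as the positive
#' class: sensitivity is the fraction of atypicals detected, specificity the
#' fraction of typicals correctly kept, and balanced accuracy their mean. A
#' metric whose defining class or prediction is absent is reported as `NA`,
#' not 0.
#'
#' @param predictions Character vector of `"neurotypical"` /
#'   `"neuroatypical"` labels.
#' @param truth Character vector of true labels, same length.
#' @return List of class `evaluation_report` with `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `balanced_accuracy`, and the raw counts.
#' @export
compute_metrics <- function(predictions, truth) {
  stopifnot(length(predictions) == length(truth))
  lv <- c("neurotypical", "neuroatypical")
  if (!all(c(predictions, truth) %in% lv))
    stop("labels must be 'neurotypical' or 'neuroatypical'", call. = FALSE)
  tp <- sum(predictions == "neuroatypical" & truth == "neuroatypical")
  tn <- sum(predictions == "neurotypical" & truth == "neurotypical")
  fp <- sum(predictions == "neuroatypical" & truth == "neurotypical")
  fn <- sum(predictions == "neurotypical" & truth == "neuroatypical")
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  structure(list(accuracy = (tp + tn) / length(truth),
                 sensitivity = sens, specificity = spec,
                 ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
                 balanced_accuracy = (sens + spec) / 2,
                 counts = c(tp = tp, tn = tn, fp = fp, fn = fn)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report (positive class: neuroatypical)\n")
  fmt <- function(v) ifelse(is.na(v), "  NA", sprintf("%.3f", v))
  cat(sprintf("  accuracy          %s\n", fmt(x$accuracy)))
  cat(sprintf("  sensitivity       %s\n", fmt(x$sensitivity)))
  cat(sprintf("  specificity       %s\n", fmt(x$specificity)))
  cat(sprintf("  PPV               %s\n", fmt(x$ppv)))
  cat(sprintf("  NPV               %s\n", fmt(x$npv)))
  cat(sprintf("  balanced accuracy %s\n", fmt(x$balanced_accuracy)))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p     %s (%d permutations)\n",
                fmt(x$p_value), x$n_permutations))
  invisible(x)
}

#' Permutation p-value of the balanced accuracy
#'
#' Tests the observed balanced accuracy against the null of
#' label-independent predictions by shuffling the true labels. With the
#' default `replace = FALSE` the labels are permuted without replacement
#' (class counts preserved); `replace = TRUE` resamples them with
#' replacement instead. The add-one estimator
#' p = (1 + #\{permuted BA >= observed BA\}) / (n_permutations + 1)
#' avoids zero p-values.
#'
#' @param predictions,truth Label vectors as in [compute_metrics()].
#' @param n_permutations Number of label shuffles (>= 100).
#' @param seed Integer seed for the shuffles.
#' @param replace Resample labels with replacement instead of permuting.
#' @return Numeric p-value in (0, 1].
#' @export
permutation_pvalue <- function(predictions, truth, n_permutations = 10000L,
                               seed = 0L, replace = FALSE) {
  if (n_permutations < 100) stop("n_permutations must be >= 100",
                                 call. = FALSE)
  if (length(unique(truth)) < 2)
    stop("permutation test needs both classes in the truth labels",
         call. = FALSE)
  obs <- balanced_accuracy_of(predictions, truth)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_permutations)) {
      perm <- sample(truth, replace = replace)
      ba <- balanced_accuracy_of(predictions, perm)
      if (!is.na(ba) && ba >= obs) hits <- hits + 1L
    }
    (1 + hits) / (n_permutations + 1)
  })
}

#' Full evaluation with permutation test
#'
#' Convenience wrapper: [compute_metrics()] plus [permutation_pvalue()].
#'
#' @inheritParams permutation_pvalue
#' @param alpha Significance level recorded on the report (default 0.05).
#' @return An `evaluation_report` with `p_value`, `n_permutations`, `alpha`
#'   and `seed` filled in.
#' @export
evaluate_predictions <- function(predictions, truth,
                                 n_permutations = 10000L, seed = 0L,
                                 alpha = 0.05, replace = FALSE) {
  rep <- compute_metrics(predictions, truth)
  rep$p_value <- permutation_pvalue(predictions, truth, n_permutations,
                                    seed, replace)
  rep$n_permutations <- as.integer(n_permutations)
  rep$alpha <- alpha
  rep$seed <- as.integer(seed)
  rep
}
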