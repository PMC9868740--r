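# End-to-end driver: simulate (or accept) a cohort, transform and clean per
# network, split, train per-network candidates across folds, enumerate and
# rank ensembles, evaluate the best one with a permutation test, and map
# explanation-based ROI centrality.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the cohort to simulate, or `NULL`
#'   when `data` is supplied to [run_pipeline()] directly.
#' @param cleaning A [cleaning_params()].
#' @param architectures Named list: network name -> list of
#'   [gan_architecture()] candidates. The full-scale operating point uses 2
#'   candidates each for Default, VentralAttn and CO+SN, 3 for
#'   FrontoParietal and 4 for DorsalAttn.
#' @param training A [gan_training_config()].
#' @param strategy Ensemble decision rule, `"mean"` or `"vote"`.
#' @param criterion Fold-selection criterion, `"pct_above"` or
#'   `"mean_score"`.
#' @param n_permutations Permutations for the evaluation p-value.
#' @param explain_subjects Maximum evaluation subjects explained per group
#'   per network (explanations dominate run time; `Inf` explains all).
#' @param lime Named list of overrides passed to [lime_explain()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            cleaning = cleaning_params(),
                            architectures = NULL,
                            training = gan_training_config(),
                            strategy = c("vote", "mean"),
                            criterion = c("pct_above", "mean_score"),
                            n_permutations = 1000L,
                            explain_subjects = Inf,
                            lime = list()) {
  strategy <- match.arg(strategy)
  criterion <- match.arg(criterion)
  if (is.null(architectures)) {
    nets <- if (!is.null(sim)) names(sim$network_sizes) else RSBFN_NAMES
    architectures <- stats::setNames(
      lapply(nets, function(n) list(reference_architecture())), nets)
  }
  structure(list(sim = sim, cleaning = cleaning,
                 architectures = architectures, training = training,
                 strategy = strategy, criterion = criterion,
                 n_permutations = as.integer(n_permutations),
                 explain_subjects = explain_subjects, lime = lime),
            class = "pipeline_config")
}

#' Scale presets for the pipeline
#'
#' `desk_profile()` is a reduced-scale study that runs end to end in minutes
#' on one CPU: five 16-ROI networks (120 intra-network features each, within
#' the same order as the smallest published network subset), 200 typical and
#' 80 atypical subjects at 400 timepoints, a strong hub perturbation
#' (delta = -0.4), one reference architecture per network, a 500-epoch stop
#' window, vote strategy, and a trimmed explanation stage.
#' `full_profile()` mirrors the originally reported operating point: the full cohort
#' scale (377/126 at 180 volumes), 24-40-ROI networks, candidate
#' architecture counts 2/2/2/3/4 for Default, VentralAttn, CO+SN,
#' FrontoParietal and DorsalAttn, and the 15,000-epoch stop window. It is
#' provided for completeness and takes hours.
#'
#' @param seed Simulation seed recorded in the configuration.
#' @return A [pipeline_config()].
#' @export
desk_profile <- function(seed = 0L) {
  nets <- RSBFN_NAMES
  pipeline_config(
    sim = sim_config(
      network_sizes = stats::setNames(rep(16L, 5), nets),
      n_typical = 200, n_atypical = 80, timepoints = 400,
      within_r = 0.35, between_r = 0.10,
      hub_fraction = 0.2, perturbation_delta = -0.4, seed = seed),
    architectures = stats::setNames(
      lapply(nets, function(n) list(reference_architecture())), nets),
    training = gan_training_config(stop_window = 500L, max_epochs = 6000L),
    strategy = "vote", n_permutations = 500L,
    explain_subjects = 30,
    lime = list(n_perturbations = 800L, k_features = 40L))
}

#' @rdname desk_profile
#' @export
full_profile <- function(seed = 0L) {
  ref <- reference_architecture()
  deep <- gan_architecture("deep-100/100-50-25", 100L, c(100L, 50L, 25L),
                           dropout_rate = 0.6)
  rect <- gan_architecture("rect-100/50-50", 100L, c(50L, 50L),
                           dropout_rate = 0.5, shape = "rectangular")
  wide <- gan_architecture("wide-300/150-75-35", 300L, c(150L, 75L, 35L),
                           dropout_rate = 0.5)
  pipeline_config(
    sim = sim_config(seed = seed),
    architectures = list(
      Default = list(ref, deep),
      VentralAttn = list(ref, deep),
      "CO+SN" = list(ref, deep),
      FrontoParietal = list(ref, deep, rect),
      DorsalAttn = list(ref, deep, rect, wide)),
    training = gan_training_config(),
    strategy = "vote", n_permutations = 10000L)
}

#' Run the full normative-modeling pipeline
#'
#' Stages: (1) obtain raw-r connectivity matrices (simulated from
#' `config$sim`, or passed in `data` as the list returned by
#' [simulate_cohort()] / assembled from [read_matrices()] etc.); (2) Fisher
#' transform; (3) per network: subset to intra-network features, clip/scale,
#' apply the exclusion rule; (4) build splits from the subjects retained in
#' every modeled network; (5) per network and architecture, train the five
#' fold models and select a representative fold; (6) enumerate, harmonize
#' and rank all ensembles on the validation atypicals; (7) evaluate the
#' best ensemble on the balanced evaluation set with a permutation test of
#' balanced accuracy; (8) explain the best individual model per network on
#' the evaluation subjects and derive group-stratified ROI centrality.
#' Deterministic given `seed`.
#'
#' @param config A [pipeline_config()].
#' @param data Optional pre-built cohort (list with `matrices`, `cohort`,
#'   `parcellation`, optionally `hubs`); when `NULL`, `config$sim` is
#'   simulated.
#' @param seed Master seed for splits, training, permutations and
#'   explanations.
#' @param verbose Print stage progress.
#' @return List of class `pipeline_result`: `report` (the
#'   `evaluation_report`), `best_ensemble`, `ranked_detection` (validation
#'   detection rates), `centrality` (a `centrality_map` data frame),
#'   `splits`, `datasets`, `candidates`, `hubs`, `predictions`.
#' @export
run_pipeline <- function(config, data = NULL, seed = 0L, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(data)) {
    cfg <- config$sim
    cfg$seed <- cfg$seed + seed
    say("simulating cohort (%d typical, %d atypical)",
        cfg$n_typical, cfg$n_atypical)
    data <- simulate_cohort(cfg)
  }
  parc <- data$parcellation
  nets <- names(config$architectures)
  unknown <- setdiff(nets, unique(parc$network))
  if (length(unknown))
    stop("config references network(s) absent from the parcellation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  say("Fisher transform (%d subjects)", length(data$matrices))
  zmats <- lapply(data$matrices, fisher_transform)
  say("per-network cleaning")
  datasets <- stats::setNames(lapply(nets, function(nm)
    network_dataset(zmats, parc, nm, config$cleaning)), nets)
  retained_all <- Reduce(intersect, lapply(datasets, `[[`, "retained_ids"))
  groups <- stats::setNames(data$cohort$group, data$cohort$subject_id)
  typ <- retained_all[groups[retained_all] == "neurotypical"]
  aty <- retained_all[groups[retained_all] == "neuroatypical"]
  splits <- make_splits(typ, aty, seed = seed)
  say("splits: cv %d, eval %d+%d, validation %d", length(splits$cv_pool),
      length(splits$eval_typical), length(splits$eval_atypical),
      length(splits$validation_atypical))
  train_ctl <- config$training
  candidates <- stats::setNames(vector("list", length(nets)), nets)
  for (nm in nets) {
    archs <- config$architectures[[nm]]
    candidates[[nm]] <- lapply(seq_along(archs), function(ai) {
      say("training %s, architecture %d/%d (%d features)",
          nm, ai, length(archs), ncol(datasets[[nm]]$features))
      ctl <- train_ctl
      ctl$seed <- (train_ctl$seed + seed) * 131L +
        match(nm, nets) * 17L + ai
      folds <- train_folds(datasets[[nm]], splits, archs[[ai]], ctl)
      select_fold(folds, config$criterion)
    })
  }
  say("enumerating ensembles")
  ensembles <- enumerate_ensembles(candidates)
  ensembles <- lapply(ensembles, harmonize_exclusions, datasets = datasets)
  ranked <- rank_ensembles(ensembles, datasets, splits$validation_atypical,
                           strategy = config$strategy)
  best <- ranked[[1]]
  eval_ids <- intersect(c(splits$eval_typical, splits$eval_atypical),
                        best$eligible_subjects)
  pred <- predict(best, datasets, eval_ids, strategy = config$strategy)
  truth <- unname(groups[eval_ids])
  report <- evaluate_predictions(pred$label, truth,
                                 n_permutations = config$n_permutations,
                                 seed = seed)
  say("balanced accuracy %.3f (p = %.4f)", report$balanced_accuracy,
      report$p_value)
  # explanation stage: best individual (single-model) accuracy per network
  say("explanations")
  centrality <- do.call(rbind, lapply(nets, function(nm) {
    cand <- candidates[[nm]]
    acc <- vapply(cand, function(m) {
      ids <- intersect(eval_ids, datasets[[nm]]$retained_ids)
      s <- predict(m, datasets[[nm]]$features[ids, , drop = FALSE])
      lab <- ifelse(s > train_ctl$score_threshold, "neurotypical",
                    "neuroatypical")
      mean(lab == groups[ids])
    }, 0)
    model <- cand[[which.max(acc)]]
    ids_g <- list(
      neurotypical = utils::head(
        intersect(splits$eval_typical, datasets[[nm]]$retained_ids),
        config$explain_subjects),
      neuroatypical = utils::head(
        intersect(splits$eval_atypical, datasets[[nm]]$retained_ids),
        config$explain_subjects))
    k <- sum(parc$network == nm)
    do.call(centrality_map,
            c(list(model = model, dataset = datasets[[nm]],
                   subjects_by_group = ids_g, n_rois = k,
                   roi_ids = parc$roi_id[parc$network == nm],
                   seed = seed + match(nm, nets)),
              config$lime))
  }))
  class(centrality) <- c("centrality_map", "data.frame")
  structure(list(report = report, best_ensemble = best,
                 ranked_detection = vapply(ranked, `[[`, 0,
                                           "validation_detection"),
                 predictions = pred, centrality = centrality,
                 splits = splits, datasets = datasets,
                 candidates = candidates, hubs = data$hubs,
                 parcellation = parc, seed = seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> best ensemble: %d member(s) [%s]\n",
              length(x$best_ensemble$members),
              paste(names(x$best_ensemble$members), collapse = ", ")))
  print(x$report)
  invisible(x)
}

#' Fraction of ground-truth hubs ranked as high-centrality
#'
#' For simulated cohorts with known perturbed hubs: the fraction of
#' ground-truth hub ROIs whose atypical-group |centrality| falls in the top
#' quartile of their network's |centrality| distribution.
#'
#' @param result A `pipeline_result` from a simulated cohort.
#' @param group Which group's centrality map to use (default
#'   neuroatypical).
#' @return Numeric scalar in [0, 1].
#' @export
hub_recovery <- function(result, group = "neuroatypical") {
  stopifnot(!is.null(result$hubs))
  cen <- result$centrality[result$centrality$group == group, ]
  hits <- 0L
  total <- 0L
  for (nm in unique(cen$network)) {
    cn <- cen[cen$network == nm, ]
    cut <- stats::quantile(abs(cn$centrality), 0.75, names = FALSE)
    top <- cn$roi_id[abs(cn$centrality) >= cut]
    h <- intersect(result$hubs, cn$roi_id)
    hits <- hits + length(intersect(h, top))
    total <- total + length(h)
  }
  if (total == 0) return(NA_real_)
  hits / total
}
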