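test_that("fold selection takes the argmax with deterministic tiebreaks", {
  ms <- Map(fake_model, c(0.9, 0.8, 0.7, 0.6, 0.5),
            c(0.5, 0.5, 0.5, 0.5, 0.5), 1:5)
  expect_equal(select_fold(ms, "pct_above")$fold_index, 1L)

  tie <- Map(fake_model, rep(0.8, 5), c(0.6, 0.7, 0.65, 0.7, 0.5), 1:5)
  expect_equal(select_fold(tie, "pct_above")$fold_index, 2L)  # 0.7, lowest

  set.seed(77)
  for (i in 1:30) {
    pct <- sample(seq(0, 1, 0.25), 5, replace = TRUE)
    msc <- sample(seq(0.1, 0.9, 0.2), 5, replace = TRUE)
    ms <- Map(fake_model, pct, msc, 1:5)
    picked <- select_fold(ms, "mean_score")$fold_index
    # brute-force argmax with stated tiebreaks
    best <- which(msc == max(msc))
    if (length(best) > 1) best <- best[pct[best] == max(pct[best])]
    expect_equal(picked, min(best))
  }

  expect_error(select_fold(list(list(fold_metrics = NULL)), "pct_above"),
               "fold_metrics")
})

test_that("ensemble enumeration counts 0-or-1 choices per network", {
  cands <- function(k) lapply(seq_len(k), function(i) fake_model(0.5, 0.5, i))
  paperlike <- list(Default = cands(2), VentralAttn = cands(2),
                    "CO+SN" = cands(2), FrontoParietal = cands(3),
                    DorsalAttn = cands(4))
  ens <- enumerate_ensembles(paperlike)
  expect_length(ens, 539)
  expect_equal(prod(c(2, 2, 2, 3, 4) + 1) - 1, 539)
  expect_true(all(vapply(ens, function(e) length(e$members) >= 1, TRUE)))

  expect_length(enumerate_ensembles(list(A = cands(1))), 1)
  expect_length(enumerate_ensembles(list(A = cands(2), B = cands(3))), 11)

  set.seed(3)
  for (i in 1:10) {
    ks <- sample(0:4, sample(2:4, 1), replace = TRUE)
    if (all(ks == 0)) ks[1] <- 1
    names(ks) <- paste0("n", seq_along(ks))
    got <- enumerate_ensembles(lapply(ks, cands))
    expect_length(got, prod(ks + 1) - 1)
    # signatures unique: enumeration has no duplicates
    sig <- vapply(got, function(e)
      paste(names(e$members),
            vapply(e$members, `[[`, 0L, "fold_index"), collapse = "|"), "")
    expect_equal(anyDuplicated(sig), 0L)
  }
})

test_that("exclusion harmonization intersects retained sets", {
  mk_ds <- function(net, retained) structure(
    list(network = net, retained_ids = retained,
         excluded_ids = setdiff(c("A", "B", "C", "D"), retained)),
    class = "network_dataset")
  e <- structure(list(members = list(net1 = fake_model(0.5, 0.5),
                                     net2 = fake_model(0.5, 0.5))),
                 class = "gan_ensemble")

  same <- list(net1 = mk_ds("net1", c("A", "B", "C")),
               net2 = mk_ds("net2", c("A", "B", "C")))
  expect_setequal(harmonize_exclusions(e, same)$eligible_subjects,
                  c("A", "B", "C"))

  # A excluded in net1, B excluded in net2 -> both ineligible
  cross <- list(net1 = mk_ds("net1", c("B", "C", "D")),
                net2 = mk_ds("net2", c("A", "C", "D")))
  expect_setequal(harmonize_exclusions(e, cross)$eligible_subjects,
                  c("C", "D"))

  set.seed(5)
  subj <- sprintf("s%02d", 1:20)
  for (i in 1:15) {
    r1 <- sample(subj, 15)
    r2 <- sample(subj, 15)
    ds <- list(net1 = structure(list(network = "net1", retained_ids = r1),
                                class = "network_dataset"),
               net2 = structure(list(network = "net2", retained_ids = r2),
                                class = "network_dataset"))
    expect_setequal(harmonize_exclusions(e, ds)$eligible_subjects,
                    intersect(r1, r2))
  }

  none <- list(net1 = mk_ds("net1", "A"), net2 = mk_ds("net2", "B"))
  expect_error(harmonize_exclusions(e, none), "no eligible")
  expect_error(harmonize_exclusions(e, same["net1"]), "net2")
})

test_that("mean and vote decision rules follow the strict-threshold
           conventions", {
  expect_equal(decide_mean(c(0.9, 0.2)), "neurotypical")      # mean 0.55
  expect_equal(decide_mean(0.5), "neuroatypical")             # boundary
  expect_equal(decide_vote(c(0.9, 0.2)), "neuroatypical")     # 1-1 tie
  expect_equal(decide_vote(c(0.9, 0.8, 0.2)), "neurotypical") # 2-1

  # exhaustive vote patterns for up to 5 members
  for (k in 1:5) {
    grid <- expand.grid(rep(list(c(0.1, 0.9)), k))
    for (r in seq_len(nrow(grid))) {
      sc <- as.numeric(grid[r, ])
      nt <- sum(sc > 0.5)
      expect_equal(decide_vote(sc),
                   if (nt > k - nt) "neurotypical" else "neuroatypical")
    }
  }

  # random tuples against brute-force mean comparison
  set.seed(9)
  for (i in 1:50) {
    sc <- runif(sample(1:6, 1))
    expect_equal(decide_mean(sc),
                 if (mean(sc) > 0.5) "neurotypical" else "neuroatypical")
  }

  # single-member ensembles: the two strategies agree
  for (s in c(0.2, 0.5, 0.50001, 0.8))
    expect_equal(decide_mean(s), decide_vote(s))
})

test_that("ensemble ranking orders by detection then fold-out score", {
  # build two controllable linear scorers on 3 features
  ds <- structure(list(
    network = "Default",
    features = matrix(c(0.8, 0.8, -0.8, -0.8), 4, 3,
                      dimnames = list(c("v1", "v2", "v3", "v4"), NULL)),
    retained_ids = c("v1", "v2", "v3", "v4"),
    excluded_ids = character(0)), class = "network_dataset")
  strong <- linear_scorer(c(5, 5, 5))     # hates negative features
  weak <- linear_scorer(c(-0.1, 0, 0))   # scores everyone ~0.52
  strong$fold_metrics <- list(pct_above = 1, mean_score = 0.9)
  weak$fold_metrics <- list(pct_above = 1, mean_score = 0.6)
  e1 <- structure(list(members = list(Default = strong),
                       eligible_subjects = ds$retained_ids),
                  class = "gan_ensemble")
  e2 <- structure(list(members = list(Default = weak),
                       eligible_subjects = ds$retained_ids),
                  class = "gan_ensemble")
  # validation = all-atypical subjects v3, v4 (negative features):
  # strong detects both, weak detects none
  ranked <- rank_ensembles(list(e2, e1), list(Default = ds),
                           c("v3", "v4"), strategy = "vote")
  expect_equal(ranked[[1]]$validation_detection, 1)
  expect_identical(names(ranked[[1]]$members[[1]]$fold_metrics),
                   c("pct_above", "mean_score"))
  expect_equal(ranked[[1]]$members$Default$fold_metrics$mean_score, 0.9)

  # equal detection -> higher mean fold-out neurotypicality score first
  strong2 <- linear_scorer(c(5, 5, 5))
  strong2$fold_metrics <- list(pct_above = 1, mean_score = 0.7)
  e3 <- structure(list(members = list(Default = strong2),
                       eligible_subjects = ds$retained_ids),
                  class = "gan_ensemble")
  ranked2 <- rank_ensembles(list(e3, e1), list(Default = ds),
                            c("v3", "v4"), strategy = "vote")
  expect_equal(ranked2[[1]]$members$Default$fold_metrics$mean_score, 0.9)

  expect_error(rank_ensembles(list(e1), list(Default = ds), character(0)),
               "empty validation")
})

test_that("ensemble predictions join member scores per the chosen rule", {
  ds <- structure(list(
    network = "Default",
    features = matrix(c(0.9, -0.9), 2, 2,
                      dimnames = list(c("t1", "a1"), NULL)),
    retained_ids = c("t1", "a1"), excluded_ids = character(0)),
    class = "network_dataset")
  m <- linear_scorer(c(4, 4))
  ens <- structure(list(members = list(Default = m),
                        eligible_subjects = c("t1", "a1")),
                   class = "gan_ensemble")
  pred <- predict(ens, list(Default = ds), c("t1", "a1"), strategy = "vote")
  expect_equal(pred$label, c("neurotypical", "neuroatypical"))
  predm <- predict(ens, list(Default = ds), c("t1", "a1"),
                   strategy = "mean")
  expect_equal(predm$label, pred$label)   # single member: strategies agree

  expect_error(predict(ens, list(Default = ds), "missing"), "eligible")
})
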