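test_that("network subsetting picks exactly the intra-network features", {
  p24 <- parcellation(sprintf("r%03d", 1:30),
                      rep(c("Default", "DorsalAttn"), c(24, 6)))
  expect_length(network_feature_index(p24, "Default"), 276)

  p1 <- parcellation(c("a", "b"), c("Default", "DorsalAttn"))
  expect_length(network_feature_index(p1, "Default"), 0)

  # brute-force oracle over the global pair order, and disjointness
  parc <- tiny_parcellation(c(Default = 4, DorsalAttn = 3))
  n <- 7
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
  for (net in c("Default", "DorsalAttn")) {
    oracle <- which(parc$network[pairs[, 1]] == net &
                      parc$network[pairs[, 2]] == net)
    expect_equal(network_feature_index(parc, net), oracle)
  }
  expect_length(intersect(network_feature_index(parc, "Default"),
                          network_feature_index(parc, "DorsalAttn")), 0)

  expect_error(network_feature_index(parc, "Visual"), "unknown network")

  # matrix subsetting induces the same columns
  m <- matrix(seq_len(2 * 21), 2, 21)
  expect_equal(subset_network(m, parc, "Default"),
               m[, network_feature_index(parc, "Default")])
})

test_that("cleaning clips at +/-2, rescales to [-1,1], counts modified cells", {
  params <- cleaning_params()
  x <- matrix(c(2.5, 0, -3, 1), 1)
  rownames(x) <- "s1"
  got <- clean_features(x, params)
  expect_equal(got$features[1, ], c(1, 0, -1, 0.5))
  expect_equal(unname(got$modified_fraction), 0.5)

  x0 <- matrix(0, 2, 5, dimnames = list(c("a", "b"), NULL))
  got0 <- clean_features(x0, params)
  expect_equal(unname(got0$modified_fraction), c(0, 0))

  # 4 of 20 cells out of range -> 0.20
  x4 <- matrix(0.3, 1, 20)
  x4[1, 1:4] <- c(2.3, -2.2, 5, -9)
  expect_equal(unname(clean_features(x4, params)$modified_fraction), 0.20)

  # re-cleaning cleaned values clips nothing and stays in range
  twice <- clean_features(got$features, params)
  expect_equal(unname(twice$modified_fraction), 0)
  expect_true(all(abs(twice$features) <= 1))

  xb <- matrix(c(1, NA), 1, dimnames = list("s9", NULL))
  expect_error(clean_features(xb, params), "s9")
})

test_that("cleaning matches a brute-force oracle on random data", {
  set.seed(42)
  params <- cleaning_params()
  x <- matrix(rnorm(200 * 30, sd = 1.5), 200, 30,
              dimnames = list(sprintf("s%03d", 1:200), NULL))
  got <- clean_features(x, params)
  ds <- apply_exclusion("Default", got, params)
  # element-by-element oracle
  oracle_feat <- x
  oracle_frac <- numeric(200)
  for (i in 1:200) {
    modified <- 0
    for (j in 1:30) {
      v <- x[i, j]
      if (v > 2) { v <- 2; modified <- modified + 1 }
      if (v < -2) { v <- -2; modified <- modified + 1 }
      oracle_feat[i, j] <- v / 2
    }
    oracle_frac[i] <- modified / 30
  }
  expect_equal(got$features, oracle_feat)
  expect_equal(unname(got$modified_fraction), oracle_frac)
  expect_true(all(abs(got$features) <= 1))
  expect_setequal(ds$excluded_ids, rownames(x)[oracle_frac > 0.15])
  expect_setequal(union(ds$retained_ids, ds$excluded_ids), rownames(x))
})

test_that("exclusion is strict: more than 15% modified cells", {
  params <- cleaning_params()
  frac <- c(a = 0.16, b = 0.15, c = 0, d = 0.3)
  cleaned <- list(features = matrix(0, 4, 10,
                                    dimnames = list(names(frac), NULL)),
                  modified_fraction = frac)
  ds <- apply_exclusion("Default", cleaned, params)
  expect_setequal(ds$excluded_ids, c("a", "d"))
  expect_setequal(ds$retained_ids, c("b", "c"))
})

test_that("a subject can be excluded in one network and kept in another", {
  parc <- tiny_parcellation(c(Default = 3, DorsalAttn = 3))
  mk <- function(id, default_val) {
    z <- matrix(0.1, 6, 6)
    z[1:3, 1:3] <- default_val   # Default block extreme for one subject
    diag(z) <- 0
    z <- (z + t(z)) / 2
    connectivity_matrix(z, id, state = "fisher-z")
  }
  mats <- list(mk("ok", 0.2), mk("outlier", 3), mk("ok2", 0.3))
  d_def <- network_dataset(mats, parc, "Default")
  d_dor <- network_dataset(mats, parc, "DorsalAttn")
  expect_true("outlier" %in% d_def$excluded_ids)
  expect_true("outlier" %in% d_dor$retained_ids)
})

test_that("split sizes reproduce the published arithmetic", {
  typ <- sprintf("t%03d", 1:366)
  aty <- sprintf("a%03d", 1:124)
  sp <- make_splits(typ, aty, seed = 0)
  expect_length(sp$cv_pool, 290)
  expect_length(sp$folds, 5)
  expect_true(all(lengths(sp$folds) == 58))
  expect_length(sp$eval_typical, 76)
  expect_length(sp$eval_atypical, 76)
  expect_length(sp$validation_atypical, 48)
})

test_that("splits partition subjects with the multiple-of-5 rule", {
  sp100 <- make_splits(sprintf("t%03d", 1:100), sprintf("a%03d", 1:40),
                       seed = 2)
  expect_length(sp100$cv_pool, 75)   # largest multiple of 5 < 80

  for (n in c(37, 150, 366)) {
    typ <- sprintf("t%04d", seq_len(n))
    aty <- sprintf("a%04d", seq_len(n))   # plenty of atypicals
    sp <- make_splits(typ, aty, seed = n)
    expect_equal(length(sp$cv_pool) %% 5, 0)
    expect_lt(length(sp$cv_pool), 0.8 * n)
    expect_gte(length(sp$cv_pool) + 5, 0.8 * n)
    expect_setequal(unlist(sp$folds), sp$cv_pool)
    expect_length(intersect(sp$eval_typical, sp$cv_pool), 0)
    expect_equal(length(sp$eval_typical) + length(sp$cv_pool), n)
    expect_equal(length(sp$eval_atypical), length(sp$eval_typical))
    expect_length(intersect(sp$eval_atypical, sp$validation_atypical), 0)
  }

  expect_error(make_splits(sprintf("t%02d", 1:50), c("a1", "a2"), 1),
               "cannot balance")
  # same seed reproduces the same membership
  expect_identical(make_splits(sprintf("t%03d", 1:80), sprintf("a%02d", 1:30),
                               seed = 7),
                   make_splits(sprintf("t%03d", 1:80), sprintf("a%02d", 1:30),
                               seed = 7))
})
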