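test_that("architecture constraints are enforced", {
  ref <- reference_architecture()
  expect_equal(ref$generator_hidden, 200L)
  expect_equal(ref$discriminator_hidden, c(75L, 50L, 25L))
  expect_equal(ref$dropout_rate, 0.5)
  expect_equal(ref$latent_dim, 100L)

  expect_error(gan_architecture("r", c(64, 32), 64, shape = "rectangular"),
               "rectangular")
  expect_error(gan_architecture("t", 64, c(50, 50, 25),
                                shape = "triangular"), "triangular")
  expect_error(gan_architecture("d", 64, 32, dropout_rate = 0.2),
               "dropout")
})

test_that("untrained networks respect their activation ranges", {
  arch <- tiny_arch()
  set.seed(5)
  gen <- gannorm:::gen_init(arch$latent_dim, arch$generator_hidden, 12)
  disc <- gannorm:::disc_init(12, arch$discriminator_hidden,
                              arch$dropout_rate, input_dropout = FALSE)
  x <- matrix(runif(40 * 12, -3, 3), 40)
  p <- gannorm:::disc_forward(disc, x)$p
  expect_true(all(p > 0 & p < 1))
  z <- matrix(rnorm(40 * arch$latent_dim), 40)
  g <- gannorm:::gen_forward(gen, z)$out
  expect_true(all(g >= -1 & g <= 1))
})

test_that("stop criterion matches a brute-force rolling-sd oracle", {
  ctl <- list(stop_window = 10L, stop_std_threshold = 0.01)
  expect_false(stop_criterion(rep(0.5, 9), ctl))
  expect_true(stop_criterion(rep(0.5, 10), ctl))   # fires exactly at window
  expect_false(stop_criterion(rep(c(0, 1), 20), ctl))

  set.seed(11)
  for (rep_i in 1:20) {
    h <- cumsum(rnorm(60, sd = 0.05))
    h <- pmin(pmax(0.5 + h, 0), 1)
    fired_at <- NA
    for (e in seq_along(h)) {
      if (stop_criterion(h[seq_len(e)], ctl)) { fired_at <- e; break }
    }
    oracle <- NA
    for (e in 10:60) {
      if (sd(h[(e - 9):e]) < 0.01) { oracle <- e; break }
    }
    expect_identical(fired_at, oracle)
  }
})

test_that("training is reproducible and anomaly-separating on easy data", {
  x <- easy_features(n = 120, d = 16, seed = 3)
  arch <- tiny_arch()
  m1 <- gan_normative(x, arch, tiny_control(seed = 6))
  m2 <- gan_normative(x, arch, tiny_control(seed = 6))
  expect_identical(m1$stopped_at_epoch, m2$stopped_at_epoch)
  expect_identical(predict(m1, x), predict(m2, x))

  # a different seed gives a different trajectory (stochastic training)
  m3 <- gan_normative(x, arch, tiny_control(seed = 5))
  expect_false(identical(predict(m1, x), predict(m3, x)))

  # scores: valid range, deterministic at inference, training data scored
  # as neurotypical, far outliers scored lower
  s <- predict(m1, x)
  expect_true(all(s > 0 & s < 1))
  expect_identical(s, predict(m1, x))
  expect_gt(mean(s), 0.5)
  outlier <- matrix(1, 30, 16)
  expect_gt(mean(s), mean(predict(m1, outlier)))

  expect_error(predict(m1, matrix(0, 2, 5)), "features")
  expect_error(gan_normative(x[1:10, ], arch, tiny_control()),
               "batch_size")
  expect_error(gan_normative(x * 10, arch, tiny_control()), "\\[-1, 1\\]")
})

test_that("the discriminator is frozen during the generator step", {
  set.seed(8)
  arch <- tiny_arch()
  gen <- gannorm:::gen_init(arch$latent_dim, arch$generator_hidden, 10)
  disc <- gannorm:::disc_init(10, arch$discriminator_hidden,
                              arch$dropout_rate)
  before <- disc
  z <- matrix(rnorm(32 * arch$latent_dim), 32)
  gf <- gannorm:::gen_forward(gen, z, train = TRUE)
  df <- gannorm:::disc_forward(disc, gf$out, train = TRUE)
  db <- gannorm:::disc_backward(disc, df, (df$p - 1) / 32)
  gg <- gannorm:::gen_backward(gen, gf, db$dinput)
  st <- gannorm:::adam_step(gannorm:::gen_trainable(gen), gg,
                            gannorm:::adam_init(gannorm:::gen_trainable(gen)),
                            2e-4, 0.5, 0.999)
  gen2 <- gannorm:::gen_set_trainable(gen, st$params)
  expect_identical(disc, before)                 # D untouched
  expect_false(identical(gannorm:::gen_trainable(gen2),
                         gannorm:::gen_trainable(gen)))  # G moved
})

test_that("generated samples are reproducible, bounded, and match training
           statistics on easy data", {
  x <- easy_features(n = 150, d = 12, seed = 6, noise = 0.04)
  m <- gan_normative(x, tiny_arch(), tiny_control(seed = 2,
                                                  stop_window = 400L,
                                                  max_epochs = 2500L))
  g1 <- simulate(m, nsim = 50, seed = 3)
  g2 <- simulate(m, nsim = 50, seed = 3)
  expect_identical(g1, g2)
  expect_true(all(g1 >= -1 & g1 <= 1))
  expect_equal(dim(g1), c(50, 12))

  big <- simulate(m, nsim = 1000, seed = 9)
  expect_lt(max(abs(colMeans(big) - colMeans(x))), 0.2)
})

test_that("five-fold training yields one model per fold with fold-out
           metrics", {
  feats <- easy_features(n = 80, d = 10, seed = 12)
  ds <- structure(list(network = "Default", features = feats,
                       retained_ids = rownames(feats),
                       excluded_ids = character(0)),
                  class = "network_dataset")
  sp <- make_splits(rownames(feats)[1:60], rownames(feats)[61:80], seed = 1)
  models <- train_folds(ds, sp, tiny_arch(),
                        tiny_control(seed = 3, stop_window = 60L,
                                     max_epochs = 120L))
  expect_length(models, 5)
  expect_equal(vapply(models, `[[`, 0L, "fold_index"), 1:5)
  for (m in models) {
    expect_true(is.finite(m$fold_metrics$pct_above))
    expect_true(m$fold_metrics$mean_score > 0 &&
                  m$fold_metrics$mean_score < 1)
    expect_equal(nrow(m$history), m$stopped_at_epoch)
    expect_true(all(m$history$frac_above >= 0 & m$history$frac_above <= 1))
  }
})
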