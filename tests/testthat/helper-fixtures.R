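# Shared fixtures, built in code at test time.

# A random symmetric correlation-like matrix with unit diagonal.
random_corr <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n, -0.5, 0.5), n)
  m <- (a + t(a)) / 2
  diag(m) <- 1
  m
}

# A tiny two-network parcellation for subsetting tests.
tiny_parcellation <- function(sizes = c(Default = 4, DorsalAttn = 3)) {
  parcellation(sprintf("r%02d", seq_len(sum(sizes))),
               rep(names(sizes), times = sizes))
}

# Cleaned-scale training features: n subjects around a smooth typical
# pattern, values well inside [-1, 1]. Mimics a cleaned network dataset.
easy_features <- function(n = 200, d = 20, seed = 1, noise = 0.05) {
  set.seed(seed)
  center <- seq(-0.3, 0.3, length.out = d)
  x <- matrix(rnorm(n * d, sd = noise), n, d)
  x <- x + rep(center, each = n)
  rownames(x) <- sprintf("s%03d", seq_len(n))
  x
}

# Small architecture / training settings for desk-scale GAN tests.
tiny_arch <- function() gan_architecture("tiny", generator_hidden = 16L,
                                         discriminator_hidden = c(16L, 8L),
                                         dropout_rate = 0.4)
tiny_control <- function(seed = 1, stop_window = 150L, max_epochs = 600L)
  gan_training_config(stop_window = stop_window, max_epochs = max_epochs,
                      seed = seed)

# Minimal stand-in carrying fold metrics, for selection/enumeration logic.
fake_model <- function(pct, mean_sc, fold = 1L, arch_name = "a") {
  structure(list(fold_metrics = list(pct_above = pct, mean_score = mean_sc),
                 fold_index = fold,
                 arch = list(name = arch_name)),
            class = "gan_normative")
}

# Discriminator that computes exactly sigmoid(w . x), built from the pair
# LeakyReLU(a) - LeakyReLU(-a) = (1 + slope) * a.
linear_scorer <- function(w) {
  d <- length(w)
  disc <- list(hidden = list(list(W = cbind(w, -w), b = c(0, 0))),
               out = list(W = matrix(c(1, -1) / 1.2, 2, 1), b = 0),
               rate = 0, input_rate = 0)
  structure(list(discriminator = disc, n_features = d,
                 feature_sd = rep(0.2, d), feature_mean = rep(0, d),
                 network = "Default", fold_index = 1L,
                 arch = list(name = "linear"),
                 control = gan_training_config(seed = 1)),
            class = "gan_normative")
}
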