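# The adversarial normative model. One GAN is trained per (network,
# architecture, fold) on neurotypical feature vectors only; the
# discriminator's sigmoid output is the per-subject neurotypicality score.

#' Architecture of one adversarial model pair
#'
#' The generator maps a standard-normal latent vector through dense layers
#' with batch normalization and LeakyReLU to a tanh output in the feature
#' space; the discriminator maps feature vectors through dense layers with
#' LeakyReLU and dropout to a single sigmoid node. `shape` constrains the
#' discriminator hidden widths: `"rectangular"` requires equal widths within
#' each subnetwork, `"triangular"` strictly decreasing discriminator widths.
#'
#' @param name Label for the architecture.
#' @param generator_hidden Integer vector of generator hidden-layer widths.
#' @param discriminator_hidden Integer vector of discriminator hidden-layer
#'   widths.
#' @param dropout_rate Discriminator dropout rate; the evaluated range is
#'   0.40-0.70.
#' @param latent_dim Length of the generator's input noise vector
#'   (default 100).
#' @param shape `"triangular"` or `"rectangular"`.
#' @param input_dropout Also apply dropout to the discriminator's input
#'   features (default `FALSE`). When on, every training step sees a random
#'   subset of connections — effectively a smaller feature set entering the
#'   first hidden layer — which spreads the score's reliance across
#'   features at some cost in score calibration.
#' @return A list of class `gan_architecture`.
#' @export
gan_architecture <- function(name, generator_hidden, discriminator_hidden,
                             dropout_rate = 0.5, latent_dim = 100L,
                             shape = c("triangular", "rectangular"),
                             input_dropout = FALSE) {
  shape <- match.arg(shape)
  generator_hidden <- as.integer(generator_hidden)
  discriminator_hidden <- as.integer(discriminator_hidden)
  if (any(c(generator_hidden, discriminator_hidden) < 1))
    stop("hidden widths must be positive", call. = FALSE)
  if (dropout_rate < 0.40 || dropout_rate > 0.70)
    stop("dropout_rate outside the evaluated range [0.40, 0.70]",
         call. = FALSE)
  if (shape == "rectangular") {
    if (length(unique(generator_hidden)) > 1 ||
        length(unique(discriminator_hidden)) > 1)
      stop("rectangular shape requires equal widths within each subnetwork",
           call. = FALSE)
  } else {
    if (length(discriminator_hidden) > 1 &&
        any(diff(discriminator_hidden) >= 0))
      stop("triangular shape requires strictly decreasing discriminator ",
           "widths", call. = FALSE)
  }
  structure(list(name = name, shape = shape,
                 generator_hidden = generator_hidden,
                 discriminator_hidden = discriminator_hidden,
                 dropout_rate = dropout_rate,
                 latent_dim = as.integer(latent_dim),
                 input_dropout = isTRUE(input_dropout)),
            class = "gan_architecture")
}

#' Reference architecture
#'
#' The published example configuration for a Dorsal Attention model: a
#' single 200-node generator hidden layer, 50% dropout, and 75-50-25
#' discriminator hidden layers.
#'
#' @return A `gan_architecture`.
#' @export
reference_architecture <- function() {
  gan_architecture("ref-200/75-50-25", generator_hidden = 200L,
                   discriminator_hidden = c(75L, 50L, 25L),
                   dropout_rate = 0.5, shape = "triangular")
}

#' Training configuration for the adversarial pair
#'
#' Defaults follow the published regime: mini-batches of 32 real samples,
#' Adam with learning rate 0.0002, and a stop criterion that fires when the
#' standard deviation of the fraction of training neurotypicality scores
#' above 0.5, over a moving window of 15,000 epochs, drops below 0.01.
#' `beta1 = 0.5` is the usual adversarial-training choice.
#'
#' @param batch_size Real samples per discriminator mini-batch.
#' @param learning_rate Adam learning rate (both subnetworks).
#' @param beta1,beta2 Adam moment decay rates.
#' @param stop_window Moving-window length in epochs.
#' @param stop_std_threshold Standard-deviation threshold for stopping.
#' @param score_threshold Score cut defining "above threshold" in the
#'   training metric (and in vote-based prediction).
#' @param max_epochs Hard ceiling on training epochs.
#' @param seed Integer seed; fixes weight initialization, mini-batch
#'   sampling, dropout masks and latent draws.
#' @return A list of class `gan_training_config`.
#' @export
gan_training_config <- function(batch_size = 32L, learning_rate = 2e-4,
                                beta1 = 0.5, beta2 = 0.999,
                                stop_window = 15000L,
                                stop_std_threshold = 0.01,
                                score_threshold = 0.5,
                                max_epochs = 200000L, seed = 0L) {
  if (stop_window < 1) stop("stop_window must be >= 1", call. = FALSE)
  if (score_threshold <= 0 || score_threshold >= 1)
    stop("score_threshold must lie in (0, 1)", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 stop_window = as.integer(stop_window),
                 stop_std_threshold = stop_std_threshold,
                 score_threshold = score_threshold,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "gan_training_config")
}

#' Moving-window stop criterion
#'
#' Fires once at least `stop_window` epochs have elapsed and the standard
#' deviation of the last `stop_window` values of the training metric (the
#' fraction of training neurotypicality scores above the score threshold)
#' is below `stop_std_threshold`. A constant metric stream therefore stops
#' training exactly at epoch `stop_window`.
#'
#' @param frac_history Numeric vector: the metric value at each epoch so
#'   far.
#' @param control A [gan_training_config()] (or any list with `stop_window`
#'   and `stop_std_threshold`).
#' @return Logical scalar.
#' @export
stop_criterion <- function(frac_history, control) {
  w <- control$stop_window
  n <- length(frac_history)
  if (n < w) return(FALSE)
  stats::sd(frac_history[(n - w + 1L):n]) < control$stop_std_threshold
}

#' Fit an adversarial normative model
#'
#' Trains a generator/discriminator pair on cleaned neurotypical feature
#' vectors (all values in [-1, 1]). Each epoch performs (a) one
#' discriminator step on a mini-batch of `batch_size` real samples labeled 1
#' plus an equal mini-batch of generated samples labeled 0, binary
#' cross-entropy, Adam; then (b) one generator step through the composite
#' network with the discriminator frozen, the generated batch labeled 1.
#' After each epoch the full training set is scored in inference mode and
#' the fraction above `score_threshold` is appended to the history; training
#' halts when [stop_criterion()] fires or `max_epochs` is reached. The whole
#' run is reproducible from `control$seed`.
#'
#' @param x Numeric matrix, subjects by features, values in [-1, 1].
#' @param arch A [gan_architecture()].
#' @param control A [gan_training_config()].
#' @param network Optional network label carried on the fitted object.
#' @param fold_index Optional cross-validation fold index (bookkeeping).
#' @return An object of class `gan_normative`: the trained pair, the
#'   per-epoch history (`d_loss`, `g_loss`, `frac_above`), the epoch at
#'   which training stopped, and the training-data feature means/sds used by
#'   the explanation stage.
#' @export
gan_normative <- function(x, arch, control = gan_training_config(),
                          network = NA_character_, fold_index = NA_integer_) {
  stopifnot(inherits(arch, "gan_architecture"),
            inherits(control, "gan_training_config"))
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (n < control$batch_size)
    stop(sprintf("need at least batch_size = %d samples, have %d",
                 control$batch_size, n), call. = FALSE)
  if (any(abs(x) > 1 + 1e-9))
    stop("features must be cleaned to [-1, 1] before fitting", call. = FALSE)
  b <- control$batch_size
  with_seed(control$seed, {
    gen <- gen_init(arch$latent_dim, arch$generator_hidden, d)
    disc <- disc_init(d, arch$discriminator_hidden, arch$dropout_rate,
                      input_dropout = arch$input_dropout)
    opt_d <- adam_init(disc_trainable(disc))
    opt_g <- adam_init(gen_trainable(gen))
    d_loss <- g_loss <- frac <- numeric(control$max_epochs)
    epoch <- 0L
    repeat {
      epoch <- epoch + 1L
      # (a) discriminator step: real batch labeled 1, generated batch 0
      idx <- sample.int(n, b, replace = FALSE)
      z <- matrix(stats::rnorm(b * arch$latent_dim), b)
      fake <- gen_forward(gen, z, train = FALSE)$out
      xb <- rbind(x[idx, , drop = FALSE], fake)
      yb <- c(rep(1, b), rep(0, b))
      fwd <- disc_forward(disc, xb, train = TRUE)
      d_loss[epoch] <- bce_loss(fwd$p, yb)
      if (!is.finite(d_loss[epoch]))
        stop("non-finite discriminator loss at epoch ", epoch, call. = FALSE)
      bk <- disc_backward(disc, fwd, (fwd$p - yb) / (2 * b))
      st <- adam_step(disc_trainable(disc), bk$grads, opt_d,
                      control$learning_rate, control$beta1, control$beta2)
      disc <- disc_set_trainable(disc, st$params)
      opt_d <- st$opt
      # (b) generator step: discriminator frozen, generated batch labeled 1
      z <- matrix(stats::rnorm(b * arch$latent_dim), b)
      gfwd <- gen_forward(gen, z, train = TRUE)
      gen <- gfwd$gen                       # batchnorm running stats advance
      dfwd <- disc_forward(disc, gfwd$out, train = TRUE)
      g_loss[epoch] <- bce_loss(dfwd$p, rep(1, b))
      if (!is.finite(g_loss[epoch]))
        stop("non-finite generator loss at epoch ", epoch, call. = FALSE)
      dbk <- disc_backward(disc, dfwd, (dfwd$p - 1) / b)
      ggr <- gen_backward(gen, gfwd, dbk$dinput)
      st <- adam_step(gen_trainable(gen), ggr, opt_g,
                      control$learning_rate, control$beta1, control$beta2)
      gen <- gen_set_trainable(gen, st$params)
      opt_g <- st$opt
      # training metric: fraction of the whole fold scored above threshold
      frac[epoch] <- mean(disc_forward(disc, x)$p > control$score_threshold)
      if (stop_criterion(frac[seq_len(epoch)], control) ||
          epoch >= control$max_epochs) break
    }
    structure(list(arch = arch, control = control, network = network,
                   fold_index = fold_index,
                   generator = gen, discriminator = disc,
                   n_features = d, n_train = n,
                   feature_mean = colMeans(x),
                   feature_sd = apply(x, 2, stats::sd),
                   history = data.frame(epoch = seq_len(epoch),
                                        d_loss = d_loss[seq_len(epoch)],
                                        g_loss = g_loss[seq_len(epoch)],
                                        frac_above = frac[seq_len(epoch)]),
                   stopped_at_epoch = epoch),
              class = "gan_normative")
  })
}

#' Neurotypicality scores from a fitted model
#'
#' Scores feature vectors with the trained discriminator in inference mode:
#' dropout off, batch normalization on stored moving statistics. Scores lie
#' in (0, 1); high means the sample resembles the learned neurotypical
#' pattern.
#'
#' @param object A fitted `gan_normative` model.
#' @param newdata Numeric matrix (subjects by features) or a single feature
#'   vector; width must match the training features.
#' @param ... Unused.
#' @return Numeric vector of scores, named by `rownames(newdata)`.
#' @export
predict.gan_normative <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("newdata has %d features; model expects %d",
                 ncol(newdata), object$n_features), call. = FALSE)
  p <- disc_forward(object$discriminator, newdata)$p
  names(p) <- rownames(newdata)
  p
}

#' Generate synthetic neurotypical feature vectors
#'
#' Draws standard-normal latent vectors and maps them through the trained
#' generator (inference mode), yielding vectors in [-1, 1] per feature.
#'
#' @param object A fitted `gan_normative` model.
#' @param nsim Number of vectors to generate.
#' @param seed Integer seed for the latent draws (optional).
#' @param ... Unused.
#' @return `nsim` by `n_features` numeric matrix.
#' @export
simulate.gan_normative <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    z <- matrix(stats::rnorm(nsim * object$arch$latent_dim), nsim)
    gen_forward(object$generator, z)$out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @export
print.gan_normative <- function(x, ...) {
  cat(sprintf(
    paste0("<gan_normative> %s%s: %d features, arch %s, stopped at epoch ",
           "%d\n  final training fraction above %.2f: %.3f\n"),
    if (is.na(x$network)) "unlabeled network" else x$network,
    if (is.na(x$fold_index)) "" else sprintf(" (fold %d)", x$fold_index),
    x$n_features, x$arch$name, x$stopped_at_epoch,
    x$control$score_threshold,
    x$history$frac_above[x$stopped_at_epoch]))
  invisible(x)
}

#' @export
summary.gan_normative <- function(object, ...) {
  h <- object$history
  out <- list(network = object$network, arch = object$arch$name,
              n_train = object$n_train, n_features = object$n_features,
              stopped_at_epoch = object$stopped_at_epoch,
              final_d_loss = h$d_loss[nrow(h)],
              final_g_loss = h$g_loss[nrow(h)],
              final_frac_above = h$frac_above[nrow(h)])
  class(out) <- "summary.gan_normative"
  out
}

#' @export
print.summary.gan_normative <- function(x, ...) {
  cat(sprintf("Adversarial normative model (%s, arch %s)\n",
              x$network, x$arch))
  cat(sprintf("  training samples: %d   features: %d\n",
              x$n_train, x$n_features))
  cat(sprintf("  stopped at epoch %d\n", x$stopped_at_epoch))
  cat(sprintf("  final losses: D %.4f, G %.4f; frac above threshold %.3f\n",
              x$final_d_loss, x$final_g_loss, x$final_frac_above))
  invisible(x)
}

#' Plot training history
#'
#' Two base-graphics panels: discriminator/generator loss curves and the
#' fraction of training scores above the threshold (the stop-criterion
#' metric).
#'
#' @param x A fitted `gan_normative` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.gan_normative <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$d_loss, h$g_loss), type = "l",
                    lty = 1, col = c("black", "grey50"),
                    xlab = "epoch", ylab = "BCE loss", ...)
  graphics::legend("topright", c("discriminator", "generator"),
                   lty = 1, col = c("black", "grey50"), bty = "n")
  graphics::plot(h$epoch, h$frac_above, type = "l", xlab = "epoch",
                 ylab = sprintf("frac scores > %.2f",
                                x$control$score_threshold))
  invisible(x)
}
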