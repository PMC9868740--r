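# Minimal feed-forward neural-net machinery for the adversarial pair:
# dense layers, batch normalization (generator), inverted dropout
# (discriminator), LeakyReLU/tanh/sigmoid activations, binary cross-entropy
# and Adam. Everything is plain matrix code; model sizes here (hundreds of
# features, tens of hidden units) keep BLAS calls cheap.

LRELU_SLOPE <- 0.2
BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99
ADAM_EPS <- 1e-8

# add / multiply a row vector across a matrix without sweep()'s aperm cost
addrow <- function(m, v) m + rep(v, each = nrow(m))
mulrow <- function(m, v) m * rep(v, each = nrow(m))

lrelu <- function(x) {
  neg <- x < 0
  x[neg] <- LRELU_SLOPE * x[neg]
  x
}
lrelu_grad <- function(x) (x > 0) + LRELU_SLOPE * (x <= 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# --- generator: latent -> [dense -> batchnorm -> LeakyReLU]* -> dense ->
# tanh. Dense bias is absorbed by the batchnorm shift.
gen_init <- function(latent_dim, hidden, n_features) {
  dims <- c(latent_dim, hidden)
  blocks <- lapply(seq_along(hidden), function(i)
    list(W = glorot(dims[i], dims[i + 1]),
         gamma = rep(1, hidden[i]), beta = rep(0, hidden[i])))
  stats <- lapply(hidden, function(h) list(mean = rep(0, h), var = rep(1, h)))
  # The output layer starts at a tenth of Glorot scale so early generated
  # samples sit near the center of the cleaned feature range instead of
  # filling [-1, 1]; otherwise the discriminator wins on amplitude alone
  # and the adversarial game never balances.
  list(blocks = blocks,
       out = list(W = glorot(hidden[length(hidden)], n_features) * 0.1,
                  b = rep(0, n_features)),
       stats = stats)
}

gen_forward <- function(gen, z, train = FALSE) {
  a <- z
  caches <- vector("list", length(gen$blocks))
  for (i in seq_along(gen$blocks)) {
    blk <- gen$blocks[[i]]
    s <- a %*% blk$W
    if (train) {
      mu <- colMeans(s)
      va <- colMeans(s * s) - mu * mu       # biased batch variance
      gen$stats[[i]]$mean <- BN_MOMENTUM * gen$stats[[i]]$mean +
        (1 - BN_MOMENTUM) * mu
      gen$stats[[i]]$var <- BN_MOMENTUM * gen$stats[[i]]$var +
        (1 - BN_MOMENTUM) * va
    } else {
      mu <- gen$stats[[i]]$mean
      va <- gen$stats[[i]]$var
    }
    invstd <- 1 / sqrt(va + BN_EPS)
    shat <- mulrow(addrow(s, -mu), invstd)
    h <- addrow(mulrow(shat, blk$gamma), blk$beta)
    caches[[i]] <- list(a_in = a, shat = shat, invstd = invstd, h = h)
    a <- lrelu(h)
  }
  pre <- addrow(a %*% gen$out$W, gen$out$b)
  y <- tanh(pre)
  list(out = y, a_last = a, caches = caches, gen = gen)
}

# Backward pass given dL/dy; returns gradients for the trainable parameters.
gen_backward <- function(gen, fwd, dy) {
  d <- dy * (1 - fwd$out * fwd$out)                      # through tanh
  g_out <- list(W = crossprod(fwd$a_last, d), b = colSums(d))
  da <- tcrossprod(d, gen$out$W)
  g_blocks <- vector("list", length(gen$blocks))
  for (i in rev(seq_along(gen$blocks))) {
    cc <- fwd$caches[[i]]
    dh <- da * lrelu_grad(cc$h)
    dgamma <- colSums(dh * cc$shat)
    dbeta <- colSums(dh)
    dshat <- mulrow(dh, gen$blocks[[i]]$gamma)
    ds <- mulrow(
      addrow(dshat, -colMeans(dshat)) -
        mulrow(cc$shat, colMeans(dshat * cc$shat)),
      cc$invstd)
    g_blocks[[i]] <- list(W = crossprod(cc$a_in, ds),
                          gamma = dgamma, beta = dbeta)
    da <- tcrossprod(ds, gen$blocks[[i]]$W)
  }
  list(blocks = g_blocks, out = g_out)
}

# --- discriminator: features -> [dropout] -> [dense -> LeakyReLU ->
# dropout]* -> dense -> sigmoid (the neurotypicality score). Input dropout
# makes each step see a random feature subset, so the model cannot lean on
# a handful of connections.
disc_init <- function(n_features, hidden, dropout_rate,
                      input_dropout = TRUE) {
  dims <- c(n_features, hidden)
  layers <- lapply(seq_along(hidden), function(i)
    list(W = glorot(dims[i], dims[i + 1]), b = rep(0, hidden[i])))
  list(hidden = layers,
       out = list(W = glorot(hidden[length(hidden)], 1), b = 0),
       rate = dropout_rate,
       input_rate = if (input_dropout) dropout_rate else 0)
}

drop_mask <- function(n, m, rate) {
  matrix((stats::runif(n * m) >= rate) / (1 - rate), n, m)
}

disc_forward <- function(disc, x, train = FALSE) {
  a <- x
  in_mask <- NULL
  if (train && disc$input_rate > 0) {
    in_mask <- drop_mask(nrow(a), ncol(a), disc$input_rate)
    a <- a * in_mask
  }
  caches <- vector("list", length(disc$hidden))
  for (i in seq_along(disc$hidden)) {
    ly <- disc$hidden[[i]]
    s <- addrow(a %*% ly$W, ly$b)
    h <- lrelu(s)
    mask <- NULL
    if (train && disc$rate > 0) {
      mask <- drop_mask(nrow(h), ncol(h), disc$rate)
      h <- h * mask
    }
    caches[[i]] <- list(a_in = a, s = s, mask = mask)
    a <- h
  }
  logit <- drop(a %*% disc$out$W) + disc$out$b
  list(p = sigmoid(logit), logit = logit, a_last = a, caches = caches,
       in_mask = in_mask)
}

# Backward from dL/dlogit; returns parameter gradients and dL/dinput (the
# latter is what the frozen-discriminator generator step needs).
disc_backward <- function(disc, fwd, dlogit) {
  d <- matrix(dlogit, ncol = 1)
  g_out <- list(W = crossprod(fwd$a_last, d), b = sum(d))
  da <- tcrossprod(d, disc$out$W)
  g_hidden <- vector("list", length(disc$hidden))
  for (i in rev(seq_along(disc$hidden))) {
    cc <- fwd$caches[[i]]
    if (!is.null(cc$mask)) da <- da * cc$mask
    ds <- da * lrelu_grad(cc$s)
    g_hidden[[i]] <- list(W = crossprod(cc$a_in, ds), b = colSums(ds))
    da <- tcrossprod(ds, disc$hidden[[i]]$W)
  }
  if (!is.null(fwd$in_mask)) da <- da * fwd$in_mask
  list(grads = list(hidden = g_hidden, out = g_out), dinput = da)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- Adam over nested parameter lists ------------------------------------

tree_map <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- vector("list", length(args[[1]]))
    names(out) <- names(args[[1]])
    for (i in seq_along(out))
      out[[i]] <- do.call(tree_map, c(list(f), lapply(args, `[[`, i)))
    out
  } else {
    do.call(f, args)
  }
}

tree_zeros <- function(p) tree_map(function(x) x * 0, p)

adam_init <- function(params) list(m = tree_zeros(params),
                                   v = tree_zeros(params), t = 0L)

adam_step <- function(params, grads, opt, lr, beta1, beta2) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                    opt$v, grads)
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  params <- tree_map(function(p, m, v)
    p - lr * (m / c1) / (sqrt(v / c2) + ADAM_EPS),
    params, opt$m, opt$v)
  list(params = params, opt = opt)
}

# Split the generator into its trainable part (for Adam) and running stats.
gen_trainable <- function(gen) list(blocks = lapply(gen$blocks, function(b)
  list(W = b$W, gamma = b$gamma, beta = b$beta)), out = gen$out)

gen_set_trainable <- function(gen, tr) {
  for (i in seq_along(gen$blocks)) {
    gen$blocks[[i]]$W <- tr$blocks[[i]]$W
    gen$blocks[[i]]$gamma <- tr$blocks[[i]]$gamma
    gen$blocks[[i]]$beta <- tr$blocks[[i]]$beta
  }
  gen$out <- tr$out
  gen
}

disc_trainable <- function(disc) list(hidden = disc$hidden, out = disc$out)

disc_set_trainable <- function(disc, tr) {
  disc$hidden <- tr$hidden
  disc$out <- tr$out
  disc
}
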