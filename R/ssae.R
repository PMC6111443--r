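#' Configuration for a stacked sparse autoencoder classifier
#'
#' Two sigmoid-encoder/linear-decoder autoencoder layers are pretrained
#' greedily (each on the previous layer's encodings) by scaled conjugate
#' gradient, then a softmax head is trained supervised on the second layer's
#' encodings. The feature-input variant (SSAE-f, 32-dimensional TD features)
#' uses hidden sizes (32, 16); the raw-input variant (SSAE-r, 240-dimensional
#' flattened windows) uses (100, 50).
#'
#' @param layer_sizes Hidden unit counts `(n, m)` of the two layers.
#' @param l2r L2 weight-decay coefficient (encoder and decoder weights).
#' @param sr Sparsity regularization weight on the KL penalty.
#' @param sp Sparsity proportion: target mean activation of each hidden unit.
#' @param max_iters SCG iteration budget per layer (and for the head).
#' @param scale Input scaling: `"minmax"` maps each input dimension to
#'   `[0, 1]` (sigmoid operating range, used for TD features); `"zscore"`
#'   standardizes per channel (used for raw windows).
#' @param fine_tune Optionally fine-tune the whole stack supervised after
#'   greedy pretraining (off by default: the stacked model keeps its
#'   unsupervised encoders).
#' @param seed Integer seed for the weight initialization.
#' @return A validated `ssae_config` list.
#' @export
ssae_config <- function(layer_sizes = c(32, 16), l2r = 1e-4, sr = 0.01,
                        sp = 0.5, max_iters = 400,
                        scale = c("minmax", "zscore"), fine_tune = FALSE,
                        seed = 1) {
  scale <- match.arg(scale)
  if (length(layer_sizes) != 2 || any(layer_sizes < 1)) {
    abort_field("layer_sizes", "must be two hidden sizes >= 1")
  }
  if (sp <= 0 || sp >= 1) abort_field("sp", "must lie in (0, 1)")
  if (l2r < 0 || sr < 0) abort_field("l2r/sr", "must be nonnegative")
  structure(
    list(layer_sizes = as.integer(layer_sizes), l2r = l2r, sr = sr, sp = sp,
         max_iters = max_iters, scale = scale, fine_tune = fine_tune,
         seed = as.integer(seed)),
    class = "ssae_config"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# --- sparse autoencoder objective -----------------------------------------
# theta packs W1 (d x h), b1 (h), W2 (h x d), b2 (d).

sae_unpack <- function(theta, d, h) {
  i <- 0
  W1 <- matrix(theta[(i + 1):(i + d * h)], d, h); i <- i + d * h
  b1 <- theta[(i + 1):(i + h)]; i <- i + h
  W2 <- matrix(theta[(i + 1):(i + h * d)], h, d); i <- i + h * d
  b2 <- theta[(i + 1):(i + d)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

sae_loss <- function(theta, X, h, l2r, sr, sp) {
  d <- ncol(X); n <- nrow(X)
  p <- sae_unpack(theta, d, h)
  A <- sigmoid(sweep(X %*% p$W1, 2, p$b1, "+"))
  Xhat <- sweep(A %*% p$W2, 2, p$b2, "+")
  rho <- pmin(pmax(colMeans(A), 1e-10), 1 - 1e-10)
  kl <- sp * log(sp / rho) + (1 - sp) * log((1 - sp) / (1 - rho))
  sum((Xhat - X)^2) / (2 * n) +
    (l2r / 2) * (sum(p$W1^2) + sum(p$W2^2)) +
    sr * sum(kl)
}

sae_grad <- function(theta, X, h, l2r, sr, sp) {
  d <- ncol(X); n <- nrow(X)
  p <- sae_unpack(theta, d, h)
  A <- sigmoid(sweep(X %*% p$W1, 2, p$b1, "+"))
  Xhat <- sweep(A %*% p$W2, 2, p$b2, "+")
  R <- (Xhat - X) / n
  rho <- pmin(pmax(colMeans(A), 1e-10), 1 - 1e-10)
  dW2 <- crossprod(A, R) + l2r * p$W2
  db2 <- colSums(R)
  kl_grad <- (sr / n) * (-sp / rho + (1 - sp) / (1 - rho))
  dA <- R %*% t(p$W2) + matrix(kl_grad, n, h, byrow = TRUE)
  dZ <- dA * A * (1 - A)
  dW1 <- crossprod(X, dZ) + l2r * p$W1
  db1 <- colSums(dZ)
  c(as.vector(dW1), db1, as.vector(dW2), db2)
}

glorot_init <- function(d_in, d_out) {
  r <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -r, r), d_in, d_out)
}

#' Pretrain one sparse autoencoder layer
#'
#' Minimizes the reconstruction loss
#' \deqn{J = \frac{1}{2W}\sum_i \|x_i - \hat x_i\|^2
#'   + \frac{\lambda}{2}\|W\|^2 + \beta \sum_j KL(\rho \,\|\, \hat\rho_j)}
#' with a sigmoid encoder, linear decoder, and the KL divergence between the
#' target sparsity proportion \eqn{\rho} and each hidden unit's mean
#' activation \eqn{\hat\rho_j}, using scaled conjugate gradient.
#'
#' @param X Input matrix (observations x dims), already scaled to the
#'   encoder's operating range.
#' @param hidden Number of hidden units.
#' @param cfg An [ssae_config()].
#' @param seed_tag Extra tag mixed into the layer's init seed.
#' @return List with encoder `weights` (dims x hidden) and `biases`, the
#'   decoder parameters, the final `value`, and the SCG `trace`.
#' @export
sae_pretrain_layer <- function(X, hidden, cfg, seed_tag = 1) {
  d <- ncol(X)
  theta0 <- with_seed(derive_seed(cfg$seed, "sae", seed_tag, hidden), {
    c(as.vector(glorot_init(d, hidden)), rep(0, hidden),
      as.vector(glorot_init(hidden, d)), rep(0, d))
  })
  opt <- scg_minimize(
    theta0,
    fn = function(th) sae_loss(th, X, hidden, cfg$l2r, cfg$sr, cfg$sp),
    gr = function(th) sae_grad(th, X, hidden, cfg$l2r, cfg$sr, cfg$sp),
    max_iters = cfg$max_iters
  )
  p <- sae_unpack(opt$par, d, hidden)
  list(weights = p$W1, biases = p$b1, decoder_weights = p$W2,
       decoder_biases = p$b2, value = opt$value, trace = opt$trace)
}

# --- softmax head ----------------------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

softmax_loss <- function(theta, H, Yk, l2r) {
  m <- ncol(H); K <- ncol(Yk); n <- nrow(H)
  W <- matrix(theta[seq_len(m * K)], m, K)
  b <- theta[m * K + seq_len(K)]
  P <- softmax_rows(sweep(H %*% W, 2, b, "+"))
  -sum(Yk * log(pmax(P, 1e-300))) / n + (l2r / 2) * sum(W^2)
}

softmax_grad <- function(theta, H, Yk, l2r) {
  m <- ncol(H); K <- ncol(Yk); n <- nrow(H)
  W <- matrix(theta[seq_len(m * K)], m, K)
  b <- theta[m * K + seq_len(K)]
  P <- softmax_rows(sweep(H %*% W, 2, b, "+"))
  G <- (P - Yk) / n
  c(as.vector(crossprod(H, G) + l2r * W), colSums(G))
}

one_hot <- function(y) {
  y <- factor(y)
  Y <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}

# --- input scaling ---------------------------------------------------------

fit_scaler <- function(x, scale, channel_index = NULL) {
  if (scale == "minmax") {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    rng <- hi - lo
    rng[rng == 0] <- 1
    list(type = "minmax", lo = lo, rng = rng)
  } else {
    if (is.null(channel_index)) channel_index <- seq_len(ncol(x))
    mu <- sd <- numeric(ncol(x))
    for (ch in unique(channel_index)) {
      cols <- channel_index == ch
      v <- x[, cols]
      mu[cols] <- mean(v)
      s <- stats::sd(as.vector(v))
      sd[cols] <- if (is.na(s) || s == 0) 1 else s
    }
    list(type = "zscore", mu = mu, sd = sd)
  }
}

apply_scaler <- function(scaler, x) {
  if (scaler$type == "minmax") {
    sweep(sweep(x, 2, scaler$lo), 2, scaler$rng, "/")
  } else {
    sweep(sweep(x, 2, scaler$mu), 2, scaler$sd, "/")
  }
}

# --- stacked model ---------------------------------------------------------

#' Train a stacked sparse autoencoder classifier
#'
#' Greedy layer-wise pretraining of two sparse autoencoder layers followed by
#' supervised softmax-head training (cross-entropy, scaled conjugate
#' gradient). Encoder weights stay frozen after pretraining unless
#' `cfg$fine_tune` is set.
#'
#' @param x Input matrix: flattened 4 x C features (SSAE-f) or flattened
#'   raw windows (SSAE-r).
#' @param y Class labels.
#' @param cfg An [ssae_config()].
#' @param channel_index Optional channel id per column of `x`, used by
#'   per-channel z-scoring for raw inputs.
#' @return An `emg_ssae` model.
#' @export
ssae_train <- function(x, y, cfg = ssae_config(), channel_index = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  scaler <- fit_scaler(x, cfg$scale, channel_index)
  Xs <- apply_scaler(scaler, x)
  n1 <- cfg$layer_sizes[1]; n2 <- cfg$layer_sizes[2]
  l1 <- sae_pretrain_layer(Xs, n1, cfg, seed_tag = 1)
  H1 <- sigmoid(sweep(Xs %*% l1$weights, 2, l1$biases, "+"))
  l2 <- sae_pretrain_layer(H1, n2, cfg, seed_tag = 2)
  H2 <- sigmoid(sweep(H1 %*% l2$weights, 2, l2$biases, "+"))
  Yk <- one_hot(y)
  K <- ncol(Yk)
  theta0 <- with_seed(derive_seed(cfg$seed, "head"), {
    c(as.vector(glorot_init(n2, K)), rep(0, K))
  })
  opt <- scg_minimize(
    theta0,
    fn = function(th) softmax_loss(th, H2, Yk, cfg$l2r),
    gr = function(th) softmax_grad(th, H2, Yk, cfg$l2r),
    max_iters = cfg$max_iters
  )
  Wh <- matrix(opt$par[seq_len(n2 * K)], n2, K)
  bh <- opt$par[n2 * K + seq_len(K)]
  model <- structure(
    list(
      encoders = list(
        list(weights = l1$weights, biases = l1$biases),
        list(weights = l2$weights, biases = l2$biases)
      ),
      head = list(weights = Wh, biases = bh),
      scaler = scaler, classes = levels(y), config = cfg,
      head_value = opt$value
    ),
    class = "emg_ssae"
  )
  if (isTRUE(cfg$fine_tune)) model <- ssae_fine_tune(model, Xs, Yk)
  model
}

# Supervised fine-tuning of the full encoder/head stack (optional).
ssae_fine_tune <- function(model, Xs, Yk) {
  enc <- model$encoders
  dims <- c(ncol(Xs), vapply(enc, function(e) ncol(e$weights), integer(1)))
  K <- ncol(Yk)
  pack <- function(e1, e2, h) {
    c(as.vector(e1$weights), e1$biases, as.vector(e2$weights), e2$biases,
      as.vector(h$weights), h$biases)
  }
  unpack <- function(th) {
    i <- 0
    take <- function(nr, nc) {
      M <- matrix(th[(i + 1):(i + nr * nc)], nr, nc); i <<- i + nr * nc; M
    }
    takev <- function(n) { v <- th[(i + 1):(i + n)]; i <<- i + n; v }
    e1 <- list(weights = take(dims[1], dims[2]), biases = takev(dims[2]))
    e2 <- list(weights = take(dims[2], dims[3]), biases = takev(dims[3]))
    h <- list(weights = take(dims[3], K), biases = takev(K))
    list(e1 = e1, e2 = e2, h = h)
  }
  l2r <- model$config$l2r
  n <- nrow(Xs)
  fn <- function(th) {
    p <- unpack(th)
    H1 <- sigmoid(sweep(Xs %*% p$e1$weights, 2, p$e1$biases, "+"))
    H2 <- sigmoid(sweep(H1 %*% p$e2$weights, 2, p$e2$biases, "+"))
    P <- softmax_rows(sweep(H2 %*% p$h$weights, 2, p$h$biases, "+"))
    -sum(Yk * log(pmax(P, 1e-300))) / n +
      (l2r / 2) * (sum(p$e1$weights^2) + sum(p$e2$weights^2) +
                     sum(p$h$weights^2))
  }
  gr <- function(th) {
    p <- unpack(th)
    H1 <- sigmoid(sweep(Xs %*% p$e1$weights, 2, p$e1$biases, "+"))
    H2 <- sigmoid(sweep(H1 %*% p$e2$weights, 2, p$e2$biases, "+"))
    P <- softmax_rows(sweep(H2 %*% p$h$weights, 2, p$h$biases, "+"))
    G <- (P - Yk) / n
    dWh <- crossprod(H2, G) + l2r * p$h$weights
    dbh <- colSums(G)
    dH2 <- G %*% t(p$h$weights) * H2 * (1 - H2)
    dW2 <- crossprod(H1, dH2) + l2r * p$e2$weights
    db2 <- colSums(dH2)
    dH1 <- dH2 %*% t(p$e2$weights) * H1 * (1 - H1)
    dW1 <- crossprod(Xs, dH1) + l2r * p$e1$weights
    db1 <- colSums(dH1)
    c(as.vector(dW1), db1, as.vector(dW2), db2, as.vector(dWh), dbh)
  }
  opt <- scg_minimize(pack(enc[[1]], enc[[2]], model$head), fn, gr,
                      max_iters = model$config$max_iters)
  p <- unpack(opt$par)
  model$encoders <- list(p$e1, p$e2)
  model$head <- p$h
  model
}

ssae_encode <- function(model, x) {
  Xs <- apply_scaler(model$scaler, as.matrix(x))
  H <- Xs
  for (e in model$encoders) {
    H <- sigmoid(sweep(H %*% e$weights, 2, e$biases, "+"))
  }
  H
}

#' Class probabilities from a stacked sparse autoencoder
#' @param model An `emg_ssae`.
#' @param x Input matrix on the training scale conventions.
#' @return Matrix of class probabilities, rows summing to 1.
#' @export
ssae_probs <- function(model, x) {
  H <- ssae_encode(model, x)
  softmax_rows(sweep(H %*% model$head$weights, 2, model$head$biases, "+"))
}

#' @export
predict.emg_ssae <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) {
    return(factor(character(0), levels = object$classes))
  }
  P <- ssae_probs(object, newdata)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.emg_ssae <- function(x, ...) {
  cat(sprintf(
    "<emg_ssae> layers %s -> %d classes (%s-scaled input)\n",
    paste(x$config$layer_sizes, collapse = "/"), length(x$classes),
    x$scaler$type
  ))
  invisible(x)
}
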