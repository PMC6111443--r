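#' Configuration for the single-layer convolutional network
#'
#' Architecture for 30 x 8 raw-EMG windows: one valid (unpadded) convolution
#' layer of 32 filters of size 3 x 3 giving 28 x 6 x 32 activations, ReLU,
#' 3 x 1 max pooling with stride equal to the pool size (floor division,
#' giving 9 x 6 x 32), a fully connected layer to 7 logits, and softmax.
#' Training is stochastic gradient descent with classical momentum.
#'
#' @param n_filters Number of convolution filters.
#' @param filter_shape Filter height and width (time x channel).
#' @param pool_shape Max-pool height and width; the stride equals the shape.
#' @param lr Learning rate.
#' @param l2 L2 regularization on convolution and FC weights.
#' @param momentum Classical momentum coefficient.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget (no early stopping).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(n_filters = 32, filter_shape = c(3, 3),
                       pool_shape = c(3, 1), lr = 0.1, l2 = 0.001,
                       momentum = 0.95, batch_size = 256, max_epochs = 25,
                       seed = 1) {
  stopifnot(
    n_filters >= 1, length(filter_shape) == 2, all(filter_shape >= 1),
    length(pool_shape) == 2, all(pool_shape >= 1),
    lr > 0, l2 >= 0, momentum >= 0, momentum < 1,
    batch_size >= 1, max_epochs >= 1
  )
  structure(
    list(n_filters = as.integer(n_filters),
         filter_shape = as.integer(filter_shape),
         pool_shape = as.integer(pool_shape),
         lr = lr, l2 = l2, momentum = momentum,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), seed = as.integer(seed)),
    class = "cnn_config"
  )
}

cnn_geometry <- function(L, C, cfg) {
  fh <- cfg$filter_shape[1]; fw <- cfg$filter_shape[2]
  ph <- cfg$pool_shape[1]; pw <- cfg$pool_shape[2]
  if (pw != 1) stop("only pool width 1 is supported", call. = FALSE)
  conv_r <- L - fh + 1
  conv_c <- C - fw + 1
  if (conv_r < 1 || conv_c < 1) {
    stop("filter does not fit the input window", call. = FALSE)
  }
  pool_r <- conv_r %/% ph
  if (pool_r < 1) stop("pool does not fit the convolution output",
                       call. = FALSE)
  list(L = L, C = C, fh = fh, fw = fw, ph = ph,
       conv_r = conv_r, conv_c = conv_c, pool_r = pool_r,
       fc_in = pool_r * conv_c * cfg$n_filters)
}

# im2col: (n * conv_r * conv_c) x (fh*fw) patch matrix; row order is
# conv-row fastest, then conv-col, then window; patch column order is
# filter-row fastest, then filter-col.
cnn_im2col <- function(X, geo) {
  n <- dim(X)[1]
  P <- matrix(0, n * geo$conv_r * geo$conv_c, geo$fh * geo$fw)
  for (dc in 0:(geo$fw - 1)) {
    for (dr in 0:(geo$fh - 1)) {
      slice <- X[, (1 + dr):(geo$conv_r + dr), (1 + dc):(geo$conv_c + dc),
                 drop = FALSE]
      P[, dr + 1 + geo$fh * dc] <- as.vector(aperm(slice, c(2, 3, 1)))
    }
  }
  P
}

# Pooling index vectors: rows of the conv matrix contributing member `m`
# (1..ph) of each pooled cell, in pooled row order.
pool_member_rows <- function(n, geo, m) {
  offsets <- (seq_len(n * geo$conv_c) - 1) * geo$conv_r
  rep(offsets, each = geo$pool_r) +
    rep((seq_len(geo$pool_r) - 1) * geo$ph, times = n * geo$conv_c) + m
}

cnn_forward_batch <- function(model, X, keep = FALSE) {
  geo <- model$geometry
  n <- dim(X)[1]
  Xs <- sweep(sweep(X, 3, model$scaler$mu), 3, model$scaler$sd, "/")
  P <- cnn_im2col(Xs, geo)
  Z <- sweep(P %*% model$conv_w, 2, model$conv_b, "+")
  Cact <- pmax(Z, 0)
  F <- ncol(Z)
  len <- n * geo$pool_r * geo$conv_c
  idx <- pool_member_rows(n, geo, 1)
  M <- Cact[idx, , drop = FALSE]
  Msrc <- matrix(idx, len, F)
  if (geo$ph > 1) {
    for (m in 2:geo$ph) {
      idx <- pool_member_rows(n, geo, m)
      cand <- Cact[idx, , drop = FALSE]
      upd <- cand > M
      M[upd] <- cand[upd]
      Msrc[upd] <- matrix(idx, len, F)[upd]
    }
  }
  arr <- array(M, dim = c(geo$pool_r, geo$conv_c, n, F))
  Mflat <- array(aperm(arr, c(3, 1, 2, 4)), dim = c(n, geo$fc_in))
  logits <- sweep(Mflat %*% model$fc_w, 2, model$fc_b, "+")
  probs <- softmax_rows(logits)
  if (!keep) return(probs)
  list(probs = probs, P = P, Z = Z, Mflat = Mflat, Msrc = Msrc, len = len)
}

cnn_backward_batch <- function(model, fwd, Yk, l2) {
  geo <- model$geometry
  n <- nrow(Yk)
  F <- ncol(model$conv_w)
  G <- (fwd$probs - Yk) / n
  dfc_w <- crossprod(fwd$Mflat, G) + l2 * model$fc_w
  dfc_b <- colSums(G)
  dMflat <- G %*% t(model$fc_w)
  arr <- array(dMflat, dim = c(n, geo$pool_r, geo$conv_c, F))
  dM <- array(aperm(arr, c(2, 3, 1, 4)), dim = c(fwd$len, F))
  dC <- matrix(0, nrow(fwd$Z), F)
  dC[cbind(as.vector(fwd$Msrc), rep(seq_len(F), each = fwd$len))] <-
    as.vector(dM)
  dZ <- dC * (fwd$Z > 0)
  dconv_w <- crossprod(fwd$P, dZ) + l2 * model$conv_w
  dconv_b <- colSums(dZ)
  list(conv_w = dconv_w, conv_b = dconv_b, fc_w = dfc_w, fc_b = dfc_b)
}

cnn_loss_batch <- function(model, fwd, Yk, l2) {
  -sum(Yk * log(pmax(fwd$probs, 1e-300))) / nrow(Yk) +
    (l2 / 2) * (sum(model$conv_w^2) + sum(model$fc_w^2))
}

cnn_init <- function(L, C, K, cfg) {
  geo <- cnn_geometry(L, C, cfg)
  with_seed(derive_seed(cfg$seed, "cnn-init"), {
    fan_conv <- geo$fh * geo$fw
    conv_w <- matrix(stats::rnorm(fan_conv * cfg$n_filters,
                                  sd = sqrt(2 / fan_conv)),
                     fan_conv, cfg$n_filters)
    fc_w <- matrix(stats::rnorm(geo$fc_in * K, sd = sqrt(2 / geo$fc_in)),
                   geo$fc_in, K)
    structure(
      list(conv_w = conv_w, conv_b = rep(0, cfg$n_filters),
           fc_w = fc_w, fc_b = rep(0, K),
           geometry = geo, config = cfg,
           scaler = list(mu = rep(0, C), sd = rep(1, C)),
           classes = NULL),
      class = "emg_cnn"
    )
  })
}

#' Forward pass of the convolutional network on one window
#'
#' @param model An `emg_cnn` (see [cnn_train()]).
#' @param window Numeric matrix of the model's input shape (e.g. 30 x 8).
#' @return Length-K probability vector (softmax output, sums to 1).
#' @export
cnn_forward <- function(model, window) {
  geo <- model$geometry
  window <- as.matrix(window)
  if (nrow(window) != geo$L || ncol(window) != geo$C) {
    stop(sprintf("input must be %d x %d, got %d x %d",
                 geo$L, geo$C, nrow(window), ncol(window)), call. = FALSE)
  }
  X <- array(0, dim = c(1, geo$L, geo$C))
  X[1, , ] <- window
  p <- cnn_forward_batch(model, X)
  stats::setNames(as.vector(p), model$classes)
}

#' Train the convolutional network by SGD with momentum
#'
#' Minimizes softmax cross-entropy plus L2 weight decay with classical
#' momentum updates (`v <- momentum * v - lr * grad; w <- w + v`) over
#' shuffled minibatches for a fixed epoch budget. Raw windows are
#' standardized per channel with training-set statistics.
#'
#' @param X Window array (n x L x C), e.g. from `emg_windows$windows`.
#' @param y Class labels.
#' @param cfg A [cnn_config()].
#' @return An `emg_cnn` model.
#' @export
cnn_train <- function(X, y, cfg = cnn_config()) {
  stopifnot(length(dim(X)) == 3)
  y <- factor(y)
  n <- dim(X)[1]
  if (n < 1) stop("need at least one training window", call. = FALSE)
  model <- cnn_init(dim(X)[2], dim(X)[3], nlevels(y), cfg)
  model$classes <- levels(y)
  mu <- apply(X, 3, mean)
  sd <- apply(X, 3, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  model$scaler <- list(mu = mu, sd = sd)
  Yk <- one_hot(y)
  vel <- list(conv_w = model$conv_w * 0, conv_b = model$conv_b * 0,
              fc_w = model$fc_w * 0, fc_b = model$fc_b * 0)
  losses <- numeric(cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, "cnn-epoch", epoch),
                     sample.int(n))
    batch_starts <- seq(1, n, by = cfg$batch_size)
    epoch_loss <- 0
    for (b in batch_starts) {
      idx <- ord[b:min(b + cfg$batch_size - 1, n)]
      Xb <- X[idx, , , drop = FALSE]
      Yb <- Yk[idx, , drop = FALSE]
      fwd <- cnn_forward_batch(model, Xb, keep = TRUE)
      loss <- cnn_loss_batch(model, fwd, Yb, cfg$l2)
      if (!is.finite(loss)) {
        stop(sprintf(
          "training diverged at epoch %d (non-finite loss); reduce `lr`",
          epoch
        ), call. = FALSE)
      }
      g <- cnn_backward_batch(model, fwd, Yb, cfg$l2)
      for (nm in names(vel)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$lr * g[[nm]]
        model[[nm]] <- model[[nm]] + vel[[nm]]
      }
      epoch_loss <- epoch_loss + loss * length(idx)
    }
    losses[epoch] <- epoch_loss / n
  }
  model$epoch_losses <- losses
  model
}

#' @export
predict.emg_cnn <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    X <- array(0, dim = c(1, nrow(newdata), ncol(newdata)))
    X[1, , ] <- newdata
    newdata <- X
  }
  n <- dim(newdata)[1]
  if (n == 0) return(factor(character(0), levels = object$classes))
  # chunked to bound the im2col working set
  chunk <- 4096
  labs <- integer(n)
  for (b in seq(1, n, by = chunk)) {
    idx <- b:min(b + chunk - 1, n)
    p <- cnn_forward_batch(object, newdata[idx, , , drop = FALSE])
    labs[idx] <- max.col(p, ties.method = "first")
  }
  factor(object$classes[labs], levels = object$classes)
}

#' @export
print.emg_cnn <- function(x, ...) {
  geo <- x$geometry
  cat(sprintf(
    "<emg_cnn> %dx%d input, %d filters %dx%d -> pool %dx1 -> %d classes\n",
    geo$L, geo$C, ncol(x$conv_w), geo$fh, geo$fw, geo$ph, length(x$classes)
  ))
  invisible(x)
}
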