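# Independent brute-force oracles used across tests. These are deliberately
# naive (scalar loops) and share no code with the package implementation.

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_wl <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}

oracle_zc <- function(x, threshold = 0) {
  n <- 0
  for (i in 1:(length(x) - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= threshold) n <- n + 1
  }
  n
}

oracle_ssc <- function(x, threshold = 0) {
  n <- 0
  for (i in 2:(length(x) - 1)) {
    d1 <- x[i] - x[i - 1]
    d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && max(abs(d1), abs(d2)) >= threshold) n <- n + 1
  }
  n
}

# Per-class discriminant loop for LDA: g_c(x) = x' Sinv mu_c
#   - 0.5 mu_c' Sinv mu_c + log pi_c, argmax with lowest-index tie-break.
oracle_lda_predict <- function(model, X) {
  K <- length(model$classes)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    best <- -Inf
    best_k <- 1
    for (k in seq_len(K)) {
      mu <- model$class_means[k, ]
      g <- sum(X[i, ] * (model$pooled_covariance_inverse %*% mu)) -
        0.5 * sum(mu * (model$pooled_covariance_inverse %*% mu)) +
        model$log_priors[k]
      if (g > best) {
        best <- g
        best_k <- k
      }
    }
    out[i] <- model$classes[best_k]
  }
  factor(out, levels = model$classes)
}

# Quadruple-loop convolution / pool / FC oracle for the CNN forward pass.
oracle_cnn_forward <- function(model, window) {
  geo <- model$geometry
  x <- sweep(sweep(window, 2, model$scaler$mu), 2, model$scaler$sd, "/")
  F <- ncol(model$conv_w)
  conv <- array(0, dim = c(geo$conv_r, geo$conv_c, F))
  for (f in seq_len(F)) {
    W <- matrix(model$conv_w[, f], geo$fh, geo$fw)  # row-major-in-time patch
    for (r in seq_len(geo$conv_r)) {
      for (c in seq_len(geo$conv_c)) {
        acc <- 0
        for (dr in seq_len(geo$fh)) {
          for (dc in seq_len(geo$fw)) {
            acc <- acc + x[r + dr - 1, c + dc - 1] * W[dr, dc]
          }
        }
        conv[r, c, f] <- max(acc + model$conv_b[f], 0)
      }
    }
  }
  pooled <- array(0, dim = c(geo$pool_r, geo$conv_c, F))
  for (f in seq_len(F)) {
    for (p in seq_len(geo$pool_r)) {
      for (c in seq_len(geo$conv_c)) {
        pooled[p, c, f] <- max(conv[((p - 1) * geo$ph + 1):(p * geo$ph), c, f])
      }
    }
  }
  feat <- numeric(geo$fc_in)
  i <- 0
  for (f in seq_len(F)) {
    for (c in seq_len(geo$conv_c)) {
      for (p in seq_len(geo$pool_r)) {
        i <- i + 1
        feat[i] <- pooled[p, c, f]
      }
    }
  }
  logits <- as.vector(t(model$fc_w) %*% feat) + model$fc_b
  e <- exp(logits - max(logits))
  e / sum(e)
}

# Central finite differences of fn at theta.
fd_gradient <- function(fn, theta, eps = 1e-6) {
  g <- numeric(length(theta))
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    g[i] <- (fn(tp) - fn(tm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(a)), max(abs(b)), 1e-12)
}

# Hand sums-of-squares decomposition for a balanced two-way layout with
# replication, computed from first principles.
oracle_two_way_ss <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  gm <- mean(y)
  ss_a <- 0
  for (a in levels(A)) ss_a <- ss_a + sum(A == a) * (mean(y[A == a]) - gm)^2
  ss_b <- 0
  for (b in levels(B)) ss_b <- ss_b + sum(B == b) * (mean(y[B == b]) - gm)^2
  ss_ab <- 0
  for (a in levels(A)) {
    for (b in levels(B)) {
      sel <- A == a & B == b
      ss_ab <- ss_ab + sum(sel) *
        (mean(y[sel]) - mean(y[A == a]) - mean(y[B == b]) + gm)^2
    }
  }
  ss_tot <- sum((y - gm)^2)
  list(A = ss_a, B = ss_b, AB = ss_ab,
       resid = ss_tot - ss_a - ss_b - ss_ab, total = ss_tot)
}
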