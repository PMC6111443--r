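#' Train a pooled-covariance linear discriminant classifier
#'
#' Classic multiclass LDA: class means, class-frequency priors, and a single
#' within-class (pooled) covariance. The discriminant for class c is
#' \deqn{g_c(x) = x^T \Sigma^{-1} \mu_c - \tfrac12 \mu_c^T \Sigma^{-1} \mu_c
#'   + \log \pi_c,}
#' and prediction is the argmax with ties broken toward the lower class
#' index. A small ridge (scaled by the mean covariance diagonal) keeps the
#' pooled covariance positive definite.
#'
#' @param x Numeric matrix, observations x features.
#' @param y Class labels (factor or coercible); at least 2 classes present.
#' @param ridge Ridge coefficient; `ridge * mean(diag(S))` is added to the
#'   diagonal of the pooled covariance `S`. Default `1e-6`. Set `ridge = 0`
#'   to disable (an error advises a ridge if `S` is then singular).
#' @return An `emg_lda` model.
#' @export
lda_train <- function(x, y, ridge = 1e-6) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) {
    stop("lda_train needs at least 2 classes present", call. = FALSE)
  }
  y <- droplevels(y)
  K <- nlevels(y)
  D <- ncol(x)
  n <- nrow(x)
  means <- matrix(0, K, D, dimnames = list(levels(y), colnames(x)))
  S <- matrix(0, D, D)
  for (k in seq_len(K)) {
    xk <- x[y == levels(y)[k], , drop = FALSE]
    means[k, ] <- colMeans(xk)
    if (nrow(xk) > 1) {
      xc <- sweep(xk, 2, means[k, ])
      S <- S + crossprod(xc)
    }
  }
  S <- S / (n - K)
  if (ridge > 0) S <- S + diag(ridge * mean(diag(S)), D)
  Sinv <- tryCatch(
    chol2inv(chol(S)),
    error = function(e) stop(
      "pooled covariance is singular; set a positive `ridge`",
      call. = FALSE
    )
  )
  structure(
    list(
      class_means = means,
      pooled_covariance_inverse = Sinv,
      log_priors = log(as.vector(table(y)) / n),
      classes = levels(y),
      ridge = ridge
    ),
    class = "emg_lda"
  )
}

#' Discriminant scores of an LDA model
#'
#' @param model An `emg_lda`.
#' @param x Matrix of observations (features must match the model).
#' @return Matrix of discriminant values, observations x classes.
#' @export
lda_scores <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$class_means)) {
    stop(sprintf("feature dimension mismatch: model %d, data %d",
                 ncol(model$class_means), ncol(x)), call. = FALSE)
  }
  A <- model$pooled_covariance_inverse %*% t(model$class_means)   # D x K
  const <- -0.5 * colSums(t(model$class_means) * A) + model$log_priors
  sweep(x %*% A, 2, const, "+")
}

#' @export
predict.emg_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) {
    return(factor(character(0), levels = object$classes))
  }
  g <- lda_scores(object, newdata)
  factor(object$classes[max.col(g, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.emg_lda <- function(x, ...) {
  cat(sprintf("<emg_lda> %d classes, %d features, ridge %g\n",
              length(x$classes), ncol(x$class_means), x$ridge))
  invisible(x)
}
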