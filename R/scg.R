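#' Scaled conjugate gradient minimization
#'
#' Moller's scaled conjugate gradient (SCG) algorithm: a conjugate-gradient
#' method whose step size comes from a Levenberg-Marquardt-style scaling of
#' a finite-difference curvature estimate, avoiding line searches. This is
#' the optimizer used for autoencoder pretraining and the softmax head.
#'
#' @param par Numeric vector of initial parameters.
#' @param fn Objective function `fn(par) -> scalar`.
#' @param gr Gradient function `gr(par) -> vector`.
#' @param max_iters Iteration budget.
#' @param grad_tol Stop when the gradient norm falls below this.
#' @param sigma0 Relative step for the curvature estimate (Moller's sigma).
#' @param lambda0 Initial scale parameter (Moller's lambda).
#' @return List with `par`, `value`, `iterations`, `converged`, and `trace`
#'   (objective after each accepted step).
#' @references Moller, M. F. (1993). A scaled conjugate gradient algorithm
#'   for fast supervised learning. Neural Networks 6(4), 525-533.
#' @export
scg_minimize <- function(par, fn, gr, max_iters = 400, grad_tol = 1e-6,
                         sigma0 = 1e-5, lambda0 = 1e-6) {
  w <- par
  N <- length(w)
  f_w <- fn(w)
  if (!is.finite(f_w)) stop("non-finite objective at initial point",
                            call. = FALSE)
  r <- -gr(w)
  p <- r
  lambda <- lambda0
  lambda_bar <- 0
  success <- TRUE
  k <- 0
  delta <- 0
  trace <- numeric(0)
  while (k < max_iters) {
    k <- k + 1
    p2 <- sum(p * p)
    if (sqrt(sum(r * r)) < grad_tol || p2 < .Machine$double.eps) break
    if (success) {
      sigma_k <- sigma0 / sqrt(p2)
      s <- (gr(w + sigma_k * p) + r) / sigma_k    # gr(w) = -r
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {       # make the Hessian approximation positive definite
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    f_new <- fn(w + alpha * p)
    Delta <- if (is.finite(f_new)) 2 * delta * (f_w - f_new) / mu^2 else -1
    if (Delta >= 0) {       # accepted step
      w <- w + alpha * p
      f_w <- f_new
      if (!is.finite(f_w)) {
        stop(sprintf("non-finite loss at SCG iteration %d", k), call. = FALSE)
      }
      trace <- c(trace, f_w)
      g_new <- gr(w)
      r_new <- -g_new
      lambda_bar <- 0
      success <- TRUE
      if (k %% N == 0) {
        p <- r_new          # periodic restart along the gradient
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (lambda > 1e100) break
  }
  list(par = w, value = f_w, iterations = k,
       converged = sqrt(sum(r * r)) < grad_tol, trace = trace)
}
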