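test_that("forward pass equals the quadruple-loop oracle on a 30x8 window", {
  set.seed(1)
  model <- emgdrift:::cnn_init(30, 8, 7, cnn_config(seed = 3))
  model$classes <- movement_classes()
  model$scaler <- list(mu = rnorm(8), sd = runif(8, 0.5, 2))
  w <- matrix(rnorm(240), 30, 8)
  p_fast <- cnn_forward(model, w)
  p_loop <- oracle_cnn_forward(model, w)
  expect_lt(max(abs(as.vector(p_fast) - p_loop)), 1e-6)
  expect_equal(sum(p_fast), 1)
  expect_true(all(p_fast >= 0))
  expect_error(cnn_forward(model, matrix(0, 10, 8)), "30 x 8")
})

test_that("parameter counts match the stated architecture", {
  model <- emgdrift:::cnn_init(30, 8, 7, cnn_config())
  # conv: 3*3*1*32 weights + 32 biases
  expect_equal(length(model$conv_w) + length(model$conv_b), 320)
  # valid conv 28x6, pool 3x1 floor -> 9x6x32 = 1728; FC to 7 logits
  expect_equal(model$geometry$conv_r, 28)
  expect_equal(model$geometry$conv_c, 6)
  expect_equal(model$geometry$pool_r, 9)
  expect_equal(length(model$fc_w) + length(model$fc_b), 9 * 6 * 32 * 7 + 7)
})

test_that("CNN gradients match finite differences on a micro-network", {
  cfg <- cnn_config(n_filters = 2, filter_shape = c(3, 3),
                    pool_shape = c(2, 1), seed = 5)
  model <- emgdrift:::cnn_init(4, 4, 2, cfg)   # 4x4 input, 2 filters, 2 classes
  model$classes <- c("a", "b")
  set.seed(6)
  n <- 3
  X <- array(rnorm(n * 4 * 4), dim = c(n, 4, 4))
  Yk <- emgdrift:::one_hot(c("a", "b", "a"))
  l2 <- 1e-3
  pack <- function(m) c(as.vector(m$conv_w), m$conv_b,
                        as.vector(m$fc_w), m$fc_b)
  unpack <- function(m, th) {
    i <- 0
    m$conv_w <- matrix(th[1:length(m$conv_w)], nrow(m$conv_w)); i <- length(m$conv_w)
    m$conv_b <- th[(i + 1):(i + length(m$conv_b))]; i <- i + length(m$conv_b)
    m$fc_w <- matrix(th[(i + 1):(i + length(m$fc_w))], nrow(m$fc_w))
    i <- i + length(m$fc_w)
    m$fc_b <- th[(i + 1):(i + length(m$fc_b))]
    m
  }
  fn <- function(th) {
    m <- unpack(model, th)
    fwd <- emgdrift:::cnn_forward_batch(m, X, keep = TRUE)
    emgdrift:::cnn_loss_batch(m, fwd, Yk, l2)
  }
  theta <- pack(model)
  fwd <- emgdrift:::cnn_forward_batch(model, X, keep = TRUE)
  g <- emgdrift:::cnn_backward_batch(model, fwd, Yk, l2)
  analytic <- c(as.vector(g$conv_w), g$conv_b, as.vector(g$fc_w), g$fc_b)
  numeric <- fd_gradient(fn, theta, eps = 1e-6)
  expect_lt(max_rel_err(analytic, numeric), 1e-5)
})

test_that("training is deterministic and fits an easy 2-class problem", {
  set.seed(7)
  n <- 80
  X <- array(rnorm(n * 30 * 8, sd = 0.2), dim = c(n, 30, 8))
  y <- rep(c("CH", "OH"), each = n / 2)
  X[y == "CH", , 1:2] <- X[y == "CH", , 1:2] + 1.5
  X[y == "OH", , 5:6] <- X[y == "OH", , 5:6] + 1.5
  cfg <- cnn_config(max_epochs = 10, batch_size = 32, lr = 0.05, seed = 8)
  f1 <- cnn_train(X, y, cfg)
  f2 <- cnn_train(X, y, cfg)
  expect_identical(f1$conv_w, f2$conv_w)
  expect_identical(f1$fc_w, f2$fc_w)
  expect_identical(f1$epoch_losses, f2$epoch_losses)
  expect_gt(mean(predict(f1, X) == y), 0.95)
  f3 <- cnn_train(X, y, cnn_config(max_epochs = 10, batch_size = 32,
                                   lr = 0.05, seed = 9))
  expect_false(identical(f1$conv_w, f3$conv_w))
})

test_that("divergence is reported with advice to reduce the learning rate", {
  set.seed(9)
  n <- 16
  X <- array(rnorm(n * 30 * 8), dim = c(n, 30, 8)) * 10
  y <- rep(c("CH", "OH"), each = n / 2)
  expect_error(
    cnn_train(X, y, cnn_config(lr = 1e80, max_epochs = 5, batch_size = 8,
                               seed = 1)),
    "lr"
  )
})
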