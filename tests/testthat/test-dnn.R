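test_that("layer forward implements f(Wx + b)", {
  id <- layer_params(diag(3), rep(0, 3), "relu")
  expect_equal(layer_forward(c(1, 2, 3), id), c(1, 2, 3))
  expect_equal(layer_forward(c(-1, 2, -3), id), c(0, 2, 0))
  sig <- layer_params(matrix(c(1, 2), 1), 0.5, "sigmoid")
  expect_equal(layer_forward(c(1, 1), sig), 1 / (1 + exp(-3.5)), tolerance = 1e-12)
  expect_error(layer_forward(c(1, 2), id), "features")
})

test_that("mlp forward composes layers", {
  m <- mlp_init(3, hidden = integer(0), seed = 1)
  m$layers <- list(layer_params(diag(3), rep(0, 3), "identity"))
  m$output_dim <- 3L
  expect_equal(mlp_forward(c(1, -2, 3), m), c(1, -2, 3))

  m2 <- m
  m2$layers <- list(
    layer_params(2 * diag(3), rep(0, 3), "identity"),
    layer_params(3 * diag(3), rep(0, 3), "identity")
  )
  expect_equal(mlp_forward(c(1, -2, 3), m2), 6 * c(1, -2, 3))

  # independent hand-rolled matrix arithmetic oracle on a random 2-layer net
  m3 <- mlp_init(4, hidden = 5, seed = 9)
  x <- phytofuse:::with_seed(2, stats::rnorm(4))
  W1 <- m3$layers[[1]]$W; b1 <- m3$layers[[1]]$b
  W2 <- m3$layers[[2]]$W; b2 <- m3$layers[[2]]$b
  by_hand <- drop(W2 %*% pmax(W1 %*% x + b1, 0) + b2)
  expect_equal(mlp_forward(x, m3), by_hand, tolerance = 1e-12)
})

test_that("the gradient-descent update is theta - eta * grad", {
  expect_equal(grad_step(c(1, 2), c(0, 0), 0.1), c(1, 2))
  expect_equal(grad_step(1, 2, 0.001), 0.998)
  expect_equal(
    grad_step(list(W = diag(2), b = c(1, 1)), list(W = diag(2), b = c(2, 0)), 0.5),
    list(W = 0.5 * diag(2), b = c(0, 1))
  )
  # geometric convergence on the quadratic (theta - 3)^2
  theta <- 0
  for (i in 1:100) theta <- grad_step(theta, 2 * (theta - 3), 0.1)
  expect_lt(abs(theta - 3), 1e-6)
  expect_error(grad_step(c(1, 2), 1, 0.1), "shape")
})

test_that("backprop gradients match central finite differences", {
  shapes <- list(
    list(input = 3, hidden = c(4), act = "relu"),
    list(input = 5, hidden = c(6, 4), act = "relu"),
    list(input = 4, hidden = c(5, 3), act = "sigmoid"),
    list(input = 2, hidden = c(8), act = "sigmoid")
  )
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    m <- mlp_init(sh$input, hidden = sh$hidden, activation = sh$act, seed = 40 + i)
    dat <- phytofuse:::with_seed(60 + i, list(
      X = matrix(stats::rnorm(3 * sh$input), 3), y = stats::rnorm(3)
    ))
    an <- phytofuse:::grads_flat(m, dat$X, dat$y)$grads
    num <- finite_diff_grads(m, dat$X, dat$y)
    expect_lt(max_rel_grad_err(an, num), 1e-5)
  }
})

test_that("backprop boundary behaviour: zero at the optimum, linear in residuals", {
  m <- mlp_init(2, hidden = 3, seed = 7)
  x <- c(0.3, -0.4)
  y_star <- mlp_forward(x, m)
  bp <- mlp_backprop(m, matrix(x, 1), y_star)
  expect_true(all(vapply(bp$grads, function(g) max(abs(g$W), abs(g$b)), numeric(1)) < 1e-12))

  bp1 <- mlp_backprop(m, matrix(x, 1), y_star - 1)
  bp2 <- mlp_backprop(m, matrix(x, 1), y_star - 2)
  L <- length(bp1$grads)
  expect_equal(bp2$grads[[L]]$b, 2 * bp1$grads[[L]]$b, tolerance = 1e-12)
})

test_that("training is seeded, deterministic, and skippable", {
  ds <- phytofuse:::with_seed(3, {
    X <- matrix(stats::rnorm(200), 50)
    list(X = X, y = drop(X %*% c(1, -2, 0.5, 1)) + stats::rnorm(50, sd = 0.01))
  })
  m <- mlp_init(4, hidden = 8, seed = 5)
  cfg <- train_config(epochs = 0)
  out0 <- train_model(m, ds$X, ds$y, config = cfg)
  expect_identical(phytofuse:::get_params(out0$model), phytofuse:::get_params(m))
  expect_identical(nrow(out0$history), 0L)

  cfg5 <- train_config(epochs = 5, seed = 17)
  a <- train_model(m, ds$X, ds$y, ds$X, ds$y, cfg5)
  b <- train_model(m, ds$X, ds$y, ds$X, ds$y, cfg5)
  expect_identical(a$history, b$history)
  expect_identical(phytofuse:::get_params(a$model), phytofuse:::get_params(b$model))
})

test_that("a linear-capacity net approaches the least-squares noise floor", {
  sigma <- 0.01
  n <- 4000 # enough optimizer steps at the default batch size to reach the floor
  ds <- phytofuse:::with_seed(8, {
    X <- matrix(stats::rnorm(4 * n), n)
    w_star <- c(0.8, -1.2, 0.5, 0.3)
    list(X = X, y = drop(X %*% w_star) + stats::rnorm(n, sd = sigma))
  })
  m <- mlp_init(4, hidden = integer(0), seed = 2) # single linear layer
  fit <- train_model(m, ds$X, ds$y, config = train_config(
    epochs = 100, augment_noise_sd = 0, seed = 4
  ))
  final_mse <- mean((predict_batch(fit$model, ds$X) - ds$y)^2)
  # the OLS fit bounds what any linear model can achieve
  ols_mse <- mean(stats::lm.fit(ds$X, ds$y)$residuals^2)
  expect_lte(final_mse, 2 * sigma^2)
  expect_gte(final_mse, ols_mse - 1e-12)
  expect_lt(fit$history$train_loss[100], fit$history$train_loss[1])
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- phytofuse:::with_seed(1, list(X = matrix(stats::rnorm(40), 10), y = stats::rnorm(10)))
  m <- mlp_init(4, hidden = 4, seed = 1)
  expect_error(
    train_model(m, ds$X, ds$y, config = train_config(
      learning_rate = 1e6, optimizer = "gd", epochs = 50
    )),
    "non-finite"
  )
})
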