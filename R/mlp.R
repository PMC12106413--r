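# Feed-forward network: layer rule y^l = f(W^l x^{l-1} + b^l), exact
# reverse-mode gradients of the batch-mean squared error.

activation_fn <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    sigmoid = list(
      f = function(z) 1 / (1 + exp(-z)),
      df = function(z, a) a * (1 - a)
    ),
    identity = list(f = function(z) z, df = function(z, a) array(1, dim(z))),
    stop(sprintf("unknown activation '%s'", name), call. = FALSE)
  )
}

#' Construct one fully connected layer
#'
#' @param W Weight matrix, `out x in`.
#' @param b Bias vector, length `out`.
#' @param activation `"relu"`, `"sigmoid"`, or `"identity"`.
#' @return Object of class `layer_params`.
#' @export
layer_params <- function(W, b, activation = c("relu", "sigmoid", "identity")) {
  activation <- match.arg(activation)
  W <- as.matrix(W)
  b <- as.numeric(b)
  if (nrow(W) != length(b)) {
    stop("bias length must equal the layer's output dimension", call. = FALSE)
  }
  structure(list(W = W, b = b, activation = activation), class = "layer_params")
}

#' Forward pass through one layer
#'
#' Computes `f(W x + b)` elementwise: the weighted sum plus bias, passed
#' through the activation.
#'
#' @param x Input vector of the layer's input dimension, or an `n x in`
#'   matrix of row vectors.
#' @param layer A [layer_params()] object.
#' @return Activated output, same row structure as `x`.
#' @export
layer_forward <- function(x, layer) {
  stopifnot(inherits(layer, "layer_params"))
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(xm) != ncol(layer$W)) {
    stop(sprintf(
      "input has %d features but layer expects %d", ncol(xm), ncol(layer$W)
    ), call. = FALSE)
  }
  z <- xm %*% t(layer$W) + rep(layer$b, each = nrow(xm))
  a <- activation_fn(layer$activation)$f(z)
  if (is.matrix(x)) a else drop(a)
}

#' Initialize a multilayer perceptron
#'
#' Builds a fully connected regression network with the given hidden widths,
#' hidden activation, and a linear (identity) output head. Weights use
#' He-style scaled uniform initialization `U(-sqrt(6/fan_in),
#' sqrt(6/fan_in))`; biases start at zero.
#'
#' @param input_dim Number of input features (a flattened window `T * d`).
#' @param hidden Integer vector of hidden-layer widths; default two layers of
#'   64 units.
#' @param activation Hidden activation, `"relu"` (default) or `"sigmoid"`.
#' @param output_dim Output dimension (1 for scalar forecasting).
#' @param seed Integer seed for the weight draw.
#' @return Object of class `mlp_model`.
#' @export
mlp_init <- function(input_dim, hidden = c(64, 64),
                     activation = c("relu", "sigmoid"),
                     output_dim = 1L, seed = 1L) {
  activation <- match.arg(activation)
  input_dim <- check_count(input_dim, "input_dim")
  output_dim <- check_count(output_dim, "output_dim")
  dims <- c(input_dim, hidden, output_dim)
  acts <- c(rep(activation, length(hidden)), "identity")
  layers <- with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]
      lim <- sqrt(6 / fan_in)
      W <- matrix(stats::runif(dims[l + 1L] * fan_in, -lim, lim),
        nrow = dims[l + 1L]
      )
      layer_params(W, rep(0, dims[l + 1L]), acts[l])
    })
  })
  structure(
    list(layers = layers, input_dim = input_dim, output_dim = output_dim),
    class = "mlp_model"
  )
}

#' @export
print.mlp_model <- function(x, ...) {
  widths <- vapply(x$layers, function(l) nrow(l$W), integer(1))
  cat(sprintf(
    "Feed-forward network: %d -> %s (%s hidden activation)\n",
    x$input_dim, paste(widths, collapse = " -> "),
    x$layers[[1]]$activation
  ))
  invisible(x)
}

#' Forward pass through a multilayer perceptron
#'
#' @param x Input vector or `n x input_dim` matrix.
#' @param model An `mlp_model`.
#' @return Prediction vector (length `n` for scalar output).
#' @export
mlp_forward <- function(x, model) {
  stopifnot(inherits(model, "mlp_model"))
  if (length(model$layers) == 0L) stop("model has no layers", call. = FALSE)
  was_vector <- !is.matrix(x)
  a <- if (was_vector) matrix(x, nrow = 1) else x
  for (layer in model$layers) a <- layer_forward(a, layer)
  if (model$output_dim == 1L || was_vector) drop(a) else a
}

#' One gradient-descent step
#'
#' The parameter update `theta - eta * grad`. Accepts numerics, matrices, or
#' (possibly nested) lists of them, which are updated recursively.
#'
#' @param theta Current parameter value(s).
#' @param grad Gradient with the same structure.
#' @param eta Learning rate, `> 0`.
#' @return Updated parameters, same structure as `theta`.
#' @export
grad_step <- function(theta, grad, eta) {
  check_scalar(eta, "eta", lower = 0, strict_lower = TRUE)
  step <- function(p, g) {
    if (is.list(p)) {
      stopifnot(is.list(g), length(p) == length(g))
      return(mapply(step, p, g, SIMPLIFY = FALSE))
    }
    if (length(p) != length(g)) stop("gradient shape mismatch", call. = FALSE)
    p - eta * g
  }
  step(theta, grad)
}

#' Backpropagation through a multilayer perceptron
#'
#' Exact reverse-mode gradients of the batch-mean squared error
#' `mean((pred - y)^2)` with respect to every weight matrix and bias.
#'
#' @param model An `mlp_model`.
#' @param X `n x input_dim` matrix of inputs (a vector is treated as one row).
#' @param y Length-`n` target vector.
#' @return List with `grads` (per layer: `W`, `b`), `loss`, and `pred`.
#' @export
mlp_backprop <- function(model, X, y) {
  stopifnot(inherits(model, "mlp_model"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  n <- nrow(X)
  if (n == 0L) stop("empty batch", call. = FALSE)
  stopifnot(length(y) == n)

  L <- length(model$layers)
  zs <- vector("list", L)
  as_ <- vector("list", L + 1L)
  as_[[1]] <- X
  for (l in seq_len(L)) {
    layer <- model$layers[[l]]
    z <- as_[[l]] %*% t(layer$W) + rep(layer$b, each = n)
    if (any(!is.finite(z))) stop("non-finite activations in forward pass", call. = FALSE)
    zs[[l]] <- z
    as_[[l + 1L]] <- activation_fn(layer$activation)$f(z)
  }
  pred <- drop(as_[[L + 1L]])
  resid <- pred - y
  loss <- mean(resid^2)

  grads <- vector("list", L)
  delta <- matrix(2 * resid / n, ncol = 1) # identity head
  for (l in rev(seq_len(L))) {
    layer <- model$layers[[l]]
    act <- activation_fn(layer$activation)
    dz <- delta * act$df(zs[[l]], as_[[l + 1L]])
    grads[[l]] <- list(W = t(dz) %*% as_[[l]], b = colSums(dz))
    if (l > 1L) delta <- dz %*% layer$W
  }
  list(grads = grads, loss = loss, pred = pred)
}

# Parameter plumbing shared with the trainer ---------------------------------

#' @export
get_params.mlp_model <- function(model) {
  params <- list()
  for (l in seq_along(model$layers)) {
    params[[paste0("W", l)]] <- model$layers[[l]]$W
    params[[paste0("b", l)]] <- model$layers[[l]]$b
  }
  params
}

#' @export
set_params.mlp_model <- function(model, params) {
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$W <- params[[paste0("W", l)]]
    model$layers[[l]]$b <- params[[paste0("b", l)]]
  }
  model
}

#' @export
grads_flat.mlp_model <- function(model, X, y) {
  bp <- mlp_backprop(model, X, y)
  flat <- list()
  for (l in seq_along(bp$grads)) {
    flat[[paste0("W", l)]] <- bp$grads[[l]]$W
    flat[[paste0("b", l)]] <- bp$grads[[l]]$b
  }
  list(grads = flat, loss = bp$loss)
}

#' @export
predict_batch.mlp_model <- function(model, X) mlp_forward(X, model)
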