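# Shared minibatch training loop for the feed-forward and attention
# forecasters: plain gradient descent (the printed update rule) or Adam.

get_params <- function(model) UseMethod("get_params")
set_params <- function(model, params) UseMethod("set_params")
grads_flat <- function(model, X, y) UseMethod("grads_flat")

#' Predict over a batch of windows
#'
#' Dispatches on the forecaster class: an `mlp_model` consumes an
#' `n x (T*d)` matrix of flattened windows, an `attention_model` an
#' `n x T x d` array (or list of `T x d` matrices).
#'
#' @param model A trained `mlp_model` or `attention_model`.
#' @param X Batch of inputs in the model's format.
#' @return Numeric vector of predictions.
#' @export
predict_batch <- function(model, X) UseMethod("predict_batch")

#' Training configuration
#'
#' Defaults follow the experiment configuration used throughout the package:
#' Adam with learning rate 0.001, batch size 32, 100 epochs, mean-squared
#'-error loss. Plain gradient descent (`optimizer = "gd"`) applies the
#' textbook update `theta - eta * grad` instead. `augment_noise_sd` adds
#' i.i.d. Gaussian noise to training inputs each step (in standardized
#' units) to enrich the training data; 0 disables augmentation.
#'
#' @param learning_rate Step size `eta`, `> 0`.
#' @param batch_size Minibatch size, `>= 1`.
#' @param epochs Number of training epochs, `>= 0`.
#' @param optimizer `"adam"` (default) or `"gd"`.
#' @param augment_noise_sd Sd of Gaussian input augmentation (default 0.01
#'   standardized units).
#' @param seed Integer seed governing shuffling and augmentation.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 32L, epochs = 100L,
                         optimizer = c("adam", "gd"),
                         augment_noise_sd = 0.01, seed = 1L) {
  optimizer <- match.arg(optimizer)
  structure(
    list(
      learning_rate = check_scalar(learning_rate, "learning_rate",
        lower = 0, strict_lower = TRUE
      ),
      batch_size = check_count(batch_size, "batch_size", lower = 1L),
      epochs = check_count(epochs, "epochs", lower = 0L),
      optimizer = optimizer,
      augment_noise_sd = check_scalar(augment_noise_sd, "augment_noise_sd", lower = 0),
      seed = check_count(seed, "seed", lower = 0L)
    ),
    class = "train_config"
  )
}

subset_inputs <- function(X, idx) {
  if (is.matrix(X)) X[idx, , drop = FALSE] else X[idx, , , drop = FALSE]
}

perturb_inputs <- function(X, sd) {
  if (sd <= 0) return(X)
  X + stats::rnorm(length(X), sd = sd)
}

#' Train a forecaster by minibatch gradient descent or Adam
#'
#' Runs seeded minibatch training of an `mlp_model` (on flattened windows,
#' `n x (T*d)` matrices) or an `attention_model` (on `n x T x d` window
#' arrays), minimizing mean squared error. The per-epoch training loss is the
#' average of the minibatch losses; the validation loss is computed on the
#' full validation set after each epoch. Training aborts with a diagnostic if
#' the loss becomes non-finite.
#'
#' @param model An `mlp_model` or `attention_model`.
#' @param x_train,y_train Training inputs and targets.
#' @param x_val,y_val Optional validation inputs and targets.
#' @param config A [train_config()].
#' @return List with `model` (trained) and `history` (data frame `epoch`,
#'   `train_loss`, `val_loss`).
#' @export
train_model <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                        config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  n <- length(y_train)
  if (n == 0L) stop("empty training set", call. = FALSE)

  params <- get_params(model)
  opt_state <- NULL
  if (config$optimizer == "adam") {
    zeros <- lapply(params, function(x) x * 0)
    opt_state <- list(m = zeros, v = zeros, t = 0L)
  }
  eta <- config$learning_rate

  history <- data.frame(
    epoch = integer(0), train_loss = numeric(0), val_loss = numeric(0)
  )
  if (config$epochs == 0L) {
    return(list(model = model, history = history))
  }

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample.int(n)
      batch_starts <- seq(1L, n, by = config$batch_size)
      batch_losses <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        idx <- order_idx[batch_starts[bi]:min(batch_starts[bi] + config$batch_size - 1L, n)]
        Xb <- perturb_inputs(subset_inputs(x_train, idx), config$augment_noise_sd)
        gf <- grads_flat(set_params(model, params), Xb, y_train[idx])
        if (!is.finite(gf$loss)) {
          stop(sprintf(
            "training aborted: non-finite loss at epoch %d, batch %d", epoch, bi
          ), call. = FALSE)
        }
        batch_losses[bi] <- gf$loss
        if (config$optimizer == "gd") {
          params <- grad_step(params, gf$grads, eta)
        } else {
          opt_state$t <- opt_state$t + 1L
          b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
          for (nm in names(params)) {
            g <- gf$grads[[nm]]
            opt_state$m[[nm]] <- b1 * opt_state$m[[nm]] + (1 - b1) * g
            opt_state$v[[nm]] <- b2 * opt_state$v[[nm]] + (1 - b2) * g^2
            mhat <- opt_state$m[[nm]] / (1 - b1^opt_state$t)
            vhat <- opt_state$v[[nm]] / (1 - b2^opt_state$t)
            params[[nm]] <- params[[nm]] - eta * mhat / (sqrt(vhat) + eps)
          }
        }
      }
      val_loss <- NA_real_
      if (!is.null(x_val)) {
        pv <- predict_batch(set_params(model, params), x_val)
        val_loss <- mean((pv - y_val)^2)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(batch_losses), val_loss = val_loss
      ))
    }
  })
  list(model = set_params(model, params), history = history)
}
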