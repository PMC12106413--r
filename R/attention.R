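# Multi-head scaled-dot-product attention encoder for window-level
# forecasting, with an exact analytic backward pass.

row_softmax <- function(S) {
  # max-subtraction keeps exp() finite for logits of any magnitude
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Project a window into query, key and value spaces
#'
#' Plain matrix products `Q = X W_Q`, `K = X W_K`, `V = X W_V` mapping the
#' `T x d` input window into a `d_k`-dimensional subspace for one attention
#' head.
#'
#' @param X Input window, `T x d`.
#' @param W_Q,W_K,W_V Projection matrices, each `d x d_k`.
#' @return List with matrices `Q`, `K`, `V`, each `T x d_k`.
#' @export
project_qkv <- function(X, W_Q, W_K, W_V) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(W_Q) || ncol(X) != nrow(W_K) || ncol(X) != nrow(W_V)) {
    stop("projection matrices must have d rows matching ncol(X)", call. = FALSE)
  }
  list(Q = X %*% W_Q, K = X %*% W_K, V = X %*% W_V)
}

#' Scaled dot-product attention
#'
#' Computes the attention matrix `A = softmax(Q K' / sqrt(d_k))` row-wise and
#' the attended output `A V`. Every row of `A` is a probability vector, so
#' each output row is a convex combination of the rows of `V`.
#'
#' @param Q,K Query and key matrices with `d_k` columns.
#' @param V Value matrix with as many rows as `K`.
#' @param d_k Key dimension used in the `1/sqrt(d_k)` scaling; defaults to
#'   `ncol(K)`.
#' @return List with `output` (`nrow(Q) x ncol(V)`) and the row-stochastic
#'   attention matrix `A`.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (d_k <= 0) stop("'d_k' must be positive", call. = FALSE)
  if (ncol(Q) != ncol(K)) stop("Q and K must share the key dimension", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must have the same number of rows", call. = FALSE)
  A <- row_softmax(Q %*% t(K) / sqrt(d_k))
  list(output = A %*% V, A = A)
}

#' Initialize a multi-head attention forecaster
#'
#' Per-head query/key/value projections, an output map `W_O` over the
#' concatenated head outputs, and an affine prediction head applied to the
#' pooled window representation. As in the printed attention equations there
#' is no positional encoding by default; an optional sinusoidal encoding can
#' be switched on.
#'
#' @param d Input feature dimension.
#' @param h Number of attention heads (default 4).
#' @param d_k Per-head subspace dimension (default 16).
#' @param pooling How the `T x d` encoder output becomes one representation:
#'   `"last"` row (default, the forecasting convention) or `"mean"`.
#' @param positional If `TRUE`, add a sinusoidal positional encoding to the
#'   window before projection (off by default; the attention equations alone
#'   are permutation-equivariant).
#' @param seed Integer seed for the weight draw.
#' @return Object of class `attention_model`.
#' @export
attention_init <- function(d, h = 4L, d_k = 16L, pooling = c("last", "mean"),
                           positional = FALSE, seed = 1L) {
  pooling <- match.arg(pooling)
  d <- check_count(d, "d"); h <- check_count(h, "h"); d_k <- check_count(d_k, "d_k")
  params <- with_seed(seed, {
    lim <- sqrt(6 / d)
    draw <- function(nr, nc, l) matrix(stats::runif(nr * nc, -l, l), nr, nc)
    p <- list()
    for (j in seq_len(h)) {
      p[[paste0("W_Q", j)]] <- draw(d, d_k, lim)
      p[[paste0("W_K", j)]] <- draw(d, d_k, lim)
      p[[paste0("W_V", j)]] <- draw(d, d_k, lim)
    }
    p$W_O <- draw(h * d_k, d, sqrt(6 / (h * d_k)))
    p$head_w <- stats::runif(d, -sqrt(6 / d), sqrt(6 / d))
    p$head_b <- 0
    p
  })
  structure(
    list(params = params, d = d, h = h, d_k = d_k,
         pooling = pooling, positional = positional),
    class = "attention_model"
  )
}

#' @export
print.attention_model <- function(x, ...) {
  cat(sprintf(
    "Multi-head attention forecaster: %d heads x d_k = %d over d = %d features (%s pooling%s)\n",
    x$h, x$d_k, x$d, x$pooling,
    if (x$positional) ", sinusoidal positional encoding" else ""
  ))
  invisible(x)
}

positional_encoding <- function(T, d) {
  pe <- matrix(0, T, d)
  pos <- seq_len(T) - 1
  for (i in seq_len(d)) {
    angle <- pos / 10000^((2 * ((i - 1) %/% 2)) / d)
    pe[, i] <- if (i %% 2 == 1) sin(angle) else cos(angle)
  }
  pe
}

#' Multi-head attention over a window
#'
#' Runs every head's scaled dot-product attention on `X`, concatenates the
#' head outputs along the feature axis and applies the output map `W_O`,
#' returning a `T x d` representation plus each head's attention matrix.
#'
#' @param X Input window, `T x d`.
#' @param model An `attention_model`.
#' @return List with `output` (`T x d`) and `attention` (list of `T x T`
#'   row-stochastic matrices, one per head).
#' @export
multi_head <- function(X, model) {
  stopifnot(inherits(model, "attention_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    stop(sprintf("window has %d features, model expects %d", ncol(X), model$d),
      call. = FALSE
    )
  }
  if (model$positional) X <- X + positional_encoding(nrow(X), model$d)
  p <- model$params
  if (nrow(p$W_O) != model$h * model$d_k) {
    stop("W_O rows must equal h * d_k", call. = FALSE)
  }
  outs <- vector("list", model$h)
  attn <- vector("list", model$h)
  for (j in seq_len(model$h)) {
    qkv <- project_qkv(X, p[[paste0("W_Q", j)]], p[[paste0("W_K", j)]],
      p[[paste0("W_V", j)]]
    )
    sda <- scaled_dot_attention(qkv$Q, qkv$K, qkv$V, model$d_k)
    outs[[j]] <- sda$output
    attn[[j]] <- sda$A
  }
  concat <- do.call(cbind, outs)
  list(output = concat %*% p$W_O, attention = attn)
}

#' Encode a window and predict the next value
#'
#' Pools the multi-head output over time (last row by default, mean
#' optionally) and applies the affine prediction head, yielding the scalar
#' one-step-ahead forecast for the window.
#'
#' @param X Input window, `T x d` (non-empty).
#' @param model An `attention_model`.
#' @param pooling Override of the model's pooling, if given.
#' @return Scalar prediction.
#' @export
temporal_encode_predict <- function(X, model, pooling = NULL) {
  stopifnot(inherits(model, "attention_model"))
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty window", call. = FALSE)
  pooling <- if (is.null(pooling)) model$pooling else match.arg(pooling, c("last", "mean"))
  mh <- multi_head(X, model)
  pooled <- if (pooling == "last") mh$output[nrow(X), ] else colMeans(mh$output)
  sum(model$params$head_w * pooled) + model$params$head_b
}

#' Backpropagation through the attention forecaster
#'
#' Exact reverse-mode gradients of the batch-mean squared error with respect
#' to every parameter: per-head `W_Q`, `W_K`, `W_V`, the output map `W_O`,
#' and the affine prediction head.
#'
#' @param model An `attention_model`.
#' @param X_list List of `T x d` windows (one per batch element).
#' @param y Length-matching target vector.
#' @return List with `grads` (named like the model parameters), `loss`, and
#'   `pred`.
#' @export
attention_backprop <- function(model, X_list, y) {
  stopifnot(inherits(model, "attention_model"))
  n <- length(X_list)
  if (n == 0L) stop("empty batch", call. = FALSE)
  stopifnot(length(y) == n)
  p <- model$params
  h <- model$h; d_k <- model$d_k
  scale <- 1 / sqrt(d_k)

  grads <- lapply(p, function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)))
  preds <- numeric(n)
  caches <- vector("list", n)

  for (i in seq_len(n)) {
    X <- as.matrix(X_list[[i]])
    if (model$positional) X <- X + positional_encoding(nrow(X), model$d)
    Ti <- nrow(X)
    Qs <- Ks <- Vs <- As <- Os <- vector("list", h)
    for (j in seq_len(h)) {
      Qs[[j]] <- X %*% p[[paste0("W_Q", j)]]
      Ks[[j]] <- X %*% p[[paste0("W_K", j)]]
      Vs[[j]] <- X %*% p[[paste0("W_V", j)]]
      As[[j]] <- row_softmax(Qs[[j]] %*% t(Ks[[j]]) * scale)
      Os[[j]] <- As[[j]] %*% Vs[[j]]
    }
    concat <- do.call(cbind, Os)
    out <- concat %*% p$W_O
    pooled <- if (model$pooling == "last") out[Ti, ] else colMeans(out)
    preds[i] <- sum(p$head_w * pooled) + p$head_b
    caches[[i]] <- list(X = X, Q = Qs, K = Ks, V = Vs, A = As,
                        concat = concat, pooled = pooled, Ti = Ti)
  }
  if (any(!is.finite(preds))) stop("non-finite predictions in forward pass", call. = FALSE)
  resid <- preds - y
  loss <- mean(resid^2)

  for (i in seq_len(n)) {
    cc <- caches[[i]]
    dpred <- 2 * resid[i] / n
    grads$head_w <- grads$head_w + dpred * cc$pooled
    grads$head_b <- grads$head_b + dpred
    dpooled <- dpred * p$head_w
    dout <- matrix(0, cc$Ti, model$d)
    if (model$pooling == "last") {
      dout[cc$Ti, ] <- dpooled
    } else {
      dout <- matrix(rep(dpooled / cc$Ti, each = cc$Ti), cc$Ti)
    }
    grads$W_O <- grads$W_O + t(cc$concat) %*% dout
    dconcat <- dout %*% t(p$W_O)
    for (j in seq_len(h)) {
      cols <- ((j - 1) * d_k + 1):(j * d_k)
      dO <- dconcat[, cols, drop = FALSE]
      A <- cc$A[[j]]
      dA <- dO %*% t(cc$V[[j]])
      dV <- t(A) %*% dO
      dS <- A * (dA - rowSums(dA * A)) # row-wise softmax Jacobian
      dQ <- scale * dS %*% cc$K[[j]]
      dK <- scale * t(dS) %*% cc$Q[[j]]
      tX <- t(cc$X)
      grads[[paste0("W_Q", j)]] <- grads[[paste0("W_Q", j)]] + tX %*% dQ
      grads[[paste0("W_K", j)]] <- grads[[paste0("W_K", j)]] + tX %*% dK
      grads[[paste0("W_V", j)]] <- grads[[paste0("W_V", j)]] + tX %*% dV
    }
  }
  list(grads = grads, loss = loss, pred = preds)
}

# Parameter plumbing shared with the trainer ---------------------------------

#' @export
get_params.attention_model <- function(model) model$params

#' @export
set_params.attention_model <- function(model, params) {
  model$params <- params
  model
}

# X here is an n x T x d array (or a list of T x d matrices)
as_window_list <- function(X) {
  if (is.list(X)) return(X)
  stopifnot(length(dim(X)) == 3L)
  lapply(seq_len(dim(X)[1]), function(i) {
    matrix(X[i, , ], nrow = dim(X)[2], ncol = dim(X)[3])
  })
}

#' @export
grads_flat.attention_model <- function(model, X, y) {
  bp <- attention_backprop(model, as_window_list(X), y)
  list(grads = bp$grads, loss = bp$loss)
}

#' @export
predict_batch.attention_model <- function(model, X) {
  vapply(as_window_list(X), temporal_encode_predict, numeric(1), model = model)
}
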