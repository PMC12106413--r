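# Convex fusion of module predictions and the evaluation metrics for both
# prediction accuracy and ecological restoration.

#' Convex fusion weights
#'
#' @param w Nonnegative weights summing to 1 (within 1e-12), one per module;
#'   names identify the modules.
#' @return Object of class `fusion_weights`.
#' @export
fusion_weights <- function(w) {
  w <- unlist(w)
  if (any(!is.finite(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-12) {
    stop("weights must be nonnegative and sum to 1", call. = FALSE)
  }
  structure(as.numeric(w), names = names(w), class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat("Convex fusion weights:\n")
  nm <- if (is.null(names(x))) paste0("module", seq_along(x)) else names(x)
  for (i in seq_along(x)) cat(sprintf("  %-12s %.4f\n", nm[i], x[i]))
  invisible(x)
}

as_pred_matrix <- function(preds) {
  if (is.list(preds) && !is.data.frame(preds)) {
    lens <- vapply(preds, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("module prediction series must have equal length", call. = FALSE)
    }
    preds <- do.call(cbind, preds)
  }
  as.matrix(preds)
}

#' Fuse module predictions by convex weighted averaging
#'
#' The fused forecast `yhat_t = sum_i w_i y_i(t)`: an elementwise convex
#' combination of the per-module prediction series.
#'
#' @param preds Module predictions: a numeric matrix (`N x n_modules`) or a
#'   list/data frame of equal-length series.
#' @param w A [fusion_weights()] vector (or plain weights on the simplex),
#'   one per module.
#' @return Fused prediction series of length `N`.
#' @export
weighted_fusion <- function(preds, w) {
  P <- as_pred_matrix(preds)
  if (!inherits(w, "fusion_weights")) w <- fusion_weights(w)
  if (ncol(P) != length(w)) {
    stop(sprintf("%d prediction series but %d weights", ncol(P), length(w)),
      call. = FALSE
    )
  }
  drop(P %*% as.numeric(w))
}

#' Optimize fusion weights on validation data
#'
#' Finds the convex weights minimizing validation mean squared error:
#' `argmin_w ||P w - y||^2` subject to `w >= 0`, `sum(w) = 1`. Solved exactly
#' by active-set enumeration: for every non-empty subset of modules the
#' equality-constrained least-squares problem is solved via its KKT system
#' and feasible candidates are compared, so the returned weights attain an
#' MSE no larger than any single-module (vertex) weighting. Degenerate inputs
#' where all module predictions are identical return uniform weights with a
#' warning.
#'
#' @param preds Validation-period module predictions (matrix or list; `>=` 2
#'   time points).
#' @param truth Validation targets.
#' @return A [fusion_weights()] vector with attribute `"mse"`, the attained
#'   validation MSE.
#' @export
optimize_weights <- function(preds, truth) {
  P <- as_pred_matrix(preds)
  N <- nrow(P); n_mod <- ncol(P)
  if (N < 2L) stop("need at least 2 validation points", call. = FALSE)
  stopifnot(length(truth) == N)
  module_names <- colnames(P)
  if (is.null(module_names)) module_names <- paste0("module", seq_len(n_mod))

  if (n_mod == 1L) {
    w <- fusion_weights(stats::setNames(1, module_names))
    attr(w, "mse") <- mean((P[, 1] - truth)^2)
    return(w)
  }
  spread <- max(apply(P, 1, function(r) diff(range(r))))
  if (spread <= 1e-12) {
    warning("all module predictions are identical; returning uniform weights")
    w <- fusion_weights(stats::setNames(rep(1 / n_mod, n_mod), module_names))
    attr(w, "mse") <- mean((P[, 1] - truth)^2)
    return(w)
  }

  best <- NULL
  best_mse <- Inf
  # enumerate all non-empty active sets; exact for the small module counts here
  for (size in seq_len(n_mod)) {
    combos <- utils::combn(n_mod, size)
    for (ci in seq_len(ncol(combos))) {
      S <- combos[, ci]
      Ps <- P[, S, drop = FALSE]
      m <- length(S)
      # KKT system of min ||Ps w - y||^2 s.t. sum(w) = 1
      G <- crossprod(Ps)
      kkt <- rbind(cbind(2 * G, rep(1, m)), c(rep(1, m), 0))
      rhs <- c(2 * crossprod(Ps, truth), 1)
      sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      ws <- sol[seq_len(m)]
      if (any(ws < -1e-10)) next
      ws <- pmax(ws, 0)
      ws <- ws / sum(ws)
      w_full <- numeric(n_mod)
      w_full[S] <- ws
      mse <- mean((drop(P %*% w_full) - truth)^2)
      if (mse < best_mse - 1e-15) {
        best_mse <- mse
        best <- w_full
      }
    }
  }
  w <- fusion_weights(stats::setNames(best, module_names))
  attr(w, "mse") <- best_mse
  w
}

#' Prediction-accuracy metrics
#'
#' Mean squared error `MSE = mean((pred - truth)^2)`, its square root RMSE,
#' and tolerance-band accuracy `mean(|pred - truth| <= epsilon)`. For
#' continuous forecasts an exact-equality indicator is degenerate, so
#' accuracy counts predictions within the tolerance `epsilon`, which is
#' always reported alongside.
#'
#' @param pred,truth Equal-length prediction and target series (`N >= 1`).
#' @param epsilon Accuracy tolerance, `>= 0`; default 0.1 (standardized
#'   units).
#' @return Object of class `prediction_metrics`: list `mse`, `rmse`,
#'   `accuracy`, `epsilon`, `n`.
#' @export
prediction_metrics <- function(pred, truth, epsilon = 0.1) {
  if (length(pred) == 0L) stop("empty input", call. = FALSE)
  if (length(pred) != length(truth)) stop("length mismatch", call. = FALSE)
  # an infinite tolerance is legitimate (accuracy saturates at 1)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) || epsilon < 0) {
    stop("'epsilon' must be a single nonnegative number", call. = FALSE)
  }
  err <- pred - truth
  mse <- mean(err^2)
  structure(
    list(
      mse = mse, rmse = sqrt(mse),
      accuracy = mean(abs(err) <= epsilon),
      epsilon = epsilon, n = length(pred)
    ),
    class = "prediction_metrics"
  )
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf(
    "Prediction metrics (N = %d): MSE = %.6g, RMSE = %.6g, accuracy = %.3f at tolerance %.3g\n",
    x$n, x$mse, x$rmse, x$accuracy, x$epsilon
  ))
  invisible(x)
}

#' Soil fertility change
#'
#' `delta F = F_after - F_before`, the gain in the soil fertility index over
#' the remediation period. Vectorized over plots.
#'
#' @param F_after,F_before Fertility index after and before remediation.
#' @return The difference(s).
#' @export
delta_fertility <- function(F_after, F_before) {
  if (any(!is.finite(F_after)) || any(!is.finite(F_before))) {
    stop("fertility values must be finite", call. = FALSE)
  }
  F_after - F_before
}

#' Percentage increase in plant growth rate
#'
#' `100 * (growth_after - growth_before) / growth_before`, the standard
#' relative percent change in growth rate over the remediation period.
#' Vectorized over plots.
#'
#' @param growth_after,growth_before Growth rates after and before; the
#'   before-rate must be strictly positive.
#' @return Percent change(s).
#' @export
pipgr <- function(growth_after, growth_before) {
  if (any(!is.finite(growth_after)) || any(!is.finite(growth_before))) {
    stop("growth rates must be finite", call. = FALSE)
  }
  if (any(growth_before <= 0)) {
    stop("'growth_before' must be strictly positive", call. = FALSE)
  }
  100 * (growth_after - growth_before) / growth_before
}

#' Shannon diversity index
#'
#' `H' = -sum_i p_i ln(p_i)` over species relative abundances `p_i =
#' count_i / sum(counts)`, natural logarithm; zero-count species are dropped
#' before normalization. Ranges from 0 (single species) to `ln(S)` at uniform
#' abundance.
#'
#' @param counts Nonnegative species abundance counts, at least one positive.
#' @return Shannon index `H'` (nats).
#' @export
shannon_index <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("all counts are zero", call. = FALSE)
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Evaluate a full run: fused predictions plus restoration indicators
#'
#' Fuses the enabled modules' prediction series (optimizing weights on the
#' validation period unless fixed weights are supplied), computes prediction
#' metrics on the test period, and summarizes a restoration survey (mean
#' fertility gain, mean growth-rate increase, Shannon diversity before and
#' after over pooled abundances). Any module can be ablated by omitting it
#' from `enabled`.
#'
#' @param val_preds,test_preds Named lists of per-module prediction series
#'   for the validation and test periods.
#' @param val_truth,test_truth Matching target series.
#' @param survey Optional restoration survey (list with `plots` and
#'   `abundance`) as from [generate_restoration_survey()].
#' @param enabled Modules to keep; default all in `val_preds`.
#' @param weights Optional fixed [fusion_weights()]; by default optimized on
#'   the validation period.
#' @param epsilon Accuracy tolerance passed to [prediction_metrics()].
#' @return Object of class `evaluation_report`: list with `weights`,
#'   `metrics`, per-module test MSEs, and (when a survey is given)
#'   `restoration` indicators.
#' @export
evaluate_run <- function(val_preds, val_truth, test_preds, test_truth,
                         survey = NULL, enabled = names(val_preds),
                         weights = NULL, epsilon = 0.1) {
  stopifnot(is.list(val_preds), is.list(test_preds))
  if (length(enabled) == 0L) stop("no enabled modules", call. = FALSE)
  missing_mod <- setdiff(enabled, names(val_preds))
  if (length(missing_mod)) {
    stop(sprintf("unknown module(s): %s", paste(missing_mod, collapse = ", ")),
      call. = FALSE
    )
  }
  val_preds <- val_preds[enabled]
  test_preds <- test_preds[enabled]

  if (is.null(weights)) {
    weights <- optimize_weights(val_preds, val_truth)
  } else if (!inherits(weights, "fusion_weights")) {
    weights <- fusion_weights(weights)
  }
  fused_test <- weighted_fusion(test_preds, weights)
  metrics <- prediction_metrics(fused_test, test_truth, epsilon)
  module_mse <- vapply(test_preds, function(p) mean((p - test_truth)^2), numeric(1))

  restoration <- NULL
  if (!is.null(survey)) {
    ab <- survey$abundance
    before <- stats::aggregate(count ~ species_id, data = ab[ab$period == "before", ], sum)
    after <- stats::aggregate(count ~ species_id, data = ab[ab$period == "after", ], sum)
    restoration <- list(
      delta_F = mean(delta_fertility(survey$plots$F_after, survey$plots$F_before)),
      pipgr_percent = mean(pipgr(survey$plots$growth_after, survey$plots$growth_before)),
      shannon_before = shannon_index(before$count),
      shannon_after = shannon_index(after$count)
    )
  }
  structure(
    list(
      enabled = enabled,
      weights = weights,
      metrics = metrics,
      module_test_mse = module_mse,
      fused_test = fused_test,
      restoration = restoration
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat("  modules:", paste(x$enabled, collapse = ", "), "\n")
  print(x$weights)
  print(x$metrics)
  if (!is.null(x$restoration)) {
    r <- x$restoration
    cat(sprintf(
      "  restoration: delta_F = %.3f, PIPGR = %.1f%%, H' before = %.3f, after = %.3f\n",
      r$delta_F, r$pipgr_percent, r$shannon_before, r$shannon_after
    ))
  }
  invisible(x)
}
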