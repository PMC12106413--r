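# End-to-end pipeline: scenario -> gap filling -> standardization ->
# windowing -> three forecasting modules -> convex fusion -> evaluation.

#' Estimate the effective decay rate from an observed series
#'
#' Log-linear regression of concentration on time: under first-order decay
#' `log C(t) = log C0 - k_eff t`, so the negated slope of
#' `lm(log(C) ~ t)` estimates the effective rate constant. Non-positive
#' observations (possible under additive sensor noise at low concentrations)
#' are dropped before taking logs.
#'
#' @param concentration Observed concentration series (mg/kg).
#' @param time_h Observation times (h).
#' @return List with `k_eff` (1/h), `log_C0`, and `n_used`.
#' @export
estimate_decay_rate <- function(concentration, time_h = seq_along(concentration) - 1) {
  stopifnot(length(concentration) == length(time_h))
  keep <- is.finite(concentration) & concentration > 0
  if (sum(keep) < 3L) stop("need at least 3 positive observations", call. = FALSE)
  fit <- stats::lm(log(concentration[keep]) ~ time_h[keep])
  list(
    k_eff = -unname(stats::coef(fit)[2]),
    log_C0 = unname(stats::coef(fit)[1]),
    n_used = sum(keep)
  )
}

# Mechanistic one-step-ahead forecast on the standardized scale: propagate the
# last observed (raw-scale) concentration one step with the estimated rate.
mechanistic_predictions <- function(raw_conc, ds, idx, k_eff, dt, stats) {
  c_last <- raw_conc[ds$end_row[idx]]
  c_next <- c_last * exp(-k_eff * dt)
  (c_next - stats$mean[[ds$target_col]]) / stats$sd[[ds$target_col]]
}

#' Run the full hybrid forecasting pipeline on a synthetic scenario
#'
#' Generates a monitoring scenario, fills gaps (linear interpolation for
#' temperature and pH, nearest-neighbour for the other series), standardizes
#' every feature with Z-scores fitted on the training period only, cuts
#' fixed-length windows, splits them chronologically 70/15/15, trains the
#' feed-forward and attention forecasters, adds the mechanistic forecaster
#' (one-step decay propagation at the rate estimated from the training
#' period), optimizes convex fusion weights on the validation windows, and
#' evaluates on the test windows.
#'
#' @param config A [scenario_config()] describing the scenario.
#' @param window Window length in time steps (default 24).
#' @param fractions Chronological train/validation/test fractions.
#' @param training A [train_config()]; its seed also seeds weight
#'   initialization.
#' @param modules Modules to include: subset of `"biogeochem"`, `"dnn"`,
#'   `"attention"` (ablation switches).
#' @param hidden Hidden widths of the feed-forward net.
#' @param h,d_k Attention head count and per-head dimension.
#' @param epsilon Accuracy tolerance (standardized units).
#' @param survey Optional restoration survey to fold into the report.
#' @return List of class `pipeline_result`: the `report`
#'   ([evaluate_run()] output), per-module `histories`, the fitted
#'   `stats`, `split`, `dataset`, estimated `k_eff`, and the baseline test
#'   MSE of the mean predictor (`baseline_mse`).
#' @export
run_pipeline <- function(config = scenario_config(),
                         window = 24L,
                         fractions = c(0.70, 0.15, 0.15),
                         training = train_config(),
                         modules = c("biogeochem", "dnn", "attention"),
                         hidden = c(64, 64),
                         h = 4L, d_k = 16L,
                         epsilon = 0.1,
                         survey = NULL) {
  modules <- match.arg(modules, several.ok = TRUE)
  scenario <- generate_scenario(config)
  filled <- fill_missing_table(scenario$table)

  # windows on the raw filled table fix the chronology; standardization stats
  # come from the training period only, then windows are rebuilt standardized
  ds_raw <- make_windows(filled, T = window)
  split <- split_chronological(ds_raw, fractions)
  train_rows <- seq_len(max(ds_raw$end_row[split$train]) + 1L)
  stats <- zscore_fit(filled[train_rows, ], columns = setdiff(names(filled), "timestamp"))
  std <- zscore_apply(filled, stats)
  ds <- make_windows(std, T = window)

  idx <- split
  y <- ds$y
  val_preds <- list(); test_preds <- list(); histories <- list()

  k_eff <- NA_real_
  if ("biogeochem" %in% modules) {
    est <- estimate_decay_rate(
      filled$pollutant_mg_per_kg[train_rows],
      (train_rows - 1) * config$dt
    )
    k_eff <- est$k_eff
    val_preds$biogeochem <- mechanistic_predictions(
      filled$pollutant_mg_per_kg, ds, idx$validation, k_eff, config$dt, stats
    )
    test_preds$biogeochem <- mechanistic_predictions(
      filled$pollutant_mg_per_kg, ds, idx$test, k_eff, config$dt, stats
    )
  }

  if ("dnn" %in% modules) {
    Xtr <- flatten_windows(ds, idx$train)
    mlp <- mlp_init(ncol(Xtr), hidden = hidden, seed = training$seed)
    fit <- train_model(
      mlp, Xtr, y[idx$train],
      flatten_windows(ds, idx$validation), y[idx$validation], training
    )
    histories$dnn <- fit$history
    val_preds$dnn <- predict_batch(fit$model, flatten_windows(ds, idx$validation))
    test_preds$dnn <- predict_batch(fit$model, flatten_windows(ds, idx$test))
  }

  if ("attention" %in% modules) {
    att <- attention_init(ds$d, h = h, d_k = d_k, seed = training$seed)
    fit <- train_model(
      att, ds$X[idx$train, , , drop = FALSE], y[idx$train],
      ds$X[idx$validation, , , drop = FALSE], y[idx$validation], training
    )
    histories$attention <- fit$history
    val_preds$attention <- predict_batch(fit$model, ds$X[idx$validation, , , drop = FALSE])
    test_preds$attention <- predict_batch(fit$model, ds$X[idx$test, , , drop = FALSE])
  }

  report <- evaluate_run(
    val_preds, y[idx$validation], test_preds, y[idx$test],
    survey = survey, epsilon = epsilon
  )
  baseline_mse <- mean((y[idx$test] - mean(y[idx$test]))^2)

  structure(
    list(
      report = report,
      histories = histories,
      stats = stats,
      split = split,
      dataset = ds,
      k_eff = k_eff,
      baseline_mse = baseline_mse,
      scenario = scenario
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "Hybrid forecasting run: %d windows, baseline (mean-predictor) test MSE = %.4g\n",
    length(x$dataset$y), x$baseline_mse
  ))
  print(x$report)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param result A `pipeline_result` or `evaluation_report`.
#' @param path File to write; when `NULL` the JSON string is returned.
#' @param seed Seed recorded in the report, if any.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(result, path = NULL, seed = NULL) {
  report <- if (inherits(result, "pipeline_result")) result$report else result
  stopifnot(inherits(report, "evaluation_report"))
  out <- list(
    mse = report$metrics$mse,
    rmse = report$metrics$rmse,
    accuracy = report$metrics$accuracy,
    epsilon = report$metrics$epsilon,
    weights = as.list(stats::setNames(
      as.numeric(report$weights), names(report$weights)
    )),
    module_test_mse = as.list(report$module_test_mse)
  )
  if (!is.null(report$restoration)) out <- c(out, report$restoration)
  if (!is.null(seed)) out$seed <- seed
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
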