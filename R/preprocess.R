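#' Fill missing values in a series
#'
#' Gap filling for monitoring series. `"linear"` interpolates straight lines
#' in time between the flanking observations and holds edge gaps at the
#' nearest observed value (suited to smooth signals such as temperature and
#' pH); `"nearest"` copies the temporally closest observation, an equidistant
#' gap taking the earlier neighbour (suited to more irregular series such as
#' pollutant concentrations). Observed entries are never altered.
#'
#' @param x Numeric series, possibly containing `NA`; at least one value must
#'   be observed.
#' @param method `"linear"` or `"nearest"`.
#' @param time Observation times; defaults to equal spacing.
#' @return `x` with every `NA` replaced.
#' @export
fill_missing <- function(x, method = c("linear", "nearest"), time = seq_along(x)) {
  method <- match.arg(method)
  stopifnot(length(time) == length(x))
  obs <- which(!is.na(x))
  if (length(obs) == 0L) stop("cannot fill an all-missing series", call. = FALSE)
  if (length(obs) == length(x)) return(x)
  if (length(obs) == 1L) {
    x[is.na(x)] <- x[obs]
    return(x)
  }
  miss <- which(is.na(x))
  if (method == "linear") {
    x[miss] <- stats::approx(time[obs], x[obs], xout = time[miss], rule = 2)$y
  } else {
    # nearest observation in time; ties go to the earlier neighbour
    prev_i <- findInterval(time[miss], time[obs])
    prev_i[prev_i == 0L] <- 1L
    next_i <- pmin(prev_i + 1L, length(obs))
    d_prev <- abs(time[miss] - time[obs][prev_i])
    d_next <- abs(time[obs][next_i] - time[miss])
    pick <- ifelse(d_next < d_prev, next_i, prev_i)
    x[miss] <- x[obs][pick]
  }
  x
}

#' Fill all value columns of a monitoring table
#'
#' Applies [fill_missing()] column-wise. By default smooth physical signals
#' (`temperature_c`, `ph`) are linearly interpolated and the remaining series
#' (pollutant concentration, moisture, growth index) use nearest-neighbour
#' filling.
#'
#' @param table Data frame with a `timestamp` first column.
#' @param methods Named character vector mapping column names to `"linear"` or
#'   `"nearest"`; unnamed columns default to `"nearest"`.
#' @return The table with no missing values.
#' @export
fill_missing_table <- function(table,
                               methods = c(temperature_c = "linear", ph = "linear")) {
  stopifnot(is.data.frame(table), "timestamp" %in% names(table))
  time <- as.numeric(table$timestamp)
  for (col in setdiff(names(table), "timestamp")) {
    m <- if (col %in% names(methods)) methods[[col]] else "nearest"
    table[[col]] <- fill_missing(table[[col]], method = m, time = time)
  }
  table
}

#' Fit Z-score standardization statistics
#'
#' Per-column mean and population (1/N) standard deviation, to be fitted on
#' training rows only so that no information leaks from validation or test
#' data into the standardization.
#'
#' @param table Data frame of training rows.
#' @param columns Columns to standardize; defaults to all numeric columns.
#' @return Object of class `zscore_stats`: named lists `mean` and `sd`.
#' @export
zscore_fit <- function(table, columns = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  mu <- sdv <- stats::setNames(numeric(length(columns)), columns)
  for (col in columns) {
    x <- table[[col]]
    if (anyNA(x)) stop(sprintf("column '%s' contains missing values", col), call. = FALSE)
    mu[col] <- mean(x)
    sdv[col] <- sqrt(mean((x - mu[col])^2))
    if (sdv[col] <= 0) {
      stop(sprintf("column '%s' is constant; cannot standardize", col), call. = FALSE)
    }
  }
  structure(list(mean = mu, sd = sdv, columns = columns), class = "zscore_stats")
}

#' Apply (or invert) Z-score standardization
#'
#' @param table Data frame containing the fitted columns.
#' @param stats A `zscore_stats` object from [zscore_fit()].
#' @return The table with fitted columns standardized.
#' @export
zscore_apply <- function(table, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  for (col in stats$columns) {
    table[[col]] <- (table[[col]] - stats$mean[col]) / stats$sd[col]
  }
  table
}

#' @rdname zscore_apply
#' @param x Standardized numeric vector.
#' @param column Which fitted column's statistics to invert with.
#' @return `zscore_invert`: `x` mapped back to original units.
#' @export
zscore_invert <- function(x, stats, column) {
  stopifnot(inherits(stats, "zscore_stats"), column %in% stats$columns)
  x * stats$sd[[column]] + stats$mean[[column]]
}

#' Cut a monitoring table into fixed-length forecasting windows
#'
#' Window `j` (stride `s`, length `T`) covers rows `(j-1)s + 1 ...
#' (j-1)s + T` and its target is the pollutant value at row `(j-1)s + T + 1`,
#' so every window ends strictly before its target. The number of windows is
#' `floor((L - T - 1)/s) + 1` for a table of `L` rows.
#'
#' @param table Data frame with no missing values.
#' @param T Window length in time steps (default 24, one day of hourly data).
#' @param stride Offset between consecutive windows.
#' @param target_col Column predicted one step ahead.
#' @param feature_cols Feature columns entering each window; defaults to all
#'   non-timestamp columns.
#' @return Object of class `windowed_dataset`: `X` an `n x T x d` array, `y`
#'   the `n` targets, plus `T`, `d`, `feature_cols`, `target_col`, and
#'   `end_row` (the table row index each window ends at).
#' @export
make_windows <- function(table, T = 24L, stride = 1L,
                         target_col = "pollutant_mg_per_kg",
                         feature_cols = NULL) {
  stopifnot(is.data.frame(table))
  T <- check_count(T, "T", lower = 1L)
  stride <- check_count(stride, "stride", lower = 1L)
  if (is.null(feature_cols)) feature_cols <- setdiff(names(table), "timestamp")
  stopifnot(target_col %in% names(table), all(feature_cols %in% names(table)))
  L <- nrow(table)
  if (L <= T) stop(sprintf("need more than T = %d rows, got %d", T, L), call. = FALSE)
  vals <- as.matrix(table[, feature_cols, drop = FALSE])
  if (anyNA(vals) || anyNA(table[[target_col]])) {
    stop("table must be gap-filled before windowing", call. = FALSE)
  }
  n <- (L - T - 1L) %/% stride + 1L
  d <- length(feature_cols)
  X <- array(NA_real_, dim = c(n, T, d))
  y <- numeric(n)
  end_row <- integer(n)
  for (j in seq_len(n)) {
    start <- (j - 1L) * stride + 1L
    X[j, , ] <- vals[start:(start + T - 1L), , drop = FALSE]
    y[j] <- table[[target_col]][start + T]
    end_row[j] <- start + T - 1L
  }
  structure(
    list(
      X = X, y = y, T = T, d = d, stride = stride,
      feature_cols = feature_cols, target_col = target_col,
      end_row = end_row
    ),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "Windowed forecasting dataset: %d windows of %d steps x %d features (target: %s)\n",
    length(x$y), x$T, x$d, x$target_col
  ))
  invisible(x)
}

#' Chronological train/validation/test split
#'
#' Splits windows in time order: the earliest fraction goes to training, the
#' next to validation, the most recent to testing. Counts use the floor rule
#' with the remainder assigned to the test set; shuffling is deliberately
#' avoided so no future information reaches training.
#'
#' @param ds A `windowed_dataset` (or anything with a length via `n`).
#' @param fractions Train/validation/test proportions, positive, summing to 1.
#' @param n Number of windows; inferred from `ds` when supplied.
#' @return Object of class `data_split`: integer index vectors `train`,
#'   `validation`, `test`.
#' @export
split_chronological <- function(ds = NULL, fractions = c(0.70, 0.15, 0.15), n = NULL) {
  if (is.null(n)) {
    stopifnot(inherits(ds, "windowed_dataset"))
    n <- length(ds$y)
  }
  if (length(fractions) != 3L || any(!is.finite(fractions)) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("'fractions' must be three values summing to 1", call. = FALSE)
  }
  n_tr <- floor(fractions[1] * n)
  n_va <- floor(fractions[2] * n)
  n_te <- n - n_tr - n_va
  if (n_tr < 1 || n_va < 1 || n_te < 1) {
    stop("split produces an empty set; adjust fractions or supply more windows",
      call. = FALSE
    )
  }
  structure(
    list(
      train = seq_len(n_tr),
      validation = seq.int(n_tr + 1L, n_tr + n_va),
      test = seq.int(n_tr + n_va + 1L, n)
    ),
    class = "data_split"
  )
}

# Flatten selected windows into the n x (T*d) matrix a feed-forward net consumes.
flatten_windows <- function(ds, idx = seq_along(ds$y)) {
  stopifnot(inherits(ds, "windowed_dataset"))
  matrix(ds$X[idx, , , drop = FALSE], nrow = length(idx))
}
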