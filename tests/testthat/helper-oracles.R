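# Shared oracles and fixture builders for the test suite.

# Central finite-difference gradient of the batch-mean squared error with
# respect to every model parameter; independent of the backprop code path.
finite_diff_grads <- function(model, X, y, h = 1e-5) {
  p <- phytofuse:::get_params(model)
  forward <- function(params) {
    m <- phytofuse:::set_params(model, params)
    mean((predict_batch(m, X) - y)^2)
  }
  lapply(stats::setNames(names(p), names(p)), function(nm) {
    g <- p[[nm]] * 0
    for (i in seq_along(p[[nm]])) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
      g[i] <- (forward(pp) - forward(pm)) / (2 * h)
    }
    g
  })
}

max_rel_grad_err <- function(analytic, numeric) {
  max(mapply(
    function(a, b) max(abs(a - b) / (abs(b) + 1e-6)),
    analytic, numeric
  ))
}

# A small constant-environment, noise-free scenario for exact checks.
quiet_scenario_config <- function(duration_steps = 200, seed = 11, ...) {
  scenario_config(
    duration_steps = duration_steps,
    temp_amplitude = 0, moisture_amplitude = 0,
    ph_sd = 0, obs_noise_sd = 0, missing_rate = 0,
    seed = seed, ...
  )
}

# Simplex grid search at the given resolution: the brute-force oracle for
# convex weight optimization over two or three modules.
grid_search_weights <- function(P, truth, step = 0.01) {
  n_mod <- ncol(P)
  best <- NULL; best_mse <- Inf
  grid <- seq(0, 1, by = step)
  if (n_mod == 2L) {
    for (w1 in grid) {
      w <- c(w1, 1 - w1)
      mse <- mean((drop(P %*% w) - truth)^2)
      if (mse < best_mse) { best_mse <- mse; best <- w }
    }
  } else if (n_mod == 3L) {
    for (w1 in grid) for (w2 in seq(0, 1 - w1, by = step)) {
      w <- c(w1, w2, 1 - w1 - w2)
      mse <- mean((drop(P %*% w) - truth)^2)
      if (mse < best_mse) { best_mse <- mse; best <- w }
    }
  } else {
    stop("grid oracle supports 2 or 3 modules")
  }
  list(w = best, mse = best_mse)
}
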