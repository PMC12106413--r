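#' Kinetic parameters of the soil-plant pollutant model
#'
#' Bundles the rate constants of the mechanistic remediation model: first-order
#' soil degradation (`k`), plant uptake through the root system (`r_p`), and
#' in-plant metabolic transformation of absorbed pollutant (`k_t`), together
#' with the initial soil concentration `C0`.
#'
#' @param C0 Initial soil pollutant concentration (mg/kg), `>= 0`.
#' @param k Soil degradation rate constant (1/h), `>= 0`.
#' @param r_p Plant uptake rate constant (1/h), `>= 0`.
#' @param k_t In-plant transformation rate constant (1/h), `>= 0`.
#'
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(C0 = 100, k = 0.2, r_p = 0.05, k_t = 0.1)
#' @export
kinetic_params <- function(C0, k, r_p, k_t) {
  structure(
    list(
      C0 = check_scalar(C0, "C0", lower = 0),
      k = check_scalar(k, "k", lower = 0),
      r_p = check_scalar(r_p, "r_p", lower = 0),
      k_t = check_scalar(k_t, "k_t", lower = 0)
    ),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Soil-plant kinetic parameters\n")
  cat(sprintf("  C0  = %g mg/kg (initial soil concentration)\n", x$C0))
  cat(sprintf("  k   = %g 1/h   (soil degradation)\n", x$k))
  cat(sprintf("  r_p = %g 1/h   (plant uptake)\n", x$r_p))
  cat(sprintf("  k_t = %g 1/h   (in-plant transformation)\n", x$k_t))
  invisible(x)
}

#' Environmental drivers modulating degradation and uptake rates
#'
#' Temperature and moisture series (or constants) plus the parameters of the
#' rate modifier: a Q10 temperature factor and a saturating moisture factor.
#' When series are supplied, `time` gives their sampling times in hours and the
#' simulator interpolates linearly between samples.
#'
#' @param temperature_c Temperature (deg C), scalar or series.
#' @param moisture Volumetric soil moisture fraction in `[0, 1]`, scalar or
#'   series of the same length as `temperature_c`.
#' @param q10 Multiplicative rate change per 10 deg C increase, `> 0`.
#' @param t_ref Reference temperature (deg C) at which the temperature factor
#'   is 1.
#' @param moisture_opt Moisture fraction at (and above) which the moisture
#'   factor saturates at 1; in `(0, 1]`.
#' @param time Sampling times (h) for series inputs; defaults to
#'   `0, 1, 2, ...`.
#'
#' @return An object of class `env_drivers`.
#' @export
env_drivers <- function(temperature_c, moisture, q10 = 2, t_ref = 15,
                        moisture_opt = 0.6, time = NULL) {
  if (length(temperature_c) != length(moisture)) {
    stop("'temperature_c' and 'moisture' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(moisture)) || any(moisture < 0 | moisture > 1)) {
    stop("'moisture' must lie in [0, 1]", call. = FALSE)
  }
  q10 <- check_scalar(q10, "q10", lower = 0, strict_lower = TRUE)
  moisture_opt <- check_scalar(moisture_opt, "moisture_opt",
    lower = 0, upper = 1, strict_lower = TRUE
  )
  t_ref <- check_scalar(t_ref, "t_ref")
  if (is.null(time)) time <- seq_along(temperature_c) - 1
  if (length(time) != length(temperature_c)) {
    stop("'time' must match the length of the driver series", call. = FALSE)
  }
  structure(
    list(
      temperature_c = as.numeric(temperature_c),
      moisture = as.numeric(moisture),
      q10 = q10, t_ref = t_ref, moisture_opt = moisture_opt,
      time = as.numeric(time)
    ),
    class = "env_drivers"
  )
}

#' Closed-form first-order decay
#'
#' Evaluates the analytic solution `C0 * exp(-k * t)` of the first-order
#' degradation equation `dC/dt = -k C`.
#'
#' @param C0 Initial concentration (mg/kg), `>= 0`.
#' @param k Rate constant (1/h), `>= 0`.
#' @param t Time (h), `>= 0`; may be a vector.
#' @return Concentration(s) at time `t` (mg/kg).
#' @examples
#' decay_closed_form(100, log(2), 1) # one half-life -> 50
#' @export
decay_closed_form <- function(C0, k, t) {
  check_scalar(C0, "C0", lower = 0)
  check_scalar(k, "k", lower = 0)
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  C0 * exp(-k * t)
}

#' Environmental rate modifier
#'
#' Dimensionless multiplier applied to the kinetic rate constants:
#' `q10^((T - t_ref)/10) * min(moisture / moisture_opt, 1)`. Equals 1 at the
#' reference temperature with moisture at or above the optimum; strictly
#' positive for moisture `> 0`.
#'
#' @param temperature_c Temperature (deg C), vectorized.
#' @param moisture Moisture fraction in `[0, 1]`, vectorized.
#' @param env An [env_drivers()] object supplying `q10`, `t_ref`,
#'   `moisture_opt`.
#' @return Dimensionless multiplier(s).
#' @export
rate_modifier <- function(temperature_c, moisture, env) {
  stopifnot(inherits(env, "env_drivers"))
  if (any(!is.finite(moisture)) || any(moisture < 0 | moisture > 1)) {
    stop("'moisture' must lie in [0, 1]", call. = FALSE)
  }
  env$q10^((temperature_c - env$t_ref) / 10) * pmin(moisture / env$moisture_opt, 1)
}

#' Instantaneous plant uptake amount
#'
#' Literal evaluation of the uptake relation `M_p = r_p * C`: the amount of
#' pollutant absorbed by plants at soil concentration `C` under uptake rate
#' `r_p`. The dynamic simulator uses the same product as an uptake flux; this
#' function exposes the instantaneous-amount reading.
#'
#' @param r_p Plant uptake rate constant (1/h), `>= 0`.
#' @param C Soil concentration (mg/kg), `>= 0`; vectorized.
#' @return `r_p * C` (mg/kg soil-equivalent).
#' @export
plant_uptake_amount <- function(r_p, C) {
  check_scalar(r_p, "r_p", lower = 0)
  if (any(!is.finite(C)) || any(C < 0)) stop("'C' must be >= 0", call. = FALSE)
  r_p * C
}

#' Simulate the coupled soil-plant remediation system
#'
#' Integrates the mass-conserving compartment model
#' \deqn{dC/dt = -m(t) (k + r_p) C}
#' \deqn{dM_{active}/dt = m(t) r_p C - k_t M_{active}}
#' \deqn{dM_{metab}/dt = k_t M_{active}}
#' \deqn{dM_{degr}/dt = m(t) k C}
#' where `m(t)` is the environmental [rate_modifier()] (identically 1 when
#' `env` is `NULL`). The four pools partition the initial mass: soil
#' concentration `C`, active in-plant pollutant, cumulatively metabolized
#' pollutant, and cumulatively soil-degraded pollutant, so their sum stays at
#' `C0` up to integrator error.
#'
#' @param params A [kinetic_params()] object.
#' @param env Optional [env_drivers()] object; series are interpolated
#'   linearly in time (held constant beyond their range).
#' @param horizon Simulation horizon (h), `> 0`.
#' @param dt Fixed integrator step (h), `0 < dt <= horizon`.
#' @param scheme Integration scheme, `"rk4"` (default) or `"euler"`.
#' @return A data frame of class `remediation_trajectory` with columns
#'   `time_h`, `C_mg_per_kg`, `M_active`, `M_metabolized`, `M_degraded`, and
#'   the kinetic parameters stored in attribute `"params"`.
#' @examples
#' traj <- simulate_soil_plant(kinetic_params(100, 0.2, 0.05, 0.1),
#'   horizon = 24, dt = 0.01
#' )
#' mass_balance_check(traj)
#' @export
simulate_soil_plant <- function(params, env = NULL, horizon, dt,
                                scheme = c("rk4", "euler")) {
  stopifnot(inherits(params, "kinetic_params"))
  scheme <- match.arg(scheme)
  horizon <- check_scalar(horizon, "horizon", lower = 0, strict_lower = TRUE)
  dt <- check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  if (dt > horizon) stop("'dt' must not exceed 'horizon'", call. = FALSE)

  if (is.null(env)) {
    modifier <- function(t) 1
  } else {
    stopifnot(inherits(env, "env_drivers"))
    m_series <- rate_modifier(env$temperature_c, env$moisture, env)
    modifier <- if (length(m_series) == 1L) {
      function(t) m_series
    } else {
      stats::approxfun(env$time, m_series, rule = 2)
    }
  }

  k <- params$k; r_p <- params$r_p; k_t <- params$k_t
  deriv <- function(t, y, p) {
    m <- modifier(t)
    list(c(
      -m * (k + r_p) * y[1],
      m * r_p * y[1] - k_t * y[2],
      k_t * y[2],
      m * k * y[1]
    ))
  }
  times <- seq(0, horizon, by = dt)
  y0 <- c(C = params$C0, M_active = 0, M_metabolized = 0, M_degraded = 0)
  sol <- deSolve::ode(y0, times, deriv, parms = NULL, method = scheme)

  traj <- data.frame(
    time_h = sol[, "time"],
    C_mg_per_kg = sol[, "C"],
    M_active = sol[, "M_active"],
    M_metabolized = sol[, "M_metabolized"],
    M_degraded = sol[, "M_degraded"]
  )
  attr(traj, "params") <- params
  class(traj) <- c("remediation_trajectory", "data.frame")
  traj
}

#' Mass-balance residual of a remediation trajectory
#'
#' In a closed system the four pollutant pools must sum to the initial soil
#' concentration at every time step. Returns the maximum relative residual
#' `max_t |sum(pools)(t) - C0| / C0`, a direct check on integrator accuracy.
#'
#' @param traj A `remediation_trajectory` from [simulate_soil_plant()].
#' @return Maximum relative mass-balance residual (dimensionless).
#' @export
mass_balance_check <- function(traj) {
  stopifnot(inherits(traj, "remediation_trajectory"), nrow(traj) > 0)
  params <- attr(traj, "params")
  C0 <- params$C0
  total <- traj$C_mg_per_kg + traj$M_active + traj$M_metabolized + traj$M_degraded
  if (C0 == 0) {
    if (any(abs(total) > 0)) stop("C0 = 0 but pools are nonzero", call. = FALSE)
    return(0)
  }
  max(abs(total - C0)) / C0
}
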