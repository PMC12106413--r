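---
title: "phytofuse: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phytofuse: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each module
computes, which assumptions it makes, why the defaults are what they are, and
where the design was genuinely open.

## 1. The mechanistic soil–plant model

The kinetic core treats a single pollutant in a closed soil–plant system.
Soil degradation is first order, `dC/dt = -kC`; plant uptake is proportional
to the soil concentration with rate `r_p`; pollutant absorbed by the plant is
metabolized into harmless products at rate `k_t`. Stated independently these
relations do not conserve mass, and without conservation "how much pollutant
went where" — the quantity a remediation assessment needs — is undefined. The
simulator therefore couples them into one compartment system:

```
dC/dt           = -m(t) (k + r_p) C        # soil losses: degradation + uptake
dM_active/dt    =  m(t) r_p C - k_t M_a    # in-plant active pool
dM_metab/dt     =  k_t M_a                 # cumulative metabolized
dM_degraded/dt  =  m(t) k C                # cumulative soil-degraded
```

Two readings of the uptake relation are possible — an instantaneous amount
(`M_p = r_p C`, exposed verbatim as `plant_uptake_amount()`) or a flux. The
dynamic system uses the flux reading, since only a flux can move mass between
pools. Likewise the in-plant transformation `dM_p/dt = k_t M_p` taken
literally would grow the plant pool exponentially; because transformation
turns absorbed pollutant into harmless products, the simulator lets `k_t`
drain the active pool into a cumulative metabolized pool. The printed forms
remain available as the static helpers; the coupled system is what the
trajectory and all mass accounting use.

**Environmental modulation.** Degradation and uptake depend on temperature
and moisture. The dependence is represented as a dimensionless multiplier
`m(t) = q10^((T - T_ref)/10) * min(theta/theta_opt, 1)`: a Q10 temperature
factor (default `q10 = 2`, the common soil-biology value; `T_ref = 15` °C)
times a moisture factor that rises linearly to an optimum fraction
(`theta_opt = 0.6`) and saturates. This is the simplest form that is positive,
monotone in each driver, and equal to 1 at reference conditions. pH is
carried as an observed covariate but does not enter the modifier: no
speciation chemistry is modelled.

**Integration.** Fixed-step rk4 (default, `dt = 0.01` h) and explicit Euler
(retained for the convergence check) via the `deSolve` integrators.
Time-varying drivers are linearly interpolated between samples and held
constant beyond their range. With rk4 at `dt = 0.01` over 24 h, the pure
decay trajectory matches `C0·e^{-kt}` to ≤ 1e-6 relative error and the pool
sum stays within 1e-6 relative of `C0`; the test suite also checks the
schemes' convergence orders (Euler error halves with `dt`, rk4 drops ~16×).

## 2. The synthetic-data generator

The generator emulates the structure of agricultural monitoring records:
hourly `timestamp, pollutant_mg_per_kg, soil_moisture, temperature_c, ph,
plant_growth_index` tables. Its defaults are the package's study conditions:

* **Kinetics** `C0 = 100` mg/kg, `k = 8e-4`, `r_p = 4e-4`, `k_t = 0.01` 1/h —
  a slow field-scale remediation in which roughly 90 % of the pollutant is
  removed over a 2000-hour campaign.
* **Forcing** — temperature as a seasonal sinusoid (mean 18 °C, amplitude
  8 °C) plus a daily cycle at a quarter of that amplitude and Gaussian jitter
  at 5 % of it; moisture as a phase-shifted seasonal sinusoid (mean 0.45,
  amplitude 0.15) with proportional jitter, clipped to [0, 1]; pH as i.i.d.
  Gaussian readings (6.8 ± 0.15). Scaling the jitter with the amplitude makes
  "amplitude zero" a genuinely constant environment, which the exact-recovery
  tests rely on.
* **Noise and gaps** — additive Gaussian observation noise on the pollutant
  column (default sd 0.5 mg/kg, 0.5 % of `C0`) and missing-completely-at-
  random Bernoulli masking of every non-timestamp cell (default rate 0.05).
* **Latent trajectory** — the exact piecewise-constant-rate solution
  `C_i = C0 · exp(-(k + r_p) · dt · Σ m_j)`, so under a constant environment
  the latent series equals the closed form to machine precision and
  log-linear regression recovers the effective rate exactly. The generator
  is therefore not an ODE-solver round trip, and generator-based recovery
  tests are independent of the integrator.
* **Plant growth** — logistic growth (`r_g = 0.005`/h towards carrying
  capacity 1) whose rate is suppressed by the remaining pollutant fraction
  (factor `1 - 0.5·C/C0`); no growth law is implied by the monitoring-table
  structure itself, and this is the simplest form that links growth to
  remediation progress.

All randomness flows from one generator seeded per call; the caller's RNG
state is untouched. Restoration surveys are generated analogously: fertility
gains and relative growth gains with configurable means (defaults 0.15 and
18 %), and species abundances whose post-remediation profile gains
`species_shift` species and moves halfway toward uniform, raising Shannon
diversity from ≈ 1.46 to ≈ 1.72 nats under the default five-species
community.

What the generator does **not** emulate: spatially correlated multi-site
structure, informative (non-MCAR) missingness, sensor drift or
autocorrelated noise, and pollutant re-inputs. Tests passing on these
scenarios show the machinery is correct under the model's own assumptions,
not that the model fits arbitrary field data.

## 3. Preprocessing protocol

Gap filling: linear interpolation in time for smooth signals (temperature,
pH), nearest-neighbour for the remaining series, with equidistant ties going
to the earlier observation (the causal choice) and edge gaps held at the
nearest observed value. Standardization: Z-scores with the population (1/N)
standard deviation, fitted on the training period only — fitting on the full
series would leak the test period's distribution into training. Windowing:
length-24 windows (24 hourly steps; configurable), stride 1, each window's
target the value one step after it ends. Splits: chronological 70/15/15 by
the floor rule with the remainder to test; shuffled splits would let the
network train on the future.

## 4. The learned modules

The feed-forward network defaults to two hidden layers of 64 ReLU units with
a linear head on the flattened window (no architecture is canonical for this
problem; 2×64 is a conventional small-regression default and everything is
configurable). Initialization is He-style scaled uniform from the run seed.
Training: mean squared error, Adam (lr 0.001, batch 32, 100 epochs) by
default; plain gradient descent is implemented as well since the update rule
`θ ← θ - η∇L` is the textbook procedure the architecture is described with.
Optional Gaussian input augmentation (default sd 0.01 in standardized units)
enriches training data; the magnitude is a free choice since only the
presence of augmentation, not its scale, is specified anywhere.

The attention module uses `h = 4` heads of dimension `d_k = 16` (again a
conventional small default), last-row pooling (the forecasting convention;
mean pooling available) and an affine head. There is **no positional
encoding by default**: the projections and scaled-dot-product attention are
permutation-equivariant as written, and the module is kept faithful to that
form. The consequence — the encoder cannot distinguish time order, only
feature content — is real and tested; an optional sinusoidal encoding
(`positional = TRUE`) is provided for users who want order sensitivity.
Softmax rows are computed with max-subtraction so ±1e4 logits stay finite.

Both architectures use exact analytic backpropagation, validated against
central finite differences (h = 1e-5) to ≤ 1e-5 relative error over dozens
of random configurations.

## 5. Fusion and evaluation

Fusion weights minimize validation MSE over the probability simplex. The
problem is a tiny quadratic program (2–3 modules), solved exactly by
enumerating active sets: for each non-empty module subset the
equality-constrained least-squares KKT system is solved and feasible
candidates compared. This is deterministic, needs no tolerance tuning, and
by construction can never do worse on validation than the best single module
(the vertices are in the feasible set). When all module predictions are
numerically identical the weights are undefined; uniform weights are
returned with a warning.

The mechanistic module enters fusion as a genuine forecaster: the effective
decay rate is estimated by log-linear regression on the training period and
each window's last observed concentration is propagated one step. The
alternative coupling — appending the mechanistic trajectory as an input
feature of the learned modules — is supported by adding the simulated series
as a column before windowing, but prediction-level fusion is the default:
it keeps the modules separable, which the ablation switches need.

Accuracy for continuous forecasts cannot use exact equality (it would be
identically zero), so the package reports the fraction of predictions within
a tolerance ε, default 0.1 standardized units, with ε always carried in the
report. MSE/RMSE are the usual formulas; fertility gain is a plain
difference; plant-growth improvement is the standard relative percent
change; Shannon diversity uses natural logarithms with zero-count species
dropped before normalization.

## 6. Problem sizes and determinism

The test suite and the acceptance script run desk-scale problems chosen to
exercise every property at comfortable margins: 2000-step scenarios
(≈ 1976 windows; 1383 train / 296 validation / 297 test), 100-epoch training
at the default batch size, 24-configuration gradient checks, 100-case
attention property sweeps, and 200-plot surveys. A full pipeline run takes
about two minutes on one CPU core. Every stochastic step — scenario
generation, weight initialization, shuffling, augmentation — derives from an
explicit integer seed, and repeated runs with the same seed are identical.

## 7. Known limitations

* Single pollutant, no sorption isotherms, pH speciation, or microbial
  dynamics; the environmental modifier is a heuristic, not calibrated soil
  chemistry.
* The attention encoder is a single layer without residual connections,
  layer normalization or masking — deliberately minimal, not a Transformer.
* The mechanistic forecaster assumes approximately first-order observed
  decay; under strong seasonal modulation its single fitted rate is an
  average, and the learned modules must absorb the residual structure.
* Restoration indicators summarize synthetic surveys; no field-data
  significance testing is provided.
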