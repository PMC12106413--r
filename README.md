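# phytofuse

Hybrid mechanistic–neural forecasting of soil pollutant concentrations during
phytoremediation, with ecological-restoration assessment.

## The problem

Phytoremediation — using plants to extract and metabolize soil pollutants —
produces monitoring time series (pollutant concentration, soil moisture,
temperature, pH, plant growth) whose dynamics mix well-understood first-order
kinetics with messier environmental and biological effects. Purely mechanistic
models miss the nonlinear structure; purely data-driven models ignore the
physics and extrapolate badly as concentrations decay out of the training
range. `phytofuse` is for environmental modellers and agricultural-monitoring
practitioners who want both: a mechanistic kinetics simulator, a feed-forward
neural network, and a multi-head attention encoder, fused by convex weights
optimized on held-out validation data.

## The model

**Mechanistic core.** Soil concentration follows first-order decay
`dC/dt = -k C` (closed form `C(t) = C0 e^{-kt}`), plants absorb pollutant at
rate `r_p` (`M_p = r_p C`), and absorbed pollutant is metabolized at rate
`k_t`. The simulator couples these into a mass-conserving compartment system,

```
dC/dt           = -m(t) (k + r_p) C
dM_active/dt    =  m(t) r_p C - k_t M_active
dM_metab/dt     =  k_t M_active
dM_degraded/dt  =  m(t) k C
```

where `m(t) = q10^((T - T_ref)/10) * min(theta/theta_opt, 1)` modulates the
rates with temperature and soil moisture. The four pools always sum to `C0`
(relative residual ≤ 1e-6 with the default rk4 integrator at dt = 0.01 h).

**Neural modules.** A fully connected network applies
`y^l = f(W^l x^{l-1} + b^l)` layer by layer to flattened 24-step windows; the
attention module projects each window `X ∈ R^{T×d}` into per-head query, key
and value spaces (`Q = X W^Q`, …), computes
`A = softmax(Q K' / sqrt(d_k)) V` per head, concatenates the `h` heads
through `W^O`, pools over time and applies an affine head. Both are trained
by exact backpropagation with Adam (learning rate 0.001, batch 32, 100
epochs) or plain gradient descent `θ ← θ - η ∇L`.

**Fusion.** Module predictions combine as `ŷ_t = Σ_i w_i y_i(t)` with
`w_i ≥ 0, Σ w_i = 1`, the weights chosen to minimize validation MSE (exact
active-set solution of the simplex-constrained least-squares problem).

**Evaluation.** Prediction: MSE, RMSE, and tolerance-band accuracy
`mean(|ŷ - y| ≤ ε)`. Restoration: soil fertility gain `ΔF = F_after -
F_before`, percentage increase in plant growth rate (PIPGR), and Shannon
diversity `H' = -Σ p_i ln p_i` before and after remediation.

A seeded synthetic-data generator produces monitoring scenarios with the
structure the model assumes — mechanistic decay under seasonal forcing,
observation noise, missing cells — retaining the ground truth for recovery
tests.

## Worked example

```r
library(phytofuse)

traj <- simulate_soil_plant(kinetic_params(C0 = 100, k = 0.2, r_p = 0.05, k_t = 0.1),
                            horizon = 24, dt = 0.01)
mass_balance_check(traj)
#> [1] 3.410605e-15

res <- run_pipeline(scenario_config(duration_steps = 2000, seed = 42),
                    training = train_config(seed = 42),
                    survey = generate_restoration_survey(200, seed = 42))
print(res)
#> Hybrid forecasting run: 1976 windows, baseline (mean-predictor) test MSE = 0.001386
#> Evaluation report
#>   modules: biogeochem, dnn, attention
#> Convex fusion weights:
#>   biogeochem   0.6675
#>   dnn          0.0159
#>   attention    0.3166
#> Prediction metrics (N = 297): MSE = 0.000694497, RMSE = 0.0263533, accuracy = 0.997 at tolerance 0.1
#>   restoration: delta_F = 0.150, PIPGR = 17.7%, H' before = 1.458, after = 1.721
```

Reading this: a two-year hourly scenario is generated, gap-filled,
standardized on the training period, windowed (24 steps) and split
chronologically 70/15/15. The mechanistic forecaster (one-step decay at the
rate estimated from training data) earns most of the fusion weight, the
attention module refines it, and the fused test MSE (0.0007, standardized
units) halves the mean-predictor baseline (0.0014). The survey summary shows
a fertility gain of 0.15 index units, an 18 % growth-rate increase, and
Shannon diversity rising from 1.46 to 1.72 nats.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/phytofuse.R generate --seed 5 --out data/
Rscript inst/cli/phytofuse.R simulate --horizon 24 --dt 0.01 --out traj.csv
Rscript inst/cli/phytofuse.R evaluate --seed 7 --disable attention --out report.json
```

## Documentation

The methods vignette (`vignettes/phytofuse-methods.Rmd`) documents the model
assumptions, parameter choices, numerical decisions and known limitations.
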