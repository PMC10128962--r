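# gliomaRT

Regrowth-time modelling and prediction for diffuse low-grade gliomas (LGG)
after radiotherapy (RT).

LGG are invasive brain tumors whose mean radiological radius (measured on
T2-FLAIR MRI, with a ±1 mm error) grows roughly linearly before treatment.
After RT the radius shrinks for months to years before regrowing at its
former speed. Patients and clinicians both want the **regrowth time** — the
date at which shrinkage stops — predicted as early as possible, when only a
handful of measurements exist. `gliomaRT` is for biostatisticians and
modellers working with such longitudinal radius follow-ups.

## The model and the estimators

The radius follows a four-parameter piecewise law with `t = 0` at the start
of RT:

    R(t) = R0 + v t                          (t < 0)
    R(t) = R0 + v t - k (1 - exp(-t / tau))  (t >= 0)

with `R0` the radius at RT (mm), `v` the asymptotic growth speed (mm/yr,
clinically 0.5–4), `k` the decay amplitude (mm) and `tau` its characteristic
time (yr). When `k/(tau v) > 1` the curve has a unique minimum at the
regrowth time

    t_min = tau * ln( k / (tau v) ).

Three estimators target `t_min` from a follow-up `{(t_i, R_i)}`:

* **plain** — bound-constrained least squares on
  `chi2 = sum_i [R_i - R(t_i)]^2 / sigma_i^2` (needs an informative
  follow-up);
* **constrained** — adds a quadratic prior
  `sum_i [(x_i - mu_i)/sigma_i]^2` on the decorrelated combinations
  `X = T p`, where `T` diagonalizes the parameter covariance of a packaged
  20-patient reference ensemble; fits are solvable with as few as 3 points;
* **loose** — fits only the pre/post-RT slopes (a continuous
  piecewise-linear least squares) and converts the collapse speed
  `v_d = k/tau` through the empirical power law `t_min = a / v_d^b`
  (`a ≈ 9.0`, `b ≈ 0.62` on the reference ensemble); less biased for slow
  responders, wider intervals.

Monte-Carlo virtual patients (`mc_predict()`, `cohort_study()`) quantify
what a given MRI schedule can deliver for each estimator.

## Worked example

```r
library(gliomaRT)

ens   <- reference_ensemble()              # packaged 20-patient best fits
prior <- build_prior(ens, powerlaw = TRUE) # decorrelated Gaussian prior
fit_powerlaw(ens)
#>         a         b
#> 8.9526585 0.6186045

# a slow responder (true t_min = 4.16 yr) measured at -6, 0, +3 months:
truth  <- model_params(R0 = 20.21, v = 1.30, k = 14.84, tau = 3.64)
design <- measurement_design(c(-6, 0, 3) / 12, sigma = 1)
mc_predict(truth, design, prior, n_reps = 400, seed = 1)
#> <prediction_distribution> 400 replicates (1 degenerate)
#>   t_min: mean 1.98 yr, [5%, 95%] = [1.30, 2.30] yr
```

Three months of data carry no curvature information for so slow a
responder, so the prediction is dominated by the prior and settles near the
ensemble-typical 2 yr — a known underestimate, but large enough to justify
waiting for another MRI. With a fourth point at 12 months the
slope-based loose estimator re-centers on the truth, at the price of a much
wider interval:

```r
design4 <- measurement_design(c(-6, 0, 3, 12) / 12, sigma = 1)
mc_predict_loose(truth, design4, prior$powerlaw, n_reps = 400, seed = 1)
#> <prediction_distribution> 400 replicates (59 degenerate)
#>   t_min: mean 5.21 yr, [5%, 95%] = [2.23, 10.11] yr
```

Individual follow-ups are fitted directly:

```r
set.seed(4)
fu <- generate_followup(truth, schedule_spec(times = seq(-1.5, 7, by = 0.85)),
                        patient_id = "demo")
fit_plain(fu)
#> <fit_result> mode = plain, n = 11, objective = 8.586, converged = TRUE
#> <model_params> R0 = 20.97 mm, v = 1.96 mm/yr, k = 20.81 mm, tau = 4.207 yr
#>   regrowth time: 3.90 yr
```

A command-line front end (`inst/scripts/gliomart.R`) exposes `fit`,
`build-prior`, `mc` and `simulate` subcommands over the same functions.
See the vignette in `vignettes/regrowth-modelling.Rmd` for the full
methods account.

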