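# catchbond

Statistical machinery for single-molecule force-spectroscopy studies of
receptor–ligand bonds under load, built around the cadherin–catenin/F-actin
linkage: is a bond a *slip bond* (detaches faster under force) or a two-state
*catch bond* (lives longer over some force range because load drives a
weak→strong conformational switch)?

The package is for biophysicists analysing optical-trap force–lifetime data
(or building/validating such analyses). It provides:

* **Models.** Bell–Evans transition rates
  k(F) = k⁰·exp(|F|·x / k_BT), with optional direction-specific distances
  x₋/x₊ along the polar filament; three candidate lifetime models — a
  one-state slip bond, a two-state slip mixture, and a two-state catch bond
  in which the observed lifetime is the first-passage time to the unbound
  state 0 of a Markov chain on bound states 1 (weak) and 2 (strong) with
  sub-generator Q and exit rates (k₁₀, k₂₀): survival S(τ) = π·exp(Qτ)·1,
  mean lifetime ⟨τ⟩ = −π·Q⁻¹·1. All densities/survivals are closed-form,
  log-safe and vectorized.
* **Fitting.** Maximum likelihood on last-step force–lifetime records:
  L-BFGS-B with multi-start for slip-type models; a seeded genetic algorithm
  (100 epochs, population 200, with L-BFGS-B polish) for the eight-parameter
  catch bond, constrained to a zero-force mean lifetime ≤ 100 s. AIC/BIC
  comparison, empirical bootstrap percentile CIs and mean-lifetime envelopes.
* **Detection.** Constant-force assay: 40 kHz→1 kHz decimation, change
  points from Gaussian second-derivative convolution, loading-phase (5 ms)
  and slackening (1.5 pN) exclusion filters, multi-step/last-step
  annotation. Low-force assay: sliding 256-point spectral power above
  300 Hz, events at 180% of the baseline mean.
* **Statistics.** Binned mean lifetimes, empirical survival curves and
  log-rank/KS comparison, 4 pN sliding-window lifetime ratios with bootstrap
  envelopes, and per-filament directionality summaries.
* **Synthetic data.** Inverse-CDF and Gillespie samplers, multi-molecule
  multi-step rupture events, and raw trace synthesis with ground-truth
  annotations, so every stage is testable without instrument data.

## Worked example

Simulate a pooled-size dataset (n = 1001) from a slip bond with
k⁰ = 0.49 s⁻¹, x = 0.48 nm, fit both slip-type models, and bootstrap the fit:

```r
library(catchbond)

rec <- simulate_dataset(slip_model(bell_transition(0.49, 0.48)), 1001,
                        molecules_per_event = 1, seed = 42)
fit <- fit_mle_local("slip", rec, seed = 1)
fit
#> slip model fit (L-BFGS-B): n = 1001, logL = -1036.190, AIC = 2076.38, BIC = 2086.20
#> bu.log10_k0        bu.x
#>     -0.2877      0.4303

bs <- bootstrap_mle(rec, "slip", n_boot = 200, boot_restarts = 1,
                    seed = 2, point_fit = fit)
bs
#> bootstrap_summary: slip model, 200 replicates (0 failed), 95% CIs
#>             estimate   lower   upper
#> bu.log10_k0  -0.2877 -0.3529 -0.2087
#> bu.x          0.4303  0.3236  0.5292

compare_fits(list(slip = fit,
                  two_state_slip = fit_mle_local("two_state_slip", rec, seed = 1)))
#>                         model     logL n_free      aic      bic delta_aic delta_bic
#> slip                     slip -1036.19      2 2076.379 2086.197         0   0.00000
#> two_state_slip two_state_slip -1036.19      5 2082.379 2106.923         6  20.72626
```

The fitted rate is 10^−0.2877 = 0.52 s⁻¹ with 95% CI (0.44, 0.62), covering
the generating 0.49 s⁻¹; the distance estimate 0.43 nm covers 0.48 nm. Both
information criteria prefer the one-state slip bond over the two-state slip
mixture on these single-exponential data (ΔBIC ≈ 21), the same comparison
used to conclude that a deletion construct binds in a single state.

Catch-bond data are fitted with `fit_catch_genetic(records, epochs = 100,
population = 200, seed = ...)`; judge the result by its mean-lifetime curve
(`mean_lifetime_curve`, `mean_lifetime_envelope`), not by individual rate
constants, which are honestly wide (see the methods vignette,
`vignettes/catchbond-methods.Rmd`).

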