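---
title: "Force-dependent bond lifetime models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-dependent bond lifetime models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catchbond)
```

## The scientific problem

Single-molecule optical-trap experiments on the cadherin--catenin/F-actin
linkage measure how long a protein--filament bond survives under a known
tensile load. A *slip bond* detaches faster as force grows; a *catch bond*
paradoxically lives longer over some force range. The mechanistic picture for
αE-catenin is a two-bound-state kinetic scheme: a weak state 1 (five-helix
actin-binding domain, H0/H1 docked), a strong state 2 (four-helix bundle,
H0/H1 undocked), and the unbound state 0. Load accelerates both dissociations
and the weak-to-strong switch, but slows the strong-to-weak return, so mean
lifetime rises with force before the slip regime takes over.

`catchbond` implements the full statistical machinery used to discriminate
these models from force--lifetime data: the candidate lifetime models,
maximum-likelihood estimation with global search, information-criterion
comparison, bootstrap uncertainty, event detection in raw trap traces, and
descriptive statistics (binned lifetimes, survival curves, lifetime ratios,
filament directionality) -- plus a synthetic-data generator so that every
stage is testable without instrument data.

## Models

All transition rates follow the Bell--Evans law

$$k_{i \to j}(F) = k^0_{i \to j} \exp(|F| \, x_{i \to j} / k_B T),$$

with zero-force rate $k^0$ (s⁻¹) and distance parameter $x$ (nm). A negative
$x$ means force *slows* the transition. Forces are signed in the instrument
frame; the magnitude enters the exponential, while the sign selects the
direction-specific distance ($x_-$ vs $x_+$) when a transition is fitted
directionally. We use $|F|$ for nondirectional fits because constant-force
events are all recorded under tension; the sign encodes orientation along
the polar filament, not compression.

Three candidate models are provided:

* **One-state slip bond** (`slip_model`): lifetimes are exponential with rate
  $k_{B\to U}(F)$.
* **Two-state slip mixture** (`two_state_slip_model`): binding lands in one
  of two non-interconverting states (probability $p_1$), giving a
  two-component exponential mixture.
* **Two-state catch bond** (`catch_model`): the observed lifetime is the
  first-passage time to state 0 of a continuous-time Markov chain on the two
  bound states with sub-generator
  $Q = \begin{pmatrix} -(k_{10}+k_{12}) & k_{12} \\ k_{21} & -(k_{20}+k_{21}) \end{pmatrix}$
  and exit rates $r = (k_{10}, k_{20})$. Survival is
  $S(\tau) = \pi e^{Q\tau} \mathbf{1}$, the density
  $f(\tau) = \pi e^{Q\tau} r$, and the mean lifetime $-\pi Q^{-1}\mathbf{1}$,
  a biexponential family consistent with the biphasic survival curves seen
  in the data.

**Initial occupancy.** The experimental literature does not state the
occupancy of the bound states at the moment of binding. We default to
$\pi = (1, 0)$ -- binding initiates in the weak state -- because the
mechanistic model has the weak (docked) conformation as the binding-competent
one, with the strong state reached by force-driven rearrangement. This is a
genuine modelling choice, exposed as the `pi0` argument, and fitted
parameters should be read conditional on it.

**Thermal energy.** $k_B T$ defaults to 4.11 pN·nm (298 K) and is
configurable; every fitted distance scales linearly with this choice.

## Numerical design

The catch-bond survival and density are evaluated through the closed-form
2×2 matrix exponential
$e^{Qt} = e^{\mu t}\left[\cosh(dt)\,I + \frac{\sinh(dt)}{d}(Q - \mu I)\right]$
with $\mu = \mathrm{tr}(Q)/2$ and $d = \sqrt{((a-d_{22})/2)^2 + k_{12}k_{21}}$.
Two cancellations matter in practice and both are handled analytically:

* the slow eigenvalue $\mu + d$ is computed as $-\det(Q)/(d - \mu)$, and
* $\det(Q)$ is expanded to the all-positive sum
  $k_{10}k_{20} + k_{10}k_{21} + k_{12}k_{20}$.

Without these, parameter sets with fast interconversion (rates spanning many
decades, which global search routinely visits) produce garbage likelihoods.
The $\sinh(dt)/d$ factor is evaluated with `expm1`, which passes smoothly
through the degenerate equal-eigenvalue case $d \to 0$ (the
$(1 + ct)e^{\lambda t}$ limit) without a special branch. All densities are
computed in log space, so lifetimes up to $10^4$ s do not underflow, and all
evaluations vectorize over observation pairs $(\tau_i, F_i)$.

## Fitting

`negative_log_likelihood` sums $-\log f(\tau_i \mid F_i)$ over last-step
records. Rates are optimized as $\log_{10} k^0$ (the plausible range spans
six decades), distances linearly. Default bounds are
$k^0 \in [10^{-3}, 10^3]$ s⁻¹ and $x \in [-5, 20]$ nm; any parameter can be
frozen via the `fixed` argument.

* **Slip-type models** (`fit_mle_local`): bounded quasi-Newton (L-BFGS-B)
  with 10 seeded random restarts, the first anchored at a moment estimate
  ($k^0 \approx 1/\bar\tau$).
* **Catch bond** (`fit_catch_genetic`): a generational genetic algorithm
  (population 200, tournament selection $k=3$, uniform crossover $p=0.5$,
  Gaussian mutation with σ = 10% of each parameter range, elitism 2) for
  100 generations, followed by L-BFGS-B polish of the five best individuals.
  Candidates whose zero-force mean lifetime exceeds 100 s receive an
  infinite objective -- this rejection-based constraint is simple and exactly
  reproducible. The GA locates the basin; the quasi-Newton step finds its
  floor. Every fit is fully determined by its seed.

AIC ($2p - 2\log L$) and BIC ($p\ln n - 2\log L$) compare candidates;
`compare_fits` adds Δ-criteria. Raw catch-bond parameters are weakly
identified (bootstrap CIs on interconversion rates can span the full bound
range), so model adequacy should be judged on the mean-lifetime curve
$\langle\tau\rangle(F) = \int_0^\infty t\,f(t\mid F)\,dt$, not on individual
rate constants.

**Bootstrap.** `bootstrap_mle` resamples records with replacement (replicate
size = sample size), refits each replicate (catch refits use 20 GA epochs;
slip-type refits start from the point estimate), and reports percentile CIs
(2.5/97.5 by default) plus per-force percentile envelopes of
$\langle\tau\rangle(F)$ via `mean_lifetime_envelope`. The reference analysis
uses 10,000 replicates; simulation studies in the test suite use 500, which
is ample for 95% endpoints of smooth statistics.

## Event detection

Constant-force assay: raw 40 kHz summed-force traces are block-averaged to
1 kHz (`decimate_trace`). Events are excursions above the baseline by a
binding threshold (default 1.5 pN; the source experiments state only that a
threshold was used). Change points come from convolving the force with the
second derivative of a Gaussian kernel (σ default 5 ms, truncated at 4σ,
reflected boundaries) and taking zero-crossings whose flanking response
lobes both exceed an amplitude floor (default 5× the baseline response SD).
Event delimitation uses a lightly smoothed copy of the trace with hysteresis
(runs extend outward to half the threshold) so weak final plateaus are not
clipped, and event edges are refined to the nearest change point; plateau
forces and change points are always measured on the raw 1 kHz series.
Because convolution zero-crossings drift when two ruptures fall within a
few kernel widths of each other, each detected boundary is refined by a
local two-plateau least-squares split, and every plateau is then scanned
for a residual split whose step height reaches the binding threshold --
catching ruptures the kernel merged. Events that do not outlive the 5 ms
loading ramp are excluded (`loading_phase`), as are events with a sustained
drop more than 1.5 pN below baseline (`slackening`). Where the original
workflow verified each event manually, `write_detected_events` exports an
editable CSV that round-trips through `read_records`.

Low-force assay: a 256-point periodogram slides one sample at a time over
the 1 kHz trace; power above 300 Hz is summed (`lowforce_band_power`), and
maximal runs exceeding 180% of the baseline mean become events
(`detect_lowforce_events`). Because any window within half a window of a
binding interval overlaps it, raw runs are debiased by half a window per
edge. The event force is the mean force offset relative to baseline.

## The synthetic-data generator

`simulate_dataset` emulates the study conditions: constant-force assay
forces from a truncated Gaussian centred at 6 pN (sd 2.5, clipped to
(0.5, 13] pN), matching the concentration of measured interactions between
4 and 8 pN; low-force assay forces uniform on 0.2--2.5 pN. Events carry
$M \ge 1$ molecules (default: 60% single-step with a geometric multi-step
tail) with i.i.d. lifetimes at the event force; the recorded last-step
lifetime is the gap between the two largest rupture times. Trace synthesis
(`simulate_constant_force_trace`) gives each bound molecule an equal force
share, so an $M$-molecule event steps down from $M F$ to 0 in $M$ discrete
plateaus after a 5 ms loading ramp; noise is white Gaussian (default
0.5 pN at 1 kHz bandwidth). `simulate_lowforce_trace` transmits a 150 Hz
stage oscillation (with configurable harmonics, some of which fall above
the 300 Hz detection band) scaled by a coupling factor, on top of a mean
offset drawn from 0.2--2.5 pN.

What the generator deliberately does *not* model: load redistribution among
molecules after each rupture (molecule lifetimes are independent),
bead--filament hydrodynamics and correlated (Ornstein--Uhlenbeck) noise,
filament compliance, and rebinding. Passing tests therefore demonstrate the
correctness of the statistical machinery under the stated model, not that
real traces satisfy the independent-molecule or white-noise idealizations.

## Problem sizes and validation

The test suite validates each stage at sizes chosen to make Monte-Carlo
noise negligible relative to the tolerances: sampler/analytic agreement by
Kolmogorov--Smirnov distance at $10^5$ draws (KS < 0.01); closed-form
means/densities against adaptive quadrature to $10^{-6}$ relative; slip
recovery at $n = 2000$ over 50 seeds (median error < 10%); catch-bond GA
recovery of the generating mean-lifetime curve at $n = 2000$ with forces
uniform over the assessed 0--12 pN range (median relative error < 15%;
the extreme high-force grid points are data-sparse, which is why the median
-- the identifiability-appropriate statistic -- is used); BIC selection of
the true one-state model in ≥ 90/100 replicates at $n = 500$; bootstrap
coverage of generating parameters in ≥ 90/100 outer replicates at
$n = 1000$, 500 replicates each; detector recovery of ≥ 95% of injected
events ≥ 20 ms with ≤ 5 ms lifetime error at 0.5 pN noise and zero false
events on event-free traces; and lifetime-ratio/directionality statistics
against analytic values. `scripts/acceptance.R` recomputes all of these
from scratch for any seed.

## Statistics conventions

* Sliding lifetime ratios use a 4 pN window on $|F|$ over 0--13 pN with a
  0.5 pN step and at least 5 records per window in each dataset; the
  summary "mean LR" is the unweighted mean over reported windows. LR
  envelopes use 90% percentile bootstrap bands.
* Directionality: per filament, events split by force sign; the inferred
  barbed (+) end is assigned to the shorter-mean group (ties to the $F>0$
  group), making the pooled (−)/(+) ratio ≥ 1 by construction -- an upper
  bound on directional asymmetry. Pooling across filaments after assignment
  is the default; per-filament averaging is available via `per_filament`.
* Survival comparisons default to the log-rank test (`survival::survdiff`);
  a two-sample KS option is provided. The source analysis did not name its
  test.
* Lifetime-ratio computations default to constant-force last-step records
  only; whether low-force events should enter is not settled, so they are
  excluded unless the caller pools them explicitly.

## Known limitations

Raw catch-bond rate constants are reported with honest, often very wide,
bootstrap intervals; treat the mean-lifetime curve as the inferential
object. The detector's defaults were chosen for 1 kHz data with ~0.5 pN
noise; traces with drift or correlated noise need the thresholds re-examined
(all are exposed as arguments). The pipeline treats all lifetimes as fully
observed -- there is no censoring machinery -- and models with more than two
bound states or force-ramp loading protocols are out of scope.
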