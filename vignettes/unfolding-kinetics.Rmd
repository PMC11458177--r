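---
title: "Methods: single-turnover unfolding kinetics with unfoldkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-turnover unfolding kinetics with unfoldkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unfoldkin)
```

## The kinetic scheme and its assumptions

A hexameric AAA+ motor (the motivating system is *E. coli* ClpB on
RepA-Titin substrates) is pre-bound to its substrate, and the reaction is
started by rapid mixing with ATP under single-turnover conditions: free
motor is trapped, so each complex acts once. The motor proceeds through `n`
irreversible, sequential unfolding steps, each first-order with the same
rate constant `k_U` (s^-1). Each step processes `m` amino acids on average
— the *kinetic* step-size, i.e. the spacing between rate-limiting events,
not necessarily a physical stride. After the last step the motor sits at
the C-terminal fluorophore (the "last intermediate") and dissociates with
rate constant `k_end` (s^-1). Fluorescence is ascribed to the last
intermediate (amplitude `F1`) and to the released unfolded product
(amplitude `F2`); all earlier intermediates are dark.

Assumptions inherited from this scheme: homogeneous per-step rates, no
dissociation from internal intermediates (dissociation during unfolding
enters only the separate processivity algebra, through the per-intermediate
rate constant `k_d` — deliberately a different symbol from `k_end`), no
rebinding, and no instrument dead-time correction.

Because `n = (L - C)/m` — substrate length minus the pre-translocated +
excluded length, divided by the step-size — `n` is generically
**non-integer**, and the optimizer needs continuity in `m`. The model is
therefore evaluated with a real-valued `n` (generalized-gamma chain), the
integer case being a special case.

## Evaluating the signal

The last-intermediate occupancy is the inverse Laplace transform of
`k_U^n / ((s + k_U)^n (s + k_end))`: the convolution of a gamma(`n`, `k_U`)
arrival density with the exponential survival of the terminal state. Three
regimes, all cancellation-free:

* `k_U > k_end`: log-space closed form via the regularized lower incomplete
  gamma, `I(t) = exp(n log(k_U/a) + log P(n, a t) - k_end t)` with
  `a = k_U - k_end` (`P` from `pgamma`). Stable arbitrarily close to
  `a = 0` because the `n log a` terms cancel analytically inside `pgamma`'s
  log form.
* `k_U <= k_end`, `x = (k_end - k_U) t <= 500`: positive-term Kummer series
  `M(n, n+1, x)`, iterated to machine convergence. At `x = 0` the series is
  exactly 1, so the degenerate case `k_U = k_end` — where the whole chain is
  a single-rate Erlang — is evaluated *exactly*, with no perturbation of
  `k_end`.
* `x > 500` (where the series would overflow): the exact integral
  `∫ (t-u)^(n-1) e^{-(k_end-k_U)u} du` is confined to a boundary layer
  `u ≲ 45/(k_end - k_U)`; 80-node Gauss-Legendre quadrature on that layer
  gives near machine precision.

A fixed-Talbot contour inversion was considered and rejected: for
non-integer `n` the transform has a branch point at `s = -k_U`, and a
Talbot contour wraps into exactly that region. The time-domain convolution
has no such hazard.

The product fraction is `P(n, k_U t) - I(t)` (everything that has completed
the gamma chain is either still in the last intermediate or released), and
the signal is `F(t) = F1 I(t) + F2 D(t)`.

Verification is dual-route everywhere: an independent
`backend = "quadrature"` integrates the convolution adaptively per time
point, and `ode_oracle()` integrates the (n+2)-state master equation with
`deSolve::lsoda` for integer `n`. The tests require agreement to 1e-8
(closed vs ODE, on fractions above 1e-4, which is the ODE solver's
absolute-error floor) and 1e-7 (closed vs quadrature, including non-integer
`n`). Comparisons are made where fractions are non-negligible; below ~1e-6
both reference routes are themselves truncation-limited.

## The synthetic data generator

`simulate_dataset()` emulates the deposited trace structure: per substrate
(lengths 168/265/362 aa), per delay time `dt1`, per replicate, a raw trace

    y(t) = F0 + labeling_efficiency * extent_of_binding * F(t)
           + drift * t + Gaussian noise,

on a log-spaced grid (default 0.01-5000 s, 2000 points, matching
stopped-flow sampling and peak times up to ~3000 s). The pre-translocated
distance grows linearly with the delay time,
`C(dt1) = excluded_length + v_gammaS * dt1`, representing slow ATPgS-driven
pre-unfolding during the ageing period. Noise is i.i.d. Gaussian with sd
proportional to each trace's noiseless peak amplitude (default 2%):
photodetector noise at these signal levels is well approximated as
Gaussian, and proportional scaling keeps SNR comparable across substrates.
The noise magnitude is a stand-in — replicate-level noise is not published
— so it is recorded in every manifest and never asserted against external
values. Streams are derived deterministically from
`(seed, substrate, dt1, replicate)`, so replicates are independent but
bit-reproducible.

What the generator does *not* emulate: motor assembly and binding kinetics,
the 2 ms mixing dead time, shot-to-shot chemical-equilibration drift
(represented only through `C(dt1)`), photobleaching, and non-Gaussian
outliers. Passing recovery tests therefore show that the *analysis* is
correct and well-conditioned under the model's own statistical structure,
not that real instrument pathologies are handled.

### Default parameter choices

* `k_U = 0.017` /s, `m = 56.5` aa (1:1 ATP:ATPgS); `k_U = 0.055` /s,
  `m = 58` aa (3:1); `k_U = 0.0042` /s, `m = 26` aa (ATPgS only) — the
  reference estimates for this assay, used as generating truth.
* `F1 = 1`, `F2 = 0.05` (arbitrary units). PIFE requires the motor within a
  few nm of the dye, so most enhancement is lost on dissociation; the small
  residual product amplitude stands for refolding-related signal. A small
  `F2/F1` is also what permits a peak when dissociation is fast.
* Terminal dissociation, closure datasets: `(0.08, 0.01, 0.05)` /s for the
  one-, two-, three-domain constructs — local variability inside the
  observed 0.01-0.15 /s range, assigned so that (i) every trace keeps the
  characteristic lag/rise/decay (at least ~20% decay from peak within the
  window) and (ii) together with the labeling efficiencies (0.70, 0.95,
  0.80) the two-domain construct shows the tallest peak, as in the real
  data, where it is the best-labeled substrate.
* Terminal dissociation, kinematic (multi-`dt1`) designs:
  `k_end_kinematic = k_U`, a single common value. This is not cosmetic: at
  `k_end = k_U` the chain is a pure Erlang and the peak of
  `F1 I + F2 D` solves `n/t - k_U = -F2 k_U / F1`, i.e.

      t_peak = n / (k_U (1 - F2/F1))

  — *exactly linear in n*. Substrate length vs peak time is then exactly
  the kinematic line `L = C + m k_U (1 - F2/F1) t`, the intercept equals
  `C` with zero bias, and the pre-translocation rate is recovered exactly
  from the intercept-vs-delay slope. Away from this regime the intercept
  carries a constant offset (which still cancels in the delay-time slope to
  first order) and the kinematic slope underestimates `m k_U` by the factor
  `(1 - F2/F1)` plus finite-`n` curvature — which is why the tests assert
  slope agreement with `m k_U` only within 15%.
* `F0 = 5` arbitrary units baseline, so the relative-enhancement
  normalization is nontrivial; `excluded_length = 48` aa and `v_gammaS = 0.09` aa/s (1:1
  condition) for the pre-translocation model; 3 replicates.

## Preprocessing

`relative_enhancement()` implements `|F0_av - F(t)| / F0_av` with `F0_av`
the mean of the first `n_baseline = 10` points (the source description says
only "first few"; 10 gives a robust mean well before the lag ends at these
rates). The absolute value is implemented exactly as specified; PIFE
(signal increase) is the documented default interpretation. The ratio makes
the result invariant to the raw intensity scale.

One subtlety matters for noiseless closure at small `n`: the early signal
rises as `(k_U t)^n`, so the "constant" baseline window carries a ~1e-4
relative signal contribution, and the normalized trace differs from the
model by a small additive constant. The global fit therefore profiles a
free per-trace baseline offset (see below); without it, noiseless recovery
of `k_U` is biased by up to ~1%.

Replicate averaging requires exactly matching grids (mismatch is an error
— no silent interpolation) and attaches the pointwise sample sd. Smoothing
is a local polynomial (Savitzky-Golay-type) regression performed in *time*,
not sample index, so it reproduces polynomials exactly on the log-spaced
grid, with shrinking windows at the ends; `window = 1` is the identity.

## Model-independent analysis

`detect_peak()` takes the global maximum of the smoothed trace over the
interior (first and last 1% excluded; boundary maxima are flagged, ties go
to the earliest time) and refines it with a local quadratic through the
three neighboring smoothed points — sub-sample interpolation that never
moves the estimate by more than one grid interval. Peak height is read from
the unsmoothed trace.

`fit_length_vs_peaktime()` regresses length (response, aa) on peak time
(regressor, s) — the orientation of the assay's kinematic plots, yielding
the rate directly in aa/s — weighted by `1/sd^2` with sd from replicate
peak-time scatter, unweighted when replicates are absent. The intercept is
reported as the pre-translocated distance with the documented caveat that,
away from the `k_end = k_U` regime, it carries a constant peak-offset bias;
no bias correction is applied. `fit_pretranslocation_vs_dt1()` applies the
same contract with the delay time as regressor. Standard errors come from
the weighted normal equations with the residual variance estimated from the
fit (the `lm` convention); with two or three points they are indicative
only.

## Model-dependent analysis

`fit_global()` minimizes the summed squared residuals of all traces with
`m, k_U` global and `k_end` local, `n_i = (L_i - C_i)/m` substituted into
the signal. Design choices:

* **Variable projection.** `F1`, `F2`, and the baseline offset enter
  linearly, so they are solved per trace by (sign-constrained for the
  amplitudes) linear least squares at every objective evaluation. The
  nonlinear search runs over only `2 + T` parameters for `T` traces.
* **Log parameterization and bounds.** Rates and `m` are searched in log
  space within `k_U, k_end ∈ [1e-4, 10]` /s and `m ∈ [5, 200]` aa.
* **Multi-start.** `n_starts >= 10`: three data-driven starts built from
  the peak-time line (each trial step-size implies a peak-consistent
  `k_U`), with per-trace `k_end` seeded from the post-peak decay half-time,
  plus seeded log-uniform random starts. Remaining starts are skipped once
  one attains an essentially perfect fit (RSS below 1e-8 of the signal
  power), which only noiseless data reach. Seeds are required arguments —
  no wall-clock entropy anywhere.
* **Refusal on multimodality.** If the two best optima differ by less than
  1% in objective but more than 20% in some parameter, the fit refuses to
  report (configurable to a warning). A single substrate length triggers a
  weak-identifiability flag, since one length constrains only `m * k_U`.
* **Weighting.** Residuals are unweighted within a trace and traces are
  equally weighted; this is documented rather than hidden.
* **C handling.** `C` comes from the model-independent per-replicate
  intercept in the pipeline; closure tests may fix it from the generator
  manifest so the two stages can be validated independently.

`fit_local_n()` is the diagnostic mode: `k_U` shared, `n_i` and `k_end_i`
free, followed by the weighted `n` vs `L` line whose slope estimates `1/m`
and whose x-intercept estimates `C`. With `n` free, near-mimicking
`(n, k_end)` pairs form a shallow objective background in which the exact
optimum sits as a narrow cleft; after the multi-start, each trace's `n` is
therefore scanned on a fine grid with its `k_end` re-optimized, and the
result polished jointly. Without this refinement the slope of `n` vs `L`
can sit on the background, ~10% off, even for noiseless data.

`bootstrap_uncertainty()` offers residual-resampling percentile intervals
(seeded; aborts if more than 20% of refits fail); `replicate_summary()`
reproduces the assay's summary convention — inverse-variance weighted mean
(equivalently, the best weighted zero-slope line) with the across-replicate
sd as the error.

## Processivity algebra

`p_from_rates()` (`P = k_U/(k_U + k_d)`), `p_from_step_and_N()`
(`P = exp(-m/N)`), and `N_from_p_and_step()` are exact inverses to 1e-12
and reject the degenerate `P = 1` rather than returning infinity. The
amplitude model `X * P^n * F` is strictly decreasing in `n` for `P < 1`,
matching the interpretation that a reduced peak reflects less motor bound,
lower processivity, or both. Following the printed convention, `N` is taken
as the full observed substrate length (362 aa) in the reference
conversions, without subtracting the excluded length.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at the study's native scale:
2000-point grids, three substrates, delay times {300, 420, 600} s, three
replicates at 2% noise for the stochastic checks; optimizer-heavy unit
tests use 150-500-point grids of the same span. Noiseless closure recovers
`(m, k_U)` to well within 0.5% for all three reference conditions;
noisy-replicate recovery is asserted within 10% at fixed seeds. Oracle
agreement contracts are as stated above; the Kummer series truncates at a
relative term below 1e-17, and `optimize()` brackets peak refinement to
1e-6 relative.

## Known limitations

* Heterogeneous per-step rates, reversible steps, and dissociation from
  internal intermediates are out of scope for the signal model.
* The peak-time intercept is bias-free only in the `k_end ≈ k_U`,
  `F2 << F1` regime; elsewhere it is offset by a constant that cancels in
  delay-time slopes but not in the excluded-length point estimate.
* Standard errors from two- or three-point weighted lines are nominal;
  replicate scatter or the bootstrap should be preferred.
* The local-`n` diagnostic is intrinsically ill-conditioned: with noise,
  individual `n_i` carry large uncertainties even when the constrained fit
  is precise.
* Raw (un-normalized) traces are not fit; normalization is part of the
  contract.
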