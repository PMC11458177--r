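# unfoldkin

Transient-state kinetic analysis of processive protein unfolding by AAA+
motor proteins, built around single-turnover stopped-flow fluorescence
experiments of the kind used to study *E. coli* ClpB acting on RepA-Titin
substrates (70 unstructured RepA residues as a binding site followed by 1-3
tandem Titin I27 domains and a C-terminal dye). A pre-bound motor is mixed
with ATP; protein-induced fluorescence enhancement (PIFE) reports its
arrival at the C-terminal fluorophore, so each trace shows a lag (unfolding
in progress), a rise (arrival), and a decay (dissociation).

The package is aimed at enzymologists who want to estimate unfolding rate
constants, kinetic step-sizes, and processivity from such traces — or to
test, with synthetic data, whether a given experimental design can recover
them.

## The model

The motor steps through `n` sequential unfolding events with rate constant
`k_U` (each step unfolds `m` amino acids on average, the *kinetic
step-size*), reaching the fluorophore-adjacent last intermediate, then
dissociates from the C-terminal end with rate constant `k_end`. Only the
last intermediate (amplitude `F1`) and the released product (amplitude `F2`)
fluoresce. The signal is the inverse Laplace transform

    F(t) = L^-1 { F1 k_U^n / ((k_end + s)(k_U + s)^n)
                + F2 k_end k_U^n / (s (k_end + s)(k_U + s)^n) }

evaluated for real (non-integer) `n`, since `n = (L - C)/m` where `L` is the
substrate length and `C` the pre-translocated + excluded length at mixing.
In the time domain this is the convolution of a gamma(n, k_U) arrival
density with the terminal dissociation step; the package evaluates it by
cancellation-free closed forms (regularized incomplete gamma / Kummer
series / boundary-layer quadrature), cross-checked against an independent
adaptive-quadrature backend and an integer-`n` ODE chain oracle.

Two analyses are provided:

* **Model-independent (peak-time) analysis** — the peak of each trace is
  read as the motor's arrival time; substrate length vs peak time is a
  kinematic position-time plot whose slope is the overall rate `m * k_U`
  (aa/s) and whose intercept is `C` (aa). Repeating the experiment at
  several delay times between pre-incubation and ATP addition and fitting
  intercept vs delay time yields the slow ATPgS-driven pre-translocation
  rate and the excluded length.
* **Model-dependent (global) analysis** — all traces are fit simultaneously
  to the signal model with `m` and `k_U` shared and `k_end`, `F1`, `F2` (and
  a baseline offset) local, by multi-start bounded Levenberg-Marquardt with
  the linear parameters profiled out.

The processivity module converts between the per-step continuation
probability `P = k_U / (k_U + k_d)` and the processivity in amino acids `N`
via `P = exp(-m/N)`, and models the single-turnover peak amplitude as
`X * P^n * F` (extent of binding x survival x fluorescence factor).

## Worked example

Simulate a noiseless multi-delay dataset at the 1:1 ATP:ATPgS reference
condition and run both analyses:

```r
library(unfoldkin)

design <- experiment_design(
  dt1 = c(300, 420, 600), condition = "atp_atpgs_1to1",
  k_end = clpb_conditions("atp_atpgs_1to1")$k_end_kinematic,
  noise_sd = 0, n_replicates = 1)
dataset <- simulate_dataset(design)

pk <- run_peaktime_pipeline(dataset)
pk$per_dt1
#>   dt1_s slope_aa_per_s  slope_sd intercept_aa intercept_sd
#> 1   300         0.9125 3.029e-06         75.0    0.0006834
#> 2   420         0.9125 6.897e-07         85.8    0.0001481
#> 3   600         0.9125 1.790e-06        102.0    0.0003556
pk$dt1_fit
#> <dt1_fit> v_gammaS = 0.09 +/- 3e-06 aa/s; excluded length = 48 +/- 0.0013 aa

traces600 <- lapply(
  Filter(function(tc) tc$meta$dt1 == 600, dataset$traces),
  relative_enhancement)
fit <- fit_global(traces600, C = pk$per_dt1$intercept_aa[3],
                  n_starts = 10, seed = 42)
fit
#> <global_fit> m = 56.5 aa, k_U = 0.017 /s (m*k_U = 0.9605 aa/s)
#>   3 trace(s), RSS = 3.429e-13, 1 start(s) run

p_from_step_and_N(fit$m, 362)
#> [1] 0.855
```

The per-delay kinematic slope (0.91 aa/s) estimates the overall unfolding
rate; the intercepts grow linearly with delay time at 0.09 aa/s (the
ATPgS-driven pre-translocation rate) from a 48 aa excluded length. The
global fit recovers the generating step-size (56.5 aa) and unfolding rate
constant (0.017 /s) from the traces alone, and `P = 0.855` is the implied
per-step continuation probability if the motor's processivity is the full
362 aa substrate.

`run_pipeline(config, out_dir)` chains simulation (or reading a dataset
from disk), normalization, both analyses, and the processivity summary,
writing every intermediate table as CSV plus a JSON report.

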