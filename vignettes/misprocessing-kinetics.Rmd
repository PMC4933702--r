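---
title: "Kinetics of co-translational huntingtin misprocessing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of co-translational huntingtin misprocessing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httkin)
```

## The model

Huntington's disease arises from expansion of the CAG repeat in exon 1 of
*HTT*. This package implements a chemical-kinetic account of how that
expansion could impair a co-translational event: exon 1 encodes the
N17 localization signal (codons 1–17), the polyglutamine tract (codons 18
to 17 + `N_CAG`), and a 38-codon proline-rich region immediately
downstream. Proline codons are translated slowly, so the proline-rich
region acts as a brake on elongation. In the reference Q35 construct the
brake engages exactly as N17 becomes available to a co-translationally
acting factor (CAF); every added repeat pushes the brake one codon further
downstream, shortening the time the factor has to act.

Three assumptions make the scheme solvable in closed form:

1. CAF binding to N17 is irreversible in its optimal-binding region (no
   off-rate is exposed anywhere in the package).
2. The on-rate `k_on` is nonzero only while the ribosome decodes codons
   53–72 (the `binding_window()`), matching the ~20-residue optimal-binding
   spans observed for factors such as SRP.
3. Elongation uses two codon classes: fast codons decoded in `τ_A` (N17,
   polyQ) and slow codons decoded in `s·τ_A` (the proline-rich region).

Under these assumptions the probability that a nascent chain escapes
binding is the survival function of an inhomogeneous-in-time but
piecewise-constant Poisson process, `exp(−k_on·τ_AFB)`, where `τ_AFB` is
the total dwell time over the window codons. The amount misprocessed at
available time `τ_AFB` is `A_mp = A_mp(τ_AFB = 0)·exp(−k_on·τ_AFB)`
(`amount_misprocessed()`), and the fraction misprocessed *relative to the
35-repeat reference* is

$$f_{mp}(N_{CAG}) = \exp\left[-k_{on}\,(\tau_{AFB}(N_{CAG}) -
\tau_{AFB}(35))\right] - 1 .$$

The unknown prefactor cancels — a property the test suite asserts to
machine precision (relative tolerance 1e-12) by forming the amount ratio
explicitly for several prefactors. `f_mp` is a relative fraction: it is
zero at the reference, unbounded above, and deliberately not clamped at 1.
Repeat numbers below 35 are rejected rather than extrapolated, since the
model is defined only relative to that reference.

With the default window and slowdown, `τ_AFB(N) = 40 − clamp(N − 35, 0,
20)` in `τ_A` units: it falls by one `τ_A` per added repeat and bottoms out
at 20 `τ_A` at `N_CAG = 55`, after which `f_mp` is constant (the plateau).

## Parameters, units and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `k_on` | effective first-order CAF on-rate (s⁻¹) | 0.0366 | DnaJ bimolecular rate 3.3×10⁵ M⁻¹s⁻¹ × 1.11×10⁻⁷ M median cytosolic/nuclear chaperone concentration |
| `tau_a` | fast-codon decoding time (s) | 1 | sets the time unit; only the product `β = k_on·τ_A` enters `f_mp` |
| `slowdown_s` | proline slowdown factor | 2 | lower end of the 2–6× range reported for proline translation |
| window | codons with nonzero `k_on` | 53–72 | proline-region start in the Q35 construct + a 20-codon optimal span |

`τ_AFB` is carried in units of `τ_A` and the exponent is evaluated as
`β·τ_AFB`. No absolute codon time is asserted anywhere; `tau_a = 1 s` is a
unit convention that makes `β = 0.0366` with the default rate, the only
pairing that reproduces the reference correlations. The actual CAF is not
identified — DnaJ is an order-of-magnitude stand-in — so
`effective_kon()`, `median_cytoplasmic_concentration()` and
`copies_to_concentration()` expose all three ingredients of the estimate
instead of hard-coding the product.

The schedule models all 38 proline-region codons as slow although only 28
of the 38 residues are prolines: the model never distinguishes
sub-positions, and only window codons enter any computed quantity.
Schedules end at codon `55 + N_CAG`; the downstream HEAT-repeat portion of
huntingtin never enters the window for the repeat ranges analyzed. A
consequence worth noting: the remark that widening the binding window does
not change `f_mp` holds within the modeled construct for downstream
extensions up to codon 90 (codons 73–90 are proline-region for every
repeat number between 35 and 55, so the added dwell is constant and
cancels); windows beyond the construct raise a bounds error rather than
silently inventing downstream dwell times.

## Correlation stage

`correlate_fmp_vs_ncag()` evaluates `f_mp` at each integer repeat number
and returns a `correlation_result` (Pearson r, R², two-sided p from the
exact Student-t tail on n − 2 degrees of freedom — the sample sizes are
12–14, so no normal approximation — and the OLS line). With defaults:

```{r}
glance(correlate_fmp_vs_ncag(40, 53))
glance(correlate_fmp_vs_ncag(39, 50))
```

`correlate_onset_vs_fmp()` maps each onset record's repeat number to its
model `f_mp` and correlates onset age against it; records below 36 repeats
are rejected (the correlation is a disease-range analysis). Replicate ages
per repeat number enter individually by default; `aggregate = "mean"`
averages per repeat first. R² values are reported to 3 decimal places in
summaries. `sensitivity_scan()` repeats the `f_mp`-vs-repeat correlation
across slowdown factors; over `s = 2..6` the R² declines monotonically but
stays above 0.9, so the conclusion is not an artifact of the 2× choice.

## Monte-Carlo validation

`simulate_translation()` is an independent stochastic check of the closed
form, not part of the model itself. Each replicate ribosome traverses the
schedule; inside the window, binding arrivals are exponential waiting
times with rate `k_on` clipped to the per-codon dwell intervals, and the
first arrival (if any) is recorded. Two dwell modes exist:

* `"fixed"` — the scheduled dwell times exactly, matching the model's
  deterministic-elongation assumption; survival is `exp(−k_on·τ_AFB)` and
  depends on `τ_AFB` only.
* `"exponential"` — dwell times exponentially distributed with the
  scheduled means, a robustness extension; by memorylessness each window
  codon is an independent competition and survival is
  `∏ 1/(1 + k_on·τ_i)`. This mode probes sensitivity to the
  deterministic-dwell assumption; it is not part of the closed-form model.

`compare_to_analytic()` reports the discrepancy in binomial standard
errors, computed under the analytic survival probability so the z-score is
defined even at empirical fractions of 0 or 1; agreement within 3 SE is
the pass criterion. A single RNG stream keyed by the seed drives each run,
so results are exactly reproducible. The test suite runs 10⁵ replicates
(about a second) for the 3-SE check and 10³–10⁵ for the convergence-rate
check.

## Synthetic data: what it does and does not show

No clinical or proteomic tables ship with the package; the generators
produce data with the statistical structure the analysis assumes.

`generate_onset_dataset()` draws onset ages around a line declining 3
years per repeat (the clinically reported slope) from a base age of 60
years at the range minimum, with additive Gaussian noise (default SD 3
years — a placeholder, since the error structure of the digitized clinical
curves is not published) truncated at 1 year. An exponential-decline mode
(`age = a + b·exp(−c·(N − 35))`, defaults a = 20, b = 70, c = 0.08 chosen
to bend plausibly across the 36–60 repeat range) mimics the curvature of
real repeat/onset curves; it is off by default. A parameter-recovery test
fixes the realism bar: at 10 records per repeat over 40–53, OLS recovers
the −3 yr/repeat slope within ±0.5.

`generate_chaperone_table()` emulates a HeLa chaperone-abundance survey:
log-normal concentrations with compartment labels, rescaled (and, for
odd-sized subsets, snapped at the central order statistic) so the
cytosolic/nuclear median equals the target **exactly**. That makes the
downstream 0.0366 s⁻¹ estimate deterministic — the table is a structural
stand-in, clearly labelled synthetic, not a re-derivation of measured
abundances.

Passing tests on these data therefore demonstrate internal consistency of
the pipeline and recoverability of known structure — not agreement with
any particular clinical dataset. The onset-age-vs-`f_mp` correlation on
real digitized data cannot be reproduced in value here because those
digitized tables are not published; on noise-free synthetic data the
correlation is r < −0.99 by construction of the near-linear model curve.

## Numerical choices and degenerate inputs

* Closed-form identities (cancellation, window invariance) are asserted at
  relative tolerance 1e-12; everything else at testthat defaults.
* `k_on = 0` is allowed in the kinetics (no binding; `f_mp ≡ 0`) but makes
  correlations undefined — the zero-variance error is raised by
  `pearson()` and propagates through `sensitivity_scan()` rows and
  `run_curve()` (e.g. at `slowdown_s = 1`).
* Medians use the midpoint convention for even counts; compartment labels
  match case-insensitively.
* The linearized fraction `x = β·(τ_AFB(35) − τ_AFB(N))` obeys
  `|f_mp − x| ≤ x²·eˣ/2` (Lagrange remainder), asserted across the full
  repeat range.
* Generators and the simulator call `set.seed()` internally with the
  supplied seed, so equal specs give byte-identical CSV output.

## Pipeline and reproducibility

The `run_*()` wrappers (`run_curve`, `run_correlate`, `run_simulate`,
`run_kon`, `run_sensitivity`, `run_synth`) write each stage's outputs
(CSV/JSON) plus the resolved `run_config.json` into an output directory;
`read_run_config()` restores a configuration identical to the one written,
so any run is reproducible from its emitted configuration alone. Problem
sizes throughout the examples and tests — 14-point repeat ranges, 10⁵
Monte-Carlo replicates, 109-record chaperone tables — were chosen as the
natural desk scale of the model itself; each stage completes in seconds.

## Known limitations

* The model is relative: it predicts fold-changes in misprocessing versus
  the Q35 reference, never absolute misprocessed amounts (the prefactor
  cancels by design and is unknowable within the model).
* Two dwell classes ignore codon-usage, tRNA-abundance and mRNA-structure
  effects; the 38-codon proline region is treated as uniformly slow.
* One ribosome at a time: no polysome interference, drop-off, or factor
  depletion.
* The CAF is hypothetical; `k_on` is an order-of-magnitude estimate built
  from DnaJ measurements, and the window placement at codons 53–72 is
  deliberate but partly arbitrary (the downstream edge in particular).
* Onset correlations on synthetic data show form, not clinical fact.
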