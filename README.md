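# httkin

A chemical-kinetic model of co-translational huntingtin (Htt) misprocessing,
for researchers studying how CAG-repeat expansion in *HTT* exon 1 could
perturb events that act on the nascent chain during translation.

## The model

Exon 1 of huntingtin encodes, in order, the 17-residue N17 localization
signal, a polyglutamine tract of `N_CAG` repeats (disease threshold 35), and
a 38-residue proline-rich region. Translation elongation is modeled with two
codon classes: fast codons decoded in time `τ_A` (N17 and polyQ) and slow
codons decoded in `s·τ_A` (the proline-rich region; `s = 2` by default, the
lower end of the 2–6× slowdown reported for proline translation).

A co-translationally acting factor (CAF) can bind N17 only while the
ribosome decodes codons 53–72 — the position at which the proline-rich
region first meets the window in the reference Q35 construct. Binding is an
irreversible pseudo-first-order process with rate `k_on`, so the fraction of
nascent chains that escape binding during the available time `τ_AFB` (the
total dwell time over window codons) is `exp(−k_on·τ_AFB)`. Each repeat
added beyond 35 pushes the proline-rich brake downstream, replacing one slow
codon in the window with a fast one, until `τ_AFB` bottoms out at 20 `τ_A`
at `N_CAG = 55`. The misprocessed fraction relative to the Q35 reference is

    f_mp(N_CAG) = exp[ −k_on · (τ_AFB(N_CAG) − τ_AFB(35)) ] − 1

The unknown zero-binding amount cancels in the ratio; with the in-vivo rate
estimate `k_on = 3.3×10⁵ M⁻¹s⁻¹ × 1.11×10⁻⁷ M = 0.0366 s⁻¹` (DnaJ on-rate ×
median cytosolic/nuclear chaperone concentration in HeLa cells), `f_mp`
correlates near-perfectly with `N_CAG` over the clinically observed repeat
ranges, and hence with the declining age of symptom onset (~3 years earlier
per added repeat).

The package provides the dwell-schedule construction, the `τ_AFB`/`f_mp`
kinetics, the effective-rate estimation, a Monte-Carlo single-ribosome
simulation validating the closed-form survival probability, the Pearson
correlation stage, synthetic-data generators (onset ages, chaperone tables),
and `run_*()` pipeline wrappers that write CSV/JSON outputs with a
reproducible configuration.

## Worked example

```r
library(httkin)

curve <- misprocessing_curve(40, 53)
head(curve, 4)
#> # A tibble: 4 × 3
#>   n_cag tau_afb_tau_a  f_mp
#>   <int>         <dbl> <dbl>
#> 1    40            35 0.201
#> 2    41            34 0.246
#> 3    42            33 0.292
#> 4    43            32 0.340

glance(correlate_fmp_vs_ncag(40, 53))
#> # A tibble: 1 × 3
#>   r.squared  p.value  nobs
#>       <dbl>    <dbl> <int>
#> 1     0.996 1.35e-15    14

effective_kon(3.3e5, 1.11e-7)
#> [1] 0.03663

compare_to_analytic(35, n_ribosomes = 1e5, seed = 1)
#> # A tibble: 1 × 8
#>   dwell_model n_cag empirical_survival analytic_survival standard_error z_score
#>   <chr>       <int>              <dbl>             <dbl>          <dbl>   <dbl>
#> 1 fixed          35              0.232             0.231        0.00133   0.383
```

At 40 repeats the window still holds 15 slow codons (`τ_AFB = 35 τ_A`) and
the misprocessed fraction is 20% above the Q35 reference; by 53 repeats it
approaches the plateau. The squared Pearson correlation between `f_mp` and
`N_CAG` over 40–53 is 0.996 (p ≈ 1×10⁻¹⁵); the Monte-Carlo unbound fraction
at the reference construct (0.232 of 10⁵ ribosomes) sits within one binomial
standard error of the closed form `exp(−0.0366 × 40) = 0.231`.

`autoplot()` methods draw the curve and correlation scatter;
`plot_schedule()` shows the per-codon dwell profile with the binding window
shaded.

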