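# gcdeadtime

Dead-time losses of a gamma camera in Lu-177 imaging, and how thin
shielding filters reduce them.

## The problem

Quantitative imaging during Lu-177 radionuclide therapy (e.g.
Lu-177-DOTATATE for neuroendocrine tumors) measures count rates in the
208 keV ± 10% energy window. Although the 208.4-keV line carries only
11% of decays, the lower-energy emissions (113 keV and the 54–65 keV
X-rays) still pile into the detector electronics and paralyse them, so
counts are lost even though those photons never enter the analysis
window. For patients with a high tumor burden and slow excretion this
dead-time loss stays at the percent level for days and biases dosimetry.

A simple hardware fix is to cover the collimator face with a thin
filter — a 0.5-mm lead sheet or 1.2-mm tungsten functional paper (TFP,
paper loaded with ~80 wt% tungsten) — that absorbs the low-energy lines
while letting most 208-keV photons through. This package simulates and
analyses that trade-off end to end.

## The model

Counting follows the paralyzable dead-time model

    R_obs = R_true · exp(−R_true · τ_w)

where `τ_w` is the *apparent* dead time of the analysis window. It is
longer than the full-window dead time `τ` because every full-window
arrival paralyses the electronics:

    τ_w = τ / wf^η,    wf = counts in window / counts in full window

with `η` a camera-dependent exponent (≈1.4 in published fits; exactly 1
when pile-up is absent). Filters raise `wf` by stripping low-energy
counts, which shortens `τ_w` and cuts the loss

    loss(%) = (R_true − R_obs) / R_true × 100

evaluated on TEW (triple-energy-window) scatter-corrected primary
counts. The package provides:

* the Lu-177 line set and Monte Carlo source sampling;
* materials, log-log interpolated mass-attenuation tables, filter
  transmission, Klein–Nishina Compton physics;
* a simplified geometric body phantom (liver/spleen/kidneys in a water
  box, 7.4 GBq injected, 52 %IA retained at 24 h) viewed by anterior
  and posterior detectors through an ideal-angular-gate collimator,
  transported with an unbiased next-event estimator;
* an event-level detector model: NaI intrinsic efficiency, 9.4% FWHM
  energy resolution at 208 keV, paralyzable dead time (0.5 µs full
  window) with optional pile-up summation;
* energy windows, window fractions, TEW primary counts;
* the dead-time mathematics (forward/inverse paralyzable law, `τ_w`
  and `η` estimators);
* a 24–120 h analytical time course driven by a retention curve;
* an orchestrated experiment (3 filter configurations × 2 detectors)
  with Welch's t-tests and Bonferroni correction.

## Worked example

```r
library(gcdeadtime)

## filter transmission at the Lu-177 lines (208.4, 113, 55.8 keV)
round(transmission(filter_lead_05(), c(208.4, 113, 55.8)), 3)
#> [1] 0.596 0.098 0.032
round(transmission(filter_tfp_12(),  c(208.4, 113, 55.8)), 3)
#> [1] 0.789 0.355 0.240
```

Both filters pass most of the photopeak but suppress the low-energy
lines; lead is the more aggressive of the two.

```r
## paralyzable law at the published mean no-filter dead time (9.3 us)
paralyzable_observed(5.6e3, 9.3e-6)
#> [1] 5315.816        # 5.6 kcps true -> 5.3 kcps observed (~5% loss)
paralyzable_true(5315.816, 9.3e-6)
#> [1] 5600             # exact round-trip on the physical branch

## the full simulated comparison
ex <- run_experiment(experiment_config(n_histories = 1e4), seed = 1)
ex
#> <gc_experiment> seed 1, 10000 histories
#> # A tibble: 6 × 6
#>   detector filter wf_mean tau_w_us_mean true_primary_cps loss_pct_mean
#>      <int> <chr>    <dbl>         <dbl>            <dbl>         <dbl>
#> 1        1 none     0.202          2.83           56582.         34.3
#> 2        1 tfp      0.360          2.32           44597.         18.6
#> 3        1 lead     0.510          1.82           33776.          9.57
#> 4        2 none     0.207          2.84           43241.         27.1
#> 5        2 tfp      0.366          2.28           34104.         12.7
#> 6        2 lead     0.502          1.91           25736.          5.40
```

Reading the table: filters raise the window fraction (`wf_mean`,
lead > TFP > none), which shortens the apparent dead time
(`tau_w_us_mean`, lead < TFP < none) and cuts the dead-time loss
(`loss_pct_mean`, none > TFP > lead); the anterior detector (1) sees
higher rates than the posterior one because the liver — which carries
most of the activity — sits anteriorly. TFP loses less primary signal
than lead, which is its selling point. The absolute window fractions
and dead times of this simplified geometric transport sit above/below
the published voxel-phantom values respectively; the orderings, which
drive the filter comparison, reproduce throughout.

```r
ex$eta                    # fitted window-fraction exponent (pile-up on)
#> # A tibble: 2 × 3
#>   detector   eta    se
#>      <int> <dbl> <dbl>
#> 1        1  1.28 0.203
#> 2        2  1.31 0.205

autoplot(ex)              # 24-120 h loss time course per filter
```

## Configuration

Experiments are declarative: every stage parameter lives in one YAML
file (see `inst/extdata/default-config.yaml` for the fully spelled-out
schema) loaded with `read_experiment_config()`. A standalone forward/
inverse dead-time calculator for CSV rate tables ships in
`inst/scripts/deadtime_correct.R`.
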