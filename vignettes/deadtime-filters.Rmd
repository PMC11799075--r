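---
title: "Methods: simulating gamma-camera dead-time losses for Lu-177 with shielding filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating gamma-camera dead-time losses for Lu-177 with shielding filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdeadtime)
```

## The physics being modelled

A gamma camera counting Lu-177 decays records events in the
208 keV ± 10% window, but its electronics are paralysed by *every*
interaction in the crystal, including the 113-keV gamma line and the
54–65-keV X-rays that never enter the analysis window. The package
models this with the paralyzable dead-time law

$$R_{wo} = R_{wt}\, e^{-R_{wt}\tau_w},$$

where $R_{wt}$ and $R_{wo}$ are the true and observed rates in a window
and $\tau_w$ is the *apparent* dead time of that window. Because
out-of-window arrivals still paralyse the electronics, $\tau_w$ exceeds
the full-window dead time $\tau$ according to

$$\tau_w = \tau / wf^{\eta},$$

with $wf$ the window fraction (window counts over full-window counts)
and $\eta$ a positive exponent. Losses are reported on
triple-energy-window (TEW) scatter-corrected *primary* counts:

$$\mathrm{loss}(\%) = \frac{R_{wt} - R_{wo}}{R_{wt}} \times 100 .$$

A thin filter on the collimator face (0.5-mm lead or 1.2-mm tungsten
functional paper) preferentially absorbs the low-energy lines, raising
$wf$, shortening $\tau_w$ and reducing the loss, at the price of some
photopeak attenuation. Everything else in the package exists to give
these four equations realistic inputs.

## Source term

`lu177_spectrum()` carries the six photon lines relevant to imaging
(208.4 and 113.0 keV gammas; 64.9, 63.2, 55.8 and 54.6 keV X-rays),
with per-decay intensities summing to 0.229. Beta particles and the
weak high-energy gamma lines are omitted: neither reaches the crystal
through a parallel-hole collimator in this regime. Other nuclides can
be loaded from a two-column text table (`read_emission_table()`).

## Photon physics

Per-element mass-attenuation tables (H, C, O, Na, Al, I, W, Pb;
20–500 keV) are packaged as plain text and interpolated log-log, the
standard treatment for photon cross-sections in this range. Grid points
straddle the K edges of iodine (33.17 keV), tungsten (69.525 keV) and
lead (88 keV) so interpolation never crosses an edge. The tables are
compact tabulations consistent with standard compilations: the
incoherent part follows the exact Klein–Nishina cross-section and the
photoelectric part piecewise power laws calibrated between edges.
Materials combine elements by the mixture rule on mass fractions
computed from mole fractions (`weight_fractions()`); coherent
scattering is not modelled separately, and the non-Compton remainder of
the total attenuation is treated as absorption. This is a deliberate
simplification: at these energies coherent scatter changes neither the
window fractions nor the orderings the analysis rests on.

The density of tungsten functional paper is not a settled literature
value; the packaged default is 3.4 g/cm³ (`material_tfp()`,
`tfp_density_g_cm3` in the config) and should be overridden by users
who know their sheet. Sensitivity is monotone and mild: transmission at
208.4 keV is $e^{-\mu/\rho\,\cdot\,\rho d}$ with
$\rho d = 0.41\ \mathrm{g/cm^2}$ at the default.

## The synthetic phantom and transport

The generator replaces a voxel-anatomy Monte Carlo study with a
desk-scale stand-in that keeps the features the dead-time analysis
feeds on — absolute rates, an anterior/posterior asymmetry, and a
scatter continuum under the photopeak:

* a water box (30 × 20 × 40 cm) holding a box-shaped liver placed
  anteriorly with the majority of the activity (a high tumor-burden
  scenario), a posterior spleen and two posterior ellipsoidal kidneys;
* organ percentages summing to 52 %IA at 24 h after a 7.4-GBq
  administration (the anchored patient condition); the organ-level
  split and depths are synthetic defaults, stated in
  `inst/extdata/default-config.yaml`;
* detectors facing the anterior (+y, detector 1) and posterior sides,
  with the parallel-hole collimator idealised as an angular gate of
  half-angle 3°: a photon is accepted if its direction lies within the
  gate of the face normal. No septal penetration and no
  point-spread-function modelling; the backscatter compartment behind
  the crystal is folded into the energy blur rather than modelled
  geometrically.

Transport samples a decay position proportional to organ activity, a
line energy, and an isotropic direction; free paths are exponential in
water; an interaction Compton-scatters with probability
$\mu_C/\mu_{tot}$ (Klein–Nishina angle by rejection sampling) and is
otherwise absorbed, up to `max_scatters = 2` orders — enough to build a
realistic TEW scatter tail without chasing exact voxel-study fidelity.

Detection is scored with an unbiased *next-event estimator*: at every
emission and scatter vertex the expected contribution into the
acceptance cone (cone solid-angle fraction, or the Klein–Nishina
density at the deflection angle towards the face normal, times the
water attenuation along the exit path and the filter transmission at
the outgoing energy) is tallied into the energy histogram. Analog
photons that leave the body are then discarded — the detector is a
virtual tally plane, so nothing is double-counted. Two consequences
matter for users:

* spectra are smooth at modest history counts (the default is
  2 × 10⁴ histories; the packaged tests run 6–8 × 10³);
* one transport pass tallies *all* placements and filters from the
  same decay histories, so filter and detector comparisons are exactly
  paired. `spectrum_pair()` exposes this for the two heads; a filter
  never increases any bin of a paired spectrum by construction.

## Detector model

Incident spectra are converted to per-second event streams:

* intrinsic efficiency $1 - e^{-\mu_{NaI}(E)\, d}$ for the 0.95-cm
  crystal;
* Gaussian energy blur with 9.4% FWHM at 208.4 keV, scaled as
  $E^{-1/2}$ — the statistical scintillator law; the reference point is
  a published camera value, the exponent is a modelling choice
  (configurable);
* a homogeneous Poisson stream at the detected rate, each event
  carrying a blurred energy and a primary/scatter label;
* the paralyzable rule applied at event level: an arrival is recorded
  only if the gap since the immediately preceding arrival exceeds
  $\tau$ (default 0.5 µs for the 20–400 keV full window — the full
  window is not pinned down by published camera settings, so it is a
  configurable default);
* optional pile-up: arrivals within the integration window (default
  $\tau$) of a recorded event are summed into its recorded energy.
  Pile-up defaults ON for headline runs because spectral distortion is
  what pushes the fitted $\eta$ above 1; with it off the package
  reproduces $\tau_w = \tau/wf$ exactly ($\eta = 1$), which the test
  suite asserts. How a production camera's electronics handle pile-up
  spectra is not uniquely published; the switch brackets the
  possibilities.

`record_measurement()` simulates whole seconds until the observed
main-window counts exceed 10,000 (the published stop rule), with a
`min_seconds` floor (default 5 in experiments) so that per-second
distributions exist for the significance tests the per-second protocol
implies.

## Spectroscopy choices

The main window is 208 keV ± 10% centred on the physical 208.4-keV
peak (a nominal-208 variant is provided). The "10%" TEW sub-window
width is read as 10% *of the photopeak energy* (20.84 keV), abutting
the main window; reading it as 10% of the main-window width is
selectable (`basis = "window"`) since published usage is ambiguous.
TEW scatter is the trapezoid estimate
$S = (C_L/w_L + C_U/w_U)\, w_M/2$, clamped at zero with a flag when it
exceeds the main-window counts. Sub-window counts are taken from the
observed (post-dead-time) spectrum, as a camera would; the *true*
primary reference for the loss is the loss-free unscattered main-window
count taken directly from the labelled event stream. Applying TEW to
both streams instead changes the loss denominator by the (small) TEW
bias and is easy to compute from the stored per-second tables; the
labelled reference was chosen because it makes the loss a pure
dead-time quantity.

## Estimators

* Per-second apparent dead time: the single-pair solve
  $\tau_w = \ln(R_{wt}/R_{wo})/R_{wt}$ (`solve_tau()`), matching a
  per-second protocol. A regression estimator over a rate sweep
  (`fit_tau()`, least squares of $\ln(R_{wo}/R_{wt})$ on $R_{wt}$
  through the origin) is provided for decaying-source-style data; both
  are exposed because the published per-second estimator is not spelled
  out.
* $\eta$: regression through the origin of $\ln(\tau_w/\tau)$ on
  $\ln(1/wf)$ (`fit_eta()`), which degrades gracefully to the
  closed-form single-point solve. The experiment fits $\eta$ from its
  own simulation rather than assuming it; 1.4 remains the default for
  *predictive* use of the scaling law because published window-fraction
  and dead-time pairs are most nearly consistent with it — the test
  suite recovers ≈1.39 from those published pairs.
* Inversion of the paralyzable law (`paralyzable_true()`): safeguarded
  Newton iteration converging on the physical sub-peak branch
  $R_{wt}\tau_w \le 1$; the super-peak root is never returned, observed
  rates above $1/(e\tau_w)$ raise an error, and the round-trip is exact
  to 1e-10 relative (cross-checked against an independent product-log
  implementation in the tests).

## Time course

True rates at 24 h scale with a retention curve;
the default is a synthetic mono-exponential stand-in for a
slow-excretion patient — effective half-life 80 h, anchored to 52 %IA
at 24 h — because per-patient excretion tables are not published.
Measured curves can be supplied as two-column tables. Apparent dead
times are held fixed over 24–120 h (window-fraction drift over time is
ignored), observed rates follow the forward law, and losses follow the
percent-deficit definition; `loss_ratio_summary()` averages per-filter
loss ratios over the grid. In the small-loss regime the ratio
analytically approaches $(R\tau)_{filter}/(R\tau)_{none}$, which is the
consistency check the acceptance arithmetic uses.

## Statistical comparison

Welch's unequal-variance t-test (two-sided, α = 0.05) compares each
filter against no filter per detector and per metric (window fraction,
apparent dead time, loss) across the recorded seconds; p-values are
Bonferroni-corrected within each metric family and the family size m is
recorded in the report.

## Seeds, determinism and problem sizes

One integer seed drives everything: the transport derives per-run
substreams, and each recorded second derives its own stream seed, so
`run_experiment()` is bit-reproducible for a fixed seed and
configuration. Default problem sizes — 2 × 10⁴ histories (10⁴ in the
acceptance script, 6–8 × 10³ in tests), ≥5 recorded seconds per
configuration, 2-keV histogram bins — were chosen so a full comparison
completes in seconds on one CPU while leaving Monte Carlo noise well
below the effect sizes of interest (the filter-induced changes in
window fraction are tens of standard errors at these sizes).

## What passing tests do and do not show

The generator reproduces the *structure* of a patient measurement —
line spectrum plus Compton continuum, anterior/posterior asymmetry,
absolute rates of the right magnitude, paralyzable losses, pile-up
distortion — so tests passing on it validate the dead-time
mathematics, the TEW and window logic, the estimators, and the
qualitative filter physics (orderings of window fraction, apparent
dead time and loss, and the premise that both filters favour 208.4 keV
over every lower line). It does not emulate voxel anatomy, septal
penetration, collimator scatter or the backscatter compartment, so
absolute window fractions and apparent dead times differ from
voxel-study values (the simplified geometry yields higher window
fractions, hence shorter apparent dead times) and should not be
compared number-for-number against published camera measurements.
Published reference values are packaged separately
(`lu177_reference_values()`) for arithmetic that needs them.

## Known limitations

* No imaging chain: projections, PSF and reconstruction are out of
  scope; the package reasons about rates and spectra only.
* The TFP density default is an assumption (see above).
* Energy resolution is anchored at a single published point; the
  $E^{-1/2}$ extrapolation is conventional but unvalidated off-peak.
* The retention default is synthetic; conclusions about a specific
  patient require their measured curve.
* Only the paralyzable model is implemented; non-paralyzable or hybrid
  electronics are out of scope.
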