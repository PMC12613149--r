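---
title: "Methods: ion-mobility-assisted suspect screening with timscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion-mobility-assisted suspect screening with timscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timscreen)
```

## The problem

Target and suspect screening of complex biological and environmental
matrices (urine, serum, breastmilk, dust, wastewater) by LC-HRMS suffers
from coeluting isomeric and isobaric matrix compounds: ions that share the
m/z window and retention-time window of an analyte of interest and so
produce false-positive annotations at the MS1 level, or contaminate its
MS2 spectra through the precursor isolation window. Trapped ion mobility
spectrometry (TIMS) adds a third, matrix-independent separation
coordinate: the collision cross section (CCS), derived from the measured
inverse reduced mobility 1/K0. `timscreen` implements the full desk-side
workflow around that idea -- CCS calibration, extraction, windowed
annotation with interference classification, mobility-gated MS2 matching,
and the evaluation experiments -- together with a synthetic 4D data
generator whose ground-truth ledger makes every stage testable without
instrument data.

## CCS calibration

For an ion of mass $m = z \cdot m/z$ in a drift gas of molecular mass $M$
(nitrogen, 28.0134 Da), the Mason-Schamp relation makes the collision
cross section proportional to the measured mobility through the reduced
mass $\mu = mM/(m+M)$:

$$ \Omega \;=\; C \cdot \frac{z \,(1/K_0)}{\sqrt{\mu}} , $$

where the constant $C$ absorbs temperature, pressure, number density and
the physical constants. `fit_ccs_calibration()` estimates $C$ by ordinary
least squares on calibrant ions of known CCS (for example the six
tune-mix ions with their published compendium values). Design choices:

* **Proportional form.** The default fit has a zero intercept, the
  conventional form for single-field TIMS calibration; an intercept can be
  requested for robustness (`fit_intercept = TRUE`). The choice of the
  proportional Mason-Schamp predictor (rather than a fit linear in 1/K0
  itself) is an assumption of this package and is isolated in one place.
* **No weighting.** Ordinary, unweighted least squares; residual RMS is
  reported per fit so a poor calibration is visible.
* **Electron mass.** The ion mass is taken as $z \cdot m/z$; the electron
  mass correction (~0.5 mDa per charge) is orders of magnitude below the
  calibration residuals and is ignored.
* **Mobility units.** Peak tables must carry 1/K0 directly
  (V s/cm$^2$); the vendor's scan-number-to-mobility mapping is out of
  scope.

The companion conversions `inv_k0_to_ccs()` / `ccs_to_inv_k0()` are exact
inverses of each other; the test suite checks the round trip to $10^{-9}$
relative on a thousand random ions, and that a forward-generated calibrant
set refits its constant exactly.

## Annotation windows and interference classification

A screened ion is looked up by three windows, with the package defaults
matching the established workflow values: m/z within **5 ppm**, retention
time within **+/- 0.25 min**, and CCS within **3 %** of the library value
for a true annotation. A mobilogram peak further than **5 %** from the
reference CCS is associated as a *distinct* interfering species. The
deliberate gap between 3 % and 5 % is conservative: peaks falling inside
it count toward neither a match nor an interference and are reported as
*ambiguous* evidence.

`screen()` runs, per library ion: EIC extraction in the m/z window;
chromatographic peak detection; candidate selection as the peak whose apex
is *nearest the expected RT* (not the most intense -- the workflow anchors
on RT agreement) within the RT window; EIM extraction over that peak's
integration bounds; CCS conversion; and classification by
`classify_eim_peaks()`:

| analyte match (< 3 %) | interference (> 5 %) | category |
|---|---|---|
| yes | no | `true_annotation` |
| yes | yes | `true_with_interference` |
| no | yes | `false_positive` |
| no | no, but 3-5 % band peak(s) | `ambiguous` |
| no peaks | -- | `not_detected` |

Further conventions, each chosen once where the workflow leaves them open:

* Relative CCS deviations use the **library reference CCS as the
  denominator**, signed, thresholded on the absolute value.
* Among several in-window peaks the **most intense** is the match; ties
  break on smallest deviation. The count of in-window peaks is reported
  (`n_true_window`): a value above one flags isomer clusters the mobility
  dimension cannot separate at the annotation level, as with the
  reference-mixture pair at 142.98 and 144.23 A^2 whose spacing (0.9 %)
  lies far inside the 3 % window.
* The 3 % window is applied to the **apex CCS** of each mobilogram peak,
  not a peak average.
* Blank subtraction is an optional pre-filter: an ion whose mean point
  intensity in the blank cloud exceeds the sample's is flagged and
  reported as not detected.

For building a screening database from dilution series,
`select_characteristic_peak()` implements the characteristic-peak rule:
link mobilogram peaks across concentration levels into clusters within 1 %
relative CCS, regress each cluster's summed area on concentration, and
choose the **lowest-CCS cluster with response $R^2 > 0.8$**; remaining
clusters become additional CCS values. `assess_dimer()` contrasts log-log
response slopes of a low-CCS and a high-CCS peak at the same m/z: dimer
formation during ionization is concentration dependent, so a slope near 2
against the monomer's 1 is labelled `consistent_with_dimer`.

## Extraction and peak detection

EICs and EIMs are binned traces (defaults: 0.02 min and 0.002 V s/cm$^2$,
about 500 mobility bins over a 0.45-1.45 scan range). Peak detection uses
a 3-bin moving average, local maxima above an intensity floor, 3-point
quadratic apex interpolation, bounds at the first local minimum or the
crossing below 10 % of the apex, and trapezoidal areas. Numerical
conventions worth stating:

* **Intensity floor.** Default is five times the baseline level, estimated
  as the median of nonzero bins below 1 % of the trace maximum; for a
  trace that is a single clean peak (no such bins) it falls back to 5 % of
  the maximum. Traces extracted through a 5 ppm window are extremely
  sparse, so a fixed global threshold would be meaningless.
* **Isolated-bin rejection.** A detected apex must have signal in at least
  two adjacent raw bins. A single stray background point can otherwise
  masquerade as a peak; real peaks span several scans in both dimensions.
* **No deconvolution.** Overlapping peaks are not model-fitted; the
  classification logic uses apex positions only, so apexes suffice.
* Peaks that merge in the chromatographic dimension (coeluting
  interferences) are deliberately integrated together; the mobility
  dimension then separates them in the EIM.

At resolving power 200 and the default bin widths, the apex interpolation
recovers placed CCS values with a median absolute error around 0.002 %
(noise-free) and well below 0.1 % under the default noise model -- an
order of magnitude inside the 3 % annotation window, so measurement error
never flips a classification.

## Mobility-gated MS2 matching

PASEF-style acquisition records each data-dependent MS2 event with a 1 m/z
isolation window *and* a mobility gate. `extract_ms2()` merges events
whose precursor lies within the isolation half-width and whose gate
overlaps the requested mobility interval: requesting the narrow gate
around one species of a co-isolated pair returns only that species'
fragments, which is precisely how TIMS cleans spectra of coeluting
contaminants. The test suite asserts the property form: whenever a
contaminant is co-isolated with a disjoint gate, the gated spectrum scores
strictly higher against the clean reference than the ungated one.

The spectral score is a square-root-intensity cosine with greedy
one-to-one fragment pairing (descending intensity product, 0.01 Th
tolerance):

$$ s \;=\; \frac{\left(\sum_{\text{pairs}} \sqrt{I_a I_b}\right)^2}
                {\sum I_a \cdot \sum I_b} \in [0, 1]. $$

Vendor library-search scores are proprietary, so this package uses the
standard cosine form, isolated behind one function and cross-checked in
tests against an exhaustive-pairing oracle on small spectra. Identification
confidence follows the two-level convention used in screening reports:
**level 1** (confirmed by MS2, score at or above the threshold, default
0.7) versus **level 4** (no MS2 coverage or poor matching). The 0.7
default is a design choice; `spectral_coverage()` and the score
distributions it reports make threshold sensitivity easy to scan.

## The synthetic-data generator

`scenario_config()` fixes the statistical structure of a simulated run;
`generate_library()`, `generate_peak_cloud()` and
`generate_dilution_series()` derive everything deterministically from the
seed. What it emulates, and the defaults:

* **Charge-state trendlines.** Features follow per-charge power laws
  $CCS = A\,(m/z)^B$ with multiplicative Gaussian scatter (default 4 %).
  The three charge states place singly charged features around 110-250
  A^2, doubly charged around 300-500 and triply charged around 500-700,
  the layout complex-matrix feature tables show. Analytes are singly
  charged, as screening libraries of small-molecule contaminants are.
* **Peak shapes.** Gaussian in RT (sigma 0.05 min) and mobility (FWHM =
  (1/K0)/resolving power; default resolving power 200, the conservative
  lower edge of the instrument's 200-400 range), delta-like in m/z with
  +/- 1.5 ppm per-point jitter. Centroids sit on global RT/mobility scan
  grids (0.01 min, 5e-4 V s/cm^2) at half-step offsets, emulating a fixed
  acquisition cycle; extraction bins that are integer multiples of the
  scan spacing therefore never alias.
* **Reproducibility jitter.** True analytes deviate from their library
  values by a truncated Gaussian: CCS s.d. 0.3 % (clamped at 1 %),
  matching the intra-batch CCS stability screening instruments achieve,
  and RT s.d. 0.03 min (clamped at 0.1 min).
* **Interferences.** A configurable fraction of library ions (default
  20 %) receives a matrix interference placed *inside* the m/z and RT
  annotation windows (default |dm/z| up to 2.5 ppm, co-eluting within
  0.08 min of the analyte peak when the analyte is present) but offset in
  CCS by a uniform draw from +/- [6 %, 35 %] -- strictly beyond the 5 %
  association boundary, and bracketing the observed real-world examples
  (14 %, 29 %, 32 %). The lower bound sits at 6 % rather than at the
  boundary itself so that apex-measurement error (< 0.1 %) cannot move a
  generated interference across the 5 % threshold; the generator's
  contract is that the truth ledger fully determines the correct
  classification.
* **Absent analytes.** A `missing_fraction` (default 10 %) of library
  ions is left out of the sample; their interferences, when drawn, become
  false-positive bait -- the mechanism behind the false-positive versus
  interference-to-true-annotation dichotomy.
* **Matrix features** are rejection-sampled outside the joint m/z+RT
  window of every library entry. Real matrices do collide with screening
  windows; the generator excludes that case on purpose so that exactness
  tests have a single well-defined expected outcome.
* **Dilution series** share one truth draw across concentrations
  (defaults 0.5, 1, 5, 10, 500 ng/mL); analyte areas scale linearly
  through log-normal per-compound response factors (s.d. 0.3, base
  response 1e4 counts per ng/mL), dimer-artifact areas quadratically.
* **Noise.** Uniform background points (density 0.1 per unit
  RT x mobility x Th volume, exponential intensities) plus 5 %
  multiplicative intensity jitter per centroid. A 5 ppm m/z window makes
  noise essentially invisible to screening; it exists to keep the
  extraction stage honest.
* **MS2 events.** Eligible precursors yield an event with probability
  0.9, gated at +/- 1.5 FWHM around the precursor's mobility. With the
  configured contamination rate an event also carries fragments of a
  co-isolated neighbour (same isolation window, overlapping gate) or, when
  none exists, of an unresolved isobaric background species at a
  configurable relative intensity. Fragment m/z values are reproducible
  draws keyed to the compound identity -- stand-ins for real fragmentation
  chemistry, adequate for testing matching logic but not for spectral
  realism.

What passing tests on this generator do **not** show: real matrices
violate several of these idealisations (peak tailing, detector
saturation, isotope patterns, correlated noise, window-straddling
features, retention-time drift). Results on synthetic scenarios validate
the *logic* of the workflow -- window arithmetic, classification,
gating -- not its field performance on instrument data.

## Evaluation experiments

`rt_window_sensitivity()` re-screens with the RT window scaled by given
factors (the suspect-screening situation where predicted retention times
force wider windows); false-positive counts are non-decreasing in the
factor, and on synthetic data the widened window captures exactly the
ledger-known far-shifted interferences. `spectral_coverage()` reports the
percentage of matched annotations reaching level 1 -- the denominator is
annotations with a matched peak (per-ion, not per-compound), false
positives excluded. `fit_trendlines()` fits the per-charge power laws by
log-log least squares (charges with fewer than three features are skipped
with a notice). `align_features()` counts features shared between samples
by greedy one-to-one nearest-neighbour matching in ascending m/z within
joint m/z, RT and CCS tolerances. `prediction_accuracy()` reports
R-squared as the squared Pearson correlation -- the convention in CCS/RT
prediction comparisons -- alongside the 1 - SSE/SST form when they
differ, plus RMSE and MAE in input units.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on generated
data at desk scale: scenarios of 5-100 analytes (100-scenario exactness
sweeps, a 400-analyte coverage scenario, a 769-analyte library-generation
scale check), chosen to exercise every code path in minutes on a single
core. All randomness flows from explicit seeds; identical seed and
configuration give byte-identical libraries, clouds and ledgers, and the
per-compound MS2 spectra are keyed to compound identity so they survive
re-generation.

## Known limitations

* The calibration's proportional Mason-Schamp form is asserted, not
  derived from instrument physics; instruments whose calibration is
  genuinely nonlinear in the predictor need the intercept form or an
  external calibration.
* Overlapping mobilogram peaks closer than about two FWHM merge into one
  apex; the classifier then sees a single peak at an intermediate CCS.
  Real deconvolution is out of scope.
* The synthetic fragmentation model carries no chemistry; spectral scores
  on synthetic data are meaningful only relative to one another.
* Isotope-pattern evidence, structure elucidation of interferences, and
  vendor raw-file access are outside the package's scope.
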