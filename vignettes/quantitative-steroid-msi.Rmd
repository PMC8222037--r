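---
title: "Quantitative MALDI-MSI of Girard-derivatized corticosteroids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MALDI-MSI of Girard-derivatized corticosteroids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steroidMSI)
```

## The problem

Corticosteroids such as budesonide ionize poorly under soft ionization:
they are hard to protonate and are suppressed by the abundant
phospholipids of lung tissue. On-tissue chemical derivatization with
Girard's reagent P condenses the C3 ketone with the reagent's hydrazide,
losing one water and leaving a permanently charged pyridinium hydrazone
that MALDI detects readily. This package implements the downstream
quantitative imaging workflow for such experiments: given centroided
imzML data of a slide carrying a lung section and homogenate control
sections with an on-tissue dilution series, it extracts the relevant ion
images, finds the tissue and the calibration spots, normalizes the
analyte against a co-sprayed internal standard, fits calibration lines
per lipid level, tests whether lipid content distorts them (ion
suppression), and back-calculates tissue amounts.

## Mass arithmetic

Target m/z values are computed from elemental compositions with
monoisotopic atomic masses, never typed in:

* Girard-P hydrazone cation: `steroid + C7H10N3O (cation) - H2O - e^-`.
  The product is a pre-charged cation; no proton is added, because the
  quaternary pyridinium nitrogen carries the charge. Vendor software and
  the MSI literature conventionally label these ions "[M + H]+"; the
  package keeps that label as an alias but does the pre-charged
  arithmetic, which is what matches observed values.
* Heme B is modeled as a radical cation (M - e^-), ferulic acid as a
  protonated molecule (M + proton).
* The electron mass is always included: at Orbitrap accuracy (sub-mDa) it
  matters.

```{r}
defaultTargets()
```

One numerical subtlety: the conventional ferulic-acid lock-mass value
195.0657 corresponds to adding a neutral hydrogen atom rather than a
proton; the protonated value is 195.0652. The 0.5 mDa difference is far
inside the 5 mDa extraction window and we leave the convention as an
observation rather than resolving it.

## Ion images

`extractIonImage()` uses a symmetric, *closed* window
`|mz - target| <= tolerance` (default 0.005 Da, matching the extraction
tolerance of high-resolution Orbitrap MSI practice). Centroids on the
exact boundary are included; this is documented and tested. Within the
window, centroid intensities are **summed** by default: summing is
robust against centroid splitting by the peak picker. `max` aggregation
is available for users who prefer it; nothing downstream depends on the
choice at the default window width.

Missing is not zero: a pixel of the bounding box that was never scanned
becomes `NA`, while a scanned pixel with no centroid in the window
becomes 0. The log10 transform (used for segmentation and thresholding,
matching how count-like MSI intensities are usually handled) sends zeros
to `NA` flagged "below detection" rather than inventing a pseudo-count;
ratios are always computed on the linear scale, so no pseudo-count is
ever needed.

Lock-mass recalibration is off by default (Orbitrap acquisitions apply
it on-line). When enabled, the default mode is multiplicative: all m/z
of a pixel are scaled by `lock/observed`, which removes a uniform
*relative* (ppm) drift at every mass. An additive constant-shift mode is
provided, but note that a constant shift anchored at m/z 195 cannot
correct a ppm drift at m/z 564 - the ppm mode is the scientifically
sensible default for Orbitrap-type drift.

## Segmentation

Tissue sections are found on the log10 heme B image: Otsu's threshold
computed on the histogram (256 bins) of non-missing pixels, a 3x3 binary
closing, 8-connected component labeling, and an area filter. Otsu on
well-separated classes has a plateau of equivalent thresholds across the
empty histogram gap; we take the plateau midpoint, the conventional and
most robust cut. Labels are ordered row-major by integer-rounded
centroid (ties broken by decreasing area) so that label identity is
reproducible.

Calibration spots are found on the log10 tiotropium image with a fixed
threshold, 5.6 by default. The threshold is interpreted on the log10
scale because all signals are log10-transformed before analysis in this
workflow; it is a configuration value, not a constant. Detected spots
are matched to the calibration design by nearest expected position; the
matching must be bijective, and ambiguities or missing spots are
reported as errors naming the design cells involved, replacing manual
annotation with a deterministic, auditable rule.

## Calibration model and ion-suppression tests

The calibration response is the per-spot **median** of the pixel-wise
analyte/IS ratio against the deposited amount (ng = concentration x
500 nL drop volume), on the linear scale. The median commutes with
monotone transforms, so summarizing linear-scale ratios by medians is
rank-equivalent to subtracting log signals; the IQR accompanies it as
the spread measure.

The model is ordinary least squares with lipid level as a categorical
covariate and its interaction with amount:

```
median_ratio ~ amount * factor(lipid_level)
```

Lipid level is categorical because the experimental design has three
discrete levels (0, 4, 8 mg/g poractant alfa); a continuous covariate
would impose a linearity assumption the design cannot check.

Two effects are tested at alpha = 0.05: the lipid main effect
(intercepts) and the lipid x amount interaction (slopes). Because pixel
noise is multiplicative, the residual spread of spot medians grows with
the mean, and the classical F test is anticonservative in this design
(empirical size of roughly 0.10-0.13 at nominal 0.05 in our design
simulations). The default test therefore studentizes the effect with an
HC3 sandwich covariance and calibrates it with a null-imposed wild
(Rademacher) bootstrap (B = 299 by default), which restored nominal size
(about 0.05) at full power in the same simulations. The classical F test
remains available via `testMethod = "classical"`. Noise-free inputs are
handled deterministically: when a null model already fits exactly the
p-value is 1, and when only the alternative does it is 0, instead of
returning an unstable 0/0 F ratio. Point estimates, per-level
intercept/slope tables, and R^2 come from the plain OLS fit; weighted
regression is deliberately out of scope.

Inverse prediction is `(ratio - intercept)/slope` with a first-order
delta-method interval from the (HC3) coefficient covariance. Ratios
below the intercept yield 0 with a `below_calibration` flag rather than
a negative amount.

## The synthetic slide generator

No public data accompany this workflow, so the package generates
centroided imzML slides with the study's structure and full ground
truth. The generator emulates:

* one elliptical "lung" section plus two rectangular spiked control
  homogenate sections (2.5 and 10 ng) per distribution slide;
* calibration slides with one homogenate section per lipid level
  (0/4/8 mg/g) carrying a 5 x 4 grid of 500 nL spots at 0.2, 2, 5, 20,
  40 ng/uL (amounts 0.1-20 ng), radius 3 px at a 400 um raster;
* a uniformly sprayed internal-standard channel, heme B confined to
  tissue, tiotropium confined to spots, a ferulic-acid matrix peak
  everywhere, a small chemical-background centroid inside every
  extraction window, and uniform random background peaks;
* per-pixel, per-channel independent multiplicative lognormal noise
  (sdlog 0.10 by default) and 2 ppm m/z jitter - the pixel-to-pixel
  variability that IS normalization exists to cancel (a correlated-noise
  option makes the cancellation exact, so that property is directly
  testable);
* a response `ratio = intercept + slope x amount` with intercept 1.0,
  slope 0.05 per ng, and a configurable additive intercept shift of
  +10% of the intercept at 8 mg/g (+5% at 4 mg/g) with no slope change -
  the ion-suppression pattern the pipeline must detect. Both shifts are
  free parameters, so the "slope affected" alternative is equally
  testable.

Unspiked tissue emits no structured analyte peak - only chemical
background - so an untreated section reads as below-calibration, and
treated versus untreated sections are separated by more than three
orders of magnitude in the raw analyte channel.

The response and noise defaults were fixed once by a design-time power
analysis: with 5 amounts x 4 replicates x 3 lipid levels and 29-pixel
spots, sdlog 0.10 noise gives the wild-bootstrap intercept test
near-unit power for the configured 10% shift while the slope test stays
at nominal size, consistent with a study design in which such an effect
was detectable. Seeds fix all randomness: identical spec + seed gives
byte-identical imzML payloads (the writer derives the file UUID from the
payload checksum).

What the generator does **not** emulate: desorption/ionization physics,
isotope envelopes, profile spectra, chromatographic-like spot edge
effects (spots are uniform discs by default), spatial noise correlation,
and matrix clusters. Passing tests therefore demonstrate the correctness
and statistical calibration of the *pipeline*, not instrument-level
realism of the data.

## imzML I/O

Both imzML 1.1 binary layouts are supported: continuous (one shared m/z
axis) and processed (per-pixel axes). m/z arrays are written as 64-bit
floats by default and intensities as 32-bit (the usual centroid export),
both switchable to 64-bit, where the write-read round trip is exactly
the identity. The reader verifies the 16-byte ibd UUID against the XML
declaration and the ibd MD5 checksum when present, refuses profile-mode
data, and rejects non-ascending m/z arrays instead of silently
reordering them. Coordinates follow the imzML convention (1-based, x =
column, y = row); every image matrix is indexed [row, col] with the
mapping documented on the classes, which is the guard against the
classic transposition bug. Files written by the package are readable by
the independent pyimzML parser (exercised in the test suite).

## Pipeline and reproducibility

`runPipeline()` drives simulate -> extract -> segment -> normalize ->
calibrate -> quantify from one validated config (YAML or list); every
stage logs one line with its parameters, and a manifest records the
config echo and an MD5 checksum of every output. Rerunning with the same
config and seed reproduces all outputs byte-for-byte; the calibration
bootstrap is seeded from the config seed.

## Problem sizes and numerical choices

The test-suite and acceptance problem sizes are chosen to exercise the
full path at meaningful statistical resolution: 200 Monte-Carlo slides
(about 5800 pixels each) for the calibration recovery study, 20 seeds
for geometry recovery, and 1000 random grids for the extraction oracle
check. Key numerical decisions, collected: closed extraction window;
sum aggregation; Otsu plateau midpoint; 8-connectivity; ROI ordering
row-major by rounded centroid then by area; exact-fit guards at relative
RSS 1e-16; amounts below the intercept clamped to 0 with a flag; unit
density (1 g/mL) in the w/w spiking arithmetic.

## Limitations

* The calibration transfers a spot-deposition response to embedded
  tissue analyte; like the on-tissue calibration it models, this assumes
  comparable extraction/derivatization efficiency - a systematic
  uncertainty no slide-internal statistic can remove.
* LOD/LOQ formalism and weighted regression are out of scope.
* Segmentation assumes marker channels separate cleanly from background;
  touching spots are not watershed-split (the design keeps spots apart).
* The effect tests are calibrated for the generator's noise family;
  grossly different error structures may need `testMethod = "classical"`
  plus diagnostics, or larger B.
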