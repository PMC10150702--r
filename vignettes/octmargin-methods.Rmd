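---
title: "Methods: residual tumor detection from intraoperative OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual tumor detection from intraoperative OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During brain-tumor surgery the surgeon must decide, at the resection
margin, whether infiltrated tissue remains. Optical coherence tomography
(OCT) images the margin contactlessly to a depth of a few hundred
micrometers, and tumor infiltration changes how strongly white matter
scatters and attenuates light: myelin degradation lowers both the
attenuation coefficient and the backscattered intensity, and emerging
microstructure (cysts, calcifications, vessel proliferation) disturbs the
signal's homogeneity. `octmargin` implements the full analysis chain that
turns raw OCT volumes into residual-tumor calls — and, because clinical
in vivo volumes of this kind are not publicly available, it pairs the
chain with a physics-based synthetic cohort generator so that every stage
is testable end to end.

## Forward model and synthetic cohorts

Each A-scan follows the single-scattering model

\[ A^2(z) = I\,e^{-2\mu z}, \]

with attenuation coefficient \(\mu\) (mm\(^{-1}\)) and peak backscattered
intensity \(I\); the simulator multiplies this by the system's roll-off
and focus sensitivity profiles, adds an additive detection noise floor,
and applies fully developed speckle as multiplicative unit-mean
exponential intensity noise. Speckle statistics are not stated by typical
clinical reports; the exponential intensity model is the standard choice
for coherent imaging and is what our tests assume when they check that
speckle averages out.

Tissue classes are the six histology labels (GM0, WM0, WM0–30, WM30–60,
WM>60, WME). Only *relative* attenuation differences at 830 nm are
anchored to reported comparisons — gray matter 56% below healthy white
matter, edematous white matter about 40% below — while the absolute
healthy-white-matter value is configuration (`wm0_mu`, default
6.0 mm\(^{-1}\)): published absolute values come from 1300 nm systems
(about 3.5 mm\(^{-1}\) for infiltrated tissue) and scattering grows toward
shorter wavelengths, so no absolute value at 830 nm can be taken from the
literature directly. Peak intensities span the 40–70 dB display range that
separates the "deep blue" from the "deep red" archetype. All class
parameters decrease with infiltration grade.

Heterogeneity — the texture that distinguishes homogeneous healthy white
matter from disturbed infiltrated tissue — enters as spatially coherent
log-intensity fields, split between a lateral amplitude field (shared
across the B-scans of a scan; this is what an en-face view shows) and a
2-D lateral-by-depth texture field (this is what curves individual A-scan
decays and lowers the fit's determination coefficient). A pixel-iid
formulation would be wrong twice over: it would average away laterally,
and it would leave log-averaged profiles perfectly linear, making \(r^2\)
blind to heterogeneity.

Surface topography is Gaussian per-column jitter
(`surface_roughness_um`); microstructures are Poisson-placed shadow
columns attenuated below a random depth, emulating the signal shadowing
that cysts, calcifications and hypervascularization cast. Artifact
injection mirrors the two failure modes seen intraoperatively: fold-over
(bright signal wrapped into the shallowest rows, as when tissue crosses
the zero-delay line) and dropout (a contiguous block of columns at the
noise floor). Dropout is deliberately contiguous: isolated dead columns
would be bridged by the 5-column median smoothing of surface detection
and would model a different, milder defect.

The default cohort reproduces the study structure: 21 patients, 5 scans
per patient, subvolumes of 40 B-scans, and an artifact fraction of 0.6 —
the fraction of gathered scans that quality screening discarded. A
`tumor_surface_scan` flag adds one tumor-surface scan per patient; the
printed total of 108 scans does not resolve exactly into per-patient
counts, so both knobs are exposed and the default keeps 5 scans/patient.
The axial pixel pitch defaults to 4 µm/pixel (no pitch is printed; this
makes a 56-pixel patch span ~224 µm, a plausible near-surface footprint),
and the refractive index used to convert pixel depth to physical depth is
a configuration scalar defaulting to 1 (resolutions are quoted in air).

What the generator does **not** emulate: multiple scattering and
depth-dependent beam geometry beyond the focus profile, real speckle
correlation lengths, arachnoid-mater misdetection over cortex, motion
between B-scans, and the manual white-light/en-face ROI matching of the
clinical workflow (ground-truth ROI coordinates stand in). Passing tests
on synthetic cohorts therefore demonstrate the *internal* correctness and
statistical behavior of the chain, not clinical accuracy on real tissue.

## Preprocessing

All computation happens on linear intensity; storage and display use
dB = 10·log10(linear). Indices are 0-based in depth with half-open
windows; depth increases away from the objective.

1. **Sensitivity compensation** divides the linear signal per depth pixel
   by roll-off × focus. The additive detection floor is *not* subject to
   the system sensitivity, so dividing it along with the signal amplifies
   it at depth. The chain therefore tracks the compensated floor profile
   and removes it later, on patch-averaged profiles (see below), rather
   than clamping per pixel — per-pixel subtraction before lateral
   averaging introduces a Jensen-type bias that we measured at several
   percent of \(\mu\) for low-SNR classes.
2. **Surface detection** takes the first depth pixel whose 5-column
   median-smoothed intensity exceeds the noise floor by 6 dB (no
   algorithm is prescribed by the source workflow; this is the simplest
   robust choice). Columns that never cross are marked missing.
3. **Surface normalization** shifts each A-scan so its surface sits at
   row 0, pads vacated deep rows with the floor, and flags missing-surface
   columns invalid. Because detection is laterally smoothed, re-detection
   after flattening is flat only to the smoother's resolution (a few
   pixels) on rough surfaces, and exactly flat on laterally constant ones
   — the tests check both.
4. **Quality control** flags fold-over when too many columns have their
   detected surface in the shallowest rows, and dropout when too many
   columns have no detectable surface. Thresholds (10% and 20%) are pure
   configuration.
5. **Patch extraction** tiles flattened B-scans at the surface into
   144 × 56-pixel patches (the published footprint), keeping patches with
   no invalid columns and at least 60% of pixels above the floor.

## Optical-property extraction

Patches are averaged laterally in linear units to one A-scan, the
compensated floor profile is subtracted, and the natural logarithm is
taken, making the model the straight line \(\ln I - 2\mu z\). The fit
window is 300 µm long and starts 20 µm after the measured intensity
maximum; the start rounds up to the next sample, the window holds
⌊300/pitch⌋ samples, and ties in the maximum take the shallowest sample.
Ordinary least squares gives \(\mu = -b/2\) and \(I = e^{a}\), and fit
quality is \(r^2 = 1 - \sum(y_i - f_i)^2 / \sum(y_i - \bar y)^2\), used
downstream as the homogeneity proxy. A zero-variance window yields
\(\mu = 0\), \(I = e^{\bar y}\) and an undefined \(r^2\) flag.

One geometric consequence of the 4 µm default pitch: a 56-pixel axial
patch spans 224 µm and cannot host a 20 µm + 300 µm window. The package
therefore counts patches at the published 144 × 56 footprint but fits an
axially extended 144 × 112 patch (448 µm) at the same location; the extra
depth also absorbs the speckle-driven wander of the profile maximum.
"Logarithmized" is taken as the natural log of linear intensity so that
the model is exactly linear and \(\mu\) comes out in mm\(^{-1}\).

Group statistics follow the stated protocol: Shapiro–Wilk normality per
class and pairwise Wilcoxon tests with stars at 0.05/0.01/0.001 (a
p-value of exactly 0.05 earns no star). The source protocol names the
signed-rank variant for what are apparently unpaired tissue groups with
no stated pairing unit; the package uses the unpaired rank-sum variant,
which is the test that matches the data structure.

## The visual classifier

Five qualitative criteria are graded per subvolume: signal intensity
(high/low), homogeneity, penetration depth (high when signal depth
exceeds 500 µm), uniformity of penetration, and microstructures
(shadowing). Intensity is the major criterion — high intensity means
myelinated white matter, full stop. Among low-intensity scans, the
all-benign combination is "rather not tumorous", one specific combination
(homogeneous, deep, uniform, no microstructures) is "rather tumorous /
gray matter", the all-malignant combination is "tumorous", and the
remaining 13 combinations are "rather tumorous". The classifier is a
total function on its 32-point domain, and its enumeration
(16/1/1/1/13) is frozen in the tests.

For end-to-end testing an automated grading surrogate maps measurements
to criteria: near-surface mean intensity against 55 dB (midpoint of the
70/40 dB archetypes), median column penetration against 500 µm, the sd of
log en-face tile intensity against 0.15 (a coefficient-of-variation
scale), the sd of per-column penetration against 100 µm, and detected
shadow columns (4 dB below the column median at mid-depth). All
thresholds are configuration; the surrogate makes no claim of
reproducing human perception. Binarization maps "white matter" and
"rather not tumorous" to non-tumor and the rest to tumor; whether the
gray-matter class counts as tumor follows its "rather tumorous" prefix
and is exposed as configuration. Inter-observer concordance is
cross-tabulation plus Cohen's kappa (undefined when both observers use a
single identical class).

## Classification tasks and evaluation

Task I uses all six labels (healthy gray and white matter
non-pathological, everything else pathological — whether edema is
pathological is configurable, default yes); task II restricts to white
matter, healthy vs any infiltration; task III keeps only healthy white
matter and >60% infiltration. Evaluation is leave-one-patient-out: a
linear-kernel SVM with regularization cost 0.1 per fold, features
standardized with training-fold statistics (recorded in the report),
folds with single-class training data skipped with a warning. Overall
performance is the mean per-fold sensitivity and specificity — not the
pooled confusion — with balanced accuracy the mean of those two means,
and reported percentages rounded half away from zero. Diagnostic
arithmetic (sensitivity, specificity, accuracy, balanced accuracy) is
exact rational computation before rounding.

The network protocols are implemented at the same protocol fidelity —
mini-batches of 32 patches, z-scored patches, leave-one-patient-out or a
seeded 30% random split, 100 epochs as the faithful default — around
compact dense feed-forward networks (average-pooling front end,
configurable layer widths, mini-batch SGD) and a mirror-symmetric dense
autoencoder whose encoder output, standardized with training statistics,
feeds the classifier. The original architectures are not published, so
architecture is data-driven configuration, not code; the tests train
small networks for 10–25 epochs on constructed separable classes, which
checks the protocol, not any claim about real-data accuracy.

## Numerical choices and problem sizes

* dB ↔ linear: dB = 10·log10(linear), everywhere.
* Window endpoints: start rounded up, length ⌊300 µm/pitch⌋ samples,
  half-open; argmax ties take the shallowest sample.
* Degenerate inputs: zero-variance fit windows flag \(r^2\) undefined;
  zero-variance patches refuse z-scoring; empty en-face bands, empty ROIs
  and mismatched profile lengths are errors.
* SGD learning rates: 0.2 for the bounded-output classifiers and 0.02 for
  the autoencoder regression, which diverges at the classifier rate.
* Tests and the acceptance script use desk-scale sizes chosen for a
  laptop run: 200 speckled patches per class for recovery studies, the
  full 21-patient default cohort (about 4,200 B-scans simulated, 840
  patches fitted) for the end-to-end properties, and 10–25-epoch network
  runs. These sizes are the package's reproducibility conditions, stated
  here so they can be scaled up knowingly.

## Known limitations

The synthetic generator's realism bounds what green tests mean: class
separations are set by configuration, so absolute synthetic accuracies
(task II near 100%) exceed what the clinical study reports, and only
*relative* structure — task II easier than task I, gray matter confusable
with infiltration, \(r^2\) falling with heterogeneity — carries over.
Attenuation fitting assumes a single exponential within the window; no
depth-resolved or multi-layer model is provided. The visual-criteria
surrogate is a measurement stand-in for human grading. Real-data use of
the chain requires volumes in the package's TIFF + JSON format with an
ROI from configuration in place of the simulator's ground-truth ROI.
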