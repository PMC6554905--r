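---
title: "Models and methods behind grasshsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grasshsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grasshsi)
```

`grasshsi` implements a complete chemometric pipeline for predicting
forage-quality attributes of perennial ryegrass from line-scan
hyperspectral images (235 bands, 550–1700 nm), together with a synthetic
scene generator that stands in for plant data. This vignette explains the
models, the tunable parameters and the design choices, in the order the
pipeline runs them.

## Radiometric calibration

Raw irradiance counts are converted to reflectance with the standard
white/dark correction

$$R = \frac{I - D}{W - D},$$

where $W$ and $D$ are reference frames acquired from a Spectralon tile and
with the lens cap on. Because the instrument is a line scanner, references
are stored per (sample, band) and broadcast along the line axis; scalar or
full-cube references are also accepted. Two deliberate choices:

* **Reflectance is not clipped to [0, 1].** Bright, specular pseudostem
  tissue can legitimately exceed the white tile's reflectance, and clipping
  would destroy exactly the tissue contrast the pseudostem/blade analyses
  rely on.
* **Pixels with $W - D \le 0$ are flagged, not dropped.** Calibration is
  undefined there; they are recorded in `invalid_mask`, excluded from
  segmentation and every downstream statistic, and carry the placeholder
  value 0 so arrays stay finite.

Calibration is invariant to any common positive gain and offset applied to
$I$, $W$ and $D$ — a property the test suite asserts directly.

## Segmentation and plant spectra

Plant pixels are those with reflectance at least 0.3 at the band nearest
1080 nm, a wavelength chosen because it is little affected by water
content. Both thresholds are inclusive and configurable. Plant-level
spectra are the per-band arithmetic means over the mask, averaged
(unweighted) over the 2–3 replicate acquisitions of a plant. Plants whose
replicate-average pixel count falls below a threshold (5000 pixels on the
full 400×320 frame) are flagged excluded rather than erroring: a tiny
region of interest signals a failed acquisition, not a broken pipeline.
At reduced scene sizes the threshold scales with frame area so the rule
bites at the same relative plant size.

## SNV preprocessing

The standard normal variate transform standardizes each spectrum to mean 0
and unit sample standard deviation ($n-1$ denominator; the choice of
denominator only rescales all spectra by a common factor, which the
regression absorbs — the tests pin $n-1$). Since a per-pixel
multiplicative lighting gradient together with an offset is exactly an
affine transform of the spectrum, SNV removes it; this is what makes both
the plant-level models and the per-pixel maps indifferent to the
illumination ramp of the rig. Restricted-range models (550–900 nm,
900–1700 nm) recompute SNV on the restricted band set rather than
inheriting full-spectrum statistics. Constant spectra have no SNV image;
at plant level that is an error, at pixel level such (saturated or flat)
pixels are masked.

## PLS regression

The core regressor is single-response PLS fitted by NIPALS with deflation
of X only. X is mean-centered (autoscaling is off by default because SNV
already puts bands on a common scale); y is centered. Components are
extracted until the requested count or until the residual X carries no
covariance with y, in which case the model truncates and records a
warning. The collapsed regression vector $B = W(P'W)^{-1}q$ reproduces the
component-by-component predictions to $10^{-8}$, successive score vectors
are orthogonal to the same tolerance, and with as many components as the
data rank PLS equals ordinary least squares — all three are standing
invariants of the test suite, and the coefficient path is additionally
cross-checked against an independent PLS implementation (mixOmics) in one
test.

R² is reported as the squared Pearson correlation between observed and
predicted values, the convention that pairs naturally with the separately
reported validation regression $y_{measured} = a + b\,y_{predicted}$
(slope, intercept, their standard errors) and bias
$\mathrm{mean}(\hat y - y)$; the coefficient-of-determination variant is
available as a switch in `model_report()`.

## Latent-variable selection

The LV count is chosen on the calibration set by Monte Carlo
cross-validation: for each replicate a fresh random 10-fold partition,
one PLS decomposition per training fold, held-out squared errors pooled
over folds and replicates into a per-LV mean squared error curve
(pooled as MSE, then rooted where an RMSE is displayed — pooling fold
RMSEs would bias the curve). The default grid is 1–50 LVs with 100
replicates; the desk-scale study uses 20 replicates, which leaves the
selected LV unchanged on this data while keeping runtimes comfortable.

The Adjusted Wold criterion walks the curve and stops at the first $k$
with $\mathrm{press}(k+1)/\mathrm{press}(k) \ge \theta$, with thresholds
$\theta = 1$ (first non-improvement) and $\theta = 0.99$ (each extra
component must buy at least 1% error reduction; provably never selects
more LVs than $\theta = 1$). One numerical guard: on noise-free low-rank
data the curve collapses to machine zero, where the ratio is meaningless;
a press value below $10^{-12} \cdot \mathrm{press}(1)$ is treated as
converged and that $k$ is selected. A known property of the
first-non-improvement rule is that it under-selects on curves with an
early plateau — attributes whose spectral signal is weak relative to the
variance contributed by stronger attributes can stall at 1 LV; the 0.99
threshold and the full curve are available when that matters.

## Wavelength selection

**CARS** (competitive adaptive reweighted sampling) runs 50 Monte Carlo
iterations; each fits PLS to a random 80% of calibration plants, ranks
surviving bands by absolute regression coefficient, applies an enforced
exponential retention schedule $r_i = a e^{-ki}$ calibrated so that
$r_1 = 1$ (keep everything) and $r_{50} = 2/p$ (keep two bands), then
resamples the retained set with probability proportional to coefficient
magnitude. Each iteration's subset is scored by 5-fold CV RMSE on the full
calibration set and the best subset wins. When the coefficient
distribution is so skewed that resampling would collapse below two unique
bands, the enforced-retention set is kept for that iteration instead.

**VIP** selection keeps bands with variable-importance-in-projection score
at least 1. VIP is defined so the mean of its squares is exactly 1 —
an algebraic identity asserted for every model in the test suite — so the
threshold selects above-average bands. Contiguous selections are reported
as nm ranges.

## The method-comparison harness

`run_method()` runs eleven regressors behind one interface. The four PLSR
variants use this package's core; the generic learners delegate to
standard implementations (kernlab Gaussian process, e1071 SVM,
randomForest, `lm`, glmnet lasso, MASS `rlm`), each at fixed default
hyperparameters — per-method tuning is deliberately out of scope. The
MLR family (MLR, stepwise, robust) cannot invert a 235-band design with
~130 samples, so those methods operate on every-5th-band subsampled
spectra (thinned further if still wider than $n-2$); stepwise selection is
forward–backward on coefficient p-values with entry/exit thresholds
0.05/0.10. On exactly-linear noise-free data the linear-family methods
recover the response to R² ≥ 0.99 by construction; kernel and tree
learners at fixed defaults plateau around 0.85–0.95 on the same data
(an RBF kernel or a piecewise-constant forest only approximates a plane),
which the tests assert at an honest 0.8 bound rather than pretending
otherwise.

## Per-pixel trait maps

A plant-level calibration is applied at pixel scale by preprocessing each
pixel spectrum exactly as the calibration spectra (SNV, any range
restriction or band subsampling) and pushing it through the model.
Background pixels (below the segmentation threshold) and pixels whose mean
reflectance is below 0.05 are masked white. Because SNV is applied per
pixel, maps are invariant to the multiplicative lighting ramp — verified
by generating the same scene with the gradient on and off. Applying a
plant-mean calibration to individual pixels is a calibration transfer;
single-pixel predictions inherit its bias, while zone averages (the
quantity the analyses use) are well behaved. False-colour renderings use
558/740/937 nm, min–max scaled per channel with a zero-range channel
mapping to 0.

## Tissue contrasts and classification

Pseudostem/blade contrasts are paired: both tissues come from the same
plants, so the test is a paired two-sided t-test on within-plant
differences. The signed convention is fixed as BL − PS (positive for
nitrogen, negative for the sugars) with magnitudes reported alongside.
The relative partitioning of low- versus high-molecular-weight sugars is
the ratio of blade/pseudostem concentration ratios, invariant to common
rescaling. Crude protein is total nitrogen × 6.25.

Tissue classification projects every-2nd-wavelength SNV spectra (117
bands) onto canonical variates of the between/within scatter problem
$W^{-1}B$; with more bands than samples the within matrix is
ridge-regularized by $\lambda\,\mathrm{tr}(W)/p$ with $\lambda = 10^{-6}$,
raised automatically until invertible. Wilks' lambda
$\prod_a (1+\phi_a)^{-1}$ summarizes separation. Canonical scores are
invariant (up to sign) to common affine transforms of the spectra.

## The synthetic scene generator

The generator exists so every stage above is testable end to end without
plant data. It emulates, by construction:

* **Attribute distributions.** Population mean/SD/min/max for the 13
  attributes follow the published validation-set summaries of the combined
  blades+pseudostems dataset. Because clipping a normal draw to
  [min, max] shrinks its spread (severely so for the wide
  high-molecular-weight sugar distribution), the generator first solves
  for latent censored-normal parameters whose *clipped* distribution has
  exactly the target mean and SD (closed-form censored moments,
  Nelder–Mead on latent mean and log-SD). Whole-plant values are the
  tissue-fraction-weighted mean of PS and BL values; tissue values are
  clipped to the range shifted by that tissue's mean offset.
* **Tissue structure.** Within a plant, PS and BL values are bivariate
  normal with correlation $\sqrt{R^2}$ and a mean offset per attribute
  (nitrogen 1.1% higher in blades, sugars strongly concentrated in
  pseudostems, couplings 0.50–0.89 for the attributes with reported
  tissue-resolved data); tissue SDs carry a common inflation factor chosen
  so the whole-plant SD equals the spec SD exactly.
* **Spectra.** Tissue baselines have low visible reflectance, a red-edge
  rise to a NIR plateau and water dips at 1000/1200/1450 nm; the
  pseudostem baseline sits higher at 800–1100 nm and lower at
  1200–1500 nm than the blade baseline. Attribute concentrations attenuate
  the baseline through Gaussian absorption features via a Beer–Lambert
  exponential, $R = b(\lambda)\exp(-\sum_f a_f c\, G_f(\lambda))$ — smooth,
  monotone in concentration (deepening a feature can only lower
  reflectance at its center, a tested invariant) and invertible. Feature
  centers for nitrogen and sugars sit inside the wavelength regions that
  drive their prediction (≈560, 640–750, 890, 935, 1350–1460,
  1510–1700 nm). Amplitudes are not published anywhere; they were chosen
  once so that absorption depths at mean concentrations are a plausible
  0.05–0.3 optical-depth scale. A `linear` encoding variant
  ($R = b(1 - \sum a_f c G_f)$) makes spectra exactly affine in
  concentrations, used for closed-loop identity tests where PLS must
  recover the response to machine precision.
* **Scene structure.** The foreground is an elliptical blob covering
  exactly `round(plant_fraction × pixels)` pixels (rank thresholding of a
  radial field, deterministic); blob size is tied to the plant's
  visual-yield value so ROI pixel count is an informative predictor of
  yield. A multiplicative linear ramp along the line axis emulates the
  single-beam illumination falloff (default ±10% edge to edge); additive
  Gaussian sensor noise (default SD 0.01 reflectance) is applied per pixel
  and band. Background reflectance is flat 0.08, safely below the 0.3
  segmentation threshold. Raw irradiance is reconstructed as
  $I = R(W - D) + D$ from a flat white frame and a noisy positive dark
  frame, so calibration inverts the forward model exactly.

Identical seeds give bit-identical tables and cubes throughout.

### What the generator does *not* emulate

Passing the recovery tests shows the pipeline is correct, not that the
real-data accuracies are reproducible. The generator's spectra are exactly
(log-)linear in concentrations with independent Gaussian noise; real
forage spectra carry canopy geometry, shading, specularity, water-band
saturation and wet-chemistry measurement error, none of which are modelled.
Consequently the synthetic validation R² for nitrogen and sugars is near
1 rather than the 0.5–0.7 seen on real plants, and the end-to-end checks
are parameter-recovery tests, not accuracy claims. Diurnal sugar dynamics,
leaf geometry and radiative canopy transfer are out of scope;
concentrations are static per plant.

## Desk-scale study sizes

The default study simulates 185 plants (15 with separate pseudostem and
blade acquisitions, giving 200 sample units), 2–3 replicate images each,
on a reduced 80×64-pixel frame with the full 235-band grid; the
pixel-count exclusion threshold scales with frame area (200 pixels). The
full 400×320 instrument frame (128,000 pixel spectra) is exercised where
geometry itself is under test. Monte Carlo CV uses 20 replicates in the
study driver. These sizes are the package's chosen benchmark conditions;
all of them are plain arguments (`study_config()`, `scene_config()`) and
scale up freely.

## Known limitations

* The Adjusted Wold threshold-1 rule can stall at 1 LV for attributes
  whose signal is weak relative to interfering variance (see above).
* Per-pixel application of a plant-level calibration is a calibration
  transfer; pixel-scale predictions for tissue mixtures or unusual pixels
  are biased, and no spectral un-mixing is attempted.
* The CARS internals follow common practice for the retention schedule and
  reweighted sampling; other CARS variants differ in detail, so selected
  band sets are comparable across runs of this package but not necessarily
  across implementations.
* The generic learners in the comparison harness run at fixed default
  hyperparameters by design; their rankings say nothing about their tuned
  potential.
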