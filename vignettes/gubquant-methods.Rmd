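---
title: "Models and methods behind gubquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gubquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gubquant)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters with their units
and defaults, what the synthetic-data generators do and do not emulate,
the numerical choices, and the open design decisions with the reasoning
behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The biological problem

The fetal gubernaculum anchors and guides the descending testis: a
mesenchymal core infiltrated and surrounded by cremaster muscle, with a
distal tip continuing into the gubernacular cord. Androgen receptor (AR)
signaling in its mesenchyme is required for normal development, and
regional differences — AR enrichment at the tip, stiffness peaking at the
midportion — are candidate mechanisms for cryptorchidism susceptibility in
strains with impaired AR signaling. The package provides the three
quantitative readouts used to characterize this organ: regional AR
immunofluorescence in cleared confocal volumes, apparent elastic modulus
by micropipette aspiration, and muscle-fiber morphometry from an
outgrowth assay.

## 2. Imaging pipeline

### Model and steps

Segmentation operates on the nuclear counterstain (e.g. DRAQ5) channel of
a multi-channel 3D stack with anisotropic voxel spacing in micrometres.
The enhancement chain, in order:

1. **3D median filter**, physical kernel 3.3 × 3.3 × 4.3 µm (x, y, z).
   Conversion to voxels takes the nearest odd integer per axis (minimum 1;
   half-integer ties round up so a kernel spanning exactly two voxels maps
   to three, keeping the filter centred). If the kernel is below one voxel
   on every axis the step is skipped with a warning.
2. **Plane-by-plane rolling-ball background estimation**, radius 66.4 µm
   converted on the in-plane axes. The ball is the classical non-flat
   kernel (cap height equal to the pixel-unit radius); radii above ten
   pixels are computed on a min-pooled grid and bilinearly upsampled, the
   standard large-radius approximation. The estimated background is
   *subtracted* by default. The historical description of this step does
   not say whether the smooth background or the background-free signal
   feeds the next stage, so `rolling_ball_mode = "background"` retains the
   estimate instead; subtraction is the standard reading of the term and
   is the documented default.
3. **Grayscale morphological closing** with a flat ellipsoidal structuring
   element of radius 20 µm per axis (nearest integer ≥ 1 voxel). Closing
   is grayscale, not binary, because it precedes thresholding; its purpose
   is to fill the inter-nuclear gaps so the organ thresholds as a solid.
   The implementation decomposes the ellipsoidal min/max filter into
   variable-width running-line filters (monotonic-deque sliding windows),
   which makes the default element tractable on a 128 × 128 × 64 grid.
4. **Hysteresis thresholding**: voxels at or above the high threshold are
   seeds; voxels at or above the low threshold are kept iff 26-connected
   to a seed. Thresholds were not published; the automatic default is
   high = Otsu threshold of the enhanced volume and low = 0.5 × high, both
   overridable as absolute intensities. 26-connectivity is chosen as the
   fullest 3D connectivity, matching the gap-filling intent. No voxel
   reaching the high threshold yields an *empty mask with a warning*, not
   an error.

Manual observer steps are represented as explicit file inputs, never
re-automated: residual abdominal-wall tissue is removed via an exclusion
mask (zeroed before thresholding, and guaranteed absent from the output),
and the tip region is an observer-supplied tip mask
(`load_region_labels()`).

### Regional quantification

Region labels partition the organ into tip (2) and core (1); the regional
summary is the mean of the **raw** AR channel over each label set — never
the enhanced channel — plus the tip:core ratio. Empty regions are
undefined (`NA`), not zero. For synthetic pipelines,
`default_tip_partition()` stands in for the observer geometrically: PCA of
the mask voxel coordinates gives the principal axis, oriented toward the
cord landmark, and the tip is the stated fraction of the extent nearest
the landmark. The tip-vs-core comparison within a (strain, day) group is
paired across specimens, two-sided, paired *t* by default with an exact
sign-flip permutation alternative; the source analysis does not state
sidedness or the exact paired test, so both are exposed and every report
names the test used.

No intensity normalization is applied across specimens (raw means are the
published readout); cross-specimen comparability is the user's burden.
The muscle shell is not excluded from the core, matching the published
region definition; an optional muscle mask can exclude it.

## 3. Aspiration mechanics

The elastic half-space model maps one aspiration record to an apparent
modulus, `E_app = 3 a Δp / (2 π L Φ)`, in kPa when the radius and
aspirated length share units and the pressure is in kPa. Pressures are
stored as positive magnitudes (the protocol applies suction, nominally
70 kPa through pipettes trimmed to about 80 µm diameter); using magnitudes
avoids sign errors in moduli. The published rendering of the wall function
is typographically ambiguous; the adopted reading is

Φ = ½ (1 + w/a)(1 + w/(2a)) ln(8a/w),

chosen because it evaluates to ≈ 2.1–2.6 over realistic wall-to-radius
ratios, the magnitude reported for half-space wall corrections. The
alternative parenthesization (1 + w/(2a)) ln(8a/w) / (2(1 + w/a)) is
available as `phi_form = "ratio"`, and all roundtrip tests parameterize
over both. The domain requires 0 < w < 8a (the logarithm must be
positive); Φ depends only on w/a and is scale-invariant.

Anatomic position comes from a height fraction (0 = pelvic floor, 1 =
cord): base ≤ 0.25, midportion 0.40–0.60, tip ≥ 0.75; fractions between
bands are unassigned and excluded. Regional analysis runs a one-way ANOVA
across positions per (strain, day) and a two-sample comparison across
days per (strain, position) — pooled *t* by default, Mann-Whitney as the
nonparametric option, since the published figure legend names an
"independent sample t test" without resolving which. After each ANOVA,
Tukey-style pairwise contrasts are reported descriptively; the ANOVA *p*
is the headline, because the original post-hoc structure is unstated. No
multiple-testing correction is applied (none was applied originally); the
report counts the tests performed. Aspirated length is an *input*: it was
measured manually from stereoscope photographs, and image-based length
extraction is out of scope. The model is the 3-minute steady-state
elastic approximation; creep/viscoelastic modeling is out of scope.

## 4. Fiber morphometry

`measure_objects()` starts from a labeled 2D mask (the proprietary
histogram-based masking that produced such masks originally is not
reproduced): area is pixel count × pixel area; feret diameters come from
rotating calipers over the convex hull of the pixel *outlines* (each
pixel a unit square, so a 10 × 100 px rectangle measures 10 µm across
rather than 9); aspect = feret max / feret min ≥ 1, following the
ratio-of-feret convention of the original software. Single-pixel objects
are degenerate and report feret min = feret max = pixel size.

The background-exclusion rule deletes records with aspect < 5 **or**
area < 500; the cutoffs are strict, so boundary records at exactly 5 and
500 are retained. Two readings of the published sentence are possible;
the adopted one ("delete if either criterion fails") follows the
"respectively" pairing, and `rule = "both"` provides the alternative. The
area cutoff's units are not stated; µm² is assumed and the cutoff is
configurable. Group summaries are geometric means and geometric SDs of
area, length (feret max) and aspect — the published plots are on a log
scale — with one-way ANOVAs of the log endpoints across groups; when an
`organ_id` column is present the organ (not the object) is the default
unit of analysis, via per-organ geometric means.

## 5. Statistics toolbox

All tests are computed from explicit sums of squares or rank arithmetic;
only the final tail probabilities use R's F/t/normal distribution
functions (accuracy of those routines is far beyond the 1e-8 target and
they are the environment's canonical incomplete-beta implementations).
Design points:

* one-way ANOVA: classical between/within SS, df (k−1, N−k); all-identical
  data gives F = 0, p = 1; zero within-variance with unequal means gives
  the F = ∞, p = 0 limit explicitly.
* two-sample *t*: pooled (default) and Welch; double-zero-variance with
  equal means is p = 1 by convention.
* Mann-Whitney U: midranks; exact two-sided p by full enumeration of all
  C(N, nx) labelings when N ≤ 12 without ties (the two-sided measure is
  the probability of a |U − μ| at least as large, which for the symmetric
  untied null equals the doubled smaller tail); otherwise a normal
  approximation with tie and continuity corrections. All-tied data gives
  p = 1.
* two-way ANOVA: classical balanced sums of squares (equal to Type-III
  tests for balanced designs); unbalanced designs are *restricted to a
  balanced subset* (first min cell-count observations per cell) with a
  warning rather than silently reweighted; one observation per cell makes
  the interaction untestable and main effects are tested against the
  additive-model residual.
* every result carries the test name, statistic, df, two-sided p, α
  (default 0.05) and the verdict p < α.

The oracle tests run the whole implementations against independent code
paths (`stats::aov`, `t.test`, `wilcox.test`) on random fixtures, and
against hand-computed sums of squares on the fixed integer toy
({1,2,3},{2,3,4},{3,4,5} → F = 3 with SSB = SSW = 6).

## 6. The synthetic world

### Confocal phantom

The phantom is an ellipsoidal organ body (default semi-axes
55 × 38 × 38 µm) with a cylindrical cord (18 µm long, 7 µm radius) at the
+z pole, on a 64 × 128 × 128 voxel grid at 2.15 × 1.1 × 1.1 µm spacing —
a plausible 25× confocal sampling chosen so the standard median kernel
maps to 3 × 3 × 3 voxels (no acquisition spacing was published; this is a
placeholder, not a measured value). Its stated-world parameters:

* **Nuclei**: 2 per 1000 µm³ (one ~10 µm cell per nucleus — dense fetal
  mesenchyme), radius 3.5 µm, solid spheres by default (Gaussian blobs
  optional). Placement is *stratified*: one jittered nucleus per cubic
  lattice cell. Confluent tissue is close-packed, and a Poisson process
  would give per-region count fluctuations (≈ 1/√n) that real mesenchyme
  does not show; stratification reproduces near-uniform packing and makes
  regional painted fractions stable.
* **Intensities** (arbitrary units on a 16-bit-like scale): nuclear
  channel 3000 over background 100; AR per-nucleus means core 1500, tip
  2250 (contrast 1.5), muscle shell 450 (AR is excluded from muscle
  cells), background 100. AR is painted at nucleus locations only,
  reflecting nuclear receptor localization; a cytoplasmic fraction is
  configurable and defaults to 0. The level painted at a voxel is the
  *voxel's* region mean, so nuclei straddling the tip boundary do not
  cross-contaminate regional means.
* **Regions**: the tip is the organ within the stated fraction (default
  0.25) of the organ's z-extent measured from the cord end — the same
  quantity the geometric observer stand-in computes, so generator truth
  and `default_tip_partition()` agree by construction. The muscle shell
  is a 10 µm surface layer of the body outside the tip.
* **Noise**: additive Gaussian, default σ = 75 (5 % of the core AR level),
  *unclipped* (detector-offset convention) so regional means stay
  unbiased; Poisson noise is optional. Channels are float-valued.

What the phantom does **not** emulate: point-spread blur, light-sheet or
clearing artifacts, depth-dependent attenuation, nuclear shape variation,
per-cell expression variability, and any dose-response behaviour. A green
segmentation test therefore establishes that the pipeline recovers a
known geometry under realistic sampling, noise and packing — not that it
is robust to every optical artifact of real cleared-organ imaging.

One measurement subtlety is worth stating plainly: the regional mean of a
nucleus-localized stain over *all* region voxels equals (painted volume
fraction) × (nuclear level), so it conflates expression with local cell
density, and in a small tip (a thin cap plus the cord, a few dozen
nuclei) the realized regional ratio fluctuates several percent from seed
to seed and sits systematically below the per-nucleus contrast (boundary
nuclei are clipped by the organ surface). This is a property of the
*measure*, not an estimator error — the pipeline recovers the per-seed
generative truth to well under 1 %. For contrast-recovery experiments the
`contrast_phantom_spec()` preset therefore removes the dilution terms (no
AR background, no muscle shell) and *calibrates* the painted tip
intensities so the generative regional-mean ratio equals the requested
contrast exactly (`calibrate_ratio`); recovery is then measured against
that pinned generative value.

### Aspiration cohorts

Aspirated lengths are drawn through the forward model
L = 3aΔp / (2πE·Φ(a,w)) at group-specific true moduli, then perturbed
multiplicatively (Gaussian, relative SD 0.15 by default, resampled to stay
positive). Protocol constants: pipette radius ~N(40, 2) µm, wall 8 µm,
pressure 70 kPa. The true-modulus design emulates the published
qualitative pattern — wild-type midportion 1.5× stiffer than base/tip,
1.5× stiffening from E19 to E21, flat in the cryptorchid-model strain —
at field-plausible magnitudes of a few kPa; the source figures print no
numbers, so these are stated-world values, chosen once. With zero noise
the forward-inverse roundtrip is exact to machine precision, which the
acceptance suite asserts at 1e-12.

### Intensity cohorts and fiber tables

Power/type-I simulations of the tip-vs-core contrast use a summary-level
cohort generator (per-specimen tip/core means with log-normal
specimen baselines, σ_log = 0.2, and 10 % measurement noise) rather than
rendering hundreds of volumes; the volume-level and summary-level worlds
share the same regional-mean model. Fiber tables draw fibers as
long/large objects (log-normal area around 1500 µm², shifted-log-normal
aspect ≥ 5) and debris as small/round objects whose area and aspect
distributions deliberately cross the filtering cutoffs; feret diameters
derive from area and aspect through a rectangular packing factor of 0.8;
a hidden `true_class` column is retained for testing only. Multi-organ
cohorts add a log-normal per-organ size effect (σ_log = 0.15) so the
organ-level unit of analysis has realistic between-organ variance.

## 7. Numerical and I/O choices

* µm→voxel conversions: nearest odd ≥ 1 for the median kernel, nearest
  integer ≥ 1 for morphology radii; all conversions are per axis because
  spacing is anisotropic.
* Morphological border handling is the shrinking-window convention, which
  keeps closing extensive and idempotent on piecewise-constant inputs.
* Otsu's threshold uses a 256-bin histogram of the enhanced volume;
  degenerate (constant) enhanced volumes yield an empty mask with a
  warning rather than an arbitrary split.
* Volumes are stored as multi-page grayscale TIFF (pages channel-major),
  uint16 when lossless, float32 otherwise, with voxel spacing, channel
  roles and metadata in a sidecar JSON that is also embedded as the TIFF
  ImageDescription. The codec implements only the uncompressed baseline
  subset — no TIFF library is available among the allowed dependencies —
  and rejects compressed or tiled files with a clear error. Configs are
  JSON for the same reason (no YAML parser available).
* All generators are pure functions of (spec, seed): they save and
  restore the caller's RNG state, and identical specs reproduce outputs
  bit for bit.

## 8. Known limitations

* The hysteresis thresholds of the original analysis are unknown; the
  Otsu-based default is reproducible but need not match the original
  per-volume choices.
* Feret measurements treat pixels as squares; sub-pixel boundary effects
  are within ~1 % for objects larger than a few pixels but matter for
  very small debris.
* The two-way ANOVA handles unbalanced designs by balanced subsetting,
  which discards data; it is intended for the near-balanced designs of
  this pipeline, not as a general linear-model replacement.
* Litter-level clustering is not modeled (fetuses are pooled across
  litters, as in the source analyses).
* The mechanics model assumes an elastic half-space at steady state;
  finite organ thickness and viscoelasticity are outside the model.
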