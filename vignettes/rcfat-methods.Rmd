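---
title: "Quantifying 3D intramuscular fat distribution: models and methods"
author: "rcfat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D intramuscular fat distribution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcfat)
```

## The measurement problem

Fat infiltration of the rotator cuff muscles is a key prognostic factor in
the management of rotator cuff tears, and it is spatially inhomogeneous:
degeneration often starts in particular regions of a muscle long before the
whole-muscle average moves.  Chemical-shift (Dixon-type) fat-water MRI
yields co-registered fat-only and water-only magnitude images from which a
voxelwise **fat fraction** can be computed,

$$\%\mathrm{fat} = \frac{\mathrm{Fat}}{\mathrm{Fat} + \mathrm{Water}} \times 100,$$

and, given a manual segmentation of each muscle, whole-muscle and regional
summaries of fat content and volume.  `rcfat` implements this quantification
pipeline for three rotator cuff regions of interest (supraspinatus "SS",
combined infraspinatus/teres minor "IS", subscapularis "SC"), the spatial
partitioning of each muscle into superior–inferior quartile bands and
lateral-to-medial slice tertiles, and the measurement-property statistics
(ICC, SEM, MDC, sample size) with which such a method's reliability is
established.  Because segmentation is manual and rater-dependent, the
package also ships a synthetic phantom and rater-variability simulator so
the entire pipeline — including the reliability analysis — can be exercised
and validated end to end without patient data.

## Conventions and geometry

All volumes live on a canonical `(row, col, slice)` grid: rows run superior
to inferior, columns anterior to posterior, and slices lateral to medial
(the sagittal-oblique acquisition direction).  Voxel spacing is read from
the NIfTI header; the default emulated acquisition uses 1.2 × 1.2 mm
in-plane pixels and 2.0 mm slices.  Readers re-orient any input carrying a
valid qform/sform to this canonical order.  One anatomical ambiguity cannot
be resolved from the header alone: whether "lateral to medial" corresponds
to the patient's right-to-left or left-to-right direction depends on which
shoulder was imaged, so the reader takes a `side` option (default
`"right"`) and additionally accepts an explicit `axes:` override (axis
permutation plus flips) for headerless or unconventionally stored files.
Masks are filled voxel labelings (0 = background), never contours.  All
user-facing region indices are 1-based; quartile Q1 is the superior-most
band.

## Whole-muscle estimators

Two whole-muscle percent-fat estimators are computed and reported side by
side:

* **slice-mean** (default): the mean over slices containing the muscle of
  each slice's in-muscle mean — the literal "average over consecutive
  images", in which every image contributes equally regardless of
  cross-sectional area;
* **voxel-weighted**: the plain mean over all labelled voxels, the
  self-consistent 3D estimator (regional voxel-weighted means recombine
  exactly to it).

They differ whenever cross-sectional area covaries with fat content along
the muscle; reporting both makes the choice explicit rather than silent.
Muscle volume is the sum over slices of labelled-voxel count × pixel area,
times the slice thickness, reported in cm³ — a voxel-counting rule, with no
sub-voxel contour integration, because the input is a voxel labeling.

Voxels whose total signal is zero have no defined fat fraction; they are
marked `NA`, excluded from every mean, counted, and reported.  Imputing
either 0% or 100% would bias regional means, so neither is done.

## Spatial partitions

**Superior–inferior quartiles.** Within each slice, the occupied row extent
`[r_min, r_max]` of the muscle is divided into four bands of height
`h = (r_max − r_min + 1)/4`; the voxel at row `r` joins band
`min(4, ⌊(r − r_min)/h⌋ + 1)`.  The rule is deterministic, exhaustive, and
independent of voxel iteration order, and band row-counts within a slice
differ by at most one.  Bands are computed per slice (not from one 3D
bounding box) because the muscle cross-section drifts superiorly/inferiorly
across sagittal slices; a `extent = "global"` option provides the
bounding-box alternative.  One consequence of the floor rule worth knowing:
when the row extent is not a multiple of four the band sizes are slightly
asymmetric (extent 10 gives sizes 3, 2, 3, 2), so reflecting the volume
superior↔inferior maps Q1↔Q4/Q2↔Q3 exactly only on extents divisible by
four; the validation suite exercises the reflection symmetry on such
extents.

**Lateral/intermediate/medial tertiles.** The contiguous span of slices the
muscle occupies — operationally "from the glenoid to the medial scapular
border", since the segmentation is bounded by those landmarks — is split
into three contiguous near-equal slice groups: `⌊n/3⌋` slices each, with
the `n mod 3` remainder slices handed out one per group, lateral-first by
default (`remainder = "medial"` or `"intermediate"` reassigns them; the
choice is arbitrary but deterministic, as "equal thirds" underdetermines
it).  Fewer than three occupied slices is a degenerate extent and an error.

Both partitions are exact set partitions of the muscle's voxels: regional
voxel counts and volumes sum to the whole-muscle values, and voxel-weighted
regional means recombine exactly to the whole-muscle mean.

## Reliability statistics

Ratings are a complete subjects × raters design per variable.  The two-way
ANOVA decomposition gives between-subject (`MSR`), between-rater (`MSC`)
and residual (`MSE`) mean squares, from which:

* **ICC**, default form *two-way random effects, absolute agreement,
  single measures* — appropriate when raters are interchangeable:
  $$\mathrm{ICC} = \frac{MSR - MSE}{MSR + (k-1)\,MSE + \tfrac{k}{n}(MSC - MSE)};$$
  the *two-way mixed, consistency* form (which ignores systematic rater
  offsets) is selectable.  95% confidence intervals use the standard
  F-distribution intervals, with a Satterthwaite degrees-of-freedom
  approximation for the absolute-agreement form.  Empirically (and in the
  test suite) the interval covers a true ICC of 0.8 in ≈95% of simulated
  n = 30, k = 2 designs.
* **Qualitative bands**: poor < 0.20, fair 0.21–0.40, moderate 0.41–0.60,
  good 0.61–0.80, very good 0.81–1.00.  The verbal scale leaves gaps
  between its cut-points, so the implementation uses half-open intervals at
  the midpoints (0.205, 0.405, 0.605, 0.805) — every real value gets
  exactly one band and the classification is monotone.
* **SEM**: default `SD_pooled × sqrt(1 − ICC)` (the classic reliability
  formula, with the SD pooled over all measurements); the ANOVA variant
  `sqrt(MSE)` is provided because the two differ in general and published
  reports rarely say which was used.
* **MDC**: `z·√2·SEM` with default `z = 1`.  The √2 default (rather than
  the conventional MDC95 multiplier 1.96·√2) matches the arithmetic of the
  published reliability tables this package's validation targets reproduce,
  in which every self-consistent SEM/MDC cell satisfies MDC = √2 × SEM;
  `z = qnorm(0.975)` recovers MDC95.
* **Concurrent validity** between two measurement methods reuses the ICC
  machinery with the methods as the two "raters", paired by subject.
* **Sample size** for an ICC study uses the variance-stabilising transform
  `u(ρ) = ½·log((1 + (k−1)ρ)/(1 − ρ))` with approximate variance
  `k / (2(k−1)(n−2))`, solving
  `n = 2 + k(z_α + z_β)² / (2(k−1)(u(ρ₁) − u(ρ₀))²)` and rounding up.
  Published calculations of this kind vary by ±1 subject depending on the
  degrees-of-freedom convention (n−1 vs n−2 vs n−3/2); the suite therefore
  validates the returned n with a Monte-Carlo power oracle (one-sided test
  via the lower confidence bound) rather than against a single printed
  number.  For ρ₀ = 0.75, ρ₁ = 0.95, one-sided α = 0.05, power 0.80,
  k = 2 the function returns 11.

Degenerate inputs are errors, not guesses: incomplete designs, fewer than
two subjects or raters, and zero total variance all fail loudly.  Perfect
agreement (zero residual variance with positive subject variance) is the
one special case handled explicitly: the ICC is exactly 1 with a degenerate
interval, since the F-based interval formulas divide by `MSE`.

## The phantom generator

`phantom_spec()`/`make_phantom()` build a digital stand-in for a
sagittal-oblique shoulder acquisition: a 64 × 64 × 24 grid at the
acquisition's 1.2 × 1.2 × 2.0 mm spacing (a desk-scale reduction of a
320 × 320 × 120 scan; the spacing, not the matrix, is what the estimators
are sensitive to), with three non-overlapping muscles shaped as per-slice
ellipses linearly interpolated across their occupied slice ranges.  True
fat-fraction fields are a base level (defaults 11.69 / 10.51 / 13.12 %fat
for SS / IS / SC, inside the 8–16% range typical of rotator cuff pathology
cohorts) plus optional superior–inferior and medial–lateral linear
gradients, or piecewise-constant tertile values.  Channel intensities are
`fat = W·f/100`, `water = W·(1 − f/100)` (W = 1000 by default) plus
independent Gaussian noise in each channel at in-mask voxels, clipped at
zero with the clipped count recorded; background voxels carry pure water
signal.

Design notes and what the phantom does *not* emulate:

* **Gaussian, not Rician, noise.** The pipeline consumes reconstructed
  magnitude fat/water pairs; Gaussian noise keeps the ground truth analytic
  and is adequate at the simulated SNR.  Rician floor effects at very low
  signal are not represented.
* **No bias fields, chemical-shift artifacts, coil profiles, or partial
  volume** — a noise-free phantom is recovered *exactly* (to double
  precision) by the pipeline, which is the point: it isolates the
  arithmetic of the estimators from acquisition physics.  Passing these
  tests therefore demonstrates correctness of the computation, not
  robustness to real-scan artifacts.
* **Ratio bias.** With noise, `E[fat/(fat+water)]` differs from the true
  fraction by a term of order `(σ/W)²`; at the default 0.5–1% noise this
  floor is ≪ the sampling variation, and the suite checks that estimates
  tighten with voxel count in that regime.

`perturb_mask()` emulates a second rater: each muscle is independently
translated by up to `max_shift` voxels per axis and its surface roughened —
boundary voxels (6-connectivity) removed and adjacent background voxels
added, each with probability `boundary_op_prob`.  Mean Dice overlap with
the original decreases monotonically in that probability.
`simulate_ratings()` draws the classic additive variance-components model
`y_ij = μ + s_i + r_j + e_ij`; its implied true ICC is
`σ_s²/(σ_s² + σ_r² + σ_e²)`.  One subtlety the test design respects: with
`k = 2` raters the single realized rater contrast `r_1 − r_2` never
averages out over subjects, so the absolute-agreement estimate converges to
a quantity involving the *realized* rater variance (`χ²₁`-distributed
around `σ_r²`), not the component ratio itself.  Tight parameter-recovery
checks therefore use `σ_rater = 0`, and the `σ_rater > 0` case is checked
in expectation across independent rater draws.

## The simulated reliability study

`simulate_study()` reproduces the computational portion of a two-rater
reliability study: 13 subjects by default (a typical reliability-cohort
size), each a phantom with between-subject variation in fat level
(`subject_ff_sd = 2.5` %fat; published rotator cuff reliability tables
imply a between-subject pooled SD of roughly 6 %fat via SEM/√(1−ICC), and
2.5 keeps every simulated field comfortably inside the 8–16% envelope) and
muscle size (log-normal scale factor, SD 0.06).  Rater 1 keeps the
reference segmentation; additional raters get perturbed masks of the same
scan, mirroring the real protocol in which raters segment the same images.
With perturbation disabled the raters are bit-identical and every ICC is
exactly 1 with SEM = MDC = 0 — a structural sanity check the acceptance
suite enforces.  The reliability CSVs mirror the published layout: quartile
tables carry %fat over Q1–Q4, tertile tables carry %fat and volume side by
side over whole/lateral/intermediate/medial (12 rows for three muscles).
The concurrent-comparison table pairs the slice-mean and voxel-weighted
estimators as two "methods"; an external-software comparison arm is out of
scope, so this table demonstrates the machinery on the two internal
estimators and is labelled accordingly.

## Problem sizes used in validation

The shipped validation suite runs phantoms at 64 × 64 × 24 (one
convergence check at 96 × 96 × 46), ICC recovery at n = 2000, CI coverage
over 1000 replicates of n = 30 designs, partition properties over 50
randomized masks, and two full 13-subject, 2-rater simulated studies —
sizes chosen so the whole suite runs in about a minute while keeping every
Monte-Carlo margin several standard errors wide.

## Known limitations

* Anatomical landmarks (glenoid, medial border) are operationalized by the
  mask's occupied slice span, not detected from the images; masks that
  overshoot the landmarks will shift the tertile boundaries accordingly.
* The quartile floor rule's mild asymmetry on non-divisible extents (above)
  is inherent to any integer banding; it is deterministic and documented
  rather than hidden by randomized tie-breaking.
* The absolute-agreement ICC at k = 2 cannot separate the realized rater
  offset from its population variance (above); reported intervals are
  conditional on the raters at hand, as in any two-rater study.
* The phantom validates computation, not acquisition robustness: no claim
  is made about bias-field, motion, or fat-spectrum effects upstream of the
  fat/water pair.
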