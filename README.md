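# rcfat

Quantification of three-dimensional intramuscular fat infiltration and its
spatial distribution in rotator cuff muscles from Dixon fat-water MRI,
together with the reliability toolkit (ICC, SEM, MDC, sample size) used to
validate such measurements.

## What it computes, for whom

Fat infiltration of the rotator cuff is a central prognostic factor in the
surgical management of rotator cuff tears, and it is spatially
inhomogeneous.  Given a pair of co-registered fat-only and water-only
volumes (NIfTI) and a multi-label muscle segmentation mask, `rcfat`
computes:

- the voxelwise **fat fraction**, `%fat = Fat / (Fat + Water) × 100`;
- **whole-muscle %fat** (slice-mean and voxel-weighted estimators) and
  **muscle volume** (Σ per-slice area × slice thickness, in cm³) for the
  supraspinatus, combined infraspinatus/teres minor, and subscapularis;
- **regional %fat and volume** over two anatomic partitions of each
  muscle: four superior→inferior quartile bands (Q1–Q4, Q1 superior-most,
  banded per slice from each slice's occupied row extent) and three
  lateral/intermediate/medial slice tertiles spanning the muscle from the
  glenoid level to the medial scapular border;
- **measurement properties** from repeated segmentations: the two-way
  ANOVA intraclass correlation coefficient (absolute-agreement or
  consistency form, single measures) with 95% F-based confidence
  intervals and qualitative bands, the standard error of measurement
  (`SD·√(1−ICC)` or `√MSE`), the minimal detectable change
  (`MDC = z·√2·SEM`, default `z = 1`), concurrent validity between two
  methods, and the number of subjects needed for an ICC reliability study
  (variance-stabilising transform);
- **synthetic phantoms**: fat-water volumes with muscle-shaped masks,
  known spatially varying fat fields and exact ground truth; simulated
  second-rater segmentations (boundary roughening + translation); and
  variance-components ratings tables — so the whole pipeline, including a
  13-subject two-rater reliability study, runs end to end without any
  patient data.

It is aimed at musculoskeletal imaging researchers building or validating
quantitative muscle-composition pipelines.

## Worked example

```r
library(rcfat)

# a synthetic scan: three muscles, mild fat gradients, 0.5% intensity noise
ph  <- make_phantom(phantom_spec(noise_sd = 5), seed = 1)
map <- compute_fat_fraction(ph$volume)
muscle_summary(map, ph$mask)
#>   label mean_fat_pct_slice mean_fat_pct_voxel volume_cm3 n_voxels n_slices
#> 1    SS              11.70              11.75      13.20     4585       20
#> 2    IS              10.50              10.47      14.65     5086       20
#> 3    SC              13.11              13.10      12.17     4225       20

# spatial distribution in the supraspinatus, superior (Q1) to inferior (Q4)
rs <- regional_stats(map, ph$mask, partition_quartiles(ph$mask, "SS"))
rs[, c("region", "mean_fat_pct_slice", "volume_cm3", "n_voxels")]
#>   region mean_fat_pct_slice volume_cm3 n_voxels
#> 1     Q1              11.03      3.300     1146
#> 2     Q2              11.54      3.839     1333
#> 3     Q3              12.02      3.977     1381
#> 4     Q4              12.47      2.088      725

# reliability of a repeated measurement (13 subjects, 2 raters)
r   <- simulate_ratings(mu = 12, sigma_subject = 3, sigma_rater = 0.3,
                        sigma_error = 0.6, n_subjects = 13, k_raters = 2,
                        seed = 2)
fit <- icc(r)
fit
#> ICC (two_way_random_absolute_single): 0.905  95% CI [0.674, 0.971]  (very_good)
#>   n = 13 subjects, k = 2 raters
s <- sem(r, fit$icc); c(SEM = s, MDC = mdc(s))
#>       SEM       MDC
#> 0.8489265 1.2005630
```

The phantom's supraspinatus was built with a base fat fraction of 11.69%
and a mild superior–inferior gradient: the whole-muscle estimators land on
the construction (11.70 / 11.75%), the quartile means rise monotonically
from Q1 to Q4 as built, and the volume equals the labelled voxel count
times the 1.2 × 1.2 × 2.0 mm voxel.  In the ratings example the
variance-components truth is σ²s/(σ²s+σ²r+σ²e) ≈ 0.952; the
absolute-agreement ICC estimates it from 13 subjects with the wide interval
such a small cohort implies, and the MDC is √2 × SEM.

A complete simulated reliability study — per-muscle, per-region ICC/SEM/MDC
tables in the published layout — is one call:

```r
st <- simulate_study(n_subjects = 13, k_raters = 2, seed = 1)
head(st$reliability)
```

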