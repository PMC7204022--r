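# collprof

Stain-free collagen structural profiling from two-channel SHG/TPE tissue
images, with cohort-level survival stratification.

Second harmonic generation (SHG) microscopy images fibrillar collagen
without staining; pixel brightness tracks fibril packing density. Paired
with a two-photon excitation (TPE) autofluorescence channel showing the
whole tissue, an SHG image of a tumor core carries quantitative
information about collagen architecture in the tumor microenvironment —
information that predicts patient outcome but is invisible to routine
staining. `collprof` is for image-analysis and translational-research
groups who want that architecture as a small table of named numbers per
sample, and who want the downstream survival statistics in the same box.

## What it computes

Per sample, from a two-channel TIFF:

1. **Sample mask** covering the tissue area (two-mode Gaussian mixture on
   the TPE channel, with a BIC gate against fitting noise).
2. **Collagen binary image**: a two-component Gaussian mixture
   `w1 N(mu1, s1^2) + w2 N(mu2, s2^2)` is fitted to masked SHG intensities
   by EM, and pixels are thresholded at the Bayes boundary — the intensity
   `t` between the means with `w1 phi1(t) = w2 phi2(t)` (posterior 0.5).
3. **ATC / DTC compartments**: grayscale morphological opening with a disc
   of diameter `3.5 x` the preliminary fiber thickness erases every
   isolated fiber and keeps aggregated thick collagen (ATC); the rest of
   the mask is dispersed thin collagen (DTC).
4. **Fiber morphometry** per region (ATC, DTC, ALL), from the Guo-Hall
   skeleton of the collagen binary:
   - CAR — collagen area / region area
   - CFD — summed SHG intensity over collagen pixels / their count
   - CFL — skeleton branch lengths, geodesic (1, sqrt 2) metric
   - CFT — 2 x distance-transform ridge at skeleton pixels − 1
   - CRI — junction clusters / total skeleton length
   - ATC area ratio — ATC area / tissue area

Per cohort, from the feature table joined to survival records: each
feature is dichotomized at the percentile cutpoint (10th–90th, 10% grid)
whose binary split best separates survival (univariate Cox score test),
and the two-feature ATC-CFD x DTC-CFL four-group model is fitted with
Kaplan-Meier curves and log-rank tests per endpoint (DFS, OS).

A seeded synthetic-scene generator (Gaussian-profile fiber tubes with
per-fiber ground truth, clustered aggregates, simulated cohorts with
planted cutpoints) makes every stage testable without any imaging data.

## Worked example

```r
library(collprof)

# a synthetic TMA core: one dense aggregate + 5 isolated fibers
spec <- random_scene_spec(
  n_isolated = 5,
  clusters   = list(list(center = c(90, 90), radius = 40, n_fibers = 55)),
  seed = 42)
scene <- generate_scene(spec)
write_scene(scene, "tma_core.tif")          # 2-page TIFF + ground-truth JSON

img <- read_tma_image("tma_core.tif")
fv  <- profile_image(img)                    # mask -> GMM -> split -> features
print(fv)
```

```
<feature_vector> tma_core | ATC area ratio 0.094 | collagen threshold 40.99
 region     car    cfd cfl_mean cfl_median cft_mean     cri n_junctions
    ATC 1.00000 217.23    19.14     19.142   71.558 0.00000           0
    DTC 0.04763  60.67    19.43      6.657    3.868 0.02131          12
    ALL 0.13683 167.84    21.06     12.657   16.995 0.02257          20
```

Reading it: 9.4% of the tissue is aggregated collagen (ATC area ratio).
The ATC region is solid collagen (CAR 1.0) and much brighter than the
dispersed compartment (CFD 217 vs 61 intensity units — denser fibril
packing), and its distance-ridge "thickness" reflects the blob scale
rather than single fibers. The DTC skeleton has 12 junction clusters over
its branches (CRI 0.021 junctions/px); dispersed fibers are ~4 px thick.

Cohort side, with a planted cutpoint:

```r
co   <- generate_cohort(cohort_spec(n_patients = 200, planted_percentile = 40,
                                    hazard_ratio = 2.5, seed = 7))
scan <- dichotomize_best_separation(co$feature, co$time, co$event)
print(scan)
```

```
selected: 40th percentile (threshold 0.971, p = 3.58e-08)
note: selected p-value is the minimum over 9 candidate cutpoints and is
anti-conservative under the null; interpret as descriptive, not as a
calibrated test
```

The scan recovers the planted 40th-percentile cutpoint; the printed note
is part of the result on purpose. `four_group_stratify()` then crosses
two such thresholds into the four prognostic groups, and
`run_profile()` / `run_cohort()` (or the CLI at `inst/cli/collprof.R`)
batch the whole pipeline over directories of images and CSV tables.

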