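---
title: "Stain-free collagen structural profiling: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain-free collagen structural profiling: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collprof)
```

# The problem

Second harmonic generation (SHG) microscopy images fibrillar collagen
without any stain: pixel brightness scales with the packing density of
fibrils inside a fiber. Paired with a two-photon excitation (TPE)
autofluorescence channel that shows the whole tissue, an SHG image of a
tumor tissue core carries quantitative information about how collagen is
organized in the tumor microenvironment — how much there is, how bright
(dense) it is, how long and thick the fibers are, and how interconnected
the network is. `collprof` turns a two-channel SHG/TPE image into a small
set of named imaging features, separately for two texture compartments of
the tissue, and provides the cohort-level statistics that relate those
features to patient survival.

The pipeline has five stages, run in this order:

1. **Sample mask** — find the tissue area on the frame.
2. **Collagen segmentation** — classify each masked pixel as collagen or
   background with a two-component Gaussian mixture threshold.
3. **Compartment separation** — split the tissue into *aggregated thick
   collagen* (ATC) and *dispersed thin collagen* (DTC) by grayscale
   morphological opening.
4. **Fiber morphometry** — skeletonize the collagen binary image and
   measure, per compartment and for the whole tissue (ALL):
   collagen area ratio (CAR), collagen fiber density (CFD), fiber length
   (CFL), fiber thickness (CFT), reticular index (CRI), junction count,
   and the ATC area ratio.
5. **Cohort statistics** — dichotomize each feature at its best-separating
   percentile cutpoint and build the two-feature four-group prognostic
   stratification with Kaplan-Meier and log-rank outputs.

The order matters: segmentation precedes a preliminary fiber-thickness
pass on the whole collagen binary, which sizes the structuring element for
the compartment split; per-region features are computed last, on the
compartment-restricted binaries.

# Models and estimators

## Mixture threshold

Masked pixel intensities are modelled as a two-component Gaussian mixture
(background and collagen). The EM fit is deterministic: initialization
splits the sample at its median, components are reported sorted by mean,
and iteration stops when the relative log-likelihood change drops below
1e-6 (or at 500 iterations). Intensities are treated as continuous — no
histogram binning — so the threshold does not depend on a bin width. The
binarization threshold is the *Bayes boundary*: the intensity between the
two means where the weighted component densities are equal (posterior
probability 0.5). When the weighted densities do not cross between the
means (pathological overlap) the midpoint of the means is used and
flagged. The same engine drives the tissue mask on the TPE channel.

Two consequences are worth knowing. The threshold is equivariant under
affine intensity rescaling, so detector gain does not change the
segmentation. And on data that are genuinely bimodal the threshold attains
the Bayes-optimal misclassification rate of the fitted mixture; the test
suite checks both properties.

A two-component fit is only *meaningful* when the histogram really has two
modes. The sample-mask stage therefore accepts a fit only when it beats a
single Gaussian by BIC; an EM split of a homogeneous frame yields almost
no likelihood gain and is rejected. A frame whose TPE channel is
homogeneous but whose SHG channel shows clear collagen contrast is treated
as tissue spanning the whole frame; a frame with contrast in neither
channel raises an empty-mask error rather than returning a fabricated
mask.

## Compartment separation

ATC is detected by *grayscale* morphological opening of the SHG channel
with a disc whose diameter is `atc_se_scale` (default 3.5, constrained
≥ 3) times the preliminary fiber thickness. Opening erases any bright
structure that cannot contain the disc — in particular every isolated
fiber, whose width is a single fiber thickness — while bright regions of
aggregated collagen survive with their full extent. The opened image is
re-thresholded at the *same* collagen threshold (no new free parameter)
and intersected with the sample mask; the remainder of the mask is DTC.
ATC and DTC partition the mask exactly, by construction, and the ATC area
is non-increasing in the structuring-element scale.

No dilation is applied after re-thresholding. Grayscale opening preserves
the envelope of every region that can contain the disc, so the
re-thresholded image already covers whole aggregated structures; dilating
it back would push the ATC boundary one disc radius into the dispersed
compartment.

The preliminary thickness that sizes the disc is the *median* (not mean)
distance-transform value over skeleton pixels: the mean would be inflated
by the thick aggregate blobs whose detection is the point of the exercise.

## Skeleton morphometry

The collagen binary image is thinned with the Guo-Hall two-subiteration
algorithm, which is topology preserving and leaves diagonal runs strictly
one pixel wide. Junction pixels are skeleton pixels whose *crossing
number* — the count of 0→1 transitions around the ordered 8-neighbor
ring — is at least 3; this is the branch degree of the pixel and, unlike a
raw neighbor count, does not fire on the staircase corners of oblique
lines. Junction pixels are clustered by 8-adjacency, and clusters whose
centroids lie within 5 px are merged, since one physical crossing can thin
into two nearby T-points depending on its orientation. Short twigs ending
in a free endpoint next to a junction (< 3 px by default) are pruned
iteratively as thinning artifacts before the final graph is assembled.

Branches are the connected components of the skeleton with junction pixels
removed; two branch arms are never connected diagonally *around* the
junction pixel that separates them. Branch length is geodesic — orthogonal
steps count 1, diagonal steps √2 — applied consistently everywhere. This
metric overestimates the Euclidean length of oblique lines by up to 8%
(about +5% averaged over orientations), which is visible as a CFL
recovery slope slightly above 1.

The features:

* **CAR** = collagen-positive pixels / region area.
* **CFD** = summed SHG intensity over collagen-positive pixels / their
  count — mean collagen signal, the fibril-packing proxy. Exactly linear
  in intensity and independent of collagen-free area.
* **CFL** = per-branch geodesic lengths (mean and median), after spur
  pruning. A "fiber" is a skeleton branch — the only unambiguous
  decomposition of a network; individual fibers are not tracked across
  junctions.
* **CFT** = 2·d − 1, where d is the Euclidean distance transform of the
  binary image read at the medial ridge (8-neighborhood maximum) under
  each non-junction skeleton pixel. The −1 refers the estimate to
  edge-to-edge width (a bar of odd width w measures exactly w); the ridge
  read compensates the one-pixel placement freedom of thinning on
  diagonal structures.
* **CRI** = junction count / total skeleton length; 0 for an empty or
  junction-free skeleton.

All features are computed three times, on ATC, DTC and ALL (their union),
by restricting the collagen binary to the region and re-deriving the
skeleton of the restriction, so branches crossing a compartment boundary
are split at the boundary. Two exact identities follow and are asserted in
the tests: ALL collagen area equals ATC + DTC collagen area (integer
equality), and ALL CAR is the region-area-weighted mean of the
compartment CARs. Empty regions yield missing values, never zeros, so a
sample without aggregates does not drag cohort means toward zero.

Features are reported in pixels; physical units require only the pixel
size, which TIFF metadata rarely carries reliably, so it is a
configuration override.

## Cohort statistics

Disease-free and overall survival are handled as two endpoint columns with
one interface. For each numeric feature the cohort is dichotomized at each
of its percentiles on a 10% grid (10th–90th); each split is scored by the
p-value of a univariate Cox proportional-hazards score test (a log-rank
metric is available by flag — for a binary split the two are
asymptotically the same test), and the split with the smallest p-value
wins, ties going to the lower threshold. Candidates leaving a group below
10% of the cohort are skipped. "+" means feature ≥ threshold. Thresholds
are learned on the full cohort, without cross-validation, exactly as such
cutpoint analyses are usually run — and for the same reason the selected
p-value is a minimum over nine candidates and is anti-conservative under
the null. The scan result carries an explicit multiplicity warning and the
full per-candidate table; the null simulation in the test suite
demonstrates the inflation rather than hiding it.

The four-group model crosses two dichotomized features (by default ATC CFD
× DTC CFL, the prognostic pair): each patient gets a sign-pair label, and
Kaplan-Meier curves plus a 3-df log-rank test are computed per endpoint.
Empty groups are flagged, not fatal. Group comparisons of feature values
use one-way ANOVA with Tukey HSD adjusted pairwise p-values and
significance tiers at 0.05 / 0.01 / 0.001 / 0.0001. Kaplan-Meier, Cox and
log-rank computations delegate to the `survival` package; the scan and
stratification logic is this package's own.

# The synthetic-scene generator

No imaging data ship with the package, so every downstream stage is
validated against synthetic scenes with exact per-fiber ground truth.

A fiber is a polyline with a Gaussian cross-section whose full width at
half maximum equals the planted thickness; the centerline reaches the
planted peak intensity, contributions of different fibers add, and a
fiber never self-accumulates (the minimum distance to its whole polyline
is used). The SHG channel is the fiber sum plus Gaussian background noise
clipped at zero; the TPE channel is the tissue silhouette (full frame or a
centered disk) plus the same noise model; both channels are quantized to
integer grey levels, as a photon-counting detector would deliver — which
also makes TIFF round-trips bit-exact. Optional Poisson shot noise can be
added on top. Equal seeds give byte-equal scenes.

Ground truth records, per fiber, the polyline arc length, thickness and
peak; the collagen mask is the union of per-fiber half-peak supports (so
its width equals the planted thickness); true junctions are the exact
pairwise polyline intersections; and the aggregate (ATC) mask is the
clustered-fiber tube union closed with a disc of half the cluster radius —
the filled region a reader would outline as "aggregated collagen" without
extending beyond it.

Default conditions, chosen once: background N(20, 6); isolated-fiber peaks
45–65 (centerline signal-to-noise around 8–11, the regime in which the
mixture threshold lands near half-amplitude, as it does in calibrated SHG
imaging with clear collagen contrast); cluster fibers brighter (60–90) and
dense (55 chords across a 40-px-radius disk) so the aggregate is a
genuinely solid bright region; 256×256 px frames. Simulated cohorts draw a
feature from a log-normal, plant a cutpoint at a chosen decile, and draw
exponential event times whose hazard jumps by a known ratio above the
cutpoint; censored subjects are a Bernoulli draw at the stated rate,
observed at a uniform fraction of their event time, keeping censoring
independent of group.

What the generator does *not* emulate — and hence what passing tests do
not show about real tissue: curved and branching fibers (polylines are
straight in the stock scenes), spatially varying autofluorescence,
scanner shading and stitching seams, anisotropic point-spread functions,
and the continuum between "aggregated" and "dispersed" that real stroma
exhibits. The compartment ground truth is unambiguous by construction;
histology is not.

# Validation design and numerical choices

Each stage is validated against its own oracle. Segmentation is scored as
pixel agreement with the planted collagen mask through the full pipeline
(mask → fit → threshold); ≥ 98% agreement across ten seeded scenes.
Morphometry is scored on planted ground-truth masks — regression slopes of
measured CFL and CFT on planted length and thickness within [0.9, 1.1]
across twenty single-fiber scenes spanning 30–200 px length and 2–8 px
thickness — so the estimator is not conflated with the threshold-dependent
binary width, which the agreement criterion already bounds. Topology is
exact: a plus-cross yields one junction and four branches; k
well-separated planted crossings yield exactly k junction clusters; a
straight fiber has CRI 0. Compartment separation must reach Jaccard ≥ 0.9
against the planted aggregate with every isolated fiber in DTC. Survival
machinery must match hand-computed product-limit and log-rank values on
small toys exactly, and the percentile scan must recover a cutpoint
planted at the 40th percentile with hazard ratio 2.5 (n = 200) in at
least 80 of 100 replicates.

Numerical details that matter:

* Coordinates are 1-based (row, col) matrix indices throughout, the native
  R convention.
* EM subsamples uniformly (seeded) above 10^6 pixels; the variance floor
  is 10^-6 of the sample variance.
* The threshold root is found by `uniroot` on the log-density difference
  between the means, tolerance 1e-10; ties in the cutpoint scan break
  toward the lower threshold.
* EBImage's grayscale morphology expects intensities in [0, 1]; the
  opening normalizes by the image maximum and rescales, which is exact
  because rank filters commute with positive scaling.
* Problem sizes in the tests and the acceptance script (256–420 px
  frames, 10–40 scenes per experiment, 100-replicate cutpoint
  simulations) were chosen as the smallest sizes at which the Monte-Carlo
  error of each checked quantity is comfortably below its tolerance.

# Known limitations

* Rotation stability of CFL and CRI holds to the stated tolerances on
  networks whose crossings are well separated and not too shallow; at
  near-tangential crossing angles the direction-dependent thinning can
  flip a borderline junction-cluster merge and move branch-based CFL by a
  few percent. CAR and CFD are exactly rotation invariant; CFT is stable
  via the ridge read.
* The geodesic length metric biases CFL upward by up to 8% for oblique
  straight fibers; comparisons *between* samples are unaffected because
  the bias depends only on orientation distribution.
* The cutpoint scan's selected p-value must not be read as a calibrated
  test; it is a descriptive minimum over nine candidates, as its
  multiplicity warning states. A resampling-honest variant is a natural
  extension and is deliberately not bundled into the default scan.
* Whole-slide (pyramidal) images, 3D stacks and fiber orientation
  statistics are out of scope.
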