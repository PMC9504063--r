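---
title: "Methods: segmentation, morphometrics and shape modes in mgmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, morphometrics and shape modes in mgmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgmorph)
```

`mgmorph` quantifies microglial morphology in 2-D fluorescence micrographs.
This vignette is the package's own account of what each stage assumes and
computes, which parameters matter, and where genuinely open design choices
were resolved — and how.

## Segmentation model and assumptions

A micrograph is a non-negative intensity raster with a known pixel scale
(default 0.575 px/µm, a 63x confocal calibration). Segmentation assumes:

* staining is bright on a darker background, so a single global threshold
  separates cells from background;
* cells of interest exceed a physical minimum area (default 800 µm², half
  the ~1600 µm² literature size of a microglial cell, chosen as a lower
  bound so no true cell is excluded);
* touching cells need not be split — the method counts separable cells and
  removes ambiguity at the border instead of resolving it.

The stages run in a fixed order: Gaussian blur → global threshold → strict
binarization (`pixel > threshold`) → small-object removal → hole filling →
border clearing → relabeling in reading order. The cleaning order matters
and is tested: a sub-threshold ring must be removed *before* hole filling
could inflate it past the cutoff.

Key parameters:

| parameter | default | units | role |
|---|---|---|---|
| `blur_sigma_px` | 0.25 | px | denoising before thresholding; sub-pixel, nearly identity, kept for fidelity to the established workflow |
| `threshold_method` | mean | — | arithmetic mean of all intensities; six histogram methods available for the comparison panel |
| `min_cell_area_um2` | 800 | µm² | physical small-object cutoff; 265 px at 0.575 px/µm |
| `connectivity` | 8 | — | thin diagonal branches must stay attached to their soma |

Numerical choices worth knowing:

* **Cutoff rounding is half-up.** 800 · 0.575² = 264.5 px; half-up gives
  265, banker's rounding would give 264. The product is additionally
  rounded to 9 decimals first because 0.575² in doubles lands fractionally
  below 264.5.
* **Binarization is strict (`>`)**, so a constant image thresholded at its
  own mean yields an empty foreground rather than an all-foreground mask.
* **Blur boundaries are half-sample symmetric (reflect).** With a
  normalized symmetric kernel this conserves total intensity exactly, so
  frame edges do not darken and bias the mean threshold. The kernel radius
  is `ceiling(4σ)`.
* **Histogram methods use 256 bins** over the intensity range. Otsu
  reports the midpoint between the two classes it separates, so strict
  binarization reproduces its optimal split exactly; on histograms with an
  empty valley any threshold inside the valley is equally optimal and the
  induced masks, not the threshold values, are the comparable quantity.
* **Degenerate inputs**: histogram methods raise a parameter error on
  constant images; the mean method still returns the constant (empty
  foreground). In the try-all panel these become per-method annotations,
  not failures.

## Per-cell features

Area is the pixel count (and `area / s²` in µm²). Solidity is pixel count
over convex-hull pixel count, where the hull is taken over pixel centers
and hull membership is boundary-inclusive; collinear (1-px-wide) regions
get solidity 1. Aspect ratio comes from the second central moments of the
pixel coordinates with the 1/12 per-pixel variance term, so single-pixel-
wide regions stay finite. Regions under 3 pixels cannot form a hull; they
are flagged `degenerate`, excluded from downstream statistics, and counted.

The perimeter estimator is genuinely underdetermined in common practice, so
both conventions are available:

* `weighted` (default): length of the ordered boundary-pixel walk, axial
  steps 1, diagonal steps √2 — the polygon-perimeter convention of
  mainstream region-property tools;
* `crack`: the count of exposed pixel edges, exactly hand-checkable (a 3×3
  square has crack perimeter 12 and walk perimeter 8).

Circularity `4πA/P²` is reported unclamped: rasterized near-discs can
slightly exceed 1 under some estimators, and clamping would hide estimator
bias. Both features are dimensionless and identical in px or µm — this is
tested, as is exact agreement of area, hull count and crack perimeter with
brute-force enumeration on all 307 fixed polyominoes of up to 6 pixels.

Density is cells per field area, default mm². Counts per µm² of a confocal
field are ~10⁻⁵-scale numbers; mm⁻² keeps densities in a readable range.

## Shape modes

Every cell's outer boundary is traced along pixel cracks as a simple closed
polygon (counter-clockwise; at diagonal pinch points the polygon touches
itself so that the whole 8-connected region stays enclosed), resampled to
`n_points = 50` equal-arc points starting from the vertex farthest from the
centroid (ties broken by polar angle), and registered: centroid to the
origin, second-moment major axis horizontal, the 180° ambiguity resolved by
putting the farthest point in the right half-plane. Nearly circular
contours, whose axis is undefined, are left unrotated.

**Correspondence alignment.** Registration alone leaves a large nuisance
term: for branched, nearly symmetric outlines the major axis and the
farthest-point start are close to arbitrary, so the same physical shape
appears at many rotations/start shifts and that phase — not shape —
dominates the coordinate variance. Before PCA the package therefore aligns
each contour to the (iteratively refined) mean shape by full planar
Procrustes over all cyclic start shifts, each with its closed-form optimal
rotation; scale is never touched. The reference shape is stored in the
model and prediction aligns new contours to it, which makes assignments
invariant to translation and rotation of the input (tested).

**Embedding and clustering.** PCA retains the smallest number of leading
components reaching 95% cumulative variance (configurable); component
signs are canonicalized (largest-magnitude loading positive) so centroids
do not depend on eigenvector sign conventions. k-means uses k-means++
seeding with 50 restarts and keeps the best within-cluster sum of squares;
the tool this emulates is stochastic and unspecified, and restarts
stabilize mode identity. Defaults: `k = 5` modes, 80:20 stratified
train:test split (per-group `round(0.8 n)`; groups under 2 cells go wholly
to test, logged).

Open choices and how they were resolved:

* **No scale normalization by default**: shape modes are meant to separate
  on size as well as shape (amoeboid vs hypertrophic cells differ in area);
  `normalize_scale = TRUE` reduces them to pure shape.
* **Cluster on PC scores, not raw coordinates**: keeps k-means
  well-conditioned in ~10–25 dimensions instead of 100.
* **Mode labels are renumbered by increasing mean aspect ratio** of member
  contours, so SM1…SMk mean the same thing across runs and seeds; an
  average-linkage dendrogram over centroids records mode relatedness.
* **One global stratified split** rather than independent per-group splits:
  a single model sees every group's training share, and each group's test
  cells are scored against the same modes.
* **Assignment ties** (equidistant centroids) go to the lower SM index.

Frequency tables report, per group, the percentage of test cells in each
mode (rows sum to 100 within 1e-6) plus the sample variance (n−1
denominator, the spreadsheet VAR convention) of the k percentages — a
concentration measure: a group living in one mode has variance
`var(c(100,0,0,0,0)) = 2000`, a uniform group 0.

## The statistical battery

* `welch_or_student_t()` runs the F-test of variances first and applies
  Welch's correction when its p < 0.05. The always-Welch default is the
  statistically cleaner choice, but the gate reproduces the common
  Prism-style workflow this package mirrors; both component results are
  returned so the pretest can be bypassed.
* `f_test_variance()` uses larger-over-smaller variance with matched
  degrees of freedom and a two-sided p (twice the upper tail, capped at 1).
* `kruskal_dunn()` wraps the tie-corrected Kruskal–Wallis H and implements
  Dunn's pairwise z-tests with the usual tie term; the family-wise
  adjustment default is Holm (uniformly more powerful than Bonferroni,
  which is available, as is no adjustment). The adjustment method is not
  fixed by convention in this workflow, so it is a documented default.
* `normality_suite()` runs D'Agostino–Pearson K² (transformed skewness and
  kurtosis; implemented from the standard formulas and cross-checked
  against an independent implementation), Anderson–Darling, Shapiro–Wilk,
  and Kolmogorov–Smirnov *with the Lilliefors correction* — the normal
  parameters are estimated from the sample, and the uncorrected KS null
  would be badly conservative. Samples under n = 8 run the subset of tests
  their small-sample theory supports, with a logged skip. QQ data pairs the
  sorted sample with standard normal quantiles at `(i − 0.5)/n`.
* `ddct_fold_change()` averages replicate Cts per well set, forms
  ΔCt = target − reference per sample, centers on the *mean* ΔCt of the
  control group (mean vs median is unspecified in common usage; mean makes
  the control group's geometric-mean fold exactly 1, which is tested), and
  reports 2^−ΔΔCt.

All three null calibrations (t/Welch gate, F, Kruskal–Wallis) are verified
by 10,000-replicate simulations in the test suite, with rejection rates
required to fall in [0.04, 0.06] at α = 0.05.

## What the synthetic generator emulates — and what it does not

`cohort_spec()`/`generate_cohort()` emulate 63x confocal Iba-1 fields:
bright cell silhouettes on a dim noisy background at 0.575 px/µm, with
planted group differences in density and shape-class mixture. Cells are an
elliptical soma (area-preserving elongation) plus branches grown as
unit-step random walks from the soma boundary with heading jitter
proportional to `tortuosity`, dilated to the branch width. Built-in
classes: `amoeboid_class()` (~1600 µm² ellipse, the literature cell size)
and `ramified_class()` (smaller soma, four ~28 µm processes). Placement is
rejection sampling (100 tries per cell) of expanded bounding boxes kept
fully inside the field, so planted cells never touch the border and
neighbours stay separable — matching the counting method's assumptions.
Intensity is background (0.05) + 0.8 on cell pixels, an optional PSF-like
blur (σ = 1 px), then Gaussian noise (sd 0.01), clipped to [0, 1]. The
background and noise defaults keep the mean threshold comfortably above
background even in sparse fields, the regime bright immunostaining
operates in; a global mean threshold degrades sharply once the
background-to-threshold margin shrinks toward the noise scale, which is a
property of the method worth knowing before applying it to dim data.

All randomness flows through one seed hierarchy (cohort seed → per-image
seeds → per-cell seeds), so any single image can be replayed bit-exactly.

The generator does **not** emulate: 3-D stacks or out-of-focus light, a
full PSF model, intensity variation within cells, autofluorescence
gradients, touching/overlapping cells, or a second (DAPI) channel.
Passing tests therefore demonstrate correctness of the pipeline's
geometry, bookkeeping and statistics under controlled conditions — not
segmentation robustness on low-SNR or densely packed real tissue.

## Problem sizes and determinism

The validation suite uses, as the package's chosen working points: 20
noiseless 512×512 fields of ~15 cells for segmentation recovery (≥95%
recall, zero spurious labels); 400 cells (two planted classes) for k = 2
shape-mode recovery at adjusted Rand index ≥ 0.9 and five classes at
k = 5 for ARI ≥ 0.7; 10,000-replicate null simulations for the test
calibrations; and a two-group cohort run twice end-to-end to confirm the
CSV outputs are byte-identical under a fixed seed.

## Known limitations

* The mean threshold is global; uneven illumination or sparse dim fields
  will shift it. The try-all panel exists precisely to sanity-check the
  choice per dataset.
* Touching cells are not split; merged cells appear as one large object.
* The crack-contour start point and the 180° registration rule are
  conventions; any fixed convention works, and the Procrustes alignment
  absorbs most of what they leave over.
* Shape modes are a clustering, not a biological taxonomy: k is a choice,
  and mode identity is stabilized (aspect-ratio ordering, seeded restarts)
  rather than canonical.
* ΔΔCt assumes near-perfect amplification efficiency for both genes;
  efficiency correction and replicate-outlier rejection are out of scope.
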