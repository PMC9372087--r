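---
title: "Evaluating auto-segmented radiotherapy structures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating auto-segmented radiotherapy structures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a deep-learning model delineates radiotherapy planning structures —
the clinical target volume (CTV) and the organs at risk (OARs) — two
questions matter clinically. First, how close are the auto contours to the
reference manual contours geometrically? Second, and more importantly, if
the auto contours are dropped into the *existing* treatment plan (the dose
distribution optimized on the manual contours), how much do the dose-volume
indices read off those contours change? A contour can look acceptable by
overlap metrics yet move a dose readout enough to matter, and vice versa.

`rtseval` implements that evaluation workflow end-to-end for a pelvic
(cervical-cancer-like) structure set: nine structures (CTV, spinal cord,
left/right kidney, bladder, left/right femoral head, pelvic bone, rectum),
geometric agreement metrics, a DVH engine with the standard pelvic
constraint set, and the comparison statistics. Because clinical imaging
cannot ship with a package, it also provides a synthetic phantom cohort
generator and a small encoder-decoder segmentation network so the whole
pipeline — including "segment, then evaluate" — runs on generated data.

## Geometric metrics

For binary masks \(A\) (reference) and \(B\) (test) on one grid:

* Dice similarity coefficient \(\mathrm{DSC} = 2|A\cap B|/(|A|+|B|)\)
* Jaccard coefficient \(\mathrm{JC} = |A\cap B|/|A\cup B|\)
* Hausdorff distance
  \(\mathrm{HD} = \max(h(A,B),\, h(B,A))\) with directed distance
  \(h(A,B) = \max_{b\in B}\min_{a\in A}\lVert a-b\rVert\) over surface
  points, in physical millimetres.

Design choices the metrics literature leaves open, fixed here:

* **Surface definition.** A voxel is a surface voxel iff it is inside the
  structure and at least one of its six face-neighbors is outside; the
  volume border counts as outside. This is the most common convention and
  makes small closed-form cases exact (a solid 3×3×3 cube has 26 surface
  voxels).
* **Percentile Hausdorff.** The 95% HD replaces each directed maximum with
  the 95th percentile of that directed distance distribution (computed per
  direction, then the maximum of the two), using linear interpolation
  between order statistics (R's default quantile type 7). This matches the
  dominant convention in the segmentation literature; the tests pin it to
  an exhaustive all-pairs oracle.
* **Distances are exact.** Surface-to-surface distances are computed with a
  Felzenszwalb–Huttenlocher Euclidean distance transform extended to
  anisotropic spacing (implemented in C++ in `src/`). Distances go to the
  nearest surface-voxel *center*, which is exactly the all-pairs
  point-set distance, so the implementation is bit-comparable to the brute
  force oracle; no installed R package provides a 3D anisotropic EDT.
* **Degenerate input.** Metrics on two empty masks raise an error rather
  than returning a conventional value; empty or missing structures in a
  cohort evaluation are flagged rows, never silent drops. Masks are never
  cropped before comparison.

## Dose-volume indices

Doses are carried in cGy throughout. The cumulative DVH uses 1 cGy bins by
default — at prescriptions of 4500–5040 cGy the interpolation error of any
percentile-type index is then far below a clinically meaningful difference,
and the tests bound it by one bin. Indices:

* `D_mean`, `D_max`: mean/maximum of in-structure voxel doses, computed on
  the voxels, not the binned curve (`D_max` is the literal maximum, kept
  distinct from `D_0.03cc`).
* `D_x%` / `D_x cc`: minimum dose to the hottest x% (or x cc), by linear
  interpolation on the cumulative curve.
* `V100`: percent of the structure receiving at least 100% of
  prescription (relative volume).

The constraint table mirrors standard pelvic EBRT planning: CTV
`D99% > prescription` and `D_max < 110%`; spinal cord `D_max < 4000` cGy;
kidney `D_mean < 1200` cGy; bladder and rectum `D50% < 100%` and
`D0.03cc < 110%` of prescription; femoral head `D15% < 3000` and
`D_mean < 2000` cGy; pelvic bone `D_mean < 3000` cGy. Small intestine is
not evaluated.

The paired evaluation enforces the *transmit-into-original-plan* protocol
structurally: the dose grid is computed once (for the synthetic cohort,
from the manual contours) and frozen; auto contours only ever re-read that
grid. Masks are binary — no partial-volume voxel weighting — and when dose
and mask grids differ the dose is resampled to the mask grid by trilinear
interpolation (nearest-neighbor for masks), so structure boundaries are
never degraded by resampling.

## Statistics

* **Bland–Altman.** Differences `auto − manual` per case; bias ± 1.96·SD
  (sample SD) gives the 95% limits of agreement. The P-value for zero bias
  is a two-sided one-sample t-test, preceded by a Shapiro–Wilk normality
  check at α = 0.05: when normality fails the agreement call is reported as
  not applicable, because a t-based bias test is not trustworthy for
  clearly non-normal differences. `P > 0.05` (with normality holding) is
  read as agreement between the two segmentation methods.
* **Wilcoxon paired signed-rank.** Zero differences dropped, midranks for
  ties. Up to 25 nonzero differences the two-sided P is exact by
  dynamic-programming enumeration of all sign assignments (doubling the
  midranks makes them integers, so ties are handled exactly); beyond that,
  the normal approximation with tie-corrected variance and continuity
  correction. The Z statistic reported alongside always comes from the
  normal approximation, as commonly printed.
* **Spearman.** Pearson correlation of midranks with the two-sided
  t-approximation for P. Correlations of geometric metrics (DSC, 95%HD,
  JC) against per-case dosimetric differences are tabulated per structure
  and metric of record; `|r| ≥ 0.8` is labelled strong.
* **ΔDose.** The dosimetric difference is the magnitude `|auto − manual|`:
  a signed difference would make "better overlap ↔ smaller difference"
  incoherent across structures, and magnitudes are what the correlation
  analysis needs.
* No multiple-testing correction is applied (per-structure reporting);
  this is recorded in the report metadata.

## The synthetic cohort

Each phantom is a 64×64×24 grid at (2, 2, 5) mm — deliberately
anisotropic, mirroring thick-slice pelvic CT, and small enough that a
30-case cohort evaluates in about a minute. Structures are parametric
solids (ellipsoidal kidneys/bladder, tubular rectum and cord, spherical
femoral heads, a ring-like pelvic bone, a union-of-ellipsoids CTV) with
per-case jitter in position and size, carved to mutual disjointness. The
CT-like image gives every structure a distinct mean intensity plus
Gaussian noise (SD 5 at contrasts ≥ 20), which makes segmentation
intentionally *easy*: the phantom exists to exercise the pipeline, not to
pose a hard vision problem.

The "auto" arm perturbs each manual mask independently through its signed
distance field: a Gaussian rigid shift, a signed dilation/erosion draw, a
spatially correlated boundary-displacement field (8 mm correlation
length), and optional deletion of the superior/inferior border slice —
the error modes reported for encoder-decoder auto-segmentation, including
systematic border over/under-reach. The default magnitudes were calibrated
once so a default cohort reproduces the fidelity profile typical of pelvic
auto-segmentation — kidneys ≈ 0.93–0.95, bladder ≈ 0.91,
femoral heads ≈ 0.88, CTV ≈ 0.76, spinal cord ≈ 0.75, rectum ≈ 0.72,
pelvic bone ≈ 0.65 in mean DSC — and then frozen; the ordering (not the
absolute values) is the regression target.

The dose surrogate is geometric, not a physics calculation: prescription ×
1.04 inside the CTV expanded by a 5 mm margin, Gaussian falloff (σ =
13 mm) outside, times a smooth multiplicative noise field (SD 0.5%).
Parameters were chosen once from the phantom geometry so that the manual
contours satisfy every constraint in the table above (the femoral-head
mean-dose bound is the binding one) and manual CTV V100 = 100% by
construction. Prescription defaults to 4500 cGy in 25 fractions.

What the phantoms do *not* emulate: CT texture and HU calibration,
deformable anatomy, inter-observer variability, realistic beam physics.
Passing tests on phantoms therefore demonstrates the correctness of the
metrics, DVH arithmetic and statistics, and the qualitative behavior of
the workflow — not clinical performance of any segmentation model.

## The segmentation network

A compact 2D encoder-decoder: an input projection, three encoder levels
(3×3 stride-1 convolution → batch normalization → ReLU → 2×2 max-pool),
three decoder levels (2×2 stride-2 transposed convolution → concatenation
with the same-level encoder features → convolution block), and a
pixel-classification head; softmax cross-entropy loss; cut (random shift
with zero padding) and flip augmentation. Channel widths default to
(16, 32, 64) and all stochastic choices are fixed by the training seed.
Volumes are segmented slice-by-slice and reassembled.

Engineering decisions worth recording:

* The network is implemented in base R matrix algebra (im2col convolutions
  backed by BLAS, with a finite-difference-verified backward pass). It is
  a deliberately small educational implementation sized for CPU training
  on phantom slices in minutes.
* Pixel classes are wildly imbalanced (background ≈ 90%), so training
  weights each class by the inverse square root of its pixel frequency by
  default; plain cross-entropy is available (`class_weighting = "none"`)
  but converges much more slowly on the rare structures.
* A horizontal flip mirrors lateralized anatomy, so paired "… L"/"… R"
  classes swap labels under the flip. Without the swap, flip augmentation
  actively teaches left/right confusion.
* Optimizer (Adam, lr 5·10⁻³ in the examples), epochs and channel widths
  are declared defaults chosen for phantom convergence; no claim is made
  of reproducing any clinical training regime, and clinical-scale DSC
  values are out of scope by design.

## Problem sizes and reproducibility

Defaults used by the shipped tests and the acceptance script: 30-case
cohorts for the statistics and fidelity-profile checks, 10 cases for the
end-to-end identity check, 20 training slices / 60 epochs for the
segmenter check, 2000 replicates for the Wilcoxon type-I-error
calibration and 1000 differences for the Bland–Altman coverage check.
Every stochastic artifact is a pure function of the seeds in the
configuration objects; rerunning a configuration reproduces its CSV
outputs byte-for-byte.

## Known limitations

* NIfTI is the supported volume format; DICOM-RT export/import is out of
  scope.
* The DVH model is binary-mask based; no partial-volume weighting.
* Bland–Altman limits come without confidence intervals, and no
  proportional-bias regression is fitted.
* The dose surrogate supports comparative evaluation only; absolute
  dosimetry on phantoms has no clinical meaning.
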