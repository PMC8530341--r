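---
title: "Morphometric and shape-encoding biomarkers of knee osteoarthritis: models and methods"
author: "kneemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric and shape-encoding biomarkers of knee osteoarthritis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Knee osteoarthritis (KOA) is graded clinically on ordinal scales — the
Kellgren-Lawrence grade (KLG, 0-4) and medial/lateral joint space narrowing
(mJSN/lJSN, 0-3) — and hard endpoints such as total knee replacement (TKR).
Given labeled 3-D segmentations of six knee structures (femoral bone FB,
tibial bone TB, femoral cartilage FC, medial/lateral tibial cartilage
mTC/lTC, medial/lateral meniscus mM/lM), this package computes two families
of quantitative candidate biomarkers and evaluates how well each family
classifies the current grade and predicts incident KOA or TKR:

* **MEAS** — 14 direct measurements: height-normalized volumes of FC, total
  TC, mTC, lTC, mM, lM (mm³/m); meniscal surface areas (mm²); meniscal
  area-to-volume ratios (1/mm); medio-lateral meniscal extrusions (mm); and
  tibial coverages (% of the tibial-cartilage footprint covered by the
  meniscus).
* **LDSE** — a low-dimensional shape encoding: per structure, a statistical
  shape model (Procrustes mean plus orthonormal variation modes ordered by
  explained variance) is fitted on the cohort and each knee is encoded by
  its leading mode coefficients. Per-structure encodings keep up to 300
  coefficients; the combined encoding (`LDSE-COMB`) concatenates the first
  75 coefficients of FB, TB, mM and lM into a 300-vector.

Because the clinical image data behind this problem are access-restricted,
the package ships a synthetic cohort generator that emulates the study
design end to end, so every stage is testable without any download.

## Geometry layer

Volumes are counted **directly on the labeled voxels** (count × voxel
volume); surfaces are used only where an area is needed. Boundary surfaces
are extracted by marching tetrahedra (the six-tetrahedra Kuhn decomposition
of each grid cell, which is conforming across cells and invariant under
axis permutations) at the 0.5 iso-level of the binarized label.

One numerical choice deserves emphasis: the binary indicator is smoothed
with a small Gaussian (default σ = 0.5 mm, a physical scale independent of
the grid) before iso-surfacing. The iso-surface of a *raw* binary mask
carries 45° staircase facets whose total area overestimates a smooth
boundary's area by roughly 10% regardless of resolution; with the 0.5 mm
pre-smoothing the surface area of a voxelized sphere (r = 10 mm, 0.5 mm
spacing) is recovered to about 0.03% and its enclosed volume to well under
1%. The cost is slight rounding of genuinely sharp edges (a 10 mm cube at
1 mm spacing loses about 2% of its mesh-enclosed volume — volumes are
measured on voxels, so this affects only the mesh oracle). Mesh-level
smoothing or decimation is never applied.

Voxelization of closed meshes uses even-odd ray parity per voxel column
with the interval closed on the left, so an axis-aligned 10 mm cube at 1 mm
spacing contains exactly 1,000 voxel centers. Structures must be disjoint;
a voxel claimed by two meshes is an error naming the pair.

## MEAS definitions

* **Extrusion** is operationalized as the maximum over antero-posterior
  rows of the medio-lateral overhang of the meniscus footprint past the
  plateau footprint (TB ∪ compartment TC) in axial projection, on the
  compartment's outer side, clamped at 0. The side flag of the volume
  decides which direction is "outer". The exact reference construction in
  the clinical literature varies (bone edge vs cartilage edge, single slice
  vs 3-D); this contract is the normative definition for this package and
  it is exactly what the generator plants, so recovery is testable to one
  voxel.
* **Coverage** is the percentage of compartment tibial-cartilage voxel
  columns overlapped by meniscus columns. Footprints are computed on voxel
  columns, not meshes: exact, fast, and resolution-tied.
* Volumes are normalized by subject height in metres (mm³/m); the
  area-to-volume ratio uses the raw volume. A missing or non-positive
  height marks the dependent features missing; rows with missing features
  are dropped at evaluation time, mirroring the discard rule used with
  missing clinical labels.

## Shape model

Corresponded shapes (identical triangulation across a cohort) are aligned
by generalized Procrustes analysis with **rigid** transforms — rotation and
translation, no scaling — iterated to a mean-movement tolerance of 1e-6 mm.
Scale is retained deliberately: size change (e.g. osteophytes) is
osteoarthritis-relevant signal. Left knees are mirrored to the right-knee
convention before alignment because a rigid alignment cannot absorb a
reflection.

The model is a tangent-space principal component analysis about the
Procrustes mean: modes are eigenvectors of the centered vertex-coordinate
covariance, ordered by variance, signs fixed so each mode's
largest-magnitude component is positive. This linearization of Riemannian
shape statistics agrees with the manifold treatment to first order for
desk-scale deformations and has an exact eigen-oracle for testing. The
retained mode count is `min(300, n - 1, 3V - 7)`; blocks shorter than 75
are zero-padded only when building the combined encoding.

A Procrustes mean is defined only up to a global rotation, so fitted modes
live in an arbitrary frame; `align_model_frame()` re-expresses a model in a
reference frame (e.g. the generator template) for coefficient-wise
comparisons. Encodings and variances are frame-invariant.

Each visit's cohort is modelled independently — no state is shared across
cohorts, avoiding inter-subject correlation across repeated scans of the
same knees.

## Evaluation harness

Tasks follow a fixed grid: KLG 5-class, 3-class ([0;1] vs 2 vs [3;4]),
binary ([0;1] vs [2;3;4], 0 vs 2, 0 vs 4); mJSN and lJSN 4-class; incident
KOA (reaching KLG ≥ 2 with JSN, among knees with baseline KLG < 2) and TKR
within 1-5 years. Feature sets are MEAS, the four per-structure LDSE sets,
LDSE-COMB, and any of these concatenated with MEAS (`"LDSE-COMB + MEAS"` is
314-dimensional).

Evaluation is balanced Monte-Carlo cross-validation: per repeat, every
class is subsampled without replacement to the minority class size, split
90/10 stratified by class, min-max normalized on the training split
(held-out values may leave [0, 1]; constant features map to 0), and
classified with a linear support vector machine at default regularization
(`cost = 1`; multi-class one-vs-rest with arg-max over margins). The
balancing is re-drawn in every repeat. Each repeat draws from its own child
seed spawned by the master seed, so any single repeat is reproducible in
isolation. Defaults are 1,000 repeats at 10% test fraction; the bundled
demonstrations use 50 repeats at n = 300 so the full pipeline runs on a
laptop in minutes.

Metrics: balanced accuracy (macro-recall, the multi-class generalization
consistent with (sensitivity+specificity)/2), weighted kappa for ordinal
agreement (linear disagreement weights by default, quadratic selectable —
the weighting is reported with results), and ROC AUC computed from the
SVM decision margins via the Mann-Whitney formulation with ties counted as
one half (hard labels would waste the threshold information).

Feature importance for TKR uses maximum-likelihood logistic regression on
the MEAS features, standardized to unit SD so the per-feature odds ratios
are comparable across units (mm³, mm, %); Wald 95% intervals; perfect
separation is flagged per feature with an unbounded interval. Whether
clinically reported odds ratios are per raw unit or per SD is often
ambiguous; this package fixes per-SD and documents it.

## The synthetic cohort generator

Each knee carries a scalar latent severity `s ~ Uniform(0, 1)`. Shapes are
template meshes (ellipsoidal bones with condyle bumps, thin ellipsoidal
cartilage slabs, C-shaped capped-torus menisci in a shared anatomical
frame) plus two deformation sources:

1. **Random variation modes** — per structure, smooth orthonormal
   displacement fields (random combinations of low-order polynomial fields
   projected orthogonal to the rigid-motion tangent space, so Procrustes
   alignment leaves them intact), with strictly descending coefficient SDs
   (default 4, 3, 2, 1.5, 1 mm in the unit-norm convention). The planted
   spectrum is the ground truth that shape-model recovery tests check.
2. **Severity-coupled deformations** — cartilage thinning (volume fraction
   0.35·s), medial meniscal extrusion (4 mm·s) and volume-preserving
   flattening (height loss 0.25·s, width widened to conserve volume),
   lateral meniscal extrusion (2 mm·s, no shape change), and marginal bone
   bumps on FB (2 mm·s) and TB (1.5 mm·s). Each structure reads the knee's
   severity with independent Gaussian noise (SD 0.15): structures progress
   at different rates, which is exactly why combining encodings of several
   structures outperforms any single one. The lateral meniscus deforms only
   by translation, which rigid alignment removes — its encoding is a
   deliberately decoupled negative control for prediction tasks.

The medial meniscus template's outer rim is calibrated to touch the
tibial-plateau footprint edge at the central AP row, so baseline extrusion
is exactly zero and a planted shift is recovered one-to-one (±1 voxel).

Grades are thresholded noisy severity (ordered-probit style; KLG cuts at
0.2/0.4/0.6/0.8, reading noise SD 0.05, an optional 2% of knees with
missing grades to exercise the discard path). Events follow a logistic link
on severity with per-horizon intercepts; one latent uniform per knee and
outcome nests events across horizons (an event within 1 year implies the
event within 5). Event rates are deliberately higher than observational
cohorts report (tens of events at n = 300) so that balanced splitting is
feasible at demonstration scale; incident KOA at clinical incidence would
need tens of thousands of knees. Heights are Normal(1.68 m, 0.09 m),
truncated at 1.40 m. Sides are drawn 50/50 and left knees mirrored on the
medio-lateral axis, so side-handling code paths are exercised throughout.

**What the generator does not emulate:** MRI intensities and contrast,
segmentation errors, longitudinal within-knee trajectories, multi-factor
disease processes, or realistic grade distributions. Passing tests
demonstrate that the pipeline recovers planted geometry and planted
statistical structure — not that the features would attain any particular
accuracy on clinical data.

## Numerical choices and degenerate inputs

* Ray casting uses tiny irrational offsets of the ray origin so rays never
  hit mesh edges of rationally-placed geometry; crossing intervals are
  closed on the left.
* Surface extraction of a structure touching the volume border yields an
  open mesh; enclosed-volume computation refuses open meshes.
* A reflection of the voxel grid re-orients the tetrahedral decomposition,
  so surface-derived features of mirrored volumes agree to voxel tolerance
  (relative ~1e-3), not machine precision; voxel-counting features agree
  exactly.
* `weighted_kappa` is undefined (error) when both vectors are constant;
  balanced accuracy errors on a class with no true cases; AUC errors when
  one class is absent.
* Null calibration of the cross-validated SVM must re-permute labels in
  every repeat: a single fixed permutation retains a chance feature-label
  correlation that cross-validation legitimately detects, biasing the
  repeat-mean away from 1/k.
* Shape-model fits drop numerically-zero variances (relative 1e-12) so an
  all-identical training set yields a modeless model rather than noise
  modes.

## Problem sizes

The bundled demonstrations and checks use: spheres at 0.5 mm spacing for
morphometry oracles; planted-mode cohorts of 50-200 shapes; a 300-knee
cohort at 1 mm spacing with 50 Monte-Carlo repeats for the end-to-end
evaluation; 10,000 draws for chance-level agreement; 100 seeds × 5,000
observations for odds-ratio recovery. These sizes were chosen so the whole
suite runs in a few minutes on one CPU while keeping Monte-Carlo error well
below the effect sizes being checked.

## Known limitations

* Correspondence establishment is out of scope: real meshes must already
  share a triangulation (the generator guarantees it; clinical surfaces
  would need groupwise registration first).
* The linear SVM is the libsvm hinge-loss machine at `cost = 1`; the
  squared-hinge variant differs only in loss shape, not in the evaluated
  properties.
* Absolute surface-area values are implementation-relative (they depend on
  the extraction algorithm and smoothing scale); comparisons should use
  features computed by one pipeline version, which the feature-table
  provenance hash enforces.
* Extrusion is clamped at zero; medial "intrusion" is not measured.
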