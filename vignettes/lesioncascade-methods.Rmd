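---
title: "Multi-instance lung lesion segmentation with cascade false-positive reduction"
author: "lesioncascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-instance lung lesion segmentation with cascade false-positive reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Automatic delineation of *all* lung lesions in a thoracic CT scan — not
just the primary tumor — supports tumor-burden quantification, treatment
planning and longitudinal response assessment. Segmentation networks solve
most of this problem but leave two characteristic failure modes:

1. **Preprocessing failures.** Cropping the scan to a lung mask saves
   computation and removes irrelevant anatomy, but density-based lung
   segmentation excludes large masses and wall-attached lesions (they are
   soft-tissue dense, not aerated parenchyma), so a naive lung-mask crop
   truncates exactly the lesions that matter most.
2. **False-positive candidates.** Instance-labeled predictions contain
   spurious candidates: structures outside the lungs entirely, and
   intrapulmonary mimics (vessels, scarring, noise responses).

`lesioncascade` implements a three-stage pipeline addressing both:

* **Stage 1 — thoracic bounding box.** The tight box around a lung mask,
  with a per-dimension minimum-size fallback: if the box is smaller than
  the smallest plausible adult lung extent along an axis (210, 150 and
  120 mm for x, y, z), the whole image is used along that axis instead.
  The rule is per-axis, idempotent and extensive (the result always
  contains the input box), and an empty lung mask (total masker failure)
  maps to the full image.
* **Stage 2 — multi-instance segmentation.** A pluggable binary
  segmentation backend runs on the crop; foreground components are
  labeled by a conventional 3-D connected-components pass with
  26-connectivity, and the labeled mask is padded back to the original
  grid. No size filtering happens here: false positives are removed by
  classification, not by ad hoc cutoffs.
* **Stage 3 — cascade false-positive reduction (CFPR).** Each candidate
  is scored by two classifiers operating on (raw, candidate-mask) patch
  pairs. The *extrapulmonary classifier* (XPC) sees the full coronal
  slice through the candidate centroid, resampled to 128×128 at 1×1 mm —
  the full plane, because judging whether a candidate lies outside the
  lungs requires body context. A candidate whose extrapulmonary score
  `1 − P(lesion)` reaches `thr_e` is removed. Survivors are validated by
  the *lesion validator* (LVC) on a 96 mm cube centered on the candidate,
  resampled to 96³ at 1 mm isotropic; candidates whose lesion probability
  does not surpass `thr_i` are removed. The cascade only ever deletes
  candidates, so the no-cascade pipeline is recovered exactly with
  sentinel thresholds (`thr_e > 1`, `thr_i < 0`).

The five ablation pipelines (`LLS`, `LLSB`, `LLSB_XPC`, `LLSB_LVC`,
`LLSB_CFPR`) differ only in stage toggles (`ablationConfig()`), which
gives the lattice guarantee `foreground(LLSB_CFPR) ⊆ foreground(LLSB_XPC)
⊆ foreground(LLSB)` for fixed classifiers and thresholds.

# Conventions that matter

* Grids are `(x, y, z)` = (left–right, anterior–posterior,
  inferior–superior); NIfTI volumes with a recognizable orientation are
  reoriented to RAS on load. Voxel `(i, j, k)` (1-based, R convention) has
  its center at `origin + (c(i,j,k) − 1) * spacing` mm.
* Bounding boxes use 1-based inclusive corners, so the physical side
  length is `(hi − lo + 1) * spacing`. The fallback minima are compared in
  millimetres, not voxels — spacing varies several-fold across scanners,
  so a voxel-count comparison would be meaningless.
* Classifiers output `P(class 1)` with class 1 = "true lesion", matching
  the candidate-labeling convention (a candidate is labeled 1 iff its best
  Dice overlap with any ground-truth lesion is positive). The XPC gate
  thresholds the complementary score `1 − P(lesion)`; this keeps both
  classifiers on one output convention. Boundary semantics: XPC drops at
  `pE ≥ thr_e`, LVC keeps at `pLvc > thr_i` (strict).
* Patch raw channels are min-max normalized to [0, 1] per patch; constant
  patches map to 0. Out-of-volume regions of the LVC cube are filled with
  the volume's minimum HU (air) *before* normalization.
* The XPC patch is produced by a single trilinear resampling from the
  native grid onto the 128×128 target spanning the full coronal plane.
  This composes the "resample to 1 mm, then resize" convention into one
  interpolation, avoiding double-resampling blur at no cost in geometry.

# Learned components

No deep-learning framework is available to R in this package's dependency
set, and the pipeline's contracts deliberately do not depend on one. Both
learned components are compact dense neural networks (single hidden ReLU
layer, sigmoid output) trained by the same engine with minibatch Adam on
binary cross-entropy with L2 weight decay — learning rate 1e-3, weight
decay 1e-4, batch size 32, early stopping after 30 epochs without
validation-loss improvement, and random translation/flip/zoom/Gaussian
noise augmentation of training patches. Any stronger model (a 3-D U-Net
served from another process, a convolutional classifier) can be attached
through the same two interfaces:

* `SegmentationBackend`: `fitBackend()` / `predictMask()`. The shipped
  trainable backend (`voxelNetBackend()`) classifies voxels from
  multiscale intensity features: two display-window normalizations (a
  wide lung window and a narrow soft-tissue window that spreads the small
  lesion-vs-soft-tissue contrast over the feature range),
  Gaussian-smoothed values at 3 and 6 mm, a center-surround contrast,
  local SDs in both windows (the wide-window SD flags air/tissue
  interfaces), and a ~10 mm wide-window context mean that separates
  "inside the lung", "at the pleural interface" and "inside the body".
  Features are standardized with training statistics. Background voxels
  are sampled stratified: one third uniform, one third from
  tissue-density voxels and one third from tissue-density
  high-interface-variance voxels — pleural partial-volume bands are rare
  globally but are exactly what a lesion-intensity classifier confuses,
  so uniform sampling starves the decision boundary of them. Because
  training voxels are sampled near-balanced while the true lesion prior
  is ~1e-4, the probability cutoff is calibrated after training by
  maximizing whole-volume Dice on training volumes over a log-spaced
  threshold grid; the posterior map is lightly smoothed (at the 3 mm
  feature scale) before thresholding, which suppresses isolated-voxel
  noise responses. A fixed HU-threshold backend (`thresholdBackend()`)
  is also shipped; on noise-free phantoms it reproduces the rasterized
  ground truth exactly and serves as the segmentation oracle in tests.
* `CandidateClassifier`: `fitClassifier()` / `predictProb()`. The shipped
  classifier (`denseNetClassifier()`) average-pools the raw, mask and
  raw×mask channels of a patch pair onto a coarse grid and classifies the
  concatenated descriptor. The mask and product channels are renormalized
  to peak 1 so small candidates stay visible after pooling (a few-voxel
  candidate would otherwise pool to ~1e-3 and the classifier could not
  even locate it); candidate size travels separately as a `log1p` voxel
  count, and two support scalars carry the mean raw intensity under the
  candidate and in a blurred ring around it — the ring mean is the
  pulmonary-boundary context the coronal classifier hypothesizes on, at
  any candidate size. 3-D (LVC) descriptors add a second, central-crop
  scale so small lesions keep shape information (the coarse scale bins a
  96 mm crop at 12 mm). Training defaults pool the LVC to 8³ with the
  central second scale, and the XPC to 8×8 with a wider hidden layer and
  more augmentation copies: its training subset (extrapulmonary
  non-lesions plus all lesions) is the smallest, and fewer nuisance
  dimensions generalize better. Because candidate datasets are heavily
  non-lesion dominated, the cross-entropy is class-balanced by default
  (`balanceClasses` in `trainConfig()`); without it the minority lesion
  class is systematically under-scored, which starves the threshold
  tuner.

Patch pairs can be materialized to disk (`buildCandidateDataset(...,
patchDir=)`) and are then loaded one at a time during training: a 96³
float patch is ~7 MB, so cohort-scale training should not hold them all in
memory. Materialized patches store the raw channel quantized to 16 bits
(it is already min-max normalized, so the quantization error is 1.5e-5).

# Training workflow and threshold tuning

The candidate dataset is built by running the no-cascade pipeline (LLSB)
on training cases: every predicted instance becomes a record with a 0/1
label (best-Dice overlap with ground truth > 0) and a location tag from
its lung-mask overlap fraction (0 → extrapulmonary, 1 → intrapulmonary,
otherwise partial). The LVC trains on all records; the XPC trains on the
subset of extrapulmonary non-lesions plus all true lesions
(`subsetForXpc()`) — its task is only to recognize candidates outside the
lungs, so intrapulmonary negatives would blur its decision boundary.

Cases are assigned to 5 folds stratified by source tag and binned
z-spacing (`zResolutionBin()`: ≤1, 1–3, >3 mm; the bins are a package
choice — reconstruction protocols cluster around thin-slice, standard and
thick-slice regimes). Candidates inherit their case's fold, so no
candidate from a validation case ever appears in training. Per-fold
classifiers are compared by validation AUROC and the best is kept.

`tuneThresholds()` grid-searches `(thr_e, thr_i)` over `{0, 0.01, …, 1}²`
maximizing image-level mean Dice after the cascade, subject to pooled
lesion sensitivity within `delta = 0.01` of the best sensitivity any grid
point achieves; ties break toward higher sensitivity, then lower `thr_i`,
then the more conservative (higher) `thr_e` — with the LVC behind it many
XPC drops are redundant, equal-Dice ties along `thr_e` are common, and
riding the validation boundary generalizes poorly.
Candidate probabilities are computed once per case and cached, so the
10 201-point sweep is vectorized bookkeeping. When no grid point is
feasible the function warns and returns pass-through sentinels. The
default grid step (0.01) matters: classifier posteriors concentrate near
0 and 1, and the usable operating points can sit within a few hundredths
of the extremes.

# The phantom model

The study cohorts behind this class of pipeline are private, so the
package ships a seedable generator of thoracic CT phantoms that supports
every contract end to end. A phantom is an elongated body ellipsoid
(soft tissue, 0 HU) on an air background (−1000 HU) containing two lung
ellipsoids (−800 HU); lesions are lobulated unions of 2–4 overlapping
ellipsoids at +20 HU; Gaussian noise (default SD 10 HU) is added to the
CT only — ground truth is the noise-free geometric rasterization. The
palette is deliberately unambiguous so that a fixed threshold is an exact
segmentation oracle on noise-free phantoms, while the +20 HU
lesion-vs-body contrast keeps the learned pipeline honest in the presence
of noise.

Defaults emulate the heterogeneous multicenter regime at desk scale:

* grid 128×128×80 at (3, 3, 2.5) mm — a 384×384×200 mm field of view
  whose in-plane extent matches the ~400 mm clinical regime; the z extent
  is reduced so a phantom rasterizes in under a second;
* lesion diameters uniform on 10–26 mm and lesion counts `1 +
  Poisson(1.5)` (cohort median 2 per scan);
* per-case spacing jitter — in-plane 2.5–3.5 mm, z 1.2–5 mm — standing in
  for scanner/protocol heterogeneity and varying the physical field of
  view;
* lesion placement tags: intrapulmonary, wall-attached (straddling the
  lung boundary, biased toward the lateral pleural wall — the
  configuration that defeats density-based lung masks and motivates the
  bounding-box fallback), and optionally fully extrapulmonary;
* planted false-candidate structures sharing the lesion HU but excluded
  from ground truth: vessel-like tubes inside the lungs and soft-tissue
  blobs in the chest wall. The end-to-end studies plant ~4 per scan,
  which together with the segmentation backend's own noise responses
  yields on the order of 5 non-lesion candidates per scan — the density
  segmentation-only pipelines produce on clinical cohorts.

What the phantom does **not** model: realistic CT texture and noise
correlation, partial-volume and reconstruction-kernel effects,
contrast-agent enhancement, respiratory motion, and the full morphological
variety of real lesions. Tests passing on phantoms therefore demonstrate
the pipeline's *contracts* (geometry, labeling, cascade logic, metric
definitions, trainability and the directional benefit of the cascade),
not clinical-grade performance.

# Evaluation protocol

Detection uses existence-of-overlap matching: a predicted lesion is a
true positive iff it overlaps any ground-truth annotation (pairwise
Dice > 0); an unmatched prediction is a false positive and an unmatched
ground-truth lesion a false negative. One prediction covering two
ground-truth lesions detects both and counts once as a non-FP; detection
metrics are pooled over all lesions (micro-average). Ground-truth lesions
below the size filter (default 10 mm maximum axial Feret diameter, the
measurable-lesion convention; set 0 to disable) are excluded from the
recall denominator and confer no TP status. Predictions are never
size-filtered — removing false predictions is the cascade's job.

Segmentation is reported at two levels: image-level Dice (per-case
whole-mask Dice, macro-averaged over scans) and lesion-level Dice (per
ground-truth lesion, the highest pairwise Dice among its matches, 0 when
unmatched). Lesion-level Hd-95 averages the lowest pairwise 95th-percentile
Hausdorff distance over *matched* lesions only (the distance is undefined
without a match, and the count of contributing lesions is reported); the
best-Dice and best-Hd-95 partners may be different predictions. Surface
distances use 6-connectivity surface voxels and anisotropic spacing. A
both-empty Dice is reported as 1 with a degeneracy flag — the convention
for lesion-free scans.

FROC curves sweep a keep-threshold over per-candidate scores (the LVC
probabilities of surviving candidates in the full pipeline) and report
pooled sensitivity against mean false positives per scan. Volume agreement
is computed on per-case *total* lesion volume in liters — total tumor
burden, including FP/FN effects — via least-squares R² and Bland–Altman
bias ± 1.96 SD limits. All confidence intervals resample *cases* (not
lesions; lesions within a scan are not independent) with 1,000 bootstrap
replicates and percentile 2.5/97.5 bounds, deterministic under a seed.

# Problem sizes and numerical choices

The shipped end-to-end study trains the segmentation backend on 30
bbox-cropped phantoms, builds its candidate dataset (typically 200–400
candidates) from the same cohort, trains two per-fold classifiers per
cascade stage, tunes thresholds on 8 validation cases and evaluates 10
held-out cases — sizes chosen so the whole study runs on one CPU core in
minutes while still exercising every stage with learned components.
Other choices a maintainer should know:

* connected-component labels are assigned in column-major scan order of
  each component's first voxel — a deterministic tie-break; cropping a
  labeled mask preserves label identity (and may therefore leave label
  gaps, which the containers tolerate), while `labelInstances()` and
  `runCfpr()` always emit contiguous labels;
* the fallback box always contains its input box and is idempotent, but
  enlarging a lung mask can legitimately *shrink* the final box when the
  enlargement pushes an axis across its minimum (the fallback then stops
  substituting the whole image on that axis);
* survivors of the cascade are relabeled `1..m` preserving relative
  order, and the per-candidate decision log (both probabilities, deciding
  stage) is part of the pipeline's provenance record, together with the
  crop box, candidate counts before/after, seeds and a config hash;
* grid congruence between a volume and its masks (shape, spacing, origin
  to 1e-6 mm) is enforced at every module boundary;
* the Hd-95 percentile is the type-7 quantile of the pooled directed
  surface distances in both directions;
* `cascadeDecide()` raises an error if a candidate passes the XPC gate
  without an LVC probability — silently keeping or dropping it would bias
  the cascade;
* bootstrap resamples on which a metric is undefined are skipped and
  counted, with a warning above 1%.

# Known limitations

* The voxel-feature backend has no shape prior; its errors are isolated
  noise responses (mitigated by posterior smoothing and then by the
  cascade) and under-segmentation of lesion boundaries at coarse spacing.
* The XPC learns from whatever extrapulmonary negatives the segmentation
  stage produces; when those are dominated by small noise blobs, its
  decision can lean on candidate size rather than anatomical position,
  and threshold tuning will then rely more heavily on the LVC. The
  conservative sensitivity constraint in `tuneThresholds()` is what keeps
  this safe.
* The 2.5-D multi-plane LVC variants and pretrained convolutional
  backbones that a GPU setting would use are out of scope; the interfaces
  accept them.
* DICOM ingestion, inter-patient resampling and registration are out of
  scope; NIfTI-1 is the exchange format.

# The command-line interface

`inst/cli/lesioncascade.R` wraps the data-facing operations (`phantom`,
`bbox`, `segment`, `cfpr`, `run`, `evaluate`) for shell use with NIfTI
files, CSV manifests and RDS model checkpoints. Training and threshold
tuning are R-session workflows (this vignette and the function reference
document them); they produce the checkpoints the CLI consumes.
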