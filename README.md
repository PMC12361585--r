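# lesioncascade

Multi-instance lung lesion segmentation for thoracic CT with cascade
false-positive reduction — an R implementation of a three-stage pipeline:

1. **Thoracic bounding box.** Crop the scan to the tight box around a lung
   mask, with a per-dimension minimum-size fallback: if the predicted box
   is smaller than the smallest plausible adult lung extent along an axis
   (210 / 150 / 120 mm for x / y / z), the whole image is used along that
   axis. This absorbs the classic failure of density-based lung maskers,
   which exclude large or wall-attached soft-tissue masses.
2. **Multi-instance segmentation.** A pluggable binary segmentation
   backend runs on the crop; foreground is split into lesion instances by
   3-D connected components (26-connectivity) and padded back to the
   original grid.
3. **Cascade false-positive reduction (CFPR).** Each candidate is scored
   by an extrapulmonary classifier (XPC: full coronal slice through the
   candidate centroid, 128×128 at 1×1 mm) and, if it passes the `thr_e`
   gate, by a lesion validator (LVC: 96 mm cube at 1 mm isotropic, 96³).
   A candidate survives iff its extrapulmonary score `1 − P(lesion)` is
   below `thr_e` and its LVC probability surpasses `thr_i`; everything
   else is erased from the mask. The cascade is removal-only, so the five
   ablation pipelines (LLS, LLSB, LLSB_XPC, LLSB_LVC, LLSB_CFPR) nest.

The package also ships the full multi-lesion evaluation protocol
(detection by DSC > 0 overlap matching; image- and lesion-level Dice;
95th-percentile Hausdorff distance; RECIST-style ≥ 10 mm measurable-lesion
filtering; FROC analysis; lesion-volume R² and Bland–Altman agreement;
case-resampling bootstrap CIs with 1,000 replicates), a seedable thoracic
CT phantom generator with ground-truth lesion instances and planted
false-candidate structures, and a training workflow for the cascade
classifiers (candidate-dataset builder, stratified 5-fold CV,
BCE/Adam training with early stopping, AUROC-based model selection and
grid search of the cascade thresholds under a sensitivity-preservation
constraint).

Who it is for: researchers prototyping lesion-detection pipelines and
evaluation protocols on CT-like data, and anyone needing a reference
implementation of the cascade logic and multi-lesion metrics with
attachable stronger models (the segmentation backend and both classifiers
are interfaces; the shipped implementations are compact CPU-trainable
neural networks).

## Worked example

```r
library(lesioncascade)

# a synthetic thoracic CT with 2 lesions and 2 planted false structures
case <- generatePhantom(phantomSpec(nLesions = 2, nFpIntra = 1,
                                    nFpExtra = 1, noiseSd = 0, seed = 11))
ct <- phantomCt(case)

# oracle components: threshold segmentation + overlap-oracle classifiers
lung <- phantomLung(case); gt <- phantomGt(case)
xpc <- functionClassifier(function(p) {
  ctx <- attr(p, "context")
  as.numeric(sum(voxelData(ctx$pred) == ctx$label &
                 voxelData(lung) != 0) > 0)
})
lvc <- functionClassifier(function(p) {
  ctx <- attr(p, "context")
  as.numeric(sum(voxelData(ctx$pred) == ctx$label &
                 voxelData(gt) != 0) > 0)
})
cfg <- ablationConfig("LLSB_CFPR", backend = thresholdBackend(10),
                      xpc = xpc, lvc = lvc,
                      cascade = cascadeConfig(thrE = 0.5, thrI = 0.5))
out <- runPipeline(ct, cfg, lungMask = lung)
out$provenance$nCandidatesBefore   # 4  (2 lesions + 2 planted FPs)
nInstances(out$mask)               # 2  (the cascade removed both FPs)

tb <- matchLesions(gt, out$mask)
detectionMetrics(list(tb), sizeFilter(0))$recall   # 1
tb@pairs$dsc                                       # 1 1  (exact recovery)
```

The candidate counts show the cascade at work: the segmentation stage
proposes four instances (two true lesions, one vessel-like intrapulmonary
distractor, one chest-wall blob); the XPC removes the extrapulmonary blob,
the LVC the vessel, and both true lesions survive with per-lesion Dice 1.0
against ground truth.

The learned workflow (train `voxelNetBackend()` on phantom crops, build
the candidate dataset with `buildCandidateDataset()`, train XPC/LVC with
`trainFoldClassifier()`, pick models and thresholds with
`selectBestAndTuneThresholds()`) is documented in the methods vignette
(`vignettes/lesioncascade-methods.Rmd`).

A thin command-line front end for the data-facing steps (phantom
generation, bbox, segmentation, CFPR, end-to-end runs, evaluation) lives
at `inst/cli/lesioncascade.R`.

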