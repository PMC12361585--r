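# Shared fixtures: small, fast phantom specifications and oracle pipeline
# components. Phantom grids here are coarser than the package defaults so
# individual tests stay quick.

tinySpec <- function(seed = 1L, nLesions = 2, noiseSd = 10, nFpIntra = 0,
                     nFpExtra = 0, ...) {
  phantomSpec(shape = c(64, 64, 40), spacing = c(5, 5, 5),
              nLesions = nLesions, lesionDiameterRange = c(12, 24),
              noiseSd = noiseSd, nFpIntra = nFpIntra, nFpExtra = nFpExtra,
              seed = seed, ...)
}

gtBinary <- function(case) {
  g <- phantomGt(case)
  BinaryMask(array(as.integer(voxelData(g) != 0), dim(voxelData(g))),
             voxelSpacing(g), voxelOrigin(g))
}

# oracle cascade classifiers: XPC scores 1 iff the candidate overlaps the
# reference lung mask, LVC scores 1 iff it overlaps a ground-truth lesion.
# The candidate voxel set comes from the evaluation context runCfpr attaches
# to each patch pair.
oracleXpc <- function(lungMask) {
  functionClassifier(function(pair) {
    ctx <- attr(pair, "context")
    cand <- voxelData(ctx$pred) == ctx$label
    if (sum(cand & (voxelData(lungMask) != 0)) > 0) 1 else 0
  })
}

oracleLvc <- function(gt) {
  functionClassifier(function(pair) {
    ctx <- attr(pair, "context")
    cand <- voxelData(ctx$pred) == ctx$label
    if (sum(cand & (voxelData(gt) != 0)) > 0) 1 else 0
  })
}
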