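# Synthetic thoracic CT phantoms with ground-truth lesion instances.
#
# The phantom is a deliberately simple intensity model (air -1000 HU, body
# soft tissue 0 HU, lung parenchyma -800 HU, lesions +20 HU, additive
# Gaussian noise) on an anatomically plausible layout: an elongated body
# ellipsoid containing two lung ellipsoids. Lesions are lobulated unions of
# ellipsoids placed intrapulmonary, wall-attached (straddling the lung
# boundary) or extrapulmonary. Planted distractor structures (vessel-like
# tubes inside the lungs, soft-tissue blobs in the chest wall) share the
# lesion HU but are excluded from ground truth: they are the false
# candidates the cascade classifier stage exists to remove.

.HU_AIR <- -1000
.HU_BODY <- 0
.HU_LUNG <- -800
.HU_LESION <- 20

# body/lung layout as fractions of the physical extent
.bodyLayout <- function(ext) {
  list(
    bodyC = c(ext[1] / 2, ext[2] / 2, ext[3] / 2),
    bodyS = c(0.42 * ext[1], 0.36 * ext[2], 0.85 * ext[3]),
    lungC = list(c(ext[1] / 2 - 0.18 * ext[1], ext[2] / 2, ext[3] / 2),
                 c(ext[1] / 2 + 0.18 * ext[1], ext[2] / 2, ext[3] / 2)),
    lungS = c(0.125 * ext[1], 0.21 * ext[2], 0.34 * ext[3]))
}

# inside-ellipsoid field over the whole grid, via separable axis terms
.ellipsoidMask <- function(shape, spacing, center, semi) {
  ax <- ((seq_len(shape[1]) - 1) * spacing[1] - center[1]) / semi[1]
  ay <- ((seq_len(shape[2]) - 1) * spacing[2] - center[2]) / semi[2]
  az <- ((seq_len(shape[3]) - 1) * spacing[3] - center[3]) / semi[3]
  q <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  q <= 1
}

# Rasterize a union-of-ellipsoids blob into voxel indices (n x 3 matrix of
# 1-based indices), evaluated only inside a local window for speed.
.rasterBlob <- function(shape, spacing, comps, pad = 2) {
  rmax <- max(vapply(comps, function(cp) max(cp$semi) +
                       sqrt(sum((cp$center - comps[[1]]$center)^2)), 0))
  c0 <- comps[[1]]$center
  lo <- pmax(1L, floor((c0 - rmax) / spacing) + 1L - pad)
  hi <- pmin(shape, ceiling((c0 + rmax) / spacing) + 1L + pad)
  if (any(hi < lo)) return(matrix(integer(), 0, 3))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  inside <- array(FALSE, c(length(ix), length(iy), length(iz)))
  for (cp in comps) {
    ax <- ((ix - 1) * spacing[1] - cp$center[1]) / cp$semi[1]
    ay <- ((iy - 1) * spacing[2] - cp$center[2]) / cp$semi[2]
    az <- ((iz - 1) * spacing[3] - cp$center[3]) / cp$semi[3]
    inside <- inside | (outer(outer(ax^2, ay^2, `+`), az^2, `+`) <= 1)
  }
  w <- which(inside, arr.ind = TRUE)
  if (nrow(w) == 0) return(matrix(integer(), 0, 3))
  cbind(ix[w[, 1]], iy[w[, 2]], iz[w[, 3]])
}

# voxels within `radius` mm of the segment p0-p1 (vessel-like tube)
.rasterTube <- function(shape, spacing, p0, p1, radius) {
  lo <- pmax(1L, floor((pmin(p0, p1) - radius) / spacing) + 1L - 1L)
  hi <- pmin(shape, ceiling((pmax(p0, p1) + radius) / spacing) + 1L + 1L)
  if (any(hi < lo)) return(matrix(integer(), 0, 3))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  p <- .voxelCenters(g, spacing, c(0, 0, 0))
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- pmin(1, pmax(0, ((p[, 1] - p0[1]) * v[1] + (p[, 2] - p0[2]) * v[2] +
                          (p[, 3] - p0[3]) * v[3]) / len2))
  dx <- p[, 1] - (p0[1] + t * v[1])
  dy <- p[, 2] - (p0[2] + t * v[2])
  dz <- p[, 3] - (p0[3] + t * v[3])
  g[dx^2 + dy^2 + dz^2 <= radius^2, , drop = FALSE]
}

# uniform point in the unit ball
.runifBall <- function() {
  repeat {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) <= 1) return(u)
  }
}

.runifDir <- function() {
  repeat {
    u <- stats::rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-9) return(u / n)
  }
}

# lobulated lesion components: primary ellipsoid with in-plane diameter D
# plus 1-3 surface bumps contained in the primary's circumscribed sphere
.lesionComps <- function(center, diamMm) {
  r <- diamMm / 2
  primary <- list(center = center,
                  semi = c(r, r * stats::runif(1, 0.8, 1),
                           r * stats::runif(1, 0.7, 0.95)))
  comps <- list(primary)
  for (b in seq_len(sample(1:3, 1))) {
    bs <- r * stats::runif(1, 0.25, 0.45)
    off <- .runifDir() * stats::runif(1, 0.3, 1) * (r - bs) * 0.95
    comps[[length(comps) + 1L]] <-
      list(center = center + off, semi = rep(bs, 3))
  }
  comps
}

# does `vox` (n x 3 indices) stay clear of occupied voxels, including their
# 26-neighborhood (so separate structures stay separate components)?
.clearOfOccupied <- function(vox, occupied, shape) {
  if (nrow(vox) == 0) return(FALSE)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    v <- vox
    v[, 1] <- v[, 1] + dx; v[, 2] <- v[, 2] + dy; v[, 3] <- v[, 3] + dz
    keep <- v[, 1] >= 1 & v[, 1] <= shape[1] & v[, 2] >= 1 &
      v[, 2] <= shape[2] & v[, 3] >= 1 & v[, 3] <= shape[3]
    v <- v[keep, , drop = FALSE]
    if (nrow(v) && any(occupied[v] != 0)) return(FALSE)
  }
  TRUE
}

#' Generate one synthetic thoracic CT phantom
#'
#' Deterministic under `spec@seed` (bit-identical output for identical
#' specs). Ground-truth lesion masks are the noise-free geometric
#' rasterizations; noise is added to the CT only.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomCase-class].
#' @examples
#' case <- generatePhantom(phantomSpec(shape = c(64, 64, 40),
#'                                     spacing = c(5, 5, 5), seed = 7))
#' nInstances(phantomGt(case))
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  .withSeed(spec@seed, .generatePhantomImpl(spec))
}

.generatePhantomImpl <- function(spec) {
  shape <- spec@shape
  sp <- spec@spacing
  ext <- shape * sp
  lay <- .bodyLayout(ext)

  body <- .ellipsoidMask(shape, sp, lay$bodyC, lay$bodyS)
  lungL <- .ellipsoidMask(shape, sp, lay$lungC[[1]], lay$lungS)
  lungR <- .ellipsoidMask(shape, sp, lay$lungC[[2]], lay$lungS)
  lung <- (lungL | lungR) & body

  hu <- array(.HU_AIR, shape)
  hu[body] <- .HU_BODY
  hu[lung] <- .HU_LUNG

  lungArr <- array(0L, shape); lungArr[lung] <- 1L
  lungDil <- .dilateArr(lungArr, 1L)

  gt <- array(0L, shape)
  occupied <- array(0L, shape)

  # location tags drawn up front so the generated composition is exact
  nL <- spec@nLesions
  tags <- character(0)
  if (nL > 0) {
    u <- stats::runif(nL)
    tags <- ifelse(u < spec@pExtrapulmonary, "extrapulmonary",
                   ifelse(u < spec@pExtrapulmonary + spec@pWallAttached,
                          "wall", "intrapulmonary"))
  }

  info <- data.frame(label = integer(), centerX = numeric(),
                     centerY = numeric(), centerZ = numeric(),
                     diameterMm = numeric(), tag = character(),
                     stringsAsFactors = FALSE)

  for (i in seq_len(nL)) {
    diam <- stats::runif(1, spec@lesionDiameterRange[1],
                         spec@lesionDiameterRange[2])
    placed <- FALSE
    for (try in seq_len(60)) {
      tag <- tags[i]
      side <- sample(1:2, 1)
      lc <- lay$lungC[[side]]
      ls <- lay$lungS
      r <- diam / 2
      if (tag == "intrapulmonary") {
        margin <- ls - r - max(sp)
        if (any(margin <= 0)) stop("infeasible placement for lesion ", i,
                                   ": lesion too large for lung")
        center <- lc + .runifBall() * margin
      } else if (tag == "wall") {
        # center on the lung boundary so the lesion straddles it; the
        # direction is damped in z so masses attach along the pleural
        # (lateral/anterior) wall rather than the lung poles
        dir <- .runifDir()
        dir[3] <- 0.3 * dir[3]
        dir <- dir / sqrt(sum(dir^2))
        center <- lc + dir * ls
      } else { # extrapulmonary: in the body, clear of the lungs
        center <- lay$bodyC + .runifBall() * (lay$bodyS - r - max(sp)) *
          c(1, 1, 0.8)
      }
      vox <- .rasterBlob(shape, sp, .lesionComps(center, diam))
      if (nrow(vox) == 0) next
      # geometric placement constraints
      if (any(!body[vox])) next
      if (tag == "intrapulmonary" && any(lungDil[vox] == 0)) next
      if (tag == "extrapulmonary" && any(lungDil[vox] != 0)) next
      if (tag == "wall" &&
          (all(lungArr[vox] != 0) || all(lungArr[vox] == 0))) next
      if (!.clearOfOccupied(vox, occupied, shape)) next
      gt[vox] <- i
      occupied[vox] <- 1L
      hu[vox] <- .HU_LESION
      info <- rbind(info, data.frame(
        label = i, centerX = center[1], centerY = center[2],
        centerZ = center[3], diameterMm = diam, tag = tag,
        stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible placement for lesion ", i,
                      " after bounded retries")
  }

  dinfo <- data.frame(id = integer(), type = character(),
                      centerX = numeric(), centerY = numeric(),
                      centerZ = numeric(), sizeMm = numeric(),
                      stringsAsFactors = FALSE)
  did <- 0L

  # intrapulmonary vessel-like distractor tubes
  for (i in seq_len(spec@nFpIntra)) {
    for (try in seq_len(60)) {
      side <- sample(1:2, 1)
      lc <- lay$lungC[[side]]
      ls <- lay$lungS
      len <- stats::runif(1, 22, 34)
      rad <- stats::runif(1, max(sp) * 0.9, max(sp) * 1.3)
      axis <- .runifDir()
      margin <- ls - len / 2 - rad - max(sp)
      if (any(margin <= 0)) next
      center <- lc + .runifBall() * margin
      vox <- .rasterTube(shape, sp, center - axis * len / 2,
                         center + axis * len / 2, rad)
      if (nrow(vox) == 0) next
      if (any(lungArr[vox] == 0)) next
      if (!.clearOfOccupied(vox, occupied, shape)) next
      occupied[vox] <- 1L
      hu[vox] <- .HU_LESION
      did <- did + 1L
      dinfo <- rbind(dinfo, data.frame(
        id = did, type = "vesselFP", centerX = center[1],
        centerY = center[2], centerZ = center[3], sizeMm = len,
        stringsAsFactors = FALSE))
      break
    }
  }

  # extrapulmonary soft-tissue distractor blobs
  for (i in seq_len(spec@nFpExtra)) {
    for (try in seq_len(60)) {
      diam <- stats::runif(1, max(10, 2 * max(sp)), 16)
      r <- diam / 2
      center <- lay$bodyC + .runifBall() * (lay$bodyS - r - max(sp)) *
        c(1, 1, 0.8)
      vox <- .rasterBlob(shape, sp, .lesionComps(center, diam))
      if (nrow(vox) == 0) next
      if (any(!body[vox])) next
      if (any(lungDil[vox] != 0)) next
      if (!.clearOfOccupied(vox, occupied, shape)) next
      occupied[vox] <- 1L
      hu[vox] <- .HU_LESION
      did <- did + 1L
      dinfo <- rbind(dinfo, data.frame(
        id = did, type = "extraFP", centerX = center[1],
        centerY = center[2], centerZ = center[3], sizeMm = diam,
        stringsAsFactors = FALSE))
      break
    }
  }

  if (spec@noiseSd > 0)
    hu <- hu + array(stats::rnorm(prod(shape), 0, spec@noiseSd), shape)

  new("PhantomCase",
      ct = CTVolume(hu, spacing = sp),
      gtLesions = InstanceMask(gt, spacing = sp),
      lungMask = BinaryMask(lungArr, spacing = sp),
      lesionInfo = info, distractorInfo = dinfo)
}

#' Default lesion-count sampler for synthetic cohorts
#'
#' `1 + Poisson(1.5)` draws: at least one lesion per scan and a cohort
#' median of two lesions per CT, matching the study-cohort regime.
#'
#' @param n number of draws.
#' @return integer vector of lesion counts.
#' @export
defaultLesionCountSampler <- function(n) 1L + stats::rpois(n, 1.5)

#' Generate a cohort of phantoms with acquisition heterogeneity
#'
#' Per-case voxel spacing is jittered (uniformly within `spacingJitter`)
#' to emulate multicenter acquisition variability, which also varies the
#' physical field of view; lesion counts are drawn from `countSampler`.
#'
#' @param nCases number of cases (>= 1).
#' @param baseSpec a [PhantomSpec-class] used as the template.
#' @param spacingJitter list with `inPlane` and `z` ranges in mm.
#' @param countSampler function(n) returning integer lesion counts.
#' @param seed cohort RNG seed; each case derives its own sub-seed.
#' @return list of [PhantomCase-class].
#' @export
generateCohort <- function(nCases, baseSpec = phantomSpec(),
                           spacingJitter = list(inPlane = c(2.5, 3.5),
                                                z = c(1.2, 5)),
                           countSampler = defaultLesionCountSampler,
                           seed = 1L) {
  stopifnot(nCases >= 1)
  .withSeed(seed, {
    sxy <- stats::runif(nCases, spacingJitter$inPlane[1],
                        spacingJitter$inPlane[2])
    sz <- stats::runif(nCases, spacingJitter$z[1], spacingJitter$z[2])
    counts <- countSampler(nCases)
    seeds <- sample.int(.Machine$integer.max - 1L, nCases)
    lapply(seq_len(nCases), function(i) {
      spec <- baseSpec
      spec@spacing <- c(sxy[i], sxy[i], sz[i])
      spec@nLesions <- as.integer(counts[i])
      spec@seed <- seeds[i]
      validObject(spec)
      generatePhantom(spec)
    })
  })
}

#' Reference threshold-based lung masker
#'
#' A stand-in for an external lung-segmentation model behind the same
#' contract: threshold the CT at -400 HU, keep low-density connected
#' components that do not touch the x/y image border (discarding background
#' air) and are at least `minVolumeCm3`, then apply a morphological closing.
#' An empty mask is a legal output; the bounding-box stage handles it via
#' its fallback. Like any parenchyma-threshold masker, it excludes
#' soft-tissue-density masses from the lung field, so large wall-attached
#' lesions fall outside the raw mask -- the failure mode the bounding-box
#' minimum-size fallback exists to absorb.
#'
#' @param ct a [CTVolume-class] in HU.
#' @param thresholdHu HU threshold below which tissue counts as lung/air.
#' @param minVolumeCm3 minimum component volume kept, in cm^3.
#' @param closingIter box-closing iterations.
#' @return a [BinaryMask-class] grid-congruent with `ct`.
#' @export
referenceLungMasker <- function(ct, thresholdHu = -400, minVolumeCm3 = 50,
                                closingIter = 1L) {
  stopifnot(is(ct, "CTVolume"))
  arr <- ct@data < thresholdHu
  shape <- dim(arr)
  lab <- .label26(array(as.integer(arr), shape))
  n <- attr(lab, "n_components")
  keep <- array(0L, shape)
  if (n > 0) {
    border <- unique(c(lab[1, , ], lab[shape[1], , ],
                       lab[, 1, ], lab[, shape[2], ]))
    voxVol <- prod(voxelSpacing(ct))
    counts <- tabulate(lab[lab > 0], nbins = n)
    good <- setdiff(which(counts * voxVol / 1000 >= minVolumeCm3), border)
    if (length(good)) keep[lab %in% good] <- 1L
  }
  if (closingIter > 0 && any(keep > 0)) keep <- .closeArr(keep, closingIter)
  BinaryMask(keep, spacing = voxelSpacing(ct), origin = voxelOrigin(ct))
}
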