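# Independent brute-force oracles used to check the package's voxel-level
# primitives. These deliberately share no code with the implementation:
# connected components go through igraph, distances through dense R
# arithmetic, bounding boxes through an exhaustive scan.

# 26-connectivity component partition via an igraph adjacency graph
oracleLabel26 <- function(arr) {
  d <- dim(arr)
  fg <- which(arr != 0)
  lab <- array(0L, d)
  if (length(fg) == 0) return(lab)
  ijk <- arrayInd(fg, d)
  key <- (ijk[, 1] - 1) + d[1] * ((ijk[, 2] - 1) + d[2] * (ijk[, 3] - 1))
  lookup <- seq_along(fg)
  names(lookup) <- as.character(key)
  edges <- integer(0)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(offs))) {
    ni <- ijk[, 1] + offs[r, 1]
    nj <- ijk[, 2] + offs[r, 2]
    nk <- ijk[, 3] + offs[r, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nkey <- (ni - 1) + d[1] * ((nj - 1) + d[2] * (nk - 1))
    hit <- ok & as.character(nkey) %in% names(lookup)
    if (any(hit))
      edges <- c(edges, rbind(lookup[hit],
                              lookup[as.character(nkey[hit])]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # relabel in order of first appearance along the column-major scan
  ord <- order(fg)
  first <- !duplicated(comp[ord])
  remap <- integer(max(comp))
  remap[comp[ord][first]] <- seq_len(sum(first))
  lab[fg] <- remap[comp]
  lab
}

# Dice via explicit set arithmetic on linear indices
oracleDsc <- function(a, b) {
  sa <- which(a != 0)
  sb <- which(b != 0)
  if (length(sa) + length(sb) == 0) return(1)
  2 * length(intersect(sa, sb)) / (length(sa) + length(sb))
}

# surface voxels by explicit 6-neighbor check in R
oracleSurface <- function(arr) {
  d <- dim(arr)
  ijk <- which(arr != 0, arr.ind = TRUE)
  keep <- logical(nrow(ijk))
  for (r in seq_len(nrow(ijk))) {
    p <- ijk[r, ]
    for (a in 1:3) for (s in c(-1L, 1L)) {
      q <- p
      q[a] <- q[a] + s
      if (q[a] < 1 || q[a] > d[a] || arr[q[1], q[2], q[3]] == 0) {
        keep[r] <- TRUE
      }
    }
  }
  ijk[keep, , drop = FALSE]
}

# Hd-95 by all-pairs distances between oracle surfaces
oracleHd95 <- function(a, b, spacing) {
  pa <- sweep(oracleSurface(a) - 1, 2, spacing, `*`)
  pb <- sweep(oracleSurface(b) - 1, 2, spacing, `*`)
  dm <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
              Vectorize(function(i, j) sqrt(sum((pa[i, ] - pb[j, ])^2))))
  dab <- apply(dm, 1, min)
  dba <- apply(dm, 2, min)
  as.numeric(stats::quantile(c(dab, dba), 0.95, type = 7))
}

# exhaustive-scan bounding box
oracleBbox <- function(arr) {
  d <- dim(arr)
  lo <- c(Inf, Inf, Inf)
  hi <- c(-Inf, -Inf, -Inf)
  found <- FALSE
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (arr[i, j, k] != 0) {
      found <- TRUE
      lo <- pmin(lo, c(i, j, k))
      hi <- pmax(hi, c(i, j, k))
    }
  }
  if (!found) NULL else list(lo = lo, hi = hi)
}

# independently coded cascade truth table
oracleCascade <- function(pE, pLvc, thrE, thrI) {
  if (pE >= thrE) return("dropXPC")
  if (pLvc > thrI) "keep" else "dropLVC"
}

# random sparse binary mask
randomMask <- function(shape, p = 0.08) {
  array(as.integer(stats::runif(prod(shape)) < p), shape)
}
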