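#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Voxel-level primitives shared by the segmentation, cascade and evaluation
// stages. Arrays are column-major (x fastest), matching R.

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// 26-connectivity labeling by breadth-first search. Labels are assigned in
// column-major scan order of each component's first (minimum linear index)
// voxel, which makes the labeling deterministic.
// [[Rcpp::export(name = ".cc26_label")]]
IntegerVector cc26_label(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      R_xlen_t rem = cur - (R_xlen_t)k * nx * ny;
      int j = (int)(rem / nx);
      int i = (int)(rem - (R_xlen_t)j * nx);
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t q = idx3(ii, jj, kk, nx, ny);
            if (mask[q] != 0 && lab[q] == 0) {
              lab[q] = next;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Binary dilation/erosion with a 3x3x3 box structuring element, iterated
// `iter` times (box of radius `iter`).
static IntegerVector morph_box(IntegerVector mask, IntegerVector dims,
                               int iter, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector cur = clone(mask);
  for (int t = 0; t < iter; ++t) {
    IntegerVector out(n);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          bool hit = dilate ? false : true;
          for (int dk = -1; dk <= 1 && (dilate ? !hit : hit); ++dk) {
            int kk = k + dk;
            for (int dj = -1; dj <= 1 && (dilate ? !hit : hit); ++dj) {
              int jj = j + dj;
              for (int di = -1; di <= 1 && (dilate ? !hit : hit); ++di) {
                int ii = i + di;
                bool inside = ii >= 0 && ii < nx && jj >= 0 && jj < ny &&
                              kk >= 0 && kk < nz;
                int v = inside ? cur[idx3(ii, jj, kk, nx, ny)] : 0;
                if (dilate && v != 0) hit = true;
                if (!dilate && v == 0) hit = false;
              }
            }
          }
          out[idx3(i, j, k, nx, ny)] = hit ? 1 : 0;
        }
    cur = out;
  }
  return cur;
}

// [[Rcpp::export(name = ".dilate_box")]]
IntegerVector dilate_box(IntegerVector mask, IntegerVector dims, int iter) {
  return morph_box(mask, dims, iter, true);
}

// [[Rcpp::export(name = ".erode_box")]]
IntegerVector erode_box(IntegerVector mask, IntegerVector dims, int iter) {
  return morph_box(mask, dims, iter, false);
}

// Separable 1-D convolution along one axis (0, 1 or 2) with reflect padding;
// kernel length must be odd.
// [[Rcpp::export(name = ".convolve_axis")]]
NumericVector convolve_axis(NumericVector img, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (img.size() != n) stop("image length does not match dims");
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  const int half = kl / 2;
  const int len = dims[axis];
  NumericVector out(n);
  R_xlen_t stride = 1;
  for (int a = 0; a < axis; ++a) stride *= dims[a];
  R_xlen_t nlines = n / len;
  std::vector<double> line(len);
  for (R_xlen_t l = 0; l < nlines; ++l) {
    // base index of this line
    R_xlen_t inner = l % stride;
    R_xlen_t outer = l / stride;
    R_xlen_t base = inner + outer * stride * len;
    for (int p = 0; p < len; ++p) line[p] = img[base + (R_xlen_t)p * stride];
    for (int p = 0; p < len; ++p) {
      double acc = 0.0;
      for (int q = -half; q <= half; ++q) {
        int pp = p + q;
        if (pp < 0) pp = -pp - 1;            // reflect
        if (pp >= len) pp = 2 * len - pp - 1;
        if (pp < 0) pp = 0;                  // guard for len < half
        if (pp >= len) pp = len - 1;
        acc += line[pp] * kernel[q + half];
      }
      out[base + (R_xlen_t)p * stride] = acc;
    }
  }
  return out;
}

// Trilinear resampling of a source grid onto an arbitrary target grid.
// Voxel (i,j,k) (0-based) has its center at origin + (i,j,k) * spacing (mm).
// Target voxels whose center falls outside the source grid get `fill`.
// [[Rcpp::export(name = ".resample_grid")]]
NumericVector resample_grid(NumericVector src, IntegerVector sdims,
                            NumericVector sspacing, NumericVector sorigin,
                            IntegerVector odims, NumericVector ospacing,
                            NumericVector oorigin, double fill) {
  const int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    double pz = oorigin[2] + k * ospacing[2];
    double fz = (pz - sorigin[2]) / sspacing[2];
    for (int j = 0; j < oy; ++j) {
      double py = oorigin[1] + j * ospacing[1];
      double fy = (py - sorigin[1]) / sspacing[1];
      for (int i = 0; i < ox; ++i) {
        double px = oorigin[0] + i * ospacing[0];
        double fx = (px - sorigin[0]) / sspacing[0];
        double val = fill;
        if (fx >= 0 && fx <= sx - 1 && fy >= 0 && fy <= sy - 1 &&
            fz >= 0 && fz <= sz - 1) {
          int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy),
              z0 = (int)std::floor(fz);
          int x1 = x0 < sx - 1 ? x0 + 1 : x0;
          int y1 = y0 < sy - 1 ? y0 + 1 : y0;
          int z1 = z0 < sz - 1 ? z0 + 1 : z0;
          double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          double c000 = src[idx3(x0, y0, z0, sx, sy)];
          double c100 = src[idx3(x1, y0, z0, sx, sy)];
          double c010 = src[idx3(x0, y1, z0, sx, sy)];
          double c110 = src[idx3(x1, y1, z0, sx, sy)];
          double c001 = src[idx3(x0, y0, z1, sx, sy)];
          double c101 = src[idx3(x1, y0, z1, sx, sy)];
          double c011 = src[idx3(x0, y1, z1, sx, sy)];
          double c111 = src[idx3(x1, y1, z1, sx, sy)];
          double c00 = c000 * (1 - tx) + c100 * tx;
          double c10 = c010 * (1 - tx) + c110 * tx;
          double c01 = c001 * (1 - tx) + c101 * tx;
          double c11 = c011 * (1 - tx) + c111 * tx;
          double c0 = c00 * (1 - ty) + c10 * ty;
          double c1 = c01 * (1 - ty) + c11 * ty;
          val = c0 * (1 - tz) + c1 * tz;
        }
        out[idx3(i, j, k, ox, oy)] = val;
      }
    }
  }
  return out;
}

// Surface voxels: foreground with at least one 6-neighbor that is background
// or outside the grid.
// [[Rcpp::export(name = ".surface6")]]
IntegerVector surface6(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t q = idx3(i, j, k, nx, ny);
        if (mask[q] == 0) continue;
        bool border = false;
        for (int t = 0; t < 6 && !border; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            border = true;
          else if (mask[idx3(ii, jj, kk, nx, ny)] == 0)
            border = true;
        }
        if (border) out[q] = 1;
      }
  return out;
}

// For each point (row) in A, the minimum Euclidean distance to any row of B.
// Points are physical coordinates in mm.
// [[Rcpp::export(name = ".directed_min_dists")]]
NumericVector directed_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int a = 0; a < na; ++a) {
    double best = DBL_MAX;
    double ax = A(a, 0), ay = A(a, 1), az = A(a, 2);
    for (int b = 0; b < nb; ++b) {
      double dx = ax - B(b, 0), dy = ay - B(b, 1), dz = az - B(b, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

// Maximum pairwise Euclidean distance among 2-D points (mm).
// [[Rcpp::export(name = ".max_pairwise_dist2d")]]
double max_pairwise_dist2d(NumericMatrix P) {
  const int n = P.nrow();
  double best = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double dx = P(a, 0) - P(b, 0), dy = P(a, 1) - P(b, 1);
      double d = dx * dx + dy * dy;
      if (d > best) best = d;
    }
  return std::sqrt(best);
}

// Average pooling of a 3-D array onto a coarse grid of shape `odims`
// (bins cover the input evenly; used to build dense-net inputs from patches).
// [[Rcpp::export(name = ".avg_pool3d")]]
NumericVector avg_pool3d(NumericVector src, IntegerVector sdims,
                         IntegerVector odims) {
  const int sx = sdims[0], sy = sdims[1], sz = sdims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int k = 0; k < oz; ++k) {
    int z0 = (int)std::floor((double)k * sz / oz);
    int z1 = (int)std::floor((double)(k + 1) * sz / oz);
    if (z1 <= z0) z1 = z0 + 1;
    for (int j = 0; j < oy; ++j) {
      int y0 = (int)std::floor((double)j * sy / oy);
      int y1 = (int)std::floor((double)(j + 1) * sy / oy);
      if (y1 <= y0) y1 = y0 + 1;
      for (int i = 0; i < ox; ++i) {
        int x0 = (int)std::floor((double)i * sx / ox);
        int x1 = (int)std::floor((double)(i + 1) * sx / ox);
        if (x1 <= x0) x1 = x0 + 1;
        double acc = 0.0;
        long cnt = 0;
        for (int kk = z0; kk < z1 && kk < sz; ++kk)
          for (int jj = y0; jj < y1 && jj < sy; ++jj)
            for (int ii = x0; ii < x1 && ii < sx; ++ii) {
              acc += src[idx3(ii, jj, kk, sx, sy)];
              ++cnt;
            }
        out[idx3(i, j, k, ox, oy)] = cnt > 0 ? acc / cnt : 0.0;
      }
    }
  }
  return out;
}
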