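// Low-level raster primitives shared by the extraction pipeline and the
// synthetic-scene generator. All functions use R's (row, col) matrix layout;
// coordinates passed across the boundary are 1-based unless noted.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// mirror an out-of-range index back into [0, n)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_conv_sep(NumericMatrix img, NumericVector kvert,
                           NumericVector khorz) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rv = (kvert.size() - 1) / 2, rh = (khorz.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int a = -rv; a <= rv; ++a)
        s += img(reflect_idx(i + a, nr), j) * kvert[a + rv];
      tmp(i, j) = s;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int b = -rh; b <= rh; ++b)
        s += tmp(i, reflect_idx(j + b, nc)) * khorz[b + rh];
      out(i, j) = s;
    }
  return out;
}

// Grayscale erosion/dilation with an arbitrary (possibly non-flat)
// structuring element given as offsets (di, dj) and heights h. Pixels whose
// offset falls outside the image are ignored (the usual border convention).
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(NumericMatrix img, IntegerVector di,
                             IntegerVector dj, NumericVector h) {
  const int nr = img.nrow(), nc = img.ncol(), k = di.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_PosInf;
      for (int q = 0; q < k; ++q) {
        const int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = img(ii, jj) - h[q];
        if (v < m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(NumericMatrix img, IntegerVector di,
                              IntegerVector dj, NumericVector h) {
  const int nr = img.nrow(), nc = img.ncol(), k = di.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int q = 0; q < k; ++q) {
        const int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = img(ii, jj) + h[q];
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving thinning.
//
// A foreground pixel is "simple" (deletable without changing topology, in the
// (8, 4) connectivity pair) iff its 8-neighbourhood contains exactly one
// 8-connected foreground component and exactly one 4-connected background
// component touching a 4-neighbour. Simplicity over the 256 neighbourhood
// configurations is precomputed once. Deletion is sequential (each pixel is
// re-tested against the current image), so every deletion is of a pixel that
// is simple at that moment: component count and Euler number are preserved
// exactly. Endpoints (<= 1 neighbour) are never deleted, which preserves
// open line ends.
// ---------------------------------------------------------------------------

// ring order: N, NE, E, SE, S, SW, W, NW
static const int RDI[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int RDJ[8] = {0, 1, 1, 1, 0, -1, -1, -1};

static uint8_t g_simple_lut[256];
static bool g_lut_ready = false;

static int uf_find(int *p, int x) {
  while (p[x] != x) x = p[x] = p[p[x]];
  return x;
}

static void build_simple_lut() {
  for (int cfg = 0; cfg < 256; ++cfg) {
    // foreground 8-components within the ring
    int parent[8];
    for (int a = 0; a < 8; ++a) parent[a] = a;
    for (int a = 0; a < 8; ++a) {
      if (!(cfg & (1 << a))) continue;
      for (int b = a + 1; b < 8; ++b) {
        if (!(cfg & (1 << b))) continue;
        if (std::abs(RDI[a] - RDI[b]) <= 1 && std::abs(RDJ[a] - RDJ[b]) <= 1)
          parent[uf_find(parent, a)] = uf_find(parent, b);
      }
    }
    int fg_comp = 0;
    for (int a = 0; a < 8; ++a)
      if ((cfg & (1 << a)) && uf_find(parent, a) == a) ++fg_comp;

    // background 4-components within the ring, counting only those that
    // include a 4-neighbour of the centre (positions 0, 2, 4, 6)
    int bparent[8];
    for (int a = 0; a < 8; ++a) bparent[a] = a;
    for (int a = 0; a < 8; ++a) {
      if (cfg & (1 << a)) continue;
      for (int b = a + 1; b < 8; ++b) {
        if (cfg & (1 << b)) continue;
        if (std::abs(RDI[a] - RDI[b]) + std::abs(RDJ[a] - RDJ[b]) == 1)
          bparent[uf_find(bparent, a)] = uf_find(bparent, b);
      }
    }
    bool seen[8] = {false, false, false, false, false, false, false, false};
    int bg_comp = 0;
    for (int a = 0; a < 8; a += 2) {  // 4-neighbours only
      if (cfg & (1 << a)) continue;
      const int r = uf_find(bparent, a);
      if (!seen[r]) { seen[r] = true; ++bg_comp; }
    }
    g_simple_lut[cfg] = (fg_comp == 1 && bg_comp == 1) ? 1 : 0;
  }
  g_lut_ready = true;
}

static inline int neighbour_cfg(const std::vector<uint8_t> &px, int nr, int nc,
                                int i, int j) {
  int cfg = 0;
  for (int a = 0; a < 8; ++a) {
    const int ii = i + RDI[a], jj = j + RDJ[a];
    if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && px[(size_t)jj * nr + ii])
      cfg |= (1 << a);
  }
  return cfg;
}

//' @noRd
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix bin) {
  if (!g_lut_ready) build_simple_lut();
  const int nr = bin.nrow(), nc = bin.ncol();
  std::vector<uint8_t> px((size_t)nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      px[(size_t)j * nr + i] = bin(i, j) ? 1 : 0;

  // directional sub-passes: delete from N, S, W, E borders in turn
  const int bdi[4] = {-1, 1, 0, 0};
  const int bdj[4] = {0, 0, -1, 1};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      // mark the current boundary layer first, then delete sequentially
      // (re-testing simplicity against the evolving image), so each
      // sub-pass peels at most one layer from its side and the skeleton
      // stays centred
      cand.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!px[(size_t)j * nr + i]) continue;
          const int bi = i + bdi[d], bj = j + bdj[d];
          if (bi < 0 || bi >= nr || bj < 0 || bj >= nc ||
              !px[(size_t)bj * nr + bi])
            cand.push_back(j * nr + i);
        }
      for (size_t q = 0; q < cand.size(); ++q) {
        const int i = cand[q] % nr, j = cand[q] / nr;
        if (!px[(size_t)j * nr + i]) continue;
        const int cfg = neighbour_cfg(px, nr, nc, i, j);
        int nb = 0;
        for (int a = 0; a < 8; ++a) nb += (cfg >> a) & 1;
        if (nb <= 1) continue;  // endpoint or isolated: keep
        if (g_simple_lut[cfg]) {
          px[(size_t)j * nr + i] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = px[(size_t)j * nr + i] != 0;
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix bin) {
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int j0 = 0; j0 < nc; ++j0)
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!bin(i0, j0) || lab(i0, j0)) continue;
      ++next;
      lab(i0, j0) = next;
      stack.clear();
      stack.push_back(j0 * nr + i0);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int i = p % nr, j = p / nr;
        for (int a = 0; a < 8; ++a) {
          const int ii = i + RDI[a], jj = j + RDJ[a];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (bin(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            stack.push_back(jj * nr + ii);
          }
        }
      }
    }
  return lab;
}

// Rotate an image by `angle` radians (counter-clockwise with the y axis
// pointing up, i.e. the usual mathematical convention applied to a matrix
// whose rows increase downwards). The canvas is enlarged to hold the rotated
// extent; out-of-range samples take `fill`.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_rotate(NumericMatrix img, double angle, bool bilinear,
                         double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const double c = std::cos(angle), s = std::sin(angle);
  const double w = nc - 1.0, h = nr - 1.0;
  const double wo = std::fabs(w * c) + std::fabs(h * s);
  const double ho = std::fabs(w * s) + std::fabs(h * c);
  const int nro = (int)std::ceil(ho - 1e-9) + 1;
  const int nco = (int)std::ceil(wo - 1e-9) + 1;
  const double cxi = w / 2.0, cyi = h / 2.0;
  const double cxo = (nco - 1) / 2.0, cyo = (nro - 1) / 2.0;
  NumericMatrix out(nro, nco);
  for (int jo = 0; jo < nco; ++jo)
    for (int io = 0; io < nro; ++io) {
      const double xo = jo - cxo, yo = -(io - cyo);
      // inverse rotation
      const double xi = c * xo + s * yo;
      const double yi = -s * xo + c * yo;
      const double cc = xi + cxi, rr = -yi + cyi;
      double v = fill;
      if (bilinear) {
        const int r0 = (int)std::floor(rr), c0 = (int)std::floor(cc);
        if (r0 >= -1 && r0 <= nr - 1 && c0 >= -1 && c0 <= nc - 1) {
          const double fr = rr - r0, fc = cc - c0;
          double acc = 0.0;
          const double wts[4] = {(1 - fr) * (1 - fc), (1 - fr) * fc,
                                 fr * (1 - fc), fr * fc};
          const int ri[4] = {r0, r0, r0 + 1, r0 + 1};
          const int ci[4] = {c0, c0 + 1, c0, c0 + 1};
          for (int q = 0; q < 4; ++q) {
            const double vv = (ri[q] >= 0 && ri[q] < nr && ci[q] >= 0 &&
                               ci[q] < nc)
                                  ? img(ri[q], ci[q])
                                  : fill;
            acc += wts[q] * vv;
          }
          v = acc;
        }
      } else {
        const int r0 = (int)std::lround(rr), c0 = (int)std::lround(cc);
        if (r0 >= 0 && r0 < nr && c0 >= 0 && c0 < nc) v = img(r0, c0);
      }
      out(io, jo) = v;
    }
  return out;
}

// Render a supersampled scene: stamp unit pixels at the given fine-grid
// coordinates (1-based), blur with an isotropic Gaussian (sigma in fine
// pixels, zero padding at the frame edge), then block-mean downscale by
// `factor`. The fine frame is (nr_coarse * factor) x (nc_coarse * factor)
// and never crosses the R boundary.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_render_scene(IntegerVector pr, IntegerVector pc,
                               double value, double sigma, int factor,
                               int nr_coarse, int nc_coarse) {
  const int nr = nr_coarse * factor, nc = nc_coarse * factor;
  std::vector<float> fine((size_t)nr * nc, 0.0f);
  for (int q = 0; q < pr.size(); ++q) {
    const int i = pr[q] - 1, j = pc[q] - 1;
    if (i >= 0 && i < nr && j >= 0 && j < nc)
      fine[(size_t)j * nr + i] = (float)value;
  }
  const int R = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<float> ker(2 * R + 1);
  double ksum = 0.0;
  for (int a = -R; a <= R; ++a) {
    ker[a + R] = (float)std::exp(-0.5 * a * a / (sigma * sigma));
    ksum += ker[a + R];
  }
  for (int a = 0; a <= 2 * R; ++a) ker[a] = (float)(ker[a] / ksum);

  // scatter-based separable blur: only non-zero sources contribute
  std::vector<float> tmp((size_t)nr * nc, 0.0f);
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const float v = fine[off + i];
      if (v == 0.0f) continue;
      const int lo = std::max(0, i - R), hi = std::min(nr - 1, i + R);
      for (int ii = lo; ii <= hi; ++ii) tmp[off + ii] += v * ker[ii - i + R];
    }
  }
  std::fill(fine.begin(), fine.end(), 0.0f);
  for (int j = 0; j < nc; ++j) {
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const float v = tmp[off + i];
      if (v == 0.0f) continue;
      const int lo = std::max(0, j - R), hi = std::min(nc - 1, j + R);
      for (int jj = lo; jj <= hi; ++jj)
        fine[(size_t)jj * nr + i] += v * ker[jj - j + R];
    }
  }

  NumericMatrix out(nr_coarse, nc_coarse);
  const double norm = 1.0 / ((double)factor * factor);
  for (int j = 0; j < nc; ++j) {
    const int J = j / factor;
    const size_t off = (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const float v = fine[off + i];
      if (v != 0.0f) out(i / factor, J) += v;
    }
  }
  for (int j = 0; j < nc_coarse; ++j)
    for (int i = 0; i < nr_coarse; ++i) out(i, j) *= norm;
  return out;
}

// Chebyshev (8-neighbourhood) binary dilation by `radius` pixels.
//' @noRd
// [[Rcpp::export]]
LogicalMatrix cpp_cheb_dilate(LogicalMatrix bin, int radius) {
  const int nr = bin.nrow(), nc = bin.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!bin(i, j)) continue;
      const int ilo = std::max(0, i - radius), ihi = std::min(nr - 1, i + radius);
      const int jlo = std::max(0, j - radius), jhi = std::min(nc - 1, j + radius);
      for (int jj = jlo; jj <= jhi; ++jj)
        for (int ii = ilo; ii <= ihi; ++ii) out(ii, jj) = true;
    }
  return out;
}

// Count of 8-neighbours that are foreground, for every pixel.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_neighbour_count(LogicalMatrix bin) {
  const int nr = bin.nrow(), nc = bin.ncol();
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int nb = 0;
      for (int a = 0; a < 8; ++a) {
        const int ii = i + RDI[a], jj = j + RDJ[a];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && bin(ii, jj)) ++nb;
      }
      out(i, j) = nb;
    }
  return out;
}
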