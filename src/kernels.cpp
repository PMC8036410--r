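#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Array convention: R arrays with dim = c(n1, n2, n3), column-major, so
// linear index = i1 + n1*(i2 + n2*i3). Axis 1 is z throughout the package.

static inline R_xlen_t IDX(int i1, int i2, int i3, int n1, int n2) {
  return (R_xlen_t)i1 + (R_xlen_t)n1 * ((R_xlen_t)i2 + (R_xlen_t)n2 * i3);
}

// ---------------------------------------------------------------------------
// Trilinear resampling onto a new lattice. Voxel centers sit at
// (i + 0.5) * spacing (0-based i); both grids share the physical origin.
// Out-of-range samples clamp to the nearest voxel center.
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector src, IntegerVector sdim,
                                     NumericVector sspc, IntegerVector odim,
                                     NumericVector ospc) {
  const int n1 = sdim[0], n2 = sdim[1], n3 = sdim[2];
  const int m1 = odim[0], m2 = odim[1], m3 = odim[2];
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  const double *s = src.begin();
  double *o = out.begin();

  std::vector<double> f1(m1), f2(m2), f3(m3);
  std::vector<int> b1(m1), b2(m2), b3(m3);
  for (int a = 0; a < 3; ++a) {
    int m = (a == 0 ? m1 : a == 1 ? m2 : m3);
    int n = (a == 0 ? n1 : a == 1 ? n2 : n3);
    std::vector<double> *f = (a == 0 ? &f1 : a == 1 ? &f2 : &f3);
    std::vector<int> *b = (a == 0 ? &b1 : a == 1 ? &b2 : &b3);
    for (int i = 0; i < m; ++i) {
      double x = ((i + 0.5) * ospc[a]) / sspc[a] - 0.5;  // fractional src index
      if (x < 0) x = 0;
      if (x > n - 1) x = n - 1;
      int lo = (int)std::floor(x);
      if (lo > n - 2) lo = n - 2;
      if (lo < 0) lo = 0;
      (*b)[i] = lo;
      (*f)[i] = x - lo;
    }
  }
  if (n1 == 1) { b1[0] = 0; f1[0] = 0.0; }

  for (int k = 0; k < m3; ++k) {
    int k0 = b3[k]; double tz = f3[k];
    int k1 = (n3 > 1) ? k0 + 1 : k0;
    for (int j = 0; j < m2; ++j) {
      int j0 = b2[j]; double ty = f2[j];
      int j1 = (n2 > 1) ? j0 + 1 : j0;
      for (int i = 0; i < m1; ++i) {
        int i0 = b1[i]; double tx = f1[i];
        int i1 = (n1 > 1) ? i0 + 1 : i0;
        double c000 = s[IDX(i0, j0, k0, n1, n2)];
        double c100 = s[IDX(i1, j0, k0, n1, n2)];
        double c010 = s[IDX(i0, j1, k0, n1, n2)];
        double c110 = s[IDX(i1, j1, k0, n1, n2)];
        double c001 = s[IDX(i0, j0, k1, n1, n2)];
        double c101 = s[IDX(i1, j0, k1, n1, n2)];
        double c011 = s[IDX(i0, j1, k1, n1, n2)];
        double c111 = s[IDX(i1, j1, k1, n1, n2)];
        double c00 = c000 + tx * (c100 - c000);
        double c10 = c010 + tx * (c110 - c010);
        double c01 = c001 + tx * (c101 - c001);
        double c11 = c011 + tx * (c111 - c011);
        double c0 = c00 + ty * (c10 - c00);
        double c1 = c01 + ty * (c11 - c01);
        o[IDX(i, j, k, m1, m2)] = c0 + tz * (c1 - c0);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Patchwise non-local means. For every search offset, the patchwise squared
// distance field is produced by three separable sliding-window box-filter
// passes (O(N) per offset, independent of patch size); symmetric offsets
// are processed once and accumulated on both endpoints. Patch distance d2
// is the mean squared difference over the (2p+1)^3 patch clipped to the
// valid region; weight = exp(-max(d2 - 2*sigma^2, 0) / h^2).

// fused: squared differences of a row pair, then sliding-window sums along
// axis 1 (contiguous), window [i-p, i+p] clipped to [a1, b1]
static void boxRowDiff(const float *p0, const float *q0, float *out,
                       int a1, int b1, int p) {
  int n = b1 - a1 + 1;
  if (n <= 0) return;
  std::vector<float> d(n);
  for (int t = 0; t < n; ++t) {
    float df = p0[a1 + t] - q0[a1 + t];
    d[t] = df * df;
  }
  double acc = 0;
  int hi0 = std::min(n - 1, p);
  for (int t = 0; t <= hi0; ++t) acc += d[t];
  out[a1] = (float)acc;
  for (int i = 1; i < n; ++i) {
    if (i + p <= n - 1) acc += d[i + p];
    if (i - p - 1 >= 0) acc -= d[i - p - 1];
    out[a1 + i] = (float)acc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_nlm3d(NumericVector src, IntegerVector dim, double sigma,
                        double h, int patch, int search) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  const R_xlen_t plane = (R_xlen_t)n1 * n2;
  const double *sd = src.begin();
  // all internal accumulation in single precision: weights are O(1), the
  // weighted sums are O(intensity), and ~350 terms at float precision keep
  // the relative error near 1e-5, far below the noise being removed
  std::vector<float> sF(N);
  for (R_xlen_t t = 0; t < N; ++t) sF[t] = (float)sd[t];
  const float *s = sF.data();
  std::vector<float> oF(sF);          // self weight 1
  std::vector<float> wsum(N, 1.0f);
  std::vector<float> B1(N), B2(N);
  std::vector<float> inv1(n1), cnt2(n2), cnt3(n3);

  // exp(-a) lookup on [0, 12], step 1/32, linear interpolation
  static float expTab[12 * 32 + 2];
  for (int t = 0; t < 12 * 32 + 2; ++t)
    expTab[t] = (float)std::exp(-t / 32.0);
  const float h2 = (float)(h * h);
  const float twoSig2 = (float)(2.0 * sigma * sigma);

  for (int d3 = -search; d3 <= search; ++d3) {
    for (int d2 = -search; d2 <= search; ++d2) {
      for (int d1 = -search; d1 <= search; ++d1) {
        // half-space: pair (x, x+d) handled once
        if (d3 < 0) continue;
        if (d3 == 0 && d2 < 0) continue;
        if (d3 == 0 && d2 == 0 && d1 <= 0) continue;
        // valid region for x such that x+d in bounds
        int a1 = std::max(0, -d1), b1 = n1 - 1 - std::max(0, d1);
        int a2 = std::max(0, -d2), b2 = n2 - 1 - std::max(0, d2);
        int a3 = std::max(0, -d3), b3 = n3 - 1 - std::max(0, d3);
        if (a1 > b1 || a2 > b2 || a3 > b3) continue;
        const R_xlen_t doff = (R_xlen_t)d1 + (R_xlen_t)n1 * d2 + plane * d3;

        // squared differences fused with the axis-1 box filter: src -> B2
        for (int k = a3; k <= b3; ++k)
          for (int j = a2; j <= b2; ++j) {
            R_xlen_t r = IDX(0, j, k, n1, n2);
            boxRowDiff(s + r, s + r + doff, &B2[r], a1, b1, patch);
          }
        // axis-2 box filter: B2 -> B1, rolling sum of contiguous rows
        for (int k = a3; k <= b3; ++k) {
          const R_xlen_t kb = (R_xlen_t)k * plane;
          for (int j = a2; j <= b2; ++j) {
            int jl = std::max(a2, j - patch), jh = std::min(b2, j + patch);
            float *dst = &B1[kb + (R_xlen_t)j * n1];
            if (j == a2) {
              for (int i = a1; i <= b1; ++i) dst[i] = 0.0f;
              for (int jt = jl; jt <= jh; ++jt) {
                const float *rw = &B2[kb + (R_xlen_t)jt * n1];
                for (int i = a1; i <= b1; ++i) dst[i] += rw[i];
              }
            } else {
              const float *prev = &B1[kb + (R_xlen_t)(j - 1) * n1];
              int jlp = std::max(a2, j - 1 - patch);
              int jhp = std::min(b2, j - 1 + patch);
              const float *add = (jh > jhp) ?
                &B2[kb + (R_xlen_t)jh * n1] : nullptr;
              const float *sub = (jl > jlp) ?
                &B2[kb + (R_xlen_t)jlp * n1] : nullptr;
              if (add && sub)
                for (int i = a1; i <= b1; ++i)
                  dst[i] = prev[i] + add[i] - sub[i];
              else if (add)
                for (int i = a1; i <= b1; ++i) dst[i] = prev[i] + add[i];
              else if (sub)
                for (int i = a1; i <= b1; ++i) dst[i] = prev[i] - sub[i];
              else
                for (int i = a1; i <= b1; ++i) dst[i] = prev[i];
            }
          }
        }
        // axis-3 box filter: B1 -> B2, rolling sum of planes
        for (int k = a3; k <= b3; ++k) {
          int kl = std::max(a3, k - patch), kh = std::min(b3, k + patch);
          for (int j = a2; j <= b2; ++j) {
            float *dst = &B2[(R_xlen_t)k * plane + (R_xlen_t)j * n1];
            if (k == a3) {
              for (int i = a1; i <= b1; ++i) dst[i] = 0.0f;
              for (int kt = kl; kt <= kh; ++kt) {
                const float *rw = &B1[(R_xlen_t)kt * plane +
                                      (R_xlen_t)j * n1];
                for (int i = a1; i <= b1; ++i) dst[i] += rw[i];
              }
            } else {
              const float *prev = &B2[(R_xlen_t)(k - 1) * plane +
                                      (R_xlen_t)j * n1];
              int klp = std::max(a3, k - 1 - patch);
              int khp = std::min(b3, k - 1 + patch);
              const float *add = (kh > khp) ?
                &B1[(R_xlen_t)kh * plane + (R_xlen_t)j * n1] : nullptr;
              const float *sub = (kl > klp) ?
                &B1[(R_xlen_t)klp * plane + (R_xlen_t)j * n1] : nullptr;
              if (add && sub)
                for (int i = a1; i <= b1; ++i)
                  dst[i] = prev[i] + add[i] - sub[i];
              else if (add)
                for (int i = a1; i <= b1; ++i) dst[i] = prev[i] + add[i];
              else if (sub)
                for (int i = a1; i <= b1; ++i) dst[i] = prev[i] - sub[i];
              else
                for (int i = a1; i <= b1; ++i) dst[i] = prev[i];
            }
          }
        }
        // per-axis clipped window lengths (reciprocal along axis 1)
        for (int i = a1; i <= b1; ++i)
          inv1[i] = 1.0f / (std::min(b1, i + patch) -
                            std::max(a1, i - patch) + 1);
        for (int j = a2; j <= b2; ++j)
          cnt2[j] = std::min(b2, j + patch) - std::max(a2, j - patch) + 1;
        for (int k = a3; k <= b3; ++k)
          cnt3[k] = std::min(b3, k + patch) - std::max(a3, k - patch) + 1;

        // weights and symmetric accumulation
        for (int k = a3; k <= b3; ++k)
          for (int j = a2; j <= b2; ++j) {
            const float icjk = 1.0f / (cnt2[j] * cnt3[k]);
            R_xlen_t x = IDX(a1, j, k, n1, n2);
            const float *Sv = &B2[x];
            for (int i = a1; i <= b1; ++i, ++x, ++Sv) {
              float d2m = *Sv * (icjk * inv1[i]) - twoSig2;
              float w;
              if (d2m <= 0) w = 1.0f;
              else {
                float a = d2m / h2;
                if (a >= 12.0f) continue;       // weight ~ 0
                float fi = a * 32.0f;
                int ti = (int)fi;
                w = expTab[ti] + (expTab[ti + 1] - expTab[ti]) * (fi - ti);
              }
              R_xlen_t y = x + doff;
              oF[x] += w * s[y]; wsum[x] += w;
              oF[y] += w * s[x]; wsum[y] += w;
            }
          }
      }
    }
  }
  NumericVector out(N);
  double *o = out.begin();
  for (R_xlen_t t = 0; t < N; ++t) o[t] = (double)oF[t] / wsum[t];
  return out;
}

// ---------------------------------------------------------------------------
// Hysteresis thresholding: voxels >= low that are 26-connected to a voxel
// >= high, via flood fill seeded at strong voxels.
// [[Rcpp::export]]
LogicalVector cpp_hysteresis(NumericVector src, IntegerVector dim,
                             double low, double high) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  const double *s = src.begin();
  std::vector<uint8_t> state(N, 0);  // 1 = in mask
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  for (R_xlen_t t = 0; t < N; ++t)
    if (s[t] >= high && !state[t]) { state[t] = 1; stack.push_back(t); }
  while (!stack.empty()) {
    R_xlen_t t = stack.back(); stack.pop_back();
    int i = (int)(t % n1);
    int j = (int)((t / n1) % n2);
    int k = (int)(t / ((R_xlen_t)n1 * n2));
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk; if (kk < 0 || kk >= n3) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj; if (jj < 0 || jj >= n2) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di; if (ii < 0 || ii >= n1) continue;
          R_xlen_t u = IDX(ii, jj, kk, n1, n2);
          if (!state[u] && s[u] >= low) { state[u] = 1; stack.push_back(u); }
        }
      }
    }
  }
  LogicalVector out(N);
  for (R_xlen_t t = 0; t < N; ++t) out[t] = (state[t] != 0);
  return out;
}

// ---------------------------------------------------------------------------
// Largest 26-connected foreground component.
// [[Rcpp::export]]
LogicalVector cpp_largest_component(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  const int *m = LOGICAL(mask);
  std::vector<int> label(N, 0);
  std::vector<R_xlen_t> stack;
  int nlab = 0;
  R_xlen_t bestSize = 0; int bestLab = 0;
  for (R_xlen_t t0 = 0; t0 < N; ++t0) {
    if (!m[t0] || label[t0]) continue;
    ++nlab;
    R_xlen_t size = 0;
    label[t0] = nlab; stack.push_back(t0);
    while (!stack.empty()) {
      R_xlen_t t = stack.back(); stack.pop_back();
      ++size;
      int i = (int)(t % n1);
      int j = (int)((t / n1) % n2);
      int k = (int)(t / ((R_xlen_t)n1 * n2));
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= n3) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= n2) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= n1) continue;
            R_xlen_t u = IDX(ii, jj, kk, n1, n2);
            if (m[u] && !label[u]) { label[u] = nlab; stack.push_back(u); }
          }
        }
      }
    }
    if (size > bestSize) { bestSize = size; bestLab = nlab; }
  }
  LogicalVector out(N);
  for (R_xlen_t t = 0; t < N; ++t) out[t] = (label[t] == bestLab && bestLab > 0);
  return out;
}

// ---------------------------------------------------------------------------
// Fill internal cavities: background is flood-filled 6-connected from the
// array border; unreached background becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  const int *m = LOGICAL(mask);
  std::vector<uint8_t> outside(N, 0);
  std::vector<R_xlen_t> stack;
  // a singleton axis (2D image embedded as (1, ny, nx)) must not make
  // every voxel a border voxel: border status is judged per non-degenerate
  // axis only
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        bool edge = (n1 > 1 && (i == 0 || i == n1 - 1)) ||
                    (n2 > 1 && (j == 0 || j == n2 - 1)) ||
                    (n3 > 1 && (k == 0 || k == n3 - 1));
        if (!edge) continue;
        R_xlen_t t = IDX(i, j, k, n1, n2);
        if (!m[t] && !outside[t]) { outside[t] = 1; stack.push_back(t); }
      }
  const int d1[6] = {1, -1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, 1, -1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    R_xlen_t t = stack.back(); stack.pop_back();
    int i = (int)(t % n1);
    int j = (int)((t / n1) % n2);
    int k = (int)(t / ((R_xlen_t)n1 * n2));
    for (int q = 0; q < 6; ++q) {
      int ii = i + d1[q], jj = j + d2[q], kk = k + d3[q];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      R_xlen_t u = IDX(ii, jj, kk, n1, n2);
      if (!m[u] && !outside[u]) { outside[u] = 1; stack.push_back(u); }
    }
  }
  LogicalVector out(N);
  for (R_xlen_t t = 0; t < N; ++t) out[t] = (m[t] || !outside[t]);
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (sigma per axis, in voxels; replicate edges).
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector src, IntegerVector dim,
                         NumericVector sigma) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const R_xlen_t N = (R_xlen_t)n1 * n2 * n3;
  std::vector<double> a(src.begin(), src.end()), b(N);
  for (int ax = 0; ax < 3; ++ax) {
    double sg = sigma[ax];
    if (sg <= 0) continue;
    int r = (int)std::ceil(3.0 * sg);
    std::vector<double> ker(2 * r + 1);
    double s = 0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (sg * sg));
      s += ker[t + r];
    }
    for (double &v : ker) v /= s;
    int n = (ax == 0 ? n1 : ax == 1 ? n2 : n3);
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int ii = i, jj = j, kk = k;
            int *p = (ax == 0 ? &ii : ax == 1 ? &jj : &kk);
            *p += t;
            if (*p < 0) *p = 0;
            if (*p >= n) *p = n - 1;
            acc += ker[t + r] * a[IDX(ii, jj, kk, n1, n2)];
          }
          b[IDX(i, j, k, n1, n2)] = acc;
        }
    a.swap(b);
  }
  return NumericVector(a.begin(), a.end());
}

// ---------------------------------------------------------------------------
// Iso-surface area by marching tetrahedra on a scalar field (voxel centers at
// (i+0.5)*spacing). Each cell is split into 6 tetrahedra around the main
// diagonal; triangle areas are accumulated, nothing is stored.

struct P3 { double x, y, z; };

static inline P3 lerpP(const P3 &A, const P3 &B, double va, double vb,
                       double iso) {
  double t = (iso - va) / (vb - va);
  P3 r; r.x = A.x + t * (B.x - A.x); r.y = A.y + t * (B.y - A.y);
  r.z = A.z + t * (B.z - A.z);
  return r;
}

static inline double triArea(const P3 &a, const P3 &b, const P3 &c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

static double tetArea(const P3 pt[4], const double v[4], double iso) {
  int in[4], ni = 0, out[4], no = 0;
  for (int t = 0; t < 4; ++t) {
    if (v[t] >= iso) in[ni++] = t; else out[no++] = t;
  }
  if (ni == 0 || ni == 4) return 0.0;
  if (ni == 1 || ni == 3) {
    int apex = (ni == 1) ? in[0] : out[0];
    int oth[3], c = 0;
    for (int t = 0; t < 4; ++t) if (t != apex) oth[c++] = t;
    P3 p0 = lerpP(pt[apex], pt[oth[0]], v[apex], v[oth[0]], iso);
    P3 p1 = lerpP(pt[apex], pt[oth[1]], v[apex], v[oth[1]], iso);
    P3 p2 = lerpP(pt[apex], pt[oth[2]], v[apex], v[oth[2]], iso);
    return triArea(p0, p1, p2);
  }
  // two in, two out: quad
  int A = in[0], B = in[1], C = out[0], D = out[1];
  P3 p0 = lerpP(pt[A], pt[C], v[A], v[C], iso);
  P3 p1 = lerpP(pt[A], pt[D], v[A], v[D], iso);
  P3 p2 = lerpP(pt[B], pt[D], v[B], v[D], iso);
  P3 p3 = lerpP(pt[B], pt[C], v[B], v[C], iso);
  return triArea(p0, p1, p2) + triArea(p0, p2, p3);
}

// [[Rcpp::export]]
double cpp_surface_area_mt(NumericVector field, IntegerVector dim,
                           NumericVector spacing, double iso) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double *f = field.begin();
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  // cube corners in (i,j,k) offsets; main diagonal corner 0 -> corner 6
  static const int co[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  double area = 0.0;
  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        double cv[8];
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          cv[c] = f[IDX(i + co[c][0], j + co[c][1], k + co[c][2], n1, n2)];
          if (cv[c] >= iso) anyIn = true; else anyOut = true;
        }
        if (!anyIn || !anyOut) continue;
        P3 cp[8];
        for (int c = 0; c < 8; ++c) {
          cp[c].x = (i + co[c][0]) * s1;
          cp[c].y = (j + co[c][1]) * s2;
          cp[c].z = (k + co[c][2]) * s3;
        }
        for (int t = 0; t < 6; ++t) {
          P3 pt[4]; double v[4];
          for (int c = 0; c < 4; ++c) {
            pt[c] = cp[tets[t][c]];
            v[c] = cv[tets[t][c]];
          }
          area += tetArea(pt, v, iso);
        }
      }
  return area;
}
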