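// 3D voxel kernels shared by the segmentation and measurement modules.
// All arrays are R arrays with dim = (nz, ny, nx); linear index
// i = z + nz*(y + ny*x) (z fastest, matching R's column-major layout).
// Physical spacing is (dz, dy, dx) in micrometres.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
#include <cstdint>
#include <climits>
#include <unordered_map>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Dims {
  int d0, d1, d2;      // nz, ny, nx
  Dims(const IntegerVector& d) : d0(d[0]), d1(d[1]), d2(d[2]) {}
  inline long long n() const { return (long long)d0 * d1 * d2; }
  inline long long idx(int z, int y, int x) const {
    return (long long)z + (long long)d0 * ((long long)y + (long long)d1 * x);
  }
  inline void unidx(long long i, int& z, int& y, int& x) const {
    z = (int)(i % d0); long long r = i / d0;
    y = (int)(r % d1); x = (int)(r / d1);
  }
};

// Neighbour offsets for 6/18/26 connectivity.
static void neighbour_offsets(int connectivity,
                              std::vector<int>& dz,
                              std::vector<int>& dy,
                              std::vector<int>& dx) {
  dz.clear(); dy.clear(); dx.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis (reflect boundary).
// axis: 0 = z, 1 = y, 2 = x. Kernel is odd-length, centred.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector arr, IntegerVector dims,
                                NumericVector kernel, int axis) {
  Dims D(dims);
  int n = (axis == 0) ? D.d0 : (axis == 1) ? D.d1 : D.d2;
  long long stride = (axis == 0) ? 1LL
                   : (axis == 1) ? (long long)D.d0
                   : (long long)D.d0 * D.d1;
  int klen = kernel.size();
  int kr = (klen - 1) / 2;
  NumericVector out(arr.size());
  std::vector<double> line(n), res(n);

  // iterate over all lines along `axis`
  int m1, m2; long long s1, s2;
  if (axis == 0)      { m1 = D.d1; m2 = D.d2; s1 = (long long)D.d0; s2 = (long long)D.d0 * D.d1; }
  else if (axis == 1) { m1 = D.d0; m2 = D.d2; s1 = 1LL;             s2 = (long long)D.d0 * D.d1; }
  else                { m1 = D.d0; m2 = D.d1; s1 = 1LL;             s2 = (long long)D.d0; }

  for (int j2 = 0; j2 < m2; ++j2) {
    for (int j1 = 0; j1 < m1; ++j1) {
      long long base = s1 * j1 + s2 * j2;
      for (int i = 0; i < n; ++i) line[i] = arr[base + stride * i];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = -kr; k <= kr; ++k) {
          int p = i + k;
          if (p < 0) p = -p - 1;            // reflect
          else if (p >= n) p = 2 * n - 1 - p;
          acc += line[p] * kernel[k + kr];
        }
        res[i] = acc;
      }
      for (int i = 0; i < n; ++i) out[base + stride * i] = res[i];
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Clipped moving (box) sum along one axis: window [i - rlo, i + rhi],
// clipped at borders (no padding). Used by the local-mean threshold.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_box_sum_axis(NumericVector arr, IntegerVector dims,
                               int rlo, int rhi, int axis) {
  Dims D(dims);
  int n = (axis == 0) ? D.d0 : (axis == 1) ? D.d1 : D.d2;
  long long stride = (axis == 0) ? 1LL
                   : (axis == 1) ? (long long)D.d0
                   : (long long)D.d0 * D.d1;
  NumericVector out(arr.size());
  std::vector<double> pref(n + 1);

  int m1, m2; long long s1, s2;
  if (axis == 0)      { m1 = D.d1; m2 = D.d2; s1 = (long long)D.d0; s2 = (long long)D.d0 * D.d1; }
  else if (axis == 1) { m1 = D.d0; m2 = D.d2; s1 = 1LL;             s2 = (long long)D.d0 * D.d1; }
  else                { m1 = D.d0; m2 = D.d1; s1 = 1LL;             s2 = (long long)D.d0; }

  for (int j2 = 0; j2 < m2; ++j2) {
    for (int j1 = 0; j1 < m1; ++j1) {
      long long base = s1 * j1 + s2 * j2;
      pref[0] = 0.0;
      for (int i = 0; i < n; ++i) pref[i + 1] = pref[i] + arr[base + stride * i];
      for (int i = 0; i < n; ++i) {
        int lo = i - rlo; if (lo < 0) lo = 0;
        int hi = i + rhi; if (hi > n - 1) hi = n - 1;
        out[base + stride * i] = pref[hi + 1] - pref[lo];
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// generalised to anisotropic sample spacing. Returns, for every TRUE
// voxel of `mask`, the distance (µm) to the nearest FALSE voxel
// (0 on FALSE voxels). If the mask has no FALSE voxel, distances are Inf.
// ---------------------------------------------------------------------------
// Squared distances above BIG are treated as "no site on this line";
// the parabola arithmetic stays exact with a large finite sentinel.
static const double BIG = 1e30;

static void dt1d(std::vector<double>& f, int n, double s,
                 std::vector<double>& d, std::vector<int>& v,
                 std::vector<double>& zz) {
  int k = 0;
  v[0] = 0;
  zz[0] = -INF;
  zz[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sth;
    while (true) {
      double xv = v[k] * s;
      sth = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (sth <= zz[k]) {
        --k;
        if (k < 0) { k = 0; v[0] = q; zz[0] = -INF; zz[1] = INF; sth = NA_REAL; break; }
      } else break;
    }
    if (ISNAN(sth)) continue;           // q replaced the only parabola
    ++k;
    v[k] = q;
    zz[k] = sth;
    zz[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zz[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

static void edt_axis(std::vector<double>& g, const Dims& D, double s, int axis) {
  int n = (axis == 0) ? D.d0 : (axis == 1) ? D.d1 : D.d2;
  long long stride = (axis == 0) ? 1LL
                   : (axis == 1) ? (long long)D.d0
                   : (long long)D.d0 * D.d1;
  int m1, m2; long long s1, s2;
  if (axis == 0)      { m1 = D.d1; m2 = D.d2; s1 = (long long)D.d0; s2 = (long long)D.d0 * D.d1; }
  else if (axis == 1) { m1 = D.d0; m2 = D.d2; s1 = 1LL;             s2 = (long long)D.d0 * D.d1; }
  else                { m1 = D.d0; m2 = D.d1; s1 = 1LL;             s2 = (long long)D.d0; }
  std::vector<double> f(n), d(n), zz(n + 1);
  std::vector<int> v(n);
  for (int j2 = 0; j2 < m2; ++j2) {
    for (int j1 = 0; j1 < m1; ++j1) {
      long long base = s1 * j1 + s2 * j2;
      for (int i = 0; i < n; ++i) f[i] = g[base + stride * i];
      dt1d(f, n, s, d, v, zz);
      for (int i = 0; i < n; ++i) g[base + stride * i] = d[i];
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  Dims D(dims);
  long long n = D.n();
  std::vector<double> g(n);
  for (long long i = 0; i < n; ++i) g[i] = mask[i] ? BIG : 0.0;
  edt_axis(g, D, spacing[0], 0);
  edt_axis(g, D, spacing[1], 1);
  edt_axis(g, D, spacing[2], 2);
  NumericVector out(n);
  for (long long i = 0; i < n; ++i)
    out[i] = (g[i] >= BIG) ? R_PosInf : std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary mask (6/18/26 connectivity).
// Labels are assigned in raster order of the component's first voxel,
// so the result is deterministic.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Dims D(dims);
  long long n = D.n();
  IntegerVector lab(n);
  std::vector<int> oz, oy, ox;
  neighbour_offsets(connectivity, oz, oy, ox);
  int nb = oz.size();
  std::vector<long long> stack;
  int next = 0;
  for (long long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      long long p = stack.back(); stack.pop_back();
      int z, y, x; D.unidx(p, z, y, x);
      for (int k = 0; k < nb; ++k) {
        int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
        if (zz < 0 || yy < 0 || xx < 0 || zz >= D.d0 || yy >= D.d1 || xx >= D.d2) continue;
        long long q = D.idx(zz, yy, xx);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Background flood from the volume border (6-connectivity on !mask).
// Returns TRUE for background voxels reachable from the border; holes
// (background not reached) can then be filled in R.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector cpp_flood_background(LogicalVector mask, IntegerVector dims) {
  Dims D(dims);
  long long n = D.n();
  LogicalVector vis(n);
  std::vector<long long> stack;
  auto push = [&](int z, int y, int x) {
    long long i = D.idx(z, y, x);
    if (!mask[i] && !vis[i]) { vis[i] = true; stack.push_back(i); }
  };
  for (int y = 0; y < D.d1; ++y)
    for (int x = 0; x < D.d2; ++x) { push(0, y, x); push(D.d0 - 1, y, x); }
  for (int z = 0; z < D.d0; ++z)
    for (int x = 0; x < D.d2; ++x) { push(z, 0, x); push(z, D.d1 - 1, x); }
  for (int z = 0; z < D.d0; ++z)
    for (int y = 0; y < D.d1; ++y) { push(z, y, 0); push(z, y, D.d2 - 1); }
  static const int oz[6] = {1,-1,0,0,0,0}, oy[6] = {0,0,1,-1,0,0}, ox[6] = {0,0,0,0,1,-1};
  while (!stack.empty()) {
    long long p = stack.back(); stack.pop_back();
    int z, y, x; D.unidx(p, z, y, x);
    for (int k = 0; k < 6; ++k) {
      int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
      if (zz < 0 || yy < 0 || xx < 0 || zz >= D.d0 || yy >= D.d1 || xx >= D.d2) continue;
      long long q = D.idx(zz, yy, xx);
      if (!mask[q] && !vis[q]) { vis[q] = true; stack.push_back(q); }
    }
  }
  vis.attr("dim") = dims;
  return vis;
}

// ---------------------------------------------------------------------------
// Morphological reconstruction by dilation (Vincent 1993 hybrid algorithm).
// marker <= ceiling pointwise; result is the largest image <= ceiling whose
// regional maxima structure is controlled by marker. The H-minima transform
// of I at depth h is obtained in R as -reconstruct_dilation(-(I + h), -I).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker, NumericVector ceiling_,
                                       IntegerVector dims, int connectivity) {
  Dims D(dims);
  long long n = D.n();
  NumericVector J(clone(marker));
  std::vector<int> oz, oy, ox;
  neighbour_offsets(connectivity, oz, oy, ox);
  int nb = oz.size();
  // split neighbourhood into "already scanned" (N-) and "not yet" (N+)
  std::vector<int> minus, plus;
  for (int k = 0; k < nb; ++k) {
    long long off = (long long)oz[k] + (long long)D.d0 * ((long long)oy[k] + (long long)D.d1 * ox[k]);
    if (off < 0) minus.push_back(k); else plus.push_back(k);
  }
  auto inb = [&](int z, int y, int x) {
    return z >= 0 && y >= 0 && x >= 0 && z < D.d0 && y < D.d1 && x < D.d2;
  };
  // forward raster scan
  for (long long i = 0; i < n; ++i) {
    int z, y, x; D.unidx(i, z, y, x);
    double m = J[i];
    for (size_t kk = 0; kk < minus.size(); ++kk) {
      int k = minus[kk];
      int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
      if (!inb(zz, yy, xx)) continue;
      double v = J[D.idx(zz, yy, xx)];
      if (v > m) m = v;
    }
    J[i] = std::min(m, ceiling_[i]);
  }
  // backward raster scan + queue seeding
  std::queue<long long> fifo;
  for (long long i = n - 1; i >= 0; --i) {
    int z, y, x; D.unidx(i, z, y, x);
    double m = J[i];
    for (size_t kk = 0; kk < plus.size(); ++kk) {
      int k = plus[kk];
      int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
      if (!inb(zz, yy, xx)) continue;
      double v = J[D.idx(zz, yy, xx)];
      if (v > m) m = v;
    }
    J[i] = std::min(m, ceiling_[i]);
    for (size_t kk = 0; kk < plus.size(); ++kk) {
      int k = plus[kk];
      int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
      if (!inb(zz, yy, xx)) continue;
      long long q = D.idx(zz, yy, xx);
      if (J[q] < J[i] && J[q] < ceiling_[q]) { fifo.push(i); break; }
    }
  }
  // queue propagation
  while (!fifo.empty()) {
    long long p = fifo.front(); fifo.pop();
    int z, y, x; D.unidx(p, z, y, x);
    for (int k = 0; k < nb; ++k) {
      int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
      if (!inb(zz, yy, xx)) continue;
      long long q = D.idx(zz, yy, xx);
      if (J[q] < J[p] && ceiling_[q] != J[q]) {
        J[q] = std::min(J[p], ceiling_[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = dims;
  return J;
}

// ---------------------------------------------------------------------------
// Regional minima of an image restricted to a mask. A regional minimum is a
// connected plateau (equal values) with no neighbour of lower value inside
// the mask. Returns an integer labelling of the minima (0 elsewhere).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_regional_minima(NumericVector img, LogicalVector mask,
                                  IntegerVector dims, int connectivity) {
  Dims D(dims);
  long long n = D.n();
  IntegerVector lab(n);             // 0 unvisited, -1 visited non-minimum, >0 minimum id
  std::vector<int> oz, oy, ox;
  neighbour_offsets(connectivity, oz, oy, ox);
  int nb = oz.size();
  std::vector<long long> comp, stack;
  int next = 0;
  for (long long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    double v = img[i];
    bool is_min = true;
    comp.clear(); stack.clear();
    stack.push_back(i);
    lab[i] = -2;                    // temporary in-plateau mark
    comp.push_back(i);
    while (!stack.empty()) {
      long long p = stack.back(); stack.pop_back();
      int z, y, x; D.unidx(p, z, y, x);
      for (int k = 0; k < nb; ++k) {
        int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
        if (zz < 0 || yy < 0 || xx < 0 || zz >= D.d0 || yy >= D.d1 || xx >= D.d2) continue;
        long long q = D.idx(zz, yy, xx);
        if (!mask[q]) continue;
        if (img[q] < v) { is_min = false; continue; }
        if (img[q] == v && lab[q] == 0) {
          lab[q] = -2; comp.push_back(q); stack.push_back(q);
        }
      }
    }
    int tag;
    if (is_min) { ++next; tag = next; } else tag = -1;
    for (size_t k = 0; k < comp.size(); ++k) lab[comp[k]] = tag;
  }
  for (long long i = 0; i < n; ++i) if (lab[i] < 0) lab[i] = 0;
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed by priority flooding. `priority` is the
// topographic surface (flooded in ascending order); `markers` holds seed
// labels (>0) at seed voxels; flooding is restricted to `mask`. Ties on
// plateaus are broken deterministically by insertion age (FIFO), so fronts
// advance evenly across flat regions and meet midway.
// Every mask voxel reachable from a marker receives exactly one label.
// ---------------------------------------------------------------------------
struct WsNode {
  double val;
  long long key;     // deterministic tie-break
  long long idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.val != b.val) return a.val > b.val;   // min-heap on value
    return a.key > b.key;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed(NumericVector priority, IntegerVector markers,
                                   LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  Dims D(dims);
  long long n = D.n();
  IntegerVector lab(n);
  std::vector<int> oz, oy, ox;
  neighbour_offsets(connectivity, oz, oy, ox);
  int nb = oz.size();
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  std::vector<char> queued(n, 0);
  long long age = 0;
  for (long long i = 0; i < n; ++i) {
    if (markers[i] > 0) { pq.push({priority[i], age++, i, markers[i]}); queued[i] = 1; }
  }
  // each voxel is pushed once, by the first front reaching it; since every
  // queue entry for a voxel would carry the voxel's own priority and ties
  // resolve by insertion age, the single-push scheme is exact
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    lab[nd.idx] = nd.label;
    int z, y, x; D.unidx(nd.idx, z, y, x);
    for (int k = 0; k < nb; ++k) {
      int zz = z + oz[k], yy = y + oy[k], xx = x + ox[k];
      if (zz < 0 || yy < 0 || xx < 0 || zz >= D.d0 || yy >= D.d1 || xx >= D.d2) continue;
      long long q = D.idx(zz, yy, xx);
      if (mask[q] && !queued[q]) { pq.push({priority[q], age++, q, nd.label}); queued[q] = 1; }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// One-pass per-label accumulators: voxel count, coordinate sums and second
// moments (µm, voxel centres), bounding box (voxel indices, 0-based), and
// per-channel intensity sums. Labels must be 1..nlab (0 = background).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_label_stats(IntegerVector labels, IntegerVector dims,
                     NumericVector spacing, List channels) {
  Dims D(dims);
  long long n = D.n();
  int nlab = 0;
  for (long long i = 0; i < n; ++i) if (labels[i] > nlab) nlab = labels[i];
  int nc = channels.size();
  NumericMatrix mom(nlab, 10);   // n, sz, sy, sx, szz, syy, sxx, szy, szx, syx
  IntegerMatrix bbox(nlab, 6);   // zmin, zmax, ymin, ymax, xmin, xmax
  NumericMatrix inten(nlab, std::max(nc, 1));
  for (int l = 0; l < nlab; ++l) {
    bbox(l, 0) = bbox(l, 2) = bbox(l, 4) = INT_MAX;
    bbox(l, 1) = bbox(l, 3) = bbox(l, 5) = -1;
  }
  std::vector<const double*> chp(nc);
  for (int c = 0; c < nc; ++c) chp[c] = REAL(channels[c]);
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  for (long long i = 0; i < n; ++i) {
    int l = labels[i];
    if (l <= 0) continue;
    int z, y, x; D.unidx(i, z, y, x);
    double pz = z * dz, py = y * dy, px = x * dx;
    int r = l - 1;
    mom(r, 0) += 1.0;
    mom(r, 1) += pz;  mom(r, 2) += py;  mom(r, 3) += px;
    mom(r, 4) += pz * pz; mom(r, 5) += py * py; mom(r, 6) += px * px;
    mom(r, 7) += pz * py; mom(r, 8) += pz * px; mom(r, 9) += py * px;
    if (z < bbox(r, 0)) bbox(r, 0) = z;
    if (z > bbox(r, 1)) bbox(r, 1) = z;
    if (y < bbox(r, 2)) bbox(r, 2) = y;
    if (y > bbox(r, 3)) bbox(r, 3) = y;
    if (x < bbox(r, 4)) bbox(r, 4) = x;
    if (x > bbox(r, 5)) bbox(r, 5) = x;
    for (int c = 0; c < nc; ++c) inten(r, c) += chp[c][i];
  }
  return List::create(_["moments"] = mom, _["bbox"] = bbox, _["intensity"] = inten);
}

// ---------------------------------------------------------------------------
// Surface area of the `level` iso-surface of a scalar field, by marching
// tetrahedra (each cube cell split into 6 tetrahedra around the main
// diagonal, iso-vertices by linear interpolation). Physical spacing applied.
// ---------------------------------------------------------------------------
static inline void interp_pt(const double* pa, const double* pb, double va,
                             double vb, double level, double* out) {
  double t = (level - va) / (vb - va);
  out[0] = pa[0] + t * (pb[0] - pa[0]);
  out[1] = pa[1] + t * (pb[1] - pa[1]);
  out[2] = pa[2] + t * (pb[2] - pa[2]);
}
static inline double tri_area(const double* a, const double* b, const double* c) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double w[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
  return 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
}

// [[Rcpp::export]]
double cpp_surface_area(NumericVector vol, IntegerVector dims,
                        NumericVector spacing, double level) {
  Dims D(dims);
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  // 6-tetrahedra decomposition of the unit cube around diagonal 0-7;
  // cube corner c = (cz, cy, cx) bit-coded as cz + 2*cy + 4*cx.
  static const int tets[6][4] = {
    {0,1,3,7}, {0,3,2,7}, {0,2,6,7}, {0,6,4,7}, {0,4,5,7}, {0,5,1,7}
  };
  double area = 0.0;
  double corner[8][3];
  double val[8];
  for (int x = 0; x < D.d2 - 1; ++x)
    for (int y = 0; y < D.d1 - 1; ++y)
      for (int z = 0; z < D.d0 - 1; ++z) {
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int cz = c & 1, cy = (c >> 1) & 1, cx = (c >> 2) & 1;
          val[c] = vol[D.idx(z + cz, y + cy, x + cx)];
          corner[c][0] = (z + cz) * dz;
          corner[c][1] = (y + cy) * dy;
          corner[c][2] = (x + cx) * dx;
          if (val[c] > level) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4]; double vv[4]; const double* vp[4];
          int nin = 0;
          for (int k = 0; k < 4; ++k) {
            vi[k] = tets[t][k];
            vv[k] = val[vi[k]];
            vp[k] = corner[vi[k]];
            if (vv[k] > level) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          int in_[4], out_[4]; int ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (vv[k] > level) in_[ni++] = k; else out_[no++] = k;
          }
          double p1[3], p2[3], p3[3], p4[3];
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in_[0] : out_[0];
            int o[3]; int c2 = 0;
            for (int k = 0; k < 4; ++k) if (k != a) o[c2++] = k;
            interp_pt(vp[a], vp[o[0]], vv[a], vv[o[0]], level, p1);
            interp_pt(vp[a], vp[o[1]], vv[a], vv[o[1]], level, p2);
            interp_pt(vp[a], vp[o[2]], vv[a], vv[o[2]], level, p3);
            area += tri_area(p1, p2, p3);
          } else { // nin == 2: quad
            int a = in_[0], b = in_[1], c1 = out_[0], c2o = out_[1];
            interp_pt(vp[a], vp[c1],  vv[a], vv[c1],  level, p1);
            interp_pt(vp[a], vp[c2o], vv[a], vv[c2o], level, p2);
            interp_pt(vp[b], vp[c2o], vv[b], vv[c2o], level, p3);
            interp_pt(vp[b], vp[c1],  vv[b], vv[c1],  level, p4);
            area += tri_area(p1, p2, p3);
            area += tri_area(p1, p3, p4);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Rasterise ellipsoids into an integer label volume. `centers` (µm, z/y/x),
// `quadrics` holds the 3x3 inside-test matrix M of each ellipsoid row-major
// (voxel inside iff d' M d <= 1, d in µm), `radius` the per-ellipsoid
// bounding radius (µm). Contested voxels go to the ellipsoid with the
// smallest quadratic form value (deepest inside).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_rasterize_ellipsoids(IntegerVector dims, NumericVector spacing,
                                       NumericMatrix centers, NumericMatrix quadrics,
                                       NumericVector radius) {
  Dims D(dims);
  long long n = D.n();
  IntegerVector lab(n);
  std::vector<double> qbest(n, INF);
  double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  int nell = centers.nrow();
  for (int e = 0; e < nell; ++e) {
    double cz = centers(e, 0), cy = centers(e, 1), cx = centers(e, 2);
    double r = radius[e];
    int z0 = std::max(0, (int)std::floor((cz - r) / dz));
    int z1 = std::min(D.d0 - 1, (int)std::ceil((cz + r) / dz));
    int y0 = std::max(0, (int)std::floor((cy - r) / dy));
    int y1 = std::min(D.d1 - 1, (int)std::ceil((cy + r) / dy));
    int x0 = std::max(0, (int)std::floor((cx - r) / dx));
    int x1 = std::min(D.d2 - 1, (int)std::ceil((cx + r) / dx));
    double m00 = quadrics(e, 0), m01 = quadrics(e, 1), m02 = quadrics(e, 2);
    double m11 = quadrics(e, 4), m12 = quadrics(e, 5), m22 = quadrics(e, 8);
    for (int x = x0; x <= x1; ++x) {
      double ddx = x * dx - cx;
      for (int y = y0; y <= y1; ++y) {
        double ddy = y * dy - cy;
        for (int z = z0; z <= z1; ++z) {
          double ddz = z * dz - cz;
          double q = m00*ddz*ddz + m11*ddy*ddy + m22*ddx*ddx
                   + 2.0*(m01*ddz*ddy + m02*ddz*ddx + m12*ddy*ddx);
          if (q <= 1.0) {
            long long i = D.idx(z, y, x);
            if (q < qbest[i]) { qbest[i] = q; lab[i] = e + 1; }
          }
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---------------------------------------------------------------------------
// Joint overlap counts between two label volumes (for Jaccard scoring).
// Returns a matrix with columns (label_a, label_b, voxels) over all pairs
// with label_a > 0 or label_b > 0.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_overlap_counts(IntegerVector a, IntegerVector b) {
  long long n = a.size();
  int amax = 0, bmax = 0;
  for (long long i = 0; i < n; ++i) {
    if (a[i] > amax) amax = a[i];
    if (b[i] > bmax) bmax = b[i];
  }
  std::unordered_map<long long, int> counts;
  for (long long i = 0; i < n; ++i) {
    if (a[i] == 0 && b[i] == 0) continue;
    long long key = (long long)a[i] * (bmax + 1) + b[i];
    ++counts[key];
  }
  IntegerMatrix out(counts.size(), 3);
  int r = 0;
  for (auto& kv : counts) {
    out(r, 0) = (int)(kv.first / (bmax + 1));
    out(r, 1) = (int)(kv.first % (bmax + 1));
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}
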