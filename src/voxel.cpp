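#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Shape kinds (kept in sync with .shape_code() on the R side):
// 1 box, 2 cylinder, 3 deformed cylinder, 4 prism, 5 ellipsoid, 6 tube.
//
// Conventions: x spans the a dimension, y the b dimension, z the height h.
// z runs from 0 to h; x and y are centred on the shape axis. Cortical layers
// are grown inward, so the printed dimensions are outer dimensions. The
// spongiosa is the erosion of the shape by the face-specific thicknesses,
// and the cortical label is (inside shape) minus (inside spongiosa); both the
// voxel and the analytic paths share this definition.

struct ShapeCtx {
  int kind;
  double h, a, b, c, d;
  // cortical offsets, meaning depends on kind (see R side packing)
  double t0, t1, t2, t3, t4, t5;
  // prism helpers
  double apex, side_norm;
};

static inline bool inside_shape(const ShapeCtx &S, double x, double y, double z) {
  if (z < 0.0 || z > S.h) return false;
  switch (S.kind) {
  case 1: // box
    return std::fabs(x) <= S.a / 2.0 && std::fabs(y) <= S.b / 2.0;
  case 2: { // elliptic cylinder
    double u = x / (S.a / 2.0), v = y / (S.b / 2.0);
    return u * u + v * v <= 1.0;
  }
  case 3: { // deformed cylinder: axes interpolated linearly along z
    double t = z / S.h;
    double A = S.a + (S.c - S.a) * t, B = S.b + (S.d - S.b) * t;
    double u = x / (A / 2.0), v = y / (B / 2.0);
    return u * u + v * v <= 1.0;
  }
  case 4: { // isosceles triangular prism, base edge a on y = 0, apex at y = m
    if (y < 0.0) return false;
    double a2 = S.a / 2.0, m = S.apex;
    // right edge: x/a2 + y/m <= 1; left edge mirrored
    return (x * m + y * a2 - a2 * m) <= 0.0 && (-x * m + y * a2 - a2 * m) <= 0.0;
  }
  case 5: { // ellipsoid with axes a (x), b (y), h (z)
    double u = x / (S.a / 2.0), v = y / (S.b / 2.0), w = (z - S.h / 2.0) / (S.h / 2.0);
    return u * u + v * v + w * w <= 1.0;
  }
  case 6: { // tube: annulus between circles of diameter b (inner) and a (outer)
    double r2 = x * x + y * y;
    double ro = S.a / 2.0, ri = S.b / 2.0;
    return r2 <= ro * ro && r2 >= ri * ri;
  }
  }
  return false;
}

static inline bool inside_spongiosa(const ShapeCtx &S, double x, double y, double z) {
  switch (S.kind) {
  case 1: { // offsets: xlo xhi ylo yhi zlo zhi
    return x >= -S.a / 2.0 + S.t0 && x <= S.a / 2.0 - S.t1 &&
           y >= -S.b / 2.0 + S.t2 && y <= S.b / 2.0 - S.t3 &&
           z >= S.t4 && z <= S.h - S.t5;
  }
  case 2: { // t0 lateral, t1 zlo, t2 zhi
    if (z < S.t1 || z > S.h - S.t2) return false;
    double A = S.a - 2.0 * S.t0, B = S.b - 2.0 * S.t0;
    if (A <= 0.0 || B <= 0.0) return false;
    double u = x / (A / 2.0), v = y / (B / 2.0);
    return u * u + v * v <= 1.0;
  }
  case 3: { // t0 lateral
    if (z < 0.0 || z > S.h) return false;
    double t = z / S.h;
    double A = S.a + (S.c - S.a) * t - 2.0 * S.t0;
    double B = S.b + (S.d - S.b) * t - 2.0 * S.t0;
    if (A <= 0.0 || B <= 0.0) return false;
    double u = x / (A / 2.0), v = y / (B / 2.0);
    return u * u + v * v <= 1.0;
  }
  case 4: { // t0 base (ah), t1 right (bh), t2 left (ch), t3 zlo, t4 zhi
    if (z < S.t3 || z > S.h - S.t4) return false;
    if (y < S.t0) return false;
    double a2 = S.a / 2.0, m = S.apex, nrm = S.side_norm;
    double dr = -(x * m + y * a2 - a2 * m) / nrm; // inward distance to right edge
    double dl = -(-x * m + y * a2 - a2 * m) / nrm;
    return dr >= S.t1 && dl >= S.t2;
  }
  case 5: { // t0 total: erode all three axes
    double A = S.a - 2.0 * S.t0, B = S.b - 2.0 * S.t0, H = S.h - 2.0 * S.t0;
    if (A <= 0.0 || B <= 0.0 || H <= 0.0) return false;
    double u = x / (A / 2.0), v = y / (B / 2.0), w = (z - S.h / 2.0) / (H / 2.0);
    return u * u + v * v + w * w <= 1.0;
  }
  case 6: { // t0 lateral (outer), t1 zlo, t2 zhi
    if (z < S.t1 || z > S.h - S.t2) return false;
    double ro = S.a / 2.0 - S.t0, ri = S.b / 2.0;
    if (ro <= ri) return false;
    double r2 = x * x + y * y;
    return r2 <= ro * ro && r2 >= ri * ri;
  }
  }
  return false;
}

static ShapeCtx make_ctx(int kind, NumericVector dims, NumericVector cort) {
  ShapeCtx S;
  S.kind = kind;
  S.h = dims[0]; S.a = dims[1]; S.b = dims[2];
  S.c = dims.size() > 3 && R_finite(dims[3]) ? dims[3] : 0.0;
  S.d = dims.size() > 4 && R_finite(dims[4]) ? dims[4] : 0.0;
  S.t0 = S.t1 = S.t2 = S.t3 = S.t4 = S.t5 = 0.0;
  if (cort.size() > 0) S.t0 = cort[0];
  if (cort.size() > 1) S.t1 = cort[1];
  if (cort.size() > 2) S.t2 = cort[2];
  if (cort.size() > 3) S.t3 = cort[3];
  if (cort.size() > 4) S.t4 = cort[4];
  if (cort.size() > 5) S.t5 = cort[5];
  S.apex = 0.0; S.side_norm = 1.0;
  if (kind == 4) {
    double a2 = S.a / 2.0;
    S.apex = std::sqrt(S.b * S.b - a2 * a2);
    S.side_norm = std::sqrt(S.apex * S.apex + a2 * a2);
  }
  return S;
}

// Label a shape on an isotropic grid by centre-point sampling.
// Returns 0 background, 1 spongiosa (marrow), 3 cortical bone.
// [[Rcpp::export]]
IntegerVector cpp_label_shape(int kind, NumericVector dims, double vox,
                              IntegerVector n, NumericVector orig,
                              NumericVector cort) {
  ShapeCtx S = make_ctx(kind, dims, cort);
  const int nx = n[0], ny = n[1], nz = n[2];
  IntegerVector lab(static_cast<R_xlen_t>(nx) * ny * nz);
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    double z = orig[2] + (k + 0.5) * vox;
    for (int j = 0; j < ny; ++j) {
      double y = orig[1] + (j + 0.5) * vox;
      for (int i = 0; i < nx; ++i, ++idx) {
        double x = orig[0] + (i + 0.5) * vox;
        if (!inside_shape(S, x, y, z)) continue;
        lab[idx] = inside_spongiosa(S, x, y, z) ? 1 : 3;
      }
    }
  }
  lab.attr("dim") = n;
  return lab;
}

// Count voxels strictly inside the shape (no labelling), for volume oracles
// on grids too large to keep in memory comfortably.
// [[Rcpp::export]]
double cpp_count_inside(int kind, NumericVector dims, double vox,
                        IntegerVector n, NumericVector orig) {
  NumericVector cort(0);
  ShapeCtx S = make_ctx(kind, dims, cort);
  const int nx = n[0], ny = n[1], nz = n[2];
  double cnt = 0.0;
  for (int k = 0; k < nz; ++k) {
    double z = orig[2] + (k + 0.5) * vox;
    for (int j = 0; j < ny; ++j) {
      double y = orig[1] + (j + 0.5) * vox;
      for (int i = 0; i < nx; ++i) {
        double x = orig[0] + (i + 0.5) * vox;
        if (inside_shape(S, x, y, z)) cnt += 1.0;
      }
    }
  }
  return cnt;
}

// Stamp cylindrical rods into the marrow phase (label 1 -> 2), in order,
// stopping at the first rod for which the converted-voxel count reaches
// `target`. If keeping that rod leaves the count farther from the target than
// dropping it, the rod is reverted. Returns the per-rod cumulative counts up
// to the last rod considered. `labels` is modified in place.
// Rod matrix columns: cx, cy, cz, ux, uy, uz, radius, half-length.
// [[Rcpp::export]]
List cpp_stamp_rods(IntegerVector labels, IntegerVector n, double vox,
                    NumericVector orig, NumericMatrix rods, double target) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const R_xlen_t nxy = static_cast<R_xlen_t>(nx) * ny;
  std::vector<double> cum;
  cum.reserve(rods.nrow());
  double tot = 0.0;
  std::vector<R_xlen_t> touched;
  int used = 0;
  bool reached = false;
  for (int r = 0; r < rods.nrow(); ++r) {
    double cx = rods(r, 0), cy = rods(r, 1), cz = rods(r, 2);
    double ux = rods(r, 3), uy = rods(r, 4), uz = rods(r, 5);
    double rad = rods(r, 6), hl = rods(r, 7);
    double ex = hl * std::fabs(ux) + rad, ey = hl * std::fabs(uy) + rad,
           ez = hl * std::fabs(uz) + rad;
    int i0 = std::max(0, (int)std::floor((cx - ex - orig[0]) / vox - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + ex - orig[0]) / vox - 0.5));
    int j0 = std::max(0, (int)std::floor((cy - ey - orig[1]) / vox - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + ey - orig[1]) / vox - 0.5));
    int k0 = std::max(0, (int)std::floor((cz - ez - orig[2]) / vox - 0.5));
    int k1 = std::min(nz - 1, (int)std::ceil((cz + ez - orig[2]) / vox - 0.5));
    touched.clear();
    double r2 = rad * rad;
    for (int k = k0; k <= k1; ++k) {
      double z = orig[2] + (k + 0.5) * vox - cz;
      for (int j = j0; j <= j1; ++j) {
        double y = orig[1] + (j + 0.5) * vox - cy;
        for (int i = i0; i <= i1; ++i) {
          R_xlen_t idx = static_cast<R_xlen_t>(k) * nxy + static_cast<R_xlen_t>(j) * nx + i;
          if (labels[idx] != 1) continue;
          double x = orig[0] + (i + 0.5) * vox - cx;
          double proj = x * ux + y * uy + z * uz;
          if (std::fabs(proj) > hl) continue;
          double perp2 = x * x + y * y + z * z - proj * proj;
          if (perp2 > r2) continue;
          labels[idx] = 2;
          touched.push_back(idx);
        }
      }
    }
    double newtot = tot + touched.size();
    if (newtot >= target) {
      // keep or revert the crossing rod, whichever lands closer to target
      if (newtot - target > target - tot) {
        for (size_t q = 0; q < touched.size(); ++q) labels[touched[q]] = 1;
        used = r; // rod r not used
        cum.push_back(tot);
      } else {
        tot = newtot;
        used = r + 1;
        cum.push_back(tot);
      }
      reached = true;
      break;
    }
    tot = newtot;
    cum.push_back(tot);
    used = r + 1;
  }
  return List::create(_["cumulative"] = wrap(cum), _["rods_used"] = used,
                      _["converted"] = tot, _["reached"] = reached);
}

// ---- exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher)

static void edt_1d(const std::vector<double> &f, std::vector<double> &d, int n,
                   std::vector<int> &v, std::vector<double> &zbuf) {
  int k = 0;
  v[0] = 0;
  zbuf[0] = -INFINITY;
  zbuf[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zbuf[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zbuf[k] = s;
    zbuf[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Local thickness of the TRUE phase of `mask`: for every foreground voxel,
// the diameter (in mm) of the largest inscribed sphere containing it
// (Hildebrand-Rueegsegger definition, computed by sphere painting over the
// exact EDT). Returns a numeric array; background voxels are 0.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector n, double vox) {
  const int nx = n[0], ny = n[1], nz = n[2];
  const R_xlen_t nxy = static_cast<R_xlen_t>(nx) * ny;
  const R_xlen_t N = nxy * nz;
  const double BIG = 1e12;
  std::vector<double> dt(N);
  for (R_xlen_t i = 0; i < N; ++i) dt[i] = mask[i] ? BIG : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), dcol(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = k * nxy + static_cast<R_xlen_t>(j) * nx;
      for (int i = 0; i < nx; ++i) f[i] = dt[base + i];
      edt_1d(f, dcol, nx, v, zbuf);
      for (int i = 0; i < nx; ++i) dt[base + i] = dcol[i];
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = k * nxy + i;
      for (int j = 0; j < ny; ++j) f[j] = dt[base + static_cast<R_xlen_t>(j) * nx];
      edt_1d(f, dcol, ny, v, zbuf);
      for (int j = 0; j < ny; ++j) dt[base + static_cast<R_xlen_t>(j) * nx] = dcol[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = static_cast<R_xlen_t>(j) * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = dt[base + k * nxy];
      edt_1d(f, dcol, nz, v, zbuf);
      for (int k = 0; k < nz; ++k) dt[base + k * nxy] = dcol[k];
    }

  // Paint every maximal ball except those provably contained in a
  // neighbour's ball: ball(p, r_p) is inside ball(q, r_q) when
  // dist(p, q) + r_p <= r_q, and containment is transitive, so pruning by
  // the 6-neighbourhood is exact and removes most interior voxels.
  NumericVector out(N);
  const R_xlen_t strides[6] = {1, -1, nx, -nx, nxy, -nxy};
  for (R_xlen_t p = 0; p < N; ++p) {
    if (dt[p] <= 0.0) continue;
    double r = std::sqrt(dt[p]);
    int pk = (int)(p / nxy);
    int pj = (int)((p - (R_xlen_t)pk * nxy) / nx);
    int pi = (int)(p - (R_xlen_t)pk * nxy - (R_xlen_t)pj * nx);
    bool contained = false;
    for (int s = 0; s < 6 && !contained; ++s) {
      int qi = pi, qj = pj, qk = pk;
      if (s == 0) ++qi; else if (s == 1) --qi;
      else if (s == 2) ++qj; else if (s == 3) --qj;
      else if (s == 4) ++qk; else --qk;
      if (qi < 0 || qi >= nx || qj < 0 || qj >= ny || qk < 0 || qk >= nz)
        continue;
      double dq = dt[p + strides[s]];
      if (dq > 0.0 && std::sqrt(dq) >= r + 1.0 - 1e-9) contained = true;
    }
    if (contained) continue;
    // half-voxel correction: centre-to-centre distances overshoot the
    // continuous inscribed radius by about half a voxel on each side
    double th = 2.0 * r - 0.5;
    if (th <= 0.0) th = 1.0;
    int ir = (int)std::ceil(r);
    double r2 = dt[p];
    for (int dk = -ir; dk <= ir; ++dk) {
      int k = pk + dk;
      if (k < 0 || k >= nz) continue;
      for (int dj = -ir; dj <= ir; ++dj) {
        int j = pj + dj;
        if (j < 0 || j >= ny) continue;
        double dd = (double)dk * dk + (double)dj * dj;
        if (dd > r2) continue;
        R_xlen_t base = (R_xlen_t)k * nxy + (R_xlen_t)j * nx;
        for (int di = -ir; di <= ir; ++di) {
          int i = pi + di;
          if (i < 0 || i >= nx) continue;
          if (dd + (double)di * di > r2) continue;
          R_xlen_t q = base + i;
          if (dt[q] > 0.0 && out[q] < th) out[q] = th;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < N; ++i) out[i] *= vox;
  out.attr("dim") = n;
  return out;
}
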