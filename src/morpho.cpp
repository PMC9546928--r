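// Low-level grid operations shared by the morphometry modules:
//  - connected-component labelling (8-connectivity in 2D, 26 in 3D)
//  - anisotropic squared Euclidean distance transform (Felzenszwalb-Huttenlocher)
//  - separable Gaussian smoothing on 2D/3D grids
//  - iso-surface area by marching tetrahedra (6-tet cube decomposition)
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims) {
  const int nd = dims.size();
  const int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);
  std::vector<int> parent(1, 0); // parent[0] unused (background)
  std::vector<int> lab(n, 0);
  int next = 0;
  // raster scan, union with already-visited neighbours (full connectivity)
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (!mask[i]) continue;
        int best = 0;
        for (int dz = -1; dz <= 0; ++dz) {
          int zz = z + dz;
          if (zz < 0) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
              int xx = x + dx;
              if (xx < 0 || xx >= nx) continue;
              R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
              if (lab[j]) {
                if (!best) best = lab[j];
                else unite(parent, best, lab[j]);
              }
            }
          }
        }
        if (!best) {
          best = ++next;
          parent.push_back(best);
        } else {
          best = find_root(parent, best);
        }
        lab[i] = best;
      }
    }
  }
  // second pass: resolve roots, relabel consecutively in scan order
  std::vector<int> remap(next + 1, 0);
  int k = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!lab[i]) continue;
    int r = find_root(parent, lab[i]);
    if (!remap[r]) remap[r] = ++k;
    out[i] = remap[r];
  }
  out.attr("n_objects") = k;
  return out;
}

// 1D squared distance transform on a sampled line (Felzenszwalb-Huttenlocher).
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double h, int n, std::vector<int> &v, std::vector<double> &zb) {
  int q = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      int p = v[q];
      s = ((f[i] + h * h * i * i) - (f[p] + h * h * p * p)) / (2.0 * h * (i - p));
      if (s <= zb[q]) { --q; } else break;
    }
    ++q;
    v[q] = i;
    zb[q] = s;
    zb[q + 1] = std::numeric_limits<double>::infinity();
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    while (zb[q + 1] < h * i) ++q;
    double dx = h * (i - v[q]);
    d[i] = dx * dx + f[v[q]];
  }
}

// Squared Euclidean distance (physical units) from each voxel to the nearest
// zero voxel of `mask`. spacing gives the voxel edge per axis.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nd = dims.size();
  const int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = 1e12;  // large but non-absorbing: INF + h^2 i^2 stays exact
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);

  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, spacing[0], nx, v, zb);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, spacing[1], ny, v, zb);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  if (nd == 3) {
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) f[z] = out[base + (R_xlen_t)z * nx * ny];
        dt1d(f, d, spacing[2], nz, v, zb);
        for (int z = 0; z < nz; ++z) out[base + (R_xlen_t)z * nx * ny] = d[z];
      }
  }
  return out;
}

// Separable Gaussian smoothing with reflecting boundaries; sigma per axis in
// voxel units (sigma <= 0 skips that axis).
// [[Rcpp::export(name = ".gauss_smooth_cpp")]]
NumericVector gauss_smooth_cpp(NumericVector vol, IntegerVector dims, NumericVector sigma) {
  const int nd = dims.size();
  const int nx = dims[0], ny = dims[1], nz = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(vol);

  int axes_n[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < nd; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    double ksum = 0;
    for (int i = -r; i <= r; ++i) { kern[i + r] = std::exp(-0.5 * i * i / (s * s)); ksum += kern[i + r]; }
    for (auto &k : kern) k /= ksum;
    NumericVector nxt(n);
    int len = axes_n[ax];
    R_xlen_t st = strides[ax];
    // iterate all lines along this axis
    R_xlen_t nlines = n / len;
    for (R_xlen_t li = 0; li < nlines; ++li) {
      // compute base index of this line
      R_xlen_t rem = li, base = 0;
      for (int a = 0; a < nd; ++a) {
        if (a == ax) continue;
        R_xlen_t sz = axes_n[a];
        R_xlen_t c = rem % sz;
        rem /= sz;
        base += c * strides[a];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int k = -r; k <= r; ++k) {
          int j = i + k;
          if (j < 0) j = -j - 1;            // reflect
          if (j >= len) j = 2 * len - j - 1;
          acc += kern[k + r] * cur[base + (R_xlen_t)j * st];
        }
        nxt[base + (R_xlen_t)i * st] = acc;
      }
    }
    cur = nxt;
  }
  return cur;
}

static inline void interp_pt(const double *p1, const double *p2, double v1, double v2,
                             double level, double *out) {
  double t = (level - v1) / (v2 - v1);
  for (int k = 0; k < 3; ++k) out[k] = p1[k] + t * (p2[k] - p1[k]);
}

static inline double tri_area(const double *a, const double *b, const double *c) {
  double u[3], w[3];
  for (int k = 0; k < 3; ++k) { u[k] = b[k] - a[k]; w[k] = c[k] - a[k]; }
  double cx = u[1] * w[2] - u[2] * w[1];
  double cy = u[2] * w[0] - u[0] * w[2];
  double cz = u[0] * w[1] - u[1] * w[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Total iso-surface area of a scalar field at `level`, in physical units.
// The caller should zero-pad the field so surfaces close at the boundary.
// [[Rcpp::export(name = ".surface_area_cpp")]]
double surface_area_cpp(NumericVector vol, IntegerVector dims, NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  // cube corner offsets (unit cube)
  static const int co[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6 tetrahedra sharing the main diagonal v0-v6
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0;
  double cpos[8][3], cval[8];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          int xx = x + co[c][0], yy = y + co[c][1], zz = z + co[c][2];
          cval[c] = vol[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
          cpos[c][0] = xx * hx; cpos[c][1] = yy * hy; cpos[c][2] = zz * hz;
          if (cval[c] > level) any_hi = true; else any_lo = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int hi[4], lo[4], nh = 0, nl = 0;
          for (int k = 0; k < 4; ++k) {
            if (cval[id[k]] > level) hi[nh++] = id[k]; else lo[nl++] = id[k];
          }
          if (nh == 0 || nh == 4) continue;
          double p[4][3];
          if (nh == 1 || nh == 3) {
            int a = (nh == 1) ? hi[0] : lo[0];
            int *oth = (nh == 1) ? lo : hi;
            for (int k = 0; k < 3; ++k)
              interp_pt(cpos[a], cpos[oth[k]], cval[a], cval[oth[k]], level, p[k]);
            area += tri_area(p[0], p[1], p[2]);
          } else { // 2-2 split: quad on edges (h0,l0),(h0,l1),(h1,l1),(h1,l0)
            interp_pt(cpos[hi[0]], cpos[lo[0]], cval[hi[0]], cval[lo[0]], level, p[0]);
            interp_pt(cpos[hi[0]], cpos[lo[1]], cval[hi[0]], cval[lo[1]], level, p[1]);
            interp_pt(cpos[hi[1]], cpos[lo[1]], cval[hi[1]], cval[lo[1]], level, p[2]);
            interp_pt(cpos[hi[1]], cpos[lo[0]], cval[hi[1]], cval[lo[0]], level, p[3]);
            area += tri_area(p[0], p[1], p[2]);
            area += tri_area(p[0], p[2], p[3]);
          }
        }
      }
  return area;
}
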