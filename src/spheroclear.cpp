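// Low-level volumetric kernels used by the segmentation and simulation code.
// All volumes are R arrays with dim = c(nz, ny, nx); flat index (0-based) is
// iz + nz * (iy + ny * ix).  Boundaries are handled by reflection.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;
  return k;
}

// Convolve along one axis (0 = z, 1 = y, 2 = x) with a symmetric kernel.
static void conv_axis(std::vector<double> &v, int nz, int ny, int nx,
                      int axis, const std::vector<double> &k) {
  int r = ((int)k.size() - 1) / 2;
  int n = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(n);
  if (axis == 0) {
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy) {
        size_t base = (size_t)nz * (iy + (size_t)ny * ix);
        for (int i = 0; i < n; ++i) line[i] = v[base + i];
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j) s += k[j + r] * line[reflect(i + j, n)];
          v[base + i] = s;
        }
      }
  } else if (axis == 1) {
    for (int ix = 0; ix < nx; ++ix)
      for (int iz = 0; iz < nz; ++iz) {
        size_t base = iz + (size_t)nz * ny * ix;
        for (int i = 0; i < n; ++i) line[i] = v[base + (size_t)nz * i];
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j) s += k[j + r] * line[reflect(i + j, n)];
          v[base + (size_t)nz * i] = s;
        }
      }
  } else {
    size_t stride = (size_t)nz * ny;
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        size_t base = iz + (size_t)nz * iy;
        for (int i = 0; i < n; ++i) line[i] = v[base + stride * i];
        for (int i = 0; i < n; ++i) {
          double s = 0.0;
          for (int j = -r; j <= r; ++j) s += k[j + r] * line[reflect(i + j, n)];
          v[base + stride * i] = s;
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector sc_gauss_blur3d(NumericVector vol, IntegerVector dim,
                              double sigma_z, double sigma_y, double sigma_x) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  if (sigma_z > 0 && nz > 1) conv_axis(v, nz, ny, nx, 0, gauss_kernel(sigma_z));
  if (sigma_y > 0) conv_axis(v, nz, ny, nx, 1, gauss_kernel(sigma_y));
  if (sigma_x > 0) conv_axis(v, nz, ny, nx, 2, gauss_kernel(sigma_x));
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// Discrete Laplacian; the z second-difference is divided by zscale^2 so that
// anisotropic voxels (z_step != pixel_size) are treated in physical units.
// [[Rcpp::export]]
NumericVector sc_laplacian3d(NumericVector vol, IntegerVector dim,
                             double zscale) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  double wz = 1.0 / (zscale * zscale);
  NumericVector out(vol.size());
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        size_t c = iz + (size_t)nz * (iy + (size_t)ny * ix);
        double v0 = vol[c];
        double lap = 0.0;
        lap += vol[reflect(iz - 1, nz) + (size_t)nz * (iy + (size_t)ny * ix)] +
               vol[reflect(iz + 1, nz) + (size_t)nz * (iy + (size_t)ny * ix)] -
               2.0 * v0;
        double ly =
            vol[iz + (size_t)nz * (reflect(iy - 1, ny) + (size_t)ny * ix)] +
            vol[iz + (size_t)nz * (reflect(iy + 1, ny) + (size_t)ny * ix)] -
            2.0 * v0;
        double lx =
            vol[iz + (size_t)nz * (iy + (size_t)ny * reflect(ix - 1, nx))] +
            vol[iz + (size_t)nz * (iy + (size_t)ny * reflect(ix + 1, nx))] -
            2.0 * v0;
        out[c] = lap * wz + ly + lx;
      }
  out.attr("dim") = dim;
  return out;
}

// Indices (1-based, flat) of voxels that are >= all 26 neighbours and exceed
// `threshold`.  Plateau duplicates are left to downstream suppression.
// [[Rcpp::export]]
IntegerVector sc_local_maxima3d(NumericVector vol, IntegerVector dim,
                                double threshold) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<int> hits;
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        size_t c = iz + (size_t)nz * (iy + (size_t)ny * ix);
        double v0 = vol[c];
        if (!(v0 > threshold)) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1 && ismax; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int jz = iz + dz, jy = iy + dy, jx = ix + dx;
              if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 ||
                  jx >= nx)
                continue;
              if (vol[jz + (size_t)nz * (jy + (size_t)ny * jx)] > v0) {
                ismax = false;
                break;
              }
            }
        if (ismax) hits.push_back((int)c + 1);
      }
  return IntegerVector(hits.begin(), hits.end());
}

struct QItem {
  double prio;
  unsigned long order;
  size_t idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // lowest relief first
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Seeded watershed by priority flooding on `relief`, restricted to `mask`,
// 26-connected.  `seeds` is an n x 3 matrix of 1-based (z, y, x) indices.
// Mask voxels in components containing no seed remain 0.
// [[Rcpp::export]]
IntegerVector sc_seeded_watershed(NumericVector relief, LogicalVector mask,
                                  IntegerVector dim, IntegerMatrix seeds) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector labels(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long order = 0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    size_t idx = (seeds(s, 0) - 1) +
                 (size_t)nz * ((seeds(s, 1) - 1) + (size_t)ny * (seeds(s, 2) - 1));
    if (!mask[idx]) continue;
    if (labels[idx] != 0) continue;  // coincident seeds: first one wins
    labels[idx] = s + 1;
    pq.push({relief[idx], order++, idx, s + 1});
  }
  while (!pq.empty()) {
    QItem it = pq.top();
    pq.pop();
    int iz = (int)(it.idx % nz);
    int iy = (int)((it.idx / nz) % ny);
    int ix = (int)(it.idx / ((size_t)nz * ny));
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          int jz = iz + dz, jy = iy + dy, jx = ix + dx;
          if (jz < 0 || jz >= nz || jy < 0 || jy >= ny || jx < 0 || jx >= nx)
            continue;
          size_t j = jz + (size_t)nz * (jy + (size_t)ny * jx);
          if (!mask[j] || labels[j] != 0) continue;
          labels[j] = it.label;
          pq.push({std::max(it.prio, relief[j]), order++, j, it.label});
        }
  }
  labels.attr("dim") = dim;
  return labels;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(std::vector<double> &f, double w2) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
      } else
        break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
  f = d;
}

// Euclidean distance (pixel units; z weighted by `z_aspect`) from each
// foreground voxel to the nearest background voxel.
// [[Rcpp::export]]
NumericVector sc_edt3d(LogicalVector mask, IntegerVector dim, double z_aspect) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  const double BIG = 1e18;
  std::vector<double> f(n);
  for (size_t i = 0; i < n; ++i) f[i] = mask[i] ? BIG : 0.0;
  std::vector<double> line;
  // z axis
  line.resize(nz);
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy) {
      size_t base = (size_t)nz * (iy + (size_t)ny * ix);
      for (int i = 0; i < nz; ++i) line[i] = f[base + i];
      dt1d(line, z_aspect * z_aspect);
      for (int i = 0; i < nz; ++i) f[base + i] = line[i];
    }
  // y axis
  line.resize(ny);
  for (int ix = 0; ix < nx; ++ix)
    for (int iz = 0; iz < nz; ++iz) {
      size_t base = iz + (size_t)nz * ny * ix;
      for (int i = 0; i < ny; ++i) line[i] = f[base + (size_t)nz * i];
      dt1d(line, 1.0);
      for (int i = 0; i < ny; ++i) f[base + (size_t)nz * i] = line[i];
    }
  // x axis
  line.resize(nx);
  size_t stride = (size_t)nz * ny;
  for (int iy = 0; iy < ny; ++iy)
    for (int iz = 0; iz < nz; ++iz) {
      size_t base = iz + (size_t)nz * iy;
      for (int i = 0; i < nx; ++i) line[i] = f[base + stride * i];
      dt1d(line, 1.0);
      for (int i = 0; i < nx; ++i) f[base + stride * i] = line[i];
    }
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(std::min(f[i], BIG));
  out.attr("dim") = dim;
  return out;
}
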