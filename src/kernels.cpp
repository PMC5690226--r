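#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample a 3D grid at continuous 1-based index coordinates.
// mode: 0 = trilinear, 1 = nearest. oob: 0 = constant fill, 1 = clamp to edge.
// [[Rcpp::export]]
NumericVector cpp_sample3d(NumericVector vol,
                           NumericVector qx, NumericVector qy, NumericVector qz,
                           double fill, bool clamp, bool nearest) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = qx.size();
  NumericVector out(n);
  const double *v = vol.begin();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t i = 0; i < n; ++i) {
    double x = qx[i] - 1.0, y = qy[i] - 1.0, z = qz[i] - 1.0;  // 0-based
    if (nearest) {
      long ix = (long)std::lround(x), iy = (long)std::lround(y), iz = (long)std::lround(z);
      if (clamp) {
        ix = ix < 0 ? 0 : (ix > nx - 1 ? nx - 1 : ix);
        iy = iy < 0 ? 0 : (iy > ny - 1 ? ny - 1 : iy);
        iz = iz < 0 ? 0 : (iz > nz - 1 ? nz - 1 : iz);
      } else if (ix < 0 || ix > nx - 1 || iy < 0 || iy > ny - 1 || iz < 0 || iz > nz - 1) {
        out[i] = fill;
        continue;
      }
      out[i] = v[ix + sy * iy + sz * iz];
    } else {
      if (clamp) {
        x = x < 0 ? 0 : (x > nx - 1 ? nx - 1 : x);
        y = y < 0 ? 0 : (y > ny - 1 ? ny - 1 : y);
        z = z < 0 ? 0 : (z > nz - 1 ? nz - 1 : z);
      } else if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 || z < 0 || z > nz - 1) {
        out[i] = fill;
        continue;
      }
      int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
      if (x0 > nx - 2) x0 = nx >= 2 ? nx - 2 : 0;
      if (y0 > ny - 2) y0 = ny >= 2 ? ny - 2 : 0;
      if (z0 > nz - 2) z0 = nz >= 2 ? nz - 2 : 0;
      double fx = x - x0, fy = y - y0, fz = z - z0;
      int x1 = nx >= 2 ? x0 + 1 : x0, y1 = ny >= 2 ? y0 + 1 : y0, z1 = nz >= 2 ? z0 + 1 : z0;
      const double c000 = v[x0 + sy * y0 + sz * z0];
      const double c100 = v[x1 + sy * y0 + sz * z0];
      const double c010 = v[x0 + sy * y1 + sz * z0];
      const double c110 = v[x1 + sy * y1 + sz * z0];
      const double c001 = v[x0 + sy * y0 + sz * z1];
      const double c101 = v[x1 + sy * y0 + sz * z1];
      const double c011 = v[x0 + sy * y1 + sz * z1];
      const double c111 = v[x1 + sy * y1 + sz * z1];
      const double c00 = c000 * (1 - fx) + c100 * fx;
      const double c10 = c010 * (1 - fx) + c110 * fx;
      const double c01 = c001 * (1 - fx) + c101 * fx;
      const double c11 = c011 * (1 - fx) + c111 * fx;
      const double c0 = c00 * (1 - fy) + c10 * fy;
      const double c1 = c01 * (1 - fy) + c11 * fy;
      out[i] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &x : k) x /= s;
  return k;
}

static inline int reflect_idx(int i, int n) {
  // symmetric (edge-inclusive) reflection, valid for |overhang| < n
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - 1 - i;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// Separable Gaussian smoothing of a 3D grid; sigma per axis in voxels.
// Axes with sigma below 1e-8 are left untouched.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, NumericVector sigma) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(vol);
  std::vector<double> buf(ntot);
  double *a = out.begin();
  double *b = buf.data();
  const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (!(s > 1e-8)) continue;
    std::vector<double> k = gauss_kernel(s);
    const int r = ((int)k.size() - 1) / 2;
    const int nA = axis == 0 ? nx : (axis == 1 ? ny : nz);
    const R_xlen_t strA = axis == 0 ? 1 : (axis == 1 ? sy : sz);
    // iterate over all lines along `axis`
    const int nB = axis == 0 ? ny : nx;
    const R_xlen_t strB = axis == 0 ? sy : 1;
    const int nC = axis == 2 ? ny : nz;
    const R_xlen_t strC = axis == 2 ? sy : sz;
    for (int c = 0; c < nC; ++c) {
      for (int bi = 0; bi < nB; ++bi) {
        const R_xlen_t base = strB * bi + strC * c;
        for (int i = 0; i < nA; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int ii = i + j;
            if (ii < 0 || ii >= nA) ii = reflect_idx(ii, nA);
            acc += k[j + r] * a[base + strA * ii];
          }
          b[base + strA * i] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  if (a != out.begin())
    std::copy(a, a + ntot, out.begin());
  return out;
}
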