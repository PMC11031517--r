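#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable Gaussian (derivative) convolution along one axis of a 3-D array,
// with replicate boundary handling. order: 0 = smooth, 1 = first, 2 = second
// derivative (in voxel units).
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      const int n[3], int axis,
                      const std::vector<double>& kernel) {
  const int kr = ((int)kernel.size() - 1) / 2;
  const int nx = n[0], ny = n[1], nz = n[2];
  long stride = (axis == 0) ? 1 : (axis == 1) ? nx : (long)nx * ny;
  int len = n[axis];
  (void)nz;
  // iterate over all 1-D lines along `axis`
  int oa1 = (axis == 0) ? 1 : 0;
  int oa2 = (axis == 2) ? 1 : 2;
  long s1 = (oa1 == 0) ? 1 : (oa1 == 1) ? nx : (long)nx * ny;
  long s2 = (oa2 == 0) ? 1 : (oa2 == 1) ? nx : (long)nx * ny;
  for (int j = 0; j < n[oa2]; ++j)
    for (int i = 0; i < n[oa1]; ++i) {
      long base = i * s1 + j * s2;
      for (int k = 0; k < len; ++k) {
        double acc = 0.0;
        for (int t = -kr; t <= kr; ++t) {
          int q = k + t;
          if (q < 0) q = 0;
          if (q >= len) q = len - 1;
          acc += kernel[t + kr] * in[base + (long)q * stride];
        }
        out[base + (long)k * stride] = acc;
      }
    }
}

static std::vector<double> gauss_kernel(double sigma, int order) {
  int kr = (int)std::ceil(3.5 * sigma);
  if (kr < 1) kr = 1;
  std::vector<double> k(2 * kr + 1);
  double s2 = sigma * sigma;
  double norm = 0.0;
  for (int t = -kr; t <= kr; ++t) {
    double g = std::exp(-0.5 * t * t / s2);
    norm += g;
  }
  for (int t = -kr; t <= kr; ++t) {
    double g = std::exp(-0.5 * t * t / s2) / norm;
    if (order == 0) k[t + kr] = g;
    else if (order == 1) k[t + kr] = -t / s2 * g;
    else k[t + kr] = (t * t / s2 - 1.0) / s2 * g;
  }
  return k;
}

// Gaussian-derivative filter of a 3-D volume: order_{x,y,z} in {0,1,2} per
// axis, sigma in voxel units per axis. Derivatives are in voxel units.
// [[Rcpp::export]]
NumericVector gauss_deriv3d_cpp(NumericVector vol, IntegerVector dim,
                                NumericVector sigma_vox, IntegerVector order) {
  int n[3] = {dim[0], dim[1], dim[2]};
  long total = (long)n[0] * n[1] * n[2];
  std::vector<double> a(vol.begin(), vol.end()), b(total);
  for (int axis = 0; axis < 3; ++axis) {
    std::vector<double> k = gauss_kernel(sigma_vox[axis], order[axis]);
    conv_axis(a, b, n, axis, k);
    std::swap(a, b);
  }
  NumericVector out(total);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dim;
  return out;
}

// Eigenvalues of symmetric 3x3 matrices given componentwise as arrays
// (hxx, hyy, hzz, hxy, hxz, hyz), sorted by increasing |lambda|.
// Closed-form trigonometric method (Smith 1961).
// [[Rcpp::export]]
List eig3_sym_cpp(NumericVector hxx, NumericVector hyy, NumericVector hzz,
                  NumericVector hxy, NumericVector hxz, NumericVector hyz) {
  long nvox = hxx.size();
  NumericVector l1(nvox), l2(nvox), l3(nvox);
  for (long i = 0; i < nvox; ++i) {
    double a = hxx[i], b = hyy[i], c = hzz[i];
    double d = hxy[i], e = hxz[i], f = hyz[i];
    double p1 = d * d + e * e + f * f;
    double ev[3];
    if (p1 < 1e-300) {
      ev[0] = a; ev[1] = b; ev[2] = c;
    } else {
      double q = (a + b + c) / 3.0;
      double p2 = (a - q) * (a - q) + (b - q) * (b - q) + (c - q) * (c - q) +
                  2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // B = (A - q I) / p ; r = det(B) / 2
      double b11 = (a - q) / p, b22 = (b - q) / p, b33 = (c - q) / p;
      double b12 = d / p, b13 = e / p, b23 = f / p;
      double r = (b11 * (b22 * b33 - b23 * b23) -
                  b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13)) / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      ev[0] = q + 2.0 * p * std::cos(phi);
      ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      ev[1] = 3.0 * q - ev[0] - ev[2];
    }
    // sort by |lambda| ascending
    for (int u = 0; u < 2; ++u)
      for (int v = 0; v < 2 - u; ++v)
        if (std::fabs(ev[v]) > std::fabs(ev[v + 1])) std::swap(ev[v], ev[v + 1]);
    l1[i] = ev[0]; l2[i] = ev[1]; l3[i] = ev[2];
  }
  return List::create(_["l1"] = l1, _["l2"] = l2, _["l3"] = l3);
}
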