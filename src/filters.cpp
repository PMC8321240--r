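#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Reflect an out-of-range index into [0, n-1] (mirror without repeating the
// edge pixel twice only for single reflection; sufficient for radius < n).
static inline int reflect_idx(int i, int n) {
  if (i < 0) i = -i - 1;
  if (i >= n) i = 2 * n - i - 1;
  if (i < 0) i = 0;
  if (i >= n) i = n - 1;
  return i;
}

// Median filter with a circular footprint of the given radius (pixels whose
// centre distance is <= radius) and mirror edge handling.
// [[Rcpp::export(name = ".cpp_median_filter")]]
NumericMatrix cpp_median_filter(NumericMatrix img, int radius) {
  if (radius < 1) stop("radius must be >= 1");
  int nr = img.nrow(), nc = img.ncol();
  // precompute footprint offsets
  std::vector<int> di, dj;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { di.push_back(a); dj.push_back(b); }
  int k = (int)di.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      for (int m = 0; m < k; ++m) {
        int ii = reflect_idx(i + di[m], nr);
        int jj = reflect_idx(j + dj[m], nc);
        buf[m] = img(ii, jj);
      }
      // median: lower-middle / mean of two middles for even counts
      size_t mid = k / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (k % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = (med + lo) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// 1D parabolic erosion: d[p] = min_q f[q] + (p-q)^2 / c
// Felzenszwalb & Huttenlocher lower-envelope algorithm, O(n).
static void parab_erode_1d(const double* f, double* d, int n, double inv_c) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s = 0.0;
    while (true) {
      int vk = v[k];
      s = ((f[q] + inv_c * q * q) - (f[vk] + inv_c * vk * vk)) /
          (2.0 * inv_c * (q - vk));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = inv_c * dq * dq + f[v[k]];
  }
}

static void parab_transform(NumericMatrix& m, double inv_c, bool erode) {
  int nr = m.nrow(), nc = m.ncol();
  double sgn = erode ? 1.0 : -1.0;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = sgn * m(i, j);
    parab_erode_1d(f.data(), d.data(), nr, inv_c);
    for (int i = 0; i < nr; ++i) m(i, j) = sgn * d[i];
  }
  // rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = sgn * m(i, j);
    parab_erode_1d(f.data(), d.data(), nc, inv_c);
    for (int j = 0; j < nc; ++j) m(i, j) = sgn * d[j];
  }
}

// Grayscale opening with a paraboloid structuring element z(r) = -r^2/curvature
// (separable: r^2 = x^2 + y^2). Returns the background estimate.
// [[Rcpp::export(name = ".cpp_parabola_opening")]]
NumericMatrix cpp_parabola_opening(NumericMatrix img, double curvature) {
  if (curvature <= 0) stop("curvature must be > 0");
  double inv_c = 1.0 / curvature;
  NumericMatrix m = clone(img);
  parab_transform(m, inv_c, true);   // erosion
  parab_transform(m, inv_c, false);  // dilation
  return m;
}
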