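// Exact Euclidean distance transform of a 3D point set (separable
// lower-envelope-of-parabolas algorithm), with anisotropic voxel spacing.
// Input: logical array marking "sites"; output: for every voxel the exact
// Euclidean distance (in mm) from its center to the nearest site center.
#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform along samples at positions i*w, i=0..n-1.
static void dt1d(std::vector<double>& f, int n, double w,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& d) {
  // only finite entries can seed parabolas; a column with no finite entry
  // transforms to all-infinite distances
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      const double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (z[k + 1] < xq) ++k;
    const double xv = v[k] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector sites, IntegerVector dims,
                       NumericVector spacing) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const long N = (long)D * H * W;
  NumericVector g(N);
  for (long i = 0; i < N; ++i) g[i] = sites[i] ? 0.0 : INF;
  const int nmax = std::max(D, std::max(H, W));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass along axis 1 (fastest)
  for (long w = 0; w < W; ++w)
    for (long h = 0; h < H; ++h) {
      double* col = g.begin() + D * (h + (long)H * w);
      for (int i = 0; i < D; ++i) f[i] = col[i];
      dt1d(f, D, spacing[0], v, z, d);
      for (int i = 0; i < D; ++i) col[i] = d[i];
    }
  // pass along axis 2
  for (long w = 0; w < W; ++w)
    for (long dd = 0; dd < D; ++dd) {
      double* base = g.begin() + dd + (long)D * H * w;
      for (int i = 0; i < H; ++i) f[i] = base[(long)i * D];
      dt1d(f, H, spacing[1], v, z, d);
      for (int i = 0; i < H; ++i) base[(long)i * D] = d[i];
    }
  // pass along axis 3
  for (long h = 0; h < H; ++h)
    for (long dd = 0; dd < D; ++dd) {
      double* base = g.begin() + dd + (long)D * h;
      for (int i = 0; i < W; ++i) f[i] = base[(long)i * D * H];
      dt1d(f, W, spacing[2], v, z, d);
      for (int i = 0; i < W; ++i) base[(long)i * D * H] = d[i];
    }
  for (long i = 0; i < N; ++i) g[i] = std::sqrt(g[i]);
  g.attr("dim") = IntegerVector::create(D, H, W);
  return g;
}
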