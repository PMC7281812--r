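// 3D convolution kernels: im2col + GEMM forward, and the matching
// backward passes. Layout conventions (all R column-major):
//   activations: array [D, H, W, C]
//   weights:     matrix [k^3 * C_in, C_out], rows ordered (kd, kh, kw, ci)
//                with kd fastest, i.e. the flattening of an R array
//                dim = c(k, k, k, C_in, C_out)
// Zero padding `pad` on every spatial side, cubic kernel k, stride s.
// The patch matrix is held transposed (voxels x features) so that the
// innermost depth-axis runs are contiguous in both source and destination.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// Fill colsT (Nout x k^3*C): column f = feature (kd, kh, kw, ci), rows in
// output-voxel order (od fastest).
static void im2colT(const double* x, int D, int H, int W, int C,
                    int k, int s, int p, arma::mat& colsT) {
  const int Do = out_dim(D, k, s, p);
  const int Ho = out_dim(H, k, s, p);
  const int Wo = out_dim(W, k, s, p);
  const long Nout = (long)Do * Ho * Wo;
  colsT.zeros((arma::uword)Nout, (arma::uword)(k * k * k * C));
  for (int ci = 0; ci < C; ++ci) {
    const double* xc = x + (long)ci * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          double* col = colsT.colptr(
            (arma::uword)(kd + k * (kh + k * (kw + k * ci))));
          // valid od range: 0 <= od*s - p + kd < D
          const int od_lo = std::max(0, (p - kd + s - 1) / s);
          const int od_hi = std::min(Do - 1, (D - 1 + p - kd) / s);
          if (od_hi < od_lo) continue;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * s - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * s - p + kh;
              if (ih < 0 || ih >= H) continue;
              double* dst = col + od_lo + (long)Do * (oh + (long)Ho * ow);
              const double* src =
                xc + (od_lo * s - p + kd) + (long)D * (ih + (long)H * iw);
              const int nrun = od_hi - od_lo + 1;
              if (s == 1) {
                std::memcpy(dst, src, nrun * sizeof(double));
              } else {
                for (int i = 0; i < nrun; ++i) dst[i] = src[(long)i * s];
              }
            }
          }
        }
  }
}

// Scatter-add the transposed patch matrix back onto an input-shaped grid.
static void col2imT(const arma::mat& colsT, int D, int H, int W, int C,
                    int k, int s, int p, double* dx) {
  const int Do = out_dim(D, k, s, p);
  const int Ho = out_dim(H, k, s, p);
  const int Wo = out_dim(W, k, s, p);
  std::fill(dx, dx + (long)D * H * W * C, 0.0);
  for (int ci = 0; ci < C; ++ci) {
    double* xc = dx + (long)ci * D * H * W;
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh)
        for (int kd = 0; kd < k; ++kd) {
          const double* col = colsT.colptr(
            (arma::uword)(kd + k * (kh + k * (kw + k * ci))));
          const int od_lo = std::max(0, (p - kd + s - 1) / s);
          const int od_hi = std::min(Do - 1, (D - 1 + p - kd) / s);
          if (od_hi < od_lo) continue;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * s - p + kw;
            if (iw < 0 || iw >= W) continue;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * s - p + kh;
              if (ih < 0 || ih >= H) continue;
              const double* src = col + od_lo + (long)Do * (oh + (long)Ho * ow);
              double* dst =
                xc + (od_lo * s - p + kd) + (long)D * (ih + (long)H * iw);
              const int nrun = od_hi - od_lo + 1;
              if (s == 1) {
                for (int i = 0; i < nrun; ++i) dst[i] += src[i];
              } else {
                for (int i = 0; i < nrun; ++i) dst[(long)i * s] += src[i];
              }
            }
          }
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector dims,
                            NumericMatrix Wm, NumericVector b,
                            int kernel, int stride, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = out_dim(D, kernel, stride, pad);
  const int Ho = out_dim(H, kernel, stride, pad);
  const int Wo = out_dim(W, kernel, stride, pad);
  const int Cout = Wm.ncol();
  arma::mat colsT;
  im2colT(x.begin(), D, H, W, C, kernel, stride, pad, colsT);
  const arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat Y = colsT * Wa;  // Nout x Cout
  Y.each_row() += arma::rowvec(b.begin(), Cout);
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector dims, NumericMatrix Wm,
                   NumericVector dy, int kernel, int stride, int pad) {
  const int D = dims[0], H = dims[1], W = dims[2], C = dims[3];
  const int Do = out_dim(D, kernel, stride, pad);
  const int Ho = out_dim(H, kernel, stride, pad);
  const int Wo = out_dim(W, kernel, stride, pad);
  const long Nout = (long)Do * Ho * Wo;
  const int Cout = Wm.ncol();
  arma::mat colsT;
  im2colT(x.begin(), D, H, W, C, kernel, stride, pad, colsT);
  const arma::mat dY(dy.begin(), (arma::uword)Nout, (arma::uword)Cout, false);
  const arma::mat Wa(Wm.begin(), Wm.nrow(), Wm.ncol(), false);
  arma::mat dW = colsT.t() * dY;            // k3*Cin x Cout
  arma::rowvec db = arma::sum(dY, 0);       // 1 x Cout
  NumericVector dx((long)D * H * W * C);
  if (stride == 1) {
    // backward-data as a convolution of dy with the spatially flipped,
    // channel-transposed kernel at padding k-1-p (exact for stride 1)
    const int k = kernel;
    arma::mat Wflip((arma::uword)(k * k * k * Cout), (arma::uword)C);
    for (int ci = 0; ci < C; ++ci)
      for (int co = 0; co < Cout; ++co)
        for (int kw = 0; kw < k; ++kw)
          for (int kh = 0; kh < k; ++kh)
            for (int kd = 0; kd < k; ++kd)
              Wflip((arma::uword)(kd + k * (kh + k * (kw + k * co))),
                    (arma::uword)ci) =
                Wa((arma::uword)((k - 1 - kd) + k * ((k - 1 - kh) +
                     k * ((k - 1 - kw) + k * ci))), (arma::uword)co);
    arma::mat dyColsT;
    im2colT(dy.begin(), Do, Ho, Wo, Cout, k, 1, k - 1 - pad, dyColsT);
    arma::mat dX = dyColsT * Wflip;         // N x Cin
    std::copy(dX.begin(), dX.end(), dx.begin());
  } else {
    arma::mat dcolsT = dY * Wa.t();         // Nout x k3*Cin
    col2imT(dcolsT, D, H, W, C, kernel, stride, pad, dx.begin());
  }
  dx.attr("dim") = IntegerVector::create(D, H, W, C);
  NumericMatrix dWr(dW.n_rows, dW.n_cols);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
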