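// Convolution and max-pooling kernels for the CNN trainer.
//
// Layout contract (matches R's column-major arrays):
//   activations  H x W x C x N
//   conv weights F x (k*k*C), rows = filters, columns in (dh, dw, c)
//     column-major order of a (k, k, C) block
//   idx          (k*k*C) x P gather index, 1-based within one image block,
//     precomputed in R at layer-build time; P = OH * OW output positions.
//
// The backward scatter relies on stride-1 (conv) / window-disjointness
// (pool, per kernel offset) so no atomic accumulation is needed; plain
// += over positions is correct because collisions cannot occur within a
// single offset row and images are processed independently.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector conv_forward_cpp(NumericVector Xp, IntegerVector dims,
                               NumericMatrix W, NumericVector b,
                               IntegerMatrix idx, int OH, int OW) {
  const int Hp = dims[0], Wp = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)Hp * Wp * C;
  const int k2c = idx.nrow(), P = idx.ncol();
  const int F = W.nrow();
  arma::mat Wm(W.begin(), F, k2c, false, true);
  arma::vec bv(b.begin(), F, false, true);
  NumericVector out((size_t)OH * OW * F * N);
  out.attr("dim") = IntegerVector::create(OH, OW, F, N);
  arma::mat cols(k2c, P);
  const double* xptr = Xp.begin();
  double* optr = out.begin();
  const int* iptr = idx.begin();
  for (int n = 0; n < N; ++n) {
    const double* xi = xptr + (size_t)n * plane;
    for (int p = 0; p < P; ++p) {
      const int* ip = iptr + (size_t)p * k2c;
      double* cp = cols.colptr(p);
      for (int r = 0; r < k2c; ++r) cp[r] = xi[ip[r] - 1];
    }
    arma::mat Y = Wm * cols;  // F x P
    Y.each_col() += bv;
    double* oi = optr + (size_t)n * P * F;
    for (int f = 0; f < F; ++f) {
      const double* yr = Y.memptr() + f;  // row f, stride F
      double* od = oi + (size_t)f * P;
      for (int p = 0; p < P; ++p) od[p] = yr[(size_t)p * F];
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv_backward_cpp(NumericVector Xp, IntegerVector dims,
                       NumericMatrix W, NumericVector dY,
                       IntegerMatrix idx, int OH, int OW) {
  const int Hp = dims[0], Wp = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)Hp * Wp * C;
  const int k2c = idx.nrow(), P = idx.ncol();
  const int F = W.nrow();
  arma::mat Wm(W.begin(), F, k2c, false, true);
  arma::mat dW(F, k2c, arma::fill::zeros);
  arma::vec db(F, arma::fill::zeros);
  NumericVector dXp(Xp.size());
  arma::mat cols(k2c, P);
  arma::mat Ym(F, P);
  const double* xptr = Xp.begin();
  const double* dyptr = dY.begin();
  double* dxptr = dXp.begin();
  const int* iptr = idx.begin();
  for (int n = 0; n < N; ++n) {
    const double* xi = xptr + (size_t)n * plane;
    for (int p = 0; p < P; ++p) {
      const int* ip = iptr + (size_t)p * k2c;
      double* cp = cols.colptr(p);
      for (int r = 0; r < k2c; ++r) cp[r] = xi[ip[r] - 1];
    }
    const double* dyi = dyptr + (size_t)n * P * F;  // (P x F) block
    for (int f = 0; f < F; ++f) {
      const double* src = dyi + (size_t)f * P;
      double* dst = Ym.memptr() + f;
      for (int p = 0; p < P; ++p) dst[(size_t)p * F] = src[p];
    }
    dW += Ym * cols.t();
    db += arma::sum(Ym, 1);
    arma::mat dcols = Wm.t() * Ym;  // k2c x P
    double* dxi = dxptr + (size_t)n * plane;
    for (int p = 0; p < P; ++p) {
      const int* ip = iptr + (size_t)p * k2c;
      const double* dc = dcols.colptr(p);
      for (int r = 0; r < k2c; ++r) dxi[ip[r] - 1] += dc[r];
    }
  }
  return List::create(_["dW"] = wrap(dW), _["db"] = wrap(db),
                      _["dXp"] = dXp);
}

// [[Rcpp::export]]
List pool_forward_cpp(NumericVector X, IntegerVector dims,
                      IntegerMatrix idx, int OH, int OW) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)H * W;
  const int k2 = idx.nrow(), P = idx.ncol();
  const int planes = C * N;
  NumericVector out((size_t)OH * OW * C * N);
  out.attr("dim") = IntegerVector::create(OH, OW, C, N);
  IntegerVector amax((size_t)P * planes);
  const double* xptr = X.begin();
  double* optr = out.begin();
  int* aptr = amax.begin();
  const int* iptr = idx.begin();
  for (int q = 0; q < planes; ++q) {
    const double* xi = xptr + (size_t)q * plane;
    double* oi = optr + (size_t)q * P;
    int* ai = aptr + (size_t)q * P;
    for (int p = 0; p < P; ++p) {
      const int* ip = iptr + (size_t)p * k2;
      double best = xi[ip[0] - 1];
      int arg = 1;
      for (int r = 1; r < k2; ++r) {
        double v = xi[ip[r] - 1];
        if (v > best) { best = v; arg = r + 1; }
      }
      oi[p] = best;
      ai[p] = arg;
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericVector pool_backward_cpp(NumericVector dY, IntegerVector amax,
                                IntegerMatrix idx, IntegerVector dims) {
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  const size_t plane = (size_t)H * W;
  const int k2 = idx.nrow(), P = idx.ncol();
  const int planes = C * N;
  NumericVector dX((size_t)plane * planes);
  const double* dyptr = dY.begin();
  const int* aptr = amax.begin();
  const int* iptr = idx.begin();
  double* dxptr = dX.begin();
  for (int q = 0; q < planes; ++q) {
    const double* dyi = dyptr + (size_t)q * P;
    const int* ai = aptr + (size_t)q * P;
    double* dxi = dxptr + (size_t)q * plane;
    for (int p = 0; p < P; ++p) {
      const int* ip = iptr + (size_t)p * k2;
      dxi[ip[ai[p] - 1] - 1] += dyi[p];
    }
  }
  dX.attr("dim") = dims;
  return dX;
}
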