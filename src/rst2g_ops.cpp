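// Compute kernels for the hot inner loops: stride-1 2D cross-correlation
// (forward and backward via im2col + BLAS) and per-channel reductions /
// affine maps used by batch normalisation. Tensors arrive as R arrays in
// (B, C, H, W) column-major layout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims4(const NumericVector& x, int d[4]) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a 4D array");
  for (int i = 0; i < 4; ++i) d[i] = dd[i];
}

// im2col with implicit zero padding; rows ordered (c, ki, kj), cols (b, h, w)
static arma::mat build_A(const double* x, int B, int C, int H, int W,
                         int K, int pad, int Ho, int Wo) {
  arma::mat A(C * K * K, (size_t)B * Ho * Wo, arma::fill::zeros);
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int b = 0; b < B; ++b) {
        size_t col = (size_t)b + (size_t)B * ho + (size_t)B * Ho * wo;
        double* Ac = A.colptr(col);
        int r = 0;
        for (int kj = 0; kj < K; ++kj) {
          int wi = wo + kj - pad;
          for (int ki = 0; ki < K; ++ki) {
            int hi = ho + ki - pad;
            if (wi >= 0 && wi < W && hi >= 0 && hi < H) {
              const double* xp = x + (size_t)b + (size_t)B * C * hi
                                   + (size_t)B * C * H * wi;
              for (int c = 0; c < C; ++c) Ac[r + c] = xp[(size_t)B * c];
            }
            r += C;
          }
        }
      }
    }
  }
  return A;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 Nullable<NumericVector> bias, int pad) {
  int xd[4], wd[4];
  dims4(x, xd); dims4(w, wd);
  int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], K = wd[2];
  if (wd[1] != C) stop("channel mismatch");
  int Ho = H - K + 1 + 2 * pad, Wo = W - K + 1 + 2 * pad;
  arma::mat A = build_A(x.begin(), B, C, H, W, K, pad, Ho, Wo);
  arma::mat Wm(w.begin(), Cout, C * K * K, false, true);
  arma::mat om = Wm * A;
  if (bias.isNotNull()) {
    NumericVector bv(bias);
    arma::vec bb(bv.begin(), Cout, false, true);
    om.each_col() += bb;
  }
  NumericVector out((size_t)B * Cout * Ho * Wo);
  double* op = out.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int b = 0; b < B; ++b) {
        size_t col = (size_t)b + (size_t)B * ho + (size_t)B * Ho * wo;
        const double* oc = om.colptr(col);
        double* dst = op + (size_t)b + (size_t)B * Cout * ho
                         + (size_t)B * Cout * Ho * wo;
        for (int c = 0; c < Cout; ++c) dst[(size_t)B * c] = oc[c];
      }
  out.attr("dim") = IntegerVector::create(B, Cout, Ho, Wo);
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector grad,
                         int pad, bool need_dx, bool has_bias) {
  int xd[4], wd[4];
  dims4(x, xd); dims4(w, wd);
  int B = xd[0], C = xd[1], H = xd[2], W = xd[3];
  int Cout = wd[0], K = wd[2];
  int Ho = H - K + 1 + 2 * pad, Wo = W - K + 1 + 2 * pad;
  size_t BHW = (size_t)B * Ho * Wo;
  // gather grad (B, Cout, Ho, Wo) into (Cout, B*Ho*Wo)
  arma::mat G(Cout, BHW);
  const double* gp = grad.begin();
  for (int wo = 0; wo < Wo; ++wo)
    for (int ho = 0; ho < Ho; ++ho)
      for (int b = 0; b < B; ++b) {
        size_t col = (size_t)b + (size_t)B * ho + (size_t)B * Ho * wo;
        double* gc = G.colptr(col);
        const double* src = gp + (size_t)b + (size_t)B * Cout * ho
                               + (size_t)B * Cout * Ho * wo;
        for (int c = 0; c < Cout; ++c) gc[c] = src[(size_t)B * c];
      }
  arma::mat A = build_A(x.begin(), B, C, H, W, K, pad, Ho, Wo);
  arma::mat dWm = G * A.t();
  NumericVector dw(dWm.begin(), dWm.end());
  dw.attr("dim") = IntegerVector::create(Cout, C, K, K);
  NumericVector db;
  if (has_bias) {
    arma::vec s = arma::sum(G, 1);
    db = NumericVector(s.begin(), s.end());
  }
  NumericVector dx;
  if (need_dx) {
    arma::mat Wm(w.begin(), Cout, C * K * K, false, true);
    arma::mat dA = Wm.t() * G;
    dx = NumericVector((size_t)B * C * H * W);
    double* dp = dx.begin();
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho)
        for (int b = 0; b < B; ++b) {
          size_t col = (size_t)b + (size_t)B * ho + (size_t)B * Ho * wo;
          const double* Ac = dA.colptr(col);
          int r = 0;
          for (int kj = 0; kj < K; ++kj) {
            int wi = wo + kj - pad;
            for (int ki = 0; ki < K; ++ki) {
              int hi = ho + ki - pad;
              if (wi >= 0 && wi < W && hi >= 0 && hi < H) {
                double* xp = dp + (size_t)b + (size_t)B * C * hi
                                + (size_t)B * C * H * wi;
                for (int c = 0; c < C; ++c) xp[(size_t)B * c] += Ac[r + c];
              }
              r += C;
            }
          }
        }
    dx.attr("dim") = IntegerVector::create(B, C, H, W);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// per-channel sum and sum of squares over (B, H, W)
// [[Rcpp::export]]
List cpp_channel_sums(NumericVector x) {
  int d[4];
  dims4(x, d);
  int B = d[0], C = d[1];
  size_t HW = (size_t)d[2] * d[3];
  NumericVector s(C), s2(C);
  const double* xp = x.begin();
  for (size_t hw = 0; hw < HW; ++hw)
    for (int c = 0; c < C; ++c) {
      const double* p = xp + (size_t)B * c + (size_t)B * C * hw;
      double a = 0, b2 = 0;
      for (int b = 0; b < B; ++b) { a += p[b]; b2 += p[b] * p[b]; }
      s[c] += a; s2[c] += b2;
    }
  return List::create(_["sum"] = s, _["sumsq"] = s2);
}

// per-channel sum of x * y
// [[Rcpp::export]]
NumericVector cpp_channel_dot(NumericVector x, NumericVector y) {
  int d[4];
  dims4(x, d);
  int B = d[0], C = d[1];
  size_t HW = (size_t)d[2] * d[3];
  NumericVector s(C);
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (size_t hw = 0; hw < HW; ++hw)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)B * c + (size_t)B * C * hw;
      double a = 0;
      for (int b = 0; b < B; ++b) a += xp[off + b] * yp[off + b];
      s[c] += a;
    }
  return s;
}

// y = x * a[c] + b[c]
// [[Rcpp::export]]
NumericVector cpp_scale_shift(NumericVector x, NumericVector a, NumericVector b) {
  int d[4];
  dims4(x, d);
  int B = d[0], C = d[1];
  size_t HW = (size_t)d[2] * d[3];
  NumericVector y((size_t)B * C * HW);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t hw = 0; hw < HW; ++hw)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)B * c + (size_t)B * C * hw;
      double ac = a[c], bc = b[c];
      for (int bb = 0; bb < B; ++bb) yp[off + bb] = xp[off + bb] * ac + bc;
    }
  y.attr("dim") = x.attr("dim");
  return y;
}

// y = g * a[c] + x * b[c] + cvec[c]
// [[Rcpp::export]]
NumericVector cpp_axpb_channels(NumericVector g, NumericVector x,
                                NumericVector a, NumericVector b,
                                NumericVector cvec) {
  int d[4];
  dims4(x, d);
  int B = d[0], C = d[1];
  size_t HW = (size_t)d[2] * d[3];
  NumericVector y((size_t)B * C * HW);
  const double* gp = g.begin();
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t hw = 0; hw < HW; ++hw)
    for (int c = 0; c < C; ++c) {
      size_t off = (size_t)B * c + (size_t)B * C * hw;
      double ac = a[c], bc = b[c], cc = cvec[c];
      for (int bb = 0; bb < B; ++bb)
        yp[off + bb] = gp[off + bb] * ac + xp[off + bb] * bc + cc;
    }
  y.attr("dim") = x.attr("dim");
  return y;
}
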