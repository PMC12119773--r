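// Convolution / pooling kernels for the compact network engine.
//
// Layout conventions (column-major, as R stores arrays):
//   feature maps: (H, W, C)   -> index y + H*(x + W*c)
//   conv weights: (k, k, Cin, Cout), k odd, stride 1, zero "same" padding
//
// Convolutions run as im2col + BLAS matrix products: the patch matrix K is
// (k*k*Cin) x (H*W) with row index dy + k*(dx + k*ci), so the weight array
// reshapes directly to (k*k*Cin) x Cout.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double* in, int H, int W, int Ci, int k) {
  const int p = k / 2;
  const arma::uword N = (arma::uword)H * W;
  arma::mat K((arma::uword)k * k * Ci, N, arma::fill::zeros);
  for (int ci = 0; ci < Ci; ++ci) {
    const double* plane = in + (arma::uword)ci * H * W;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const arma::uword r = dy + k * (dx + k * ci);
        const int x0 = std::max(0, p - dx), x1 = std::min(W, W + p - dx);
        const int y0 = std::max(0, p - dy), y1 = std::min(H, H + p - dy);
        for (int x = x0; x < x1; ++x) {
          const double* src = plane + (arma::uword)(x + dx - p) * H + (dy - p);
          double* dst = K.colptr((arma::uword)x * H) + r;
          // K(r, y + H*x) = plane(y + dy - p, x + dx - p)
          for (int y = y0; y < y1; ++y) {
            dst[(arma::uword)y * K.n_rows] = src[y];
          }
        }
      }
    }
  }
  return K;
}

// [[Rcpp::export(name = ".cn_conv2d_fwd")]]
NumericVector cn_conv2d_fwd(NumericVector input, NumericVector w,
                            NumericVector b) {
  IntegerVector di = input.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = di[0], W = di[1], Ci = di[2];
  const int k = dw[0], Co = dw[3];
  if (dw[1] != k || dw[2] != Ci || b.size() != Co)
    stop("conv2d: inconsistent weight dimensions");
  arma::mat K = im2col(&input[0], H, W, Ci, k);
  const arma::mat Wm(const_cast<double*>(&w[0]), (arma::uword)k * k * Ci, Co,
                     false, true);
  NumericVector out((R_xlen_t)H * W * Co);
  arma::mat O(&out[0], (arma::uword)H * W, Co, false, true);
  O = K.t() * Wm;
  O.each_row() += arma::rowvec(const_cast<double*>(&b[0]), Co, false, true);
  out.attr("dim") = IntegerVector::create(H, W, Co);
  return out;
}

// [[Rcpp::export(name = ".cn_conv2d_bwd")]]
List cn_conv2d_bwd(NumericVector input, NumericVector w, NumericVector gout) {
  IntegerVector di = input.attr("dim");
  IntegerVector dw = w.attr("dim");
  const int H = di[0], W = di[1], Ci = di[2];
  const int k = dw[0], Co = dw[3], p = k / 2;
  arma::mat K = im2col(&input[0], H, W, Ci, k);
  const arma::mat Wm(const_cast<double*>(&w[0]), (arma::uword)k * k * Ci, Co,
                     false, true);
  const arma::mat Gm(const_cast<double*>(&gout[0]), (arma::uword)H * W, Co,
                     false, true);
  NumericVector gw((R_xlen_t)k * k * Ci * Co);
  arma::mat GW(&gw[0], (arma::uword)k * k * Ci, Co, false, true);
  GW = K * Gm;
  NumericVector gb(Co);
  arma::rowvec GB(&gb[0], Co, false, true);
  GB = arma::sum(Gm, 0);
  // gin: scatter-add of (k2Ci x N) = Wm * Gm.t() back into image space
  arma::mat G2 = Wm * Gm.t();
  NumericVector gin((R_xlen_t)H * W * Ci);
  double* gp = &gin[0];
  for (int ci = 0; ci < Ci; ++ci) {
    double* plane = gp + (arma::uword)ci * H * W;
    for (int dx = 0; dx < k; ++dx) {
      for (int dy = 0; dy < k; ++dy) {
        const arma::uword r = dy + k * (dx + k * ci);
        const int x0 = std::max(0, p - dx), x1 = std::min(W, W + p - dx);
        const int y0 = std::max(0, p - dy), y1 = std::min(H, H + p - dy);
        for (int x = x0; x < x1; ++x) {
          double* dst = plane + (arma::uword)(x + dx - p) * H + (dy - p);
          for (int y = y0; y < y1; ++y) {
            dst[y] += G2(r, (arma::uword)y + (arma::uword)x * H);
          }
        }
      }
    }
  }
  gin.attr("dim") = IntegerVector::create(H, W, Ci);
  gw.attr("dim") = IntegerVector::create(k, k, Ci, Co);
  return List::create(_["gin"] = gin, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2; H and W must be even
// [[Rcpp::export(name = ".cn_maxpool2_fwd")]]
List cn_maxpool2_fwd(NumericVector input) {
  IntegerVector di = input.attr("dim");
  const int H = di[0], W = di[1], C = di[2];
  if (H % 2 || W % 2) stop("maxpool2: H and W must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * C);
  const double* in = &input[0];
  for (int c = 0; c < C; ++c) {
    for (int xo = 0; xo < Wo; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        double best = R_NegInf;
        R_xlen_t besti = 0;
        for (int dx = 0; dx < 2; ++dx) {
          for (int dy = 0; dy < 2; ++dy) {
            R_xlen_t ii = (R_xlen_t)(2 * yo + dy) +
              (R_xlen_t)H * ((2 * xo + dx) + (R_xlen_t)W * c);
            if (in[ii] > best) { best = in[ii]; besti = ii; }
          }
        }
        R_xlen_t oi = (R_xlen_t)yo + (R_xlen_t)Ho * (xo + (R_xlen_t)Wo * c);
        out[oi] = best;
        idx[oi] = (int)besti;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cn_maxpool2_bwd")]]
NumericVector cn_maxpool2_bwd(NumericVector gout, IntegerVector idx, int H,
                              int W, int C) {
  NumericVector gin((R_xlen_t)H * W * C);
  for (R_xlen_t i = 0; i < gout.size(); ++i) gin[idx[i]] += gout[i];
  gin.attr("dim") = IntegerVector::create(H, W, C);
  return gin;
}
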