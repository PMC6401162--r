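// Minimal convolutional primitives for the cross-modality generator and
// discriminator. Layout: activations are (H, W, C) cubes, weights are
// (K, K, Cin, Cout). Convolutions are 'same' with zero padding, stride 1;
// pooling and the transposed convolution use a fixed 2x2 / stride-2 scheme.
// im2col + BLAS matrix products keep single-core training fast enough for
// desk-scale experiments.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Patch matrix, one column per kernel tap (ki, kj, c) in the native R weight
// ordering m = ki + K*kj + K*K*c, one row per output pixel n = i + H*j.
// Column segments are contiguous in both source and destination, so the fill
// is memcpy-speed; the convolution itself is one BLAS product.
static mat im2col(const cube& x, int K) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, P = (K - 1) / 2;
  mat cols(H * W, K * K * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.slice_memptr(c);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        double* dst = cols.colptr(ki + K * kj + K * K * c);
        const int i0 = std::max(0, P - ki);        // valid output rows
        const int i1 = H - 1 - std::max(0, ki - P);
        const int len = i1 - i0 + 1;
        if (len <= 0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - P;
          if (sj < 0 || sj >= W) continue;
          std::memcpy(dst + j * H + i0, xc + sj * H + i0 + (ki - P),
                      len * sizeof(double));
        }
      }
    }
  }
  return cols;
}

static cube col2im(const mat& cols, int H, int W, int C, int K) {
  const int P = (K - 1) / 2;
  cube x(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* xc = x.slice_memptr(c);
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const double* src = cols.colptr(ki + K * kj + K * K * c);
        const int i0 = std::max(0, P - ki);
        const int i1 = H - 1 - std::max(0, ki - P);
        const int len = i1 - i0 + 1;
        if (len <= 0) continue;
        for (int j = 0; j < W; ++j) {
          const int sj = j + kj - P;
          if (sj < 0 || sj >= W) continue;
          double* d = xc + sj * H + i0 + (ki - P);
          const double* s = src + j * H + i0;
          for (int t = 0; t < len; ++t) d[t] += s[t];
        }
      }
    }
  }
  return x;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_conv2d_fwd(Rcpp::NumericVector x_,
                                   Rcpp::NumericVector w_,
                                   Rcpp::NumericVector b_) {
  Rcpp::IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2];
  const int K = wd[0], Co = wd[3];
  cube x(x_.begin(), H, W, Ci, false);
  mat cols = im2col(x, K);
  const mat Wm(const_cast<double*>(w_.begin()), K * K * Ci, Co, false);
  Rcpp::NumericVector out(H * W * Co);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, Co);
  mat y(out.begin(), H * W, Co, false);
  y = cols * Wm;                          // (H*W) x Co, matches cube layout
  for (int co = 0; co < Co; ++co) y.col(co) += b_[co];
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv2d_bwd(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                          Rcpp::NumericVector gy_) {
  Rcpp::IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2];
  const int K = wd[0], Co = wd[3];
  cube x(x_.begin(), H, W, Ci, false);
  const mat gym(const_cast<double*>(gy_.begin()), H * W, Co, false);
  mat cols = im2col(x, K);
  const mat Wm(const_cast<double*>(w_.begin()), K * K * Ci, Co, false);
  Rcpp::NumericVector gw_(K * K * Ci * Co), gx_(H * W * Ci), gb_(Co);
  gw_.attr("dim") = Rcpp::IntegerVector::create(K, K, Ci, Co);
  gx_.attr("dim") = Rcpp::IntegerVector::create(H, W, Ci);
  mat gW(gw_.begin(), K * K * Ci, Co, false);
  gW = cols.t() * gym;
  for (int co = 0; co < Co; ++co) gb_[co] = accu(gym.col(co));
  mat gcols = gym * Wm.t();               // (H*W) x (K*K*Ci)
  cube gx = col2im(gcols, H, W, Ci, K);
  std::copy(gx.begin(), gx.end(), gx_.begin());
  return Rcpp::List::create(Rcpp::Named("gx") = gx_,
                            Rcpp::Named("gw") = gw_,
                            Rcpp::Named("gb") = gb_);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_avgpool_fwd(Rcpp::NumericVector x_) {
  Rcpp::IntegerVector xd = x_.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], Ho = H / 2, Wo = W / 2;
  cube x(x_.begin(), H, W, C, false);
  Rcpp::NumericVector out(Ho * Wo * C);
  out.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C);
  cube y(out.begin(), Ho, Wo, C, false);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_avgpool_bwd(Rcpp::NumericVector gy_) {
  Rcpp::IntegerVector gd = gy_.attr("dim");
  const int Ho = gd[0], Wo = gd[1], C = gd[2], H = 2 * Ho, W = 2 * Wo;
  cube gy(gy_.begin(), Ho, Wo, C, false);
  Rcpp::NumericVector out(H * W * C);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C);
  cube gx(out.begin(), H, W, C, false);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = 0.25 * gy(i, j, c);
        gx(2 * i, 2 * j, c) = g; gx(2 * i + 1, 2 * j, c) = g;
        gx(2 * i, 2 * j + 1, c) = g; gx(2 * i + 1, 2 * j + 1, c) = g;
      }
  return out;
}

// transposed convolution, kernel 2x2, stride 2: w is (2, 2, Cin, Cout)
// [[Rcpp::export]]
Rcpp::NumericVector cpp_upconv_fwd(Rcpp::NumericVector x_,
                                   Rcpp::NumericVector w_,
                                   Rcpp::NumericVector b_) {
  Rcpp::IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], Co = wd[3];
  cube x(x_.begin(), H, W, Ci, false);
  Rcpp::NumericVector out(4 * H * W * Co);
  out.attr("dim") = Rcpp::IntegerVector::create(2 * H, 2 * W, Co);
  cube y(out.begin(), 2 * H, 2 * W, Co, false);
  for (int co = 0; co < Co; ++co) y.slice(co).fill(b_[co]);
  for (int co = 0; co < Co; ++co)
    for (int ci = 0; ci < Ci; ++ci)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          const double wv = w_[a + 2 * (b + 2 * (ci + Ci * co))];
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i)
              y(2 * i + a, 2 * j + b, co) += wv * x(i, j, ci);
        }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_upconv_bwd(Rcpp::NumericVector x_, Rcpp::NumericVector w_,
                          Rcpp::NumericVector gy_) {
  Rcpp::IntegerVector xd = x_.attr("dim"), wd = w_.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], Co = wd[3];
  cube x(x_.begin(), H, W, Ci, false);
  cube gy(gy_.begin(), 2 * H, 2 * W, Co, false);
  Rcpp::NumericVector gx_(H * W * Ci), gw_(4 * Ci * Co);
  gx_.attr("dim") = Rcpp::IntegerVector::create(H, W, Ci);
  gw_.attr("dim") = Rcpp::IntegerVector::create(2, 2, Ci, Co);
  cube gx(gx_.begin(), H, W, Ci, false);
  Rcpp::NumericVector gb_(Co);
  for (int co = 0; co < Co; ++co) {
    double gb = 0;
    for (int j = 0; j < 2 * W; ++j)
      for (int i = 0; i < 2 * H; ++i) gb += gy(i, j, co);
    gb_[co] = gb;
    for (int ci = 0; ci < Ci; ++ci)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          const double wv = w_[a + 2 * (b + 2 * (ci + Ci * co))];
          double gw = 0;
          for (int j = 0; j < W; ++j)
            for (int i = 0; i < H; ++i) {
              const double g = gy(2 * i + a, 2 * j + b, co);
              gx(i, j, ci) += wv * g;
              gw += g * x(i, j, ci);
            }
          gw_[a + 2 * (b + 2 * (ci + Ci * co))] = gw;
        }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx_,
                            Rcpp::Named("gw") = gw_,
                            Rcpp::Named("gb") = gb_);
}
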