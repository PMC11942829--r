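// Low-level numerical kernels for the denoising networks.
//
// Tensor layout convention (matches R arrays, column-major):
//   activations  dim = (H, W, C, N)   index = h + H*(w + W*(c + C*n))
//   conv weights dim = (k, k, Cin, Cout)
//
// Convolutions are computed by im2col + GEMM in single precision; the
// im2col matrix is built over the whole batch so one GEMM serves all N
// images. Gradients with respect to input and parameters are exposed
// separately so that transposed convolutions can reuse the same kernels
// with the roles of forward and backward swapped.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int conv_out_size(int in, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (in + 2 * pad - eff) / stride + 1;
}

// Fill the im2col matrix: rows = k*k*C, cols = Ho*Wo*N.
// Row index r = ki + k*(kj + k*c); col index j = ho + Ho*(wo + Wo*n).
static void im2col(const double* x, arma::fmat& col,
                   int H, int W, int C, int N,
                   int k, int stride, int pad, int dil,
                   int Ho, int Wo) {
  const int R = k * k * C;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)H * W * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t j = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        float* cj = col.colptr(j);
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)H * W * c;
          for (int kj = 0; kj < k; ++kj) {
            int w = wo * stride - pad + kj * dil;
            bool wok = (w >= 0 && w < W);
            for (int ki = 0; ki < k; ++ki) {
              int h = ho * stride - pad + ki * dil;
              float v = 0.0f;
              if (wok && h >= 0 && h < H)
                v = (float)xc[h + (size_t)H * w];
              cj[ki + k * (kj + k * c)] = v;
            }
          }
        }
        (void)R;
      }
    }
  }
}

// Scatter-add the im2col-shaped gradient back to input layout.
static void col2im(const arma::fmat& col, double* gx,
                   int H, int W, int C, int N,
                   int k, int stride, int pad, int dil,
                   int Ho, int Wo) {
  for (int n = 0; n < N; ++n) {
    double* xn = gx + (size_t)H * W * C * n;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const size_t j = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
        const float* cj = col.colptr(j);
        for (int c = 0; c < C; ++c) {
          double* xc = xn + (size_t)H * W * c;
          for (int kj = 0; kj < k; ++kj) {
            int w = wo * stride - pad + kj * dil;
            if (w < 0 || w >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int h = ho * stride - pad + ki * dil;
              if (h < 0 || h >= H) continue;
              xc[h + (size_t)H * w] += (double)cj[ki + k * (kj + k * c)];
            }
          }
        }
      }
    }
  }
}

static arma::fmat weights_as_mat(const NumericVector& w, int k, int Cin, int Cout) {
  // (k,k,Cin,Cout) column-major -> (k*k*Cin) x Cout, then transpose to Cout rows
  arma::fmat wm(k * k * Cin, Cout);
  const double* p = w.begin();
  for (size_t i = 0; i < (size_t)k * k * Cin * Cout; ++i)
    wm[i] = (float)p[i];
  return wm.t();  // Cout x (k*k*Cin)
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("channel mismatch: input has %d, weights expect %d", C, Cin);
  int Ho = conv_out_size(H, k, stride, pad, dil);
  int Wo = conv_out_size(W, k, stride, pad, dil);
  if (Ho < 1 || Wo < 1) stop("input too small for this convolution");

  arma::fmat col(k * k * C, (size_t)Ho * Wo * N);
  im2col(x.begin(), col, H, W, C, N, k, stride, pad, dil, Ho, Wo);
  arma::fmat wm = weights_as_mat(w, k, C, Cout);
  arma::fmat y = wm * col;  // Cout x (Ho*Wo*N)

  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* o = out.begin();
  const double* bp = b.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < Cout; ++f) {
      double bf = bp[f];
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t j = (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n);
          o[ho + (size_t)Ho * (wo + (size_t)Wo * (f + (size_t)Cout * n))] =
            (double)y(f, j) + bf;
        }
    }
  return out;
}

// Gradient w.r.t. the convolution input.
// [[Rcpp::export(name = ".conv2d_bwd_input")]]
NumericVector conv2d_bwd_input(NumericVector gy, NumericVector w,
                               int stride, int pad, int dil,
                               int Hin, int Win) {
  IntegerVector gd = gy.attr("dim");
  IntegerVector wd = w.attr("dim");
  int Ho = gd[0], Wo = gd[1], Cout = gd[2], N = gd[3];
  int k = wd[0], Cin = wd[2];
  if ((int)wd[3] != Cout) stop("weight/grad channel mismatch");

  // Gy as Cout x (Ho*Wo*N)
  arma::fmat gym(Cout, (size_t)Ho * Wo * N);
  const double* g = gy.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < Cout; ++f)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          gym(f, (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n)) =
            (float)g[ho + (size_t)Ho * (wo + (size_t)Wo * (f + (size_t)Cout * n))];

  arma::fmat wm = weights_as_mat(w, k, Cin, Cout);  // Cout x (k*k*Cin)
  arma::fmat colg = wm.t() * gym;                   // (k*k*Cin) x (Ho*Wo*N)

  NumericVector gx((size_t)Hin * Win * Cin * N);
  gx.attr("dim") = IntegerVector::create(Hin, Win, Cin, N);
  std::fill(gx.begin(), gx.end(), 0.0);
  col2im(colg, gx.begin(), Hin, Win, Cin, N, k, stride, pad, dil, Ho, Wo);
  return gx;
}

// Gradients w.r.t. weights and bias.
// [[Rcpp::export(name = ".conv2d_bwd_params")]]
List conv2d_bwd_params(NumericVector x, NumericVector gy,
                       int k, int stride, int pad, int dil) {
  IntegerVector xd = x.attr("dim");
  IntegerVector gd = gy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = gd[0], Wo = gd[1], Cout = gd[2];
  if ((int)gd[3] != N) stop("batch mismatch");

  arma::fmat col(k * k * C, (size_t)Ho * Wo * N);
  im2col(x.begin(), col, H, W, C, N, k, stride, pad, dil, Ho, Wo);

  arma::fmat gym(Cout, (size_t)Ho * Wo * N);
  const double* g = gy.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < Cout; ++f)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          gym(f, (size_t)ho + (size_t)Ho * (wo + (size_t)Wo * n)) =
            (float)g[ho + (size_t)Ho * (wo + (size_t)Wo * (f + (size_t)Cout * n))];

  arma::fmat gw = gym * col.t();  // Cout x (k*k*C)

  NumericVector gwv((size_t)k * k * C * Cout);
  gwv.attr("dim") = IntegerVector::create(k, k, C, Cout);
  for (int f = 0; f < Cout; ++f)
    for (size_t r = 0; r < (size_t)k * k * C; ++r)
      gwv[r + (size_t)k * k * C * f] = (double)gw(f, r);

  NumericVector gb(Cout);
  arma::fvec rs = arma::sum(gym, 1);
  for (int f = 0; f < Cout; ++f) gb[f] = (double)rs[f];

  return List::create(_["gw"] = gwv, _["gb"] = gb);
}

// 2x2 max pooling, stride 2, storing flat argmax offsets (0-based, within
// the (H,W,C,N) input array) for index-preserving unpooling.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  NumericVector idx((size_t)Ho * Wo * C * N);  // double holds indices exactly
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t base = (size_t)H * W * (c + (size_t)C * n);
      size_t obase = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          size_t best = base + (2 * ho) + (size_t)H * (2 * wo);
          double bv = xp[best];
          size_t cand[3] = {
            base + (2 * ho + 1) + (size_t)H * (2 * wo),
            base + (2 * ho) + (size_t)H * (2 * wo + 1),
            base + (2 * ho + 1) + (size_t)H * (2 * wo + 1)};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          size_t o = obase + ho + (size_t)Ho * wo;
          y[o] = bv;
          idx[o] = (double)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, NumericVector idx, int H, int W) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[2], N = gd[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::fill(gx.begin(), gx.end(), 0.0);
  for (R_xlen_t i = 0; i < gy.size(); ++i)
    gx[(size_t)idx[i]] += gy[i];
  return gx;
}

// Index-preserving 2x2 unpooling: each value returns to its stored argmax
// position; all other positions are zero.
// [[Rcpp::export(name = ".maxunpool2_fwd")]]
NumericVector maxunpool2_fwd(NumericVector x, NumericVector idx, int H, int W) {
  IntegerVector xd = x.attr("dim");
  int C = xd[2], N = xd[3];
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  std::fill(y.begin(), y.end(), 0.0);
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[(size_t)idx[i]] += x[i];
  return y;
}

// [[Rcpp::export(name = ".maxunpool2_bwd")]]
NumericVector maxunpool2_bwd(NumericVector gy, NumericVector idx,
                             int Ho, int Wo) {
  IntegerVector gd = gy.attr("dim");
  int C = gd[2], N = gd[3];
  NumericVector gx((size_t)Ho * Wo * C * N);
  gx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (R_xlen_t i = 0; i < gx.size(); ++i)
    gx[i] = gy[(size_t)idx[i]];
  return gx;
}
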