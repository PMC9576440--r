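// Convolutional-network primitives for the 2D ResUnet.
// Tensors are R arrays in column-major order:
//   activations (H, W, C, N), kernels (k, k, C_in, C_out).
// Convolutions use "same" zero padding and are computed as im2col + GEMM so
// the heavy lifting is done by the BLAS R links against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& P) {
  // P: (H*W) x (k*k*C); column r = i + k*j + k*k*c
  const int pad = (k - 1) / 2;
  P.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int r = i + k * j + k * k * c;
        double* Pcol = P.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int sw = w + j - pad;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, pad - i);
          const int h1 = std::min(H, H + pad - i);
          const double* src = xc + (size_t)H * sw + (h0 + i - pad);
          double* dst = Pcol + (size_t)H * w + h0;
          std::copy(src, src + (h1 - h0), dst);
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& P, int H, int W, int C, int k,
                       double* dx) {
  const int pad = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        const int r = i + k * j + k * k * c;
        const double* Pcol = P.colptr(r);
        for (int w = 0; w < W; ++w) {
          const int sw = w + j - pad;
          if (sw < 0 || sw >= W) continue;
          const int h0 = std::max(0, pad - i);
          const int h1 = std::min(H, H + pad - i);
          double* dst = xc + (size_t)H * sw + (h0 + i - pad);
          const double* src = Pcol + (size_t)H * w + h0;
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) {  // single image: promote to N = 1
    IntegerVector d4 = IntegerVector::create(d[0], d[1], d[2], 1);
    return d4;
  }
  if (d.size() != 4) stop("expected a 3D or 4D array");
  return d;
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector wgt,
                             NumericVector bias) {
  IntegerVector dx = dims4(x);
  IntegerVector dw = wgt.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], K = dw[3];
  if (dw[1] != k) stop("kernel must be square");
  if (dw[2] != C) stop("kernel input channels do not match input");
  if (k % 2 == 0) stop("kernel size must be odd");

  arma::mat W2(const_cast<double*>(wgt.begin()), k * k * C, K, false, true);
  arma::rowvec bv(const_cast<double*>(bias.begin()), K, false, true);

  NumericVector y((size_t)H * W * K * N);
  y.attr("dim") = IntegerVector::create(H, W, K, N);
  arma::mat P(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, P);
    arma::mat Y(y.begin() + (size_t)H * W * K * n, H * W, K, false, true);
    Y = P * W2;
    Y.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector wgt, NumericVector dy) {
  IntegerVector dx4 = dims4(x);
  IntegerVector dw = wgt.attr("dim");
  const int H = dx4[0], W = dx4[1], C = dx4[2], N = dx4[3];
  const int k = dw[0], K = dw[3];

  arma::mat W2(const_cast<double*>(wgt.begin()), k * k * C, K, false, true);

  NumericVector dxv((size_t)H * W * C * N);
  dxv.attr("dim") = x.attr("dim");
  NumericVector dwv(wgt.size());
  dwv.attr("dim") = wgt.attr("dim");
  NumericVector dbv(K);
  arma::mat dW2(dwv.begin(), k * k * C, K, false, true);
  arma::rowvec db(dbv.begin(), K, false, true);

  arma::mat P(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, P);
    arma::mat dY(const_cast<double*>(dy.begin()) + (size_t)H * W * K * n,
                 H * W, K, false, true);
    dW2 += P.t() * dY;
    db += arma::sum(dY, 0);
    arma::mat dP = dY * W2.t();
    col2im_acc(dP, H, W, C, k, dxv.begin() + (size_t)H * W * C * n);
  }
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// [[Rcpp::export(name = ".cpp_maxpool2_fwd")]]
List cpp_maxpool2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("spatial size must be even for 2x2 pooling");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t i00 = base + (size_t)H * (2 * w) + 2 * h;
          size_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          size_t best = cand[0];
          for (int q = 1; q < 4; ++q)
            if (x[cand[q]] > x[best]) best = cand[q];
          y[o] = x[best];
          idx[o] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector idx,
                               IntegerVector dim_in) {
  size_t nin = 1;
  for (int i = 0; i < dim_in.size(); ++i) nin *= dim_in[i];
  NumericVector dx(nin);
  dx.attr("dim") = dim_in;
  for (R_xlen_t o = 0; o < dy.size(); ++o) dx[idx[o]] += dy[o];
  return dx;
}

// Bilinear x2 upsampling; source coordinate s = (t + 0.5)/2 - 0.5, clamped.
static inline void lin_coef(int t, int S, int& i0, int& i1, double& a) {
  double s = (t + 0.5) / 2.0 - 0.5;
  if (s < 0) s = 0;
  if (s > S - 1) s = S - 1;
  i0 = (int)std::floor(s);
  i1 = std::min(i0 + 1, S - 1);
  a = s - i0;
}

// [[Rcpp::export(name = ".cpp_upsample2_fwd")]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int t = 0; t < Ho; ++t) lin_coef(t, H, h0[t], h1[t], ah[t]);
  for (int t = 0; t < Wo; ++t) lin_coef(t, W, w0[t], w1[t], aw[t]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double v00 = xc[h0[h] + (size_t)H * w0[w]];
          double v10 = xc[h1[h] + (size_t)H * w0[w]];
          double v01 = xc[h0[h] + (size_t)H * w1[w]];
          double v11 = xc[h1[h] + (size_t)H * w1[w]];
          double top = v00 * (1 - ah[h]) + v10 * ah[h];
          double bot = v01 * (1 - ah[h]) + v11 * ah[h];
          yc[h + (size_t)Ho * w] = top * (1 - aw[w]) + bot * aw[w];
        }
    }
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample2_bwd")]]
NumericVector cpp_upsample2_bwd(NumericVector dy, IntegerVector dim_in) {
  const int H = dim_in[0], W = dim_in[1], C = dim_in[2],
            N = dim_in.size() == 4 ? dim_in[3] : 1;
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = dim_in;
  std::vector<int> h0(Ho), h1(Ho), w0(Wo), w1(Wo);
  std::vector<double> ah(Ho), aw(Wo);
  for (int t = 0; t < Ho; ++t) lin_coef(t, H, h0[t], h1[t], ah[t]);
  for (int t = 0; t < Wo; ++t) lin_coef(t, W, w0[t], w1[t], aw[t]);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* yc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double g = yc[h + (size_t)Ho * w];
          xc[h0[h] + (size_t)H * w0[w]] += g * (1 - ah[h]) * (1 - aw[w]);
          xc[h1[h] + (size_t)H * w0[w]] += g * ah[h] * (1 - aw[w]);
          xc[h0[h] + (size_t)H * w1[w]] += g * (1 - ah[h]) * aw[w];
          xc[h1[h] + (size_t)H * w1[w]] += g * ah[h] * aw[w];
        }
    }
  return dx;
}
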