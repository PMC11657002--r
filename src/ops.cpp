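// Low-level array kernels for the CNN core.
// All image tensors use R's column-major layout with dim = (H, W, C, N).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::mat im2col(const double* x, int H, int W, int C,
                               int kh, int kw, int stride, int pad,
                               int Ho, int Wo) {
  const int K = kh * kw * C;
  arma::mat col(K, (arma::uword)Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* plane = x + (size_t)H * W * c;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        const int r = ih + kh * (iw + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int w_in = ow * stride - pad + iw;
          if (w_in < 0 || w_in >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h_in = oh * stride - pad + ih;
            if (h_in < 0 || h_in >= H) continue;
            col(r, oh + (arma::uword)Ho * ow) = plane[h_in + (size_t)H * w_in];
          }
        }
      }
    }
  }
  return col;
}

static inline void col2im_acc(const arma::mat& col, double* gx, int H, int W,
                              int C, int kh, int kw, int stride, int pad,
                              int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* plane = gx + (size_t)H * W * c;
    for (int iw = 0; iw < kw; ++iw) {
      for (int ih = 0; ih < kh; ++ih) {
        const int r = ih + kh * (iw + kw * c);
        for (int ow = 0; ow < Wo; ++ow) {
          const int w_in = ow * stride - pad + iw;
          if (w_in < 0 || w_in >= W) continue;
          for (int oh = 0; oh < Ho; ++oh) {
            const int h_in = oh * stride - pad + ih;
            if (h_in < 0 || h_in >= H) continue;
            plane[h_in + (size_t)H * w_in] += col(r, oh + (arma::uword)Ho * ow);
          }
        }
      }
    }
  }
}

// x: (H,W,Cin,N); w: (kh,kw,Cin,Cout); b: length Cout
// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector w,
                                 NumericVector b, int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  if (dw[2] != C) stop("conv2d: input has %d channels, weights expect %d", C, dw[2]);
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (W + 2 * pad - kw) / stride + 1;
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const int K = kh * kw * C;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
                           kh, kw, stride, pad, Ho, Wo);
    arma::mat yt = col.t() * Wm;  // (Ho*Wo) x Cout
    yt.each_row() += bv;
    std::copy(yt.begin(), yt.end(), y.begin() + (size_t)Ho * Wo * Cout * n);
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector gy,
                         int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim"), dy = gy.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], Cout = dw[3];
  const int Ho = dy[0], Wo = dy[1];
  const int K = kh * kw * C;
  NumericVector gx(x.size()); gx.attr("dim") = dx;
  NumericVector gw(w.size()); gw.attr("dim") = dw;
  NumericVector gb(Cout);
  const arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  arma::mat gWm(gw.begin(), K, Cout, false, true);
  arma::rowvec gbv(gb.begin(), Cout, false, true);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)H * W * C * n, H, W, C,
                           kh, kw, stride, pad, Ho, Wo);
    const arma::mat gym(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * Cout * n,
                        (arma::uword)Ho * Wo, Cout, false, true);
    gWm += col * gym;
    gbv += arma::sum(gym, 0);
    arma::mat gcol = Wm * gym.t();  // K x (Ho*Wo)
    col2im_acc(gcol, gx.begin() + (size_t)H * W * C * n, H, W, C,
               kh, kw, stride, pad, Ho, Wo);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 max pooling; H and W must be even.
// [[Rcpp::export]]
List cpp_maxpool2_forward(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("maxpool2: H and W must be even (got %dx%d)", H, W);
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());  // 0-based linear index into x
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          size_t best = base + (2 * oh) + (size_t)H * (2 * ow);
          double bv = x[best];
          const int hs[2] = {2 * oh, 2 * oh + 1};
          const int ws[2] = {2 * ow, 2 * ow + 1};
          for (int a = 0; a < 2; ++a)
            for (int bi = 0; bi < 2; ++bi) {
              size_t p = base + hs[a] + (size_t)H * ws[bi];
              if (x[p] > bv) { bv = x[p]; best = p; }
            }
          y[o] = bv; idx[o] = (int)best; ++o;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_backward(NumericVector gy, IntegerVector idx,
                                    IntegerVector dims_in) {
  NumericVector gx((size_t)dims_in[0] * dims_in[1] * dims_in[2] * dims_in[3]);
  gx.attr("dim") = dims_in;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector cpp_upsample2_forward(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = (size_t)H * W * (c + (size_t)C * n);
      const size_t bo = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          y[bo + h + (size_t)Ho * w] = x[bi + h / 2 + (size_t)H * (w / 2)];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector gy) {
  IntegerVector dy = gy.attr("dim");
  const int Ho = dy[0], Wo = dy[1], C = dy[2], N = dy[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = (size_t)H * W * (c + (size_t)C * n);
      const size_t bo = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          gx[bi + h / 2 + (size_t)H * (w / 2)] += gy[bo + h + (size_t)Ho * w];
    }
  return gx;
}

// Bilinear resize (half-pixel centre alignment), forward only.
// x: (H,W,C,N) -> (Ho,Wo,C,N)
// [[Rcpp::export]]
NumericVector cpp_bilinear_resize(NumericVector x, int Ho, int Wo) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  std::vector<int> h0(Ho), h1(Ho); std::vector<double> fh(Ho);
  for (int h = 0; h < Ho; ++h) {
    double src = (h + 0.5) * sh - 0.5;
    if (src < 0) src = 0;
    if (src > H - 1) src = H - 1;
    h0[h] = (int)std::floor(src); h1[h] = std::min(h0[h] + 1, H - 1);
    fh[h] = src - h0[h];
  }
  std::vector<int> w0(Wo), w1(Wo); std::vector<double> fw(Wo);
  for (int w = 0; w < Wo; ++w) {
    double src = (w + 0.5) * sw - 0.5;
    if (src < 0) src = 0;
    if (src > W - 1) src = W - 1;
    w0[w] = (int)std::floor(src); w1[w] = std::min(w0[w] + 1, W - 1);
    fw[w] = src - w0[w];
  }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* q = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double a = p[h0[h] + (size_t)H * w0[w]], b = p[h1[h] + (size_t)H * w0[w]];
          const double cc = p[h0[h] + (size_t)H * w1[w]], d = p[h1[h] + (size_t)H * w1[w]];
          q[h + (size_t)Ho * w] =
            (a * (1 - fh[h]) + b * fh[h]) * (1 - fw[w]) +
            (cc * (1 - fh[h]) + d * fh[h]) * fw[w];
        }
    }
  return y;
}

// --- batch normalization kernels (single-pass, native layout) --------------

// per-channel mean and biased variance over (H,W,N) of an (H,W,C,N) array
// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const size_t plane = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double M = (double)plane * N;
    mean[c] = s / M;
    var[c] = s2 / M - mean[c] * mean[c];
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = x * scale[c] + shift[c]
// [[Rcpp::export]]
NumericVector cpp_bn_apply(NumericVector x, NumericVector scale,
                           NumericVector shift) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const size_t plane = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = dx;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + plane * (c + (size_t)C * n);
      double* q = y.begin() + plane * (c + (size_t)C * n);
      const double a = scale[c], b = shift[c];
      for (size_t i = 0; i < plane; ++i) q[i] = p[i] * a + b;
    }
  return y;
}

// channel sums of g and of g * xhat, with xhat = (x - mu[c]) / sd[c]
// [[Rcpp::export]]
List cpp_bn_grad_sums(NumericVector g, NumericVector x, NumericVector mu,
                      NumericVector sd) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const size_t plane = (size_t)H * W;
  NumericVector dbeta(C), dgamma(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    const double m = mu[c], s = sd[c];
    for (int n = 0; n < N; ++n) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* pg = g.begin() + off;
      const double* px = x.begin() + off;
      for (size_t i = 0; i < plane; ++i) {
        sg += pg[i];
        sgx += pg[i] * (px[i] - m) / s;
      }
    }
    dbeta[c] = sg; dgamma[c] = sgx;
  }
  return List::create(_["dbeta"] = dbeta, _["dgamma"] = dgamma);
}

// training-mode input gradient:
//   dx = (gamma/sd) * (g - dbeta/M - xhat * dgamma/M)
// [[Rcpp::export]]
NumericVector cpp_bn_backward_x(NumericVector g, NumericVector x,
                                NumericVector mu, NumericVector sd,
                                NumericVector gamma, NumericVector dgamma,
                                NumericVector dbeta) {
  IntegerVector dx_ = x.attr("dim");
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const size_t plane = (size_t)H * W;
  const double M = (double)plane * N;
  NumericVector out(x.size());
  out.attr("dim") = dx_;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = plane * (c + (size_t)C * n);
      const double* pg = g.begin() + off;
      const double* px = x.begin() + off;
      double* po = out.begin() + off;
      const double a = gamma[c] / sd[c];
      const double mb = dbeta[c] / M, mg = dgamma[c] / M;
      const double m = mu[c], s = sd[c];
      for (size_t i = 0; i < plane; ++i)
        po[i] = a * (pg[i] - mb - ((px[i] - m) / s) * mg);
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_forward(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin(); double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_backward(NumericVector g, NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* pg = g.begin(); const double* px = x.begin();
  double* q = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = px[i] > 0 ? pg[i] : 0;
  return out;
}
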