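// Compiled tensor kernels for the detector: GEMM-based 2-D convolution,
// max-pooling and nearest-neighbour upsampling, each with its adjoint.
// Array layout throughout: feature maps (H, W, C, N), weights (k, k, Cin, Cout),
// both in R's column-major order.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo, arma::mat& col) {
  // col is (Ho*Wo) x (k*k*C); column r = i + k*j + k*k*c holds patch element
  // (i,j,c) for every output position q = ho + Ho*wo (contiguous writes).
  size_t HoWo = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        double* dst = col.memptr() + HoWo * (i + k * j + (size_t)k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * stride - pad + j;
          double* d2 = dst + (size_t)Ho * wo;
          if (w < 0 || w >= W) {
            for (int ho = 0; ho < Ho; ++ho) d2[ho] = 0.0;
            continue;
          }
          const double* xcw = xc + (size_t)H * w;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * stride - pad + i;
            d2[ho] = (h >= 0 && h < H) ? xcw[h] : 0.0;
          }
        }
      }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C,
                   int k, int stride, int pad, int Ho, int Wo, double* gx) {
  size_t HoWo = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* xc = gx + (size_t)H * W * c;
    for (int j = 0; j < k; ++j)
      for (int i = 0; i < k; ++i) {
        const double* src = col.memptr() + HoWo * (i + k * j + (size_t)k * k * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int w = wo * stride - pad + j;
          if (w < 0 || w >= W) continue;
          const double* s2 = src + (size_t)Ho * wo;
          double* xcw = xc + (size_t)H * w;
          for (int ho = 0; ho < Ho; ++ho) {
            int h = ho * stride - pad + i;
            if (h >= 0 && h < H) xcw[h] += s2[ho];
          }
        }
      }
  }
}

static inline int out_size(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], O = wd[3];
  if (wd[2] != C) stop("conv2d: channel mismatch (%d vs %d)", wd[2], C);
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * O * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, O, N);
  arma::mat wmat(w.begin(), (size_t)k * k * C, O, false, true);
  if (k == 1 && stride == 1 && pad == 0) {  // pointwise conv: plain GEMM
    for (int n = 0; n < N; ++n) {
      arma::mat xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                   (size_t)H * W, C, false, true);
      arma::mat ymat(y.begin() + (size_t)Ho * Wo * O * n, (size_t)Ho * Wo, O, false, true);
      ymat = xm * wmat;
    }
    return y;
  }
  arma::mat col((size_t)Ho * Wo, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat ymat(y.begin() + (size_t)Ho * Wo * O * n, (size_t)Ho * Wo, O, false, true);
    ymat = col * wmat;
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
               int stride, int pad, bool need_gx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], O = wd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::mat wmat(w.begin(), (size_t)k * k * C, O, false, true);
  NumericVector gw((size_t)k * k * C * O);
  gw.attr("dim") = wd;
  arma::mat gwmat(gw.begin(), (size_t)k * k * C, O, false, true);
  NumericVector gx;
  if (need_gx) { gx = NumericVector((size_t)H * W * C * N); gx.attr("dim") = xd; }
  if (k == 1 && stride == 1 && pad == 0) {
    for (int n = 0; n < N; ++n) {
      arma::mat xm(const_cast<double*>(x.begin()) + (size_t)H * W * C * n,
                   (size_t)H * W, C, false, true);
      arma::mat gymat(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * O * n,
                      (size_t)Ho * Wo, O, false, true);
      gwmat += xm.t() * gymat;
      if (need_gx) {
        arma::mat gxm(gx.begin() + (size_t)H * W * C * n, (size_t)H * W, C, false, true);
        gxm = gymat * wmat.t();
      }
    }
    return List::create(_["gw"] = gw, _["gx"] = gx);
  }
  arma::mat col((size_t)Ho * Wo, (size_t)k * k * C);
  arma::mat gcol((size_t)Ho * Wo, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat gymat(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * O * n,
                    (size_t)Ho * Wo, O, false, true);
    gwmat += col.t() * gymat;
    if (need_gx) {
      gcol = gymat * wmat.t();
      col2im(gcol, H, W, C, k, stride, pad, Ho, Wo, gx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["gw"] = gw, _["gx"] = gx);
}

// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // argmax as h + H*w within plane
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = y.attr("dim");
  size_t q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -HUGE_VAL; int bidx = -1;
          for (int j = 0; j < k; ++j) {
            int w = wo * stride - pad + j;
            if (w < 0 || w >= W) continue;
            for (int i = 0; i < k; ++i) {
              int h = ho * stride - pad + i;
              if (h < 0 || h >= H) continue;
              double v = xc[h + (size_t)H * w];
              if (v > best) { best = v; bidx = h + H * w; }
            }
          }
          // column-major target offset for (ho, wo)
          size_t off = q + (size_t)ho + (size_t)Ho * wo;
          y[off] = best; idx[off] = bidx;
        }
      q += (size_t)Ho * Wo;
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
NumericVector maxpool_bw(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = xdim[0], W = xdim[1];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = xdim;
  size_t plane_in = (size_t)H * W, plane_out = (size_t)Ho * Wo;
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    double* g = gx.begin() + plane_in * p;
    const double* gyp = gy.begin() + plane_out * p;
    const int* ip = idx.begin() + plane_out * p;
    for (size_t q2 = 0; q2 < plane_out; ++q2)
      if (ip[q2] >= 0) g[ip[q2]] += gyp[q2];
  }
  return gx;
}

// [[Rcpp::export(name = ".upsample2_fw")]]
NumericVector upsample2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    const double* xp = x.begin() + (size_t)H * W * p;
    double* yp = y.begin() + (size_t)Ho * Wo * p;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double v = xp[h + (size_t)H * w];
        size_t b = (size_t)2 * h + (size_t)Ho * 2 * w;
        yp[b] = v; yp[b + 1] = v; yp[b + Ho] = v; yp[b + Ho + 1] = v;
      }
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
NumericVector upsample2_bw(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = Ho / 2, W = Wo / 2;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (size_t p = 0; p < (size_t)C * N; ++p) {
    double* xp = gx.begin() + (size_t)H * W * p;
    const double* yp = gy.begin() + (size_t)Ho * Wo * p;
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        size_t b = (size_t)2 * h + (size_t)Ho * 2 * w;
        xp[h + (size_t)H * w] = yp[b] + yp[b + 1] + yp[b + Ho] + yp[b + Ho + 1];
      }
  }
  return gx;
}

// ---- fused batch-norm and SiLU kernels (hot path of training) -------------

// [[Rcpp::export(name = ".bn_train_fw")]]
List bn_train_fw(NumericVector x, NumericVector gamma, NumericVector beta,
                 double eps) {
  IntegerVector xd = x.attr("dim");
  size_t hw = (size_t)xd[0] * xd[1]; int C = xd[2], N = xd[3];
  size_t m = hw * N;
  NumericVector mu(C), istd(C);
  for (int c = 0; c < C; ++c) {
    double s = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) s += p[i];
    }
    mu[c] = s / m;
    double v = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { double d = p[i] - mu[c]; v += d * d; }
    }
    istd[c] = 1.0 / std::sqrt(v / m + eps);
  }
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + hw * (c + (size_t)C * n);
      double* q = y.begin() + hw * (c + (size_t)C * n);
      double a = gamma[c] * istd[c], b = beta[c] - mu[c] * a;
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * a + b;
    }
  return List::create(_["y"] = y, _["mu"] = mu, _["istd"] = istd);
}

// [[Rcpp::export(name = ".bn_train_bw")]]
List bn_train_bw(NumericVector x, NumericVector gamma, NumericVector mu,
                 NumericVector istd, NumericVector g) {
  IntegerVector xd = x.attr("dim");
  size_t hw = (size_t)xd[0] * xd[1]; int C = xd[2], N = xd[3];
  size_t m = hw * N;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = hw * (c + (size_t)C * n);
      const double* px = x.begin() + off;
      const double* pg = g.begin() + off;
      for (size_t i = 0; i < hw; ++i) {
        sg += pg[i];
        sgx += pg[i] * (px[i] - mu[c]) * istd[c];
      }
    }
    dbeta[c] = sg; dgamma[c] = sgx;
  }
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = hw * (c + (size_t)C * n);
      const double* px = x.begin() + off;
      const double* pg = g.begin() + off;
      double* q = gx.begin() + off;
      double a = gamma[c] * istd[c];
      double c1 = dbeta[c] / m, c2 = dgamma[c] / m;
      for (size_t i = 0; i < hw; ++i)
        q[i] = a * (pg[i] - c1 - (px[i] - mu[c]) * istd[c] * c2);
    }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".bn_infer")]]
NumericVector bn_infer(NumericVector x, NumericVector sc, NumericVector off) {
  IntegerVector xd = x.attr("dim");
  size_t hw = (size_t)xd[0] * xd[1]; int C = xd[2], N = xd[3];
  NumericVector y(x.size());
  y.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t o = hw * (c + (size_t)C * n);
      const double* p = x.begin() + o;
      double* q = y.begin() + o;
      for (size_t i = 0; i < hw; ++i) q[i] = p[i] * sc[c] + off[c];
    }
  return y;
}

// [[Rcpp::export(name = ".silu_fw")]]
NumericVector silu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = x[i] * s;
  }
  return y;
}

// [[Rcpp::export(name = ".silu_bw")]]
NumericVector silu_bw(NumericVector x, NumericVector g) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    gx[i] = g[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return gx;
}

// forward returning both y and the sigmoid (cached for the adjoint)
// [[Rcpp::export(name = ".silu_fw2")]]
List silu_fw2(NumericVector x) {
  NumericVector y(x.size()), sig(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-x[i]));
    sig[i] = s;
    y[i] = x[i] * s;
  }
  return List::create(_["y"] = y, _["s"] = sig);
}

// adjoint with cached sigmoid: g * s * (1 + x(1-s))
// [[Rcpp::export(name = ".silu_bw2")]]
NumericVector silu_bw2(NumericVector x, NumericVector sig, NumericVector g) {
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i)
    gx[i] = g[i] * sig[i] * (1.0 + x[i] * (1.0 - sig[i]));
  return gx;
}

#ifdef __GLIBC__
#include <malloc.h>
#endif
// Raise the malloc mmap threshold so large, frequently recycled tensor
// buffers are served from the heap instead of fresh zeroed mmaps.
// [[Rcpp::export(name = ".tune_malloc")]]
void tune_malloc() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TOP_PAD, 64 * 1024 * 1024);
#endif
}

// Forward that also returns the im2col buffer for reuse by the adjoint
// (k > 1 convolutions only; pointwise convs never build one).
// [[Rcpp::export(name = ".conv2d_fw_cache")]]
List conv2d_fw_cache(NumericVector x, NumericVector w, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], O = wd[3];
  if (wd[2] != C) stop("conv2d: channel mismatch (%d vs %d)", wd[2], C);
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * O * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, O, N);
  arma::mat wmat(w.begin(), (size_t)k * k * C, O, false, true);
  size_t colsz = (size_t)Ho * Wo * k * k * C;
  NumericVector colbuf(colsz * N);
  for (int n = 0; n < N; ++n) {
    arma::mat col(colbuf.begin() + colsz * n, (size_t)Ho * Wo, (size_t)k * k * C,
                  false, true);
    im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo, col);
    arma::mat ymat(y.begin() + (size_t)Ho * Wo * O * n, (size_t)Ho * Wo, O, false, true);
    ymat = col * wmat;
  }
  return List::create(_["y"] = y, _["col"] = colbuf);
}

// [[Rcpp::export(name = ".conv2d_bw_cache")]]
List conv2d_bw_cache(NumericVector colbuf, NumericVector w, NumericVector gy,
                     IntegerVector xdim, int stride, int pad, bool need_gx) {
  IntegerVector wd = w.attr("dim");
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  int k = wd[0], O = wd[3];
  int Ho = out_size(H, k, stride, pad), Wo = out_size(W, k, stride, pad);
  arma::mat wmat(w.begin(), (size_t)k * k * C, O, false, true);
  NumericVector gw((size_t)k * k * C * O);
  gw.attr("dim") = wd;
  arma::mat gwmat(gw.begin(), (size_t)k * k * C, O, false, true);
  NumericVector gx;
  if (need_gx) { gx = NumericVector((size_t)H * W * C * N); gx.attr("dim") = xdim; }
  size_t colsz = (size_t)Ho * Wo * k * k * C;
  arma::mat gcol((size_t)Ho * Wo, (size_t)k * k * C);
  for (int n = 0; n < N; ++n) {
    arma::mat col(const_cast<double*>(colbuf.begin()) + colsz * n,
                  (size_t)Ho * Wo, (size_t)k * k * C, false, true);
    arma::mat gymat(const_cast<double*>(gy.begin()) + (size_t)Ho * Wo * O * n,
                    (size_t)Ho * Wo, O, false, true);
    gwmat += col.t() * gymat;
    if (need_gx) {
      gcol = gymat * wmat.t();
      col2im(gcol, H, W, C, k, stride, pad, Ho, Wo, gx.begin() + (size_t)H * W * C * n);
    }
  }
  return List::create(_["gw"] = gw, _["gx"] = gx);
}
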