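// Low-level tensor primitives backing the network: 2-D "same" convolution via
// im2col + GEMM, 2x2 max pooling, and nearest / bilinear 2x upsampling, each
// with its reverse-mode companion.  Feature maps are R arrays with dim
// (H, W, C, N) in column-major order; convolution weights have dim
// (kh, kw, inC, outC).  Kernels must have odd spatial extent (1x1 or 3x3 in
// practice); padding is implicit zero padding that preserves H and W.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline long idx4(int h, int w, int c, int n, int H, int W, int C) {
  return (long)h + (long)H * ((long)w + (long)W * ((long)c + (long)C * n));
}

// Patch matrix in "transposed" layout: dim (H*W*N) x (kh*kw*C), pixel index
// p = h + H*(w + W*n) along rows. Column r = ky + kh*(kx + kw*ic) matches the
// column-major flattening of the (kh, kw, inC, outC) weight array, so
// conv(x) = col * Wmat. All inner loops run contiguously over h.
static void im2col(const double* x, int H, int W, int C, int N,
                   int kh, int kw, arma::mat& col) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const long P = (long)H * W * N;
  col.zeros(P, kh * kw * C);
  for (int ic = 0; ic < C; ++ic) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        double* cp = col.colptr(ky + kh * (kx + kw * ic));
        const int h0 = std::max(0, ph - ky), h1 = std::min(H, H + ph - ky);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int sw = w + kx - pw;
            if (sw < 0 || sw >= W) continue;
            const double* xp = x + idx4(0, sw, ic, n, H, W, C) + ky - ph;
            double* dst = cp + (long)H * (w + (long)W * n);
            for (int h = h0; h < h1; ++h) dst[h] = xp[h];
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int H, int W, int C, int N,
                   int kh, int kw, double* x) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int ic = 0; ic < C; ++ic) {
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const double* cp = col.colptr(ky + kh * (kx + kw * ic));
        const int h0 = std::max(0, ph - ky), h1 = std::min(H, H + ph - ky);
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            const int sw = w + kx - pw;
            if (sw < 0 || sw >= W) continue;
            double* xp = x + idx4(0, sw, ic, n, H, W, C) + ky - ph;
            const double* src = cp + (long)H * (w + (long)W * n);
            for (int h = h0; h < h1; ++h) xp[h] += src[h];
          }
        }
      }
    }
  }
}

static IntegerVector arr_dim(const NumericVector& x) {
  return as<IntegerVector>(x.attr("dim"));
}

// [[Rcpp::export(name = ".c_conv2d_fwd")]]
NumericVector c_conv2d_fwd(NumericVector x, NumericVector Wt, NumericVector b) {
  IntegerVector dx = arr_dim(x), dw = arr_dim(Wt);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], inC = dw[2], outC = dw[3];
  if (inC != C) stop("conv2d: input has %d channels, weights expect %d", C, inC);
  if (kh % 2 == 0 || kw % 2 == 0) stop("conv2d: kernel extent must be odd");
  arma::mat col;
  im2col(x.begin(), H, W, C, N, kh, kw, col);
  arma::mat Wm(Wt.begin(), kh * kw * inC, outC, false, true);
  arma::mat out = col * Wm;                   // (H*W*N) x outC
  NumericVector y(no_init((long)H * W * outC * N));
  y.attr("dim") = IntegerVector::create(H, W, outC, N);
  double* yp = y.begin();
  const double* bp = b.begin();
  const long HW = (long)H * W, P = HW * N;
  for (int oc = 0; oc < outC; ++oc) {
    const double* op = out.colptr(oc);
    const double bv = bp[oc];
    for (int n = 0; n < N; ++n) {
      const double* src = op + HW * n;
      double* dst = yp + HW * (oc + (long)outC * n);
      for (long i = 0; i < HW; ++i) dst[i] = src[i] + bv;
    }
  }
  (void)P;
  return y;
}

// [[Rcpp::export(name = ".c_conv2d_bwd")]]
List c_conv2d_bwd(NumericVector x, NumericVector Wt, NumericVector dout) {
  IntegerVector dx = arr_dim(x), dw = arr_dim(Wt);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int kh = dw[0], kw = dw[1], inC = dw[2], outC = dw[3];
  const int R = kh * kw * inC;
  const long HW = (long)H * W, P = HW * N;
  // repack dout (H,W,outC,N) into (H*W*N) x outC
  arma::mat dm(P, outC);
  const double* dp = dout.begin();
  for (int oc = 0; oc < outC; ++oc) {
    double* dst = dm.colptr(oc);
    for (int n = 0; n < N; ++n) {
      const double* src = dp + HW * (oc + (long)outC * n);
      std::copy(src, src + HW, dst + HW * n);
    }
  }
  arma::mat col;
  im2col(x.begin(), H, W, C, N, kh, kw, col);
  arma::mat Wm(Wt.begin(), R, outC, false, true);
  arma::mat dWm = col.t() * dm;               // R x outC
  arma::mat dcol = dm * Wm.t();               // (H*W*N) x R
  NumericVector dxv((long)H * W * C * N);
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  col2im(dcol, H, W, C, N, kh, kw, dxv.begin());
  NumericVector dWv(dWm.memptr(), dWm.memptr() + (long)R * outC);
  dWv.attr("dim") = IntegerVector::create(kh, kw, inC, outC);
  NumericVector dbv(outC);
  arma::rowvec dbsum = arma::sum(dm, 0);
  for (int oc = 0; oc < outC; ++oc) dbv[oc] = dbsum[oc];
  return List::create(_["dx"] = dxv, _["dW"] = dWv, _["db"] = dbv);
}

// [[Rcpp::export(name = ".c_maxpool2_fwd")]]
List c_maxpool2_fwd(NumericVector x) {
  IntegerVector dx = arr_dim(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y(no_init((long)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector am(no_init((long)Ho * Wo * C * N));
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = am.begin();
  long q = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++q) {
          long best = idx4(2 * ho, 2 * wo, c, n, H, W, C);
          double bv = xp[best];
          for (int dw2 = 0; dw2 < 2; ++dw2)
            for (int dh = 0; dh < 2; ++dh) {
              long i = idx4(2 * ho + dh, 2 * wo + dw2, c, n, H, W, C);
              if (xp[i] > bv) { bv = xp[i]; best = i; }
            }
          yp[q] = bv;
          ap[q] = (int)best;
        }
  return List::create(_["out"] = y, _["argmax"] = am);
}

// [[Rcpp::export(name = ".c_maxpool2_bwd")]]
NumericVector c_maxpool2_bwd(NumericVector dout, IntegerVector argmax,
                             IntegerVector in_dim) {
  long nIn = (long)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector dx(nIn);
  dx.attr("dim") = in_dim;
  const double* dp = dout.begin();
  const int* ap = argmax.begin();
  double* xp = dx.begin();
  const long n = dout.size();
  for (long i = 0; i < n; ++i) xp[ap[i]] += dp[i];
  return dx;
}

// [[Rcpp::export(name = ".c_upsample2_nearest_fwd")]]
NumericVector c_upsample2_nearest_fwd(NumericVector x) {
  IntegerVector dx = arr_dim(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(no_init((long)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          yp[idx4(h, w, c, n, Ho, Wo, C)] =
            xp[idx4(h / 2, w / 2, c, n, H, W, C)];
  return y;
}

// [[Rcpp::export(name = ".c_upsample2_nearest_bwd")]]
NumericVector c_upsample2_nearest_bwd(NumericVector dout) {
  IntegerVector dd = arr_dim(dout);
  const int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dp = dout.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          xp[idx4(h / 2, w / 2, c, n, H, W, C)] +=
            dp[idx4(h, w, c, n, Ho, Wo, C)];
  return dx;
}

// 2x bilinear interpolation, half-pixel centers (source = (i + 0.5)/2 - 0.5,
// clamped).  Separable weights precomputed per output index.
static void bilin_coef(int Ho, int H, std::vector<int>& i0,
                       std::vector<int>& i1, std::vector<double>& w1) {
  i0.resize(Ho); i1.resize(Ho); w1.resize(Ho);
  for (int i = 0; i < Ho; ++i) {
    double s = (i + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > H - 1) s = H - 1;
    int lo = (int)std::floor(s);
    int hi = std::min(lo + 1, H - 1);
    i0[i] = lo; i1[i] = hi; w1[i] = s - lo;
  }
}

// [[Rcpp::export(name = ".c_upsample2_bilinear_fwd")]]
NumericVector c_upsample2_bilinear_fwd(NumericVector x) {
  IntegerVector dx = arr_dim(x);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = 2 * H, Wo = 2 * W;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilin_coef(Ho, H, h0, h1, hw);
  bilin_coef(Wo, W, w0, w1v, ww);
  NumericVector y(no_init((long)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double a = hw[h], b = ww[w];
          yp[idx4(h, w, c, n, Ho, Wo, C)] =
            (1 - a) * (1 - b) * xp[idx4(h0[h], w0[w], c, n, H, W, C)] +
            a * (1 - b) * xp[idx4(h1[h], w0[w], c, n, H, W, C)] +
            (1 - a) * b * xp[idx4(h0[h], w1v[w], c, n, H, W, C)] +
            a * b * xp[idx4(h1[h], w1v[w], c, n, H, W, C)];
        }
  return y;
}

// [[Rcpp::export(name = ".c_upsample2_bilinear_bwd")]]
NumericVector c_upsample2_bilinear_bwd(NumericVector dout) {
  IntegerVector dd = arr_dim(dout);
  const int Ho = dd[0], Wo = dd[1], C = dd[2], N = dd[3];
  const int H = Ho / 2, W = Wo / 2;
  std::vector<int> h0, h1, w0, w1v;
  std::vector<double> hw, ww;
  bilin_coef(Ho, H, h0, h1, hw);
  bilin_coef(Wo, W, w0, w1v, ww);
  NumericVector dx((long)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* dp = dout.begin();
  double* xp = dx.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          const double g = dp[idx4(h, w, c, n, Ho, Wo, C)];
          const double a = hw[h], b = ww[w];
          xp[idx4(h0[h], w0[w], c, n, H, W, C)] += (1 - a) * (1 - b) * g;
          xp[idx4(h1[h], w0[w], c, n, H, W, C)] += a * (1 - b) * g;
          xp[idx4(h0[h], w1v[w], c, n, H, W, C)] += (1 - a) * b * g;
          xp[idx4(h1[h], w1v[w], c, n, H, W, C)] += a * b * g;
        }
  return dx;
}
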