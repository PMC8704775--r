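// Batched CNN primitives: im2col + GEMM convolution, its exact adjoint
// (stride-8 transposed convolution used by the inverse-DCT layer), 2x2 max
// pooling with argmax indices, index-preserving max un-pooling, nearest 2x
// upsampling and ReLU. Tensors cross the R boundary as double arrays laid
// out (H, W, C, N) column-major; arithmetic runs in single precision (the
// usual CNN training precision, and what makes CPU training tractable).
// The whole batch shares one GEMM per convolution, and scratch buffers
// persist across calls to avoid repeated large allocations.
#include <RcppArmadillo.h>
using namespace Rcpp;

static std::vector<float>& scratch(int which, size_t n) {
  static std::vector<float> bufs[6];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

extern "C" void sgemm_(const char* transa, const char* transb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* a, const int* lda, const float* b,
                       const int* ldb, const float* beta, float* c,
                       const int* ldc);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

static void d2f(const double* src, float* dst, size_t n) {
  for (size_t i = 0; i < n; ++i) dst[i] = static_cast<float>(src[i]);
}

static NumericVector f2r(const float* p, R_xlen_t n, const IntegerVector& dim) {
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = static_cast<double>(p[i]);
  out.attr("dim") = dim;
  return out;
}

static IntegerVector dims_of(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d (H, W, C, N) array");
  return d;
}

// Fill rows [off, off+P) of the (rows x K*K*C) column-major col matrix for
// one sample; P = Ho*Wo with p = ho + Ho*wo, column r = ki + K*(kj + K*c).
static void im2col(const float* x, int H, int W, int C, int K, int s, int pad,
                   int Ho, int Wo, float* col, size_t rows, size_t off) {
  const size_t P = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const float* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        float* cp = col + rows * (ki + K * (kj + K * c)) + off;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s + kj - pad;
          const bool win = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s + ki - pad;
            cp[ho + Ho * wo] = (win && hi >= 0 && hi < H) ? xc[hi + H * wi] : 0.0f;
          }
        }
      }
    }
  }
  (void)P;
}

// Scatter-add the adjoint of im2col for one sample.
static void col2im(const float* col, size_t rows, size_t off, int H, int W,
                   int C, int K, int s, int pad, int Ho, int Wo, float* x) {
  for (int c = 0; c < C; ++c) {
    float* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < K; ++kj) {
      for (int ki = 0; ki < K; ++ki) {
        const float* cp = col + rows * (ki + K * (kj + K * c)) + off;
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * s + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * s + ki - pad;
            if (hi >= 0 && hi < H) xc[hi + H * wi] += cp[ho + Ho * wo];
          }
        }
      }
    }
  }
}

static arma::fmat load_weights(const NumericMatrix& Wm) {
  arma::fmat Wf(Wm.nrow(), Wm.ncol());
  d2f(Wm.begin(), Wf.memptr(), (size_t)Wm.nrow() * Wm.ncol());
  return Wf;
}

// x: (H,W,C,N); Wm: (K*K*C, outC) with row index ki + K*(kj + K*c); b: outC or 0.
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
                           int K, int s, int pad) {
  IntegerVector d = dims_of(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if ((int)Wm.nrow() != K * K * C) stop("weight rows do not match K*K*C");
  const int outC = Wm.ncol();
  const int Ho = (H + 2 * pad - K) / s + 1, Wo = (W + 2 * pad - K) / s + 1;
  if (Ho < 1 || Wo < 1 || (H + 2 * pad - K) % s != 0 || (W + 2 * pad - K) % s != 0)
    stop("incompatible input size for kernel/stride/padding");
  arma::fmat Wf = load_weights(Wm);
  const size_t P = (size_t)Ho * Wo, rows = P * N, sz = (size_t)H * W * C;
  float* xf = scratch(0, sz * N).data();
  d2f(x.begin(), xf, sz * N);
  float* colbuf = scratch(1, rows * (size_t)K * K * C).data();
  for (int n = 0; n < N; ++n)
    im2col(xf + sz * n, H, W, C, K, s, pad, Ho, Wo, colbuf, rows, P * n);
  // one GEMM per sample keeps the working set cache-friendly for large P;
  // small P (coarse feature maps) runs as one GEMM over the whole batch
  float* obuf = scratch(4, rows * (size_t)outC).data();
  if (P >= 4096 && N > 1) {
    for (int n = 0; n < N; ++n)
      sgemm('N', 'N', (int)P, outC, K * K * C, 1.0f, colbuf + P * n, (int)rows,
            Wf.memptr(), K * K * C, 0.0f, obuf + P * n, (int)rows);
  } else {
    sgemm('N', 'N', (int)rows, outC, K * K * C, 1.0f, colbuf, (int)rows,
          Wf.memptr(), K * K * C, 0.0f, obuf, (int)rows);
  }
  NumericVector out((R_xlen_t)P * outC * N);
  double* op = out.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < outC; ++o) {
      const float* src = obuf + rows * o + P * n;
      const double bo = (b.size() == outC) ? b[o] : 0.0;
      double* dst = op + P * (o + (size_t)outC * n);
      for (size_t p = 0; p < P; ++p) dst[p] = src[p] + bo;
    }
  out.attr("dim") = IntegerVector::create(Ho, Wo, outC, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector dout, NumericMatrix Wm,
                  bool has_bias, int K, int s, int pad, bool want_dx) {
  IntegerVector d = dims_of(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dd = dims_of(dout);
  const int Ho = dd[0], Wo = dd[1], outC = dd[2];
  if (dd[3] != N) stop("batch mismatch");
  arma::fmat Wf = load_weights(Wm);
  const size_t P = (size_t)Ho * Wo, rows = P * N, sz = (size_t)H * W * C;
  float* xf = scratch(0, sz * N).data();
  d2f(x.begin(), xf, sz * N);
  float* colbuf = scratch(1, rows * (size_t)K * K * C).data();
  for (int n = 0; n < N; ++n)
    im2col(xf + sz * n, H, W, C, K, s, pad, Ho, Wo, colbuf, rows, P * n);
  // rearrange dout (Ho,Wo,outC,N) -> (N*P x outC)
  float* dobuf = scratch(2, rows * (size_t)outC).data();
  const double* dp = dout.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < outC; ++o) {
      const double* src = dp + P * (o + (size_t)outC * n);
      float* dst = dobuf + rows * o + P * n;
      for (size_t p = 0; p < P; ++p) dst[p] = (float)src[p];
    }
  const int kkc = K * K * C;
  float* dwbuf = scratch(4, (size_t)kkc * outC).data();
  const bool chunked = (P >= 4096 && N > 1);
  if (chunked) {
    for (int n = 0; n < N; ++n)
      sgemm('T', 'N', kkc, outC, (int)P, 1.0f, colbuf + P * n, (int)rows,
            dobuf + P * n, (int)rows, n == 0 ? 0.0f : 1.0f, dwbuf, kkc);
  } else {
    sgemm('T', 'N', kkc, outC, (int)rows, 1.0f, colbuf, (int)rows,
          dobuf, (int)rows, 0.0f, dwbuf, kkc);
  }
  NumericMatrix dWr(kkc, outC);
  for (size_t i = 0; i < (size_t)kkc * outC; ++i) dWr[i] = dwbuf[i];
  NumericVector dbr(has_bias ? outC : 0);
  if (has_bias) {
    for (int o = 0; o < outC; ++o) {
      double acc = 0;
      const float* src = dobuf + rows * o;
      for (size_t p = 0; p < rows; ++p) acc += src[p];
      dbr[o] = acc;
    }
  }
  NumericVector dxr;
  if (want_dx) {
    float* dcolbuf = scratch(5, rows * (size_t)kkc).data();
    if (chunked) {
      for (int n = 0; n < N; ++n)
        sgemm('N', 'T', (int)P, kkc, outC, 1.0f, dobuf + P * n, (int)rows,
              Wf.memptr(), kkc, 0.0f, dcolbuf + P * n, (int)rows);
    } else {
      sgemm('N', 'T', (int)rows, kkc, outC, 1.0f, dobuf, (int)rows,
            Wf.memptr(), kkc, 0.0f, dcolbuf, (int)rows);
    }
    float* dxf = scratch(3, sz * N).data();
    std::fill(dxf, dxf + sz * N, 0.0f);
    for (int n = 0; n < N; ++n)
      col2im(dcolbuf, rows, P * n, H, W, C, K, s, pad, Ho, Wo, dxf + sz * n);
    dxr = f2r(dxf, (R_xlen_t)sz * N, d);
  }
  return List::create(_["dx"] = dxr, _["dW"] = dWr, _["db"] = dbr);
}

// Transposed convolution, exact adjoint of cpp_conv_fwd with the same
// weight matrix: input (Ho,Wo,outC,N) -> output (H,W,C,N). Used with
// K = s = 8 by the inverse-DCT layer (non-overlapping blocks).
// [[Rcpp::export]]
NumericVector cpp_tconv_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
                            int K, int s, int pad, int H, int W) {
  IntegerVector d = dims_of(x);
  const int Ho = d[0], Wo = d[1], outC = d[2], N = d[3];
  if ((int)Wm.ncol() != outC) stop("weight cols do not match input channels");
  const int C = Wm.nrow() / (K * K);
  arma::fmat Wf = load_weights(Wm);
  const size_t P = (size_t)Ho * Wo, rows = P * N, sz = (size_t)H * W * C;
  // rearrange x to (N*P x outC)
  float* xbuf = scratch(2, rows * (size_t)outC).data();
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < outC; ++o) {
      const double* src = xp + P * (o + (size_t)outC * n);
      float* dst = xbuf + rows * o + P * n;
      for (size_t p = 0; p < P; ++p) dst[p] = (float)src[p];
    }
  arma::fmat X(xbuf, rows, outC, false, true);
  arma::fmat Xcol = X * Wf.t();  // (N*P x KKC)
  float* of = scratch(3, sz * N).data();
  std::fill(of, of + sz * N, 0.0f);
  for (int n = 0; n < N; ++n)
    col2im(Xcol.memptr(), rows, P * n, H, W, C, K, s, pad, Ho, Wo, of + sz * n);
  NumericVector out((R_xlen_t)sz * N);
  for (size_t i = 0; i < sz * (size_t)N; ++i) out[i] = of[i];
  if (b.size() == C) {
    double* op = out.begin();
    for (int n = 0; n < N; ++n)
      for (int c = 0; c < C; ++c) {
        double* dst = op + sz * n + (size_t)H * W * c;
        for (size_t i = 0; i < (size_t)H * W; ++i) dst[i] += b[c];
      }
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// [[Rcpp::export]]
List cpp_tconv_bwd(NumericVector x, NumericVector dout, NumericMatrix Wm,
                   bool has_bias, int K, int s, int pad, bool want_dx) {
  IntegerVector d = dims_of(x);       // (Ho,Wo,outC,N)
  IntegerVector dd = dims_of(dout);   // (H,W,C,N)
  const int Ho = d[0], Wo = d[1], outC = d[2], N = d[3];
  const int H = dd[0], W = dd[1], C = dd[2];
  arma::fmat Wf = load_weights(Wm);
  const size_t P = (size_t)Ho * Wo, rows = P * N, sz = (size_t)H * W * C;
  float* df = scratch(0, sz * N).data();
  d2f(dout.begin(), df, sz * N);
  float* colbuf = scratch(1, rows * (size_t)K * K * C).data();
  for (int n = 0; n < N; ++n)
    im2col(df + sz * n, H, W, C, K, s, pad, Ho, Wo, colbuf, rows, P * n);
  arma::fmat dcol(colbuf, rows, K * K * C, false, true);
  // x rearranged to (N*P x outC)
  float* xbuf = scratch(2, rows * (size_t)outC).data();
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < outC; ++o) {
      const double* src = xp + P * (o + (size_t)outC * n);
      float* dst = xbuf + rows * o + P * n;
      for (size_t p = 0; p < P; ++p) dst[p] = (float)src[p];
    }
  arma::fmat X(xbuf, rows, outC, false, true);
  arma::fmat dW = dcol.t() * X;       // (KKC x outC)
  NumericMatrix dWr(K * K * C, outC);
  for (size_t i = 0; i < (size_t)dWr.nrow() * outC; ++i) dWr[i] = dW.memptr()[i];
  NumericVector dbr(has_bias ? C : 0);
  if (has_bias) {
    const double* op = dout.begin();
    for (int c = 0; c < C; ++c) {
      double acc = 0;
      for (int n = 0; n < N; ++n) {
        const double* src = op + sz * n + (size_t)H * W * c;
        for (size_t i = 0; i < (size_t)H * W; ++i) acc += src[i];
      }
      dbr[c] = acc;
    }
  }
  NumericVector dxr;
  if (want_dx) {
    arma::fmat dX = dcol * Wf;        // (N*P x outC)
    NumericVector dx((R_xlen_t)P * outC * N);
    double* dst0 = dx.begin();
    for (int n = 0; n < N; ++n)
      for (int o = 0; o < outC; ++o) {
        const float* src = dX.colptr(o) + P * n;
        double* dst = dst0 + P * (o + (size_t)outC * n);
        for (size_t p = 0; p < P; ++p) dst[p] = src[p];
      }
    dx.attr("dim") = d;
    dxr = dx;
  }
  return List::create(_["dx"] = dxr, _["dW"] = dWr, _["db"] = dbr);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector out(x.size());
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) op[i] = xp[i] > 0 ? xp[i] : 0.0;
  out.attr("dim") = x.attr("dim");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector g, NumericVector out) {
  NumericVector dx(g.size());
  const double* gp = g.begin();
  const double* op = out.begin();
  double* dp = dx.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) dp[i] = op[i] > 0 ? gp[i] : 0.0;
  dx.attr("dim") = out.attr("dim");
  return dx;
}

// 2x2, stride-2 max pooling; idx holds 0-based linear offsets into the
// (H, W, C) sample slice of the winning input pixel.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x) {
  IntegerVector d = dims_of(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max pooling needs even side lengths");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  for (int n = 0; n < N; ++n) {
    const double* xs = xp + (size_t)H * W * C * n;
    double* os = out.begin() + (size_t)Ho * Wo * C * n;
    int* is = idx.begin() + (size_t)Ho * Wo * C * n;
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          int base = 2 * ho + H * (2 * wo + W * c);
          int cand[4] = {base, base + 1, base + H, base + H + 1};
          int best = cand[0];
          double bv = xs[cand[0]];
          for (int k = 1; k < 4; ++k)
            if (xs[cand[k]] > bv) { bv = xs[cand[k]]; best = cand[k]; }
          os[ho + Ho * (wo + Wo * c)] = bv;
          is[ho + Ho * (wo + Wo * c)] = best;
        }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector dout, IntegerVector idx, int H, int W) {
  IntegerVector d = dims_of(dout);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    const double* ds = dout.begin() + (size_t)Ho * Wo * C * n;
    const int* is = idx.begin() + (size_t)Ho * Wo * C * n;
    double* xs = dx.begin() + (size_t)H * W * C * n;
    for (size_t i = 0; i < (size_t)Ho * Wo * C; ++i) xs[is[i]] += ds[i];
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Max un-pooling: place each coarse value back at the index its pooling
// partner recorded; everything else zero.
// [[Rcpp::export]]
NumericVector cpp_maxunpool_fwd(NumericVector x, IntegerVector idx, int H, int W) {
  IntegerVector d = dims_of(x);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector out((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)Ho * Wo * C * n;
    const int* is = idx.begin() + (size_t)Ho * Wo * C * n;
    double* os = out.begin() + (size_t)H * W * C * n;
    for (size_t i = 0; i < (size_t)Ho * Wo * C; ++i) os[is[i]] = xs[i];
  }
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_maxunpool_bwd(NumericVector dout, IntegerVector idx,
                                int Ho, int Wo) {
  IntegerVector d = dims_of(dout);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector dx((R_xlen_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    const double* ds = dout.begin() + (size_t)H * W * C * n;
    const int* is = idx.begin() + (size_t)Ho * Wo * C * n;
    double* xs = dx.begin() + (size_t)Ho * Wo * C * n;
    for (size_t i = 0; i < (size_t)Ho * Wo * C; ++i) xs[i] = ds[is[i]];
  }
  dx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fwd(NumericVector x) {
  IntegerVector d = dims_of(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  NumericVector out((R_xlen_t)4 * H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* os = out.begin() + (size_t)4 * H * W * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double v = xs[h + H * w];
          os[2 * h + 2 * H * (2 * w)] = v;
          os[2 * h + 1 + 2 * H * (2 * w)] = v;
          os[2 * h + 2 * H * (2 * w + 1)] = v;
          os[2 * h + 1 + 2 * H * (2 * w + 1)] = v;
        }
    }
  out.attr("dim") = IntegerVector::create(2 * H, 2 * W, C, N);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bwd(NumericVector dout) {
  IntegerVector d = dims_of(dout);
  const int H2 = d[0], W2 = d[1], C = d[2], N = d[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* os = dout.begin() + (size_t)H2 * W2 * (c + (size_t)C * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          xs[h + H * w] = os[2 * h + H2 * (2 * w)] + os[2 * h + 1 + H2 * (2 * w)] +
                          os[2 * h + H2 * (2 * w + 1)] + os[2 * h + 1 + H2 * (2 * w + 1)];
    }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}
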