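// Fused forward/backward for the image-domain refining chain: lift
// convolution + ReLU, `nb` residual blocks (conv-ReLU-conv with identity
// skip), and the 1-channel output projection.
//
// Convolutions (K = 3, stride 1, pad 1) are computed without an im2col
// matrix: each of the 9 kernel taps contributes one accumulated GEMM on a
// row-shifted view of the activation buffer. Activations live in a
// "guarded" layout -- each (channel, sample) column is the H*W pixel
// vector with G = H + 2 zero rows above and below -- so row shifts that
// fall off the image read zeros. The only wrong reads are shifts that
// wrap across image columns into interior pixels; those few boundary rows
// are corrected explicitly after the GEMMs. This keeps the working set
// per sample at a couple of MB instead of streaming a 9x-expanded column
// matrix through memory, which is what dominates im2col convolution here.
// Everything stays in single precision between the R boundaries.
#include <RcppArmadillo.h>
using namespace Rcpp;

extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

namespace {

struct Geom {
  int H, W, P, G, ldx;              // ldx = P + 2G, G = H + 2
  std::vector<int> boundary;        // output rows on the image border
  void set(int h, int w) {
    H = h; W = w; P = h * w; G = h + 2; ldx = P + 2 * G;
    boundary.clear();
    for (int p = 0; p < P; ++p) {
      int ho = p % H, wo = p / H;
      if (ho == 0 || ho == H - 1 || wo == 0 || wo == W - 1)
        boundary.push_back(p);
    }
  }
};

// guarded buffer: (ldx x C x N) floats, channel/sample column = ldx rows
struct GBuf {
  std::vector<float> v;
  void alloc(const Geom& g, int C, int N) {
    v.assign((size_t)g.ldx * C * N, 0.0f);
  }
  float* col(const Geom& g, int C, int n, int c) {
    return v.data() + (size_t)g.ldx * (c + (size_t)C * n);
  }
  float* base(const Geom& g, int C, int n) {
    return v.data() + (size_t)g.ldx * C * n;
  }
};

struct RefineCache {
  Geom g;
  int Cin = 0, N = 0, nb = 0, ch = 0;
  GBuf x;
  std::vector<GBuf> a, h1;
  GBuf da, dh1, da_new, dx;
};

RefineCache cache;

inline int shift_delta(const Geom& g, int k) {
  return (k % 3 - 1) + g.H * (k / 3 - 1);
}

inline bool tap_valid(const Geom& g, int p, int k) {
  const int di = k % 3 - 1, dj = k / 3 - 1;
  const int ho = p % g.H + di, wo = p / g.H + dj;
  return ho >= 0 && ho < g.H && wo >= 0 && wo < g.W;
}

// Pack the (9C x O) weight matrix (row index ki + 3 kj + 9 c) into 9
// contiguous (C x O) tap matrices in float.
static std::vector<std::vector<float>> pack_taps(const NumericMatrix& Wm, int C) {
  const int O = Wm.ncol();
  std::vector<std::vector<float>> taps(9, std::vector<float>((size_t)C * O));
  for (int k = 0; k < 9; ++k)
    for (int o = 0; o < O; ++o)
      for (int c = 0; c < C; ++c)
        taps[k][c + (size_t)C * o] = (float)Wm[(k + 9 * c) + (size_t)9 * C * o];
  return taps;
}

// out[interior] = conv(x) + bias, optionally ReLU'd; guards stay zero.
static void conv_fwd(const Geom& g, GBuf& X, int C, GBuf& Out, int O, int N,
                     const std::vector<std::vector<float>>& taps,
                     const double* bias, bool relu) {
  for (int n = 0; n < N; ++n) {
    float* xb = X.base(g, C, n);
    float* ob = Out.base(g, O, n);
    for (int k = 0; k < 9; ++k) {
      const int d = shift_delta(g, k);
      sgemm('N', 'N', g.P, O, C, 1.0f, xb + g.G + d, g.ldx,
            taps[k].data(), C, k == 0 ? 0.0f : 1.0f, ob + g.G, g.ldx);
    }
    // boundary corrections: taps that wrapped into interior pixels
    for (int p : g.boundary)
      for (int k = 0; k < 9; ++k) {
        const int d = shift_delta(g, k);
        const int src = p + d;
        if (tap_valid(g, p, k) || src < 0 || src >= g.P) continue;
        const float* tk = taps[k].data();
        for (int o = 0; o < O; ++o) {
          float acc = 0.0f;
          for (int c = 0; c < C; ++c)
            acc += xb[(size_t)g.ldx * c + g.G + src] * tk[c + (size_t)C * o];
          ob[(size_t)g.ldx * o + g.G + p] -= acc;
        }
      }
    for (int o = 0; o < O; ++o) {
      float* oc = ob + (size_t)g.ldx * o + g.G;
      const float bo = bias ? (float)bias[o] : 0.0f;
      if (relu) {
        for (int p = 0; p < g.P; ++p) {
          const float v = oc[p] + bo;
          oc[p] = v > 0 ? v : 0.0f;
        }
      } else {
        for (int p = 0; p < g.P; ++p) oc[p] += bo;
      }
    }
  }
}

// Accumulates dW (float taps) and db over the batch; optionally
// accumulates the input gradient into the pre-zeroed guarded dX.
static void conv_bwd(const Geom& g, GBuf& X, int C, GBuf& dOut, int O, int N,
                     const std::vector<std::vector<float>>& taps,
                     std::vector<std::vector<float>>& dtaps, double* db,
                     GBuf* dX) {
  for (int n = 0; n < N; ++n) {
    float* xb = X.base(g, C, n);
    float* gb = dOut.base(g, O, n);
    for (int k = 0; k < 9; ++k) {
      const int d = shift_delta(g, k);
      sgemm('T', 'N', C, O, g.P, 1.0f, xb + g.G + d, g.ldx,
            gb + g.G, g.ldx, 1.0f, dtaps[k].data(), C);
    }
    for (int p : g.boundary)
      for (int k = 0; k < 9; ++k) {
        const int d = shift_delta(g, k);
        const int src = p + d;
        if (tap_valid(g, p, k) || src < 0 || src >= g.P) continue;
        float* dt = dtaps[k].data();
        for (int o = 0; o < O; ++o) {
          const float go = gb[(size_t)g.ldx * o + g.G + p];
          if (go == 0.0f) continue;
          for (int c = 0; c < C; ++c)
            dt[c + (size_t)C * o] -= xb[(size_t)g.ldx * c + g.G + src] * go;
        }
      }
    if (db) {
      for (int o = 0; o < O; ++o) {
        double acc = 0;
        const float* oc = gb + (size_t)g.ldx * o + g.G;
        for (int p = 0; p < g.P; ++p) acc += oc[p];
        db[o] += acc;
      }
    }
    if (dX) {
      float* dxb = dX->base(g, C, n);
      for (int k = 0; k < 9; ++k) {
        const int d = shift_delta(g, k);
        sgemm('N', 'T', g.P, C, O, 1.0f, gb + g.G - d, g.ldx,
              taps[k].data(), C, 1.0f, dxb + g.G, g.ldx);
      }
      // wrong reads: output row (q - delta) wrapped into the interior
      for (int q : g.boundary)
        for (int k = 0; k < 9; ++k) {
          const int d = shift_delta(g, k);
          const int p = q - d;   // output row whose tap would touch q
          if (p < 0 || p >= g.P) continue;
          if (tap_valid(g, p, k)) continue;
          const float* tk = taps[k].data();
          for (int c = 0; c < C; ++c) {
            float acc = 0.0f;
            for (int o = 0; o < O; ++o)
              acc += gb[(size_t)g.ldx * o + g.G + p] * tk[c + (size_t)C * o];
            dxb[(size_t)g.ldx * c + g.G + q] -= acc;
          }
        }
    }
  }
}

// copy sample-major (H,W,C,N) doubles into a guarded buffer
static void guard_in(const Geom& g, const double* src, GBuf& dst, int C, int N) {
  dst.alloc(g, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* s = src + (size_t)g.P * (c + (size_t)C * n);
      float* d = dst.col(g, C, n, c) + g.G;
      for (int p = 0; p < g.P; ++p) d[p] = (float)s[p];
    }
}

static NumericMatrix taps_to_matrix(const std::vector<std::vector<float>>& taps,
                                    int C, int O) {
  NumericMatrix out(9 * C, O);
  for (int k = 0; k < 9; ++k)
    for (int o = 0; o < O; ++o)
      for (int c = 0; c < C; ++c)
        out[(k + 9 * c) + (size_t)9 * C * o] = taps[k][c + (size_t)C * o];
  return out;
}

}  // namespace

// x: (H, W, Cin, N); Ws / bs: lift, then 2 per residual block, then the
// output projection. Returns the (H, W, 1, N) projection output (the
// global skip is added by the caller) and keeps every activation cached
// for the matching cpp_refine_bwd call.
// [[Rcpp::export]]
NumericVector cpp_refine_fwd(NumericVector x, List Ws, List bs, int nblocks) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d input");
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  if ((int)Ws.size() != 2 + 2 * nblocks) stop("weight list length mismatch");
  RefineCache& c = cache;
  c.g.set(H, W);
  const Geom& g = c.g;
  NumericMatrix W0 = Ws[0];
  const int ch = W0.ncol();
  c.Cin = Cin; c.N = N; c.nb = nblocks; c.ch = ch;

  guard_in(g, REAL(x), c.x, Cin, N);
  c.a.assign(nblocks + 1, GBuf());
  c.h1.assign(nblocks, GBuf());

  c.a[0].alloc(g, ch, N);
  conv_fwd(g, c.x, Cin, c.a[0], ch, N, pack_taps(W0, Cin),
           REAL((SEXP)bs[0]), true);

  for (int k = 0; k < nblocks; ++k) {
    c.h1[k].alloc(g, ch, N);
    conv_fwd(g, c.a[k], ch, c.h1[k], ch, N,
             pack_taps(Ws[1 + 2 * k], ch), REAL((SEXP)bs[1 + 2 * k]), true);
    c.a[k + 1].alloc(g, ch, N);
    conv_fwd(g, c.h1[k], ch, c.a[k + 1], ch, N,
             pack_taps(Ws[2 + 2 * k], ch), REAL((SEXP)bs[2 + 2 * k]), false);
    float* an = c.a[k + 1].v.data();
    const float* ak = c.a[k].v.data();
    for (size_t i = 0; i < c.a[k + 1].v.size(); ++i) an[i] += ak[i];
  }
  GBuf y;
  y.alloc(g, 1, N);
  conv_fwd(g, c.a[nblocks], ch, y, 1, N,
           pack_taps(Ws[1 + 2 * nblocks], ch), REAL((SEXP)bs[1 + 2 * nblocks]),
           false);
  NumericVector out((R_xlen_t)g.P * N);
  for (int n = 0; n < N; ++n) {
    const float* src = y.col(g, 1, n, 0) + g.G;
    double* dst = REAL(out) + (size_t)g.P * n;
    for (int p = 0; p < g.P; ++p) dst[p] = src[p];
  }
  out.attr("dim") = IntegerVector::create(H, W, 1, N);
  return out;
}

// dout: (H, W, 1, N) gradient of the projection output. Returns dWs, dbs
// (aligned with Ws/bs) and, when want_dx, dx for the (H, W, Cin, N)
// input. Must follow the matching cpp_refine_fwd call.
// [[Rcpp::export]]
List cpp_refine_bwd(NumericVector dout, List Ws, bool want_dx) {
  RefineCache& c = cache;
  const Geom& g = c.g;
  const int Cin = c.Cin, N = c.N, nb = c.nb, ch = c.ch;
  if (c.a.empty()) stop("cpp_refine_bwd called without a cached forward pass");
  List dWs(Ws.size()), dbs(Ws.size());

  GBuf gy;
  guard_in(g, REAL(dout), gy, 1, N);

  // projection -> da_{nb}
  c.da.alloc(g, ch, N);
  {
    auto taps = pack_taps(Ws[1 + 2 * nb], ch);
    std::vector<std::vector<float>> dt(9, std::vector<float>((size_t)ch * 1));
    NumericVector db(1);
    conv_bwd(g, c.a[nb], ch, gy, 1, N, taps, dt, REAL(db), &c.da);
    dWs[1 + 2 * nb] = taps_to_matrix(dt, ch, 1);
    dbs[1 + 2 * nb] = db;
  }
  // residual blocks, last to first; c.da holds da_{k+1}
  for (int k = nb - 1; k >= 0; --k) {
    // through the second conv: dh1 = relu-masked conv_bwd_input(da)
    auto taps_b = pack_taps(Ws[2 + 2 * k], ch);
    std::vector<std::vector<float>> dtb(9, std::vector<float>((size_t)ch * ch));
    NumericVector dbb(ch);
    c.dh1.alloc(g, ch, N);
    conv_bwd(g, c.h1[k], ch, c.da, ch, N, taps_b, dtb, REAL(dbb), &c.dh1);
    {
      const float* h1v = c.h1[k].v.data();
      float* dv = c.dh1.v.data();
      for (size_t i = 0; i < c.dh1.v.size(); ++i)
        if (h1v[i] <= 0) dv[i] = 0.0f;
    }
    // da_k = da_{k+1} (identity skip) + conv_bwd_input(dh1)
    auto taps_a = pack_taps(Ws[1 + 2 * k], ch);
    std::vector<std::vector<float>> dta(9, std::vector<float>((size_t)ch * ch));
    NumericVector dba(ch);
    c.da_new.v = c.da.v;  // identity-skip gradient
    conv_bwd(g, c.a[k], ch, c.dh1, ch, N, taps_a, dta, REAL(dba), &c.da_new);
    c.da.v.swap(c.da_new.v);
    dWs[2 + 2 * k] = taps_to_matrix(dtb, ch, ch); dbs[2 + 2 * k] = dbb;
    dWs[1 + 2 * k] = taps_to_matrix(dta, ch, ch); dbs[1 + 2 * k] = dba;
  }
  // lift layer: ReLU mask from the stored post-ReLU activation a_0
  {
    const float* a0 = c.a[0].v.data();
    float* dv = c.da.v.data();
    for (size_t i = 0; i < c.da.v.size(); ++i)
      if (a0[i] <= 0) dv[i] = 0.0f;
    auto taps0 = pack_taps(Ws[0], Cin);
    std::vector<std::vector<float>> dt0(9, std::vector<float>((size_t)Cin * ch));
    NumericVector db0(ch);
    NumericVector dxr;
    if (want_dx) {
      c.dx.alloc(g, Cin, N);
      conv_bwd(g, c.x, Cin, c.da, ch, N, taps0, dt0, REAL(db0), &c.dx);
      dxr = NumericVector((R_xlen_t)g.P * Cin * N);
      for (int n = 0; n < N; ++n)
        for (int ci = 0; ci < Cin; ++ci) {
          const float* src = c.dx.col(g, Cin, n, ci) + g.G;
          double* dst = REAL(dxr) + (size_t)g.P * (ci + (size_t)Cin * n);
          for (int p = 0; p < g.P; ++p) dst[p] = src[p];
        }
      dxr.attr("dim") = IntegerVector::create(g.H, g.W, Cin, N);
    } else {
      conv_bwd(g, c.x, Cin, c.da, ch, N, taps0, dt0, REAL(db0), nullptr);
    }
    dWs[0] = taps_to_matrix(dt0, Cin, ch);
    dbs[0] = db0;
    return List::create(_["dWs"] = dWs, _["dbs"] = dbs, _["dx"] = dxr);
  }
}
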