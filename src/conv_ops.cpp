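// Fused convolution forward/backward for the compact CNN engine.
//
// Layout contracts (column-major, as R stores them):
//   2D tensors: [H, W, N, C]   (batch third, channels last)
//   3D tensors: [D1, D2, D3, C] (batch 1)
// The im2col matrix has rows ordered like the spatial x batch grid of the
// output and columns ordered offset-major / channel-minor: col = o*C + c.
// Weights are (k^rank * Cin) x Cout; the GEMM output lands directly in the
// tensor layout, so no transposition happens anywhere.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;




static void gather2d_f(const double* px, float* pc, int H, int W, int C, int N,
                       int k, int stride, int pad, int Ho, int Wo) {
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  const R_xlen_t plane = (R_xlen_t)H * W * N;  // one channel slab
  for (int c = 0; c < C; ++c) {
    const double* xc = px + (R_xlen_t)c * plane;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int o = dj * k + di;
        float* dst = pc + ((R_xlen_t)(o * C + c)) * nrow;
        for (int n = 0; n < N; ++n) {
          const double* xn = xc + (R_xlen_t)n * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int sj = wo * stride + dj - pad;
            float* drow = dst + ((R_xlen_t)n * Wo + wo) * Ho;
            if (sj < 0 || sj >= W) {
              std::fill(drow, drow + Ho, 0.0f);
              continue;
            }
            const double* scol = xn + (R_xlen_t)sj * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int si = ho * stride + di - pad;
              drow[ho] = (si >= 0 && si < H) ? (float)scol[si] : 0.0f;
            }
          }
        }
      }
    }
  }
}

static void scatter2d_f(const float* pc, double* px, int H, int W, int C, int N,
                        int k, int stride, int pad, int Ho, int Wo) {
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  const R_xlen_t plane = (R_xlen_t)H * W * N;
  for (int c = 0; c < C; ++c) {
    double* xc = px + (R_xlen_t)c * plane;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int o = dj * k + di;
        const float* src = pc + ((R_xlen_t)(o * C + c)) * nrow;
        for (int n = 0; n < N; ++n) {
          double* xn = xc + (R_xlen_t)n * H * W;
          for (int wo = 0; wo < Wo; ++wo) {
            const int sj = wo * stride + dj - pad;
            if (sj < 0 || sj >= W) continue;
            const float* srow = src + ((R_xlen_t)n * Wo + wo) * Ho;
            double* dcolm = xn + (R_xlen_t)sj * H;
            for (int ho = 0; ho < Ho; ++ho) {
              const int si = ho * stride + di - pad;
              if (si >= 0 && si < H) dcolm[si] += (double)srow[ho];
            }
          }
        }
      }
    }
  }
}

extern "C" void F77_NAME(sgemm)(const char* transa, const char* transb,
                                const int* m, const int* n, const int* k,
                                const float* alpha, const float* a,
                                const int* lda, const float* b, const int* ldb,
                                const float* beta, float* c, const int* ldc
                                FCLEN FCLEN);

static void sgemm_call(const char* ta, const char* tb, int m, int n, int kk,
                       const float* A, int lda, const float* B, int ldb,
                       float* C, int ldc) {
  const float one = 1.0f, zero = 0.0f;
  F77_CALL(sgemm)(ta, tb, &m, &n, &kk, &one, A, &lda, B, &ldb, &zero, C, &ldc
                  FCONE FCONE);
}

static void gather3d(const double* px, double* pc, int D1, int D2, int D3,
                     int C, int k, int stride, int pad, int O1, int O2, int O3) {
  const R_xlen_t nrow = (R_xlen_t)O1 * O2 * O3;
  for (int c = 0; c < C; ++c) {
    const double* src = px + (R_xlen_t)c * D1 * D2 * D3;
    for (int dk = 0; dk < k; ++dk)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          const int o = (dk * k + dj) * k + di;
          double* dst = pc + ((R_xlen_t)(o * C + c)) * nrow;
          for (int o3 = 0; o3 < O3; ++o3) {
            const int s3 = o3 * stride + dk - pad;
            for (int o2 = 0; o2 < O2; ++o2) {
              const int s2 = o2 * stride + dj - pad;
              double* drow = dst + ((R_xlen_t)o3 * O2 + o2) * O1;
              if (s2 < 0 || s2 >= D2 || s3 < 0 || s3 >= D3) {
                std::fill(drow, drow + O1, 0.0);
                continue;
              }
              const double* scol = src + ((R_xlen_t)s3 * D2 + s2) * D1;
              for (int o1 = 0; o1 < O1; ++o1) {
                const int s1 = o1 * stride + di - pad;
                drow[o1] = (s1 >= 0 && s1 < D1) ? scol[s1] : 0.0;
              }
            }
          }
        }
  }
}

static void scatter3d(const double* pc, double* px, int D1, int D2, int D3,
                      int C, int k, int stride, int pad, int O1, int O2, int O3) {
  const R_xlen_t nrow = (R_xlen_t)O1 * O2 * O3;
  for (int c = 0; c < C; ++c) {
    double* dst = px + (R_xlen_t)c * D1 * D2 * D3;
    for (int dk = 0; dk < k; ++dk)
      for (int dj = 0; dj < k; ++dj)
        for (int di = 0; di < k; ++di) {
          const int o = (dk * k + dj) * k + di;
          const double* src = pc + ((R_xlen_t)(o * C + c)) * nrow;
          for (int o3 = 0; o3 < O3; ++o3) {
            const int s3 = o3 * stride + dk - pad;
            if (s3 < 0 || s3 >= D3) continue;
            for (int o2 = 0; o2 < O2; ++o2) {
              const int s2 = o2 * stride + dj - pad;
              if (s2 < 0 || s2 >= D2) continue;
              const double* srow = src + ((R_xlen_t)o3 * O2 + o2) * O1;
              double* dcolm = dst + ((R_xlen_t)s3 * D2 + s2) * D1;
              for (int o1 = 0; o1 < O1; ++o1) {
                const int s1 = o1 * stride + di - pad;
                if (s1 >= 0 && s1 < D1) dcolm[s1] += srow[o1];
              }
            }
          }
        }
  }
}

static void dgemm_nn(int m, int n, int kk, const double* A, const double* B,
                     double* Cm) {
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &kk, &one, A, &m, B, &kk, &zero, Cm, &m
                  FCONE FCONE);
}

static void dgemm_tn(int m, int n, int kk, const double* A, const double* B,
                     double* Cm) {
  // C (m x n) = A^T (m x kk stored kk x m) %*% B (kk x n)
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &m, &n, &kk, &one, A, &kk, B, &kk, &zero, Cm, &m
                  FCONE FCONE);
}

static void dgemm_nt(int m, int n, int kk, const double* A, const double* B,
                     double* Cm) {
  // C (m x n) = A (m x kk) %*% B^T (kk x n stored n x kk)
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "T", &m, &n, &kk, &one, A, &m, B, &n, &zero, Cm, &m
                  FCONE FCONE);
}

// ---- 2D convolution ----
//
// Three cases:
//  * k == 1: plain GEMM on the channels-last matrix view.
//  * k == 3, stride 1, pad 1: shift-GEMM on a zero-padded float buffer.
//    The padded grid [Hp, Wp, N, C] makes every kernel offset a constant
//    linear shift s = (di-1) + Hp*(dj-1), so each offset contributes one
//    GEMM on a pointer-shifted view of the same buffer - no im2col matrix
//    is ever materialized. Slack rows at both ends absorb the shifts.
//  * anything else (strided 3x3): explicit float im2col.
// The float buffer kept for the backward pass is returned opaquely in `col`.

static const int PAD_SLACK_EXTRA = 4;

// copy [H, W, N, C] double tensor into padded float [Hp, Wp, N, C] buffer
// with `slack` float slots before and after each full tensor
static void pad_to_float(const double* px, float* xp, int H, int W, int N,
                         int C, int Hp, int Wp, R_xlen_t npr, int slack) {
  for (int c = 0; c < C; ++c) {
    float* xc = xp + slack + (R_xlen_t)c * npr;
    const double* sc = px + (R_xlen_t)c * H * W * N;
    for (int n = 0; n < N; ++n) {
      float* xn = xc + (R_xlen_t)n * Hp * Wp;
      const double* sn = sc + (R_xlen_t)n * H * W;
      for (int w = 0; w < W; ++w) {
        float* dcol = xn + (R_xlen_t)(w + 1) * Hp + 1;
        const double* scol = sn + (R_xlen_t)w * H;
        for (int h = 0; h < H; ++h) dcol[h] = (float)scol[h];
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv2d_fwd(NumericVector x, IntegerVector dims, NumericMatrix W,
                    NumericVector b, int k, int stride, int pad) {
  const int H = dims[0], Wd = dims[1], N = dims[2], C = dims[3];
  const int cout = W.ncol();
  std::vector<float> Wf(W.begin(), W.end());

  if (k == 1 && stride == 1) {
    const R_xlen_t m = (R_xlen_t)H * Wd * N;
    RawVector xraw(m * C * sizeof(float));
    float* xf = reinterpret_cast<float*>(RAW(xraw));
    const double* px = x.begin();
    for (R_xlen_t i = 0; i < m * C; ++i) xf[i] = (float)px[i];
    std::vector<float> outf((size_t)m * cout);
    sgemm_call("N", "N", (int)m, cout, C, xf, (int)m, Wf.data(), C,
               outf.data(), (int)m);
    NumericVector out(m * cout);
    double* po = out.begin();
    for (int c = 0; c < cout; ++c) {
      const double bc = b[c];
      const float* oc = outf.data() + (size_t)c * m;
      double* dc = po + (R_xlen_t)c * m;
      for (R_xlen_t i = 0; i < m; ++i) dc[i] = (double)oc[i] + bc;
    }
    out.attr("dim") = IntegerVector::create(H, Wd, N, cout);
    return List::create(_["out"] = out, _["col"] = xraw);
  }

  if (k == 3 && stride == 1 && pad == 1) {
    const int Hp = H + 2, Wp = Wd + 2;
    const R_xlen_t npr = (R_xlen_t)Hp * Wp * N;
    const int slack = Hp + 1 + PAD_SLACK_EXTRA;
    const R_xlen_t total = npr * C + 2 * slack;
    RawVector xraw(total * sizeof(float));
    float* xp = reinterpret_cast<float*>(RAW(xraw));
    std::fill(xp, xp + total, 0.0f);
    pad_to_float(x.begin(), xp, H, Wd, N, C, Hp, Wp, npr, slack);
    std::vector<float> Yp((size_t)npr * cout, 0.0f);
    const float onef = 1.0f;
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int o = dj * 3 + di;
        const R_xlen_t shift = (di - 1) + (R_xlen_t)Hp * (dj - 1);
        const int m = (int)npr, n = cout, kk = C;
        const int lda = (int)npr, ldb = 3 * 3 * C, ldc = (int)npr;
        const float* A = xp + slack + shift;
        const float* B = Wf.data() + o * C;
        F77_CALL(sgemm)("N", "N", &m, &n, &kk, &onef, A, &lda, B, &ldb,
                        &onef, Yp.data(), &ldc FCONE FCONE);
      }
    }
    NumericVector out((R_xlen_t)H * Wd * N * cout);
    double* po = out.begin();
    for (int c = 0; c < cout; ++c) {
      const double bc = b[c];
      const float* yc = Yp.data() + (size_t)c * npr;
      double* dc = po + (R_xlen_t)c * H * Wd * N;
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < Wd; ++w) {
          const float* yrow = yc + ((R_xlen_t)n * Wp + w + 1) * Hp + 1;
          double* drow = dc + ((R_xlen_t)n * Wd + w) * H;
          for (int h = 0; h < H; ++h) drow[h] = (double)yrow[h] + bc;
        }
    }
    out.attr("dim") = IntegerVector::create(H, Wd, N, cout);
    return List::create(_["out"] = out, _["col"] = xraw);
  }

  // generic strided path: explicit float im2col
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  const int kc = k * k * C;
  RawVector colraw(nrow * kc * sizeof(float));
  float* col = reinterpret_cast<float*>(RAW(colraw));
  gather2d_f(x.begin(), col, H, Wd, C, N, k, stride, pad, Ho, Wo);
  std::vector<float> outf((size_t)nrow * cout);
  sgemm_call("N", "N", (int)nrow, cout, kc, col, (int)nrow, Wf.data(), kc,
             outf.data(), (int)nrow);
  NumericVector out(nrow * cout);
  double* po = out.begin();
  for (int c = 0; c < cout; ++c) {
    const double bc = b[c];
    const float* oc = outf.data() + (size_t)c * nrow;
    double* dc = po + (R_xlen_t)c * nrow;
    for (R_xlen_t i = 0; i < nrow; ++i) dc[i] = (double)oc[i] + bc;
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, N, cout);
  return List::create(_["out"] = out, _["col"] = colraw);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector dout, RawVector colraw, IntegerVector dims,
                    NumericMatrix W, int k, int stride, int pad,
                    bool need_dx) {
  const int H = dims[0], Wd = dims[1], N = dims[2], C = dims[3];
  const int cout = W.ncol();
  std::vector<float> Wf(W.begin(), W.end());
  const double* pd = dout.begin();

  NumericVector db(cout);
  {
    const R_xlen_t mo = dout.size() / cout;
    for (int c = 0; c < cout; ++c) {
      double ssum = 0.0;
      const double* dc = pd + (R_xlen_t)c * mo;
      for (R_xlen_t i = 0; i < mo; ++i) ssum += dc[i];
      db[c] = ssum;
    }
  }

  if (k == 1 && stride == 1) {
    const R_xlen_t m = (R_xlen_t)H * Wd * N;
    const float* xf = reinterpret_cast<const float*>(RAW(colraw));
    std::vector<float> dy((size_t)m * cout);
    for (R_xlen_t i = 0; i < m * cout; ++i) dy[i] = (float)pd[i];
    std::vector<float> dWf((size_t)C * cout);
    sgemm_call("T", "N", C, cout, (int)m, xf, (int)m, dy.data(), (int)m,
               dWf.data(), C);
    NumericMatrix dW(C, cout);
    for (R_xlen_t i = 0; i < (R_xlen_t)C * cout; ++i) dW[i] = (double)dWf[i];
    NumericVector dx(0);
    if (need_dx) {
      std::vector<float> dxf((size_t)m * C);
      sgemm_call("N", "T", (int)m, C, cout, dy.data(), (int)m, Wf.data(), C,
                 dxf.data(), (int)m);
      dx = NumericVector(m * C);
      double* px = dx.begin();
      for (R_xlen_t i = 0; i < m * C; ++i) px[i] = (double)dxf[i];
      dx.attr("dim") = IntegerVector::create(H, Wd, N, C);
    }
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }

  if (k == 3 && stride == 1 && pad == 1) {
    const int Hp = H + 2, Wp = Wd + 2;
    const R_xlen_t npr = (R_xlen_t)Hp * Wp * N;
    const int slack = Hp + 1 + PAD_SLACK_EXTRA;
    const float* xp = reinterpret_cast<const float*>(RAW(colraw));
    // padded float copy of dout (zeros in pad cells and slack)
    std::vector<float> dyp(npr * cout + 2 * slack, 0.0f);
    for (int c = 0; c < cout; ++c) {
      float* yc = dyp.data() + slack + (R_xlen_t)c * npr;
      const double* sc = pd + (R_xlen_t)c * H * Wd * N;
      for (int n = 0; n < N; ++n)
        for (int w = 0; w < Wd; ++w) {
          float* yrow = yc + ((R_xlen_t)n * Wp + w + 1) * Hp + 1;
          const double* srow = sc + ((R_xlen_t)n * Wd + w) * H;
          for (int h = 0; h < H; ++h) yrow[h] = (float)srow[h];
        }
    }
    std::vector<float> dWf((size_t)9 * C * cout, 0.0f);
    const float onef = 1.0f, zerof = 0.0f;
    for (int dj = 0; dj < 3; ++dj)
      for (int di = 0; di < 3; ++di) {
        const int o = dj * 3 + di;
        const R_xlen_t shift = (di - 1) + (R_xlen_t)Hp * (dj - 1);
        const int m = C, n = cout, kk = (int)npr;
        const int lda = (int)npr, ldb = (int)npr, ldc = 3 * 3 * C;
        // dW_o = A_o^T %*% dY  (pad rows of dY are zero, so sums are exact)
        F77_CALL(sgemm)("T", "N", &m, &n, &kk, &onef, xp + slack + shift,
                        &lda, dyp.data() + slack, &ldb, &zerof,
                        dWf.data() + o * C, &ldc FCONE FCONE);
      }
    NumericMatrix dW(9 * C, cout);
    for (R_xlen_t i = 0; i < (R_xlen_t)9 * C * cout; ++i) dW[i] = (double)dWf[i];
    NumericVector dx(0);
    if (need_dx) {
      std::vector<float> dxp(npr * C + 2 * slack, 0.0f);
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di) {
          const int o = dj * 3 + di;
          const R_xlen_t shift = (di - 1) + (R_xlen_t)Hp * (dj - 1);
          const int m = (int)npr, n = C, kk = cout;
          const int lda = (int)npr, ldb = 3 * 3 * C, ldc = (int)npr;
          // dX += dY shifted by -s times W_o^T
          F77_CALL(sgemm)("N", "T", &m, &n, &kk, &onef,
                          dyp.data() + slack - shift, &lda,
                          Wf.data() + o * C, &ldb, &onef,
                          dxp.data() + slack, &ldc FCONE FCONE);
        }
      dx = NumericVector((R_xlen_t)H * Wd * N * C);
      double* px = dx.begin();
      for (int c = 0; c < C; ++c) {
        const float* xc = dxp.data() + slack + (R_xlen_t)c * npr;
        double* sc = px + (R_xlen_t)c * H * Wd * N;
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < Wd; ++w) {
            const float* xrow = xc + ((R_xlen_t)n * Wp + w + 1) * Hp + 1;
            double* srow = sc + ((R_xlen_t)n * Wd + w) * H;
            for (int h = 0; h < H; ++h) srow[h] = (double)xrow[h];
          }
      }
      dx.attr("dim") = IntegerVector::create(H, Wd, N, C);
    }
    return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
  }

  // generic strided path
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  const int kc = k * k * C;
  const R_xlen_t nrow = (R_xlen_t)Ho * Wo * N;
  const float* col = reinterpret_cast<const float*>(RAW(colraw));
  std::vector<float> dy((size_t)nrow * cout);
  for (R_xlen_t i = 0; i < nrow * cout; ++i) dy[i] = (float)pd[i];
  std::vector<float> dWf((size_t)kc * cout);
  sgemm_call("T", "N", kc, cout, (int)nrow, col, (int)nrow, dy.data(),
             (int)nrow, dWf.data(), kc);
  NumericMatrix dW(kc, cout);
  for (R_xlen_t i = 0; i < (R_xlen_t)kc * cout; ++i) dW[i] = (double)dWf[i];
  NumericVector dx(0);
  if (need_dx) {
    std::vector<float> dcol((size_t)nrow * kc);
    sgemm_call("N", "T", (int)nrow, kc, cout, dy.data(), (int)nrow, Wf.data(),
               kc, dcol.data(), (int)nrow);
    dx = NumericVector((R_xlen_t)H * Wd * N * C);
    scatter2d_f(dcol.data(), dx.begin(), H, Wd, C, N, k, stride, pad, Ho, Wo);
    dx.attr("dim") = IntegerVector::create(H, Wd, N, C);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_conv3d_fwd(NumericVector x, IntegerVector dims, NumericMatrix W,
                    NumericVector b, int k, int stride, int pad) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], C = dims[3];
  const int O1 = (D1 + 2 * pad - k) / stride + 1;
  const int O2 = (D2 + 2 * pad - k) / stride + 1;
  const int O3 = (D3 + 2 * pad - k) / stride + 1;
  const int cout = W.ncol();
  const R_xlen_t nrow = (R_xlen_t)O1 * O2 * O3;
  NumericMatrix col(nrow, (R_xlen_t)k * k * k * C);
  gather3d(x.begin(), col.begin(), D1, D2, D3, C, k, stride, pad, O1, O2, O3);
  NumericVector out(nrow * cout);
  dgemm_nn((int)nrow, cout, k * k * k * C, col.begin(), W.begin(), out.begin());
  double* po = out.begin();
  for (int c = 0; c < cout; ++c) {
    const double bc = b[c];
    double* oc = po + (R_xlen_t)c * nrow;
    for (R_xlen_t i = 0; i < nrow; ++i) oc[i] += bc;
  }
  out.attr("dim") = IntegerVector::create(O1, O2, O3, cout);
  return List::create(_["out"] = out, _["col"] = col);
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector dout, NumericMatrix col, IntegerVector dims,
                    NumericMatrix W, int k, int stride, int pad) {
  const int D1 = dims[0], D2 = dims[1], D3 = dims[2], C = dims[3];
  const int O1 = (D1 + 2 * pad - k) / stride + 1;
  const int O2 = (D2 + 2 * pad - k) / stride + 1;
  const int O3 = (D3 + 2 * pad - k) / stride + 1;
  const int cout = W.ncol();
  const int kc = k * k * k * C;
  const R_xlen_t nrow = (R_xlen_t)O1 * O2 * O3;
  NumericMatrix dW(kc, cout);
  dgemm_tn(kc, cout, (int)nrow, col.begin(), dout.begin(), dW.begin());
  NumericVector db(cout);
  const double* pd = dout.begin();
  for (int c = 0; c < cout; ++c) {
    double s = 0.0;
    const double* dc = pd + (R_xlen_t)c * nrow;
    for (R_xlen_t i = 0; i < nrow; ++i) s += dc[i];
    db[c] = s;
  }
  std::vector<double> dcol((size_t)nrow * kc);
  dgemm_nt((int)nrow, kc, cout, dout.begin(), W.begin(), dcol.data());
  NumericVector dx((R_xlen_t)D1 * D2 * D3 * C);
  scatter3d(dcol.data(), dx.begin(), D1, D2, D3, C, k, stride, pad, O1, O2, O3);
  dx.attr("dim") = IntegerVector::create(D1, D2, D3, C);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// ---- batch normalization kernels (channel = last axis) ----

// [[Rcpp::export]]
List cpp_bn_stats(NumericVector x, int nc) {
  const R_xlen_t m = x.size() / nc;
  NumericVector mu(nc), var(nc);
  const double* px = x.begin();
  for (int c = 0; c < nc; ++c) {
    const double* xc = px + (R_xlen_t)c * m;
    double s = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    mu[c] = s / m;
    var[c] = s2 / m - mu[c] * mu[c];
  }
  return List::create(_["mean"] = mu, _["var"] = var);
}

// [[Rcpp::export]]
List cpp_bn_apply(NumericVector x, NumericVector gamma, NumericVector beta,
                  NumericVector mu, NumericVector invstd) {
  const int nc = gamma.size();
  const R_xlen_t m = x.size() / nc;
  NumericVector out(x.size()), xhat(x.size());
  const double* px = x.begin();
  double* po = out.begin();
  double* ph = xhat.begin();
  for (int c = 0; c < nc; ++c) {
    const double muc = mu[c], ic = invstd[c], gc = gamma[c], bc = beta[c];
    const double* xc = px + (R_xlen_t)c * m;
    double* oc = po + (R_xlen_t)c * m;
    double* hc = ph + (R_xlen_t)c * m;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double h = (xc[i] - muc) * ic;
      hc[i] = h;
      oc[i] = gc * h + bc;
    }
  }
  out.attr("dim") = x.attr("dim");
  return List::create(_["out"] = out, _["xhat"] = xhat);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dout, NumericVector xhat, NumericVector gamma,
                NumericVector invstd) {
  const int nc = gamma.size();
  const R_xlen_t m = dout.size() / nc;
  NumericVector dx(dout.size()), dgamma(nc), dbeta(nc);
  const double* pd = dout.begin();
  const double* ph = xhat.begin();
  double* px = dx.begin();
  for (int c = 0; c < nc; ++c) {
    const double* dc = pd + (R_xlen_t)c * m;
    const double* hc = ph + (R_xlen_t)c * m;
    double sg = 0.0, sb = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) { sg += dc[i] * hc[i]; sb += dc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double k = gamma[c] * invstd[c] / m;
    double* xc = px + (R_xlen_t)c * m;
    for (R_xlen_t i = 0; i < m; ++i)
      xc[i] = k * (m * dc[i] - sb - hc[i] * sg);
  }
  dx.attr("dim") = dout.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
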