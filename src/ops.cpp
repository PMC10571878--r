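// Compiled numeric kernels: strided 2-D convolution via im2col + GEMM,
// same-padded max pooling with argmax bookkeeping, batched matrix multiply
// over cube slices, scatter-add, and IEEE-754 half-precision packing used
// for compact checkpoint serialization.
//
// Array layout convention (shared with the R side): feature maps are
// column-major arrays of dim (H, W, C, N); kernels are (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dim4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// im2col for one image (double source -> float patch matrix, so the GEMM
// runs in single precision). col is (K = kh*kw*C) x (P = Ho*Wo),
// column p = ho + Ho*wo.
static void im2col_one(const double *x, int H, int W, int C, int kh, int kw,
                       int stride, int ph, int pw, int Ho, int Wo, float *col) {
  const int K = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      float *cp = col + (size_t)(ho + (size_t)Ho * wo) * K;
      for (int c = 0; c < C; ++c) {
        const double *xc = x + (size_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          int wi = wo * stride + kj - pw;
          bool wok = (wi >= 0 && wi < W);
          for (int ki = 0; ki < kh; ++ki) {
            int hi = ho * stride + ki - ph;
            float v = 0.0f;
            if (wok && hi >= 0 && hi < H) v = (float)xc[hi + (size_t)H * wi];
            cp[ki + kh * (kj + kw * c)] = v;
          }
        }
      }
    }
  }
}

static void col2im_one(const float *col, int H, int W, int C, int kh, int kw,
                       int stride, int ph, int pw, int Ho, int Wo, double *dx) {
  const int K = kh * kw * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const float *cp = col + (size_t)(ho + (size_t)Ho * wo) * K;
      for (int c = 0; c < C; ++c) {
        double *xc = dx + (size_t)H * W * c;
        for (int kj = 0; kj < kw; ++kj) {
          int wi = wo * stride + kj - pw;
          if (wi < 0 || wi >= W) continue;
          for (int ki = 0; ki < kh; ++ki) {
            int hi = ho * stride + ki - ph;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += cp[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector bias,
                             int stride) {
  int dx_[4], dw_[4];
  get_dim4(x, dx_); get_dim4(w, dw_);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cin = dw_[2], Cout = dw_[3];
  if (Cin != C) stop("channel mismatch in conv2d");
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int Ho = (H + 2 * ph - kh) / stride + 1;
  const int Wo = (W + 2 * pw - kw) / stride + 1;
  const int K = kh * kw * C, P = Ho * Wo;

  arma::fmat wmat(K, Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) wmat.memptr()[i] = (float)w[i];
  NumericVector y((size_t)Ho * Wo * Cout * N);
  arma::fmat col(K, P), ym(P, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, ph, pw,
               Ho, Wo, col.memptr());
    ym = col.t() * wmat;
    double *yp = y.begin() + (size_t)P * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const float *sp = ym.colptr(co);
      double b = bias[co];
      for (int p = 0; p < P; ++p) yp[(size_t)P * co + p] = (double)sp[p] + b;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy, int stride,
                    bool need_dx) {
  int dx_[4], dw_[4], dyd[4];
  get_dim4(x, dx_); get_dim4(w, dw_); get_dim4(dy, dyd);
  const int H = dx_[0], W = dx_[1], C = dx_[2], N = dx_[3];
  const int kh = dw_[0], kw = dw_[1], Cout = dw_[3];
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int Ho = dyd[0], Wo = dyd[1];
  const int K = kh * kw * C, P = Ho * Wo;

  arma::fmat wmat(K, Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) wmat.memptr()[i] = (float)w[i];
  NumericVector dxv((size_t)H * W * C * N);
  NumericVector dwv(w.size());
  NumericVector dbv(Cout);
  arma::fmat dwm(K, Cout, arma::fill::zeros);
  arma::fmat col(K, P), dcol(K, P), dym(P, Cout);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (size_t)H * W * C * n, H, W, C, kh, kw, stride, ph, pw,
               Ho, Wo, col.memptr());
    const double *dp = dy.begin() + (size_t)P * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      float *tp = dym.colptr(co);
      double s = 0;
      for (int p = 0; p < P; ++p) {
        double v = dp[(size_t)P * co + p];
        tp[p] = (float)v;
        s += v;
      }
      dbv[co] += s;
    }
    dwm += col * dym;
    if (need_dx) {
      dcol = wmat * dym.t();
      col2im_one(dcol.memptr(), H, W, C, kh, kw, stride, ph, pw, Ho, Wo,
                 dxv.begin() + (size_t)H * W * C * n);
    }
  }
  for (size_t i = 0; i < (size_t)K * Cout; ++i) dwv[i] = (double)dwm.memptr()[i];
  dxv.attr("dim") = IntegerVector::create(H, W, C, N);
  dwv.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// Max pool, stride 1, same padding (k odd). Returns pooled values and the
// 1-based flat argmax index into x for each output element.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k) {
  int d[4];
  get_dim4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int p = (k - 1) / 2;
  NumericVector y(x.size());
  IntegerVector idx(x.size());
  const double *xp = x.begin();
  size_t off = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < W; ++wo) {
        for (int ho = 0; ho < H; ++ho) {
          double best = -HUGE_VAL;
          size_t bi = 0;
          int wlo = wo - p, whi = wo + p, hlo = ho - p, hhi = ho + p;
          if (wlo < 0) wlo = 0;
          if (whi >= W) whi = W - 1;
          if (hlo < 0) hlo = 0;
          if (hhi >= H) hhi = H - 1;
          for (int wi = wlo; wi <= whi; ++wi) {
            for (int hi = hlo; hi <= hhi; ++hi) {
              size_t ii = base + hi + (size_t)H * wi;
              if (xp[ii] > best) { best = xp[ii]; bi = ii; }
            }
          }
          y[off] = best;
          idx[off] = (int)(bi + 1);
          ++off;
        }
      }
    }
  }
  y.attr("dim") = x.attr("dim");
  idx.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector idx, int xlen) {
  NumericVector dx(xlen);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// Batched matrix multiply over cube slices: op(A_b) %*% op(B_b).
// [[Rcpp::export]]
NumericVector bmm_cpp(NumericVector A, NumericVector B, bool ta, bool tb) {
  IntegerVector da = A.attr("dim"), db = B.attr("dim");
  if (da.size() != 3 || db.size() != 3 || da[2] != db[2])
    stop("bmm expects two cubes with matching slice counts");
  const int nb = da[2];
  const int m = ta ? da[1] : da[0], ka = ta ? da[0] : da[1];
  const int kb = tb ? db[1] : db[0], n = tb ? db[0] : db[1];
  if (ka != kb) stop("bmm inner dimension mismatch");
  NumericVector Y((size_t)m * n * nb);
  for (int b = 0; b < nb; ++b) {
    arma::mat Am(const_cast<double *>(A.begin()) + (size_t)da[0] * da[1] * b,
                 da[0], da[1], false, true);
    arma::mat Bm(const_cast<double *>(B.begin()) + (size_t)db[0] * db[1] * b,
                 db[0], db[1], false, true);
    arma::mat Ym(Y.begin() + (size_t)m * n * b, m, n, false, true);
    if (!ta && !tb) Ym = Am * Bm;
    else if (ta && !tb) Ym = Am.t() * Bm;
    else if (!ta && tb) Ym = Am * Bm.t();
    else Ym = Am.t() * Bm.t();
  }
  Y.attr("dim") = IntegerVector::create(m, n, nb);
  return Y;
}

// [[Rcpp::export]]
NumericVector scatter_add_cpp(int n, IntegerVector idx, NumericVector vals) {
  NumericVector out(n);
  for (R_xlen_t i = 0; i < idx.size(); ++i) out[idx[i] - 1] += vals[i];
  return out;
}

static uint16_t f64_to_half(double dv) {
  float f = (float)dv;
  uint32_t u;
  memcpy(&u, &f, 4);
  uint32_t sign = (u >> 16) & 0x8000u;
  int32_t exp = (int32_t)((u >> 23) & 0xFF) - 127 + 15;
  uint32_t mant = u & 0x7FFFFFu;
  if (exp >= 31) return (uint16_t)(sign | 0x7C00u); // overflow -> inf
  if (exp <= 0) {
    if (exp < -10) return (uint16_t)sign; // underflow -> signed zero
    mant |= 0x800000u;
    uint32_t shift = (uint32_t)(14 - exp);
    return (uint16_t)(sign | (mant >> shift));
  }
  return (uint16_t)(sign | ((uint32_t)exp << 10) | (mant >> 13));
}

static double half_to_f64(uint16_t h) {
  uint32_t sign = (uint32_t)(h & 0x8000u) << 16;
  uint32_t exp = (h >> 10) & 0x1F;
  uint32_t mant = h & 0x3FFu;
  uint32_t u;
  if (exp == 0) {
    if (mant == 0) u = sign;
    else { // subnormal
      float f = (float)mant / 16777216.0f; // mant * 2^-24
      memcpy(&u, &f, 4);
      u |= sign;
    }
  } else if (exp == 31) {
    u = sign | 0x7F800000u | (mant << 13);
  } else {
    u = sign | ((exp - 15 + 127) << 23) | (mant << 13);
  }
  float f;
  memcpy(&f, &u, 4);
  return (double)f;
}

// [[Rcpp::export]]
RawVector double_to_half_cpp(NumericVector x) {
  RawVector out(2 * x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint16_t h = f64_to_half(x[i]);
    out[2 * i] = (unsigned char)(h & 0xFF);
    out[2 * i + 1] = (unsigned char)(h >> 8);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector half_to_double_cpp(RawVector r) {
  NumericVector out(r.size() / 2);
  for (R_xlen_t i = 0; i < out.size(); ++i) {
    uint16_t h = (uint16_t)r[2 * i] | ((uint16_t)r[2 * i + 1] << 8);
    out[i] = half_to_f64(h);
  }
  return out;
}

// --- fused elementwise activations -----------------------------------------

// [[Rcpp::export]]
List silu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size()), s(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double si = 1.0 / (1.0 + std::exp(-x[i]));
    s[i] = si;
    y[i] = x[i] * si;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector silu_bwd_cpp(NumericVector g, NumericVector x, NumericVector s) {
  NumericVector dx(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i)
    dx[i] = g[i] * s[i] * (1.0 + x[i] * (1.0 - s[i]));
  dx.attr("dim") = g.attr("dim");
  return dx;
}

// GELU, sigmoid form: x * sigmoid(1.702 x)
// [[Rcpp::export]]
List gelu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size()), s(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double si = 1.0 / (1.0 + std::exp(-1.702 * x[i]));
    s[i] = si;
    y[i] = x[i] * si;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["s"] = s);
}

// [[Rcpp::export]]
NumericVector gelu_bwd_cpp(NumericVector g, NumericVector x, NumericVector s) {
  NumericVector dx(g.size());
  for (R_xlen_t i = 0; i < g.size(); ++i)
    dx[i] = g[i] * (s[i] + 1.702 * x[i] * s[i] * (1.0 - s[i]));
  dx.attr("dim") = g.attr("dim");
  return dx;
}

// --- fused batch norm over (H*W, C, N) layout ------------------------------

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, int HW, int C, int N,
                NumericVector gamma, NumericVector beta,
                NumericVector mu, NumericVector va, bool use_batch_stats,
                double eps) {
  NumericVector y(x.size());
  NumericVector mu_out(C), va_out(C);
  const double M = (double)HW * N;
  if (use_batch_stats) {
    for (int c = 0; c < C; ++c) { mu_out[c] = 0; va_out[c] = 0; }
    for (int n = 0; n < N; ++n) {
      for (int c = 0; c < C; ++c) {
        const double *xp = x.begin() + (size_t)HW * (c + (size_t)C * n);
        double s = 0, s2 = 0;
        for (int i = 0; i < HW; ++i) { s += xp[i]; s2 += xp[i] * xp[i]; }
        mu_out[c] += s;
        va_out[c] += s2;
      }
    }
    for (int c = 0; c < C; ++c) {
      mu_out[c] /= M;
      va_out[c] = va_out[c] / M - mu_out[c] * mu_out[c];
    }
  } else {
    for (int c = 0; c < C; ++c) { mu_out[c] = mu[c]; va_out[c] = va[c]; }
  }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double inv = 1.0 / std::sqrt(va_out[c] + eps);
      double a = gamma[c] * inv;
      double b = beta[c] - a * mu_out[c];
      const double *xp = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double *yp = y.begin() + (size_t)HW * (c + (size_t)C * n);
      for (int i = 0; i < HW; ++i) yp[i] = a * xp[i] + b;
    }
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["mu"] = mu_out, _["va"] = va_out);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector g, NumericVector x, int HW, int C, int N,
                NumericVector gamma, NumericVector mu, NumericVector va,
                bool training, double eps) {
  NumericVector dx(g.size()), dgamma(C), dbeta(C);
  const double M = (double)HW * N;
  std::vector<double> sg(C, 0.0), sgx(C, 0.0), inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(va[c] + eps);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *gp = g.begin() + (size_t)HW * (c + (size_t)C * n);
      const double *xp = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double s = 0, s2 = 0;
      for (int i = 0; i < HW; ++i) {
        s += gp[i];
        s2 += gp[i] * (xp[i] - mu[c]) * inv[c];
      }
      sg[c] += s;
      sgx[c] += s2;
    }
  }
  for (int c = 0; c < C; ++c) { dbeta[c] = sg[c]; dgamma[c] = sgx[c]; }
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *gp = g.begin() + (size_t)HW * (c + (size_t)C * n);
      const double *xp = x.begin() + (size_t)HW * (c + (size_t)C * n);
      double *dp = dx.begin() + (size_t)HW * (c + (size_t)C * n);
      double a = gamma[c] * inv[c];
      if (training) {
        double m1 = sg[c] / M, m2 = sgx[c] / M;
        for (int i = 0; i < HW; ++i) {
          double xh = (xp[i] - mu[c]) * inv[c];
          dp[i] = a * (gp[i] - m1 - xh * m2);
        }
      } else {
        for (int i = 0; i < HW; ++i) dp[i] = a * gp[i];
      }
    }
  }
  dx.attr("dim") = g.attr("dim");
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// --- layer norm over rows of an (M, C) matrix ------------------------------

// [[Rcpp::export]]
List ln_fwd_cpp(NumericMatrix x, NumericVector gamma, NumericVector beta,
                double eps) {
  const int M = x.nrow(), C = x.ncol();
  NumericMatrix y(M, C);
  NumericVector mu(M), inv(M);
  for (int i = 0; i < M; ++i) {
    double s = 0;
    for (int c = 0; c < C; ++c) s += x(i, c);
    double m = s / C, v = 0;
    for (int c = 0; c < C; ++c) { double d = x(i, c) - m; v += d * d; }
    mu[i] = m;
    inv[i] = 1.0 / std::sqrt(v / C + eps);
  }
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < M; ++i) {
      y(i, c) = (x(i, c) - mu[i]) * inv[i] * gamma[c] + beta[c];
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv);
}

// [[Rcpp::export]]
List ln_bwd_cpp(NumericMatrix g, NumericMatrix x, NumericVector gamma,
                NumericVector mu, NumericVector inv) {
  const int M = g.nrow(), C = g.ncol();
  NumericMatrix dx(M, C);
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> t1(M, 0.0), t2(M, 0.0);
  for (int c = 0; c < C; ++c) {
    double dg = 0, db = 0;
    for (int i = 0; i < M; ++i) {
      double xh = (x(i, c) - mu[i]) * inv[i];
      double gr = g(i, c) * gamma[c];
      t1[i] += gr;
      t2[i] += gr * xh;
      dg += g(i, c) * xh;
      db += g(i, c);
    }
    dgamma[c] = dg;
    dbeta[c] = db;
  }
  for (int i = 0; i < M; ++i) { t1[i] /= C; t2[i] /= C; }
  for (int c = 0; c < C; ++c) {
    for (int i = 0; i < M; ++i) {
      double xh = (x(i, c) - mu[i]) * inv[i];
      dx(i, c) = inv[i] * (g(i, c) * gamma[c] - t1[i] - xh * t2[i]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// --- attention softmax with relative-position bias and optional mask -------
// scores: (T, T, hB) cube (softmax over dim 1); bias: (T, T, heads);
// mask: empty or (T, T, hB). y = softmax(scale * scores + bias + mask).
// [[Rcpp::export]]
NumericVector att_softmax_cpp(NumericVector scores, NumericVector bias,
                              NumericVector mask, double scale, int heads) {
  IntegerVector d = scores.attr("dim");
  const int T = d[0], T2 = d[1], HB = d[2];
  const size_t TT = (size_t)T * T2;
  const bool has_mask = mask.size() > 0;
  NumericVector y(scores.size());
  for (int b = 0; b < HB; ++b) {
    const double *sp = scores.begin() + TT * b;
    const double *bp = bias.begin() + TT * (b % heads);
    const double *mp = has_mask ? mask.begin() + TT * b : nullptr;
    double *yp = y.begin() + TT * b;
    for (int q = 0; q < T2; ++q) {
      const double *sc = sp + (size_t)T * q;
      const double *bc = bp + (size_t)T * q;
      const double *mc = has_mask ? mp + (size_t)T * q : nullptr;
      double *yc = yp + (size_t)T * q;
      double mx = -HUGE_VAL;
      for (int k = 0; k < T; ++k) {
        double v = scale * sc[k] + bc[k] + (has_mask ? mc[k] : 0.0);
        yc[k] = v;
        if (v > mx) mx = v;
      }
      double s = 0;
      for (int k = 0; k < T; ++k) { yc[k] = std::exp(yc[k] - mx); s += yc[k]; }
      for (int k = 0; k < T; ++k) yc[k] /= s;
    }
  }
  y.attr("dim") = d;
  return y;
}

// [[Rcpp::export]]
List att_softmax_bwd_cpp(NumericVector g, NumericVector y, double scale,
                         int heads) {
  IntegerVector d = y.attr("dim");
  const int T = d[0], T2 = d[1], HB = d[2];
  const size_t TT = (size_t)T * T2;
  NumericVector ds(y.size());
  NumericVector dbias(TT * heads);
  for (int b = 0; b < HB; ++b) {
    const double *gp = g.begin() + TT * b;
    const double *yp = y.begin() + TT * b;
    double *sp = ds.begin() + TT * b;
    double *dbp = dbias.begin() + TT * (b % heads);
    for (int q = 0; q < T2; ++q) {
      const double *gc = gp + (size_t)T * q;
      const double *yc = yp + (size_t)T * q;
      double *sc = sp + (size_t)T * q;
      double *dbc = dbp + (size_t)T * q;
      double dot = 0;
      for (int k = 0; k < T; ++k) dot += gc[k] * yc[k];
      for (int k = 0; k < T; ++k) {
        double dz = yc[k] * (gc[k] - dot);
        sc[k] = scale * dz;
        dbc[k] += dz;
      }
    }
  }
  ds.attr("dim") = d;
  dbias.attr("dim") = IntegerVector::create(T, T2, heads);
  return List::create(_["ds"] = ds, _["dbias"] = dbias);
}
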