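// Fused compute kernels for the convolutional branch.  Layout conventions
// match the R code: convolutional activations are (H, W, n, C) arrays
// (column-major, channels last), and the 3x3 same-padding convolution
// uses a (9 C_in x C_out) kernel matrix with rows ordered (c_in fastest,
// kernel row di, kernel col dj).
#include <Rcpp.h>
using namespace Rcpp;

// 3x3 same-padding convolution via chunked im2col + BLAS dgemm.
// Patch matrix rows are output positions (h fastest, then w, then sample
// within chunk); columns are (c_in fastest, kernel row di, kernel col dj),
// matching the (9 C_in x C_out) kernel layout.
#include <R_ext/BLAS.h>
#include <vector>
#include <cstring>

static std::vector<double>& scratch_buf(int which, R_xlen_t need) {
  static std::vector<double> bufs[4];
  std::vector<double>& b = bufs[which];
  if ((R_xlen_t)b.size() < need) b.resize(need);
  return b;
}

static void im2col_chunk(const double* x, double* P, int H, int W, int n,
                         int Cin, int s0, int m /*chunk samples*/) {
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t chan = plane * n;
  const R_xlen_t M = plane * m;
  int col = 0;
  for (int dj = 0; dj < 3; ++dj)
    for (int di = 0; di < 3; ++di)
      for (int ci = 0; ci < Cin; ++ci) {
        // column index in (ci, di, dj) order = ci + Cin*(di + 3*dj)
        double* pc = P + (R_xlen_t)(ci + Cin * (di + 3 * dj)) * M;
        for (int s = 0; s < m; ++s) {
          const double* xp = x + plane * (s0 + s) + chan * ci;
          double* dst = pc + plane * s;
          for (int w = 0; w < W; ++w) {
            const int wi = w + dj - 1;
            double* dcol = dst + (R_xlen_t)H * w;
            if (wi < 0 || wi >= W) {
              std::memset(dcol, 0, sizeof(double) * H);
              continue;
            }
            const double* xcol = xp + (R_xlen_t)H * wi;
            if (di == 1) {
              std::memcpy(dcol, xcol, sizeof(double) * H);
            } else if (di == 0) {
              dcol[0] = 0.0;
              std::memcpy(dcol + 1, xcol, sizeof(double) * (H - 1));
            } else {
              std::memcpy(dcol, xcol + 1, sizeof(double) * (H - 1));
              dcol[H - 1] = 0.0;
            }
          }
        }
        ++col;
      }
  (void)col;
}

// [[Rcpp::export]]
NumericVector conv_fwd_direct(NumericVector X, NumericMatrix K,
                              NumericVector b, int H, int W, int n,
                              int Cin) {
  const int Cout = K.ncol();
  const int KR = 9 * Cin;
  NumericVector out(no_init((R_xlen_t)H * W * n * Cout));
  out.attr("dim") = IntegerVector::create(H, W, n, Cout);
  const double* x = X.begin();
  double* o = out.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t chan = plane * n;
  const int chunk = std::min(n, 64);
  std::vector<double>& P = scratch_buf(0, (R_xlen_t)plane * chunk * KR);
  std::vector<double>& C = scratch_buf(1, (R_xlen_t)plane * chunk * Cout);
  const double one = 1.0, zero = 0.0;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int m = std::min(chunk, n - s0);
    const int M = (int)(plane * m);
    im2col_chunk(x, P.data(), H, W, n, Cin, s0, m);
    F77_CALL(dgemm)("N", "N", &M, &Cout, &KR, &one, P.data(), &M,
                    REAL(K), &KR, &zero, C.data(), &M FCONE FCONE);
    for (int co = 0; co < Cout; ++co) {
      const double bc = b[co];
      const double* src = C.data() + (R_xlen_t)co * M;
      for (int s = 0; s < m; ++s) {
        double* dst = o + plane * (s0 + s) + chan * co;
        const double* sp = src + plane * s;
        for (R_xlen_t i = 0; i < plane; ++i) dst[i] = sp[i] + bc;
      }
    }
  }
  return out;
}

// combined backward: weight/bias gradients and (optionally) the input
// gradient of the convolution
// [[Rcpp::export]]
List conv_bwd_direct(NumericVector X, NumericVector dOut, NumericMatrix K,
                     int H, int W, int n, int Cin, bool want_dx) {
  const int Cout = K.ncol();
  const int KR = 9 * Cin;
  NumericMatrix dK(KR, Cout);
  NumericVector db(Cout);
  NumericVector dX(want_dx ? (R_xlen_t)H * W * n * Cin : 0);
  if (want_dx) dX.attr("dim") = IntegerVector::create(H, W, n, Cin);
  const double* x = X.begin();
  const double* d = dOut.begin();
  const R_xlen_t plane = (R_xlen_t)H * W;
  const R_xlen_t chan = plane * n;
  const int chunk = std::min(n, 64);
  std::vector<double>& P = scratch_buf(0, (R_xlen_t)plane * chunk * KR);
  std::vector<double>& D = scratch_buf(1, (R_xlen_t)plane * chunk * Cout);
  std::vector<double>& dP = scratch_buf(2,
      want_dx ? (R_xlen_t)plane * chunk * KR : 1);
  const double one = 1.0, zero = 0.0;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int m = std::min(chunk, n - s0);
    const int M = (int)(plane * m);
    im2col_chunk(x, P.data(), H, W, n, Cin, s0, m);
    // gather dOut chunk into (M x Cout), accumulate bias sums
    for (int co = 0; co < Cout; ++co) {
      double* dst = D.data() + (R_xlen_t)co * M;
      double acc = 0.0;
      for (int s = 0; s < m; ++s) {
        const double* sp = d + plane * (s0 + s) + chan * co;
        double* dd = dst + plane * s;
        for (R_xlen_t i = 0; i < plane; ++i) { dd[i] = sp[i]; acc += sp[i]; }
      }
      db[co] += acc;
    }
    F77_CALL(dgemm)("T", "N", &KR, &Cout, &M, &one, P.data(), &M,
                    D.data(), &M, &one, REAL(dK), &KR FCONE FCONE);
    if (want_dx) {
      F77_CALL(dgemm)("N", "T", &M, &KR, &Cout, &one, D.data(), &M,
                      REAL(K), &KR, &zero, dP.data(), &M FCONE FCONE);
      // col2im scatter-add of dP into dX
      double* dx = REAL(dX);
      for (int dj = 0; dj < 3; ++dj)
        for (int di = 0; di < 3; ++di)
          for (int ci = 0; ci < Cin; ++ci) {
            const double* pc = dP.data() +
              (R_xlen_t)(ci + Cin * (di + 3 * dj)) * M;
            for (int s = 0; s < m; ++s) {
              double* xp = dx + plane * (s0 + s) + chan * ci;
              const double* src = pc + plane * s;
              for (int w = 0; w < W; ++w) {
                const int wi = w + dj - 1;
                if (wi < 0 || wi >= W) continue;
                double* xcol = xp + (R_xlen_t)H * wi;
                const double* scol = src + (R_xlen_t)H * w;
                if (di == 1) {
                  for (int h = 0; h < H; ++h) xcol[h] += scol[h];
                } else if (di == 0) {
                  for (int h = 1; h < H; ++h) xcol[h - 1] += scol[h];
                } else {
                  for (int h = 0; h < H - 1; ++h) xcol[h + 1] += scol[h];
                }
              }
            }
          }
    }
  }
  return List::create(_["dK"] = dK, _["db"] = db,
                      _["dX"] = want_dx ? (SEXP)dX : R_NilValue);
}

// fused training-mode batch normalization + leaky ReLU over channels
// (columns of the implicit (m x C) view); returns the activation, the
// normalized pre-activation and per-channel batch statistics
// [[Rcpp::export]]
List bn_lrelu_fwd_train(NumericVector X, int C, NumericVector g,
                        NumericVector b, double slope, double eps) {
  R_xlen_t m = X.size() / C;
  NumericVector out(no_init(X.size())), xhat(no_init(X.size()));
  NumericVector inv_sd(C), mu(C), var(C);
  const double* x = X.begin();
  double* o = out.begin();
  double* hh = xhat.begin();
  for (int j = 0; j < C; ++j) {
    const double* xj = x + m * j;
    double s = 0;
    for (R_xlen_t i = 0; i < m; ++i) s += xj[i];
    const double mj = s / m;
    double v = 0;
    for (R_xlen_t i = 0; i < m; ++i) { double c = xj[i] - mj; v += c * c; }
    v /= m;
    const double is = 1.0 / std::sqrt(v + eps);
    mu[j] = mj; var[j] = v; inv_sd[j] = is;
    const double gj = g[j], bj = b[j];
    double* oj = o + m * j;
    double* hj = hh + m * j;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double hv = (xj[i] - mj) * is;
      hj[i] = hv;
      const double a = gj * hv + bj;
      oj[i] = a > 0 ? a : slope * a;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["inv_sd"] = inv_sd, _["mu"] = mu, _["var"] = var);
}

// inference-mode counterpart using running statistics
// [[Rcpp::export]]
NumericVector bn_lrelu_fwd_eval(NumericVector X, int C, NumericVector g,
                                NumericVector b, NumericVector mean,
                                NumericVector var, double slope,
                                double eps) {
  R_xlen_t m = X.size() / C;
  NumericVector out(no_init(X.size()));
  const double* x = X.begin();
  double* o = out.begin();
  for (int j = 0; j < C; ++j) {
    const double is = 1.0 / std::sqrt(var[j] + eps);
    const double gj = g[j], bj = b[j], mj = mean[j];
    const double* xj = x + m * j;
    double* oj = o + m * j;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double a = gj * (xj[i] - mj) * is + bj;
      oj[i] = a > 0 ? a : slope * a;
    }
  }
  return out;
}

// fused backward pass through leaky ReLU + batch normalization.  The
// rectifier mask is recovered from the sign of the forward activation
// (the leaky rectifier preserves sign).
// [[Rcpp::export]]
List bn_lrelu_bwd(NumericVector dY, NumericVector out, NumericVector xhat,
                  NumericVector inv_sd, NumericVector g, double slope,
                  int C) {
  R_xlen_t m = dY.size() / C;
  NumericVector dX(no_init(dY.size())), dg(C), db(C);
  const double* dy = dY.begin();
  const double* oo = out.begin();
  const double* hh = xhat.begin();
  double* dx = dX.begin();
  for (int j = 0; j < C; ++j) {
    const double* dyj = dy + m * j;
    const double* oj = oo + m * j;
    const double* hj = hh + m * j;
    double* dxj = dx + m * j;
    const double gj = g[j];
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    // first pass: gradient through the rectifier, channel reductions
    for (R_xlen_t i = 0; i < m; ++i) {
      const double dyv = oj[i] > 0 ? dyj[i] : slope * dyj[i];
      dxj[i] = dyv;                 // rectified gradient, reused below
      sg += dyv * hj[i];
      sb += dyv;
      const double dh = dyv * gj;
      s1 += dh;
      s2 += dh * hj[i];
    }
    dg[j] = sg;
    db[j] = sb;
    const double f = inv_sd[j] / m;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double dh = dxj[i] * gj;
      dxj[i] = f * (m * dh - s1 - hj[i] * s2);
    }
  }
  return List::create(_["dX"] = dX, _["dg"] = dg, _["db"] = db);
}

// 2x2 stride-2 max pooling on (H, W, n, C); returns pooled values and the
// flat argmax index into the input for the backward scatter
// [[Rcpp::export]]
List pool_fwd(NumericVector X, int H, int W, int n, int C) {
  int H2 = H / 2, W2 = W / 2;
  R_xlen_t outlen = (R_xlen_t)H2 * W2 * n * C;
  NumericVector M(no_init(outlen));
  IntegerVector idx(no_init(outlen));
  M.attr("dim") = IntegerVector::create(H2, W2, n, C);
  const double* x = X.begin();
  double* mo = M.begin();
  int* io = idx.begin();
  R_xlen_t out = 0;
  for (int c = 0; c < C; ++c)
    for (int s = 0; s < n; ++s) {
      const R_xlen_t base_off = ((R_xlen_t)c * n + s) * H * W;
      const double* base = x + base_off;
      for (int w = 0; w < W2; ++w)
        for (int h = 0; h < H2; ++h) {
          const R_xlen_t i00 = (R_xlen_t)(2 * w) * H + 2 * h;
          const R_xlen_t cand[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
          double best = base[cand[0]];
          R_xlen_t bi = cand[0];
          for (int q = 1; q < 4; ++q)
            if (base[cand[q]] > best) { best = base[cand[q]]; bi = cand[q]; }
          mo[out] = best;
          io[out] = (int)(bi + base_off);
          ++out;
        }
    }
  return List::create(_["out"] = M, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool_bwd(NumericVector dM, IntegerVector idx, int H, int W,
                       int n, int C) {
  NumericVector dX((R_xlen_t)H * W * n * C);
  dX.attr("dim") = IntegerVector::create(H, W, n, C);
  double* dx = dX.begin();
  const double* dm = dM.begin();
  const int* io = idx.begin();
  for (R_xlen_t i = 0; i < dM.size(); ++i) dx[io[i]] += dm[i];
  return dX;
}

// leaky rectifier (dense layers)
// [[Rcpp::export]]
NumericVector lrelu_fwd(NumericVector X, double slope) {
  NumericVector Y(no_init(X.size()));
  if (!Rf_isNull(X.attr("dim"))) Y.attr("dim") = X.attr("dim");
  const double* x = X.begin();
  double* y = Y.begin();
  for (R_xlen_t i = 0; i < X.size(); ++i)
    y[i] = x[i] > 0 ? x[i] : slope * x[i];
  return Y;
}

// [[Rcpp::export]]
NumericVector lrelu_bwd(NumericVector dY, NumericVector X, double slope) {
  NumericVector dX(no_init(X.size()));
  if (!Rf_isNull(X.attr("dim"))) dX.attr("dim") = X.attr("dim");
  const double* dy = dY.begin();
  const double* x = X.begin();
  double* dx = dX.begin();
  for (R_xlen_t i = 0; i < X.size(); ++i)
    dx[i] = x[i] > 0 ? dy[i] : slope * dy[i];
  return dX;
}
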