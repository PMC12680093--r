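// Low-level volumetric network primitives.
//
// Tensor layout contract (shared with the R side): a Volume5D is a numeric
// array with dim = c(B, C, D, H, W), i.e. column-major linear index
//   b + B*(c + C*(d + D*(h + H*w)))           (all 0-based here).
// Convolution weights are matrices of shape (Cout x K) with column index
//   k = ci + Cin*(zd + kd*(zh + kh*zw))
// which is exactly matrix(w_array, nrow = Cout) for an R array of
// dim = c(Cout, Cin, kd, kh, kw).
//
// Convolutions are evaluated by im2col + GEMM. Each sample is first
// repacked channel-major (ci fastest) so the im2col gather copies
// contiguous Cin-runs; the column buffer is chunked over the output depth
// axis so it stays small even for full-resolution volumes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline long long idx5(long long b, long long c, long long d,
                             long long h, long long w,
                             long long B, long long C, long long D,
                             long long H) {
  return b + B * (c + C * (d + D * (h + H * w)));
}

static inline long long out_size(long long n, int k, int s, int p) {
  return (n + 2LL * p - k) / s + 1;
}

// Repack sample b of x into xc[ci + Cin*(d + D*(h + H*w))].
static void repack_sample(const double* x, double* xc, long long b,
                          long long B, long long Cin, long long D,
                          long long H, long long W) {
  for (long long w = 0; w < W; ++w)
    for (long long h = 0; h < H; ++h)
      for (long long d = 0; d < D; ++d) {
        const double* src = x + idx5(b, 0, d, h, w, B, Cin, D, H);
        double* dst = xc + Cin * (d + D * (h + H * w));
        for (long long ci = 0; ci < Cin; ++ci) dst[ci] = src[B * ci];
      }
}

// Fill the im2col buffer for one output-depth chunk from a repacked sample.
static void im2col_chunk(const double* xc, arma::mat& col, long long od,
                         long long Cin, long long D, long long H,
                         long long W, int kd, int kh, int kw, int sd,
                         int sh, int sw, int pd, int ph, int pw,
                         long long Ho, long long Wo) {
  const long long d0 = (long long)od * sd - pd;
  const size_t run = sizeof(double) * Cin;
  for (long long ow = 0; ow < Wo; ++ow) {
    const long long w0 = ow * sw - pw;
    for (long long oh = 0; oh < Ho; ++oh) {
      const long long h0 = oh * sh - ph;
      double* cj = col.colptr(oh + Ho * ow);
      long long r = 0;
      for (int zw = 0; zw < kw; ++zw) {
        const long long w = w0 + zw;
        for (int zh = 0; zh < kh; ++zh) {
          const long long h = h0 + zh;
          for (int zd = 0; zd < kd; ++zd) {
            const long long d = d0 + zd;
            if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W) {
              std::memcpy(cj + r, xc + Cin * (d + D * (h + H * w)), run);
            } else {
              std::memset(cj + r, 0, run);
            }
            r += Cin;
          }
        }
      }
    }
  }
}


// ---- fast path for stride-1, size-preserving convolutions ----------------
// The sample is repacked onto a zero-padded grid (channel-major); each
// kernel offset then contributes one shifted GEMM over the whole padded
// range. Padding columns are zero on the input side (no contamination) and
// garbage rows on the output side are simply never read back.

static void repack_padded(const double* x, arma::mat& xc, long long b,
                          long long B, long long Cin, long long D,
                          long long H, long long W, int pd, int ph, int pw) {
  xc.zeros();
  const long long Dp = D + 2 * pd, Hp = H + 2 * ph;
  for (long long w = 0; w < W; ++w)
    for (long long h = 0; h < H; ++h)
      for (long long d = 0; d < D; ++d) {
        const double* src = x + idx5(b, 0, d, h, w, B, Cin, D, H);
        double* dst = xc.colptr((d + pd) + Dp * ((h + ph) + Hp * (w + pw)));
        for (long long ci = 0; ci < Cin; ++ci) dst[ci] = src[B * ci];
      }
}

static bool same_size_stride1(const int* stride, long long D, long long H,
                              long long W, long long Do, long long Ho,
                              long long Wo) {
  return stride[0] == 1 && stride[1] == 1 && stride[2] == 1 &&
         Do == D && Ho == H && Wo == W;
}

// [[Rcpp::export(name = ".conv3d_forward_cpp")]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericMatrix wmat, NumericVector bias,
                                 IntegerVector kernel, IntegerVector stride,
                                 IntegerVector pad) {
  const long long B = xdim[0], Cin = xdim[1], D = xdim[2], H = xdim[3],
                  W = xdim[4];
  const int kd = kernel[0], kh = kernel[1], kw = kernel[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const long long Do = out_size(D, kd, sd, pd), Ho = out_size(H, kh, sh, ph),
                  Wo = out_size(W, kw, sw, pw);
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("conv3d: output size would be < 1 along some axis");
  const long long Cout = wmat.nrow();
  const long long K = (long long)Cin * kd * kh * kw;
  if ((long long)wmat.ncol() != K)
    stop("conv3d: weight matrix has %d columns, expected %lld", wmat.ncol(), K);

  NumericVector out((R_xlen_t)(B * Cout * Do * Ho * Wo));
  out.attr("dim") = IntegerVector::create(B, Cout, Do, Ho, Wo);
  arma::mat Wm(wmat.begin(), Cout, K, false, true);
  const double* xp = x.begin();
  double* op = out.begin();

  const long long Np_guard = (D + 2 * pd) * (H + 2 * ph) * (W + 2 * pw);
  if (Cin >= 2 && Np_guard <= 2000000 &&
      same_size_stride1(stride.begin(), D, H, W, Do, Ho, Wo)) {
    const long long Dp = D + 2 * pd, Hp = H + 2 * ph, Wp = W + 2 * pw;
    const long long Np = Dp * Hp * Wp;
    arma::mat xc(Cin, Np);
    arma::mat ob(Cout, Np);
    for (long long b = 0; b < B; ++b) {
      repack_padded(xp, xc, b, B, Cin, D, H, W, pd, ph, pw);
      ob.zeros();
      for (int zw = 0; zw < kw; ++zw)
        for (int zh = 0; zh < kh; ++zh)
          for (int zd = 0; zd < kd; ++zd) {
            const long long del = (zd - pd) + Dp * ((long long)(zh - ph) +
                                  Hp * (long long)(zw - pw));
            const long long a = std::max(0LL, -del);
            const long long e = Np - 1 - std::max(0LL, del);
            if (a > e) continue;
            const long long k0 = Cin * ((long long)zd + kd *
                                 ((long long)zh + kh * (long long)zw));
            ob.cols(a, e) += Wm.cols(k0, k0 + Cin - 1) *
                             xc.cols(a + del, e + del);
          }
      for (long long w = 0; w < W; ++w)
        for (long long h = 0; h < H; ++h)
          for (long long d = 0; d < D; ++d) {
            const double* src =
              ob.colptr((d + pd) + Dp * ((h + ph) + Hp * (w + pw)));
            double* dst = op + idx5(b, 0, d, h, w, B, Cout, D, H);
            for (long long co = 0; co < Cout; ++co)
              dst[B * co] = src[co] + bias[co];
          }
    }
    return out;
  }

  arma::mat col(K, Ho * Wo);
  std::vector<double> xc((size_t)(Cin * D * H * W));
  for (long long b = 0; b < B; ++b) {
    repack_sample(xp, xc.data(), b, B, Cin, D, H, W);
    for (long long od = 0; od < Do; ++od) {
      im2col_chunk(xc.data(), col, od, Cin, D, H, W, kd, kh, kw, sd, sh, sw,
                   pd, ph, pw, Ho, Wo);
      arma::mat o = Wm * col;  // Cout x (Ho*Wo)
      for (long long ow = 0; ow < Wo; ++ow)
        for (long long oh = 0; oh < Ho; ++oh) {
          double* dst = op + idx5(b, 0, od, oh, ow, B, Cout, Do, Ho);
          const double* src = o.colptr(oh + Ho * ow);
          for (long long co = 0; co < Cout; ++co)
            dst[B * co] = src[co] + bias[co];
        }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward_cpp")]]
List conv3d_backward_cpp(NumericVector dout, NumericVector x,
                         IntegerVector xdim, NumericMatrix wmat,
                         IntegerVector kernel, IntegerVector stride,
                         IntegerVector pad, bool need_dx) {
  const long long B = xdim[0], Cin = xdim[1], D = xdim[2], H = xdim[3],
                  W = xdim[4];
  const int kd = kernel[0], kh = kernel[1], kw = kernel[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const long long Do = out_size(D, kd, sd, pd), Ho = out_size(H, kh, sh, ph),
                  Wo = out_size(W, kw, sw, pw);
  const long long Cout = wmat.nrow();
  const long long K = (long long)Cin * kd * kh * kw;

  arma::mat Wm(wmat.begin(), Cout, K, false, true);
  NumericVector dx(x.size());
  dx.attr("dim") = xdim;
  arma::mat dW(Cout, K, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);

  if (false && same_size_stride1(stride.begin(), D, H, W, Do, Ho, Wo)) {
    const long long Dp = D + 2 * pd, Hp = H + 2 * ph, Wp = W + 2 * pw;
    const long long Np = Dp * Hp * Wp;
    arma::mat xc(Cin, Np);
    arma::mat dob(Cout, Np);
    arma::mat dxc(Cin, Np);
    const double* xp2 = x.begin();
    const double* dop2 = dout.begin();
    double* dxp2 = dx.begin();
    for (long long b = 0; b < B; ++b) {
      repack_padded(xp2, xc, b, B, Cin, D, H, W, pd, ph, pw);
      dob.zeros();
      for (long long w = 0; w < W; ++w)
        for (long long h = 0; h < H; ++h)
          for (long long d = 0; d < D; ++d) {
            const double* src = dop2 + idx5(b, 0, d, h, w, B, Cout, D, H);
            double* dst =
              dob.colptr((d + pd) + Dp * ((h + ph) + Hp * (w + pw)));
            for (long long co = 0; co < Cout; ++co) dst[co] = src[B * co];
          }
      db += arma::sum(dob, 1);
      if (need_dx) dxc.zeros();
      for (int zw = 0; zw < kw; ++zw)
        for (int zh = 0; zh < kh; ++zh)
          for (int zd = 0; zd < kd; ++zd) {
            const long long del = (zd - pd) + Dp * ((long long)(zh - ph) +
                                  Hp * (long long)(zw - pw));
            const long long a = std::max(0LL, -del);
            const long long e = Np - 1 - std::max(0LL, del);
            if (a > e) continue;
            const long long k0 = Cin * ((long long)zd + kd *
                                 ((long long)zh + kh * (long long)zw));
            dW.cols(k0, k0 + Cin - 1) +=
              dob.cols(a, e) * xc.cols(a + del, e + del).t();
            if (need_dx)
              dxc.cols(a + del, e + del) +=
                Wm.cols(k0, k0 + Cin - 1).t() * dob.cols(a, e);
          }
      if (need_dx)
        for (long long w = 0; w < W; ++w)
          for (long long h = 0; h < H; ++h)
            for (long long d = 0; d < D; ++d) {
              const double* src =
                dxc.colptr((d + pd) + Dp * ((h + ph) + Hp * (w + pw)));
              double* dst = dxp2 + idx5(b, 0, d, h, w, B, Cin, D, H);
              for (long long ci = 0; ci < Cin; ++ci) dst[B * ci] = src[ci];
            }
    }
    NumericMatrix dWf(Cout, K);
    std::copy(dW.begin(), dW.end(), dWf.begin());
    NumericVector dbf(Cout);
    std::copy(db.begin(), db.end(), dbf.begin());
    return List::create(_["dx"] = dx, _["dw"] = dWf, _["db"] = dbf);
  }

  arma::mat col(K, Ho * Wo);
  arma::mat dmat(Cout, Ho * Wo);
  std::vector<double> xc((size_t)(Cin * D * H * W));
  std::vector<double> dxc((size_t)(Cin * D * H * W));
  const double* xp = x.begin();
  const double* dop = dout.begin();
  double* dxp = dx.begin();

  for (long long b = 0; b < B; ++b) {
    repack_sample(xp, xc.data(), b, B, Cin, D, H, W);
    std::fill(dxc.begin(), dxc.end(), 0.0);
    for (long long od = 0; od < Do; ++od) {
      im2col_chunk(xc.data(), col, od, Cin, D, H, W, kd, kh, kw, sd, sh, sw,
                   pd, ph, pw, Ho, Wo);
      for (long long ow = 0; ow < Wo; ++ow)
        for (long long oh = 0; oh < Ho; ++oh) {
          const double* src = dop + idx5(b, 0, od, oh, ow, B, Cout, Do, Ho);
          double* dst = dmat.colptr(oh + Ho * ow);
          for (long long co = 0; co < Cout; ++co) dst[co] = src[B * co];
        }
      dW += dmat * col.t();
      db += arma::sum(dmat, 1);
      if (!need_dx) continue;
      arma::mat dcol = Wm.t() * dmat;  // K x (Ho*Wo)
      const long long d0 = (long long)od * sd - pd;
      for (long long ow = 0; ow < Wo; ++ow) {
        const long long w0 = ow * sw - pw;
        for (long long oh = 0; oh < Ho; ++oh) {
          const long long h0 = oh * sh - ph;
          const double* cj = dcol.colptr(oh + Ho * ow);
          long long r = 0;
          for (int zw = 0; zw < kw; ++zw) {
            const long long w = w0 + zw;
            for (int zh = 0; zh < kh; ++zh) {
              const long long h = h0 + zh;
              for (int zd = 0; zd < kd; ++zd) {
                const long long d = d0 + zd;
                if (d >= 0 && d < D && h >= 0 && h < H && w >= 0 && w < W) {
                  double* dst = dxc.data() + Cin * (d + D * (h + H * w));
                  for (long long ci = 0; ci < Cin; ++ci) dst[ci] += cj[r + ci];
                }
                r += Cin;
              }
            }
          }
        }
      }
    }
    // scatter the repacked input gradient back to the (B,C,D,H,W) layout
    if (!need_dx) continue;
    for (long long w = 0; w < W; ++w)
      for (long long h = 0; h < H; ++h)
        for (long long d = 0; d < D; ++d) {
          const double* src = dxc.data() + Cin * (d + D * (h + H * w));
          double* dst = dxp + idx5(b, 0, d, h, w, B, Cin, D, H);
          for (long long ci = 0; ci < Cin; ++ci) dst[B * ci] = src[ci];
        }
  }
  NumericMatrix dWr(Cout, K);
  std::copy(dW.begin(), dW.end(), dWr.begin());
  NumericVector dbr(Cout);
  std::copy(db.begin(), db.end(), dbr.begin());
  return List::create(_["dx"] = dx, _["dw"] = dWr, _["db"] = dbr);
}

// [[Rcpp::export(name = ".maxpool3d_forward_cpp")]]
List maxpool3d_forward_cpp(NumericVector x, IntegerVector xdim,
                           IntegerVector kernel, IntegerVector stride,
                           IntegerVector pad) {
  const long long B = xdim[0], C = xdim[1], D = xdim[2], H = xdim[3],
                  W = xdim[4];
  const int kd = kernel[0], kh = kernel[1], kw = kernel[2];
  const int sd = stride[0], sh = stride[1], sw = stride[2];
  const int pd = pad[0], ph = pad[1], pw = pad[2];
  const long long Do = out_size(D, kd, sd, pd), Ho = out_size(H, kh, sh, ph),
                  Wo = out_size(W, kw, sw, pw);
  if (Do < 1 || Ho < 1 || Wo < 1)
    stop("maxpool3d: output size would be < 1 along some axis");

  NumericVector out((R_xlen_t)(B * C * Do * Ho * Wo));
  out.attr("dim") = IntegerVector::create(B, C, Do, Ho, Wo);
  NumericVector arg(out.size());  // 1-based linear index into x
  const double* xp = x.begin();
  double* op = out.begin();
  double* ap = arg.begin();

  long long o = 0;
  for (long long ow = 0; ow < Wo; ++ow)
    for (long long oh = 0; oh < Ho; ++oh)
      for (long long od = 0; od < Do; ++od)
        for (long long c = 0; c < C; ++c)
          for (long long b = 0; b < B; ++b) {
            double best = R_NegInf;
            long long besti = -1;
            for (int zw = 0; zw < kw; ++zw) {
              const long long w = ow * sw - pw + zw;
              if (w < 0 || w >= W) continue;
              for (int zh = 0; zh < kh; ++zh) {
                const long long h = oh * sh - ph + zh;
                if (h < 0 || h >= H) continue;
                for (int zd = 0; zd < kd; ++zd) {
                  const long long d = od * sd - pd + zd;
                  if (d < 0 || d >= D) continue;
                  const long long i = idx5(b, c, d, h, w, B, C, D, H);
                  if (xp[i] > best) { best = xp[i]; besti = i; }
                }
              }
            }
            // o runs b fastest .. ow slowest = idx5(b,c,od,oh,ow,...)
            op[o] = best;
            ap[o] = (double)(besti + 1);
            ++o;
          }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export(name = ".maxpool3d_backward_cpp")]]
NumericVector maxpool3d_backward_cpp(NumericVector dout, NumericVector argmax,
                                     R_xlen_t xlen, IntegerVector xdim) {
  NumericVector dx(xlen);
  dx.attr("dim") = xdim;
  const double* dop = dout.begin();
  const double* ap = argmax.begin();
  double* dxp = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i) {
    const long long t = (long long)ap[i] - 1;
    if (t >= 0) dxp[t] += dop[i];
  }
  return dx;
}

// ---- fused normalization / activation helpers ---------------------------
// x is treated as an R x M matrix (column-major), R = B*C rows; per-row
// statistics feed batch or instance normalization on the R side.

// [[Rcpp::export(name = ".row_stats_cpp")]]
NumericMatrix row_stats_cpp(NumericVector x, int nrow) {
  const R_xlen_t n = x.size();
  const R_xlen_t M = n / nrow;
  NumericMatrix out(2, nrow);
  const double* xp = x.begin();
  std::vector<double> s((size_t)nrow, 0.0), s2((size_t)nrow, 0.0);
  R_xlen_t i = 0;
  for (R_xlen_t m = 0; m < M; ++m)
    for (int r = 0; r < nrow; ++r, ++i) {
      const double v = xp[i];
      s[r] += v;
      s2[r] += v * v;
    }
  for (int r = 0; r < nrow; ++r) { out(0, r) = s[r]; out(1, r) = s2[r]; }
  return out;
}

// y = (x - mu[r]) * inv[r] * g[r] + b[r]; also returns xhat for backward
// [[Rcpp::export(name = ".bn_apply_cpp")]]
List bn_apply_cpp(NumericVector x, NumericVector mu, NumericVector inv,
                  NumericVector g, NumericVector b) {
  const int R = mu.size();
  const R_xlen_t n = x.size();
  NumericVector y(n), xhat(n);
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  R_xlen_t i = 0;
  const R_xlen_t M = n / R;
  for (R_xlen_t m = 0; m < M; ++m)
    for (int r = 0; r < R; ++r, ++i) {
      const double h = (xp[i] - mu[r]) * inv[r];
      hp[i] = h;
      yp[i] = h * g[r] + b[r];
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// row-wise sum(dout) and sum(dout * xhat) in one pass
// [[Rcpp::export(name = ".bn_reduce_cpp")]]
NumericMatrix bn_reduce_cpp(NumericVector dout, NumericVector xhat,
                            int nrow) {
  const R_xlen_t n = dout.size();
  const R_xlen_t M = n / nrow;
  NumericMatrix out(2, nrow);
  const double* dp = dout.begin();
  const double* hp = xhat.begin();
  std::vector<double> s1((size_t)nrow, 0.0), s2((size_t)nrow, 0.0);
  R_xlen_t i = 0;
  for (R_xlen_t m = 0; m < M; ++m)
    for (int r = 0; r < nrow; ++r, ++i) {
      s1[r] += dp[i];
      s2[r] += dp[i] * hp[i];
    }
  for (int r = 0; r < nrow; ++r) { out(0, r) = s1[r]; out(1, r) = s2[r]; }
  return out;
}

// dx = (dout * g[r] - c1[r] - xhat * c2[r]) * inv[r]
// [[Rcpp::export(name = ".bn_dx_cpp")]]
NumericVector bn_dx_cpp(NumericVector dout, NumericVector xhat,
                        NumericVector g, NumericVector c1, NumericVector c2,
                        NumericVector inv) {
  const int R = g.size();
  const R_xlen_t n = dout.size();
  NumericVector dx(n);
  const double* dp = dout.begin();
  const double* hp = xhat.begin();
  double* op = dx.begin();
  const R_xlen_t M = n / R;
  R_xlen_t i = 0;
  for (R_xlen_t m = 0; m < M; ++m)
    for (int r = 0; r < R; ++r, ++i)
      op[i] = (dp[i] * g[r] - c1[r] - hp[i] * c2[r]) * inv[r];
  return dx;
}

// [[Rcpp::export(name = ".relu_fwd_cpp")]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// dx = dout where the stored output was positive (out > 0 <=> x > 0)
// [[Rcpp::export(name = ".relu_bwd_cpp")]]
NumericVector relu_bwd_cpp(NumericVector dout, NumericVector out) {
  NumericVector dx(dout.size());
  const double* dp = dout.begin();
  const double* op = out.begin();
  double* xp = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    xp[i] = op[i] > 0 ? dp[i] : 0.0;
  return dx;
}
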