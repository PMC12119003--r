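// Dense NCHW tensor kernels: grouped 2-D convolution (im2col + gemm),
// max pooling with saved argmax, broadcasting binary ops and shape
// reductions. Layout matches R arrays with dim = c(N, C, H, W), i.e.
// offset(n,c,h,w) = n + N*(c + C*(h + H*w)), all zero-based here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// im2col for one image and one channel group.
// col is (Cg*Kh*Kw) x (Ho*Wo), column-major (arma default).
static void im2col_one(const double* x, int N, int C, int H, int W,
                       int n, int c0, int Cg, int Kh, int Kw,
                       int sh, int sw, int ph, int pw,
                       int Ho, int Wo, arma::mat& col) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int ocol = oh + Ho * 0 + 0; // filled below
      (void)ocol;
      double* dst = col.colptr(oh * Wo + ow);
      int r = 0;
      for (int c = 0; c < Cg; ++c) {
        const int cc = c0 + c;
        for (int kh = 0; kh < Kh; ++kh) {
          const int ih = oh * sh - ph + kh;
          for (int kw = 0; kw < Kw; ++kw, ++r) {
            const int iw = ow * sw - pw + kw;
            if (ih >= 0 && ih < H && iw >= 0 && iw < W) {
              dst[r] = x[n + (size_t)N * (cc + (size_t)C * (ih + (size_t)H * iw))];
            } else {
              dst[r] = 0.0;
            }
          }
        }
      }
    }
  }
}

static void col2im_one(double* dx, int N, int C, int H, int W,
                       int n, int c0, int Cg, int Kh, int Kw,
                       int sh, int sw, int ph, int pw,
                       int Ho, int Wo, const arma::mat& col) {
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const double* src = col.colptr(oh * Wo + ow);
      int r = 0;
      for (int c = 0; c < Cg; ++c) {
        const int cc = c0 + c;
        for (int kh = 0; kh < Kh; ++kh) {
          const int ih = oh * sh - ph + kh;
          for (int kw = 0; kw < Kw; ++kw, ++r) {
            const int iw = ow * sw - pw + kw;
            if (ih >= 0 && ih < H && iw >= 0 && iw < W) {
              dx[n + (size_t)N * (cc + (size_t)C * (ih + (size_t)H * iw))] += src[r];
            }
          }
        }
      }
    }
  }
}

// Pack weights of one group as a (Coutg) x (Cg*Kh*Kw) arma matrix.
// R weight array dim = c(Cout, Cg, Kh, Kw).
static arma::mat pack_w(const double* w, int Cout, int Cg, int Kh, int Kw,
                        int co0, int Coutg) {
  arma::mat Wm(Coutg, Cg * Kh * Kw);
  for (int c = 0; c < Cg; ++c)
    for (int kh = 0; kh < Kh; ++kh)
      for (int kw = 0; kw < Kw; ++kw) {
        const int r = c * Kh * Kw + kh * Kw + kw;
        for (int co = 0; co < Coutg; ++co) {
          Wm(co, r) = w[(co0 + co) +
                        (size_t)Cout * (c + (size_t)Cg * (kh + (size_t)Kh * kw))];
        }
      }
  return Wm;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, NumericVector w,
                         Nullable<NumericVector> bias,
                         int sh, int sw, int ph, int pw, int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[0], Cg = wd[1], Kh = wd[2], Kw = wd[3];
  const int Ho = out_dim(H, Kh, sh, ph), Wo = out_dim(W, Kw, sw, pw);
  const int Coutg = Cout / groups;
  if (Cg * groups != C || Coutg * groups != Cout)
    stop("conv2d: groups incompatible with channel counts");
  NumericVector y(static_cast<R_xlen_t>(N) * Cout * Ho * Wo);
  y.attr("dim") = IntegerVector::create(N, Cout, Ho, Wo);
  const double* xp = x.begin();
  double* yp = y.begin();
  const double* bp = bias.isNotNull() ? NumericVector(bias).begin() : nullptr;
  arma::mat col(Cg * Kh * Kw, Ho * Wo);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm = pack_w(w.begin(), Cout, Cg, Kh, Kw, g * Coutg, Coutg);
    for (int n = 0; n < N; ++n) {
      im2col_one(xp, N, C, H, W, n, g * Cg, Cg, Kh, Kw, sh, sw, ph, pw, Ho, Wo, col);
      arma::mat Y = Wm * col; // Coutg x (Ho*Wo)
      for (int q = 0; q < Ho * Wo; ++q) {
        const int oh = q / Wo, ow = q % Wo; // col index used was oh*Wo+ow
        for (int co = 0; co < Coutg; ++co) {
          const int cc = g * Coutg + co;
          double v = Y(co, oh * Wo + ow);
          if (bp) v += bp[cc];
          yp[n + (size_t)N * (cc + (size_t)Cout * (oh + (size_t)Ho * ow))] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector w, NumericVector dy,
                         bool has_bias, int sh, int sw, int ph, int pw,
                         int groups) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Cout = wd[0], Cg = wd[1], Kh = wd[2], Kw = wd[3];
  const int Ho = out_dim(H, Kh, sh, ph), Wo = out_dim(W, Kw, sw, pw);
  const int Coutg = Cout / groups;
  NumericVector dx(x.size()), dw(w.size());
  dx.attr("dim") = xd; dw.attr("dim") = wd;
  NumericVector db(has_bias ? Cout : 0);
  const double* xp = x.begin();
  const double* dyp = dy.begin();
  arma::mat col(Cg * Kh * Kw, Ho * Wo);
  arma::mat dYm(Coutg, Ho * Wo);
  for (int g = 0; g < groups; ++g) {
    arma::mat Wm = pack_w(w.begin(), Cout, Cg, Kh, Kw, g * Coutg, Coutg);
    arma::mat dWm(Coutg, Cg * Kh * Kw, arma::fill::zeros);
    for (int n = 0; n < N; ++n) {
      for (int q = 0; q < Ho * Wo; ++q) {
        const int oh = q / Wo, ow = q % Wo;
        for (int co = 0; co < Coutg; ++co) {
          const int cc = g * Coutg + co;
          dYm(co, oh * Wo + ow) =
            dyp[n + (size_t)N * (cc + (size_t)Cout * (oh + (size_t)Ho * ow))];
        }
      }
      im2col_one(xp, N, C, H, W, n, g * Cg, Cg, Kh, Kw, sh, sw, ph, pw, Ho, Wo, col);
      dWm += dYm * col.t();
      arma::mat dcol = Wm.t() * dYm;
      col2im_one(dx.begin(), N, C, H, W, n, g * Cg, Cg, Kh, Kw,
                 sh, sw, ph, pw, Ho, Wo, dcol);
    }
    // unpack dWm back into dw
    for (int c = 0; c < Cg; ++c)
      for (int kh = 0; kh < Kh; ++kh)
        for (int kw = 0; kw < Kw; ++kw) {
          const int r = c * Kh * Kw + kh * Kw + kw;
          for (int co = 0; co < Coutg; ++co)
            dw[(g * Coutg + co) +
               (size_t)Cout * (c + (size_t)Cg * (kh + (size_t)Kh * kw))] = dWm(co, r);
        }
  }
  if (has_bias) {
    for (int n = 0; n < N; ++n)
      for (int cc = 0; cc < Cout; ++cc)
        for (int oh = 0; oh < Ho; ++oh)
          for (int ow = 0; ow < Wo; ++ow)
            db[cc] += dyp[n + (size_t)N * (cc + (size_t)Cout * (oh + (size_t)Ho * ow))];
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool2d(NumericVector x, int k, int s, int p) {
  IntegerVector xd = x.attr("dim");
  const int N = xd[0], C = xd[1], H = xd[2], W = xd[3];
  const int Ho = out_dim(H, k, s, p), Wo = out_dim(W, k, s, p);
  NumericVector y(static_cast<R_xlen_t>(N) * C * Ho * Wo);
  IntegerVector idx(y.size()); // 1-based linear index into x
  y.attr("dim") = IntegerVector::create(N, C, Ho, Wo);
  const double* xp = x.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int c = 0; c < C; ++c)
        for (int n = 0; n < N; ++n) {
          double best = R_NegInf; size_t bi = 0;
          for (int kh = 0; kh < k; ++kh) {
            const int ih = oh * s - p + kh;
            if (ih < 0 || ih >= H) continue;
            for (int kw = 0; kw < k; ++kw) {
              const int iw = ow * s - p + kw;
              if (iw < 0 || iw >= W) continue;
              const size_t off = n + (size_t)N * (c + (size_t)C * (ih + (size_t)H * iw));
              if (xp[off] > best) { best = xp[off]; bi = off; }
            }
          }
          const size_t o = n + (size_t)N * (c + (size_t)C * (oh + (size_t)Ho * ow));
          y[o] = best; idx[o] = static_cast<int>(bi) + 1;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2d_backward(NumericVector dy, IntegerVector idx,
                                     IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

// Broadcasting binary op on arrays of equal ndim; every axis of each operand
// is either full-size or 1. op: 0 add, 1 sub, 2 mul, 3 div.
// [[Rcpp::export]]
NumericVector cpp_bcast_bin(NumericVector a, NumericVector b,
                            IntegerVector ad, IntegerVector bd, int op) {
  const int nd = ad.size();
  std::vector<int> od(nd);
  for (int i = 0; i < nd; ++i) od[i] = std::max(ad[i], bd[i]);
  R_xlen_t n = 1; for (int i = 0; i < nd; ++i) n *= od[i];
  std::vector<R_xlen_t> sa(nd), sb(nd);
  R_xlen_t ca = 1, cb = 1;
  for (int i = 0; i < nd; ++i) {
    sa[i] = (ad[i] == 1) ? 0 : ca; ca *= ad[i];
    sb[i] = (bd[i] == 1) ? 0 : cb; cb *= bd[i];
  }
  NumericVector out(n);
  out.attr("dim") = IntegerVector(od.begin(), od.end());
  std::vector<int> ix(nd, 0);
  const double* ap = a.begin(); const double* bp = b.begin();
  R_xlen_t oa = 0, ob = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    double av = ap[oa], bv = bp[ob], r = 0.0;
    switch (op) {
      case 0: r = av + bv; break;
      case 1: r = av - bv; break;
      case 2: r = av * bv; break;
      default: r = av / bv; break;
    }
    out[i] = r;
    for (int d = 0; d < nd; ++d) {
      if (++ix[d] < od[d]) { oa += sa[d]; ob += sb[d]; break; }
      ix[d] = 0; oa -= sa[d] * (od[d] - 1); ob -= sb[d] * (od[d] - 1);
    }
  }
  return out;
}

// Sum x (dims xd) down to shape od (each axis either equal or 1).
// [[Rcpp::export]]
NumericVector cpp_sum_to(NumericVector x, IntegerVector xd, IntegerVector od) {
  const int nd = xd.size();
  R_xlen_t no = 1; for (int i = 0; i < nd; ++i) no *= od[i];
  std::vector<R_xlen_t> so(nd);
  R_xlen_t c = 1;
  for (int i = 0; i < nd; ++i) { so[i] = (od[i] == 1) ? 0 : c; c *= od[i]; }
  NumericVector out(no);
  out.attr("dim") = od;
  std::vector<int> ix(nd, 0);
  R_xlen_t oo = 0;
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    out[oo] += x[i];
    for (int d = 0; d < nd; ++d) {
      if (++ix[d] < xd[d]) { if (od[d] != 1) oo += so[d]; break; }
      ix[d] = 0; if (od[d] != 1) oo -= so[d] * (xd[d] - 1);
    }
  }
  return out;
}
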