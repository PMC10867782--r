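// Convolution kernels backing the autodiff graph.
//
// Array layout convention (matches R): images are H x W x C numeric arrays,
// column-major, so x(h, w, c) = x[h + H*(w + W*c)] with 0-based indices.
// Convolution weights are kh x kw x Cin x Cout arrays. Zero padding.
//
// The deformable convolution displaces every kernel tap by a learned
// per-output-position 2-D offset and samples the input bilinearly (zero
// outside bounds); gradients flow to the input, the weights and the offsets.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double at3(const double* x, int H, int W, int h, int w, int c) {
  return x[h + H * (w + W * c)];
}

// Build the im2col matrix: rows indexed r = t + K*c with tap t = ki + kh*kj,
// columns indexed q = oi + Ho*oj.
static arma::mat im2col(const double* x, int H, int W, int Cin,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo) {
  const int K = kh * kw;
  arma::mat cols(K * Cin, (size_t)Ho * Wo, arma::fill::zeros);
  for (int oj = 0; oj < Wo; ++oj) {
    for (int oi = 0; oi < Ho; ++oi) {
      const size_t q = oi + (size_t)Ho * oj;
      for (int kj = 0; kj < kw; ++kj) {
        const int j = oj * stride - pad + kj;
        if (j < 0 || j >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int i = oi * stride - pad + ki;
          if (i < 0 || i >= H) continue;
          const int t = ki + kh * kj;
          for (int c = 0; c < Cin; ++c)
            cols(t + K * c, q) = at3(x, H, W, i, j, c);
        }
      }
    }
  }
  return cols;
}

static arma::mat weight_mat(const NumericVector& Wt, int kh, int kw,
                            int Cin, int Cout) {
  const int K = kh * kw;
  arma::mat Wm(Cout, K * Cin);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          Wm(o, (ki + kh * kj) + K * c) =
            Wt[ki + kh * (kj + (size_t)kw * (c + (size_t)Cin * o))];
  return Wm;
}

static void check_conv_dims(const IntegerVector& xd, const IntegerVector& wd,
                            int stride, int pad, int& Ho, int& Wo) {
  if (xd.size() != 3) stop("input must be an H x W x C array");
  if (wd.size() != 4) stop("weights must be a kh x kw x Cin x Cout array");
  if (wd[2] != xd[2]) stop("input channels do not match kernel Cin");
  // floor((H + 2p - k)/s) + 1, the usual convolution output size
  Ho = (xd[0] + 2 * pad - wd[0]) / stride + 1;
  Wo = (xd[1] + 2 * pad - wd[1]) / stride + 1;
  if (xd[0] + 2 * pad < wd[0] || xd[1] + 2 * pad < wd[1])
    stop("kernel larger than padded input");
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_forward(NumericVector x, NumericVector Wt,
                                 int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  int Ho, Wo;
  check_conv_dims(xd, wd, stride, pad, Ho, Wo);
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  arma::mat cols = im2col(REAL(x), H, W, Cin, kh, kw, stride, pad, Ho, Wo);
  arma::mat Wm = weight_mat(Wt, kh, kw, Cin, Cout);
  arma::mat out = Wm * cols;  // Cout x (Ho*Wo)
  NumericVector res((size_t)Ho * Wo * Cout);
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  double* rp = REAL(res);
  for (int o = 0; o < Cout; ++o)
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
      rp[q + (size_t)Ho * Wo * o] = out(o, q);
  return res;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, NumericVector Wt,
                         NumericVector gout, int stride, int pad,
                         bool want_gw = true) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  int Ho, Wo;
  check_conv_dims(xd, wd, stride, pad, Ho, Wo);
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int K = kh * kw;

  arma::mat gout_m(Cout, (size_t)Ho * Wo);
  const double* gp = REAL(gout);
  for (int o = 0; o < Cout; ++o)
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
      gout_m(o, q) = gp[q + (size_t)Ho * Wo * o];

  arma::mat Wm = weight_mat(Wt, kh, kw, Cin, Cout);
  arma::mat gW_m;
  if (want_gw) {
    arma::mat cols = im2col(REAL(x), H, W, Cin, kh, kw, stride, pad, Ho, Wo);
    gW_m = gout_m * cols.t();               // Cout x K*Cin
  }
  arma::mat gcols = Wm.t() * gout_m;        // K*Cin x Ho*Wo

  NumericVector gx((size_t)H * W * Cin);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  double* gxp = REAL(gx);
  for (int oj = 0; oj < Wo; ++oj)
    for (int oi = 0; oi < Ho; ++oi) {
      const size_t q = oi + (size_t)Ho * oj;
      for (int kj = 0; kj < kw; ++kj) {
        const int j = oj * stride - pad + kj;
        if (j < 0 || j >= W) continue;
        for (int ki = 0; ki < kh; ++ki) {
          const int i = oi * stride - pad + ki;
          if (i < 0 || i >= H) continue;
          const int t = ki + kh * kj;
          for (int c = 0; c < Cin; ++c)
            gxp[i + H * (j + (size_t)W * c)] += gcols(t + K * c, q);
        }
      }
    }

  if (!want_gw) return List::create(_["gx"] = gx);
  NumericVector gW((size_t)kh * kw * Cin * Cout);
  gW.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  double* gWp = REAL(gW);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          gWp[ki + kh * (kj + (size_t)kw * (c + (size_t)Cin * o))] =
            gW_m(o, (ki + kh * kj) + K * c);

  return List::create(_["gx"] = gx, _["gW"] = gW);
}

// Bilinear sample with zero outside bounds.
static inline double bilin(const double* x, int H, int W, int c,
                           double pi, double pj) {
  const int i0 = (int)std::floor(pi), j0 = (int)std::floor(pj);
  const double di = pi - i0, dj = pj - j0;
  double v = 0.0;
  for (int a = 0; a <= 1; ++a)
    for (int b = 0; b <= 1; ++b) {
      const int ii = i0 + a, jj = j0 + b;
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      const double w = (a ? di : 1.0 - di) * (b ? dj : 1.0 - dj);
      v += w * at3(x, H, W, ii, jj, c);
    }
  return v;
}

static void check_offset_dims(const IntegerVector& od, int Ho, int Wo, int K) {
  if (od.size() != 3 || od[0] != Ho || od[1] != Wo || od[2] != 2 * K)
    stop("offset field must be Ho x Wo x 2K");
}

// Offsets layout: channel 2t is the row displacement and 2t+1 the column
// displacement of tap t = ki + kh*kj (0-based).
// [[Rcpp::export]]
NumericVector cpp_deform_conv_forward(NumericVector x, NumericVector Wt,
                                      NumericVector off, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  int Ho, Wo;
  check_conv_dims(xd, wd, stride, pad, Ho, Wo);
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int K = kh * kw;
  check_offset_dims(off.attr("dim"), Ho, Wo, K);
  const double* xp = REAL(x);
  const double* op = REAL(off);

  arma::mat cols(K * Cin, (size_t)Ho * Wo, arma::fill::zeros);
  for (int oj = 0; oj < Wo; ++oj)
    for (int oi = 0; oi < Ho; ++oi) {
      const size_t q = oi + (size_t)Ho * oj;
      for (int t = 0; t < K; ++t) {
        const int ki = t % kh, kj = t / kh;
        const double dr = at3(op, Ho, Wo, oi, oj, 2 * t);
        const double dc = at3(op, Ho, Wo, oi, oj, 2 * t + 1);
        const double pi = oi * stride - pad + ki + dr;
        const double pj = oj * stride - pad + kj + dc;
        for (int c = 0; c < Cin; ++c)
          cols(t + K * c, q) = bilin(xp, H, W, c, pi, pj);
      }
    }

  arma::mat Wm = weight_mat(Wt, kh, kw, Cin, Cout);
  arma::mat out = Wm * cols;
  NumericVector res((size_t)Ho * Wo * Cout);
  res.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  double* rp = REAL(res);
  for (int o = 0; o < Cout; ++o)
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
      rp[q + (size_t)Ho * Wo * o] = out(o, q);
  return res;
}

// [[Rcpp::export]]
List cpp_deform_conv_backward(NumericVector x, NumericVector Wt,
                              NumericVector off, NumericVector gout,
                              int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = Wt.attr("dim");
  int Ho, Wo;
  check_conv_dims(xd, wd, stride, pad, Ho, Wo);
  const int H = xd[0], W = xd[1], Cin = xd[2];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int K = kh * kw;
  check_offset_dims(off.attr("dim"), Ho, Wo, K);
  const double* xp = REAL(x);
  const double* op = REAL(off);

  // Rebuild sampled columns (needed for gW) and tap positions.
  arma::mat cols(K * Cin, (size_t)Ho * Wo, arma::fill::zeros);
  std::vector<double> pis((size_t)K * Ho * Wo), pjs((size_t)K * Ho * Wo);
  for (int oj = 0; oj < Wo; ++oj)
    for (int oi = 0; oi < Ho; ++oi) {
      const size_t q = oi + (size_t)Ho * oj;
      for (int t = 0; t < K; ++t) {
        const int ki = t % kh, kj = t / kh;
        const double pi = oi * stride - pad + ki + at3(op, Ho, Wo, oi, oj, 2 * t);
        const double pj = oj * stride - pad + kj + at3(op, Ho, Wo, oi, oj, 2 * t + 1);
        pis[t + (size_t)K * q] = pi;
        pjs[t + (size_t)K * q] = pj;
        for (int c = 0; c < Cin; ++c)
          cols(t + K * c, q) = bilin(xp, H, W, c, pi, pj);
      }
    }

  arma::mat gout_m(Cout, (size_t)Ho * Wo);
  const double* gp = REAL(gout);
  for (int o = 0; o < Cout; ++o)
    for (size_t q = 0; q < (size_t)Ho * Wo; ++q)
      gout_m(o, q) = gp[q + (size_t)Ho * Wo * o];

  arma::mat Wm = weight_mat(Wt, kh, kw, Cin, Cout);
  arma::mat gW_m = gout_m * cols.t();
  arma::mat gcols = Wm.t() * gout_m;

  NumericVector gx((size_t)H * W * Cin);
  gx.attr("dim") = IntegerVector::create(H, W, Cin);
  NumericVector goff((size_t)Ho * Wo * 2 * K);
  goff.attr("dim") = IntegerVector::create(Ho, Wo, 2 * K);
  double* gxp = REAL(gx);
  double* gop = REAL(goff);

  for (size_t q = 0; q < (size_t)Ho * Wo; ++q) {
    const int oi = q % Ho, oj = q / Ho;
    for (int t = 0; t < K; ++t) {
      const double pi = pis[t + (size_t)K * q], pj = pjs[t + (size_t)K * q];
      const int i0 = (int)std::floor(pi), j0 = (int)std::floor(pj);
      const double di = pi - i0, dj = pj - j0;
      double g_dr = 0.0, g_dc = 0.0;
      for (int c = 0; c < Cin; ++c) {
        const double g = gcols(t + K * c, q);
        if (g == 0.0) continue;
        double dpi = 0.0, dpj = 0.0;
        for (int a = 0; a <= 1; ++a)
          for (int b = 0; b <= 1; ++b) {
            const int ii = i0 + a, jj = j0 + b;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            const double wi = (a ? di : 1.0 - di);
            const double wj = (b ? dj : 1.0 - dj);
            gxp[ii + H * (jj + (size_t)W * c)] += g * wi * wj;
            const double xv = at3(xp, H, W, ii, jj, c);
            dpi += (a ? wj : -wj) * xv;
            dpj += (b ? wi : -wi) * xv;
          }
        g_dr += g * dpi;
        g_dc += g * dpj;
      }
      gop[oi + Ho * (oj + (size_t)Wo * (2 * t))] = g_dr;
      gop[oi + Ho * (oj + (size_t)Wo * (2 * t + 1))] = g_dc;
    }
  }

  NumericVector gW((size_t)kh * kw * Cin * Cout);
  gW.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  double* gWp = REAL(gW);
  for (int o = 0; o < Cout; ++o)
    for (int c = 0; c < Cin; ++c)
      for (int kj = 0; kj < kw; ++kj)
        for (int ki = 0; ki < kh; ++ki)
          gWp[ki + kh * (kj + (size_t)kw * (c + (size_t)Cin * o))] =
            gW_m(o, (ki + kh * kj) + K * c);

  return List::create(_["gx"] = gx, _["gW"] = gW, _["goff"] = goff);
}

// Bilinear resize used for conditioning images and data augmentation
// (half-pixel center alignment, edge clamped).
// [[Rcpp::export]]
NumericVector cpp_resize_bilinear(NumericVector x, int Ho, int Wo) {
  IntegerVector xd = x.attr("dim");
  if (xd.size() != 3) stop("input must be an H x W x C array");
  const int H = xd[0], W = xd[1], C = xd[2];
  const double* xp = REAL(x);
  NumericVector res((size_t)Ho * Wo * C);
  res.attr("dim") = IntegerVector::create(Ho, Wo, C);
  double* rp = REAL(res);
  for (int c = 0; c < C; ++c)
    for (int oj = 0; oj < Wo; ++oj) {
      double pj = (oj + 0.5) * (double)W / Wo - 0.5;
      pj = std::min(std::max(pj, 0.0), (double)(W - 1));
      for (int oi = 0; oi < Ho; ++oi) {
        double pi = (oi + 0.5) * (double)H / Ho - 0.5;
        pi = std::min(std::max(pi, 0.0), (double)(H - 1));
        const int i0 = (int)std::floor(pi), j0 = (int)std::floor(pj);
        const int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
        const double di = pi - i0, dj = pj - j0;
        rp[oi + Ho * (oj + (size_t)Wo * c)] =
          (1 - di) * (1 - dj) * at3(xp, H, W, i0, j0, c) +
          (1 - di) * dj * at3(xp, H, W, i0, j1, c) +
          di * (1 - dj) * at3(xp, H, W, i1, j0, c) +
          di * dj * at3(xp, H, W, i1, j1, c);
      }
    }
  return res;
}
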