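#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, C, N), column-major, so the index of
// (h, w, c, n) (0-based) is h + H*(w + W*(c + C*n)).  Convolution weights
// have dim (kh, kw, C_in, C_out).  Padding is zero-padding; stride is
// isotropic.  Loops are ordered so the innermost runs contiguously along h
// in both input and output, which lets the compiler vectorise.

static inline int out_dim(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], CI = wdim[2], CO = wdim[3];
  if (CI != C) stop("conv2d: input channels (%d) do not match weights (%d)", C, CI);
  const int OH = out_dim(H, KH, stride, pad), OW = out_dim(W, KW, stride, pad);
  NumericVector y(static_cast<R_xlen_t>(OH) * OW * CO * N);
  const double *xp = x.begin(), *wp = w.begin();
  const double *bp = b.begin();
  const bool has_bias = b.size() >= CO;
  double *yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int oc = 0; oc < CO; ++oc) {
      double *yplane = yp + static_cast<R_xlen_t>(OH) * OW * (oc + CO * n);
      if (has_bias) {
        const double bias = bp[oc];
        for (int i = 0; i < OH * OW; ++i) yplane[i] = bias;
      }
      for (int ic = 0; ic < C; ++ic) {
        const double *xplane = xp + static_cast<R_xlen_t>(H) * W * (ic + C * n);
        for (int kw = 0; kw < KW; ++kw)
          for (int kh = 0; kh < KH; ++kh) {
            const double wv = wp[kh + KH * (kw + KW * (ic + CI * oc))];
            if (wv == 0.0) continue;
            for (int ow = 0; ow < OW; ++ow) {
              const int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              const double *xcol = xplane + static_cast<R_xlen_t>(H) * iw;
              double *ycol = yplane + static_cast<R_xlen_t>(OH) * ow;
              if (stride == 1) {
                int oh0 = std::max(0, pad - kh);
                int oh1 = std::min(OH, H + pad - kh);
                const double *xc = xcol - pad + kh;
                for (int oh = oh0; oh < oh1; ++oh)
                  ycol[oh] += wv * xc[oh];
              } else {
                for (int oh = 0; oh < OH; ++oh) {
                  const int ih = oh * stride - pad + kh;
                  if (ih < 0 || ih >= H) continue;
                  ycol[oh] += wv * xcol[ih];
                }
              }
            }
          }
      }
    }
  y.attr("dim") = IntegerVector::create(OH, OW, CO, N);
  return y;
}

// [[Rcpp::export]]
NumericVector conv2d_bwd_input_cpp(NumericVector gy, IntegerVector ydim,
                                   NumericVector w, IntegerVector wdim,
                                   IntegerVector xdim, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], CI = wdim[2], CO = wdim[3];
  const int OH = ydim[0], OW = ydim[1];
  NumericVector gx(static_cast<R_xlen_t>(H) * W * C * N);
  const double *gp = gy.begin(), *wp = w.begin();
  double *xp = gx.begin();
  for (int n = 0; n < N; ++n)
    for (int oc = 0; oc < CO; ++oc) {
      const double *gplane = gp + static_cast<R_xlen_t>(OH) * OW * (oc + CO * n);
      for (int ic = 0; ic < C; ++ic) {
        double *xplane = xp + static_cast<R_xlen_t>(H) * W * (ic + C * n);
        for (int kw = 0; kw < KW; ++kw)
          for (int kh = 0; kh < KH; ++kh) {
            const double wv = wp[kh + KH * (kw + KW * (ic + CI * oc))];
            if (wv == 0.0) continue;
            for (int ow = 0; ow < OW; ++ow) {
              const int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              double *xcol = xplane + static_cast<R_xlen_t>(H) * iw;
              const double *gcol = gplane + static_cast<R_xlen_t>(OH) * ow;
              if (stride == 1) {
                int oh0 = std::max(0, pad - kh);
                int oh1 = std::min(OH, H + pad - kh);
                double *xc = xcol - pad + kh;
                for (int oh = oh0; oh < oh1; ++oh)
                  xc[oh] += wv * gcol[oh];
              } else {
                for (int oh = 0; oh < OH; ++oh) {
                  const int ih = oh * stride - pad + kh;
                  if (ih < 0 || ih >= H) continue;
                  xcol[ih] += wv * gcol[oh];
                }
              }
            }
          }
      }
    }
  gx.attr("dim") = xdim;
  return gx;
}

// [[Rcpp::export]]
List conv2d_bwd_weight_cpp(NumericVector x, IntegerVector xdim,
                           NumericVector gy, IntegerVector ydim,
                           IntegerVector wdim, int stride, int pad) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int KH = wdim[0], KW = wdim[1], CI = wdim[2], CO = wdim[3];
  const int OH = ydim[0], OW = ydim[1];
  NumericVector gw(static_cast<R_xlen_t>(KH) * KW * CI * CO);
  NumericVector gb(CO);
  const double *xp = x.begin(), *gp = gy.begin();
  double *wp = gw.begin(), *bp = gb.begin();
  for (int n = 0; n < N; ++n)
    for (int oc = 0; oc < CO; ++oc) {
      const double *gplane = gp + static_cast<R_xlen_t>(OH) * OW * (oc + CO * n);
      double bsum = 0.0;
      for (int i = 0; i < OH * OW; ++i) bsum += gplane[i];
      bp[oc] += bsum;
      for (int ic = 0; ic < C; ++ic) {
        const double *xplane = xp + static_cast<R_xlen_t>(H) * W * (ic + C * n);
        for (int kw = 0; kw < KW; ++kw)
          for (int kh = 0; kh < KH; ++kh) {
            double acc = 0.0;
            for (int ow = 0; ow < OW; ++ow) {
              const int iw = ow * stride - pad + kw;
              if (iw < 0 || iw >= W) continue;
              const double *xcol = xplane + static_cast<R_xlen_t>(H) * iw;
              const double *gcol = gplane + static_cast<R_xlen_t>(OH) * ow;
              if (stride == 1) {
                int oh0 = std::max(0, pad - kh);
                int oh1 = std::min(OH, H + pad - kh);
                const double *xc = xcol - pad + kh;
                for (int oh = oh0; oh < oh1; ++oh)
                  acc += gcol[oh] * xc[oh];
              } else {
                for (int oh = 0; oh < OH; ++oh) {
                  const int ih = oh * stride - pad + kh;
                  if (ih < 0 || ih >= H) continue;
                  acc += gcol[oh] * xcol[ih];
                }
              }
            }
            wp[kh + KH * (kw + KW * (ic + CI * oc))] += acc;
          }
      }
    }
  gw.attr("dim") = wdim;
  return List::create(Named("gw") = gw, Named("gb") = gb);
}

// Grey-level co-occurrence accumulation over a set of (dr, dc) offsets on an
// integer level image (1-based levels).  Returns raw (unsymmetrised) counts.
// [[Rcpp::export]]
NumericMatrix glcm_counts_cpp(IntegerMatrix img, int levels,
                              IntegerVector dr, IntegerVector dc) {
  const int R = img.nrow(), C = img.ncol(), K = dr.size();
  NumericMatrix counts(levels, levels);
  for (int k = 0; k < K; ++k) {
    const int drr = dr[k], dcc = dc[k];
    for (int c = 0; c < C; ++c) {
      const int c2 = c + dcc;
      if (c2 < 0 || c2 >= C) continue;
      for (int r = 0; r < R; ++r) {
        const int r2 = r + drr;
        if (r2 < 0 || r2 >= R) continue;
        counts(img(r, c) - 1, img(r2, c2) - 1) += 1.0;
      }
    }
  }
  return counts;
}
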