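// Low-level tensor ops for the segmentation network and metrics.
//
// Feature tensors are R arrays with dim (H, W, C, N), column-major, so the
// element (h, w, c, n) sits at h + H*(w + W*(c + C*n)).  Convolution weights
// are (kh, kw, Cin, Cout).  Stride is always 1; padding is symmetric.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int tdim(const NumericVector& x, int i) {
  IntegerVector d = x.attr("dim");
  return d[i];
}

// im2col for one sample: rows = kh*kw*Cin (r = i + kh*(j + kw*c)),
// cols = H*W output positions (col = oh + H*ow).
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, arma::mat& M) {
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        double* Mr = M.memptr();  // column-major: M(r, col)
        for (int ow = 0; ow < W; ++ow) {
          int iw = ow + j - pad;
          for (int oh = 0; oh < H; ++oh) {
            int ih = oh + i - pad;
            double v = 0.0;
            if (ih >= 0 && ih < H && iw >= 0 && iw < W)
              v = xc[ih + (size_t)iw * H];
            Mr[r + (size_t)M.n_rows * (oh + (size_t)H * ow)] = v;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::mat& M, int H, int W, int C,
                       int kh, int kw, int pad, double* gx) {
  for (int c = 0; c < C; ++c) {
    double* gxc = gx + (size_t)c * H * W;
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int r = i + kh * (j + kw * c);
        const double* Mr = M.memptr();
        for (int ow = 0; ow < W; ++ow) {
          int iw = ow + j - pad;
          if (iw < 0 || iw >= W) continue;
          for (int oh = 0; oh < H; ++oh) {
            int ih = oh + i - pad;
            if (ih < 0 || ih >= H) continue;
            gxc[ih + (size_t)iw * H] +=
              Mr[r + (size_t)M.n_rows * (oh + (size_t)H * ow)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w,
                            NumericVector b, int pad) {
  int H = tdim(x, 0), W = tdim(x, 1), C = tdim(x, 2), N = tdim(x, 3);
  int kh = tdim(w, 0), kw = tdim(w, 1), Cin = tdim(w, 2), Cout = tdim(w, 3);
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int R = kh * kw * Cin, HW = H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  NumericVector y(Rcpp::no_init((size_t)HW * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat M(R, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, pad, M);
    // output slab is (HW x Cout) in memory
    arma::mat Y(y.begin() + (size_t)n * HW * Cout, HW, Cout, false, true);
    Y = M.t() * Wm;
    for (int o = 0; o < Cout; ++o) Y.col(o) += b[o];
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy,
                   int pad) {
  int H = tdim(x, 0), W = tdim(x, 1), C = tdim(x, 2), N = tdim(x, 3);
  int kh = tdim(w, 0), kw = tdim(w, 1), Cout = tdim(w, 3);
  int R = kh * kw * C, HW = H * W;
  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  NumericVector gx((size_t)HW * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector gw((size_t)R * Cout);
  gw.attr("dim") = IntegerVector::create(kh, kw, C, Cout);
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), R, Cout, false, true);
  arma::vec gbv(gb.begin(), Cout, false, true);
  arma::mat M(R, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * C, H, W, C, kh, kw, pad, M);
    // gy slab is (HW x Cout) in memory -> arma mat (HW, Cout)
    arma::mat Gy(const_cast<double*>(gy.begin()) + (size_t)n * HW * Cout,
                 HW, Cout, false, true);
    gWm += M * Gy;
    gbv += arma::sum(Gy, 0).t();
    arma::mat gM = Wm * Gy.t();  // (R x HW)
    col2im_add(gM, H, W, C, kh, kw, pad, gx.begin() + (size_t)n * HW * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  int H = tdim(x, 0), W = tdim(x, 1), C = tdim(x, 2), N = tdim(x, 3);
  if (H % 2 || W % 2) stop("maxpool2: spatial extent must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  IntegerVector idx(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + (size_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh, ++o) {
        int best = 0;
        double bv = xs[2 * oh + (size_t)(2 * ow) * H];
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            double v = xs[2 * oh + dh + (size_t)(2 * ow + dw) * H];
            if (v > bv) { bv = v; best = dh + 2 * dw; }
          }
        y[o] = bv; idx[o] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bw(NumericVector gy, IntegerVector idx,
                              int H, int W) {
  int Ho = tdim(gy, 0), Wo = tdim(gy, 1), C = tdim(gy, 2), N = tdim(gy, 3);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    double* gs = gx.begin() + (size_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh, ++o) {
        int dh = idx[o] % 2, dw = idx[o] / 2;
        gs[2 * oh + dh + (size_t)(2 * ow + dw) * H] += gy[o];
      }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_fw(NumericVector x) {
  int H = tdim(x, 0), W = tdim(x, 1), C = tdim(x, 2), N = tdim(x, 3);
  if (H % 2 || W % 2) stop("avgpool2: spatial extent must be even");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + (size_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh, ++o)
        y[o] = 0.25 * (xs[2 * oh + (size_t)(2 * ow) * H] +
                       xs[2 * oh + 1 + (size_t)(2 * ow) * H] +
                       xs[2 * oh + (size_t)(2 * ow + 1) * H] +
                       xs[2 * oh + 1 + (size_t)(2 * ow + 1) * H]);
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool2_bw(NumericVector gy, int H, int W) {
  int Ho = tdim(gy, 0), Wo = tdim(gy, 1), C = tdim(gy, 2), N = tdim(gy, 3);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    double* gs = gx.begin() + (size_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow)
      for (int oh = 0; oh < Ho; ++oh, ++o) {
        double g = 0.25 * gy[o];
        gs[2 * oh + (size_t)(2 * ow) * H] += g;
        gs[2 * oh + 1 + (size_t)(2 * ow) * H] += g;
        gs[2 * oh + (size_t)(2 * ow + 1) * H] += g;
        gs[2 * oh + 1 + (size_t)(2 * ow + 1) * H] += g;
      }
  }
  return gx;
}

// Bilinear 2x upsampling, half-pixel-centre convention with edge clamping:
// src = (dst + 0.5)/2 - 0.5.
struct LinW { int i0, i1; double w1; };
static std::vector<LinW> up2_weights(int n_in) {
  std::vector<LinW> v(2 * n_in);
  for (int o = 0; o < 2 * n_in; ++o) {
    double s = (o + 0.5) / 2.0 - 0.5;
    int i0 = (int)std::floor(s);
    double w1 = s - i0;
    int i1 = i0 + 1;
    if (i0 < 0) i0 = 0;
    if (i1 > n_in - 1) i1 = n_in - 1;
    v[o] = {i0, i1, w1};
  }
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_fw(NumericVector x) {
  int H = tdim(x, 0), W = tdim(x, 1), C = tdim(x, 2), N = tdim(x, 3);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Rcpp::no_init((size_t)Ho * Wo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<LinW> wh = up2_weights(H), ww = up2_weights(W);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    const double* xs = x.begin() + (size_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      const LinW& cw = ww[ow];
      for (int oh = 0; oh < Ho; ++oh, ++o) {
        const LinW& ch = wh[oh];
        double a = xs[ch.i0 + (size_t)cw.i0 * H], b = xs[ch.i1 + (size_t)cw.i0 * H];
        double c = xs[ch.i0 + (size_t)cw.i1 * H], d = xs[ch.i1 + (size_t)cw.i1 * H];
        double top = a * (1 - ch.w1) + b * ch.w1;
        double bot = c * (1 - ch.w1) + d * ch.w1;
        y[o] = top * (1 - cw.w1) + bot * cw.w1;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2_bw(NumericVector gy, int H, int W) {
  int C = tdim(gy, 2), N = tdim(gy, 3);
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  std::vector<LinW> wh = up2_weights(H), ww = up2_weights(W);
  size_t o = 0;
  for (int cn = 0; cn < C * N; ++cn) {
    double* gs = gx.begin() + (size_t)cn * H * W;
    for (int ow = 0; ow < Wo; ++ow) {
      const LinW& cw = ww[ow];
      for (int oh = 0; oh < Ho; ++oh, ++o) {
        const LinW& ch = wh[oh];
        double g = gy[o];
        gs[ch.i0 + (size_t)cw.i0 * H] += g * (1 - ch.w1) * (1 - cw.w1);
        gs[ch.i1 + (size_t)cw.i0 * H] += g * ch.w1 * (1 - cw.w1);
        gs[ch.i0 + (size_t)cw.i1 * H] += g * (1 - ch.w1) * cw.w1;
        gs[ch.i1 + (size_t)cw.i1 * H] += g * ch.w1 * cw.w1;
      }
    }
  }
  return gx;
}

// Slice-wise in-plane resize of a (S, H, W) volume.  Axis 1 (fastest) is the
// axial slice axis, so a slice is strided; indexing below accounts for that.
// Bilinear for intensities, nearest-neighbour for labels.
// [[Rcpp::export]]
NumericVector cpp_resize_inplane(NumericVector x, int H2, int W2,
                                 bool nearest) {
  int S = tdim(x, 0), H = tdim(x, 1), W = tdim(x, 2);
  NumericVector y(Rcpp::no_init((size_t)S * H2 * W2));
  y.attr("dim") = IntegerVector::create(S, H2, W2);
  double fh = (double)H / H2, fw = (double)W / W2;
  for (int w2 = 0; w2 < W2; ++w2) {
    double sw = (w2 + 0.5) * fw - 0.5;
    for (int h2 = 0; h2 < H2; ++h2) {
      double sh = (h2 + 0.5) * fh - 0.5;
      if (nearest) {
        int ih = std::min(H - 1, std::max(0, (int)std::floor((h2 + 0.5) * fh)));
        int iw = std::min(W - 1, std::max(0, (int)std::floor((w2 + 0.5) * fw)));
        for (int s = 0; s < S; ++s)
          y[s + (size_t)S * (h2 + (size_t)H2 * w2)] =
            x[s + (size_t)S * (ih + (size_t)H * iw)];
      } else {
        int h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
        double ah = sh - h0, aw = sw - w0;
        int h0c = std::min(H - 1, std::max(0, h0));
        int h1c = std::min(H - 1, std::max(0, h0 + 1));
        int w0c = std::min(W - 1, std::max(0, w0));
        int w1c = std::min(W - 1, std::max(0, w0 + 1));
        for (int s = 0; s < S; ++s) {
          double a = x[s + (size_t)S * (h0c + (size_t)H * w0c)];
          double b = x[s + (size_t)S * (h1c + (size_t)H * w0c)];
          double c = x[s + (size_t)S * (h0c + (size_t)H * w1c)];
          double d = x[s + (size_t)S * (h1c + (size_t)H * w1c)];
          y[s + (size_t)S * (h2 + (size_t)H2 * w2)] =
            (a * (1 - ah) + b * ah) * (1 - aw) + (c * (1 - ah) + d * ah) * aw;
        }
      }
    }
  }
  return y;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on a sampled
// grid with physical spacing s: d[i] = min_j f[j] + (s*(i-j))^2.
static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  int k = 0;
  v[0] = 0; z[0] = -1e30; z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sint <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = sint; z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact anisotropic squared Euclidean distance transform of a 3D site mask
// (dims d1,d2,d3; spacing mm per axis): distance from every voxel centre to
// the nearest site voxel centre.  All-empty input returns +Inf everywhere.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector sites, NumericVector spacing) {
  IntegerVector d = sites.attr("dim");
  int d1 = d[0], d2 = d[1], d3 = d[2];
  size_t nt = (size_t)d1 * d2 * d3;
  NumericVector out(Rcpp::no_init(nt));
  out.attr("dim") = d;
  for (size_t i = 0; i < nt; ++i) out[i] = sites[i] ? 0.0 : 1e30;
  int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // axis 1 (stride 1)
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      size_t base = (size_t)d1 * (j + (size_t)d2 * k);
      f.assign(out.begin() + base, out.begin() + base + d1);
      dt1d(f, spacing[0], dd, v, z);
      std::copy(dd.begin(), dd.begin() + d1, out.begin() + base);
    }
  // axis 2 (stride d1)
  f.resize(d2);
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      size_t base = i + (size_t)d1 * d2 * k;
      for (int j = 0; j < d2; ++j) f[j] = out[base + (size_t)d1 * j];
      dt1d(f, spacing[1], dd, v, z);
      for (int j = 0; j < d2; ++j) out[base + (size_t)d1 * j] = dd[j];
    }
  // axis 3 (stride d1*d2)
  f.resize(d3);
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      size_t base = i + (size_t)d1 * j;
      for (int k = 0; k < d3; ++k) f[k] = out[base + (size_t)d1 * d2 * k];
      dt1d(f, spacing[2], dd, v, z);
      for (int k = 0; k < d3; ++k) out[base + (size_t)d1 * d2 * k] = dd[k];
    }
  return out;
}
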