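#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Feature maps are C x N matrices (channels in rows); a voxel (d,h,w) of a
// D x H x W grid sits in column d + D*(h + H*w). Kernel element (c,kd,kh,kw)
// of a Kd x Kh x Kw window maps to im2col row c + C*(kd + Kd*(kh + Kh*kw)).

static inline int out_extent(int in, int k, int s, int p) {
  return (in + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& x, IntegerVector sp,
                      IntegerVector k, IntegerVector s, IntegerVector p) {
  const int C = x.nrow();
  const int D = sp[0], H = sp[1], W = sp[2];
  const int Kd = k[0], Kh = k[1], Kw = k[2];
  const int Sd = s[0], Sh = s[1], Sw = s[2];
  const int Pd = p[0], Ph = p[1], Pw = p[2];
  const int Do = out_extent(D, Kd, Sd, Pd);
  const int Ho = out_extent(H, Kh, Sh, Ph);
  const int Wo = out_extent(W, Kw, Sw, Pw);
  const int K = C * Kd * Kh * Kw;
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  NumericMatrix cols(K, N);
  const double* xp = x.begin();
  double* cp = cols.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int od = 0; od < Do; ++od) {
        R_xlen_t col = od + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow);
        double* dst = cp + col * K;
        for (int kw = 0; kw < Kw; ++kw) {
          int w = ow * Sw - Pw + kw;
          for (int kh = 0; kh < Kh; ++kh) {
            int h = oh * Sh - Ph + kh;
            for (int kd = 0; kd < Kd; ++kd) {
              int d = od * Sd - Pd + kd;
              int q = C * (kd + Kd * (kh + Kh * kw));
              if (d < 0 || d >= D || h < 0 || h >= H || w < 0 || w >= W) {
                for (int c = 0; c < C; ++c) dst[q + c] = 0.0;
              } else {
                const double* src = xp + ((R_xlen_t)d + (R_xlen_t)D * (h + (R_xlen_t)H * w)) * C;
                for (int c = 0; c < C; ++c) dst[q + c] = src[c];
              }
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col3: scatter-add columns back onto a C x (D*H*W) image.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& cols, int C, IntegerVector sp,
                      IntegerVector k, IntegerVector s, IntegerVector p) {
  const int D = sp[0], H = sp[1], W = sp[2];
  const int Kd = k[0], Kh = k[1], Kw = k[2];
  const int Sd = s[0], Sh = s[1], Sw = s[2];
  const int Pd = p[0], Ph = p[1], Pw = p[2];
  const int Do = out_extent(D, Kd, Sd, Pd);
  const int Ho = out_extent(H, Kh, Sh, Ph);
  const int Wo = out_extent(W, Kw, Sw, Pw);
  const int K = C * Kd * Kh * Kw;
  if (cols.nrow() != K) stop("col2im3: row count does not match kernel");
  NumericMatrix img(C, (R_xlen_t)D * H * W);
  const double* cp = cols.begin();
  double* xp = img.begin();
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      for (int od = 0; od < Do; ++od) {
        R_xlen_t col = od + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow);
        const double* src = cp + col * K;
        for (int kw = 0; kw < Kw; ++kw) {
          int w = ow * Sw - Pw + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < Kh; ++kh) {
            int h = oh * Sh - Ph + kh;
            if (h < 0 || h >= H) continue;
            for (int kd = 0; kd < Kd; ++kd) {
              int d = od * Sd - Pd + kd;
              if (d < 0 || d >= D) continue;
              int q = C * (kd + Kd * (kh + Kh * kw));
              double* dst = xp + ((R_xlen_t)d + (R_xlen_t)D * (h + (R_xlen_t)H * w)) * C;
              for (int c = 0; c < C; ++c) dst[c] += src[q + c];
            }
          }
        }
      }
    }
  }
  return img;
}

// 2x2x2 max pooling, stride 2. Returns pooled map and 0-based argmax voxel
// index per (channel, output voxel) for the backward scatter.
// [[Rcpp::export]]
List maxpool3_fwd(const NumericMatrix& x, IntegerVector sp) {
  const int C = x.nrow();
  const int D = sp[0], H = sp[1], W = sp[2];
  if (D % 2 || H % 2 || W % 2) stop("maxpool3: spatial dims must be even");
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  NumericMatrix y(C, N);
  IntegerMatrix idx(C, N);
  const double* xp = x.begin();
  for (int ow = 0; ow < Wo; ++ow)
    for (int oh = 0; oh < Ho; ++oh)
      for (int od = 0; od < Do; ++od) {
        R_xlen_t col = od + (R_xlen_t)Do * (oh + (R_xlen_t)Ho * ow);
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf; R_xlen_t bi = 0;
          for (int kw = 0; kw < 2; ++kw)
            for (int kh = 0; kh < 2; ++kh)
              for (int kd = 0; kd < 2; ++kd) {
                R_xlen_t v = (2 * od + kd) +
                  (R_xlen_t)D * ((2 * oh + kh) + (R_xlen_t)H * (2 * ow + kw));
                double val = xp[v * C + c];
                if (val > best) { best = val; bi = v; }
              }
          y(c, col) = best;
          idx(c, col) = (int)bi;
        }
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix maxpool3_bwd(const NumericMatrix& dy, const IntegerMatrix& idx,
                           R_xlen_t n_in) {
  const int C = dy.nrow();
  NumericMatrix dx(C, n_in);
  for (R_xlen_t j = 0; j < dy.ncol(); ++j)
    for (int c = 0; c < C; ++c)
      dx(c, (R_xlen_t)idx(c, j)) += dy(c, j);
  return dx;
}

// Resample a D x H x W scalar field from `spacing` to `target` mm/voxel.
// Output grid point i sits at physical i*target; source sampled trilinearly
// (or nearest for masks) with edge clamping.
// [[Rcpp::export]]
List resample3(const NumericVector& x, IntegerVector dims,
               NumericVector spacing, NumericVector target, bool nearest) {
  const int D = dims[0], H = dims[1], W = dims[2];
  int Do = (int)std::round(D * spacing[0] / target[0]);
  int Ho = (int)std::round(H * spacing[1] / target[1]);
  int Wo = (int)std::round(W * spacing[2] / target[2]);
  if (Do < 1) Do = 1; if (Ho < 1) Ho = 1; if (Wo < 1) Wo = 1;
  NumericVector out((R_xlen_t)Do * Ho * Wo);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int w = 0; w < Wo; ++w) {
    double sw = w * target[2] / spacing[2];
    for (int h = 0; h < Ho; ++h) {
      double sh = h * target[1] / spacing[1];
      for (int d = 0; d < Do; ++d) {
        double sd = d * target[0] / spacing[0];
        R_xlen_t o = d + (R_xlen_t)Do * (h + (R_xlen_t)Ho * w);
        if (nearest) {
          int id = std::min(D - 1, std::max(0, (int)std::round(sd)));
          int ih = std::min(H - 1, std::max(0, (int)std::round(sh)));
          int iw = std::min(W - 1, std::max(0, (int)std::round(sw)));
          op[o] = xp[id + (R_xlen_t)D * (ih + (R_xlen_t)H * iw)];
        } else {
          int d0 = (int)std::floor(sd), h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
          double fd = sd - d0, fh = sh - h0, fw = sw - w0;
          double acc = 0.0;
          for (int bw = 0; bw < 2; ++bw)
            for (int bh = 0; bh < 2; ++bh)
              for (int bd = 0; bd < 2; ++bd) {
                int id = std::min(D - 1, std::max(0, d0 + bd));
                int ih = std::min(H - 1, std::max(0, h0 + bh));
                int iw = std::min(W - 1, std::max(0, w0 + bw));
                double wt = (bd ? fd : 1 - fd) * (bh ? fh : 1 - fh) * (bw ? fw : 1 - fw);
                acc += wt * xp[id + (R_xlen_t)D * (ih + (R_xlen_t)H * iw)];
              }
          op[o] = acc;
        }
      }
    }
  }
  return List::create(_["values"] = out,
                      _["dim"] = IntegerVector::create(Do, Ho, Wo));
}

// 6-connected component labelling of a 3D binary field.
// [[Rcpp::export]]
List label3(const IntegerVector& mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  IntegerVector lab(N, 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  const int* mp = mask.begin();
  int* lp = lab.begin();
  for (R_xlen_t i = 0; i < N; ++i) {
    if (!mp[i] || lp[i]) continue;
    ++cur;
    lp[i] = cur;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int d = (int)(v % D);
      int h = (int)((v / D) % H);
      int w = (int)(v / ((R_xlen_t)D * H));
      const int nd[6] = { d - 1, d + 1, d, d, d, d };
      const int nh[6] = { h, h, h - 1, h + 1, h, h };
      const int nw[6] = { w, w, w, w, w - 1, w + 1 };
      for (int t = 0; t < 6; ++t) {
        if (nd[t] < 0 || nd[t] >= D || nh[t] < 0 || nh[t] >= H ||
            nw[t] < 0 || nw[t] >= W) continue;
        R_xlen_t u = nd[t] + (R_xlen_t)D * (nh[t] + (R_xlen_t)H * nw[t]);
        if (mp[u] && !lp[u]) { lp[u] = cur; q.push(u); }
      }
    }
  }
  return List::create(_["labels"] = lab, _["n"] = cur);
}

// Fill enclosed holes of a binary mask independently on each axial slice:
// background is flood-filled from the slice border; unreached zeros become 1.
// [[Rcpp::export]]
IntegerVector fill_holes_axial(const IntegerVector& mask, IntegerVector dims) {
  const int D = dims[0], H = dims[1], W = dims[2];
  IntegerVector out = clone(mask);
  std::vector<char> reach((size_t)H * W);
  std::queue<int> q;
  for (int d = 0; d < D; ++d) {
    std::fill(reach.begin(), reach.end(), 0);
    auto at = [&](int h, int w) -> R_xlen_t {
      return d + (R_xlen_t)D * (h + (R_xlen_t)H * w);
    };
    for (int h = 0; h < H; ++h)
      for (int w = 0; w < W; ++w)
        if ((h == 0 || h == H - 1 || w == 0 || w == W - 1) &&
            !mask[at(h, w)] && !reach[h + (size_t)H * w]) {
          reach[h + (size_t)H * w] = 1;
          q.push(h + H * w);
          while (!q.empty()) {
            int s = q.front(); q.pop();
            int sh = s % H, sw = s / H;
            const int eh[4] = { sh - 1, sh + 1, sh, sh };
            const int ew[4] = { sw, sw, sw - 1, sw + 1 };
            for (int t = 0; t < 4; ++t) {
              if (eh[t] < 0 || eh[t] >= H || ew[t] < 0 || ew[t] >= W) continue;
              size_t u = eh[t] + (size_t)H * ew[t];
              if (!mask[at(eh[t], ew[t])] && !reach[u]) {
                reach[u] = 1; q.push(eh[t] + H * ew[t]);
              }
            }
          }
        }
    for (int h = 0; h < H; ++h)
      for (int w = 0; w < W; ++w)
        if (!mask[at(h, w)] && !reach[h + (size_t)H * w]) out[at(h, w)] = 1;
  }
  return out;
}

// Binary dilation/erosion with an explicit offset list (m x 3, 0-based voxel
// offsets). Outside the volume counts as background.
// [[Rcpp::export]]
IntegerVector binary_morph3(const IntegerVector& mask, IntegerVector dims,
                            const IntegerMatrix& offsets, bool dilate) {
  const int D = dims[0], H = dims[1], W = dims[2];
  const R_xlen_t N = (R_xlen_t)D * H * W;
  IntegerVector out(N);
  const int m = offsets.nrow();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        R_xlen_t v = d + (R_xlen_t)D * (h + (R_xlen_t)H * w);
        bool any = false, all = true;
        for (int t = 0; t < m; ++t) {
          int dd = d + offsets(t, 0), hh = h + offsets(t, 1), ww = w + offsets(t, 2);
          bool inside = dd >= 0 && dd < D && hh >= 0 && hh < H && ww >= 0 && ww < W;
          int val = inside ? mask[dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww)] : 0;
          if (val) any = true; else all = false;
          if (dilate && any) break;
          if (!dilate && !all) break;
        }
        out[v] = dilate ? (any ? 1 : 0) : (all ? 1 : 0);
      }
  return out;
}

// Direct stride-1 convolution. x is C x N, W is cout x (C*Kd*Kh*Kw) with
// kernel element (c,kd,kh,kw) in column c + C*(kd + Kd*(kh + Kh*kw)).
// Output spatial shape equals input shape when 2p = k - 1 per axis.
static NumericMatrix pad_cmat(const NumericMatrix& x, int D, int H, int W,
                              int Pd, int Ph, int Pw) {
  const int C = x.nrow();
  const int Dp = D + 2 * Pd, Hp = H + 2 * Ph, Wp = W + 2 * Pw;
  NumericMatrix xp(C, (R_xlen_t)Dp * Hp * Wp);
  const double* s = x.begin();
  double* t = xp.begin();
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      R_xlen_t src = ((R_xlen_t)D * (h + (R_xlen_t)H * w)) * C;
      R_xlen_t dst = ((R_xlen_t)Pd + (R_xlen_t)Dp * ((h + Ph) + (R_xlen_t)Hp * (w + Pw))) * C;
      std::copy(s + src, s + src + (R_xlen_t)C * D, t + dst);
    }
  return xp;
}

// [[Rcpp::export]]
NumericMatrix conv3s1_fwd(const NumericMatrix& x, IntegerVector sp,
                          const NumericMatrix& Wm, int cout,
                          IntegerVector k, IntegerVector p) {
  const int C = x.nrow();
  const int D = sp[0], H = sp[1], W = sp[2];
  const int Kd = k[0], Kh = k[1], Kw = k[2];
  const int Pd = p[0], Ph = p[1], Pw = p[2];
  const int Do = D + 2 * Pd - Kd + 1, Ho = H + 2 * Ph - Kh + 1,
            Wo = W + 2 * Pw - Kw + 1;
  NumericMatrix xp = pad_cmat(x, D, H, W, Pd, Ph, Pw);
  const int Dp = D + 2 * Pd, Hp = H + 2 * Ph;
  NumericMatrix y(cout, (R_xlen_t)Do * Ho * Wo);
  const double* xpb = xp.begin();
  const double* wb = Wm.begin();
  double* yb = y.begin();
  for (int kw = 0; kw < Kw; ++kw)
    for (int kh = 0; kh < Kh; ++kh)
      for (int kd = 0; kd < Kd; ++kd) {
        const double* wp = wb + (R_xlen_t)cout * C * (kd + Kd * (kh + Kh * kw));
        for (int w = 0; w < Wo; ++w)
          for (int h = 0; h < Ho; ++h) {
            const double* xv = xpb + ((R_xlen_t)kd + (R_xlen_t)Dp * ((h + kh) + (R_xlen_t)Hp * (w + kw))) * C;
            double* yv = yb + ((R_xlen_t)Do * (h + (R_xlen_t)Ho * w)) * cout;
            for (int d = 0; d < Do; ++d) {
              const double* xd = xv + (R_xlen_t)d * C;
              double* yd = yv + (R_xlen_t)d * cout;
              for (int ci = 0; ci < C; ++ci) {
                const double xc = xd[ci];
                const double* wc = wp + (R_xlen_t)cout * ci;
                for (int co = 0; co < cout; ++co) yd[co] += wc[co] * xc;
              }
            }
          }
      }
  return y;
}

// dW for the stride-1 convolution: dW[co, ci + C*off] = sum_n dy[co,n] *
// xpad[ci, n + off].
// [[Rcpp::export]]
NumericMatrix conv3s1_dw(const NumericMatrix& x, IntegerVector sp,
                         const NumericMatrix& dy, IntegerVector k,
                         IntegerVector p) {
  const int C = x.nrow();
  const int cout = dy.nrow();
  const int D = sp[0], H = sp[1], W = sp[2];
  const int Kd = k[0], Kh = k[1], Kw = k[2];
  const int Pd = p[0], Ph = p[1], Pw = p[2];
  const int Do = D + 2 * Pd - Kd + 1, Ho = H + 2 * Ph - Kh + 1,
            Wo = W + 2 * Pw - Kw + 1;
  NumericMatrix xp = pad_cmat(x, D, H, W, Pd, Ph, Pw);
  const int Dp = D + 2 * Pd, Hp = H + 2 * Ph;
  NumericMatrix dW(cout, (R_xlen_t)C * Kd * Kh * Kw);
  const double* xpb = xp.begin();
  const double* dyb = dy.begin();
  double* dwb = dW.begin();
  std::vector<double> acc((size_t)cout * C);
  for (int kw = 0; kw < Kw; ++kw)
    for (int kh = 0; kh < Kh; ++kh)
      for (int kd = 0; kd < Kd; ++kd) {
        std::fill(acc.begin(), acc.end(), 0.0);
        for (int w = 0; w < Wo; ++w)
          for (int h = 0; h < Ho; ++h) {
            const double* xv = xpb + ((R_xlen_t)kd + (R_xlen_t)Dp * ((h + kh) + (R_xlen_t)Hp * (w + kw))) * C;
            const double* dv = dyb + ((R_xlen_t)Do * (h + (R_xlen_t)Ho * w)) * cout;
            for (int d = 0; d < Do; ++d) {
              const double* xd = xv + (R_xlen_t)d * C;
              const double* dd = dv + (R_xlen_t)d * cout;
              for (int ci = 0; ci < C; ++ci) {
                const double xc = xd[ci];
                double* ac = acc.data() + (size_t)cout * ci;
                for (int co = 0; co < cout; ++co) ac[co] += dd[co] * xc;
              }
            }
          }
        double* out = dwb + (R_xlen_t)cout * C * (kd + Kd * (kh + Kh * kw));
        std::copy(acc.begin(), acc.end(), out);
      }
  return dW;
}

// Instance normalization over a C x N map: per-row standardization with
// scale/shift. Returns y, xhat and inv (cached for the backward pass).
// [[Rcpp::export]]
List inorm_fwd(const NumericMatrix& x, NumericVector gamma,
               NumericVector beta, double eps, bool keep_cache) {
  const int C = x.nrow();
  const R_xlen_t N = x.ncol();
  NumericMatrix y(C, N);
  NumericMatrix xhat(keep_cache ? C : 1, keep_cache ? N : 1);
  NumericVector inv(C);
  std::vector<double> mu(C, 0.0), var(C, 0.0);
  const double* xp = x.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* col = xp + n * C;
    for (int c = 0; c < C; ++c) mu[c] += col[c];
  }
  for (int c = 0; c < C; ++c) mu[c] /= (double)N;
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* col = xp + n * C;
    for (int c = 0; c < C; ++c) {
      double d = col[c] - mu[c];
      var[c] += d * d;
    }
  }
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(var[c] / (double)N + eps);
  double* yp = y.begin();
  double* hp = xhat.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* col = xp + n * C;
    double* yc = yp + n * C;
    double* hc = hp + n * C;
    for (int c = 0; c < C; ++c) {
      double h = (col[c] - mu[c]) * inv[c];
      if (keep_cache) hc[c] = h;
      yc[c] = gamma[c] * h + beta[c];
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["inv"] = inv);
}

// [[Rcpp::export]]
List inorm_bwd(const NumericMatrix& dy, const NumericMatrix& xhat,
               NumericVector inv, NumericVector gamma) {
  const int C = dy.nrow();
  const R_xlen_t N = dy.ncol();
  NumericMatrix dx(C, N);
  NumericVector dgamma(C), dbeta(C);
  std::vector<double> m1(C, 0.0), m2(C, 0.0);
  const double* dp = dy.begin();
  const double* hp = xhat.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* dc = dp + n * C;
    const double* hc = hp + n * C;
    for (int c = 0; c < C; ++c) {
      double dxh = dc[c] * gamma[c];
      m1[c] += dxh;
      m2[c] += dxh * hc[c];
      dgamma[c] += dc[c] * hc[c];
      dbeta[c] += dc[c];
    }
  }
  for (int c = 0; c < C; ++c) { m1[c] /= (double)N; m2[c] /= (double)N; }
  double* op = dx.begin();
  for (R_xlen_t n = 0; n < N; ++n) {
    const double* dc = dp + n * C;
    const double* hc = hp + n * C;
    double* oc = op + n * C;
    for (int c = 0; c < C; ++c) {
      oc[c] = inv[c] * (dc[c] * gamma[c] - m1[c] - hc[c] * m2[c]);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
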