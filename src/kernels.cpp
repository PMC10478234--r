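// Low-level numeric kernels for the 3-D segmentation network and the
// surface-distance metrics. All feature maps are dense double arrays in
// channel-first layout (C, D, H, W), column-major as R stores them, so the
// channel index is the fastest-moving one and per-voxel channel vectors are
// contiguous. Convolutions are stride-1 same-padding; they are evaluated as
// im2col + GEMM so the heavy lifting lands in BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int wrap_idx(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

static void get_dims4(const NumericVector& x, int& C, int& D, int& H, int& W) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (C, D, H, W) array");
  C = d[0]; D = d[1]; H = d[2]; W = d[3];
}

// im2col for a contiguous run of output voxels [n0, n1): one matrix column
// per voxel, rows ordered ic + cing*(dz + k*(dy + k*dx)) to match the weight
// layout (cing, k, k, k, cout). Columns are written sequentially (no global
// zero-fill pass); out-of-range taps are zeroed inline.
static void im2col_run(const double* xp, int C, int D, int H, int W,
                       int ci0, int cing, int k, int pad_mode,
                       size_t n0, size_t n1, arma::mat& col) {
  const int p = (k - 1) / 2;
  int dv = (int)(n0 % D);
  size_t rest = n0 / D;
  int hv = (int)(rest % H);
  int wv = (int)(rest / H);
  const size_t bytes = (size_t)cing * sizeof(double);
  for (size_t n = n0; n < n1; ++n) {
    double* cp = col.colptr(n - n0);
    int r = 0;
    for (int dx = 0; dx < k; ++dx) {
      int iw = wv + dx - p;
      if (pad_mode == 1) iw = wrap_idx(iw, W);
      const bool okw = iw >= 0 && iw < W;
      for (int dy = 0; dy < k; ++dy) {
        int ih = hv + dy - p;
        if (pad_mode == 1) ih = wrap_idx(ih, H);
        const bool okh = okw && ih >= 0 && ih < H;
        for (int dz = 0; dz < k; ++dz) {
          int id = dv + dz - p;
          if (pad_mode == 1) id = wrap_idx(id, D);
          if (okh && id >= 0 && id < D)
            std::memcpy(cp + r,
                        xp + ci0 + (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw)),
                        bytes);
          else
            std::memset(cp + r, 0, bytes);
          r += cing;
        }
      }
    }
    if (++dv == D) { dv = 0; if (++hv == H) { hv = 0; ++wv; } }
  }
}

// Adjoint: scatter-add the column matrix for voxels [n0, n1) back into gx.
static void col2im_run(const arma::mat& col, double* gxp, int C, int D, int H,
                       int W, int ci0, int cing, int k, int pad_mode,
                       size_t n0, size_t n1) {
  const int p = (k - 1) / 2;
  int dv = (int)(n0 % D);
  size_t rest = n0 / D;
  int hv = (int)(rest % H);
  int wv = (int)(rest / H);
  for (size_t n = n0; n < n1; ++n) {
    const double* cp = col.colptr(n - n0);
    int r = 0;
    for (int dx = 0; dx < k; ++dx) {
      int iw = wv + dx - p;
      if (pad_mode == 1) iw = wrap_idx(iw, W);
      const bool okw = iw >= 0 && iw < W;
      for (int dy = 0; dy < k; ++dy) {
        int ih = hv + dy - p;
        if (pad_mode == 1) ih = wrap_idx(ih, H);
        const bool okh = okw && ih >= 0 && ih < H;
        for (int dz = 0; dz < k; ++dz) {
          int id = dv + dz - p;
          if (pad_mode == 1) id = wrap_idx(id, D);
          if (okh && id >= 0 && id < D) {
            double* dst = gxp + ci0 + (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw));
            for (int c = 0; c < cing; ++c) dst[c] += cp[r + c];
          }
          r += cing;
        }
      }
    }
    if (++dv == D) { dv = 0; if (++hv == H) { hv = 0; ++wv; } }
  }
}

// Column-chunk size targeting a ~8 MB im2col working set.
static size_t conv_chunk(int rows, size_t N) {
  size_t c = (8u << 20) / ((size_t)rows * sizeof(double));
  if (c < 256) c = 256;
  if (c > N) c = N;
  return c;
}

// Grouped 3-D convolution, stride 1, same padding (zero or circular).
// x: (C, D, H, W); w: (C/groups, k, k, k, cout); b: cout. Pointwise
// ungrouped convolutions skip im2col entirely (pure GEMM on views).
// [[Rcpp::export]]
NumericVector cv_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                            int groups, int pad_mode, bool relu) {
  int C, D, H, W;
  get_dims4(x, C, D, H, W);
  IntegerVector wd = w.attr("dim");
  if (wd.size() != 5) stop("weight must be a 5-D array");
  const int cing = wd[0], k = wd[1], cout = wd[4];
  if (wd[2] != k || wd[3] != k) stop("kernel must be cubic");
  if (C != cing * groups) stop("input channels do not match weight/groups");
  if (cout % groups != 0) stop("output channels not divisible by groups");
  const int coutg = cout / groups;
  const int k3 = k * k * k;
  const size_t N = (size_t)D * H * W;

  NumericVector y((size_t)cout * N);
  double* yp = y.begin();
  const double* xp = x.begin();

  if (k == 1 && groups == 1) {
    const arma::mat X(const_cast<double*>(xp), C, N, false, true);
    const arma::mat Wm(const_cast<double*>(w.begin()), C, cout, false, true);
    arma::mat Y(yp, cout, N, false, true);
    Y = Wm.t() * X;
    for (size_t n = 0; n < N; ++n) {
      double* dst = yp + (size_t)cout * n;
      for (int c = 0; c < cout; ++c) {
        double v = dst[c] + b[c];
        if (relu && v < 0) v = 0;
        dst[c] = v;
      }
    }
    y.attr("dim") = IntegerVector::create(cout, D, H, W);
    return y;
  }

  const int rows = cing * k3;
  const size_t chunk = conv_chunk(rows, N);
  arma::mat col(rows, chunk);
  for (int g = 0; g < groups; ++g) {
    const arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * coutg * rows,
                       rows, coutg, false, true);
    const int co0 = g * coutg;
    for (size_t n0 = 0; n0 < N; n0 += chunk) {
      const size_t n1 = std::min(N, n0 + chunk);
      im2col_run(xp, C, D, H, W, g * cing, cing, k, pad_mode, n0, n1, col);
      arma::mat Yg = Wm.t() * col.cols(0, n1 - n0 - 1);  // coutg x nc
      for (size_t n = n0; n < n1; ++n) {
        double* dst = yp + co0 + (size_t)cout * n;
        const double* s = Yg.colptr(n - n0);
        for (int c = 0; c < coutg; ++c) {
          double v = s[c] + b[co0 + c];
          if (relu && v < 0) v = 0;
          dst[c] = v;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(cout, D, H, W);
  return y;
}

// Backward pass of cv_conv3d_fwd (linear part; any ReLU mask is applied by
// the caller before entry). Returns gradients w.r.t. input, weight, bias.
// [[Rcpp::export]]
List cv_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                   int groups, int pad_mode) {
  int C, D, H, W;
  get_dims4(x, C, D, H, W);
  IntegerVector wd = w.attr("dim");
  const int cing = wd[0], k = wd[1], cout = wd[4];
  const int coutg = cout / groups;
  const int k3 = k * k * k;
  const size_t N = (size_t)D * H * W;

  NumericVector gx((size_t)C * N);
  NumericVector gw(w.size());
  NumericVector gb(cout);
  const double* xp = x.begin();
  const double* gyp = gy.begin();

  if (k == 1 && groups == 1) {
    const arma::mat X(const_cast<double*>(xp), C, N, false, true);
    const arma::mat Wm(const_cast<double*>(w.begin()), C, cout, false, true);
    const arma::mat Gy(const_cast<double*>(gyp), cout, N, false, true);
    arma::mat GW(gw.begin(), C, cout, false, true);
    arma::mat GX(gx.begin(), C, N, false, true);
    GW = X * Gy.t();
    GX = Wm * Gy;
    for (size_t n = 0; n < N; ++n) {
      const double* s = gyp + (size_t)cout * n;
      for (int c = 0; c < cout; ++c) gb[c] += s[c];
    }
    gx.attr("dim") = IntegerVector::create(C, D, H, W);
    gw.attr("dim") = w.attr("dim");
    return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
  }

  const int rows = cing * k3;
  const size_t chunk = conv_chunk(rows, N);
  arma::mat col(rows, chunk);
  arma::mat Gy(coutg, chunk);
  for (int g = 0; g < groups; ++g) {
    const int co0 = g * coutg;
    const arma::mat Wm(const_cast<double*>(w.begin()) + (size_t)g * coutg * rows,
                       rows, coutg, false, true);
    arma::mat gWm(gw.begin() + (size_t)g * coutg * rows, rows, coutg, false, true);
    for (size_t n0 = 0; n0 < N; n0 += chunk) {
      const size_t n1 = std::min(N, n0 + chunk);
      const size_t nc = n1 - n0;
      for (size_t n = n0; n < n1; ++n) {
        const double* s = gyp + co0 + (size_t)cout * n;
        double* dst = Gy.colptr(n - n0);
        for (int c = 0; c < coutg; ++c) {
          dst[c] = s[c];
          gb[co0 + c] += s[c];
        }
      }
      im2col_run(xp, C, D, H, W, g * cing, cing, k, pad_mode, n0, n1, col);
      gWm += col.cols(0, nc - 1) * Gy.cols(0, nc - 1).t();
      arma::mat Gcol = Wm * Gy.cols(0, nc - 1);  // rows x nc
      col2im_run(Gcol, gx.begin(), C, D, H, W, g * cing, cing, k, pad_mode, n0, n1);
    }
  }
  gx.attr("dim") = IntegerVector::create(C, D, H, W);
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling (dims must be even). Returns pooled map and the 0-based
// flat argmax index into the input for the backward scatter.
// [[Rcpp::export]]
List cv_maxpool_fwd(NumericVector x) {
  int C, D, H, W;
  get_dims4(x, C, D, H, W);
  if (D % 2 || H % 2 || W % 2) stop("maxpool requires even spatial dims");
  const int Do = D / 2, Ho = H / 2, Wo = W / 2;
  const size_t No = (size_t)C * Do * Ho * Wo;
  NumericVector y(No);
  IntegerVector idx(No);
  const double* xp = x.begin();
  size_t o = 0;
  for (int wv = 0; wv < Wo; ++wv)
    for (int hv = 0; hv < Ho; ++hv)
      for (int dv = 0; dv < Do; ++dv)
        for (int c = 0; c < C; ++c) {
          double best = -std::numeric_limits<double>::infinity();
          size_t besti = 0;
          for (int dx = 0; dx < 2; ++dx)
            for (int dy = 0; dy < 2; ++dy)
              for (int dz = 0; dz < 2; ++dz) {
                const size_t i =
                    (size_t)c + (size_t)C * ((2 * dv + dz) +
                    (size_t)D * ((2 * hv + dy) + (size_t)H * (2 * wv + dx)));
                if (xp[i] > best) { best = xp[i]; besti = i; }
              }
          // output laid out (C, Do, Ho, Wo): recompute flat position
          const size_t oi =
              (size_t)c + (size_t)C * (dv + (size_t)Do * (hv + (size_t)Ho * wv));
          y[oi] = best;
          idx[oi] = (int)besti;
          ++o;
        }
  y.attr("dim") = IntegerVector::create(C, Do, Ho, Wo);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cv_maxpool_bwd(NumericVector gy, IntegerVector idx,
                             IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Transposed convolution, kernel 2, stride 2 (each input voxel populates a
// disjoint 2x2x2 output block). w: (cin, cout, 2, 2, 2).
// [[Rcpp::export]]
NumericVector cv_upconv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int C, D, H, W;
  get_dims4(x, C, D, H, W);
  IntegerVector wd = w.attr("dim");
  const int cin = wd[0], cout = wd[1];
  if (cin != C) stop("upconv channel mismatch");
  const size_t N = (size_t)D * H * W;
  const arma::mat X(const_cast<double*>(x.begin()), C, N, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), cin, (size_t)cout * 8, false, true);
  arma::mat Y8 = Wm.t() * X;  // (cout*8) x N

  const int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)cout * Do * Ho * Wo);
  double* yp = y.begin();
  for (int wv = 0; wv < W; ++wv)
    for (int hv = 0; hv < H; ++hv)
      for (int dv = 0; dv < D; ++dv) {
        const size_t n = (size_t)dv + (size_t)D * (hv + (size_t)H * wv);
        const double* s = Y8.colptr(n);
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy)
            for (int dz = 0; dz < 2; ++dz) {
              const int off = dz + 2 * (dy + 2 * dx);
              double* dst = yp + (size_t)cout * ((2 * dv + dz) +
                            (size_t)Do * ((2 * hv + dy) + (size_t)Ho * (2 * wv + dx)));
              const double* sv = s + (size_t)cout * off;
              for (int c = 0; c < cout; ++c) dst[c] = sv[c] + b[c];
            }
      }
  y.attr("dim") = IntegerVector::create(cout, Do, Ho, Wo);
  return y;
}

// [[Rcpp::export]]
List cv_upconv_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  int C, D, H, W;
  get_dims4(x, C, D, H, W);
  IntegerVector wd = w.attr("dim");
  const int cin = wd[0], cout = wd[1];
  const size_t N = (size_t)D * H * W;
  const int Do = 2 * D, Ho = 2 * H;

  arma::mat Gy8((size_t)cout * 8, N);
  NumericVector gb(cout);
  const double* gyp = gy.begin();
  for (int wv = 0; wv < W; ++wv)
    for (int hv = 0; hv < H; ++hv)
      for (int dv = 0; dv < D; ++dv) {
        const size_t n = (size_t)dv + (size_t)D * (hv + (size_t)H * wv);
        double* dcol = Gy8.colptr(n);
        for (int dx = 0; dx < 2; ++dx)
          for (int dy = 0; dy < 2; ++dy)
            for (int dz = 0; dz < 2; ++dz) {
              const int off = dz + 2 * (dy + 2 * dx);
              const double* src = gyp + (size_t)cout * ((2 * dv + dz) +
                                  (size_t)Do * ((2 * hv + dy) + (size_t)Ho * (2 * wv + dx)));
              double* dv8 = dcol + (size_t)cout * off;
              for (int c = 0; c < cout; ++c) {
                dv8[c] = src[c];
                gb[c] += src[c];
              }
            }
      }
  const arma::mat X(const_cast<double*>(x.begin()), C, N, false, true);
  const arma::mat Wm(const_cast<double*>(w.begin()), cin, (size_t)cout * 8, false, true);
  arma::mat gWm = X * Gy8.t();  // cin x cout*8
  arma::mat Gx = Wm * Gy8;      // cin x N

  NumericVector gx(Gx.n_elem), gw(w.size());
  std::memcpy(gx.begin(), Gx.memptr(), Gx.n_elem * sizeof(double));
  std::memcpy(gw.begin(), gWm.memptr(), gWm.n_elem * sizeof(double));
  gx.attr("dim") = IntegerVector::create(C, D, H, W);
  gw.attr("dim") = w.attr("dim");
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

struct LinIdx {
  std::vector<int> i0, i1;
  std::vector<double> f;
};

static LinIdx resize_axis(int n_in, int n_out) {
  LinIdx a;
  a.i0.resize(n_out); a.i1.resize(n_out); a.f.resize(n_out);
  const double scale = (double)n_in / n_out;
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) * scale - 0.5;
    double fl = std::floor(s);
    int i0 = (int)fl;
    double f = s - fl;
    int i1 = i0 + 1;
    if (i0 < 0) { i0 = 0; }
    if (i0 > n_in - 1) i0 = n_in - 1;
    if (i1 < 0) i1 = 0;
    if (i1 > n_in - 1) i1 = n_in - 1;
    a.i0[o] = i0; a.i1[o] = i1; a.f[o] = f < 0 ? 0 : (f > 1 ? 1 : f);
  }
  return a;
}

// Trilinear resize of a (C, D, H, W) grid to (C, od, oh, ow); half-voxel
// center alignment, edge clamped.
// [[Rcpp::export]]
NumericVector cv_resize3(NumericVector x, int od, int oh, int ow) {
  int C, D, H, W;
  get_dims4(x, C, D, H, W);
  LinIdx az = resize_axis(D, od), ay = resize_axis(H, oh), ax = resize_axis(W, ow);
  NumericVector y((size_t)C * od * oh * ow);
  const double* xp = x.begin();
  double* yp = y.begin();
  for (int wo = 0; wo < ow; ++wo)
    for (int ho = 0; ho < oh; ++ho)
      for (int dz = 0; dz < od; ++dz) {
        double* dst = yp + (size_t)C * (dz + (size_t)od * (ho + (size_t)oh * wo));
        for (int c = 0; c < C; ++c) dst[c] = 0.0;
        for (int cw = 0; cw < 2; ++cw) {
          const int iw = cw ? ax.i1[wo] : ax.i0[wo];
          const double fw = cw ? ax.f[wo] : 1 - ax.f[wo];
          if (fw == 0) continue;
          for (int ch = 0; ch < 2; ++ch) {
            const int ih = ch ? ay.i1[ho] : ay.i0[ho];
            const double fh = ch ? ay.f[ho] : 1 - ay.f[ho];
            if (fh == 0) continue;
            for (int cd = 0; cd < 2; ++cd) {
              const int id = cd ? az.i1[dz] : az.i0[dz];
              const double fd = cd ? az.f[dz] : 1 - az.f[dz];
              const double wgt = fw * fh * fd;
              if (wgt == 0) continue;
              const double* src =
                  xp + (size_t)C * (id + (size_t)D * (ih + (size_t)H * iw));
              for (int c = 0; c < C; ++c) dst[c] += wgt * src[c];
            }
          }
        }
      }
  y.attr("dim") = IntegerVector::create(C, od, oh, ow);
  return y;
}

// Adjoint of cv_resize3 (scatter the output gradient back to input size).
// [[Rcpp::export]]
NumericVector cv_resize3_adj(NumericVector gy, int id_, int ih_, int iw_) {
  int C, od, oh, ow;
  get_dims4(gy, C, od, oh, ow);
  LinIdx az = resize_axis(id_, od), ay = resize_axis(ih_, oh), ax = resize_axis(iw_, ow);
  NumericVector gx((size_t)C * id_ * ih_ * iw_);
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (int wo = 0; wo < ow; ++wo)
    for (int ho = 0; ho < oh; ++ho)
      for (int dz = 0; dz < od; ++dz) {
        const double* src = gp + (size_t)C * (dz + (size_t)od * (ho + (size_t)oh * wo));
        for (int cw = 0; cw < 2; ++cw) {
          const int iw = cw ? ax.i1[wo] : ax.i0[wo];
          const double fw = cw ? ax.f[wo] : 1 - ax.f[wo];
          if (fw == 0) continue;
          for (int ch = 0; ch < 2; ++ch) {
            const int ih = ch ? ay.i1[ho] : ay.i0[ho];
            const double fh = ch ? ay.f[ho] : 1 - ay.f[ho];
            if (fh == 0) continue;
            for (int cd = 0; cd < 2; ++cd) {
              const int id = cd ? az.i1[dz] : az.i0[dz];
              const double fd = cd ? az.f[dz] : 1 - az.f[dz];
              const double wgt = fw * fh * fd;
              if (wgt == 0) continue;
              double* dst = xp + (size_t)C * (id + (size_t)id_ * (ih + (size_t)ih_ * iw));
              for (int c = 0; c < C; ++c) dst[c] += wgt * src[c];
            }
          }
        }
      }
  gx.attr("dim") = IntegerVector::create(C, id_, ih_, iw_);
  return gx;
}

// Softmax over the channel axis of a (C, D, H, W) grid.
// [[Rcpp::export]]
NumericVector cv_softmax_c(NumericVector x) {
  int C, D, H, W;
  get_dims4(x, C, D, H, W);
  const size_t N = (size_t)D * H * W;
  NumericVector y(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  for (size_t n = 0; n < N; ++n) {
    const double* s = xp + (size_t)C * n;
    double* d = yp + (size_t)C * n;
    double mx = s[0];
    for (int c = 1; c < C; ++c) if (s[c] > mx) mx = s[c];
    double tot = 0;
    for (int c = 0; c < C; ++c) { d[c] = std::exp(s[c] - mx); tot += d[c]; }
    for (int c = 0; c < C; ++c) d[c] /= tot;
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// Backward of channel softmax: gx = y * (gy - <gy, y>_C).
// [[Rcpp::export]]
NumericVector cv_softmax_c_bwd(NumericVector y, NumericVector gy) {
  int C, D, H, W;
  get_dims4(y, C, D, H, W);
  const size_t N = (size_t)D * H * W;
  NumericVector gx(y.size());
  const double* yp = y.begin();
  const double* gp = gy.begin();
  double* xp = gx.begin();
  for (size_t n = 0; n < N; ++n) {
    const double* yv = yp + (size_t)C * n;
    const double* gv = gp + (size_t)C * n;
    double* d = xp + (size_t)C * n;
    double dot = 0;
    for (int c = 0; c < C; ++c) dot += yv[c] * gv[c];
    for (int c = 0; c < C; ++c) d[c] = yv[c] * (gv[c] - dot);
  }
  gx.attr("dim") = y.attr("dim");
  return gx;
}

// For each row of A (n x 3), the Euclidean distance to the nearest row of
// B (m x 3). Plain all-pairs scan; surfaces in this package are small.
// [[Rcpp::export]]
NumericVector cv_nn_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double a0 = A(i, 0), a1 = A(i, 1), a2 = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double d0 = a0 - B(j, 0), d1 = a1 - B(j, 1), d2 = a2 - B(j, 2);
      const double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
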