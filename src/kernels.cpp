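// Low-level numerical kernels: 3D convolution (blocked im2col + BLAS),
// trilinear/nearest resizing, in-plane rotation, smoothing filters,
// 26-connected component labeling, and a Hungarian assignment solver.
// Array convention: volumes are (D,H,W) column-major doubles, feature
// tensors (D,H,W,C); D is the cranio-caudal (depth) axis.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int out_dim(int in, int k, int pad, int stride) {
  return (in + 2 * pad - k) / stride + 1;
}

// ---------------------------------------------------------------------------
// conv3d: x (D,H,W,Cin), w (k,k,k,Cin,Cout), b (Cout), odd k, pad = (k-1)/2
// ---------------------------------------------------------------------------

// Fill one im2col column (length R, contiguous) for output voxel t.
static inline void im2col_column(const double* xp, double* cc, int t, int Do,
                                 int Ho, int D, int H, int W, int Cin, int k,
                                 int pad, int stride) {
  const int DH = D * H, DHW = D * H * W;
  const int od = t % Do, oh = (t / Do) % Ho, ow = t / (Do * Ho);
  const int id0 = od * stride - pad, ih0 = oh * stride - pad,
            iw0 = ow * stride - pad;
  const bool interior = id0 >= 0 && id0 + k <= D && ih0 >= 0 &&
                        ih0 + k <= H && iw0 >= 0 && iw0 + k <= W;
  int r = 0;
  if (interior) {
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (size_t)ci * DHW + id0;
      for (int kw = 0; kw < k; ++kw) {
        const double* xw = xc + DH * (iw0 + kw);
        for (int kh = 0; kh < k; ++kh) {
          const double* src = xw + D * (ih0 + kh);
          for (int kd = 0; kd < k; ++kd) cc[r++] = src[kd];
        }
      }
    }
  } else {
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = xp + (size_t)ci * DHW;
      for (int kw = 0; kw < k; ++kw) {
        const int iw = iw0 + kw;
        const bool okw = iw >= 0 && iw < W;
        for (int kh = 0; kh < k; ++kh) {
          const int ih = ih0 + kh;
          const bool okh = okw && ih >= 0 && ih < H;
          for (int kd = 0; kd < k; ++kd, ++r) {
            const int id = id0 + kd;
            cc[r] = (okh && id >= 0 && id < D) ? xc[id + D * ih + DH * iw] : 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".cpp_conv3d_fwd")]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[4];
  const int pad = (k - 1) / 2;
  const int Do = out_dim(D, k, pad, stride), Ho = out_dim(H, k, pad, stride),
            Wo = out_dim(W, k, pad, stride);
  const int N = Do * Ho * Wo, R = k * k * k * Cin;

  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  NumericVector out(N * Cout);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  double* op = out.begin();
  const double* xp = x.begin();

  const int B = std::min(N, 4096);
  arma::mat col(R, B);  // one contiguous column per output voxel

  for (int t0 = 0; t0 < N; t0 += B) {
    const int nb = std::min(B, N - t0);
    for (int bi = 0; bi < nb; ++bi)
      im2col_column(xp, col.colptr(bi), t0 + bi, Do, Ho, D, H, W, Cin, k, pad,
                    stride);
    arma::mat colv(col.memptr(), R, nb, false, true);
    arma::mat Y = colv.t() * Wm;  // nb x Cout (BLAS handles the transpose)
    for (int c = 0; c < Cout; ++c) {
      const double bc = b[c];
      double* oc = op + (size_t)c * N + t0;
      const double* yc = Y.colptr(c);
      for (int bi = 0; bi < nb; ++bi) oc[bi] = yc[bi] + bc;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv3d_bwd")]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                    int stride) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int k = wd[0], Cout = wd[4];
  const int pad = (k - 1) / 2;
  const int Do = out_dim(D, k, pad, stride), Ho = out_dim(H, k, pad, stride),
            Wo = out_dim(W, k, pad, stride);
  const int N = Do * Ho * Wo, R = k * k * k * Cin;

  arma::mat Wm(const_cast<double*>(w.begin()), R, Cout, false, true);
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  arma::mat GW(gw.begin(), R, Cout, false, true);
  double* gxp = gx.begin();
  const double* xp = x.begin();
  const double* gyp = gy.begin();

  const int B = std::min(N, 4096);
  arma::mat col(R, B), Gy(B, Cout);
  const int DH = D * H, DHW = D * H * W;

  for (int t0 = 0; t0 < N; t0 += B) {
    const int nb = std::min(B, N - t0);
    for (int bi = 0; bi < nb; ++bi)
      im2col_column(xp, col.colptr(bi), t0 + bi, Do, Ho, D, H, W, Cin, k, pad,
                    stride);
    for (int c = 0; c < Cout; ++c) {
      const double* gc = gyp + (size_t)c * N + t0;
      double* dst = Gy.colptr(c);
      double s = 0.0;
      for (int bi = 0; bi < nb; ++bi) { dst[bi] = gc[bi]; s += gc[bi]; }
      gb[c] += s;
    }
    arma::mat colv(col.memptr(), R, nb, false, true);
    arma::mat gyv(Gy.memptr(), B, Cout, false, true);
    arma::mat gyn = gyv.rows(0, nb - 1);
    GW += colv * gyn;                    // (R x nb)(nb x Cout)
    arma::mat gcol = Wm * gyn.t();       // R x nb, contiguous per voxel
    for (int bi = 0; bi < nb; ++bi) {
      const int t = t0 + bi;
      const int od = t % Do, oh = (t / Do) % Ho, ow = t / (Do * Ho);
      const int id0 = od * stride - pad, ih0 = oh * stride - pad,
                iw0 = ow * stride - pad;
      const double* gc = gcol.colptr(bi);
      const bool interior = id0 >= 0 && id0 + k <= D && ih0 >= 0 &&
                            ih0 + k <= H && iw0 >= 0 && iw0 + k <= W;
      int r = 0;
      if (interior) {
        for (int ci = 0; ci < Cin; ++ci) {
          double* gxc = gxp + (size_t)ci * DHW + id0;
          for (int kw = 0; kw < k; ++kw) {
            double* gw_ = gxc + DH * (iw0 + kw);
            for (int kh = 0; kh < k; ++kh) {
              double* dst = gw_ + D * (ih0 + kh);
              for (int kd = 0; kd < k; ++kd) dst[kd] += gc[r++];
            }
          }
        }
      } else {
        for (int ci = 0; ci < Cin; ++ci) {
          double* gxc = gxp + (size_t)ci * DHW;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = iw0 + kw;
            for (int kh = 0; kh < k; ++kh) {
              const int ih = ih0 + kh;
              for (int kd = 0; kd < k; ++kd, ++r) {
                const int id = id0 + kd;
                if (id >= 0 && id < D && ih >= 0 && ih < H && iw >= 0 && iw < W)
                  gxc[id + D * ih + DH * iw] += gc[r];
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// resize3d: voxel-center aligned trilinear / nearest resize of a (D,H,W) grid
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_resize3d")]]
NumericVector cpp_resize3d(NumericVector x, IntegerVector out_shape,
                           bool trilinear) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2];
  const int Do = out_shape[0], Ho = out_shape[1], Wo = out_shape[2];
  NumericVector out((size_t)Do * Ho * Wo);
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo);
  const double sd = (double)D / Do, sh = (double)H / Ho, sw = (double)W / Wo;
  const double* xp = x.begin();
  double* op = out.begin();
  const int DH = D * H;

  for (int ow = 0; ow < Wo; ++ow) {
    double fw = (ow + 0.5) * sw - 0.5;
    for (int oh = 0; oh < Ho; ++oh) {
      double fh = (oh + 0.5) * sh - 0.5;
      for (int od = 0; od < Do; ++od) {
        double fd = (od + 0.5) * sd - 0.5;
        double v;
        if (trilinear) {
          double cd = std::min(std::max(fd, 0.0), (double)(D - 1));
          double ch = std::min(std::max(fh, 0.0), (double)(H - 1));
          double cw = std::min(std::max(fw, 0.0), (double)(W - 1));
          int d0 = (int)std::floor(cd), h0 = (int)std::floor(ch),
              w0 = (int)std::floor(cw);
          int d1 = std::min(d0 + 1, D - 1), h1 = std::min(h0 + 1, H - 1),
              w1 = std::min(w0 + 1, W - 1);
          double td = cd - d0, th = ch - h0, tw = cw - w0;
          double c000 = xp[d0 + D * h0 + DH * w0], c100 = xp[d1 + D * h0 + DH * w0];
          double c010 = xp[d0 + D * h1 + DH * w0], c110 = xp[d1 + D * h1 + DH * w0];
          double c001 = xp[d0 + D * h0 + DH * w1], c101 = xp[d1 + D * h0 + DH * w1];
          double c011 = xp[d0 + D * h1 + DH * w1], c111 = xp[d1 + D * h1 + DH * w1];
          double c00 = c000 * (1 - td) + c100 * td;
          double c10 = c010 * (1 - td) + c110 * td;
          double c01 = c001 * (1 - td) + c101 * td;
          double c11 = c011 * (1 - td) + c111 * td;
          double c0 = c00 * (1 - th) + c10 * th;
          double c1 = c01 * (1 - th) + c11 * th;
          v = c0 * (1 - tw) + c1 * tw;
        } else {
          int id = std::min(std::max((int)std::lround(fd), 0), D - 1);
          int ih = std::min(std::max((int)std::lround(fh), 0), H - 1);
          int iw = std::min(std::max((int)std::lround(fw), 0), W - 1);
          v = xp[id + D * ih + DH * iw];
        }
        op[od + (size_t)Do * oh + (size_t)Do * Ho * ow] = v;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// rotate_inplane: rotate every depth slice by angle (deg) about slice center
// in the (h, w) plane; inverse mapping; bilinear or nearest; fill for outside
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_rotate_inplane")]]
NumericVector cpp_rotate_inplane(NumericVector x, double angle_deg,
                                 bool linear, double fill) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  const double a = angle_deg * M_PI / 180.0;
  const double ca = std::cos(a), sa = std::sin(a);
  const double chc = (H - 1) / 2.0, cwc = (W - 1) / 2.0;
  const double* xp = x.begin();
  double* op = out.begin();
  const int DH = D * H;

  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      // inverse rotation of output coords
      double dh = h - chc, dw = w - cwc;
      double sh = ca * dh + sa * dw + chc;
      double sw = -sa * dh + ca * dw + cwc;
      bool inside;
      if (linear) {
        inside = (sh >= 0 && sh <= H - 1 && sw >= 0 && sw <= W - 1);
        if (inside) {
          int h0 = (int)std::floor(sh), w0 = (int)std::floor(sw);
          int h1 = std::min(h0 + 1, H - 1), w1 = std::min(w0 + 1, W - 1);
          double th = sh - h0, tw = sw - w0;
          for (int d = 0; d < D; ++d) {
            double v00 = xp[d + D * h0 + DH * w0], v10 = xp[d + D * h1 + DH * w0];
            double v01 = xp[d + D * h0 + DH * w1], v11 = xp[d + D * h1 + DH * w1];
            op[d + D * h + DH * w] =
                (v00 * (1 - th) + v10 * th) * (1 - tw) +
                (v01 * (1 - th) + v11 * th) * tw;
          }
        } else {
          for (int d = 0; d < D; ++d) op[d + D * h + DH * w] = fill;
        }
      } else {
        int ih = (int)std::lround(sh), iw = (int)std::lround(sw);
        inside = (ih >= 0 && ih < H && iw >= 0 && iw < W);
        for (int d = 0; d < D; ++d)
          op[d + D * h + DH * w] = inside ? xp[d + D * ih + DH * iw] : fill;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// separable Gaussian blur with reflected edges
// ---------------------------------------------------------------------------

static void blur_axis(std::vector<double>& buf, int D, int H, int W, int axis,
                      const std::vector<double>& ker) {
  const int rad = ((int)ker.size() - 1) / 2;
  const int DH = D * H;
  std::vector<double> tmp(buf.size());
  const int dims[3] = {D, H, W};
  const int strides[3] = {1, D, DH};
  const int n = dims[axis], st = strides[axis];
  // iterate over all lines along `axis`
  int oa1 = (axis + 1) % 3, oa2 = (axis + 2) % 3;
  for (int i2 = 0; i2 < dims[oa2]; ++i2) {
    for (int i1 = 0; i1 < dims[oa1]; ++i1) {
      size_t base = (size_t)i1 * strides[oa1] + (size_t)i2 * strides[oa2];
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int t = -rad; t <= rad; ++t) {
          int j = i + t;
          if (j < 0) j = -j - 1;          // reflect
          if (j >= n) j = 2 * n - j - 1;
          s += ker[t + rad] * buf[base + (size_t)j * st];
        }
        tmp[base + (size_t)i * st] = s;
      }
    }
  }
  buf.swap(tmp);
}

// [[Rcpp::export(name = ".cpp_gaussian_blur3")]]
NumericVector cpp_gaussian_blur3(NumericVector x, double sd) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2];
  int rad = std::max(1, (int)std::ceil(3.0 * sd));
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int t = -rad; t <= rad; ++t) {
    ker[t + rad] = std::exp(-0.5 * t * t / (sd * sd));
    s += ker[t + rad];
  }
  for (auto& v : ker) v /= s;
  std::vector<double> buf(x.begin(), x.end());
  for (int ax = 0; ax < 3; ++ax) blur_axis(buf, D, H, W, ax, ker);
  NumericVector out(buf.begin(), buf.end());
  out.attr("dim") = xd;
  return out;
}

// [[Rcpp::export(name = ".cpp_median3")]]
NumericVector cpp_median3(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2];
  NumericVector out(x.size());
  out.attr("dim") = xd;
  const double* xp = x.begin();
  double* op = out.begin();
  const int DH = D * H;
  double nb[27];
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        int n = 0;
        for (int dw = -1; dw <= 1; ++dw) {
          int iw = std::min(std::max(w + dw, 0), W - 1);
          for (int dh = -1; dh <= 1; ++dh) {
            int ih = std::min(std::max(h + dh, 0), H - 1);
            for (int dd = -1; dd <= 1; ++dd) {
              int id = std::min(std::max(d + dd, 0), D - 1);
              nb[n++] = xp[id + D * ih + DH * iw];
            }
          }
        }
        std::nth_element(nb, nb + 13, nb + 27);
        op[d + D * h + DH * w] = nb[13];
      }
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labeling of a binary (D,H,W) mask
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_label_components26")]]
IntegerVector cpp_label_components26(IntegerVector mask) {
  IntegerVector xd = mask.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2];
  const int DH = D * H;
  IntegerVector lab(mask.size());
  lab.attr("dim") = xd;
  int next = 0;
  std::vector<int> stack;
  for (size_t start = 0; start < (size_t)mask.size(); ++start) {
    if (mask[start] == 0 || lab[start] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back((int)start);
    lab[start] = next;
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      int d = v % D, h = (v / D) % H, w = v / DH;
      for (int dw = -1; dw <= 1; ++dw) {
        int iw = w + dw;
        if (iw < 0 || iw >= W) continue;
        for (int dh = -1; dh <= 1; ++dh) {
          int ih = h + dh;
          if (ih < 0 || ih >= H) continue;
          for (int dd = -1; dd <= 1; ++dd) {
            int id = d + dd;
            if (id < 0 || id >= D) continue;
            int u = id + D * ih + DH * iw;
            if (mask[u] != 0 && lab[u] == 0) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Hungarian algorithm (minimum-cost rectangular assignment, rows <= cols).
// Returns, per row, the 1-based assigned column.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_hungarian_min")]]
IntegerVector cpp_hungarian_min(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector ans(n);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
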