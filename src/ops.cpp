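// Low-level numeric kernels: im2col convolutions, 2x2 max pooling,
// bilinear resize, polygon scanline rasterization, 3x3 box blur.
// Image convention everywhere: arma::cube (rows = y, cols = x, slices =
// channels), values double; pixel (x, y) covers [x, x+1) x [y, y+1) with
// its center at (x + 0.5, y + 0.5), origin top-left, 0-based.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// Transposed im2col layout: one ROW per output pixel (column-major over
// the output map), one COLUMN per (channel, kernel-offset) pair -- writes
// and the stride-1 inner loop are then contiguous in memory.
static mat im2col_t(const cube &x, int k, int pad, int stride,
                    int Hout, int Wout) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat colT((uword)Hout * Wout, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat &xc = x.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double *dst0 = colT.colptr((uword)c * k * k + kj * k + ki);
        for (int j = 0; j < Wout; ++j) {
          const int wj = j * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          double *dst = dst0 + (uword)j * Hout;
          const double *src = xc.colptr(wj);
          if (stride == 1) {
            const int i0 = std::max(0, pad - ki);
            const int i1 = std::min(Hout, H + pad - ki);
            if (i1 > i0)
              std::copy(src + i0 + ki - pad, src + i1 + ki - pad, dst + i0);
          } else {
            for (int i = 0; i < Hout; ++i) {
              const int hi = i * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              dst[i] = src[hi];
            }
          }
        }
      }
    }
  }
  return colT;
}

static void col2im_acc_t(const mat &dcolT, cube &dx, int k, int pad,
                         int stride, int Hout, int Wout) {
  const int H = dx.n_rows, W = dx.n_cols, C = dx.n_slices;
  for (int c = 0; c < C; ++c) {
    mat &xc = dx.slice(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double *src0 = dcolT.colptr((uword)c * k * k + kj * k + ki);
        for (int j = 0; j < Wout; ++j) {
          const int wj = j * stride + kj - pad;
          if (wj < 0 || wj >= W) continue;
          const double *src = src0 + (uword)j * Hout;
          double *dst = xc.colptr(wj);
          if (stride == 1) {
            const int i0 = std::max(0, pad - ki);
            const int i1 = std::min(Hout, H + pad - ki);
            for (int i = i0; i < i1; ++i) dst[i + ki - pad] += src[i];
          } else {
            for (int i = 0; i < Hout; ++i) {
              const int hi = i * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              dst[hi] += src[i];
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_fwd(const arma::cube &x, const arma::mat &w,
                          const arma::vec &b, int k, int pad, int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = (H + 2 * pad - k) / stride + 1;
  const int Wout = (W + 2 * pad - k) / stride + 1;
  const int Cout = w.n_rows;
  mat colT = im2col_t(x, k, pad, stride, Hout, Wout);
  mat oT = colT * w.t();               // (Hout*Wout) x Cout
  oT.each_row() += b.t();
  cube out(Hout, Wout, Cout);
  std::copy(oT.memptr(), oT.memptr() + oT.n_elem, out.memptr());
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::cube &x, const arma::mat &w,
                    const arma::cube &dout, int k, int pad, int stride) {
  const int H = x.n_rows, W = x.n_cols;
  const int Hout = dout.n_rows, Wout = dout.n_cols;
  const int Cout = w.n_rows;
  mat colT = im2col_t(x, k, pad, stride, Hout, Wout);
  mat domT((uword)Hout * Wout, Cout);
  std::copy(dout.memptr(), dout.memptr() + dout.n_elem, domT.memptr());
  mat dw = (colT.t() * domT).t();
  vec db = sum(domT, 0).t();
  mat dcolT = domT * w;
  cube dx(H, W, x.n_slices, fill::zeros);
  col2im_acc_t(dcolT, dx, k, pad, stride, Hout, Wout);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// 2x2 max pooling, stride 2; ceil_mode clips windows at the border so the
// output side is ceil(side / 2) (keeps SSD-style odd feature maps).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube &x, bool ceil_mode) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Hout = ceil_mode ? (H + 1) / 2 : H / 2;
  const int Wout = ceil_mode ? (W + 1) / 2 : W / 2;
  cube out(Hout, Wout, C);
  ucube idx(Hout, Wout, C);
  for (int c = 0; c < C; ++c) {
    const mat &xc = x.slice(c);
    for (int j = 0; j < Wout; ++j) {
      for (int i = 0; i < Hout; ++i) {
        const int i2 = std::min(2 * i + 1, H - 1);
        const int j2 = std::min(2 * j + 1, W - 1);
        double best = -datum::inf;
        uword bi = 0;
        for (int jj = 2 * j; jj <= j2; ++jj)
          for (int ii = 2 * i; ii <= i2; ++ii)
            if (xc(ii, jj) > best) {
              best = xc(ii, jj);
              bi = (uword)jj * H + ii;
            }
        out(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(Named("out") = out, Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::ucube &idx, const arma::cube &dout,
                            int H, int W) {
  const int C = dout.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat &dxc = dx.slice(c);
    const mat &dc = dout.slice(c);
    const Cube<uword> &ic = idx;
    for (uword j = 0; j < dc.n_cols; ++j)
      for (uword i = 0; i < dc.n_rows; ++i)
        dxc(ic(i, j, c)) += dc(i, j);
  }
  return dx;
}

// [[Rcpp::export]]
arma::cube cpp_resize_bilinear(const arma::cube &x, int oh, int ow) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(oh, ow, C);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int j = 0; j < ow; ++j) {
    double fx = (j + 0.5) * sx - 0.5;
    fx = std::max(0.0, std::min(fx, (double)W - 1));
    const int x0 = (int)std::floor(fx), x1 = std::min(x0 + 1, W - 1);
    const double wx = fx - x0;
    for (int i = 0; i < oh; ++i) {
      double fy = (i + 0.5) * sy - 0.5;
      fy = std::max(0.0, std::min(fy, (double)H - 1));
      const int y0 = (int)std::floor(fy), y1 = std::min(y0 + 1, H - 1);
      const double wy = fy - y0;
      for (int c = 0; c < C; ++c) {
        const mat &xc = x.slice(c);
        out(i, j, c) = (1 - wy) * ((1 - wx) * xc(y0, x0) + wx * xc(y0, x1)) +
                       wy * ((1 - wx) * xc(y1, x0) + wx * xc(y1, x1));
      }
    }
  }
  return out;
}

// Even-odd scanline fill at pixel centers: pixel (col x, row y) is inside
// iff the point (x + 0.5, y + 0.5) is inside the polygon.
// [[Rcpp::export]]
Rcpp::LogicalMatrix cpp_fill_polygon(const arma::vec &xs, const arma::vec &ys,
                                     int H, int W) {
  Rcpp::LogicalMatrix mask(H, W);
  const int n = xs.n_elem;
  std::vector<double> nodes;
  for (int r = 0; r < H; ++r) {
    const double py = r + 0.5;
    nodes.clear();
    for (int a = 0; a < n; ++a) {
      const int b = (a + 1) % n;
      const double y1 = ys[a], y2 = ys[b];
      if ((y1 <= py && y2 > py) || (y2 <= py && y1 > py)) {
        const double t = (py - y1) / (y2 - y1);
        nodes.push_back(xs[a] + t * (xs[b] - xs[a]));
      }
    }
    std::sort(nodes.begin(), nodes.end());
    for (size_t p = 0; p + 1 < nodes.size(); p += 2) {
      int c0 = (int)std::ceil(nodes[p] - 0.5);
      int c1 = (int)std::ceil(nodes[p + 1] - 0.5) - 1;
      c0 = std::max(c0, 0);
      c1 = std::min(c1, W - 1);
      for (int c = c0; c <= c1; ++c) mask(r, c) = true;
    }
  }
  return mask;
}

// Photometric distortion in HSV space: value shift dv, hue rotation dh
// (fraction of the circle), saturation scale fs; clamped back to [0, 1].
// [[Rcpp::export]]
arma::cube cpp_photometric(const arma::cube &x, double dv, double dh,
                           double fs) {
  const int n = x.n_rows * x.n_cols;
  cube out(x.n_rows, x.n_cols, 3);
  const double *r = x.slice(0).memptr(), *g = x.slice(1).memptr(),
               *b = x.slice(2).memptr();
  double *ro = out.slice(0).memptr(), *go = out.slice(1).memptr(),
         *bo = out.slice(2).memptr();
  for (int i = 0; i < n; ++i) {
    const double mx = std::max(r[i], std::max(g[i], b[i]));
    const double mn = std::min(r[i], std::min(g[i], b[i]));
    const double d = mx - mn;
    double h = 0;
    if (d > 0) {
      if (mx == r[i]) h = (g[i] - b[i]) / d;
      else if (mx == g[i]) h = (b[i] - r[i]) / d + 2.0;
      else h = (r[i] - g[i]) / d + 4.0;
      if (h < 0) h += 6.0;
      if (h >= 6.0) h -= 6.0;
    }
    double s = mx > 0 ? d / mx : 0.0;
    double v = mx;
    h = h / 6.0 + dh + 2.0;
    h = (h - (int)h) * 6.0;   // wrap to [0, 6)
    s = std::min(std::max(s * fs, 0.0), 1.0);
    v = std::min(std::max(v + dv, 0.0), 1.0);
    const int k = (int)h;
    const double f = h - k;
    const double p = v * (1 - s), q = v * (1 - s * f),
                 t = v * (1 - s * (1 - f));
    switch (k % 6) {
      case 0: ro[i] = v; go[i] = t; bo[i] = p; break;
      case 1: ro[i] = q; go[i] = v; bo[i] = p; break;
      case 2: ro[i] = p; go[i] = v; bo[i] = t; break;
      case 3: ro[i] = p; go[i] = q; bo[i] = v; break;
      case 4: ro[i] = t; go[i] = p; bo[i] = v; break;
      default: ro[i] = v; go[i] = p; bo[i] = q; break;
    }
  }
  return out;
}

// One 3x3 box-blur pass with edge clamping, applied per channel.
// [[Rcpp::export]]
arma::cube cpp_blur3(const arma::cube &x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube out(H, W, C);
  for (int c = 0; c < C; ++c) {
    const mat &xc = x.slice(c);
    mat &oc = out.slice(c);
    for (int j = 0; j < W; ++j) {
      const int j0 = std::max(j - 1, 0), j1 = std::min(j + 1, W - 1);
      for (int i = 0; i < H; ++i) {
        const int i0 = std::max(i - 1, 0), i1 = std::min(i + 1, H - 1);
        double s = 0;
        int m = 0;
        for (int jj = j0; jj <= j1; ++jj)
          for (int ii = i0; ii <= i1; ++ii) {
            s += xc(ii, jj);
            ++m;
          }
        oc(i, j) = s / m;
      }
    }
  }
  return out;
}
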