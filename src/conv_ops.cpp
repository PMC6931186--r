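// BLAS-backed convolution primitives for the 2D path networks and the 3D
// fusion post-processor. All 2D feature maps are arma::cube (H, W, C); 3D
// feature maps are R arrays of dim (D, H, W, C) handled through raw
// indexing. Convolutions are im2col + GEMM with the patch matrix kept
// pixel-major so every inner loop is contiguous; kernels are fixed-size
// (3x3 pad 1, 2x2 stride-2 pool/deconv, 3x3x3 pad 1) because the
// architectures are fixed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;

// pixel-major im2col for 3x3 pad 1: Kt is (H*W, C*9),
// column index = c*9 + (dj+1)*3 + (di+1)
static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat Kt(H * W, C * 9, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword col = c * 9 + (uword)(dj + 1) * 3 + (uword)(di + 1);
        double* dst = Kt.colptr(col);
        const uword j0 = (dj < 0) ? 1 : 0, j1 = (dj > 0) ? W - 1 : W;
        const uword i0 = (di < 0) ? 1 : 0, i1 = (di > 0) ? H - 1 : H;
        for (uword j = j0; j < j1; ++j) {
          const double* src = xc.colptr((uword)((int)j + dj)) + di;
          double* d = dst + j * H;
          for (uword i = i0; i < i1; ++i) d[i] = src[i];
        }
      }
    }
  }
  return Kt;
}

// transpose of im2col3: scatter-accumulate G (H*W, C*9) back to an image
static cube col2im3(const mat& G, uword H, uword W, uword C) {
  cube gx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& gc = gx.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const uword col = c * 9 + (uword)(dj + 1) * 3 + (uword)(di + 1);
        const double* src = G.colptr(col);
        const uword j0 = (dj < 0) ? 1 : 0, j1 = (dj > 0) ? W - 1 : W;
        const uword i0 = (di < 0) ? 1 : 0, i1 = (di > 0) ? H - 1 : H;
        for (uword j = j0; j < j1; ++j) {
          double* dst = gc.colptr((uword)((int)j + dj)) + di;
          const double* s = src + j * H;
          for (uword i = i0; i < i1; ++i) dst[i] += s[i];
        }
      }
    }
  }
  return gx;
}

// y = relu?(conv(x, w) + b); x: (H,W,Cin), w: (Cout, Cin*9), b: Cout
// [[Rcpp::export]]
arma::cube conv2d_fwd(const arma::cube& x, const arma::mat& w,
                      const arma::vec& b, bool relu = true) {
  const uword H = x.n_rows, W = x.n_cols, Cout = w.n_rows;
  mat Kt = im2col3(x);
  mat Y = Kt * w.t(); // (H*W, Cout)
  Y.each_row() += b.t();
  if (relu) Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  cube y(H, W, Cout);
  std::memcpy(y.memptr(), Y.memptr(), sizeof(double) * H * W * Cout);
  return y;
}

// backward of conv2d_fwd; y is the forward output (used for the ReLU mask)
// [[Rcpp::export]]
List conv2d_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& y,
                const arma::cube& gy, bool relu = true) {
  const uword H = x.n_rows, W = x.n_cols, Cin = x.n_slices, Cout = w.n_rows;
  mat GY(H * W, Cout);
  std::memcpy(GY.memptr(), gy.memptr(), sizeof(double) * H * W * Cout);
  if (relu) {
    const double* yp = y.memptr();
    double* g = GY.memptr();
    for (uword k = 0; k < H * W * Cout; ++k)
      if (yp[k] <= 0.0) g[k] = 0.0;
  }
  mat Kt = im2col3(x);
  mat gw = GY.t() * Kt;        // (Cout, Cin*9)
  vec gb = sum(GY, 0).t();
  mat G = GY * w;              // (H*W, Cin*9)
  cube gx = col2im3(G, H, W, Cin);
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// 2x2 average pooling, stride 2
// [[Rcpp::export]]
arma::cube avgpool2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H / 2, W / 2, C);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& yc = y.slice(c);
    for (uword j = 0; j < W / 2; ++j) {
      const double* c0 = xc.colptr(2 * j);
      const double* c1 = xc.colptr(2 * j + 1);
      double* d = yc.colptr(j);
      for (uword i = 0; i < H / 2; ++i)
        d[i] = 0.25 * (c0[2 * i] + c0[2 * i + 1] + c1[2 * i] + c1[2 * i + 1]);
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::cube avgpool2_bwd(const arma::cube& gy) {
  const uword h = gy.n_rows, w = gy.n_cols, C = gy.n_slices;
  cube gx(2 * h, 2 * w, C);
  for (uword c = 0; c < C; ++c) {
    const mat& gc = gy.slice(c);
    mat& xc = gx.slice(c);
    for (uword j = 0; j < w; ++j) {
      const double* s = gc.colptr(j);
      double* d0 = xc.colptr(2 * j);
      double* d1 = xc.colptr(2 * j + 1);
      for (uword i = 0; i < h; ++i) {
        const double g = 0.25 * s[i];
        d0[2 * i] = g; d0[2 * i + 1] = g;
        d1[2 * i] = g; d1[2 * i + 1] = g;
      }
    }
  }
  return gx;
}

// transposed convolution 2x2, stride 2 (doubles both spatial dims)
// x: (h, w, Cin); w: (Cout*4, Cin), row = co*4 + dj*2 + di; b: Cout
// [[Rcpp::export]]
arma::cube deconv2_fwd(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b) {
  const uword h = x.n_rows, wd = x.n_cols, Cin = x.n_slices;
  const uword Cout = w.n_rows / 4;
  mat Xt(h * wd, Cin);
  std::memcpy(Xt.memptr(), x.memptr(), sizeof(double) * h * wd * Cin);
  mat Y = Xt * w.t(); // (h*wd, Cout*4)
  cube y(2 * h, 2 * wd, Cout);
  for (uword co = 0; co < Cout; ++co) {
    mat& yc = y.slice(co);
    const double* y00 = Y.colptr(co * 4 + 0);
    const double* y10 = Y.colptr(co * 4 + 1);
    const double* y01 = Y.colptr(co * 4 + 2);
    const double* y11 = Y.colptr(co * 4 + 3);
    const double bc = b(co);
    for (uword j = 0; j < wd; ++j) {
      double* d0 = yc.colptr(2 * j);
      double* d1 = yc.colptr(2 * j + 1);
      const uword off = j * h;
      for (uword i = 0; i < h; ++i) {
        d0[2 * i] = y00[off + i] + bc;
        d0[2 * i + 1] = y10[off + i] + bc;
        d1[2 * i] = y01[off + i] + bc;
        d1[2 * i + 1] = y11[off + i] + bc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List deconv2_bwd(const arma::cube& x, const arma::mat& w, const arma::cube& gy) {
  const uword h = x.n_rows, wd = x.n_cols, Cin = x.n_slices;
  const uword Cout = w.n_rows / 4;
  mat GY(h * wd, Cout * 4);
  vec gb(Cout, fill::zeros);
  for (uword co = 0; co < Cout; ++co) {
    const mat& gc = gy.slice(co);
    double acc = 0.0;
    double* g00 = GY.colptr(co * 4 + 0);
    double* g10 = GY.colptr(co * 4 + 1);
    double* g01 = GY.colptr(co * 4 + 2);
    double* g11 = GY.colptr(co * 4 + 3);
    for (uword j = 0; j < wd; ++j) {
      const double* s0 = gc.colptr(2 * j);
      const double* s1 = gc.colptr(2 * j + 1);
      const uword off = j * h;
      for (uword i = 0; i < h; ++i) {
        g00[off + i] = s0[2 * i];
        g10[off + i] = s0[2 * i + 1];
        g01[off + i] = s1[2 * i];
        g11[off + i] = s1[2 * i + 1];
        acc += s0[2 * i] + s0[2 * i + 1] + s1[2 * i] + s1[2 * i + 1];
      }
    }
    gb(co) = acc;
  }
  mat Xt(h * wd, Cin);
  std::memcpy(Xt.memptr(), x.memptr(), sizeof(double) * h * wd * Cin);
  mat gw = GY.t() * Xt;  // (Cout*4, Cin)
  mat GX = GY * w;       // (h*wd, Cin)
  cube gx(h, wd, Cin);
  std::memcpy(gx.memptr(), GX.memptr(), sizeof(double) * h * wd * Cin);
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}

// ---- 3D convolution, 3x3x3 kernel, pad 1, dims preserved ----------------
// x: R array (D, H, W, C); w: (Cout, Cin*27), column index within a
// channel block = (dd+1) + (dh+1)*3 + (dw+1)*9; b: Cout.

static inline uword idx4(uword d, uword h, uword w_, uword D, uword H,
                         uword W, uword c) {
  return d + D * (h + H * (w_ + W * c));
}

// pixel-major im2col block (D*H, C*27) for one w-plane
static void im2col27_plane(const double* x, uword D, uword H, uword W,
                           uword Cin, uword wp, mat& Kt) {
  Kt.zeros();
  for (uword c = 0; c < Cin; ++c) {
    for (int dw = -1; dw <= 1; ++dw) {
      const int ws = (int)wp + dw;
      if (ws < 0 || ws >= (int)W) continue;
      for (int dh = -1; dh <= 1; ++dh) {
        for (int dd = -1; dd <= 1; ++dd) {
          const uword col = c * 27 + (uword)(dd + 1) + (uword)(dh + 1) * 3 +
                            (uword)(dw + 1) * 9;
          double* dst = Kt.colptr(col);
          const uword h0 = (dh < 0) ? 1 : 0, h1 = (dh > 0) ? H - 1 : H;
          const uword d0 = (dd < 0) ? 1 : 0, d1 = (dd > 0) ? D - 1 : D;
          for (uword h = h0; h < h1; ++h) {
            const double* src =
                x + idx4(0, (uword)((int)h + dh), (uword)ws, D, H, W, c) + dd;
            double* dcol = dst + h * D;
            for (uword d = d0; d < d1; ++d) dcol[d] = src[d];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd(const NumericVector& xr, const arma::mat& w,
                         const arma::vec& b, bool relu = true) {
  NumericVector dims = xr.attr("dim");
  const uword D = dims[0], H = dims[1], W = dims[2], Cin = dims[3];
  const uword Cout = w.n_rows;
  NumericVector yr(D * H * W * Cout);
  yr.attr("dim") = NumericVector::create(D, H, W, Cout);
  const double* x = xr.begin();
  double* y = yr.begin();
  mat Kt(D * H, Cin * 27);
  for (uword wp = 0; wp < W; ++wp) {
    im2col27_plane(x, D, H, W, Cin, wp, Kt);
    mat Y = Kt * w.t(); // (D*H, Cout)
    Y.each_row() += b.t();
    if (relu) Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
    for (uword co = 0; co < Cout; ++co)
      std::memcpy(y + idx4(0, 0, wp, D, H, W, co), Y.colptr(co),
                  sizeof(double) * D * H);
  }
  return yr;
}

// [[Rcpp::export]]
List conv3d_bwd(const NumericVector& xr, const arma::mat& w,
                const NumericVector& yr, const NumericVector& gyr,
                bool relu = true) {
  NumericVector dims = xr.attr("dim");
  const uword D = dims[0], H = dims[1], W = dims[2], Cin = dims[3];
  const uword Cout = w.n_rows;
  const double* x = xr.begin();
  const double* y = yr.begin();
  const double* gyp = gyr.begin();
  NumericVector gxr(D * H * W * Cin);
  gxr.attr("dim") = NumericVector::create(D, H, W, Cin);
  double* gx = gxr.begin();
  mat gw(Cout, Cin * 27, fill::zeros);
  vec gb(Cout, fill::zeros);
  mat Kt(D * H, Cin * 27);
  mat GY(D * H, Cout);
  for (uword wp = 0; wp < W; ++wp) {
    for (uword co = 0; co < Cout; ++co) {
      const double* gsrc = gyp + idx4(0, 0, wp, D, H, W, co);
      const double* ysrc = y + idx4(0, 0, wp, D, H, W, co);
      double* dst = GY.colptr(co);
      if (relu) {
        for (uword p = 0; p < D * H; ++p)
          dst[p] = ysrc[p] > 0.0 ? gsrc[p] : 0.0;
      } else {
        std::memcpy(dst, gsrc, sizeof(double) * D * H);
      }
    }
    im2col27_plane(x, D, H, W, Cin, wp, Kt);
    gw += GY.t() * Kt;
    gb += sum(GY, 0).t();
    mat G = GY * w; // (D*H, Cin*27)
    // scatter back (transpose of im2col27_plane)
    for (uword c = 0; c < Cin; ++c) {
      for (int dw = -1; dw <= 1; ++dw) {
        const int ws = (int)wp + dw;
        if (ws < 0 || ws >= (int)W) continue;
        for (int dh = -1; dh <= 1; ++dh) {
          for (int dd = -1; dd <= 1; ++dd) {
            const uword col = c * 27 + (uword)(dd + 1) + (uword)(dh + 1) * 3 +
                              (uword)(dw + 1) * 9;
            const double* src = G.colptr(col);
            const uword h0 = (dh < 0) ? 1 : 0, h1 = (dh > 0) ? H - 1 : H;
            const uword d0 = (dd < 0) ? 1 : 0, d1 = (dd > 0) ? D - 1 : D;
            for (uword h = h0; h < h1; ++h) {
              double* dst =
                  gx + idx4(0, (uword)((int)h + dh), (uword)ws, D, H, W, c) + dd;
              const double* s = src + h * D;
              for (uword d = d0; d < d1; ++d) dst[d] += s[d];
            }
          }
        }
      }
    }
  }
  return List::create(Rcpp::Named("gx") = gxr, Rcpp::Named("gw") = gw,
                      Rcpp::Named("gb") = gb);
}
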