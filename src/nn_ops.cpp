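// Low-level numerical kernels for the network layers and image resizing.
// Batches are column-major R arrays with dim (H, W, C, N); convolutions are
// stride-1 with 'same' zero padding and square odd-sized kernels.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4d(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4di(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// gather k x k x C patches around every output pixel of one sample
// row order: di + k*dj + k*k*c ; col order: i + H*j
static void im2col(const double* x, int H, int W, int C, int k, arma::mat& cols) {
  const int pad = k / 2;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double* dst = cols.colptr(i + H * j);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (std::size_t)H * W * c;
        for (int dj = 0; dj < k; ++dj) {
          const int jj = j + dj - pad;
          const bool jok = (jj >= 0 && jj < W);
          for (int di = 0; di < k; ++di, ++r) {
            const int ii = i + di - pad;
            dst[r] = (jok && ii >= 0 && ii < H) ? xc[ii + H * jj] : 0.0;
          }
        }
      }
    }
  }
}

// scatter-add transpose of im2col
static void col2im_add(const arma::mat& cols, double* dx, int H, int W, int C, int k) {
  const int pad = k / 2;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const double* src = cols.colptr(i + H * j);
      int r = 0;
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (std::size_t)H * W * c;
        for (int dj = 0; dj < k; ++dj) {
          const int jj = j + dj - pad;
          const bool jok = (jj >= 0 && jj < W);
          for (int di = 0; di < k; ++di, ++r) {
            const int ii = i + di - pad;
            if (jok && ii >= 0 && ii < H) xc[ii + H * jj] += src[r];
          }
        }
      }
    }
  }
}

// act: 0 = linear, 1 = relu, 2 = sigmoid
// [[Rcpp::export]]
NumericVector nn_conv_forward(NumericVector x, NumericVector w, NumericVector b,
                              int act) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  if (wd[2] != C) stop("kernel channel mismatch");

  arma::mat Wm(&w[0], k * k * C, F, false, true); // (k*k*C) x F, shares memory
  arma::mat cols(k * k * C, H * W);

  NumericVector y = alloc4d(H, W, F, N);
  const std::size_t plane = (std::size_t)H * W;
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + plane * C * n, H, W, C, k, cols);
    arma::mat Y = cols.t() * Wm; // (H*W) x F, matches y's memory layout
    double* yn = &y[0] + plane * F * n;
    for (int f = 0; f < F; ++f) {
      const double bf = b[f];
      double* yf = yn + plane * f;
      const double* Yf = Y.colptr(f);
      for (std::size_t p = 0; p < plane; ++p) {
        double v = Yf[p] + bf;
        if (act == 1) v = v > 0.0 ? v : 0.0;
        else if (act == 2) v = 1.0 / (1.0 + std::exp(-v));
        yf[p] = v;
      }
    }
  }
  return y;
}

// dy is the gradient wrt the ACTIVATED output; y is the activated output
// (used to undo relu/sigmoid).  Returns dx, dw, db.
// [[Rcpp::export]]
List nn_conv_backward(NumericVector x, NumericVector w, NumericVector y,
                      NumericVector dy, int act) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], F = wd[3];
  const std::size_t plane = (std::size_t)H * W;

  arma::mat Wm(&w[0], k * k * C, F, false, true);
  arma::mat dWm(k * k * C, F, arma::fill::zeros);
  NumericVector db(F);
  NumericVector dx = alloc4d(H, W, C, N);
  arma::mat cols(k * k * C, H * W);
  arma::mat dZ(H * W, F); // pre-activation gradient, sample-local

  for (int n = 0; n < N; ++n) {
    const double* yn = &y[0] + plane * F * n;
    const double* dyn = &dy[0] + plane * F * n;
    for (int f = 0; f < F; ++f) {
      double* dzf = dZ.colptr(f);
      const double* yf = yn + plane * f;
      const double* dyf = dyn + plane * f;
      double acc = 0.0;
      for (std::size_t p = 0; p < plane; ++p) {
        double g = dyf[p];
        if (act == 1) g = yf[p] > 0.0 ? g : 0.0;
        else if (act == 2) g = g * yf[p] * (1.0 - yf[p]);
        dzf[p] = g;
        acc += g;
      }
      db[f] += acc;
    }
    im2col(&x[0] + plane * C * n, H, W, C, k, cols);
    dWm += cols * dZ;                  // (k*k*C) x F
    arma::mat dcols = Wm * dZ.t();     // (k*k*C) x (H*W)
    col2im_add(dcols, &dx[0] + plane * C * n, H, W, C, k);
  }

  NumericVector dw = alloc4d(k, k, C, F);
  std::copy(dWm.memptr(), dWm.memptr() + dWm.n_elem, &dw[0]);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
List nn_maxpool_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("pooling needs even spatial dims");
  const int h = H / 2, wo = W / 2;
  NumericVector y = alloc4d(h, wo, C, N);
  IntegerVector idx = alloc4di(h, wo, C, N); // linear index into input plane
  const std::size_t plane = (std::size_t)H * W, oplane = (std::size_t)h * wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[0] + plane * (c + (std::size_t)C * n);
      double* yc = &y[0] + oplane * (c + (std::size_t)C * n);
      int* ic = &idx[0] + oplane * (c + (std::size_t)C * n);
      for (int j = 0; j < wo; ++j) {
        for (int i = 0; i < h; ++i) {
          const int i0 = 2 * i, j0 = 2 * j;
          int best = i0 + H * j0;
          double bv = xc[best];
          const int cand[3] = { i0 + 1 + H * j0, i0 + H * (j0 + 1), i0 + 1 + H * (j0 + 1) };
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
          yc[i + h * j] = bv;
          ic[i + h * j] = best;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector nn_maxpool_backward(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector yd = dy.attr("dim");
  const int h = yd[0], wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dx = alloc4d(H, W, C, N);
  const std::size_t plane = (std::size_t)H * W, oplane = (std::size_t)h * wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dyc = &dy[0] + oplane * (c + (std::size_t)C * n);
      const int* ic = &idx[0] + oplane * (c + (std::size_t)C * n);
      double* dxc = &dx[0] + plane * (c + (std::size_t)C * n);
      for (std::size_t p = 0; p < oplane; ++p) dxc[ic[p]] += dyc[p];
    }
  }
  return dx;
}

// nearest-neighbour x2 upsampling
// [[Rcpp::export]]
NumericVector nn_upsample_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y = alloc4d(2 * H, 2 * W, C, N);
  const std::size_t plane = (std::size_t)H * W, oplane = plane * 4;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = &x[0] + plane * (c + (std::size_t)C * n);
      double* yc = &y[0] + oplane * (c + (std::size_t)C * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const double v = xc[i + H * j];
          const int i0 = 2 * i, j0 = 2 * j, Ho = 2 * H;
          yc[i0 + Ho * j0] = v;
          yc[i0 + 1 + Ho * j0] = v;
          yc[i0 + Ho * (j0 + 1)] = v;
          yc[i0 + 1 + Ho * (j0 + 1)] = v;
        }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector nn_upsample_backward(NumericVector dy) {
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  const int H = Ho / 2, W = Wo / 2;
  NumericVector dx = alloc4d(H, W, C, N);
  const std::size_t plane = (std::size_t)H * W, oplane = (std::size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* dyc = &dy[0] + oplane * (c + (std::size_t)C * n);
      double* dxc = &dx[0] + plane * (c + (std::size_t)C * n);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const int i0 = 2 * i, j0 = 2 * j;
          dxc[i + H * j] = dyc[i0 + Ho * j0] + dyc[i0 + 1 + Ho * j0] +
                           dyc[i0 + Ho * (j0 + 1)] + dyc[i0 + 1 + Ho * (j0 + 1)];
        }
    }
  }
  return dx;
}

// Keys cubic convolution kernel, a = -0.5 (Catmull-Rom)
static inline double cubic_w(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0) return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

// Bicubic interpolation with centre-aligned sampling and edge replication;
// no anti-aliasing, no range clamping (caller clamps).
// [[Rcpp::export]]
NumericMatrix nn_bicubic_resize(NumericMatrix img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  std::vector<double> wy(4), wx(4);
  for (int j = 0; j < out_w; ++j) {
    const double src_x = (j + 0.5) * sx - 0.5;
    const int x0 = (int)std::floor(src_x);
    for (int t = 0; t < 4; ++t) wx[t] = cubic_w(src_x - (x0 - 1 + t));
    for (int i = 0; i < out_h; ++i) {
      const double src_y = (i + 0.5) * sy - 0.5;
      const int y0 = (int)std::floor(src_y);
      for (int t = 0; t < 4; ++t) wy[t] = cubic_w(src_y - (y0 - 1 + t));
      double acc = 0.0;
      for (int tj = 0; tj < 4; ++tj) {
        int jj = x0 - 1 + tj;
        jj = jj < 0 ? 0 : (jj >= W ? W - 1 : jj);
        double row = 0.0;
        for (int ti = 0; ti < 4; ++ti) {
          int ii = y0 - 1 + ti;
          ii = ii < 0 ? 0 : (ii >= H ? H - 1 : ii);
          row += wy[ti] * img(ii, jj);
        }
        acc += wx[tj] * row;
      }
      out(i, j) = acc;
    }
  }
  return out;
}
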