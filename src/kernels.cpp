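// Low-level numerical kernels for the Dual ResUNet layers.
//
// Tensor layout everywhere: column-major R arrays of dim (H, W, C, N).
// Convolution weights: (k, k, Cin, Cout); transposed-conv weights: (2, 2, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// im2col for one sample: output (H*W) x (k*k*C), zero padding p = (k-1)/2.
static arma::mat im2col_one(const double *x, int H, int W, int C, int k, int p) {
  arma::mat M(H * W, k * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const double *xc = x + (size_t)ci * H * W;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int q = kr + k * kc + k * k * ci;
        double *col = M.colptr(q);
        for (int w = 0; w < W; ++w) {
          int ws = w + kc - p;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            int hs = h + kr - p;
            if (hs < 0 || hs >= H) continue;
            col[h + H * w] = xc[hs + H * ws];
          }
        }
      }
    }
  }
  return M;
}

// scatter-add of a (H*W) x (k*k*C) gradient matrix back onto the input grid
static void col2im_add(const arma::mat &dM, double *dx, int H, int W, int C, int k, int p) {
  for (int ci = 0; ci < C; ++ci) {
    double *dxc = dx + (size_t)ci * H * W;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int q = kr + k * kc + k * k * ci;
        const double *col = dM.colptr(q);
        for (int w = 0; w < W; ++w) {
          int ws = w + kc - p;
          if (ws < 0 || ws >= W) continue;
          for (int h = 0; h < H; ++h) {
            int hs = h + kr - p;
            if (hs < 0 || hs >= H) continue;
            dxc[hs + H * ws] += col[h + H * w];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims4(x), wd = dims4(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[1] != k || wd[2] != C) stop("weight dims do not match input channels");
  if (b.size() != Cout) stop("bias length must equal out channels");
  int p = (k - 1) / 2;
  arma::mat Wm(const_cast<double *>(w.begin()), k * k * C, Cout, false, true);
  NumericVector y((size_t)H * W * Cout * N);
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, p);
    arma::mat Y(y.begin() + (size_t)n * H * W * Cout, H * W, Cout, false, true);
    Y = M * Wm;
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = dims4(x), wd = dims4(w), yd = dims4(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (yd[2] != Cout || yd[0] != H || yd[1] != W || yd[3] != N) stop("dy dims mismatch");
  int p = (k - 1) / 2;
  arma::mat Wm(const_cast<double *>(w.begin()), k * k * C, Cout, false, true);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * C * Cout);
  dw.attr("dim") = wd;
  arma::mat dWm(dw.begin(), k * k * C, Cout, false, true);
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col_one(x.begin() + (size_t)n * H * W * C, H, W, C, k, p);
    arma::mat dY(const_cast<double *>(dy.begin()) + (size_t)n * H * W * Cout,
                 H * W, Cout, false, true);
    dWm += M.t() * dY;
    arma::mat dM = dY * Wm.t();
    col2im_add(dM, dx.begin() + (size_t)n * H * W * C, H, W, C, k, p);
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dY.col(co));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 transposed convolution (upsampling): y has 2H x 2W.
// [[Rcpp::export]]
NumericVector tconv2_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims4(x), wd = dims4(w);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Cout = wd[3];
  if (wd[0] != 2 || wd[1] != 2 || wd[2] != C) stop("tconv weights must be (2,2,Cin,Cout)");
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      double *yc = y.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) yc[i] = b[co];
      for (int ci = 0; ci < C; ++ci) {
        const double *xc = x.begin() + (size_t)H * W * (ci + (size_t)C * n);
        const double *wk = w.begin() + 4 * (ci + C * co);
        for (int ww = 0; ww < W; ++ww) {
          for (int h = 0; h < H; ++h) {
            double v = xc[h + H * ww];
            double *base = yc + 2 * h + Ho * (2 * ww);
            base[0] += v * wk[0];
            base[1] += v * wk[1];
            base[Ho] += v * wk[2];
            base[Ho + 1] += v * wk[3];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List tconv2_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = dims4(x), wd = dims4(w), yd = dims4(dy);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  if (Ho != 2 * H || Wo != 2 * W || yd[2] != Cout || yd[3] != N) stop("dy dims mismatch");
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(4 * (size_t)C * Cout);
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double *dyc = dy.begin() + (size_t)Ho * Wo * (co + (size_t)Cout * n);
      double s = 0.0;
      for (size_t i = 0; i < (size_t)Ho * Wo; ++i) s += dyc[i];
      db[co] += s;
      for (int ci = 0; ci < C; ++ci) {
        const double *xc = x.begin() + (size_t)H * W * (ci + (size_t)C * n);
        double *dxc = dx.begin() + (size_t)H * W * (ci + (size_t)C * n);
        const double *wk = w.begin() + 4 * (ci + C * co);
        double *dwk = dw.begin() + 4 * (ci + C * co);
        for (int ww = 0; ww < W; ++ww) {
          for (int h = 0; h < H; ++h) {
            const double *base = dyc + 2 * h + Ho * (2 * ww);
            double g0 = base[0], g1 = base[1], g2 = base[Ho], g3 = base[Ho + 1];
            double v = xc[h + H * ww];
            dxc[h + H * ww] += g0 * wk[0] + g1 * wk[1] + g2 * wk[2] + g3 * wk[3];
            dwk[0] += v * g0;
            dwk[1] += v * g1;
            dwk[2] += v * g2;
            dwk[3] += v * g3;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 stride-2 max pooling; idx records the within-window argmax (0..3)
// so the backward pass can scatter gradients exactly.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool input must have even height and width");
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t m = (size_t)C * N;
  for (size_t cn = 0; cn < m; ++cn) {
    const double *xc = x.begin() + (size_t)H * W * cn;
    double *yc = y.begin() + (size_t)Ho * Wo * cn;
    int *ic = idx.begin() + (size_t)Ho * Wo * cn;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const double *base = xc + 2 * h + H * (2 * w);
        double v[4] = {base[0], base[1], base[H], base[H + 1]};
        int best = 0;
        for (int j = 1; j < 4; ++j) if (v[j] > v[best]) best = j;
        yc[h + Ho * w] = v[best];
        ic[h + Ho * w] = best;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, IntegerVector in_dim) {
  IntegerVector yd = dims4(dy);
  int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  int H = in_dim[0], W = in_dim[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  size_t m = (size_t)C * N;
  for (size_t cn = 0; cn < m; ++cn) {
    const double *dyc = dy.begin() + (size_t)Ho * Wo * cn;
    const int *ic = idx.begin() + (size_t)Ho * Wo * cn;
    double *dxc = dx.begin() + (size_t)H * W * cn;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        int j = ic[h + Ho * w];
        int dh = j % 2 == 1 ? 1 : 0;           // j in {0:(0,0),1:(1,0),2:(0,1),3:(1,1)}
        int dw = j >= 2 ? 1 : 0;
        dxc[(2 * h + dh) + H * (2 * w + dw)] += dyc[h + Ho * w];
      }
    }
  }
  return dx;
}

// per-channel mean and biased variance over H, W, N
// [[Rcpp::export]]
List bn_stats(NumericVector x) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector mean(C), var(C);
  double m = (double)hw * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
    }
    mean[c] = s / m;
    var[c] = s2 / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var, _["m"] = m);
}

// [[Rcpp::export]]
NumericVector bn_apply(NumericVector x, NumericVector mean, NumericVector var,
                       NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = xd;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double a = gamma[c] * inv, b0 = beta[c] - gamma[c] * inv * mean[c];
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + hw * (c + (size_t)C * n);
      double *yc = y.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) yc[i] = a * xc[i] + b0;
    }
  }
  return y;
}

// training-mode batch-norm backward (statistics are functions of x)
// [[Rcpp::export]]
List bn_bwd_train(NumericVector x, NumericVector mean, NumericVector var,
                  NumericVector gamma, double eps, NumericVector dy) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  double m = (double)hw * N;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + hw * (c + (size_t)C * n);
      const double *dyc = dy.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        double xh = (xc[i] - mean[c]) * inv;
        s1 += dyc[i];
        s2 += dyc[i] * xh;
      }
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    double k = gamma[c] * inv / m;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + hw * (c + (size_t)C * n);
      const double *dyc = dy.begin() + hw * (c + (size_t)C * n);
      double *dxc = dx.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        double xh = (xc[i] - mean[c]) * inv;
        dxc[i] = k * (m * dyc[i] - s1 - xh * s2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// evaluation-mode backward (running statistics are constants)
// [[Rcpp::export]]
List bn_bwd_eval(NumericVector x, NumericVector mean, NumericVector var,
                 NumericVector gamma, double eps, NumericVector dy) {
  IntegerVector xd = dims4(x);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  size_t hw = (size_t)H * W;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double a = gamma[c] * inv;
    for (int n = 0; n < N; ++n) {
      const double *xc = x.begin() + hw * (c + (size_t)C * n);
      const double *dyc = dy.begin() + hw * (c + (size_t)C * n);
      double *dxc = dx.begin() + hw * (c + (size_t)C * n);
      for (size_t i = 0; i < hw; ++i) {
        dgamma[c] += dyc[i] * (xc[i] - mean[c]) * inv;
        dbeta[c] += dyc[i];
        dxc[i] = a * dyc[i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// bilinear resize of a single 2-d matrix with half-pixel centre alignment
// [[Rcpp::export]]
NumericMatrix bilinear_resize_cpp(NumericMatrix x, int out_h, int out_w) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix y(out_h, out_w);
  double sh = (double)H / out_h, sw = (double)W / out_w;
  for (int j = 0; j < out_w; ++j) {
    double sx = (j + 0.5) * sw - 0.5;
    if (sx < 0) sx = 0;
    if (sx > W - 1) sx = W - 1;
    int x0 = (int)std::floor(sx);
    int x1 = std::min(x0 + 1, W - 1);
    double fx = sx - x0;
    for (int i = 0; i < out_h; ++i) {
      double sy = (i + 0.5) * sh - 0.5;
      if (sy < 0) sy = 0;
      if (sy > H - 1) sy = H - 1;
      int y0 = (int)std::floor(sy);
      int y1 = std::min(y0 + 1, H - 1);
      double fy = sy - y0;
      y(i, j) = (1 - fy) * ((1 - fx) * x(y0, x0) + fx * x(y0, x1)) +
                fy * ((1 - fx) * x(y1, x0) + fx * x(y1, x1));
    }
  }
  return y;
}

// distance-to-polyline rasterizer: for every pixel within `radius` of the
// polyline, record the minimum distance and the arclength position of the
// closest point (for intensity profiles). Pixel (r, c) sits at (x=c, y=r),
// 1-based, matching R matrix indexing.
// [[Rcpp::export]]
List stroke_distance_cpp(int h, int w, NumericMatrix pts, double radius) {
  NumericMatrix dist(h, w), arc(h, w);
  std::fill(dist.begin(), dist.end(), R_PosInf);
  int m = pts.nrow();
  // cumulative arclength of the polyline vertices
  std::vector<double> cum(m, 0.0);
  for (int i = 1; i < m; ++i) {
    double dx = pts(i, 0) - pts(i - 1, 0), dy = pts(i, 1) - pts(i - 1, 1);
    cum[i] = cum[i - 1] + std::sqrt(dx * dx + dy * dy);
  }
  for (int i = 0; i + 1 < m; ++i) {
    double ax = pts(i, 0), ay = pts(i, 1);
    double bx = pts(i + 1, 0), by = pts(i + 1, 1);
    double vx = bx - ax, vy = by - ay;
    double L2 = vx * vx + vy * vy;
    int c0 = std::max(0, (int)std::floor(std::min(ax, bx) - radius) - 1);
    int c1 = std::min(w - 1, (int)std::ceil(std::max(ax, bx) + radius));
    int r0 = std::max(0, (int)std::floor(std::min(ay, by) - radius) - 1);
    int r1 = std::min(h - 1, (int)std::ceil(std::max(ay, by) + radius));
    for (int c = c0; c <= c1; ++c) {
      double px = c + 1.0;
      for (int r = r0; r <= r1; ++r) {
        double py = r + 1.0;
        double t = L2 > 0 ? ((px - ax) * vx + (py - ay) * vy) / L2 : 0.0;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
        double dx = px - (ax + t * vx), dy = py - (ay + t * vy);
        double d = std::sqrt(dx * dx + dy * dy);
        if (d < dist(r, c)) {
          dist(r, c) = d;
          arc(r, c) = cum[i] + t * std::sqrt(L2);
        }
      }
    }
  }
  return List::create(_["dist"] = dist, _["arc"] = arc,
                      _["length"] = m > 0 ? cum[m - 1] : 0.0);
}
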