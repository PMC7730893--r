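// CNN primitives over H x W x C x N column-major arrays (R layout).
// 3x3 stride-1 pad-1 convolution via im2col + GEMM, 2x2 max pooling,
// adaptive average pooling and batch normalization, each with its backward.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

// im2col for one image into rows [row0, row0 + HW) of a (nrow x 9*Cin)
// column-major buffer: column (i + 3j + 9c) holds the input plane shifted
// by (i-1, j-1), zero padded. The destination rows must be pre-zeroed.
static void im2col3(const double* xn, int H, int W, int Cin,
                    double* base, size_t nrow, size_t row0) {
  const int HW = H * W;
  for (int c = 0; c < Cin; ++c) {
    const double* plane = xn + (size_t)HW * c;
    for (int j = 0; j < 3; ++j)
      for (int i = 0; i < 3; ++i) {
        double* col = base + (size_t)(i + 3 * j + 9 * c) * nrow + row0;
        const int oy = i - 1, ox = j - 1;
        for (int x = 0; x < W; ++x) {
          int sx = x + ox;
          if (sx < 0 || sx >= W) continue;
          int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
          const double* src = plane + (size_t)H * sx + oy;
          double* dst = col + (size_t)H * x;
          for (int y = y0; y < y1; ++y) dst[y] = src[y];
        }
      }
  }
}

// images are processed in chunks so the im2col buffer stays bounded
static int conv_chunk(int HW, int Cin, int N) {
  double budget = 2.5e7; // doubles (~200 MB)
  int chunk = (int)(budget / ((double)HW * 9 * Cin));
  if (chunk < 1) chunk = 1;
  if (chunk > N) chunk = N;
  return chunk;
}

// [[Rcpp::export(name = ".conv3x3_fwd")]]
NumericVector conv3x3_fwd(const NumericVector& x, const NumericVector& w,
                          const NumericVector& b) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector dw = dims4(w);
  if (dw[0] != 3 || dw[1] != 3 || dw[2] != Cin) stop("weight shape mismatch");
  const int Cout = dw[3];
  const int HW = H * W;
  NumericVector y(Rcpp::no_init((size_t)HW * Cout * N));
  y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  const mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false, true);
  const arma::rowvec bv(const_cast<double*>(b.begin()), Cout, false, true);
  const int chunk = conv_chunk(HW, Cin, N);
  mat Kt((size_t)HW * chunk, 9 * Cin);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nc = std::min(chunk, N - n0);
    if ((size_t)HW * nc != Kt.n_rows) Kt.set_size((size_t)HW * nc, 9 * Cin);
    Kt.zeros();
    for (int k = 0; k < nc; ++k) {
      im2col3(x.begin() + (size_t)HW * Cin * (n0 + k), H, W, Cin,
              Kt.memptr(), Kt.n_rows, (size_t)HW * k);
    }
    mat Y = Kt * Wm; // (HW*nc) x Cout
    Y.each_row() += bv;
    for (int k = 0; k < nc; ++k) {
      mat Yn(y.begin() + (size_t)HW * Cout * (n0 + k), HW, Cout, false, true);
      Yn = Y.rows((size_t)HW * k, (size_t)HW * (k + 1) - 1);
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv3x3_bwd")]]
List conv3x3_bwd(const NumericVector& x, const NumericVector& w,
                 const NumericVector& dy) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], Cin = d[2], N = d[3];
  IntegerVector dw_ = dims4(w);
  const int Cout = dw_[3];
  const int HW = H * W;
  const mat Wm(const_cast<double*>(w.begin()), 9 * Cin, Cout, false, true);
  NumericVector dx(Rcpp::no_init(x.size()));
  dx.attr("dim") = d;
  std::fill(dx.begin(), dx.end(), 0.0);
  mat dWm(9 * Cin, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  const int chunk = conv_chunk(HW, Cin, N);
  mat Kt((size_t)HW * chunk, 9 * Cin);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nc = std::min(chunk, N - n0);
    if ((size_t)HW * nc != Kt.n_rows) Kt.set_size((size_t)HW * nc, 9 * Cin);
    Kt.zeros();
    for (int k = 0; k < nc; ++k) {
      im2col3(x.begin() + (size_t)HW * Cin * (n0 + k), H, W, Cin,
              Kt.memptr(), Kt.n_rows, (size_t)HW * k);
    }
    mat dY((size_t)HW * nc, Cout);
    for (int k = 0; k < nc; ++k) {
      dY.rows((size_t)HW * k, (size_t)HW * (k + 1) - 1) =
        mat(const_cast<double*>(dy.begin()) + (size_t)HW * Cout * (n0 + k),
            HW, Cout, false, true);
    }
    dWm += Kt.t() * dY;
    db += arma::sum(dY, 0);
    mat dKt = dY * Wm.t(); // (HW*nc) x 9Cin
    // col2im: scatter-add each shifted column back into dx
    for (int k = 0; k < nc; ++k) {
      double* dxn = dx.begin() + (size_t)HW * Cin * (n0 + k);
      for (int c = 0; c < Cin; ++c) {
        double* plane = dxn + (size_t)HW * c;
        for (int j = 0; j < 3; ++j)
          for (int i = 0; i < 3; ++i) {
            const double* col =
              dKt.colptr(i + 3 * j + 9 * c) + (size_t)HW * k;
            const int oy = i - 1, ox = j - 1;
            for (int xcol = 0; xcol < W; ++xcol) {
              int sx = xcol + ox;
              if (sx < 0 || sx >= W) continue;
              int y0 = std::max(0, -oy), y1 = std::min(H, H - oy);
              double* dst = plane + (size_t)H * sx + oy;
              const double* src = col + (size_t)H * xcol;
              for (int y = y0; y < y1; ++y) dst[y] += src[y];
            }
          }
      }
    }
  }
  NumericVector dwv(dWm.begin(), dWm.end());
  dwv.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const NumericVector& x) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = H / 2, Wo = W / 2;
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  NumericVector y(Rcpp::no_init(HWo * C * N));
  IntegerVector idx(Rcpp::no_init(HWo * C * N));
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* q = y.begin() + HWo * (c + (size_t)C * n);
      int* qi = idx.begin() + HWo * (c + (size_t)C * n);
      for (int xo = 0; xo < Wo; ++xo)
        for (int yo = 0; yo < Ho; ++yo) {
          size_t base = (size_t)H * (2 * xo) + 2 * yo;
          size_t cand[4] = {base, base + 1, base + (size_t)H, base + (size_t)H + 1};
          size_t best = cand[0];
          double bv = p[cand[0]];
          for (int k = 1; k < 4; ++k)
            if (p[cand[k]] > bv) { bv = p[cand[k]]; best = cand[k]; }
          q[(size_t)Ho * xo + yo] = bv;
          qi[(size_t)Ho * xo + yo] = (int)(best + HW * (c + (size_t)C * n));
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(const NumericVector& dy, const IntegerVector& idx,
                           const IntegerVector& xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  const int m = dy.size();
  for (int k = 0; k < m; ++k) dx[idx[k]] += dy[k];
  return dx;
}

// PyTorch-style adaptive average pooling to a gh x gw grid
// [[Rcpp::export(name = ".adaptive_avgpool_fwd")]]
NumericVector adaptive_avgpool_fwd(const NumericVector& x, int gh, int gw) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(Rcpp::no_init((size_t)gh * gw * C * N));
  y.attr("dim") = IntegerVector::create(gh, gw, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* q = y.begin() + (size_t)gh * gw * (c + (size_t)C * n);
      for (int gx = 0; gx < gw; ++gx) {
        int x0 = (gx * W) / gw, x1 = ((gx + 1) * W + gw - 1) / gw;
        for (int gy = 0; gy < gh; ++gy) {
          int y0 = (gy * H) / gh, y1 = ((gy + 1) * H + gh - 1) / gh;
          double s = 0.0;
          for (int xx = x0; xx < x1; ++xx)
            for (int yy = y0; yy < y1; ++yy) s += p[(size_t)H * xx + yy];
          q[(size_t)gh * gx + gy] = s / ((x1 - x0) * (y1 - y0));
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".adaptive_avgpool_bwd")]]
NumericVector adaptive_avgpool_bwd(const NumericVector& dy,
                                   const IntegerVector& xdim, int gh, int gw) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = xdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* p = dx.begin() + HW * (c + (size_t)C * n);
      const double* q = dy.begin() + (size_t)gh * gw * (c + (size_t)C * n);
      for (int gx = 0; gx < gw; ++gx) {
        int x0 = (gx * W) / gw, x1 = ((gx + 1) * W + gw - 1) / gw;
        for (int gy = 0; gy < gh; ++gy) {
          int y0 = (gy * H) / gh, y1 = ((gy + 1) * H + gh - 1) / gh;
          double g = q[(size_t)gh * gx + gy] / ((x1 - x0) * (y1 - y0));
          for (int xx = x0; xx < x1; ++xx)
            for (int yy = y0; yy < y1; ++yy) p[(size_t)H * xx + yy] += g;
        }
      }
    }
  return dx;
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(const NumericVector& x) {
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = x.attr("dim");
  const double* p = x.begin();
  double* q = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0;
  return y;
}

// gradient through ReLU given the cached post-activation a
// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(const NumericVector& dh, const NumericVector& a) {
  if (dh.size() != a.size()) stop("shape mismatch in relu_bwd");
  NumericVector dz(Rcpp::no_init(dh.size()));
  dz.attr("dim") = dh.attr("dim");
  const double* p = dh.begin();
  const double* pa = a.begin();
  double* q = dz.begin();
  for (R_xlen_t i = 0; i < dh.size(); ++i) q[i] = pa[i] > 0 ? p[i] : 0;
  return dz;
}

// Batch normalization. In training mode returns batch (biased) statistics;
// in eval mode normalizes with the supplied running statistics. With
// `relu` the output is clamped at zero in the same pass.
// [[Rcpp::export(name = ".batchnorm_fwd")]]
List batchnorm_fwd(const NumericVector& x, const NumericVector& gamma,
                   const NumericVector& beta, double eps, bool training,
                   const NumericVector& rmean, const NumericVector& rvar,
                   bool relu = false) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const size_t m = HW * N;
  NumericVector mean(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + HW * (c + (size_t)C * n);
        for (size_t k = 0; k < HW; ++k) { s += p[k]; s2 += p[k] * p[k]; }
      }
      mean[c] = s / m;
      var[c] = s2 / m - mean[c] * mean[c];
      if (var[c] < 0) var[c] = 0;
    }
  } else {
    mean = clone(rmean);
    var = clone(rvar);
  }
  NumericVector y(Rcpp::no_init(x.size()));
  y.attr("dim") = d;
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double g = gamma[c], b = beta[c], mu = mean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* q = y.begin() + HW * (c + (size_t)C * n);
      if (relu) {
        for (size_t k = 0; k < HW; ++k) {
          double v = g * (p[k] - mu) * inv + b;
          q[k] = v > 0 ? v : 0;
        }
      } else {
        for (size_t k = 0; k < HW; ++k) q[k] = g * (p[k] - mu) * inv + b;
      }
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export(name = ".batchnorm_bwd")]]
List batchnorm_bwd(const NumericVector& x, const NumericVector& dy,
                   const NumericVector& gamma, const NumericVector& mean,
                   const NumericVector& var, double eps) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W;
  const double m = (double)HW * N;
  NumericVector dx(Rcpp::no_init(x.size()));
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double inv = 1.0 / std::sqrt(var[c] + eps);
    double mu = mean[c];
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + HW * (c + (size_t)C * n);
      for (size_t k = 0; k < HW; ++k) {
        sdy += pd[k];
        sdyx += pd[k] * (px[k] - mu) * inv;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + HW * (c + (size_t)C * n);
      const double* pd = dy.begin() + HW * (c + (size_t)C * n);
      double* pq = dx.begin() + HW * (c + (size_t)C * n);
      for (size_t k = 0; k < HW; ++k) {
        double xh = (px[k] - mu) * inv;
        pq[k] = g * inv * (pd[k] - sdy / m - xh * sdyx / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// bilinear resize of a whole batch (used to feed the network at a chosen
// input resolution)
// [[Rcpp::export(name = ".batch_resize")]]
NumericVector batch_resize(const NumericVector& x, int oh, int ow) {
  IntegerVector d = dims4(x);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t HW = (size_t)H * W, HWo = (size_t)oh * ow;
  NumericVector y(Rcpp::no_init(HWo * C * N));
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + (size_t)C * n);
      double* q = y.begin() + HWo * (c + (size_t)C * n);
      for (int xo = 0; xo < ow; ++xo) {
        double fx = (xo + 0.5) * sx - 0.5;
        int x0 = (int)std::floor(fx);
        double wx = fx - x0;
        int x0c = std::min(std::max(x0, 0), W - 1);
        int x1c = std::min(std::max(x0 + 1, 0), W - 1);
        for (int yo = 0; yo < oh; ++yo) {
          double fy = (yo + 0.5) * sy - 0.5;
          int y0 = (int)std::floor(fy);
          double wy = fy - y0;
          int y0c = std::min(std::max(y0, 0), H - 1);
          int y1c = std::min(std::max(y0 + 1, 0), H - 1);
          q[(size_t)oh * xo + yo] =
            (1 - wy) * ((1 - wx) * p[(size_t)H * x0c + y0c] + wx * p[(size_t)H * x1c + y0c]) +
            wy       * ((1 - wx) * p[(size_t)H * x0c + y1c] + wx * p[(size_t)H * x1c + y1c]);
        }
      }
    }
  return y;
}
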