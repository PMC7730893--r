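// Low-level image kernels: separable/generic convolution with reflected
// borders, bilinear resampling, Canny edge extraction and connected-component
// labelling. All matrices are H x W (rows = y), values in [0, 255] doubles.
#include <RcppArmadillo.h>
#include <stack>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// reflect index into [0, n) (border repeats the edge pixel: -1 -> 0, n -> n-1)
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export(name = ".sep_filter_reflect")]]
NumericMatrix sep_filter_reflect(const NumericMatrix& img,
                                 const NumericVector& krow,
                                 const NumericVector& kcol) {
  const int H = img.nrow(), W = img.ncol();
  const int kr = krow.size(), kc = kcol.size();
  const int rr = kr / 2, rc = kc / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // vertical pass (along rows/y) with krow
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      for (int k = 0; k < kr; ++k)
        s += krow[k] * img(reflect(y + k - rr, H), x);
      tmp(y, x) = s;
    }
  // horizontal pass with kcol
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      for (int k = 0; k < kc; ++k)
        s += kcol[k] * tmp(y, reflect(x + k - rc, W));
      out(y, x) = s;
    }
  return out;
}

// [[Rcpp::export(name = ".conv2d_reflect")]]
NumericMatrix conv2d_reflect(const NumericMatrix& img,
                             const NumericMatrix& kernel) {
  const int H = img.nrow(), W = img.ncol();
  const int kh = kernel.nrow(), kw = kernel.ncol();
  const int rh = kh / 2, rw = kw / 2;
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double s = 0.0;
      for (int j = 0; j < kw; ++j) {
        int xx = reflect(x + j - rw, W);
        for (int i = 0; i < kh; ++i)
          s += kernel(i, j) * img(reflect(y + i - rh, H), xx);
      }
      out(y, x) = s;
    }
  return out;
}

// [[Rcpp::export(name = ".bilinear_resize")]]
NumericMatrix bilinear_resize(const NumericMatrix& img, int oh, int ow) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(oh, ow);
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int x = 0; x < ow; ++x) {
    double fx = (x + 0.5) * sx - 0.5;
    int x0 = (int)std::floor(fx);
    double wx = fx - x0;
    int x0c = std::min(std::max(x0, 0), W - 1);
    int x1c = std::min(std::max(x0 + 1, 0), W - 1);
    for (int y = 0; y < oh; ++y) {
      double fy = (y + 0.5) * sy - 0.5;
      int y0 = (int)std::floor(fy);
      double wy = fy - y0;
      int y0c = std::min(std::max(y0, 0), H - 1);
      int y1c = std::min(std::max(y0 + 1, 0), H - 1);
      out(y, x) =
        (1 - wy) * ((1 - wx) * img(y0c, x0c) + wx * img(y0c, x1c)) +
        wy       * ((1 - wx) * img(y1c, x0c) + wx * img(y1c, x1c));
    }
  }
  return out;
}

// rotate about the image centre by `deg` counter-clockwise, bilinear
// sampling with reflected borders; output has the input's size
// [[Rcpp::export(name = ".rotate_bilinear_reflect")]]
NumericMatrix rotate_bilinear_reflect(const NumericMatrix& img, double deg) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double th = deg * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      // inverse map: source coordinates of output pixel (y, x)
      double dy = y - cy, dx = x - cx;
      double sxf =  c * dx + s * dy + cx;
      double syf = -s * dx + c * dy + cy;
      int x0 = (int)std::floor(sxf), y0 = (int)std::floor(syf);
      double wx = sxf - x0, wy = syf - y0;
      int x0r = reflect(x0, W), x1r = reflect(x0 + 1, W);
      int y0r = reflect(y0, H), y1r = reflect(y0 + 1, H);
      out(y, x) =
        (1 - wy) * ((1 - wx) * img(y0r, x0r) + wx * img(y0r, x1r)) +
        wy       * ((1 - wx) * img(y1r, x0r) + wx * img(y1r, x1r));
    }
  return out;
}

// Canny edge extraction on an intensity image: Sobel gradients, quantized
// non-maximum suppression, double-threshold hysteresis. Returns 0/1 ints.
// [[Rcpp::export(name = ".canny_edges")]]
IntegerMatrix canny_edges(const NumericMatrix& img, double low, double high) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix gx(H, W), gy(H, W), mag(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double p00 = img(reflect(y - 1, H), reflect(x - 1, W));
      double p01 = img(reflect(y - 1, H), x);
      double p02 = img(reflect(y - 1, H), reflect(x + 1, W));
      double p10 = img(y, reflect(x - 1, W));
      double p12 = img(y, reflect(x + 1, W));
      double p20 = img(reflect(y + 1, H), reflect(x - 1, W));
      double p21 = img(reflect(y + 1, H), x);
      double p22 = img(reflect(y + 1, H), reflect(x + 1, W));
      double dx = (p02 + 2 * p12 + p22) - (p00 + 2 * p10 + p20);
      double dy = (p20 + 2 * p21 + p22) - (p00 + 2 * p01 + p02);
      gx(y, x) = dx;
      gy(y, x) = dy;
      mag(y, x) = std::sqrt(dx * dx + dy * dy);
    }
  // non-maximum suppression along the quantized gradient direction
  IntegerMatrix strong(H, W), cand(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double m = mag(y, x);
      if (m < low) continue;
      double ang = std::atan2(gy(y, x), gx(y, x)) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      int dy0, dx0;
      if (ang < 22.5 || ang >= 157.5)      { dy0 = 0; dx0 = 1; }
      else if (ang < 67.5)                 { dy0 = 1; dx0 = 1; }
      else if (ang < 112.5)                { dy0 = 1; dx0 = 0; }
      else                                 { dy0 = 1; dx0 = -1; }
      double m1 = mag(reflect(y + dy0, H), reflect(x + dx0, W));
      double m2 = mag(reflect(y - dy0, H), reflect(x - dx0, W));
      if (m >= m1 && m >= m2) {
        cand(y, x) = 1;
        if (m >= high) strong(y, x) = 1;
      }
    }
  // hysteresis: keep candidates 8-connected to a strong pixel
  IntegerMatrix out(H, W);
  std::stack<std::pair<int, int> > st;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y)
      if (strong(y, x)) { out(y, x) = 1; st.push(std::make_pair(y, x)); }
  while (!st.empty()) {
    std::pair<int, int> p = st.top(); st.pop();
    for (int dy0 = -1; dy0 <= 1; ++dy0)
      for (int dx0 = -1; dx0 <= 1; ++dx0) {
        int yy = p.first + dy0, xx = p.second + dx0;
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        if (cand(yy, xx) && !out(yy, xx)) {
          out(yy, xx) = 1;
          st.push(std::make_pair(yy, xx));
        }
      }
  }
  return out;
}

// 8-connected component labelling of a binary mask; labels start at 1 in
// scan order (column-major), so the first-seen component has label 1.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::stack<std::pair<int, int> > st;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      lab(y, x) = next;
      st.push(std::make_pair(y, x));
      while (!st.empty()) {
        std::pair<int, int> p = st.top(); st.pop();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int yy = p.first + dy, xx = p.second + dx;
            if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
            if (mask(yy, xx) && !lab(yy, xx)) {
              lab(yy, xx) = next;
              st.push(std::make_pair(yy, xx));
            }
          }
      }
    }
  return lab;
}
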