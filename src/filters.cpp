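#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Symmetric (mirror) reflection of an out-of-range index: -1 -> 0, n -> n-1.
// All spatial filters in the package use this border rule.
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable correlation with a (normalised or not) 1-D kernel, mirror borders.
// The kernel is applied along rows then columns; for a product kernel this is
// identical to the full 2-D windowed sum.
// [[Rcpp::export(name = ".conv_sep_cpp")]]
NumericMatrix conv_sep_cpp(NumericMatrix x, NumericVector k) {
  const int H = x.nrow(), W = x.ncol();
  const int r = (k.size() - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  // along columns (vertical)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += k[d + r] * x(reflect(i + d, H), j);
      tmp(i, j) = s;
    }
  // along rows (horizontal)
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += k[d + r] * tmp(i, reflect(j + d, W));
      out(i, j) = s;
    }
  return out;
}

// Full 2-D correlation with mirror borders.
// [[Rcpp::export(name = ".conv2_reflect_cpp")]]
NumericMatrix conv2_reflect_cpp(NumericMatrix x, NumericMatrix k) {
  const int H = x.nrow(), W = x.ncol();
  const int rh = (k.nrow() - 1) / 2, rw = (k.ncol() - 1) / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int dj = -rw; dj <= rw; ++dj)
        for (int di = -rh; di <= rh; ++di)
          s += k(di + rh, dj + rw) * x(reflect(i + di, H), reflect(j + dj, W));
      out(i, j) = s;
    }
  return out;
}

// Full 2-D correlation with zero padding (used by the BRA local-context term).
// [[Rcpp::export(name = ".conv2_zero_cpp")]]
NumericMatrix conv2_zero_cpp(NumericMatrix x, NumericMatrix k) {
  const int H = x.nrow(), W = x.ncol();
  const int rh = (k.nrow() - 1) / 2, rw = (k.ncol() - 1) / 2;
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int dj = -rw; dj <= rw; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= W) continue;
        for (int di = -rh; di <= rh; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= H) continue;
          s += k(di + rh, dj + rw) * x(ii, jj);
        }
      }
      out(i, j) = s;
    }
  return out;
}

// One joint bilateral step: spatial Gaussian times a range Gaussian evaluated
// on the guide, normalised per pixel; window truncated at `radius`, mirror
// borders. This is the exact windowed double sum, no approximation.
// [[Rcpp::export(name = ".joint_bilateral_cpp")]]
NumericMatrix joint_bilateral_cpp(NumericMatrix input, NumericMatrix guide,
                                  double sigma_s, double sigma_r, int radius) {
  const int H = input.nrow(), W = input.ncol();
  const int r = radius;
  const double is2 = 1.0 / (2.0 * sigma_s * sigma_s);
  const double ir2 = 1.0 / (2.0 * sigma_r * sigma_r);
  // precomputed spatial weights
  NumericMatrix ws(2 * r + 1, 2 * r + 1);
  for (int dj = -r; dj <= r; ++dj)
    for (int di = -r; di <= r; ++di)
      ws(di + r, dj + r) = std::exp(-(double)(di * di + dj * dj) * is2);
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const double gp = guide(i, j);
      double num = 0.0, den = 0.0;
      for (int dj = -r; dj <= r; ++dj) {
        const int jj = reflect(j + dj, W);
        for (int di = -r; di <= r; ++di) {
          const int ii = reflect(i + di, H);
          const double dg = gp - guide(ii, jj);
          const double w = ws(di + r, dj + r) * std::exp(-dg * dg * ir2);
          num += w * input(ii, jj);
          den += w;
        }
      }
      out(i, j) = num / den;
    }
  return out;
}

// Bilinear resize with half-pixel-centre alignment; used for the coarse
// evaluation of large filter scales and for pyramid upsampling.
// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
NumericMatrix resize_bilinear_cpp(NumericMatrix x, int H2, int W2) {
  const int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H2, W2);
  const double sy = (double)H / H2, sx = (double)W / W2;
  for (int j = 0; j < W2; ++j) {
    double xc = (j + 0.5) * sx - 0.5;
    int j0 = (int)std::floor(xc);
    double fx = xc - j0;
    int j1 = j0 + 1;
    if (j0 < 0) { j0 = 0; j1 = 0; fx = 0.0; }
    if (j1 >= W) { j1 = W - 1; if (j0 >= W) j0 = W - 1; }
    for (int i = 0; i < H2; ++i) {
      double yc = (i + 0.5) * sy - 0.5;
      int i0 = (int)std::floor(yc);
      double fy = yc - i0;
      int i1 = i0 + 1;
      if (i0 < 0) { i0 = 0; i1 = 0; fy = 0.0; }
      if (i1 >= H) { i1 = H - 1; if (i0 >= H) i0 = H - 1; }
      out(i, j) = (1 - fy) * ((1 - fx) * x(i0, j0) + fx * x(i0, j1)) +
                  fy * ((1 - fx) * x(i1, j0) + fx * x(i1, j1));
    }
  }
  return out;
}
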