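#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Images are R matrices indexed [row, col] = [y, x], coordinates are 0-based
// doubles with pixel centers at integers; the valid image domain is the
// closed box [0, w-1] x [0, h-1].

static inline double bspline3(double t) {
  t = std::fabs(t);
  if (t < 1.0) return (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
  if (t < 2.0) { double u = 2.0 - t; return u * u * u / 6.0; }
  return 0.0;
}

// mirror (whole-sample symmetric) index into [0, n-1]
static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * (n - 1);
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

// in-place cubic B-spline prefilter of one line (Unser's recursive filter,
// single pole z1 = sqrt(3) - 2, mirror boundaries)
static void prefilter_line(double* c, int n, int stride) {
  if (n < 2) return;
  const double z1 = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0;
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z1)));
  if (horizon > n) horizon = n;
  for (int i = 0; i < n; ++i) c[i * stride] *= lambda;
  // causal init (mirror): c+[0] = sum_k c[k] z1^k over the reflected signal
  double sum = c[0];
  double zk = z1;
  for (int k = 1; k < horizon; ++k) {
    sum += zk * c[k * stride];
    zk *= z1;
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i * stride] += z1 * c[(i - 1) * stride];
  // anticausal init
  c[(n - 1) * stride] = (z1 / (z1 * z1 - 1.0)) *
    (c[(n - 1) * stride] + z1 * c[(n - 2) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = z1 * (c[(i + 1) * stride] - c[i * stride]);
}

// [[Rcpp::export]]
NumericMatrix cpp_bspline_prefilter(NumericMatrix img) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix coef = clone(img);
  double* p = REAL(coef);
  for (int j = 0; j < w; ++j) prefilter_line(p + (size_t)j * h, h, 1);
  for (int i = 0; i < h; ++i) prefilter_line(p + i, w, h);
  return coef;
}

static inline double eval_bspline(const double* coef, int h, int w,
                                  double x, double y) {
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  double v = 0.0;
  for (int dy = -1; dy <= 2; ++dy) {
    double wy = bspline3(y - (iy + dy));
    if (wy == 0.0) continue;
    int ry = mirror_idx(iy + dy, h);
    double acc = 0.0;
    for (int dx = -1; dx <= 2; ++dx) {
      double wx = bspline3(x - (ix + dx));
      if (wx == 0.0) continue;
      int rx = mirror_idx(ix + dx, w);
      acc += wx * coef[(size_t)rx * h + ry];
    }
    v += wy * acc;
  }
  return v;
}

static inline double eval_linear(const double* img, int h, int w,
                                 double x, double y) {
  int ix = (int)std::floor(x), iy = (int)std::floor(y);
  double fx = x - ix, fy = y - iy;
  int x0 = mirror_idx(ix, w), x1 = mirror_idx(ix + 1, w);
  int y0 = mirror_idx(iy, h), y1 = mirror_idx(iy + 1, h);
  double v00 = img[(size_t)x0 * h + y0], v10 = img[(size_t)x1 * h + y0];
  double v01 = img[(size_t)x0 * h + y1], v11 = img[(size_t)x1 * h + y1];
  return (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11);
}

// Interpolate `img` (raw intensities for order 0/1, prefiltered coefficients
// for order 3) at 0-based coordinates (xs, ys); outside the closed domain the
// background value is returned.
// [[Rcpp::export]]
NumericVector cpp_interp(NumericMatrix img, NumericVector xs, NumericVector ys,
                         int order, double background) {
  int h = img.nrow(), w = img.ncol();
  R_xlen_t n = xs.size();
  NumericVector out(n);
  const double* p = REAL(img);
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = xs[k], y = ys[k];
    if (!(x >= 0.0 && x <= w - 1.0 && y >= 0.0 && y <= h - 1.0)) {
      out[k] = background;
      continue;
    }
    if (order == 0) {
      int ix = (int)std::lround(x), iy = (int)std::lround(y);
      out[k] = p[(size_t)ix * h + iy];
    } else if (order == 1) {
      out[k] = eval_linear(p, h, w, x, y);
    } else {
      out[k] = eval_bspline(p, h, w, x, y);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(NumericMatrix img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int r = (int)std::ceil(3.5 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  NumericMatrix tmp(h, w), out(h, w);
  const double* src = REAL(img);
  // vertical pass
  for (int j = 0; j < w; ++j) {
    const double* col = src + (size_t)j * h;
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * col[mirror_idx(i + d, h)];
      tmp(i, j) = acc;
    }
  }
  // horizontal pass
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += k[d + r] * tmp(i, mirror_idx(j + d, w));
      out(i, j) = acc;
    }
  }
  return out;
}

// separable convolution with an arbitrary odd-length kernel, mirror boundary
// [[Rcpp::export]]
NumericMatrix cpp_sep_filter(NumericMatrix img, NumericVector kernel) {
  int h = img.nrow(), w = img.ncol();
  int r = ((int)kernel.size() - 1) / 2;
  NumericMatrix tmp(h, w), out(h, w);
  const double* src = REAL(img);
  for (int j = 0; j < w; ++j) {
    const double* col = src + (size_t)j * h;
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += kernel[d + r] * col[mirror_idx(i + d, h)];
      tmp(i, j) = acc;
    }
  }
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += kernel[d + r] * tmp(i, mirror_idx(j + d, w));
      out(i, j) = acc;
    }
  }
  return out;
}

// Mattes mutual information from a set of fixed-image samples.
//   movcoef : prefiltered cubic B-spline coefficients of the moving image
//   fvals   : fixed intensities at the sample points
//   xs, ys  : sample points mapped into moving-image coordinates
// Parzen windows: zero-order (box) kernel on fixed intensities, cubic
// B-spline kernel on moving intensities. Returns -MI in nats.
// [[Rcpp::export]]
List cpp_mattes_mi(NumericMatrix movcoef, NumericVector fvals,
                   NumericVector xs, NumericVector ys, int nbins,
                   double fmin, double fmax, double mmin, double mmax) {
  int h = movcoef.nrow(), w = movcoef.ncol();
  R_xlen_t n = xs.size();
  double bwf = (fmax - fmin) / nbins, bwm = (mmax - mmin) / nbins;
  const double* p = REAL(movcoef);
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  R_xlen_t nin = 0;
  if (bwf <= 0.0 || bwm <= 0.0) {
    // constant image(s): MI is zero by definition
    return List::create(_["value"] = 0.0, _["n_inside"] = (double)n,
                        _["fraction"] = 1.0, _["degenerate"] = true);
  }
  for (R_xlen_t k = 0; k < n; ++k) {
    double x = xs[k], y = ys[k];
    if (!(x >= 0.0 && x <= w - 1.0 && y >= 0.0 && y <= h - 1.0)) continue;
    ++nin;
    double m = eval_bspline(p, h, w, x, y);
    int bf = (int)std::floor((fvals[k] - fmin) / bwf);
    if (bf < 0) bf = 0;
    if (bf > nbins - 1) bf = nbins - 1;
    double u = (m - mmin) / bwm - 0.5;
    int ju = (int)std::floor(u);
    for (int d = -1; d <= 2; ++d) {
      int j = ju + d;
      double wgt = bspline3(u - j);
      if (wgt == 0.0) continue;
      if (j < 0) j = 0;
      if (j > nbins - 1) j = nbins - 1;
      joint[(size_t)j * nbins + bf] += wgt;
    }
  }
  if (nin == 0)
    return List::create(_["value"] = NA_REAL, _["n_inside"] = 0.0,
                        _["fraction"] = 0.0, _["degenerate"] = false);
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  double tot = 0.0;
  for (double v : joint) tot += v;
  for (int j = 0; j < nbins; ++j)
    for (int i = 0; i < nbins; ++i) {
      double v = joint[(size_t)j * nbins + i] / tot;
      joint[(size_t)j * nbins + i] = v;
      pf[i] += v;
      pm[j] += v;
    }
  double mi = 0.0;
  for (int j = 0; j < nbins; ++j)
    for (int i = 0; i < nbins; ++i) {
      double v = joint[(size_t)j * nbins + i];
      if (v > 0.0) mi += v * std::log(v / (pf[i] * pm[j]));
    }
  return List::create(_["value"] = -mi, _["n_inside"] = (double)nin,
                      _["fraction"] = (double)nin / (double)n,
                      _["degenerate"] = false);
}
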