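#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Conventions shared with the R layer:
//  - matrices are Y x X (row = y, col = x), pixel centers at 0-based integer
//    coordinates;
//  - affine maps passed to cpp_warp_affine are OUTPUT -> INPUT samplers
//    (xin = b11*x + b12*y + b13, yin = b21*x + b22*y + b23);
//  - displacement fields sample the moving image at (x + ux, y + uy), i.e.
//    corrected(p) = moving(p + u(p)).

static inline bool finite_d(double v) { return R_finite(v); }

// bilinear sample, NA outside support or when any contributing pixel is NA
static inline double sample_bilinear_na(const NumericMatrix& img, double x, double y) {
  int ny = img.nrow(), nx = img.ncol();
  // snap numerically-identity coordinates onto the support edge
  const double eps = 1e-9;
  if (x < 0.0 && x > -eps) x = 0.0;
  if (y < 0.0 && y > -eps) y = 0.0;
  if (x > nx - 1.0 && x < nx - 1.0 + eps) x = nx - 1.0;
  if (y > ny - 1.0 && y < ny - 1.0 + eps) y = ny - 1.0;
  if (x < 0.0 || y < 0.0 || x > nx - 1.0 || y > ny - 1.0) return NA_REAL;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
  double fx = x - x0, fy = y - y0;
  double v00 = img(y0, x0), v01 = img(y0, x1), v10 = img(y1, x0), v11 = img(y1, x1);
  double w00 = (1 - fy) * (1 - fx), w01 = (1 - fy) * fx, w10 = fy * (1 - fx), w11 = fy * fx;
  // pixels with zero weight may be NA without invalidating the sample
  if ((w00 > 0 && !finite_d(v00)) || (w01 > 0 && !finite_d(v01)) ||
      (w10 > 0 && !finite_d(v10)) || (w11 > 0 && !finite_d(v11))) return NA_REAL;
  double acc = 0.0;
  if (w00 > 0) acc += w00 * v00;
  if (w01 > 0) acc += w01 * v01;
  if (w10 > 0) acc += w10 * v10;
  if (w11 > 0) acc += w11 * v11;
  return acc;
}

// bilinear sample with clamped (replicate) border, NAs treated as 0 weight
static inline double sample_bilinear_clamp(const NumericMatrix& img, double x, double y) {
  int ny = img.nrow(), nx = img.ncol();
  if (x < 0.0) x = 0.0; if (y < 0.0) y = 0.0;
  if (x > nx - 1.0) x = nx - 1.0; if (y > ny - 1.0) y = ny - 1.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
  double fx = x - x0, fy = y - y0;
  double w[4] = { (1 - fy) * (1 - fx), (1 - fy) * fx, fy * (1 - fx), fy * fx };
  double v[4] = { img(y0, x0), img(y0, x1), img(y1, x0), img(y1, x1) };
  double acc = 0.0, wsum = 0.0;
  for (int k = 0; k < 4; ++k) if (finite_d(v[k])) { acc += w[k] * v[k]; wsum += w[k]; }
  return wsum > 0 ? acc / wsum : 0.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_affine(const NumericMatrix& img, const NumericMatrix& binv) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  double b11 = binv(0, 0), b12 = binv(0, 1), b13 = binv(0, 2);
  double b21 = binv(1, 0), b22 = binv(1, 1), b23 = binv(1, 2);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double xin = b11 * x + b12 * y + b13;
      double yin = b21 * x + b22 * y + b23;
      out(y, x) = sample_bilinear_na(img, xin, yin);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_warp_field(const NumericMatrix& img, const NumericMatrix& ux,
                             const NumericMatrix& uy) {
  int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      out(y, x) = sample_bilinear_na(img, x + ux(y, x), y + uy(y, x));
  return out;
}

// sample img at arbitrary coordinate matrices (0-based x, y), NA outside
// [[Rcpp::export]]
NumericMatrix cpp_sample(const NumericMatrix& img, const NumericMatrix& X,
                         const NumericMatrix& Y) {
  int ny = X.nrow(), nx = X.ncol();
  NumericMatrix out(ny, nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      out(y, x) = sample_bilinear_na(img, X(y, x), Y(y, x));
  return out;
}

static void gauss_kernel(double sigma, std::vector<double>& k) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  k.assign(2 * r + 1, 0.0);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;
}

// separable Gaussian smoothing, replicate border, in place on a buffer
static void smooth_gauss(std::vector<double>& a, int ny, int nx,
                         const std::vector<double>& k, std::vector<double>& tmp) {
  int r = ((int)k.size() - 1) / 2;
  tmp.resize(a.size());
  // along y (contiguous within a column for column-major layout idx = y + x*ny)
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int yy = y + i; if (yy < 0) yy = 0; if (yy >= ny) yy = ny - 1;
        acc += k[i + r] * a[yy + x * ny];
      }
      tmp[y + x * ny] = acc;
    }
  }
  // along x
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      double acc = 0.0;
      for (int i = -r; i <= r; ++i) {
        int xx = x + i; if (xx < 0) xx = 0; if (xx >= nx) xx = nx - 1;
        acc += k[i + r] * tmp[y + xx * ny];
      }
      a[y + x * ny] = acc;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_smooth(const NumericMatrix& img, double sigma) {
  int ny = img.nrow(), nx = img.ncol();
  std::vector<double> a(img.begin(), img.end()), tmp;
  std::vector<double> k; gauss_kernel(sigma, k);
  smooth_gauss(a, ny, nx, k, tmp);
  NumericMatrix out(ny, nx);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// 2x2 block-average downsampling (odd trailing row/col averaged over what exists)
static void downsample2(const std::vector<double>& a, int ny, int nx,
                        std::vector<double>& out, int& oy, int& ox) {
  oy = (ny + 1) / 2; ox = (nx + 1) / 2;
  out.assign((size_t)oy * ox, 0.0);
  for (int x = 0; x < ox; ++x) {
    for (int y = 0; y < oy; ++y) {
      double acc = 0.0; int n = 0;
      for (int dy = 0; dy < 2; ++dy) for (int dx = 0; dx < 2; ++dx) {
        int yy = 2 * y + dy, xx = 2 * x + dx;
        if (yy < ny && xx < nx) { acc += a[yy + xx * ny]; ++n; }
      }
      out[y + x * oy] = acc / n;
    }
  }
}

static inline double samp_clamp_vec(const std::vector<double>& a, int ny, int nx,
                                    double x, double y) {
  if (x < 0.0) x = 0.0; if (y < 0.0) y = 0.0;
  if (x > nx - 1.0) x = nx - 1.0; if (y > ny - 1.0) y = ny - 1.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1);
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * a[y0 + x0 * ny] + fx * a[y0 + x1 * ny]) +
         fy * ((1 - fx) * a[y1 + x0 * ny] + fx * a[y1 + x1 * ny]);
}

// bilinear upsampling of a field level to (ny, nx), scaling values by `scale`
static void upsample_field(const std::vector<double>& a, int sy, int sx,
                           std::vector<double>& out, int ny, int nx, double scale) {
  out.assign((size_t)ny * nx, 0.0);
  double ry = ny > 1 ? (double)(sy - 1) / (ny - 1) : 0.0;
  double rx = nx > 1 ? (double)(sx - 1) / (nx - 1) : 0.0;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      out[y + x * ny] = scale * samp_clamp_vec(a, sy, sx, x * rx, y * ry);
}

// Demons registration with accumulated-field Gaussian smoothing.
// Returns u with corrected(p) = moving(p + u(p)).
// iters is per pyramid level, coarsest first; length(iters) = number of levels.
// constrain_axis: 0 = none, 1 = keep ux at zero, 2 = keep uy at zero
// (applied at every iteration, so the solver works in the constrained space).
// [[Rcpp::export]]
List cpp_demons(const NumericMatrix& fixed, const NumericMatrix& moving,
                IntegerVector iters, double sigma, double tol, int constrain_axis) {
  int ny = fixed.nrow(), nx = fixed.ncol();
  int nlev = iters.size();
  // build pyramids, levels[0] = finest
  std::vector<std::vector<double> > pf(nlev), pm(nlev);
  std::vector<int> pny(nlev), pnx(nlev);
  pf[0].assign(fixed.begin(), fixed.end());
  pm[0].assign(moving.begin(), moving.end());
  pny[0] = ny; pnx[0] = nx;
  for (int l = 1; l < nlev; ++l) {
    downsample2(pf[l - 1], pny[l - 1], pnx[l - 1], pf[l], pny[l], pnx[l]);
    downsample2(pm[l - 1], pny[l - 1], pnx[l - 1], pm[l], pny[l], pnx[l]);
  }
  std::vector<double> k; gauss_kernel(sigma, k);
  std::vector<double> ux, uy, tmp;
  for (int l = nlev - 1; l >= 0; --l) {
    int lny = pny[l], lnx = pnx[l];
    size_t n = (size_t)lny * lnx;
    if (l == nlev - 1) { ux.assign(n, 0.0); uy.assign(n, 0.0); }
    else {
      std::vector<double> nux, nuy;
      upsample_field(ux, pny[l + 1], pnx[l + 1], nux, lny, lnx, 2.0);
      upsample_field(uy, pny[l + 1], pnx[l + 1], nuy, lny, lnx, 2.0);
      ux.swap(nux); uy.swap(nuy);
    }
    const std::vector<double>& f = pf[l];
    const std::vector<double>& m = pm[l];
    // fixed-image gradients (central differences, replicate border)
    std::vector<double> gx(n), gy(n);
    for (int x = 0; x < lnx; ++x) {
      int xm = std::max(x - 1, 0), xp = std::min(x + 1, lnx - 1);
      for (int y = 0; y < lny; ++y) {
        int ym = std::max(y - 1, 0), yp = std::min(y + 1, lny - 1);
        gx[y + x * lny] = 0.5 * (f[y + xp * lny] - f[y + xm * lny]);
        gy[y + x * lny] = 0.5 * (f[yp + x * lny] - f[ym + x * lny]);
      }
    }
    int nit = iters[nlev - 1 - l];  // iters given coarsest-first
    for (int it = 0; it < nit; ++it) {
      double stepSum = 0.0;
      for (int x = 0; x < lnx; ++x) {
        for (int y = 0; y < lny; ++y) {
          size_t i = y + (size_t)x * lny;
          double w = samp_clamp_vec(m, lny, lnx, x + ux[i], y + uy[i]);
          double diff = w - f[i];
          // symmetric force: average the fixed-image gradient with the
          // warped-moving gradient (sampled by central differences)
          double mgx = 0.5 * (samp_clamp_vec(m, lny, lnx, x + 1 + ux[i], y + uy[i]) -
                              samp_clamp_vec(m, lny, lnx, x - 1 + ux[i], y + uy[i]));
          double mgy = 0.5 * (samp_clamp_vec(m, lny, lnx, x + ux[i], y + 1 + uy[i]) -
                              samp_clamp_vec(m, lny, lnx, x + ux[i], y - 1 + uy[i]));
          double sgx = 0.5 * (gx[i] + mgx);
          double sgy = 0.5 * (gy[i] + mgy);
          double g2 = sgx * sgx + sgy * sgy;
          double den = g2 + diff * diff;
          if (den > 1e-9) {
            double step = -diff / den;
            ux[i] += step * sgx;
            uy[i] += step * sgy;
            stepSum += std::fabs(step * sgx) + std::fabs(step * sgy);
          }
        }
      }
      if (constrain_axis == 1) std::fill(ux.begin(), ux.end(), 0.0);
      if (constrain_axis == 2) std::fill(uy.begin(), uy.end(), 0.0);
      if (constrain_axis != 1) smooth_gauss(ux, lny, lnx, k, tmp);
      if (constrain_axis != 2) smooth_gauss(uy, lny, lnx, k, tmp);
      // converged: mean per-pixel update below tolerance
      if (stepSum / n < tol) break;
    }
  }
  NumericMatrix oux(ny, nx), ouy(ny, nx);
  std::copy(ux.begin(), ux.end(), oux.begin());
  std::copy(uy.begin(), uy.end(), ouy.begin());
  return List::create(_["ux"] = oux, _["uy"] = ouy);
}

// Pyramid least-squares translation registration (Lucas-Kanade style).
// Returns (dx, dy) such that moving shifted by (dx, dy) matches fixed, i.e.
// fixed(p) ~= moving(p - (dx, dy)).
// [[Rcpp::export]]
NumericVector cpp_lk_translation(const NumericMatrix& fixed, const NumericMatrix& moving,
                                 int levels, double sigma, int maxiter) {
  int ny = fixed.nrow(), nx = fixed.ncol();
  std::vector<std::vector<double> > pf(levels), pm(levels);
  std::vector<int> pny(levels), pnx(levels);
  pf[0].assign(fixed.begin(), fixed.end());
  pm[0].assign(moving.begin(), moving.end());
  for (size_t i = 0; i < pf[0].size(); ++i) {
    if (!finite_d(pf[0][i])) pf[0][i] = 0.0;
    if (!finite_d(pm[0][i])) pm[0][i] = 0.0;
  }
  pny[0] = ny; pnx[0] = nx;
  for (int l = 1; l < levels; ++l) {
    downsample2(pf[l - 1], pny[l - 1], pnx[l - 1], pf[l], pny[l], pnx[l]);
    downsample2(pm[l - 1], pny[l - 1], pnx[l - 1], pm[l], pny[l], pnx[l]);
  }
  std::vector<double> k, tmp; gauss_kernel(sigma, k);
  double tx = 0.0, ty = 0.0;
  for (int l = levels - 1; l >= 0; --l) {
    int lny = pny[l], lnx = pnx[l];
    std::vector<double> f = pf[l], m = pm[l];
    smooth_gauss(f, lny, lnx, k, tmp);
    smooth_gauss(m, lny, lnx, k, tmp);
    if (l < levels - 1) { tx *= 2.0; ty *= 2.0; }
    for (int it = 0; it < maxiter; ++it) {
      double a11 = 0, a12 = 0, a22 = 0, b1 = 0, b2 = 0;
      for (int x = 1; x < lnx - 1; ++x) {
        for (int y = 1; y < lny - 1; ++y) {
          // warped moving value at (x, y): moving(x - tx, y - ty)
          double w = samp_clamp_vec(m, lny, lnx, x - tx, y - ty);
          double gx = 0.5 * (samp_clamp_vec(m, lny, lnx, x + 1 - tx, y - ty) -
                             samp_clamp_vec(m, lny, lnx, x - 1 - tx, y - ty));
          double gy = 0.5 * (samp_clamp_vec(m, lny, lnx, x - tx, y + 1 - ty) -
                             samp_clamp_vec(m, lny, lnx, x - tx, y - 1 - ty));
          double r = w - f[y + (size_t)x * lny];
          a11 += gx * gx; a12 += gx * gy; a22 += gy * gy;
          b1 += gx * r; b2 += gy * r;
        }
      }
      double det = a11 * a22 - a12 * a12;
      if (std::fabs(det) < 1e-12) break;
      // residual decreases along +g direction of parameter (tx shifts sample)
      double sx = (a22 * b1 - a12 * b2) / det;
      double sy = (a11 * b2 - a12 * b1) / det;
      tx += sx; ty += sy;
      if (std::fabs(sx) < 0.01 && std::fabs(sy) < 0.01) break;
    }
  }
  return NumericVector::create(tx, ty);
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher):
// distance from each pixel to the nearest background (mask == 0) pixel center.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n,
                   std::vector<int>& v, std::vector<double>& z) {
  int q, kk = 0;
  v.assign(n, 0); z.assign(n + 1, 0.0);
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[kk]] + v[kk] * v[kk])) / (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk; v[kk] = q; z[kk] = s; z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    d[q] = (q - v[kk]) * (double)(q - v[kk]) + f[v[kk]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(const NumericMatrix& mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  const double INF = 1e18;
  std::vector<double> g((size_t)ny * nx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      g[y + (size_t)x * ny] = mask(y, x) > 0 ? INF : 0.0;
  std::vector<double> f(std::max(ny, nx)), d(std::max(ny, nx));
  std::vector<int> v; std::vector<double> z;
  // columns (y direction)
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = g[y + (size_t)x * ny];
    edt_1d(f, d, ny, v, z);
    for (int y = 0; y < ny; ++y) g[y + (size_t)x * ny] = d[y];
  }
  // rows (x direction)
  NumericMatrix out(ny, nx);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = g[y + (size_t)x * ny];
    edt_1d(f, d, nx, v, z);
    for (int x = 0; x < nx; ++x) out(y, x) = std::sqrt(d[x]);
  }
  return out;
}

// Local thickness: thickness(p) = 2 * max{ r(c) : |p - c| <= r(c) } over
// foreground centers c, with inscribed radius r(c) = dist-to-background - 0.5
// (unit-square pixel model). Zero on background.
// [[Rcpp::export]]
NumericMatrix cpp_local_thickness(const NumericMatrix& mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  NumericMatrix dt = cpp_edt(mask);
  NumericMatrix th(ny, nx);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (mask(y, x) <= 0) continue;
      double r = dt(y, x) - 0.5;
      if (r < 0) continue;
      double t = 2.0 * r;
      int ri = (int)std::floor(r);
      int y0 = std::max(y - ri, 0), y1 = std::min(y + ri, ny - 1);
      int x0 = std::max(x - ri, 0), x1 = std::min(x + ri, nx - 1);
      double r2 = r * r;
      for (int xx = x0; xx <= x1; ++xx) {
        for (int yy = y0; yy <= y1; ++yy) {
          double dx = xx - x, dy = yy - y;
          if (dx * dx + dy * dy <= r2 && th(yy, xx) < t) th(yy, xx) = t;
        }
      }
    }
  }
  return th;
}
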