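// 2D ray-driven projector/backprojector and SART solver.
//
// Conventions:
//  * Images are R matrices indexed [row, col]; row = y (increasing downward),
//    col = x.  The pixel (iy, ix) has centre coordinates
//    (ix - (nx-1)/2, iy - (ny-1)/2) in a frame whose origin is the image
//    centre.  All lengths are in pixel units; unit conversion happens in R.
//  * A view at angle `ang` (radians) integrates along the direction
//    (-sin ang, cos ang); the detector coordinate s of a ray satisfies
//    x*cos(ang) + y*sin(ang) = s.  Detector bin i (0-based) sits at
//    s = (i - (n_det-1)/2) * det_spacing.
//  * Fan beam: point source at distance `sod` from the origin, virtual flat
//    detector line through the origin, perpendicular to the source direction.
//  * Line integrals use Joseph's method: unit steps along the dominant axis,
//    linear interpolation across the other axis, step weight 1/|dominant
//    direction component|.  The inner loops run branch-free over the
//    analytically determined range of steps whose both interpolation taps lie
//    inside the grid; boundary steps are handled separately.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Geom {
  int n_det;
  double det_spacing;
  bool fan;
  double sod;
  int nx, ny;
};

struct Ray {
  bool x_major;   // dominant axis is x (columns)
  double step;    // path length per dominant-axis step
  double b, m;    // minor coordinate = b + m * k
  int N, M;       // dominant-axis extent, minor-axis extent
  int k0, k1;     // inclusive range of fully interior steps
};

static inline void make_ray(const Geom &g, double ca, double sa, int i,
                            double &ox, double &oy, double &dx, double &dy) {
  double s = (i - (g.n_det - 1) / 2.0) * g.det_spacing;
  if (!g.fan) {
    ox = s * ca;
    oy = s * sa;
    dx = -sa;
    dy = ca;
  } else {
    double sx = g.sod * ca, sy = g.sod * sa;
    double px = -s * sa, py = s * ca;
    double vx = px - sx, vy = py - sy;
    double n = std::sqrt(vx * vx + vy * vy);
    ox = sx;
    oy = sy;
    dx = vx / n;
    dy = vy / n;
  }
}

static inline void ray_coef(const Geom &g, double ox, double oy, double dx,
                            double dy, Ray &r) {
  const double cx = (g.nx - 1) / 2.0, cy = (g.ny - 1) / 2.0;
  if (std::fabs(dx) >= std::fabs(dy)) {
    r.x_major = true;
    r.step = 1.0 / std::fabs(dx);
    r.m = dy / dx;
    r.b = oy + (0.0 - cx - ox) * r.m + cy;
    r.N = g.nx;
    r.M = g.ny;
  } else {
    r.x_major = false;
    r.step = 1.0 / std::fabs(dy);
    r.m = dx / dy;
    r.b = ox + (0.0 - cy - oy) * r.m + cx;
    r.N = g.ny;
    r.M = g.nx;
  }
  const double hi = r.M - 1 - 1e-9;
  if (std::fabs(r.m) < 1e-12) {
    if (r.b >= 0.0 && r.b <= hi) { r.k0 = 0; r.k1 = r.N - 1; }
    else { r.k0 = 0; r.k1 = -1; }
  } else {
    double lo_k, hi_k;
    if (r.m > 0) { lo_k = (0.0 - r.b) / r.m; hi_k = (hi - r.b) / r.m; }
    else { lo_k = (hi - r.b) / r.m; hi_k = (0.0 - r.b) / r.m; }
    lo_k = std::min(std::max(lo_k, 0.0), (double)r.N);
    hi_k = std::min(std::max(hi_k, -1.0), (double)(r.N - 1));
    r.k0 = (int)std::ceil(lo_k);
    r.k1 = (int)std::floor(hi_k);
  }
  if (r.k1 < r.k0) {
    r.k0 = 0;
    r.k1 = -1;  // no interior; boundary loop covers [0, N)
    // skip rays whose minor coordinate never intersects the grid at all
    double t0 = r.b, t1 = r.b + r.m * (r.N - 1);
    if (std::max(t0, t1) <= -1.0 || std::min(t0, t1) >= r.M) r.N = 0;
  }
}

// One boundary step of the gather (both-taps validity not guaranteed).
static inline void edge_gather(const double *img, int ny, const Ray &r, int k,
                               double &acc, double &ws) {
  double t = r.b + r.m * k;
  int j0 = (int)std::floor(t);
  double f = t - j0;
  if (r.x_major) {
    const double *col = img + (size_t)k * ny;
    if (j0 >= 0 && j0 < r.M) { acc += (1.0 - f) * col[j0]; ws += 1.0 - f; }
    if (j0 + 1 >= 0 && j0 + 1 < r.M) { acc += f * col[j0 + 1]; ws += f; }
  } else {
    if (j0 >= 0 && j0 < r.M) { acc += (1.0 - f) * img[(size_t)j0 * ny + k]; ws += 1.0 - f; }
    if (j0 + 1 >= 0 && j0 + 1 < r.M) { acc += f * img[(size_t)(j0 + 1) * ny + k]; ws += f; }
  }
}

static inline void edge_scatter(float *num, float *den, int ny, const Ray &r,
                                int k, double val);

// Gather variant that records the interior taps (j0, f) for replay by
// scatter_cached.
static double ray_gather_cached(const double *img, int ny, const Ray &r,
                                double *wsum, int *j0s, float *fs) {
  double acc = 0.0, ws = 0.0;
  for (int k = 0; k < r.k0; ++k) edge_gather(img, ny, r, k, acc, ws);
  for (int k = r.k1 + 1; k < r.N; ++k) edge_gather(img, ny, r, k, acc, ws);
  if (r.k1 >= r.k0) {
    double t = r.b + r.m * r.k0;
    if (r.x_major) {
      for (int k = r.k0; k <= r.k1; ++k, t += r.m) {
        int j0 = (int)t;
        double f = t - j0;
        j0s[k - r.k0] = j0;
        fs[k - r.k0] = (float)f;
        const double *col = img + (size_t)k * ny;
        acc += (1.0 - f) * col[j0] + f * col[j0 + 1];
      }
    } else {
      for (int k = r.k0; k <= r.k1; ++k, t += r.m) {
        int j0 = (int)t;
        double f = t - j0;
        j0s[k - r.k0] = j0;
        fs[k - r.k0] = (float)f;
        acc += (1.0 - f) * img[(size_t)j0 * ny + k] +
               f * img[(size_t)(j0 + 1) * ny + k];
      }
    }
    ws += r.k1 - r.k0 + 1;
  }
  if (wsum) *wsum = ws * r.step;
  return acc * r.step;
}

// Scatter replaying the taps recorded by ray_gather_cached.
static void ray_scatter_cached(float *num, float *den, int ny, const Ray &r,
                               double val, const int *j0s, const float *fs) {
  for (int k = 0; k < r.k0; ++k) edge_scatter(num, den, ny, r, k, val);
  for (int k = r.k1 + 1; k < r.N; ++k) edge_scatter(num, den, ny, r, k, val);
  if (r.k1 < r.k0) return;
  const float vs = (float)(val * r.step), s = (float)r.step;
  if (r.x_major) {
    for (int k = r.k0; k <= r.k1; ++k) {
      const int j0 = j0s[k - r.k0];
      const float f = fs[k - r.k0];
      float *col = num + (size_t)k * ny;
      float *dol = den + (size_t)k * ny;
      col[j0] += vs * (1.0f - f);
      col[j0 + 1] += vs * f;
      dol[j0] += s * (1.0f - f);
      dol[j0 + 1] += s * f;
    }
  } else {
    for (int k = r.k0; k <= r.k1; ++k) {
      const int j0 = j0s[k - r.k0];
      const float f = fs[k - r.k0];
      size_t i1 = (size_t)j0 * ny + k;
      num[i1] += vs * (1.0f - f);
      num[i1 + ny] += vs * f;
      den[i1] += s * (1.0f - f);
      den[i1 + ny] += s * f;
    }
  }
}

static double ray_gather(const double *img, int ny, const Ray &r,
                         double *wsum) {
  double acc = 0.0, ws = 0.0;
  for (int k = 0; k < r.k0; ++k) edge_gather(img, ny, r, k, acc, ws);
  for (int k = r.k1 + 1; k < r.N; ++k) edge_gather(img, ny, r, k, acc, ws);
  if (r.k1 >= r.k0) {
    double t = r.b + r.m * r.k0;
    if (r.x_major) {
      for (int k = r.k0; k <= r.k1; ++k, t += r.m) {
        int j0 = (int)t;
        double f = t - j0;
        const double *col = img + (size_t)k * ny;
        acc += (1.0 - f) * col[j0] + f * col[j0 + 1];
      }
    } else {
      for (int k = r.k0; k <= r.k1; ++k, t += r.m) {
        int j0 = (int)t;
        double f = t - j0;
        acc += (1.0 - f) * img[(size_t)j0 * ny + k] +
               f * img[(size_t)(j0 + 1) * ny + k];
      }
    }
    ws += r.k1 - r.k0 + 1;
  }
  if (wsum) *wsum = ws * r.step;
  return acc * r.step;
}

static inline void edge_scatter(float *num, float *den, int ny, const Ray &r,
                                int k, double val) {
  double t = r.b + r.m * k;
  int j0 = (int)std::floor(t);
  double f = t - j0;
  size_t i1, i2;
  if (r.x_major) {
    i1 = (size_t)k * ny + j0;
    i2 = i1 + 1;
  } else {
    i1 = (size_t)j0 * ny + k;
    i2 = i1 + ny;
  }
  if (j0 >= 0 && j0 < r.M) {
    num[i1] += val * (1.0 - f) * r.step;
    den[i1] += (1.0 - f) * r.step;
  }
  if (j0 + 1 >= 0 && j0 + 1 < r.M) {
    num[i2] += val * f * r.step;
    den[i2] += f * r.step;
  }
}

static void ray_scatter(float *num, float *den, int ny, const Ray &r,
                        double val) {
  for (int k = 0; k < r.k0; ++k) edge_scatter(num, den, ny, r, k, val);
  for (int k = r.k1 + 1; k < r.N; ++k) edge_scatter(num, den, ny, r, k, val);
  if (r.k1 < r.k0) return;
  double t = r.b + r.m * r.k0;
  const double vs = val * r.step, s = r.step;
  if (r.x_major) {
    for (int k = r.k0; k <= r.k1; ++k, t += r.m) {
      int j0 = (int)t;
      double f = t - j0;
      float *col = num + (size_t)k * ny;
      float *dol = den + (size_t)k * ny;
      col[j0] += vs * (1.0 - f);
      col[j0 + 1] += vs * f;
      dol[j0] += s * (1.0 - f);
      dol[j0 + 1] += s * f;
    }
  } else {
    for (int k = r.k0; k <= r.k1; ++k, t += r.m) {
      int j0 = (int)t;
      double f = t - j0;
      size_t i1 = (size_t)j0 * ny + k;
      num[i1] += vs * (1.0 - f);
      num[i1 + ny] += vs * f;
      den[i1] += s * (1.0 - f);
      den[i1 + ny] += s * f;
    }
  }
}

// In-place transpose of an n x n column-major matrix.
static void transpose_sq(double *a, int n) {
  for (int j = 1; j < n; ++j)
    for (int i = 0; i < j; ++i)
      std::swap(a[(size_t)j * n + i], a[(size_t)i * n + j]);
}

static Geom make_geom(int n_det, double det_spacing, bool fan, double sod,
                      int nx, int ny) {
  Geom g;
  g.n_det = n_det;
  g.det_spacing = det_spacing;
  g.fan = fan;
  g.sod = sod;
  g.nx = nx;
  g.ny = ny;
  return g;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(NumericMatrix img, NumericVector angles,
                                  int n_det, double det_spacing, bool fan,
                                  double sod) {
  Geom g = make_geom(n_det, det_spacing, fan, sod, img.ncol(), img.nrow());
  int n_views = angles.size();
  NumericMatrix out(n_det, n_views);
  Ray r;
  // keep a transposed copy so the dominant-axis loop is always contiguous
  // (square parallel-beam case only)
  const bool square = g.nx == g.ny;
  std::vector<double> imgT;
  if (!fan && square) {
    imgT.assign(img.begin(), img.end());
    transpose_sq(imgT.data(), g.nx);
  }
  for (int v = 0; v < n_views; ++v) {
    double ca = std::cos(angles[v]), sa = std::sin(angles[v]);
    for (int i = 0; i < n_det; ++i) {
      double ox, oy, dx, dy;
      make_ray(g, ca, sa, i, ox, oy, dx, dy);
      const double *ip = img.begin();
      if (!fan && square && std::fabs(dy) > std::fabs(dx)) {
        std::swap(ox, oy);
        std::swap(dx, dy);
        ip = imgT.data();
      }
      ray_coef(g, ox, oy, dx, dy, r);
      out(i, v) = ray_gather(ip, g.ny, r, nullptr);
    }
  }
  return out;
}

// Per-material path lengths for a single view: returns n_det x n_materials
// matrix of interpolated intersection lengths (pixel units) of each ray with
// each material's indicator image.
// [[Rcpp::export]]
NumericMatrix cpp_path_lengths_view(IntegerMatrix labels, IntegerVector mats,
                                    double angle, int n_det,
                                    double det_spacing, bool fan, double sod) {
  int nm = mats.size();
  int ny = labels.nrow(), nx = labels.ncol();
  Geom g = make_geom(n_det, det_spacing, fan, sod, nx, ny);
  NumericMatrix out(n_det, nm);
  NumericMatrix ind(ny, nx);
  Ray r;
  for (int m = 0; m < nm; ++m) {
    int lab = mats[m];
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i)
        ind(i, j) = labels(i, j) == lab ? 1.0 : 0.0;
    double ca = std::cos(angle), sa = std::sin(angle);
    for (int i = 0; i < n_det; ++i) {
      double ox, oy, dx, dy;
      make_ray(g, ca, sa, i, ox, oy, dx, dy);
      ray_coef(g, ox, oy, dx, dy, r);
      out(i, m) = ray_gather(ind.begin(), ny, r, nullptr);
    }
  }
  return out;
}

// Interpolating backprojection for parallel-beam FBP (no angular weighting;
// the pi/n_views factor is applied in R).
// [[Rcpp::export]]
NumericMatrix cpp_back_project(NumericMatrix sino, NumericVector angles,
                               double det_spacing, int nx, int ny) {
  int n_det = sino.nrow(), n_views = angles.size();
  NumericMatrix out(ny, nx);
  const double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0;
  const double s0 = (n_det - 1) / 2.0;
  for (int v = 0; v < n_views; ++v) {
    double ca = std::cos(angles[v]), sa = std::sin(angles[v]);
    const double *pv = &sino(0, v);
    for (int j = 0; j < nx; ++j) {
      double x = j - cx;
      double s = (x * ca - cy * sa) / det_spacing + s0;
      const double s_step = sa / det_spacing;
      double *oc = &out(0, j);
      for (int i = 0; i < ny; ++i, s += s_step) {
        int k0 = (int)std::floor(s);
        double f = s - k0;
        double val = 0.0;
        if (k0 >= 0 && k0 < n_det) val += (1.0 - f) * pv[k0];
        if (k0 + 1 >= 0 && k0 + 1 < n_det) val += f * pv[k0 + 1];
        oc[i] += val;
      }
    }
  }
  return out;
}

// SART with sequential view ordering, per-view additive updates with
// ray-normalized residuals and pixel-weight normalization, optional
// nonnegativity clamp applied after each full iteration.
// Returns list(image, residuals) where residuals[k] is the L2 norm of the
// pre-update view residuals swept during iteration k.
// [[Rcpp::export]]
List cpp_sart(NumericMatrix sino, NumericVector angles, double det_spacing,
              bool fan, double sod, int nx, int ny, int n_iter, double relax,
              NumericMatrix init, bool nonneg) {
  int n_det = sino.nrow(), n_views = angles.size();
  Geom g = make_geom(n_det, det_spacing, fan, sod, nx, ny);
  NumericMatrix x(ny, nx);
  std::copy(init.begin(), init.end(), x.begin());
  NumericVector resid(n_iter);
  const double eps = 1e-8;
  const size_t npix = (size_t)nx * ny;
  std::vector<float> num(npix, 0.0f), den(npix, 0.0f);
  std::vector<int> j0s(std::max(nx, ny));
  std::vector<float> fs(std::max(nx, ny));
  Ray r;
  // the working image is kept transposed whenever the dominant ray axis is
  // y, so the inner loops always stream down matrix columns (parallel beam,
  // square grid only)
  const bool reorient = !fan && nx == ny;
  double *xp = x.begin();
  bool curT = false;

  for (int it = 0; it < n_iter; ++it) {
    double ss = 0.0;
    for (int v = 0; v < n_views; ++v) {
      double ca = std::cos(angles[v]), sa = std::sin(angles[v]);
      bool needT = reorient && std::fabs(ca) > std::fabs(sa);
      if (needT != curT) {
        transpose_sq(xp, nx);
        curT = needT;
      }
      for (int i = 0; i < n_det; ++i) {
        double ox, oy, dx, dy;
        make_ray(g, ca, sa, i, ox, oy, dx, dy);
        if (curT) {
          std::swap(ox, oy);
          std::swap(dx, dy);
        }
        ray_coef(g, ox, oy, dx, dy, r);
        double ws;
        double fp = ray_gather_cached(xp, ny, r, &ws, j0s.data(), fs.data());
        double res = sino(i, v) - fp;
        ss += res * res;
        if (ws > eps)
          ray_scatter_cached(num.data(), den.data(), ny, r, res / ws,
                             j0s.data(), fs.data());
      }
      // apply the view update and zero the accumulators in the same pass
      for (size_t j = 0; j < npix; ++j) {
        if (den[j] > eps) xp[j] += relax * num[j] / den[j];
        num[j] = 0.0f;
        den[j] = 0.0f;
      }
    }
    resid[it] = std::sqrt(ss);
    if (nonneg)
      for (size_t j = 0; j < npix; ++j)
        if (xp[j] < 0.0) xp[j] = 0.0;
    if (it > 0 && resid[it] > 10.0 * resid[0] + eps)
      stop("SART diverged: sweep residual %.3g at iteration %d exceeds 10x "
           "the initial residual %.3g",
           resid[it], it + 1, resid[0]);
  }
  if (curT) transpose_sq(xp, nx);
  return List::create(Named("image") = x, Named("residuals") = resid);
}

// True data residual ||A x - p||_2 (used by tests and diagnostics).
// [[Rcpp::export]]
double cpp_data_residual(NumericMatrix img, NumericMatrix sino,
                         NumericVector angles, double det_spacing, bool fan,
                         double sod) {
  Geom g = make_geom(sino.nrow(), det_spacing, fan, sod, img.ncol(),
                     img.nrow());
  double ss = 0.0;
  Ray r;
  for (int v = 0; v < angles.size(); ++v) {
    double ca = std::cos(angles[v]), sa = std::sin(angles[v]);
    for (int i = 0; i < g.n_det; ++i) {
      double ox, oy, dx, dy;
      make_ray(g, ca, sa, i, ox, oy, dx, dy);
      ray_coef(g, ox, oy, dx, dy, r);
      double res = ray_gather(img.begin(), g.ny, r, nullptr) - sino(i, v);
      ss += res * res;
    }
  }
  return std::sqrt(ss);
}
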