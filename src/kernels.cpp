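#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Ray tracing (incremental Siddon-style grid traversal)
//
// World coordinates: grid centred at the rotation centre, x along columns
// (increasing j), y along rows (increasing i).  A ray is a zero-width line
// p(t) = o + t * d with |d| = 1, so segment lengths are in physical units.
// Cells are identified from segment midpoints; corner grazing therefore
// produces zero-length segments which are dropped (< 1e-12).
// ---------------------------------------------------------------------------

static const double kDropLen = 1e-12;

static void trace_one(double ox, double oy, double dx, double dy,
                      int nrow, int ncol, double px,
                      std::vector<int> &idx, std::vector<double> &len) {
  const double xmin = -0.5 * ncol * px, xmax = 0.5 * ncol * px;
  const double ymin = -0.5 * nrow * px, ymax = 0.5 * nrow * px;
  const double inf = std::numeric_limits<double>::infinity();

  double t0 = -inf, t1 = inf;
  if (std::fabs(dx) < 1e-15) {
    if (ox <= xmin || ox >= xmax) return;
  } else {
    double ta = (xmin - ox) / dx, tb = (xmax - ox) / dx;
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
  }
  if (std::fabs(dy) < 1e-15) {
    if (oy <= ymin || oy >= ymax) return;
  } else {
    double ta = (ymin - oy) / dy, tb = (ymax - oy) / dy;
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
  }
  if (!(t1 - t0 > kDropLen)) return;

  // next x/y grid-plane crossings after t0, as two arithmetic sequences
  double tx = inf, dtx = inf, ty = inf, dty = inf;
  if (std::fabs(dx) >= 1e-15) {
    double xs = ox + t0 * dx;
    double fk = (xs - xmin) / px;
    double k = (dx > 0) ? std::floor(fk) + 1.0 : std::ceil(fk) - 1.0;
    tx = ((xmin + k * px) - ox) / dx;
    dtx = px / std::fabs(dx);
    while (tx <= t0 + kDropLen) tx += dtx;
  }
  if (std::fabs(dy) >= 1e-15) {
    double ys = oy + t0 * dy;
    double fk = (ys - ymin) / px;
    double k = (dy > 0) ? std::floor(fk) + 1.0 : std::ceil(fk) - 1.0;
    ty = ((ymin + k * px) - oy) / dy;
    dty = px / std::fabs(dy);
    while (ty <= t0 + kDropLen) ty += dty;
  }

  double t = t0;
  while (t < t1 - kDropLen) {
    double tn = std::min(std::min(tx, ty), t1);
    double dl = tn - t;
    if (dl > kDropLen) {
      double tm = 0.5 * (t + tn);
      int j = (int)std::floor((ox + tm * dx - xmin) / px);
      int i = (int)std::floor((oy + tm * dy - ymin) / px);
      if (i >= 0 && i < nrow && j >= 0 && j < ncol) {
        idx.push_back(i + nrow * j);  // column-major linear index
        len.push_back(dl);
      }
    }
    t = tn;
    while (tx <= t + kDropLen) tx += dtx;
    while (ty <= t + kDropLen) ty += dty;
  }
}

// [[Rcpp::export(name = ".cpp_trace_ray")]]
List cpp_trace_ray(double ox, double oy, double dx, double dy,
                   int nrow, int ncol, double pixel_size) {
  double nrm = std::sqrt(dx * dx + dy * dy);
  std::vector<int> idx;
  std::vector<double> len;
  trace_one(ox, oy, dx / nrm, dy / nrm, nrow, ncol, pixel_size, idx, len);
  return List::create(_["index"] = wrap(idx), _["length"] = wrap(len));
}

// Trace all rays of a parallel-beam geometry.  angles in radians; offsets are
// signed detector positions along the axis perpendicular to the ray.
// Returns COO triplets (0-based) in view-major ray order plus per-ray sums.
// [[Rcpp::export(name = ".cpp_trace_all")]]
List cpp_trace_all(NumericVector angles, NumericVector offsets,
                   int nrow, int ncol, double pixel_size) {
  const int n_views = angles.size(), n_det = offsets.size();
  const R_xlen_t n_rays = (R_xlen_t)n_views * n_det;
  std::vector<int> pix, ray;
  std::vector<double> val;
  pix.reserve((size_t)n_rays * (size_t)(nrow + ncol) / 2);
  ray.reserve(pix.capacity());
  val.reserve(pix.capacity());
  NumericVector row_sums(n_rays);
  std::vector<int> idx;
  std::vector<double> len;
  for (int v = 0; v < n_views; ++v) {
    const double c = std::cos(angles[v]), s = std::sin(angles[v]);
    for (int d = 0; d < n_det; ++d) {
      const double t = offsets[d];
      const double ox = -t * s, oy = t * c;  // origin on the detector axis
      idx.clear(); len.clear();
      trace_one(ox, oy, c, s, nrow, ncol, pixel_size, idx, len);
      const R_xlen_t r = (R_xlen_t)v * n_det + d;
      double rs = 0.0;
      for (size_t k = 0; k < idx.size(); ++k) {
        pix.push_back(idx[k]);
        ray.push_back((int)r);
        val.push_back(len[k]);
        rs += len[k];
      }
      row_sums[r] = rs;
    }
  }
  return List::create(_["pixel"] = wrap(pix), _["ray"] = wrap(ray),
                      _["value"] = wrap(val), _["row_sums"] = row_sums);
}

// ---------------------------------------------------------------------------
// SART
//
// The system matrix W (M x N) is handed over in CSR form: row_ptr (M+1),
// col_ind, vals -- these are exactly the @p/@i/@x slots of the dgCMatrix
// holding t(W).  Rays are view-major: view v owns rows [v*nDet, (v+1)*nDet).
// ---------------------------------------------------------------------------

// Per-view column sums sum_{i in P_phi} w_ij, dense N x n_views.
// [[Rcpp::export(name = ".cpp_view_col_sums")]]
NumericMatrix cpp_view_col_sums(IntegerVector row_ptr, IntegerVector col_ind,
                                NumericVector vals, int n_pixels,
                                int n_det, int n_views) {
  NumericMatrix out(n_pixels, n_views);
  for (int v = 0; v < n_views; ++v) {
    double *col = &out(0, v);
    const R_xlen_t r0 = (R_xlen_t)v * n_det, r1 = r0 + n_det;
    for (R_xlen_t k = row_ptr[r0]; k < row_ptr[r1]; ++k)
      col[col_ind[k]] += vals[k];
  }
  return out;
}

// One full SART sweep over all views (ascending angle order), Eq.-(6)-style
// simultaneous per-view updates.  Rays with zero row sum are skipped; pixels
// with zero per-view column sum are untouched for that view.  Non-negativity
// is applied per view or after the full sweep.
// [[Rcpp::export(name = ".cpp_sart_sweep")]]
NumericVector cpp_sart_sweep(IntegerVector row_ptr, IntegerVector col_ind,
                             NumericVector vals, NumericVector f0,
                             NumericVector sino, NumericVector row_sums,
                             NumericVector lambdas, NumericMatrix view_col_sums,
                             int n_det, int n_views,
                             bool nonneg_per_view, bool nonneg_after) {
  const int N = f0.size();
  NumericVector f = clone(f0);
  std::vector<double> num((size_t)N);
  for (int v = 0; v < n_views; ++v) {
    std::memset(num.data(), 0, sizeof(double) * (size_t)N);
    const R_xlen_t r0 = (R_xlen_t)v * n_det, r1 = r0 + n_det;
    for (R_xlen_t r = r0; r < r1; ++r) {
      if (!(row_sums[r] > 0)) continue;
      double s = 0.0;
      for (R_xlen_t k = row_ptr[r]; k < row_ptr[r + 1]; ++k)
        s += vals[k] * f[col_ind[k]];
      const double c = (sino[r] - s) / row_sums[r];
      for (R_xlen_t k = row_ptr[r]; k < row_ptr[r + 1]; ++k)
        num[col_ind[k]] += c * vals[k];
    }
    const double lam = lambdas[v];
    const double *cs = &view_col_sums(0, v);
    for (int n = 0; n < N; ++n)
      if (cs[n] > 0) f[n] += lam * num[n] / cs[n];
    if (nonneg_per_view)
      for (int n = 0; n < N; ++n) if (f[n] < 0) f[n] = 0;
  }
  if (nonneg_after)
    for (int n = 0; n < N; ++n) if (f[n] < 0) f[n] = 0;
  return f;
}

// ---------------------------------------------------------------------------
// Total-variation functionals.
//
// Four-direction per-pixel magnitude:
//   mu_ij = sqrt( (d_v^2 + d_h^2 + d_d1^2 + d_d2^2) / (2 Delta^2) + eps^2 )
// with d_v = f(i,j)-f(i-1,j), d_h = f(i,j)-f(i,j-1),
//      d_d1 = f(i,j)-f(i-1,j-1), d_d2 = f(i,j)-f(i-1,j+1);
// out-of-range neighbours contribute a zero difference.  The two-direction
// variant keeps only d_v, d_h under the same normalisation.
// ---------------------------------------------------------------------------

static inline double at(const NumericMatrix &f, int i, int j) { return f(i, j); }

static void tv_mu(const NumericMatrix &f, double eps, double delta,
                  bool four, NumericMatrix &mu) {
  const int nr = f.nrow(), nc = f.ncol();
  const double inv = 1.0 / (2.0 * delta * delta);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double fij = f(i, j);
      double s = 0.0, d;
      if (i > 0) { d = fij - f(i - 1, j); s += d * d; }
      if (j > 0) { d = fij - f(i, j - 1); s += d * d; }
      if (four) {
        if (i > 0 && j > 0)      { d = fij - f(i - 1, j - 1); s += d * d; }
        if (i > 0 && j < nc - 1) { d = fij - f(i - 1, j + 1); s += d * d; }
      }
      mu(i, j) = std::sqrt(s * inv + eps * eps);
    }
}

// [[Rcpp::export(name = ".cpp_tv_value")]]
double cpp_tv_value(NumericMatrix f, double eps, double delta, bool four) {
  NumericMatrix mu(f.nrow(), f.ncol());
  tv_mu(f, eps, delta, four, mu);
  double s = 0.0;
  for (int j = 0; j < f.ncol(); ++j)
    for (int i = 0; i < f.nrow(); ++i) s += mu(i, j);
  return s;
}

// Analytic gradient of the functional sum_ij mu_ij: every mu term in which
// f(a,b) appears contributes (sum of its differences involving f(a,b),
// signed) / (2 Delta^2 mu).
// [[Rcpp::export(name = ".cpp_tv_gradient")]]
NumericMatrix cpp_tv_gradient(NumericMatrix f, double eps, double delta,
                              bool four) {
  const int nr = f.nrow(), nc = f.ncol();
  NumericMatrix mu(nr, nc), g(nr, nc);
  tv_mu(f, eps, delta, four, mu);
  const double inv = 1.0 / (2.0 * delta * delta);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double fij = f(i, j);
      double acc = 0.0, own = 0.0;
      if (i > 0) own += fij - f(i - 1, j);
      if (j > 0) own += fij - f(i, j - 1);
      if (four) {
        if (i > 0 && j > 0)      own += fij - f(i - 1, j - 1);
        if (i > 0 && j < nc - 1) own += fij - f(i - 1, j + 1);
      }
      acc += own / mu(i, j);
      if (i < nr - 1) acc -= (f(i + 1, j) - fij) / mu(i + 1, j);
      if (j < nc - 1) acc -= (f(i, j + 1) - fij) / mu(i, j + 1);
      if (four) {
        if (i < nr - 1 && j < nc - 1)
          acc -= (f(i + 1, j + 1) - fij) / mu(i + 1, j + 1);
        if (i < nr - 1 && j > 0)
          acc -= (f(i + 1, j - 1) - fij) / mu(i + 1, j - 1);
      }
      g(i, j) = acc * inv;
    }
  return g;
}

// Literal printed-form stencil (horizontal/vertical neighbours only), using
// the four-direction mu in the denominators; provided for comparison runs.
// [[Rcpp::export(name = ".cpp_tv_gradient_printed")]]
NumericMatrix cpp_tv_gradient_printed(NumericMatrix f, double eps,
                                      double delta) {
  const int nr = f.nrow(), nc = f.ncol();
  NumericMatrix mu(nr, nc), g(nr, nc);
  tv_mu(f, eps, delta, true, mu);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double fij = f(i, j);
      double centre = 0.0, acc = 0.0;
      if (i > 0)      centre += fij - f(i - 1, j);
      if (i < nr - 1) centre += fij - f(i + 1, j);
      if (j > 0)      centre += fij - f(i, j - 1);
      if (j < nc - 1) centre += fij - f(i, j + 1);
      acc = centre / mu(i, j);
      if (i < nr - 1) acc += (fij - f(i + 1, j)) / mu(i + 1, j);
      if (i > 0)      acc += (fij - f(i - 1, j)) / mu(i - 1, j);
      if (j < nc - 1) acc += (fij - f(i, j + 1)) / mu(i, j + 1);
      if (j > 0)      acc += (fij - f(i, j - 1)) / mu(i, j - 1);
      g(i, j) = acc;
    }
  return g;
}

// ---------------------------------------------------------------------------
// Separable convolution with replicate (nearest) edge padding, used by the
// windowed SSIM.  kernel is 1-D, odd length, applied along rows then columns.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sepconv_replicate")]]
NumericMatrix cpp_sepconv_replicate(NumericMatrix img, NumericVector kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kl = kernel.size(), rad = kl / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along columns (vertical, over rows)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < kl; ++k) {
        int ii = i + k - rad;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        s += kernel[k] * img(ii, j);
      }
      tmp(i, j) = s;
    }
  // along rows (horizontal, over columns)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int k = 0; k < kl; ++k) {
        int jj = j + k - rad;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        s += kernel[k] * tmp(i, jj);
      }
      out(i, j) = s;
    }
  return out;
}
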