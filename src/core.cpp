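// Computational core: stimulus placement, pseudo-color rasterization,
// per-pixel ridge-IRLS logistic fits, and raster rotation.
// All RNG goes through R's generator so set.seed() governs everything.
#include <RcppArmadillo.h>
using namespace Rcpp;

// ---- dot placement ---------------------------------------------------------

// Rejection-sample dot centers uniformly in a disc of radius `r_allowed`,
// enforcing a minimum pairwise center distance. One call places all displays
// so the R-level loop overhead is paid once per session.
// [[Rcpp::export]]
NumericMatrix cpp_place_dots(int n_displays, int n_total, double r_allowed,
                             double min_dist, int max_tries) {
  NumericMatrix out(n_displays * n_total, 2);
  const double d2 = min_dist * min_dist;
  std::vector<double> px(n_total), py(n_total);
  for (int d = 0; d < n_displays; ++d) {
    for (int i = 0; i < n_total; ++i) {
      int tries = 0;
      for (;;) {
        if (++tries > max_tries)
          stop("dot placement failed after %d tries (radius %.3f, min distance %.3f, %d dots)",
               max_tries, r_allowed, min_dist, n_total);
        double r = r_allowed * std::sqrt(R::unif_rand());
        double th = 2.0 * M_PI * R::unif_rand();
        double x = r * std::cos(th), y = r * std::sin(th);
        bool ok = true;
        for (int j = 0; j < i; ++j) {
          double dx = x - px[j], dy = y - py[j];
          if (dx * dx + dy * dy < d2) { ok = false; break; }
        }
        if (ok) { px[i] = x; py[i] = y; break; }
      }
      out(d * n_total + i, 0) = px[i];
      out(d * n_total + i, 1) = py[i];
    }
  }
  return out;
}

// ---- rasterization ---------------------------------------------------------

// Paint dots into a G x G buffer. Coordinates in degrees, origin at display
// center, x rightward, y upward; row 0 is the top of the image.
static void paint(arma::mat &buf, const double *x, const double *y,
                  const double *col, int n, double ps, double dot_radius) {
  const int G = buf.n_rows;
  const double half = G * ps / 2.0;
  buf.zeros();
  for (int i = 0; i < n; ++i) {
    // bounding box of the disc in pixel indices
    int c0 = std::max(0, (int)std::floor((x[i] - dot_radius + half) / ps));
    int c1 = std::min(G - 1, (int)std::ceil((x[i] + dot_radius + half) / ps));
    int r0 = std::max(0, (int)std::floor((half - y[i] - dot_radius) / ps));
    int r1 = std::min(G - 1, (int)std::ceil((half - y[i] + dot_radius) / ps));
    const double rr = dot_radius * dot_radius;
    for (int r = r0; r <= r1; ++r) {
      double cy = half - (r + 0.5) * ps;
      for (int c = c0; c <= c1; ++c) {
        double cx = (c + 0.5) * ps - half;
        double dx = cx - x[i], dy = cy - y[i];
        if (dx * dx + dy * dy <= rr) {
          double v = buf(r, c) + col[i];
          buf(r, c) = std::max(-1.0, std::min(1.0, v));
        }
      }
    }
  }
}

// Separable convolution with a unit-sum 1-D kernel (zero padding).
static void smooth(arma::mat &buf, arma::mat &tmp, const arma::vec &k) {
  const int G = buf.n_rows, K = k.n_elem, h = K / 2;
  tmp.zeros();
  for (int c = 0; c < G; ++c)            // along rows (vertical)
    for (int r = 0; r < G; ++r) {
      double s = 0;
      for (int m = 0; m < K; ++m) {
        int rr = r + m - h;
        if (rr >= 0 && rr < G) s += k(m) * buf(rr, c);
      }
      tmp(r, c) = s;
    }
  for (int r = 0; r < G; ++r)            // along columns (horizontal)
    for (int c = 0; c < G; ++c) {
      double s = 0;
      for (int m = 0; m < K; ++m) {
        int cc = c + m - h;
        if (cc >= 0 && cc < G) s += k(m) * tmp(r, cc);
      }
      buf(r, c) = s;
    }
}

// [[Rcpp::export]]
arma::mat cpp_rasterize(NumericVector x, NumericVector y, NumericVector col,
                        int G, double pixel_scale, double dot_radius,
                        arma::vec kernel1d) {
  arma::mat buf(G, G), tmp(G, G);
  paint(buf, x.begin(), y.begin(), col.begin(), x.size(), pixel_scale, dot_radius);
  if (kernel1d.n_elem > 1) smooth(buf, tmp, kernel1d);
  return buf;
}

// Build the regression design: smoothed pseudo-color value at every in-mask
// pixel, for every trial and display position. Dots come as flat vectors with
// 0-based trial/display indices; `rot` is an optional per-trial rotation
// (radians, counterclockwise) applied to dot coordinates before painting.
// Returns a cube of dimension (n_trials, n_displays, n_maskpixels).
// [[Rcpp::export]]
arma::cube cpp_build_design(NumericVector x, NumericVector y, NumericVector col,
                            IntegerVector trial, IntegerVector display,
                            int n_trials, int n_displays, int G,
                            double pixel_scale, double dot_radius,
                            arma::vec kernel1d, arma::uvec mask_idx,
                            NumericVector rot) {
  const int n = x.size(), P = mask_idx.n_elem;
  arma::cube D(n_trials, n_displays, P, arma::fill::zeros);
  arma::mat buf(G, G), tmp(G, G);
  std::vector<double> dx, dy, dc;
  // dots are expected grouped by (trial, display); iterate over runs
  int i = 0;
  while (i < n) {
    int t = trial[i], k = display[i];
    dx.clear(); dy.clear(); dc.clear();
    double a = rot[t], ca = std::cos(a), sa = std::sin(a);
    while (i < n && trial[i] == t && display[i] == k) {
      dx.push_back(ca * x[i] - sa * y[i]);
      dy.push_back(sa * x[i] + ca * y[i]);
      dc.push_back(col[i]);
      ++i;
    }
    paint(buf, dx.data(), dy.data(), dc.data(), (int)dx.size(), pixel_scale, dot_radius);
    if (kernel1d.n_elem > 1) smooth(buf, tmp, kernel1d);
    for (int p = 0; p < P; ++p) D(t, k, p) = buf(mask_idx(p));
  }
  return D;
}

// ---- per-pixel ridge IRLS logistic ----------------------------------------

// Penalized deviance (ridge on slopes only) for step control.
static double pen_dev(const arma::vec &y, const arma::vec &eta,
                      const arma::vec &beta, double ridge) {
  arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
  p = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  double ll = arma::accu(y % arma::log(p) + (1.0 - y) % arma::log(1.0 - p));
  double pen = 0.5 * ridge * arma::dot(beta.tail(beta.n_elem - 1),
                                       beta.tail(beta.n_elem - 1));
  return -2.0 * ll + 2.0 * pen;
}

// One penalized logistic fit; returns convergence flag.
static bool irls_one(const arma::mat &X, const arma::vec &y, double ridge,
                     int maxit, double tol, arma::vec &beta) {
  const int q = X.n_cols;
  arma::mat pen(q, q, arma::fill::zeros);
  for (int j = 1; j < q; ++j) pen(j, j) = ridge;
  beta.zeros(q);
  arma::vec eta = X * beta;
  double dev = pen_dev(y, eta, beta, ridge);
  for (int it = 0; it < maxit; ++it) {
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = arma::clamp(p % (1.0 - p), 1e-10, 0.25);
    arma::vec z = eta + (y - p) / w;
    arma::mat XtW = X.t();
    XtW.each_row() %= w.t();
    arma::mat A = XtW * X + pen;
    arma::vec b = XtW * z;
    arma::vec beta_new;
    if (!arma::solve(beta_new, A, b, arma::solve_opts::likely_sympd))
      return false;
    // step-halving if the penalized deviance worsens
    arma::vec dir = beta_new - beta;
    double step = 1.0, dev_new;
    arma::vec cand, eta_c;
    for (int h = 0; h < 12; ++h) {
      cand = beta + step * dir;
      eta_c = X * cand;
      dev_new = pen_dev(y, eta_c, cand, ridge);
      if (dev_new <= dev + 1e-10) break;
      step *= 0.5;
    }
    double delta = arma::abs(cand - beta).max();
    beta = cand; eta = eta_c; dev = dev_new;
    if (!beta.is_finite() || arma::abs(beta).max() > 1e6) return false;
    if (delta < tol) return true;
  }
  return false;
}

// Fit, for each mask pixel independently, a logistic regression of the
// (possibly fractional) response on the pixel's six per-display pseudo-color
// values plus intercept, with an L2 penalty on the slopes. On failure the
// ridge is escalated (x10, `n_escalate` times); pixels that still fail are
// returned as NaN.
// [[Rcpp::export]]
List cpp_pixel_irls(arma::vec y, arma::cube D, double ridge, int maxit,
                    double tol, int n_escalate) {
  const int n = D.n_rows, K = D.n_cols, P = D.n_slices;
  arma::mat coef(K + 1, P, arma::fill::zeros);
  arma::vec conv(P, arma::fill::zeros), ridge_used(P);
  arma::mat X(n, K + 1);
  X.col(0).ones();
  int n_failed = 0;
  for (int p = 0; p < P; ++p) {
    X.cols(1, K) = D.slice(p);
    double rj = ridge;
    arma::vec beta;
    bool ok = false;
    for (int e = 0; e <= n_escalate && !ok; ++e, rj *= 10.0)
      ok = irls_one(X, y, rj, maxit, tol, beta);
    if (ok) {
      coef.col(p) = beta;
      conv(p) = 1;
      ridge_used(p) = rj / 10.0;
    } else {
      coef.col(p).fill(NA_REAL);
      ridge_used(p) = NA_REAL;
      ++n_failed;
    }
  }
  return List::create(_["coef"] = coef, _["converged"] = conv,
                      _["ridge"] = ridge_used, _["n_failed"] = n_failed);
}

// ---- raster rotation (stability baseline) ----------------------------------

// Rotate a raster counterclockwise about the grid center by `angle` radians,
// bilinear interpolation; targets whose source neighborhood leaves the grid
// or touches a non-finite value become NaN.
// [[Rcpp::export]]
arma::mat cpp_rotate_map(arma::mat m, double angle) {
  const int G = m.n_rows;
  const double c0 = (G - 1) / 2.0;
  arma::mat out(G, G);
  out.fill(NA_REAL);
  const double ca = std::cos(-angle), sa = std::sin(-angle);
  for (int r = 0; r < G; ++r) {
    for (int c = 0; c < G; ++c) {
      // image y axis points down: flip sign for a CCW visual rotation
      double xx = c - c0, yy = c0 - r;
      double sx = ca * xx - sa * yy + c0;
      double sy = c0 - (sa * xx + ca * yy);
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      if (x0 < 0 || y0 < 0 || x0 + 1 > G - 1 || y0 + 1 > G - 1) continue;
      double fx = sx - x0, fy = sy - y0;
      double v00 = m(y0, x0), v01 = m(y0, x0 + 1),
             v10 = m(y0 + 1, x0), v11 = m(y0 + 1, x0 + 1);
      if (!std::isfinite(v00) || !std::isfinite(v01) ||
          !std::isfinite(v10) || !std::isfinite(v11)) continue;
      out(r, c) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                  fy * ((1 - fx) * v10 + fx * v11);
    }
  }
  return out;
}
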