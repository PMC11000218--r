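#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Analytic model potentials. kind: 1 = double_well_1d, 2 = radial_binding_2d,
// 3 = harmonic_1d, 4 = flat_1d. Parameters are packed by the R constructors.

static inline double dw_energy(double x, const double* p) {
  // p[0] barrier, p[1] x0
  double u = (x / p[1]) * (x / p[1]) - 1.0;
  return p[0] * u * u;
}
static inline double dw_grad(double x, const double* p) {
  double r = x / p[1];
  return 4.0 * p[0] * x * (r * r - 1.0) / (p[1] * p[1]);
}

// radial profile: U(rho) = plateau - D exp(-(rho-rmin)^2/2s1^2)
//                          + B exp(-(rho-rb)^2/2s2^2)
// p = [D, B, rho_min, rho_b, s1, s2, plateau]
static inline double rad_energy(double rho, const double* p) {
  double e1 = std::exp(-0.5 * (rho - p[2]) * (rho - p[2]) / (p[4] * p[4]));
  double e2 = std::exp(-0.5 * (rho - p[3]) * (rho - p[3]) / (p[5] * p[5]));
  return p[6] - p[0] * e1 + p[1] * e2;
}
static inline double rad_grad(double rho, const double* p) {
  double e1 = std::exp(-0.5 * (rho - p[2]) * (rho - p[2]) / (p[4] * p[4]));
  double e2 = std::exp(-0.5 * (rho - p[3]) * (rho - p[3]) / (p[5] * p[5]));
  return p[0] * (rho - p[2]) / (p[4] * p[4]) * e1
       - p[1] * (rho - p[3]) / (p[5] * p[5]) * e2;
}

// rational switching function (1-(r/r0)^m)/(1-(r/r0)^n) with the removable
// singularity at r = r0 evaluated as the limit m/n (first-order expansion
// near the singularity keeps the evaluation smooth in doubles)
static inline double switch_fun(double r, double r0, int m, int n) {
  double x = r / r0;
  if (std::fabs(x - 1.0) < 1e-6) {
    double mn = (double)m / (double)n;
    return mn * (1.0 + 0.5 * (double)(m - n) * (x - 1.0));
  }
  return (1.0 - std::pow(x, m)) / (1.0 - std::pow(x, n));
}

// [[Rcpp::export]]
double cpp_switch_fun(double r, double r0, int m, int n) {
  return switch_fun(r, r0, m, n);
}

// [[Rcpp::export]]
NumericVector cpp_potential_energy(int kind, NumericVector params,
                                   NumericMatrix pts) {
  int np = pts.nrow();
  NumericVector out(np);
  const double* p = params.begin();
  for (int i = 0; i < np; ++i) {
    if (kind == 1) out[i] = dw_energy(pts(i, 0), p);
    else if (kind == 2) {
      double rho = std::sqrt(pts(i, 0) * pts(i, 0) + pts(i, 1) * pts(i, 1));
      out[i] = rad_energy(rho, p);
    } else if (kind == 3) out[i] = 0.5 * params[0] * pts(i, 0) * pts(i, 0);
    else out[i] = 0.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_potential_gradient(int kind, NumericVector params,
                                     NumericMatrix pts) {
  int np = pts.nrow();
  int nd = pts.ncol();
  NumericMatrix out(np, nd);
  const double* p = params.begin();
  for (int i = 0; i < np; ++i) {
    if (kind == 1) out(i, 0) = dw_grad(pts(i, 0), p);
    else if (kind == 2) {
      double x = pts(i, 0), y = pts(i, 1);
      double rho = std::sqrt(x * x + y * y);
      if (rho < 1e-12) { out(i, 0) = 0.0; out(i, 1) = 0.0; }
      else {
        double g = rad_grad(rho, p);
        out(i, 0) = g * x / rho;
        out(i, 1) = g * y / rho;
      }
    } else if (kind == 3) out(i, 0) = params[0] * pts(i, 0);
    else for (int d = 0; d < nd; ++d) out(i, d) = 0.0;
  }
  return out;
}

// Overdamped Langevin (Euler-Maruyama) interleaved with well-tempered hill
// deposition on a single biased collective variable (x for 1-D kinds, the
// radial distance rho for the 2-D kind). The bias potential and its
// derivative are accumulated on a uniform grid (one update per hill) and
// evaluated by linear interpolation, the convention of grid-based
// metadynamics codes. Uses R's RNG: seed with set.seed() on the R side.
//
// monitor_mode: 0 none; 1 stop when the monitored coordination number drops
// below monitor_threshold (escape committed); 2 stop when the biased CV
// exceeds monitor_threshold (1-D escape sense).
// [[Rcpp::export]]
List cpp_run_metad(int kind, NumericVector params,
                   NumericVector x_init,
                   double dt, double friction, double kT,
                   double nsteps_d, int save_stride,
                   double w0, int dep_stride, NumericVector sigma_cv,
                   double biasf,
                   double wall_k, double wall_rho,
                   int monitor_mode, double monitor_threshold,
                   double cn_r0, int cn_m, int cn_n, double cn_max,
                   double grid_lo, double grid_hi, int grid_n,
                   NumericVector init_grid_V, NumericVector init_grid_dV,
                   NumericVector dom_lo, NumericVector dom_hi) {
  long nsteps = (long)nsteps_d;
  int nd = (kind == 2) ? 2 : 1;
  const double* p = params.begin();
  double sigma = sigma_cv[0];

  std::vector<double> gV(grid_n, 0.0), gdV(grid_n, 0.0);
  if (init_grid_V.size() == grid_n)
    for (int i = 0; i < grid_n; ++i) gV[i] = init_grid_V[i];
  if (init_grid_dV.size() == grid_n)
    for (int i = 0; i < grid_n; ++i) gdV[i] = init_grid_dV[i];
  double gh = (grid_hi - grid_lo) / (grid_n - 1);

  // linear interpolation on the bias grid, clamped at the edges
  auto bias_at = [&](double s, double* dvdout) -> double {
    double u = (s - grid_lo) / gh;
    int i0 = (int)std::floor(u);
    if (i0 < 0) i0 = 0;
    if (i0 > grid_n - 2) i0 = grid_n - 2;
    double f = u - i0;
    if (f < 0) f = 0;
    if (f > 1) f = 1;
    if (dvdout) *dvdout = gdV[i0] * (1 - f) + gdV[i0 + 1] * f;
    return gV[i0] * (1 - f) + gV[i0 + 1] * f;
  };

  long nsave = nsteps / save_stride + 1;
  NumericMatrix pos(nsave, nd);
  NumericVector cv_rec(nsave), cn_rec(nsave), bias_rec(nsave), t_rec(nsave);
  std::vector<double> hill_t, hill_c, hill_h;

  std::vector<double> x(x_init.begin(), x_init.end());
  double noise_pref = std::sqrt(2.0 * kT * dt / friction);

  bool event = false;
  double escape_time = NA_REAL;
  long isave = 0;
  long step = 0;
  int exit_step = -1;

  auto cv_of = [&]() -> double {
    if (kind == 2) return std::sqrt(x[0] * x[0] + x[1] * x[1]);
    return x[0];
  };

  auto record = [&](long stp) {
    double s = cv_of();
    double dv;
    t_rec[isave] = stp * dt;
    for (int d = 0; d < nd; ++d) pos(isave, d) = x[d];
    cv_rec[isave] = s;
    cn_rec[isave] = (kind == 2) ? cn_max * switch_fun(s, cn_r0, cn_m, cn_n)
                                : NA_REAL;
    bias_rec[isave] = bias_at(s, &dv);
    ++isave;
  };

  record(0);

  GetRNGstate();
  for (step = 1; step <= nsteps; ++step) {
    // deterministic force: potential + bias (chain rule through the CV) + wall
    double F[2] = {0.0, 0.0};
    double s = cv_of();
    double dvb;
    bias_at(s, &dvb);
    if (kind == 2) {
      double rho = s;
      double g = (rho < 1e-12) ? 0.0 : rad_grad(rho, p);
      double gw = 0.0;
      if (wall_k > 0 && rho > wall_rho) gw = 2.0 * wall_k * (rho - wall_rho);
      double gtot = g + dvb + gw;
      if (rho >= 1e-12) {
        F[0] = -gtot * x[0] / rho;
        F[1] = -gtot * x[1] / rho;
      }
    } else {
      double g;
      if (kind == 1) g = dw_grad(x[0], p);
      else if (kind == 3) g = params[0] * x[0];
      else g = 0.0;
      F[0] = -(g + dvb);
    }

    for (int d = 0; d < nd; ++d)
      x[d] += F[d] / friction * dt + noise_pref * norm_rand();

    // domain check
    for (int d = 0; d < nd; ++d) {
      if (x[d] < dom_lo[d] || x[d] > dom_hi[d]) { exit_step = (int)step; break; }
    }
    if (exit_step >= 0) break;

    // well-tempered deposition
    if (w0 > 0 && dep_stride > 0 && step % dep_stride == 0) {
      double sc = cv_of();
      double dv;
      double vcur = bias_at(sc, &dv);
      double h = w0 * std::exp(-vcur / ((biasf - 1.0) * kT));
      hill_t.push_back(step * dt);
      hill_c.push_back(sc);
      hill_h.push_back(h);
      for (int i = 0; i < grid_n; ++i) {
        double d2 = (grid_lo + i * gh) - sc;
        double e = h * std::exp(-0.5 * d2 * d2 / (sigma * sigma));
        gV[i] += e;
        gdV[i] += -d2 / (sigma * sigma) * e;
      }
    }

    if (step % save_stride == 0) record(step);

    // commitment monitor
    if (monitor_mode != 0) {
      double sc = cv_of();
      bool hit = false;
      if (monitor_mode == 1)
        hit = cn_max * switch_fun(sc, cn_r0, cn_m, cn_n) < monitor_threshold;
      else if (monitor_mode == 2)
        hit = sc > monitor_threshold;
      if (hit) {
        event = true;
        escape_time = step * dt;
        if (step % save_stride != 0) record(step);
        break;
      }
    }
  }
  PutRNGstate();

  if (exit_step >= 0)
    stop("trajectory left the evaluation domain at step %d", exit_step);

  // truncate records to what was filled
  NumericMatrix pos_o(isave, nd);
  NumericVector cv_o(isave), cn_o(isave), bias_o(isave), t_o(isave);
  for (long i = 0; i < isave; ++i) {
    for (int d = 0; d < nd; ++d) pos_o(i, d) = pos(i, d);
    cv_o[i] = cv_rec[i]; cn_o[i] = cn_rec[i];
    bias_o[i] = bias_rec[i]; t_o[i] = t_rec[i];
  }

  return List::create(
    _["time"] = t_o, _["positions"] = pos_o, _["cv"] = cv_o,
    _["cn"] = cn_o, _["bias"] = bias_o,
    _["hill_time"] = NumericVector(hill_t.begin(), hill_t.end()),
    _["hill_center"] = NumericVector(hill_c.begin(), hill_c.end()),
    _["hill_height"] = NumericVector(hill_h.begin(), hill_h.end()),
    _["event"] = event, _["escape_time"] = escape_time,
    _["grid_V"] = NumericVector(gV.begin(), gV.end()),
    _["steps_run"] = (double)((event || step > nsteps) ? std::min(step, nsteps)
                                                       : step));
}
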