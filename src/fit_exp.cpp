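#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Status codes shared with the R side.
static const int STATUS_OK = 0;
static const int STATUS_UNFITTABLE = 1;
static const int STATUS_POOR = 2;

// Nonnegative least squares for the 2-parameter linear subproblem
//   min || y - A*e - C*1 ||^2,  0 <= A <= A_max, 0 <= C <= C_max,
// where e = exp(-t/tau) is fixed. Solves the unconstrained 2x2 normal
// equations and falls back to the box edges when the solution leaves the box.
// Returns rss; writes A, C.
static double solve_linear(const double *y, const double *e, int T,
                           double sy, double syy,
                           double A_max, double C_max,
                           double &A, double &C) {
  double see = 0.0, se1 = 0.0, sey = 0.0;
  for (int i = 0; i < T; ++i) {
    see += e[i] * e[i];
    se1 += e[i];
    sey += e[i] * y[i];
  }
  const double s11 = (double)T;
  double bestA = 0.0, bestC = 0.0, bestRss = R_PosInf;

  // candidate solutions: interior + each box edge
  double candA[5], candC[5];
  int ncand = 0;
  double det = see * s11 - se1 * se1;
  if (det > 1e-12 * see * s11) {
    candA[ncand] = (sey * s11 - se1 * sy) / det;
    candC[ncand] = (see * sy - se1 * sey) / det;
    ++ncand;
  }
  // A = 0: C = mean(y); A = A_max: C = (sy - A*se1)/T
  candA[ncand] = 0.0;            candC[ncand] = sy / s11;                        ++ncand;
  candA[ncand] = A_max;          candC[ncand] = (sy - A_max * se1) / s11;        ++ncand;
  // C = 0: A = sey/see; C = C_max: A = (sey - C*se1)/see
  if (see > 0) {
    candA[ncand] = sey / see;                     candC[ncand] = 0.0;   ++ncand;
    candA[ncand] = (sey - C_max * se1) / see;     candC[ncand] = C_max; ++ncand;
  }
  for (int k = 0; k < ncand; ++k) {
    double a = candA[k], c = candC[k];
    if (a < 0) a = 0; else if (a > A_max) a = A_max;
    if (c < 0) c = 0; else if (c > C_max) c = C_max;
    // explicit residual sum: immune to the cancellation the expanded
    // normal-equation form suffers near exact fits
    double rss = 0.0;
    for (int i = 0; i < T; ++i) {
      double r = y[i] - a * e[i] - c;
      rss += r * r;
    }
    if (rss < bestRss) { bestRss = rss; bestA = a; bestC = c; }
  }
  A = bestA; C = bestC;
  return bestRss;
}

// Profiled objective: rss at given tau with A, C optimized out.
static double profile_rss(const double *y, const double *t, int T,
                          double sy, double syy, double tau,
                          double A_max, double C_max,
                          double &A, double &C) {
  std::vector<double> e(T);
  for (int i = 0; i < T; ++i) e[i] = std::exp(-t[i] / tau);
  return solve_linear(y, e.data(), T, sy, syy, A_max, C_max, A, C);
}

// Fit I(t) = A*exp(-t/tau) + C to each column of Y (T x N) by variable
// projection: tau is profiled on a log-spaced grid in [tau_min, tau_max]
// and refined by golden-section search; A and C come from the bounded
// linear subproblem. Returns a 5 x N matrix (A, tau, C, rss, status).
//
// sat_level: intensity treated as sensor saturation; constant-zero or
// constant-saturated traces are unfittable (sentinel 0,0,0 per the failure
// rule). data_max: maximum finite intensity of the whole stack, used for the
// A + C > 2*data_max divergence flag. poor_rss_frac: fits explaining less
// than (1 - poor_rss_frac) of the trace's total variance are flagged poor.
// [[Rcpp::export(name = ".fit_exp_cpp")]]
NumericMatrix fit_exp_cpp(NumericMatrix Y, NumericVector times,
                          double tau_min, double tau_max,
                          double A_max, double C_max,
                          double sat_level, double data_max,
                          double poor_rss_frac,
                          int n_grid = 48, int n_refine = 60) {
  const int T = Y.nrow(), N = Y.ncol();
  NumericMatrix out(5, N);
  const double *t = REAL(times);

  // shared log-spaced tau grid
  std::vector<double> grid(n_grid);
  const double lmin = std::log(tau_min), lmax = std::log(tau_max);
  for (int k = 0; k < n_grid; ++k)
    grid[k] = std::exp(lmin + (lmax - lmin) * k / (n_grid - 1.0));

  const double invphi = (std::sqrt(5.0) - 1.0) / 2.0;

  for (int j = 0; j < N; ++j) {
    const double *y = &Y(0, j);
    double sy = 0.0, syy = 0.0;
    bool finite = true, all_zero = true, all_sat = true, constant = true;
    for (int i = 0; i < T; ++i) {
      if (!std::isfinite(y[i])) { finite = false; break; }
      sy += y[i]; syy += y[i] * y[i];
      if (y[i] != 0.0) all_zero = false;
      if (y[i] < sat_level) all_sat = false;
      if (y[i] != y[0]) constant = false;
    }
    if (!finite || all_zero || all_sat) {
      out(0, j) = 0; out(1, j) = 0; out(2, j) = 0; out(3, j) = 0;
      out(4, j) = STATUS_UNFITTABLE;
      continue;
    }
    if (constant) {
      // flat nonzero trace: decay unidentifiable, amplitude at lower bound
      out(0, j) = 0; out(1, j) = 0; out(2, j) = y[0]; out(3, j) = 0;
      out(4, j) = STATUS_POOR;
      continue;
    }

    // coarse grid
    int best_k = 0;
    double best_rss = R_PosInf, A, C;
    for (int k = 0; k < n_grid; ++k) {
      double rss = profile_rss(y, t, T, sy, syy, grid[k], A_max, C_max, A, C);
      if (rss < best_rss) { best_rss = rss; best_k = k; }
    }
    // golden-section refinement on log(tau) in the bracketing interval
    double lo = (best_k > 0)          ? std::log(grid[best_k - 1]) : lmin;
    double hi = (best_k < n_grid - 1) ? std::log(grid[best_k + 1]) : lmax;
    double x1 = hi - invphi * (hi - lo), x2 = lo + invphi * (hi - lo);
    double f1 = profile_rss(y, t, T, sy, syy, std::exp(x1), A_max, C_max, A, C);
    double f2 = profile_rss(y, t, T, sy, syy, std::exp(x2), A_max, C_max, A, C);
    for (int it = 0; it < n_refine; ++it) {
      if (f1 <= f2) {
        hi = x2; x2 = x1; f2 = f1;
        x1 = hi - invphi * (hi - lo);
        f1 = profile_rss(y, t, T, sy, syy, std::exp(x1), A_max, C_max, A, C);
      } else {
        lo = x1; x1 = x2; f1 = f2;
        x2 = lo + invphi * (hi - lo);
        f2 = profile_rss(y, t, T, sy, syy, std::exp(x2), A_max, C_max, A, C);
      }
    }
    double ltau = (f1 <= f2) ? x1 : x2;
    double tau = std::exp(ltau);
    double rss = profile_rss(y, t, T, sy, syy, tau, A_max, C_max, A, C);
    // keep the grid solution if refinement did not improve it
    if (best_rss < rss) {
      tau = grid[best_k];
      rss = profile_rss(y, t, T, sy, syy, tau, A_max, C_max, A, C);
    }

    int status = STATUS_OK;
    double tss = syy - sy * sy / T;
    if (tau >= tau_max * (1.0 - 1e-9)) status = STATUS_POOR;
    else if (A + C > 2.0 * data_max)   status = STATUS_POOR;
    else if (tss > 0 && rss > poor_rss_frac * tss) status = STATUS_POOR;

    out(0, j) = A; out(1, j) = tau; out(2, j) = C;
    out(3, j) = rss; out(4, j) = status;
  }
  return out;
}
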