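#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fused simulation loop for the coupled host-microbiome system.
//
// The R-level module functions (growth_rate, step_normalized, step_glv,
// window_slope, compute_all_indicators, microbiome_effect,
// direct_pull_effect, behavior_update) define the semantics; this loop is
// an exact fusion of them for speed. tests/testthat/test-sim-core.R checks
// the fused path against a composition of the R functions.
//
// Conventions:
//  - variant: 0 = normalized competition (Euler step, clip at 0, normalize,
//    inflow, second normalization), 1 = generalized Lotka-Volterra
//    (Euler step + inflow, clip at 0, no normalization).
//  - inflow_mode: 0 = mu/n_active per strain, 1 = mu per strain, 2 = none.
//  - feedback_variant: 0 = reward-circuit (trend indicators), 1 = direct pull.
//  - base_steps[t] is the signed host baseline step at time t; sigma_mag[t]
//    is the step magnitude entering the microbiome-effect term.
//  - Strains with index >= n_initial are inactive (abundance pinned at 0,
//    no inflow) until step intervention_at, when they join the community.
//  - clamp_hi_after (if >= 0) replaces clamp_hi from step clamp_switch_at on
//    (used when relapses are allowed to exceed the addiction bound R).

// [[Rcpp::export]]
List sim_core_cpp(NumericMatrix features, NumericVector d, NumericVector cost,
                  LogicalVector indep, double r_const,
                  double alpha, double beta, double rate_floor,
                  double s, double mu, int inflow_mode,
                  int variant, double delta, double glv_ceiling,
                  int feedback_variant,
                  int omega_m, int omega_h, double slope_tol,
                  int n_initial, int intervention_at,
                  NumericVector base_steps, NumericVector sigma_mag,
                  double clamp_lo, double clamp_hi,
                  int clamp_switch_at, double clamp_hi_after,
                  double b_start,
                  bool equilibrate, double stab_tol, int stab_window,
                  int stab_cap,
                  int thin, bool record_props)
{
  const int N = features.nrow();
  const int D = features.ncol();
  const int T = base_steps.size();
  if (n_initial < 1 || n_initial > N)
    stop("number of initially active strains must be in [1, N]");
  if (omega_m < 2 || omega_h < 2) stop("window lengths must be >= 2");
  if (T != sigma_mag.size()) stop("base_steps and sigma_mag lengths differ");

  std::vector<double> x(N, 0.0), xnew(N, 0.0), r(N, 0.0), rest2(N, 0.0),
      rel(N, 0.0);
  int n_active = n_initial;
  for (int i = 0; i < n_initial; ++i) x[i] = 1.0 / n_initial;
  for (int i = 0; i < N; ++i) {
    double a = 0.0;
    for (int k = 1; k < D; ++k) { double v = features(i, k); a += v * v; }
    rest2[i] = a;
  }
  bool any_effect = false;
  for (int i = 0; i < N; ++i) if (d[i] != 0.0) { any_effect = true; break; }

  // rolling windows: mh holds the last omega_m relative-abundance vectors
  // (slot-major, oldest at mh_wp once full), bh the last omega_h values of b1
  std::vector<double> mh((size_t)omega_m * N, 0.0);
  std::vector<double> bh(omega_h, 0.0);
  int mh_wp = 0, mh_n = 0, bh_wp = 0, bh_n = 0;

  double b1 = b_start;
  double max_sum_dev = 0.0, min_prop = R_PosInf;

  const double mdenom = omega_m * ((double)omega_m * omega_m - 1.0) / 12.0;
  const double hdenom = omega_h * ((double)omega_h * omega_h - 1.0) / 12.0;
  const double mxbar = (omega_m - 1) / 2.0;
  const double hxbar = (omega_h - 1) / 2.0;

  auto compute_r = [&](double b) {
    for (int i = 0; i < n_active; ++i) {
      if (indep[i]) { r[i] = r_const; continue; }
      double dx = b - features(i, 0);
      double dist = std::sqrt(dx * dx + rest2[i]);
      double g = 1.0 - beta * std::pow(dist, alpha);
      r[i] = rate_floor + (g > 0.0 ? g : 0.0);
    }
  };

  auto rel_abund = [&]() {
    if (variant == 0) {
      for (int i = 0; i < n_active; ++i) rel[i] = x[i];
      return;
    }
    double tot = 0.0;
    for (int i = 0; i < n_active; ++i) tot += x[i];
    if (tot > 0.0) for (int i = 0; i < n_active; ++i) rel[i] = x[i] / tot;
    else for (int i = 0; i < n_active; ++i) rel[i] = 0.0;
  };

  // one dynamics step; returns the largest per-strain abundance change
  auto dyn_step = [&](int step_label) -> double {
    double infl = 0.0;
    if (inflow_mode == 0) infl = mu / n_active;
    else if (inflow_mode == 1) infl = mu;
    double maxdiff = 0.0;
    if (variant == 0) {
      double sum = 0.0;
      for (int i = 0; i < n_active; ++i) {
        double xi = x[i];
        double g = xi + xi * (r[i] - s * xi - cost[i]);
        if (g < 0.0) g = 0.0;
        xnew[i] = g;
        sum += g;
      }
      if (sum <= 0.0 && inflow_mode == 2)
        stop("degenerate community: all strains extinct at step %d with no inflow",
             step_label);
      if (sum > 0.0) for (int i = 0; i < n_active; ++i) xnew[i] /= sum;
      double tot = 0.0;
      for (int i = 0; i < n_active; ++i) {
        xnew[i] += infl;
        tot += xnew[i];
      }
      for (int i = 0; i < n_active; ++i) xnew[i] /= tot;
      double chk = 0.0;
      for (int i = 0; i < n_active; ++i) chk += xnew[i];
      double dev = std::fabs(chk - 1.0);
      if (dev > max_sum_dev) max_sum_dev = dev;
    } else {
      double sumx = 0.0;
      for (int i = 0; i < n_active; ++i) sumx += x[i];
      for (int i = 0; i < n_active; ++i) {
        double xi = x[i];
        double Ax = -(1.0 - delta) * xi - delta * sumx;
        double g = xi + xi * (r[i] - cost[i] + Ax) + infl;
        if (g < 0.0) g = 0.0;
        if (g > glv_ceiling)
          stop("unstable trajectory: abundance exceeded ceiling %.3g at step %d",
               glv_ceiling, step_label);
        xnew[i] = g;
      }
    }
    for (int i = 0; i < n_active; ++i) {
      double dd = std::fabs(xnew[i] - x[i]);
      if (dd > maxdiff) maxdiff = dd;
      if (xnew[i] < min_prop) min_prop = xnew[i];
      x[i] = xnew[i];
    }
    return maxdiff;
  };

  auto push_hist = [&](double bval) {
    rel_abund();
    double* slot = &mh[(size_t)mh_wp * N];
    for (int i = 0; i < N; ++i) slot[i] = (i < n_active) ? rel[i] : 0.0;
    mh_wp = (mh_wp + 1) % omega_m;
    if (mh_n < omega_m) ++mh_n;
    bh[bh_wp] = bval;
    bh_wp = (bh_wp + 1) % omega_h;
    if (bh_n < omega_h) ++bh_n;
  };

  auto strain_slope = [&](int i) -> double {
    double mean = 0.0;
    for (int k = 0; k < omega_m; ++k)
      mean += mh[(size_t)((mh_wp + k) % omega_m) * N + i];
    mean /= omega_m;
    double num = 0.0;
    for (int k = 0; k < omega_m; ++k)
      num += (k - mxbar) *
             (mh[(size_t)((mh_wp + k) % omega_m) * N + i] - mean);
    return num / mdenom;
  };

  auto host_slope = [&]() -> double {
    double mean = 0.0;
    for (int k = 0; k < omega_h; ++k) mean += bh[(bh_wp + k) % omega_h];
    mean /= omega_h;
    double num = 0.0;
    for (int k = 0; k < omega_h; ++k)
      num += (k - hxbar) * (bh[(bh_wp + k) % omega_h] - mean);
    return num / hdenom;
  };

  push_hist(b1);  // histories include the initial state

  int equil_steps = 0;
  bool stabilized = false;
  if (equilibrate) {
    compute_r(b1);
    int consec = 0;
    for (int it = 0; it < stab_cap; ++it) {
      if ((it & 4095) == 0) Rcpp::checkUserInterrupt();
      double md = dyn_step(-(it + 1));
      push_hist(b1);
      ++equil_steps;
      if (md < stab_tol) {
        if (++consec >= stab_window) { stabilized = true; break; }
      } else {
        consec = 0;
      }
    }
  }

  NumericVector traj(T);
  std::vector<double> pbuf;
  std::vector<int> psteps;
  if (record_props && T > 0)
    pbuf.reserve(((size_t)T / (thin > 0 ? thin : 1) + 2) * N);

  double hi = clamp_hi;
  for (int t = 0; t < T; ++t) {
    if ((t & 4095) == 0) Rcpp::checkUserInterrupt();
    if (t == intervention_at) n_active = N;
    if (t == clamp_switch_at && clamp_hi_after >= 0.0) hi = clamp_hi_after;

    double M = 0.0;
    if (any_effect) {
      rel_abund();
      if (feedback_variant == 0) {
        if (bh_n >= omega_h && mh_n >= omega_m) {
          double sl = host_slope();
          int Ib = sl > slope_tol ? 1 : (sl < -slope_tol ? -1 : 0);
          if (Ib != 0) {
            double acc = 0.0;
            for (int i = 0; i < n_active; ++i) {
              if (d[i] == 0.0) continue;
              double si = strain_slope(i);
              int Im = si > slope_tol ? 1 : (si < -slope_tol ? -1 : 0);
              if (Im != 0) acc += rel[i] * d[i] * Im;
            }
            M = std::fabs(sigma_mag[t]) * Ib * acc;
          }
        }
      } else {
        double acc = 0.0;
        for (int i = 0; i < n_active; ++i) {
          if (d[i] == 0.0) continue;
          double dx = features(i, 0) - b1;
          double dist = std::sqrt(dx * dx + rest2[i]);
          if (dist < 1e-12) continue;
          acc += rel[i] * d[i] * dx / dist;
        }
        M = sigma_mag[t] * acc;
      }
    }

    double b1n = b1 + base_steps[t] + M;
    if (b1n < clamp_lo) b1n = clamp_lo;
    if (b1n > hi) b1n = hi;

    compute_r(b1);      // growth uses the behavior at time t
    dyn_step(t + 1);    // composition update also uses time-t state
    b1 = b1n;
    push_hist(b1);
    traj[t] = b1;

    if (record_props && (t % thin == 0 || t == T - 1)) {
      rel_abund();
      for (int i = 0; i < N; ++i) pbuf.push_back(i < n_active ? rel[i] : 0.0);
      psteps.push_back(t + 1);
    }
  }

  int np = (int)psteps.size();
  NumericMatrix props(np, N);
  for (int j = 0; j < np; ++j)
    for (int i = 0; i < N; ++i) props(j, i) = pbuf[(size_t)j * N + i];

  return List::create(
      _["b1"] = traj,
      _["equil_steps"] = equil_steps,
      _["stabilized"] = stabilized,
      _["final"] = NumericVector(x.begin(), x.end()),
      _["prop_steps"] = IntegerVector(psteps.begin(), psteps.end()),
      _["proportions"] = props,
      _["max_sum_dev"] = max_sum_dev,
      _["min_prop"] = (min_prop == R_PosInf ? NA_REAL : min_prop));
}
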