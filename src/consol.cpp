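#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter order is fixed across the R/C++ boundary:
// (K_w, K_z, C_w, C_z, w0, z0, tau_w, tau_z)
struct Par {
  double Kw, Kz, Cw, Cz, w0, z0, tw, tz;
};

static inline Par as_par(const NumericVector& p) {
  Par P;
  P.Kw = p[0]; P.Kz = p[1]; P.Cw = p[2]; P.Cz = p[3];
  P.w0 = p[4]; P.z0 = p[5]; P.tw = p[6]; P.tz = p[7];
  return P;
}

static inline void drift(const Par& P, double w, double z, double I,
                         double& dw, double& dz) {
  dw = (-P.Kw * (w - P.w0) * (w + P.w0) * w + P.Cw * (z - P.z0 / P.w0 * w) + I) / P.tw;
  dz = (-P.Kz * (z - P.z0) * (z + P.z0) * z + P.Cz * (w - P.w0 / P.z0 * z)) / P.tz;
}

// Classical RK4 step; the drive is sampled at the stage times t, t+dt/2,
// t+dt/2, t+dt (I1, I2, I2, I4).
static inline void rk4(const Par& P, double& w, double& z,
                       double I1, double I2, double I4, double dt) {
  double k1w, k1z, k2w, k2z, k3w, k3z, k4w, k4z;
  drift(P, w, z, I1, k1w, k1z);
  drift(P, w + 0.5 * dt * k1w, z + 0.5 * dt * k1z, I2, k2w, k2z);
  drift(P, w + 0.5 * dt * k2w, z + 0.5 * dt * k2z, I2, k3w, k3z);
  drift(P, w + dt * k3w, z + dt * k3z, I4, k4w, k4z);
  w += dt / 6.0 * (k1w + 2.0 * k2w + 2.0 * k3w + k4w);
  z += dt / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
}

// Rectangular-episode drive evaluated at a (possibly half-integer) step
// index u. Episode windows are half-open in steps: [k*period, k*period+n_on).
// n_eps < 0 encodes an unbounded episode count.
static inline double drive_steps(double u, double amp, double n_on,
                                 double period, double n_eps) {
  double k = std::floor(u / period);
  if (n_eps >= 0.0 && k >= n_eps) return 0.0;
  double phase = u - k * period;
  return (phase < n_on) ? amp : 0.0;
}

// Piecewise-linear separatrix lookup z = s(w); linear extrapolation with the
// end-segment slopes outside the tabulated range.
static inline double interp_sep(const NumericVector& xs, const NumericVector& ys,
                                double x) {
  int n = xs.size();
  if (n == 1) return ys[0];
  int lo = 0, hi = n - 1;
  if (x <= xs[0]) { lo = 0; hi = 1; }
  else if (x >= xs[n - 1]) { lo = n - 2; hi = n - 1; }
  else {
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (xs[mid] <= x) lo = mid; else hi = mid;
    }
  }
  double t = (x - xs[lo]) / (xs[hi] - xs[lo]);
  return ys[lo] + t * (ys[hi] - ys[lo]);
}

static inline int nearest_attractor(const NumericMatrix& A, double w, double z,
                                    double tol) {
  for (int i = 0; i < A.nrow(); ++i) {
    double dw = w - A(i, 0), dz = z - A(i, 1);
    if (std::sqrt(dw * dw + dz * dz) < tol) return i + 1;
  }
  return 0;
}

// Integrate with constant drive I until within `tol` of one of the listed
// attractors, or until t_max. Returns the 1-based attractor index (0 if
// non-convergent) plus the final state and time.
// [[Rcpp::export]]
List relax_cpp(double w, double z, NumericVector par, double I,
               NumericMatrix attractors, double tol, double dt, double t_max) {
  Par P = as_par(par);
  long nmax = (long)std::ceil(t_max / dt);
  int lab = nearest_attractor(attractors, w, z, tol);
  long s = 0;
  while (lab == 0 && s < nmax) {
    rk4(P, w, z, I, I, I, dt);
    ++s;
    if (!std::isfinite(w) || !std::isfinite(z))
      stop("trajectory diverged during relaxation");
    lab = nearest_attractor(attractors, w, z, tol);
  }
  return List::create(_["label"] = lab, _["w"] = w, _["z"] = z,
                      _["t"] = s * dt);
}

// Basin labelling over a grid of initial conditions (mesh-grid relaxation).
// Returns an integer matrix of dim (length(ws), length(zs)); 0 marks
// non-convergent cells.
// [[Rcpp::export]]
IntegerMatrix basin_labels_cpp(NumericVector ws, NumericVector zs,
                               NumericVector par, double I,
                               NumericMatrix attractors, double tol,
                               double dt, double t_max) {
  Par P = as_par(par);
  long nmax = (long)std::ceil(t_max / dt);
  IntegerMatrix out(ws.size(), zs.size());
  for (int i = 0; i < ws.size(); ++i) {
    for (int j = 0; j < zs.size(); ++j) {
      double w = ws[i], z = zs[j];
      int lab = nearest_attractor(attractors, w, z, tol);
      long s = 0;
      while (lab == 0 && s < nmax) {
        rk4(P, w, z, I, I, I, dt);
        ++s;
        lab = nearest_attractor(attractors, w, z, tol);
      }
      out(i, j) = lab;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Fixed-step trajectory under a rectangular-episode protocol.
// Columns: t, w, z, I (drive at the step's start time). n_eps < 0 means
// unbounded episodes.
// [[Rcpp::export]]
NumericMatrix rk4_traj_cpp(double w, double z, NumericVector par, double amp,
                           double n_on, double n_off, double n_eps,
                           double dt, double n_steps) {
  Par P = as_par(par);
  double period = n_on + n_off;
  long N = (long)n_steps;
  NumericMatrix out(N + 1, 4);
  out(0, 0) = 0.0; out(0, 1) = w; out(0, 2) = z;
  out(0, 3) = drive_steps(0.0, amp, n_on, period, n_eps);
  for (long s = 0; s < N; ++s) {
    double I1 = drive_steps((double)s, amp, n_on, period, n_eps);
    double I2 = drive_steps((double)s + 0.5, amp, n_on, period, n_eps);
    double I4 = drive_steps((double)s + 1.0, amp, n_on, period, n_eps);
    rk4(P, w, z, I1, I2, I4, dt);
    if (std::fabs(w) > 1e6 || std::fabs(z) > 1e6 ||
        !std::isfinite(w) || !std::isfinite(z))
      stop("trajectory diverged (state norm exceeded 1e6)");
    out(s + 1, 0) = (s + 1) * dt;
    out(s + 1, 1) = w;
    out(s + 1, 2) = z;
    out(s + 1, 3) = drive_steps((double)s + 1.0, amp, n_on, period, n_eps);
  }
  return out;
}

// Deliver rectangular episodes from the unpotentiated state and stop as soon
// as the trajectory crosses into the basin of the potentiated attractor
// (tested after every step against the tabulated separatrix z = s(w)).
// If the episode budget is exhausted without a crossing, a drive-free
// relaxation decides the outcome. An early exit fires when the state at
// successive episode onsets has settled (period map converged), which can
// only happen on the unpotentiated side of the separatrix.
// [[Rcpp::export]]
List run_protocol_cpp(NumericVector par, double amp, double n_on, double n_off,
                      double max_episodes, double dt,
                      NumericVector sep_w, NumericVector sep_z,
                      NumericMatrix attractors, int upper_idx,
                      double conv_tol, double t_max_relax, double settle_tol) {
  Par P = as_par(par);
  double w = -P.w0, z = -P.z0;
  double period = n_on + n_off;
  long per = (long)period;
  long non = (long)n_on;
  long maxep = (long)max_episodes;
  bool crossed = false;
  double t_cross = NA_REAL;
  long episodes = 0;
  double prev_w = NA_REAL, prev_z = NA_REAL;
  bool settled = false;
  long u = 0;  // global step counter

  for (long ep = 0; ep < maxep && !crossed; ++ep) {
    if (ep > 0) {
      double dwo = w - prev_w, dzo = z - prev_z;
      if (std::sqrt(dwo * dwo + dzo * dzo) < settle_tol) { settled = true; break; }
    }
    prev_w = w; prev_z = z;
    episodes = ep + 1;
    for (long s = 0; s < per && !crossed; ++s) {
      double I1 = drive_steps((double)u, amp, n_on, period, max_episodes);
      double I2 = drive_steps((double)u + 0.5, amp, n_on, period, max_episodes);
      double I4 = drive_steps((double)u + 1.0, amp, n_on, period, max_episodes);
      rk4(P, w, z, I1, I2, I4, dt);
      ++u;
      if (std::fabs(w) > 1e6 || std::fabs(z) > 1e6)
        stop("trajectory diverged (state norm exceeded 1e6)");
      if (z > interp_sep(sep_w, sep_z, w)) {
        crossed = true;
        t_cross = u * dt;
      }
    }
    if ((u / per) % 16 == 0) Rcpp::checkUserInterrupt();
  }

  bool potentiated = crossed;
  if (!crossed && !settled) {
    // episode budget exhausted mid-approach: relax with I = 0 to decide
    long nmax = (long)std::ceil(t_max_relax / dt);
    int lab = nearest_attractor(attractors, w, z, conv_tol);
    long s = 0;
    while (lab == 0 && s < nmax) {
      rk4(P, w, z, 0.0, 0.0, 0.0, dt);
      ++s;
      if (!crossed && z > interp_sep(sep_w, sep_z, w)) {
        crossed = true;
        t_cross = (u + s) * dt;
      }
      lab = nearest_attractor(attractors, w, z, conv_tol);
    }
    potentiated = (lab == upper_idx);
  }
  if (!potentiated) { episodes = maxep; t_cross = NA_REAL; }
  return List::create(_["potentiated"] = potentiated,
                      _["episodes"] = (double)episodes,
                      _["crossing_time"] = t_cross,
                      _["w"] = w, _["z"] = z);
}

// Separatrix as a graph z = s(w): for each w, bisect z between a bracket
// whose endpoints relax to different basins. Returns NaN where the bracket
// is invalid. Non-convergent relaxations count as "not the upper basin".
// [[Rcpp::export]]
NumericVector separatrix_bisect_cpp(NumericVector ws, NumericVector par,
                                    double zlo, double zhi,
                                    NumericMatrix attractors, int upper_idx,
                                    double tol_z, double conv_tol,
                                    double dt, double t_max) {
  Par P = as_par(par);
  long nmax = (long)std::ceil(t_max / dt);
  NumericVector out(ws.size());
  for (int i = 0; i < ws.size(); ++i) {
    double lo = zlo, hi = zhi;
    // relax from (w, z) and report whether the limit is the upper attractor
    auto upper = [&](double z0v) {
      double w = ws[i], z = z0v;
      int lab = nearest_attractor(attractors, w, z, conv_tol);
      long s = 0;
      while (lab == 0 && s < nmax) {
        rk4(P, w, z, 0.0, 0.0, 0.0, dt);
        ++s;
        lab = nearest_attractor(attractors, w, z, conv_tol);
      }
      return lab == upper_idx;
    };
    if (upper(lo) || !upper(hi)) { out[i] = NA_REAL; continue; }
    while (hi - lo > tol_z) {
      double mid = 0.5 * (lo + hi);
      if (upper(mid)) hi = mid; else lo = mid;
    }
    out[i] = 0.5 * (lo + hi);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
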