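#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit time-stepping core for the voltage-density Fokker-Planck equation
//
//   dp/dt = -d/dv[(bN - v) p] + a(N) d^2p/dv^2 + N(t) delta(v - V_R),
//   N(t)  = -a(N) dp/dv |_{V_F},  p(V_F) = 0,  p(V_min) = 0.
//
// Nodes v_i = vmin + i*dv, i = 0..J-1, with v_{J-1} = V_F and V_R on node jR.
// Both boundary nodes are pinned to zero; interior nodes are updated from
// interface fluxes so that the discrete outflux through the last interface is
// re-deposited in full on the reset node, making the update exactly
// conservative (trapezoidal mass is constant to rounding).

// status codes shared with the R side
enum Status { RUNNING = 0, REACHED_T_END = 1, STEADY = 2, BLOWUP = 3,
              CC_BREAKDOWN = 4, VMIN_LEAK = 5, MAX_STEPS = 6 };

enum Scheme { UPWIND1 = 0, WENO5 = 1, CHANG_COOPER = 2 };

// one-sided second-order derivative stencil at V_F (p[J-1] == 0)
static inline double firing_slope(const std::vector<double>& p, int J, double dv) {
  return (4.0 * p[J - 2] - p[J - 3]) / (2.0 * dv);
}

// Chang-Cooper exponential-fitting weight: delta = 1/w - 1/(e^w - 1)
// [[Rcpp::export]]
double chang_cooper_weight(double w) {
  if (std::fabs(w) < 1e-8) return 0.5 - w / 12.0;
  if (w > 500.0)  return 1.0 / w;
  if (w < -500.0) return 1.0 + 1.0 / w;
  return 1.0 / w - 1.0 / std::expm1(w);
}

// WENO5 reconstruction of the interface value from a left-biased 5-point stencil
static inline double weno5_rec(double fm2, double fm1, double f0, double fp1,
                               double fp2) {
  const double eps = 1e-6;
  double b0 = 13.0 / 12.0 * (fm2 - 2.0 * fm1 + f0) * (fm2 - 2.0 * fm1 + f0) +
              0.25 * (fm2 - 4.0 * fm1 + 3.0 * f0) * (fm2 - 4.0 * fm1 + 3.0 * f0);
  double b1 = 13.0 / 12.0 * (fm1 - 2.0 * f0 + fp1) * (fm1 - 2.0 * f0 + fp1) +
              0.25 * (fm1 - fp1) * (fm1 - fp1);
  double b2 = 13.0 / 12.0 * (f0 - 2.0 * fp1 + fp2) * (f0 - 2.0 * fp1 + fp2) +
              0.25 * (3.0 * f0 - 4.0 * fp1 + fp2) * (3.0 * f0 - 4.0 * fp1 + fp2);
  double a0 = 0.1 / ((eps + b0) * (eps + b0));
  double a1 = 0.6 / ((eps + b1) * (eps + b1));
  double a2 = 0.3 / ((eps + b2) * (eps + b2));
  double q0 = (2.0 * fm2 - 7.0 * fm1 + 11.0 * f0) / 6.0;
  double q1 = (-fm1 + 5.0 * f0 + 2.0 * fp1) / 6.0;
  double q2 = (2.0 * f0 + 5.0 * fp1 - fp2) / 6.0;
  return (a0 * q0 + a1 * q1 + a2 * q2) / (a0 + a1 + a2);
}

struct RhsResult {
  double N;
  double q;
  bool breakdown;   // implicit firing-rate relation lost its solution
};

// semi-discrete right-hand side; dp and the workspace Phi must have length J
static RhsResult rhs_eval(const std::vector<double>& p, std::vector<double>& dp,
                          std::vector<double>& Phi,
                          int J, double vmin, double dv, int jR,
                          double b, double a0, double a1, int scheme) {
  RhsResult out;
  out.breakdown = false;
  double q = firing_slope(p, J, dv);
  if (q < 0.0) q = 0.0;
  out.q = q;
  if (a1 > 0.0 && a1 * q >= 1.0) {
    out.breakdown = true;
    out.N = R_PosInf;
    return out;
  }
  double N = a0 * q / (1.0 - a1 * q);
  out.N = N;
  double a = a0 + a1 * N;
  double VF = vmin + (J - 1) * dv;

  // transport fluxes Phi[k] through interface k+1/2 (between nodes k, k+1);
  // Phi[0] = 0 is a wall at V_min (the density is required to vanish there)
  Phi[0] = 0.0;

  if (scheme == UPWIND1) {
    for (int k = 1; k <= J - 2; ++k) {
      double vk = vmin + (k + 0.5) * dv;
      double h = b * N - vk;
      double adv = (h > 0.0) ? h * p[k] : h * p[k + 1];
      Phi[k] = adv - a * (p[k + 1] - p[k]) / dv;
    }
  } else if (scheme == CHANG_COOPER) {
    for (int k = 1; k <= J - 2; ++k) {
      double vk = vmin + (k + 0.5) * dv;
      double A = vk - b * N;                 // Fokker-Planck-form drift
      double w = dv * A / a;
      double del = chang_cooper_weight(w);
      // F = A[(1-del) p_{k+1} + del p_k] + a (p_{k+1}-p_k)/dv vanishes
      // identically on densities proportional to the local Maxwellian
      double F = A * ((1.0 - del) * p[k + 1] + del * p[k]) +
                 a * (p[k + 1] - p[k]) / dv;
      Phi[k] = -F;
    }
  } else {  // WENO5 with local (Rusanov) flux splitting of the advective flux
    // ghosts: zero below V_min (fast decay); above V_F the density is
    // continued with its boundary slope so the absorbing boundary does not
    // look like a spurious kink to the smoothness indicators
    auto pv = [&](int i) -> double {
      if (i < 0) return 0.0;
      if (i > J - 1) return -(double)(i - (J - 1)) * p[J - 2];
      return p[i];
    };
    auto fv = [&](int i) -> double {
      double v = vmin + i * dv;
      return (b * N - v) * pv(i);
    };
    for (int k = 1; k <= J - 2; ++k) {
      double alpha = 0.0;  // local wave speed over the 6-node stencil
      for (int i = k - 2; i <= k + 3; ++i) {
        double v = vmin + i * dv;
        alpha = std::max(alpha, std::fabs(b * N - v));
      }
      double fp = weno5_rec(0.5 * (fv(k - 2) + alpha * pv(k - 2)),
                            0.5 * (fv(k - 1) + alpha * pv(k - 1)),
                            0.5 * (fv(k)     + alpha * pv(k)),
                            0.5 * (fv(k + 1) + alpha * pv(k + 1)),
                            0.5 * (fv(k + 2) + alpha * pv(k + 2)));
      double fm = weno5_rec(0.5 * (fv(k + 3) - alpha * pv(k + 3)),
                            0.5 * (fv(k + 2) - alpha * pv(k + 2)),
                            0.5 * (fv(k + 1) - alpha * pv(k + 1)),
                            0.5 * (fv(k)     - alpha * pv(k)),
                            0.5 * (fv(k - 1) - alpha * pv(k - 1)));
      Phi[k] = fp + fm - a * (p[k + 1] - p[k]) / dv;
    }
  }

  // the outflux through the last interface is the discrete firing flux;
  // re-depositing it on the reset node telescopes the update to exact
  // mass conservation
  double S = Phi[J - 2];
  dp[0] = 0.0;
  dp[J - 1] = 0.0;
  for (int i = 1; i <= J - 2; ++i) dp[i] = -(Phi[i] - Phi[i - 1]) / dv;
  dp[jR] += S / dv;
  return out;
}

// clip negative nodes; returns clipped mass, flags hard failures
static double clip_negatives(std::vector<double>& p, int J, double dv,
                             int scheme, bool& hard_fail) {
  double clipped = 0.0;
  for (int i = 0; i < J; ++i) {
    if (p[i] < 0.0) {
      if (p[i] < -1e-12 && scheme == CHANG_COOPER) hard_fail = true;
      clipped += -p[i] * dv;
      p[i] = 0.0;
    }
  }
  return clipped;
}

static inline double trapz_mass(const std::vector<double>& p, int J, double dv) {
  double s = 0.0;
  for (int i = 1; i <= J - 2; ++i) s += p[i];
  s += 0.5 * (p[0] + p[J - 1]);
  return s * dv;
}

// one SSP Runge-Kutta step of size dt; returns false on breakdown
struct Workspace {
  std::vector<double> dp, u1, u2, Phi;
  explicit Workspace(int J) : dp(J), u1(J), u2(J), Phi(J) {}
};

static bool ssp_step(std::vector<double>& p, Workspace& ws, int J,
                     double vmin, double dv,
                     int jR, double b, double a0, double a1, int scheme,
                     int rk_order, double dt, double& clip_acc, bool& hard_fail) {
  int n = J;
  std::vector<double>& dp = ws.dp;
  std::vector<double>& u1 = ws.u1;
  std::vector<double>& u2 = ws.u2;
  RhsResult r = rhs_eval(p, dp, ws.Phi, J, vmin, dv, jR, b, a0, a1, scheme);
  if (r.breakdown) return false;
  for (int i = 0; i < n; ++i) u1[i] = p[i] + dt * dp[i];
  clip_acc += clip_negatives(u1, J, dv, scheme, hard_fail);

  if (rk_order == 2) {
    r = rhs_eval(u1, dp, ws.Phi, J, vmin, dv, jR, b, a0, a1, scheme);
    if (r.breakdown) return false;
    for (int i = 0; i < n; ++i) p[i] = 0.5 * p[i] + 0.5 * (u1[i] + dt * dp[i]);
    clip_acc += clip_negatives(p, J, dv, scheme, hard_fail);
  } else {  // SSP-RK3 (Shu-Osher)
    r = rhs_eval(u1, dp, ws.Phi, J, vmin, dv, jR, b, a0, a1, scheme);
    if (r.breakdown) return false;
    for (int i = 0; i < n; ++i)
      u2[i] = 0.75 * p[i] + 0.25 * (u1[i] + dt * dp[i]);
    clip_acc += clip_negatives(u2, J, dv, scheme, hard_fail);
    r = rhs_eval(u2, dp, ws.Phi, J, vmin, dv, jR, b, a0, a1, scheme);
    if (r.breakdown) return false;
    for (int i = 0; i < n; ++i)
      p[i] = p[i] / 3.0 + 2.0 / 3.0 * (u2[i] + dt * dp[i]);
    clip_acc += clip_negatives(p, J, dv, scheme, hard_fail);
  }
  return true;
}

// firing rate solved from the implicit relation N = (a0 + a1 N) q
static inline double firing_N(const std::vector<double>& p, int J, double dv,
                              double a0, double a1, bool& breakdown) {
  double q = firing_slope(p, J, dv);
  if (q < 0.0) q = 0.0;
  if (a1 > 0.0 && a1 * q >= 1.0) { breakdown = true; return R_PosInf; }
  return a0 * q / (1.0 - a1 * q);
}

// relative entropy sum(pinf * (p/pinf - 1)^2) dv; far-tail nodes where pinf
// underflows carry no weight; the boundary node contributes 0 (pinf(V_F) = 0)
static double rel_entropy(const std::vector<double>& p,
                          const std::vector<double>& pinf, int J, double dv) {
  double H = 0.0;
  for (int i = 0; i < J; ++i) {
    if (pinf[i] > 1e-30) {
      double r = p[i] / pinf[i] - 1.0;
      H += pinf[i] * r * r;
    }
  }
  return H * dv;
}

// single explicit step with caller-supplied dt (unit-step interface)
// [[Rcpp::export]]
List fp_step_cpp(NumericVector p0, double vmin, double dv, int jR0,
                 double b, double a0, double a1, int scheme, int rk_order,
                 double dt) {
  int J = p0.size();
  std::vector<double> p(p0.begin(), p0.end());
  Workspace ws(J);
  double clip = 0.0;
  bool hard = false;
  bool ok = ssp_step(p, ws, J, vmin, dv, jR0, b, a0, a1, scheme, rk_order, dt,
                     clip, hard);
  bool bd = false;
  double N = ok ? firing_N(p, J, dv, a0, a1, bd) : R_PosInf;
  return List::create(_["p"] = NumericVector(p.begin(), p.end()),
                      _["N"] = N,
                      _["ok"] = ok && !bd && !hard,
                      _["clipped_mass"] = clip);
}

// [[Rcpp::export]]
List fp_run_cpp(NumericVector p0, double t0, double vmin, double dv, int jR0,
                double b, double a0, double a1, int scheme, int rk_order,
                double cfl, double t_end, NumericVector snapshot_times,
                double N_blowup, double steady_tol, double steady_window,
                double vmin_tol, Nullable<NumericVector> pinf_, double max_steps) {
  int J = p0.size();
  std::vector<double> p(p0.begin(), p0.end());
  double VF = vmin + (J - 1) * dv;

  bool track_H = pinf_.isNotNull();
  std::vector<double> pinf;
  if (track_H) {
    NumericVector tmp(pinf_);
    pinf.assign(tmp.begin(), tmp.end());
  }

  std::vector<double> tr_t, tr_N, tr_mass, tr_m1, tr_m2, tr_H;
  int stride = 1, since_rec = 0;
  const int max_rows = 400000;

  std::vector<std::vector<double> > snaps;
  std::vector<double> snap_t;
  int nsnap = snapshot_times.size();
  int isnap = 0;
  while (isnap < nsnap && snapshot_times[isnap] <= t0 + 1e-14) ++isnap;

  auto record = [&](double t, double N) {
    tr_t.push_back(t);
    tr_N.push_back(N);
    tr_mass.push_back(trapz_mass(p, J, dv));
    double m1 = 0.0, m2 = 0.0;
    for (int i = 0; i < J; ++i) {
      double v = vmin + i * dv;
      m1 += v * p[i];
      m2 += v * v * p[i];
    }
    tr_m1.push_back(m1 * dv);
    tr_m2.push_back(m2 * dv);
    if (track_H) tr_H.push_back(rel_entropy(p, pinf, J, dv));
    if ((int)tr_t.size() > max_rows) {  // thin the trace, keep endpoints
      std::vector<double>* cols[6] = { &tr_t, &tr_N, &tr_mass, &tr_m1, &tr_m2, &tr_H };
      for (int c = 0; c < 6; ++c) {
        if (cols[c]->empty()) continue;
        std::vector<double>& x = *cols[c];
        size_t m = 0;
        for (size_t i = 0; i < x.size(); i += 2) x[m++] = x[i];
        x.resize(m);
      }
      stride *= 2;
    }
  };

  bool bd0 = false;
  double N = firing_N(p, J, dv, a0, a1, bd0);
  int status = bd0 ? CC_BREAKDOWN : RUNNING;
  if (status == RUNNING &&
      (N >= N_blowup || (b > 0.0 && N * b * dv >= 0.5 * (a0 + a1 * N))))
    status = BLOWUP;
  double t = t0;
  double clip_acc = 0.0;
  double below = 0.0;
  double steps = 0.0;
  record(t, bd0 ? NA_REAL : N);

  std::vector<double> pold(J);
  Workspace ws(J);

  while (status == RUNNING) {
    if (t >= t_end - 1e-14) { status = REACHED_T_END; break; }
    if (steps >= max_steps) { status = MAX_STEPS; break; }

    double a = a0 + a1 * N;
    double maxh = std::max(std::fabs(b * N - vmin), std::fabs(b * N - VF));
    double dt = cfl * std::min(maxh > 0 ? dv / maxh : R_PosInf,
                               dv * dv / (2.0 * a));
    if (!(dt > 0.0) || dt < 1e-12 * t_end) { status = BLOWUP; break; }

    bool take_snap = false;
    if (isnap < nsnap && t + dt >= snapshot_times[isnap] - 1e-14) {
      dt = snapshot_times[isnap] - t;
      take_snap = true;
      if (dt <= 0.0) { // snapshot time == current time after rounding
        snaps.push_back(p); snap_t.push_back(t); ++isnap; continue;
      }
    }
    if (t + dt > t_end) dt = t_end - t;

    pold = p;
    bool hard = false;
    bool ok = ssp_step(p, ws, J, vmin, dv, jR0, b, a0, a1, scheme, rk_order, dt,
                       clip_acc, hard);
    if (!ok) { p = pold; status = CC_BREAKDOWN; break; }
    if (hard) { status = CC_BREAKDOWN; }

    t += dt;
    steps += 1.0;

    bool bd = false;
    N = firing_N(p, J, dv, a0, a1, bd);
    if (bd) status = CC_BREAKDOWN;

    if (++since_rec >= stride) { record(t, bd ? NA_REAL : N); since_rec = 0; }
    if (take_snap) { snaps.push_back(p); snap_t.push_back(t); ++isnap; }

    if (status != RUNNING) break;
    if (p[1] > vmin_tol) { status = VMIN_LEAK; break; }
    if (N >= N_blowup) { status = BLOWUP; break; }
    // mesh-resolution guard: when the exit boundary layer a/(bN) falls
    // below two cells the discretisation saturates at a spurious plateau
    // instead of diverging; a firing rate at that scale is numerically
    // divergent at this resolution
    if (b > 0.0 && N * b * dv >= 0.5 * (a0 + a1 * N)) { status = BLOWUP; break; }

    double l1rate = 0.0;
    for (int i = 0; i < J; ++i) l1rate += std::fabs(p[i] - pold[i]);
    l1rate *= dv / dt;
    if (l1rate < steady_tol) {
      below += dt;
      if (below >= steady_window) { status = STEADY; break; }
    } else {
      below = 0.0;
    }
    if (steps == std::floor(steps / 100000.0) * 100000.0) checkUserInterrupt();
  }

  if (since_rec > 0 || tr_t.empty() || tr_t.back() < t) {
    bool bd = false;
    double Nf = firing_N(p, J, dv, a0, a1, bd);
    record(t, bd ? NA_REAL : Nf);
  }

  NumericMatrix snap_mat(J, (int)snaps.size());
  for (size_t s = 0; s < snaps.size(); ++s)
    for (int i = 0; i < J; ++i) snap_mat(i, s) = snaps[s][i];

  List trace = List::create(
      _["time"] = NumericVector(tr_t.begin(), tr_t.end()),
      _["N"] = NumericVector(tr_N.begin(), tr_N.end()),
      _["mass"] = NumericVector(tr_mass.begin(), tr_mass.end()),
      _["m1"] = NumericVector(tr_m1.begin(), tr_m1.end()),
      _["m2"] = NumericVector(tr_m2.begin(), tr_m2.end()));
  return List::create(
      _["trace"] = trace,
      _["entropy"] = track_H ? NumericVector(tr_H.begin(), tr_H.end())
                             : NumericVector(0),
      _["snapshots"] = snap_mat,
      _["snapshot_times"] = NumericVector(snap_t.begin(), snap_t.end()),
      _["p_final"] = NumericVector(p.begin(), p.end()),
      _["t_final"] = t,
      _["status"] = status,
      _["status_time"] = t,
      _["steps"] = steps,
      _["clipped_mass"] = clip_acc);
}
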