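// Dynamic mean-field neural mass model with feedback inhibition control,
// plus the Balloon-Windkessel hemodynamic forward model.
//
// All stochastic paths draw from R's RNG (set.seed() on the R side gives
// bit-reproducible trajectories). Euler-Maruyama with noise sigma*sqrt(dt).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct DMFPar {
  double W_E, W_I, I0, w_plus, J_NMDA;
  double a_E, b_E, d_E, a_I, b_I, d_I;
  double gamma, tau_NMDA, tau_GABA, sigma;
};

static DMFPar dmf_par_from_list(const List &p) {
  DMFPar q;
  q.W_E = as<double>(p["W_E"]);       q.W_I = as<double>(p["W_I"]);
  q.I0 = as<double>(p["I_0"]);        q.w_plus = as<double>(p["w_plus"]);
  q.J_NMDA = as<double>(p["J_NMDA"]);
  q.a_E = as<double>(p["a_E"]);       q.b_E = as<double>(p["b_E"]);
  q.d_E = as<double>(p["d_E"]);       q.a_I = as<double>(p["a_I"]);
  q.b_I = as<double>(p["b_I"]);       q.d_I = as<double>(p["d_I"]);
  q.gamma = as<double>(p["gamma"]);   q.tau_NMDA = as<double>(p["tau_NMDA"]);
  q.tau_GABA = as<double>(p["tau_GABA"]); q.sigma = as<double>(p["sigma"]);
  return q;
}

// x/(1 - exp(-d x)) with the removable singularity at x = 0 (limit 1/d).
static inline double sigmoid_transfer(double I, double a, double b, double d) {
  double x = a * I - b;
  double y = d * x;
  if (std::fabs(y) < 1e-8) return (1.0 + 0.5 * y) / d;
  return x / (1.0 - std::exp(-y));
}

// [[Rcpp::export]]
NumericVector cpp_transfer(NumericVector I, double a, double b, double d) {
  int n = I.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sigmoid_transfer(I[i], a, b, d);
  return out;
}

// dH/dI of the sigmoidal transfer function (analytic; used by FIC).
static inline double transfer_slope(double I, double a, double b, double d) {
  double x = a * I - b;
  double y = d * x;
  if (std::fabs(y) < 1e-6) return a * 0.5;  // limit of dH/dx at x = 0 is 1/2
  double em = std::exp(-y);
  double den = 1.0 - em;
  return a * (den - x * d * em) / (den * den);
}

struct BalloonPar {
  double kappa, gamma_h, tau_h, alpha, rho, V0, k1, k2, k3;
};

static BalloonPar balloon_par_from_list(const List &p) {
  BalloonPar q;
  q.kappa = as<double>(p["kappa"]);  q.gamma_h = as<double>(p["gamma_h"]);
  q.tau_h = as<double>(p["tau_h"]);  q.alpha = as<double>(p["alpha"]);
  q.rho = as<double>(p["rho"]);      q.V0 = as<double>(p["V0"]);
  q.k1 = as<double>(p["k1"]);        q.k2 = as<double>(p["k2"]);
  q.k3 = as<double>(p["k3"]);
  return q;
}

struct BalloonState { double s, f, v, q; };

static inline void balloon_step(BalloonState &st, double z, double dt,
                                const BalloonPar &p, bool &bad) {
  double ia = 1.0 / p.alpha;
  double fv = std::pow(st.v, ia);
  double E = 1.0 - std::pow(1.0 - p.rho, 1.0 / st.f);
  double ds = z - p.kappa * st.s - p.gamma_h * (st.f - 1.0);
  double df = st.s;
  double dv = (st.f - fv) / p.tau_h;
  double dq = (st.f * E / p.rho - fv * st.q / st.v) / p.tau_h;
  st.s += dt * ds; st.f += dt * df; st.v += dt * dv; st.q += dt * dq;
  if (!(st.f > 0.0) || !(st.v > 0.0) || !(st.q > 0.0)) bad = true;
}

static inline double balloon_bold_of(const BalloonState &st, const BalloonPar &p) {
  return p.V0 * (p.k1 * (1.0 - st.q) + p.k2 * (1.0 - st.q / st.v) +
                 p.k3 * (1.0 - st.v));
}

// Integrate the balloon model region-by-region for a stored neural drive.
// drive: regions x steps, sampled at dt.
// [[Rcpp::export]]
NumericMatrix cpp_balloon(NumericMatrix drive, double dt, List hemo) {
  BalloonPar p = balloon_par_from_list(hemo);
  int nr = drive.nrow(), nt = drive.ncol();
  NumericMatrix out(nr, nt);
  for (int i = 0; i < nr; ++i) {
    BalloonState st = {0.0, 1.0, 1.0, 1.0};
    bool bad = false;
    for (int t = 0; t < nt; ++t) {
      balloon_step(st, drive(i, t), dt, p, bad);
      if (bad)
        stop("balloon integration failed: volume or deoxyhemoglobin became non-positive at step %d, region %d", t + 1, i + 1);
      out(i, t) = balloon_bold_of(st, p);
    }
  }
  return out;
}

// One Euler-Maruyama step of the coupled E/I gating equations.
// Returns false if the pre-clamp state left the admissible band.
static inline bool dmf_step(std::vector<double> &SE, std::vector<double> &SI,
                            std::vector<double> &rE, std::vector<double> &rI,
                            const NumericMatrix &C, double G,
                            const NumericVector &J, const DMFPar &p,
                            double dt, double sqdt, double sigma,
                            double pin_rE, double pin_rI) {
  int n = SE.size();
  bool ok = true;
  std::vector<double> coup(n, 0.0);
  if (G != 0.0) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < n; ++j) acc += C(i, j) * SE[j];
      coup[i] = acc;
    }
  }
  for (int i = 0; i < n; ++i) {
    double IE = p.W_E * p.I0 + p.w_plus * p.J_NMDA * SE[i] +
                G * p.J_NMDA * coup[i] - J[i] * SI[i];
    double II = p.W_I * p.I0 + p.J_NMDA * SE[i] - SI[i];
    double re = (pin_rE >= 0.0) ? pin_rE : sigmoid_transfer(IE, p.a_E, p.b_E, p.d_E);
    double ri = (pin_rI >= 0.0) ? pin_rI : sigmoid_transfer(II, p.a_I, p.b_I, p.d_I);
    rE[i] = re; rI[i] = ri;
    double nE = (sigma > 0.0) ? sigma * sqdt * norm_rand() : 0.0;
    double nI = (sigma > 0.0) ? sigma * sqdt * norm_rand() : 0.0;
    SE[i] += dt * (-SE[i] / p.tau_NMDA + (1.0 - SE[i]) * p.gamma * re) + nE;
    SI[i] += dt * (-SI[i] / p.tau_GABA + ri) + nI;
    if (SE[i] < -0.1 || SE[i] > 1.1 || SI[i] < -0.1 || SI[i] > 1.1) ok = false;
    if (SE[i] < 0.0) SE[i] = 0.0; else if (SE[i] > 1.0) SE[i] = 1.0;
    if (SI[i] < 0.0) SI[i] = 0.0; else if (SI[i] > 1.0) SI[i] = 1.0;
  }
  return ok;
}

// Integrate the neural model, recording every `record_every`-th step.
// pin_rE / pin_rI < 0 mean "not pinned".
// [[Rcpp::export]]
List cpp_dmf_integrate(NumericMatrix C, double G, NumericVector J, List par,
                       int n_steps, double dt, int record_every,
                       double sigma, double pin_rE, double pin_rI,
                       NumericVector SE0, NumericVector SI0) {
  DMFPar p = dmf_par_from_list(par);
  int n = C.nrow();
  std::vector<double> SE(SE0.begin(), SE0.end()), SI(SI0.begin(), SI0.end());
  std::vector<double> rE(n, 0.0), rI(n, 0.0);
  int n_rec = n_steps / record_every;
  NumericMatrix trSE(n, n_rec), trSI(n, n_rec), trRE(n, n_rec), trRI(n, n_rec);
  double sqdt = std::sqrt(dt);
  RNGScope scope;
  int k = 0;
  for (int t = 1; t <= n_steps; ++t) {
    bool ok = dmf_step(SE, SI, rE, rI, C, G, J, p, dt, sqdt, sigma, pin_rE, pin_rI);
    if (!ok)
      stop("neural integration failed: gating left [-0.1, 1.1] at step %d", t);
    if (t % record_every == 0 && k < n_rec) {
      for (int i = 0; i < n; ++i) {
        trSE(i, k) = SE[i]; trSI(i, k) = SI[i];
        trRE(i, k) = rE[i]; trRI(i, k) = rI[i];
      }
      ++k;
    }
  }
  return List::create(_["S_E"] = trSE, _["S_I"] = trSI,
                      _["r_E"] = trRE, _["r_I"] = trRI,
                      _["S_E_end"] = NumericVector(SE.begin(), SE.end()),
                      _["S_I_end"] = NumericVector(SI.begin(), SI.end()));
}

// Feedback inhibition control: damped Newton iteration on J.
// Each iteration continues the trajectory: burn_s of settling, then epoch_s
// over which the mean excitatory rate, mean excitatory input current and
// mean inhibitory gating are measured per region. The update
//   J_i <- J_i + damping * (r_i - target) / (H'(I_i) * S^I_i)
// uses the analytic local sensitivity dr/dJ = -H'(I) S^I (steps clipped to
// +-1 nA, J floored at 1e-3 nA), which handles both the strongly
// over-excited start (rates of order 100 Hz) and the fine approach to the
// low-rate target.
// [[Rcpp::export]]
List cpp_calibrate_fic(NumericMatrix C, double G, List par, double target,
                       double tol, double damping, int max_iter,
                       double epoch_s, double burn_s, double dt,
                       NumericVector J_init) {
  DMFPar p = dmf_par_from_list(par);
  int n = C.nrow();
  NumericVector J = clone(J_init);
  std::vector<double> SE(n, 0.1), SI(n, 0.1), rE(n, 0.0), rI(n, 0.0);
  NumericVector achieved(n, NA_REAL);
  std::vector<double> prev_dev(n, 0.0), step_cap(n, 1.0);
  // current-space target: invert the transfer function at the rate target
  // (bisection; H is strictly increasing). Calibrating on the mean input
  // current is much better conditioned than on the rectified rate itself.
  double lo = 0.0, hi = 2.0;
  for (int b = 0; b < 200; ++b) {
    double mid = 0.5 * (lo + hi);
    if (sigmoid_transfer(mid, p.a_E, p.b_E, p.d_E) < target) lo = mid;
    else hi = mid;
  }
  double I_target = 0.5 * (lo + hi);
  double sqdt = std::sqrt(dt);
  int burn_steps = (int)std::ceil(burn_s / dt);
  int epoch_steps = (int)std::ceil(epoch_s / dt);
  bool converged = false;
  int iter = 0;
  RNGScope scope;
  while (iter < max_iter) {
    ++iter;
    // restart from a common low-activity state: the measured rate must be a
    // function of J alone, not of which attractor the previous trial left
    // the network in (the coupled system is bistable when under-inhibited)
    std::fill(SE.begin(), SE.end(), 0.1);
    std::fill(SI.begin(), SI.end(), 0.1);
    for (int t = 0; t < burn_steps; ++t) {
      if (!dmf_step(SE, SI, rE, rI, C, G, J, p, dt, sqdt, p.sigma, -1.0, -1.0))
        stop("neural integration failed during FIC burn-in (iteration %d)", iter);
    }
    std::vector<double> acc_r(n, 0.0), acc_I(n, 0.0), acc_SI(n, 0.0);
    for (int t = 0; t < epoch_steps; ++t) {
      // measure input currents of the state preceding the step
      if (G != 0.0) {
        for (int i = 0; i < n; ++i) {
          double cp = 0.0;
          for (int j = 0; j < n; ++j) cp += C(i, j) * SE[j];
          acc_I[i] += p.W_E * p.I0 + p.w_plus * p.J_NMDA * SE[i] +
                      G * p.J_NMDA * cp - J[i] * SI[i];
        }
      } else {
        for (int i = 0; i < n; ++i)
          acc_I[i] += p.W_E * p.I0 + p.w_plus * p.J_NMDA * SE[i] - J[i] * SI[i];
      }
      for (int i = 0; i < n; ++i) acc_SI[i] += SI[i];
      if (!dmf_step(SE, SI, rE, rI, C, G, J, p, dt, sqdt, p.sigma, -1.0, -1.0))
        stop("neural integration failed during FIC epoch (iteration %d)", iter);
      for (int i = 0; i < n; ++i) acc_r[i] += rE[i];
    }
    double maxdev = 0.0;
    for (int i = 0; i < n; ++i) {
      achieved[i] = acc_r[i] / epoch_steps;
      double dev = achieved[i] - target;
      if (std::fabs(dev) > maxdev) maxdev = std::fabs(dev);
    }
    if (maxdev <= tol) { converged = true; break; }
    for (int i = 0; i < n; ++i) {
      double Ibar = acc_I[i] / epoch_steps;
      double SIbar = std::max(acc_SI[i] / epoch_steps, 0.01);
      double dev = achieved[i] - target;
      // Newton step in current units: dr/dJ = -H'(I) S_I. The transfer
      // slope is evaluated no lower than at the balanced-state current so
      // a silent region (tiny H') cannot produce an explosive step.
      double slope = transfer_slope(std::max(Ibar, I_target),
                                    p.a_E, p.b_E, p.d_E) * SIbar;
      // per-region trust region, halved whenever the deviation changes sign
      if (prev_dev[i] * dev < 0.0) step_cap[i] *= 0.5;
      prev_dev[i] = dev;
      double step = damping * dev / slope;
      if (step > step_cap[i]) step = step_cap[i];
      else if (step < -step_cap[i]) step = -step_cap[i];
      J[i] += step;
      if (J[i] < 1e-3) J[i] = 1e-3;
    }
  }
  return List::create(_["J"] = J, _["achieved_rates"] = achieved,
                      _["converged"] = converged, _["n_iter"] = iter);
}

// Fused neural + hemodynamic simulation: steps the SDE and the balloon model
// jointly at dt, discards burn_s, then records BOLD at every TR tick
// (nearest-sample downsampling). Memory stays O(regions x timepoints).
// drive_rate selects r_E (Hz) instead of the gating S_E as balloon input.
// [[Rcpp::export]]
List cpp_simulate_bold(NumericMatrix C, double G, NumericVector J, List par,
                       List hemo, int n_timepoints, double tr, double dt,
                       double burn_s, bool drive_rate) {
  DMFPar p = dmf_par_from_list(par);
  BalloonPar hp = balloon_par_from_list(hemo);
  int n = C.nrow();
  std::vector<double> SE(n, 0.1), SI(n, 0.1), rE(n, 0.0), rI(n, 0.0);
  std::vector<BalloonState> bst(n);
  for (int i = 0; i < n; ++i) bst[i] = {0.0, 1.0, 1.0, 1.0};
  NumericMatrix Y(n, n_timepoints);
  NumericVector mean_rE(n, 0.0);
  double sqdt = std::sqrt(dt);
  int burn_steps = (int)std::ceil(burn_s / dt);
  int steps_per_tr = (int)std::lround(tr / dt);
  if (steps_per_tr < 1) steps_per_tr = 1;
  long total_steps = (long)burn_steps + (long)steps_per_tr * n_timepoints;
  RNGScope scope;
  int rec = 0;
  long post = 0;
  for (long t = 1; t <= total_steps; ++t) {
    if (!dmf_step(SE, SI, rE, rI, C, G, J, p, dt, sqdt, p.sigma, -1.0, -1.0))
      stop("neural integration failed at step %ld (G = %g)", t, G);
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      double z = drive_rate ? rE[i] : SE[i];
      balloon_step(bst[i], z, dt, hp, bad);
    }
    if (bad)
      stop("balloon integration failed at step %ld (G = %g)", t, G);
    if (t > burn_steps) {
      ++post;
      for (int i = 0; i < n; ++i) mean_rE[i] += rE[i];
      if (post % steps_per_tr == 0 && rec < n_timepoints) {
        for (int i = 0; i < n; ++i) Y(i, rec) = balloon_bold_of(bst[i], hp);
        ++rec;
      }
    }
  }
  for (int i = 0; i < n; ++i) mean_rE[i] /= (double)post;
  return List::create(_["Y"] = Y, _["mean_rE"] = mean_rE);
}
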