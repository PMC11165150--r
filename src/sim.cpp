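#include <Rcpp.h>
using namespace Rcpp;

// Cycle-level engine for the PVT production model. All stochastic decisions
// draw from R's RNG (unif_rand), so set.seed() on the R side makes every
// session reproducible. Response-type codes: 0 alert, 1 lapse, 2 false start,
// 3 sleep attack (no response within the timeout).

static const int TYPE_ALERT = 0;
static const int TYPE_LAPSE = 1;
static const int TYPE_FALSE_START = 2;
static const int TYPE_SLEEP_ATTACK = 3;

struct Params {
  double upsilon, tau, lambda, phi, rho, kappa, s;
  double t_ml, t_motor, mismatch;
  int variant; // 0 CMF, 1 binned gamma, 2 trial gamma
};

static inline double plogis1(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Moderated utility: CMF uses (1+t)^rho, gamma variants use zeta.
static inline double utility(const Params &p, int n_ml, double t_min, double zeta) {
  double base = p.upsilon * std::pow(p.lambda, (double)n_ml);
  if (p.variant == 0) return base * std::pow(1.0 + t_min, p.rho);
  return base * zeta;
}

// Threshold declines with time-on-task in the CMF only.
static inline double threshold(const Params &p, double t_min) {
  if (p.variant == 0) return p.tau * std::pow(1.0 + t_min, p.kappa);
  return p.tau;
}

// P(respond fires on one pre-stimulus cycle): respond's noisy utility exceeds
// both the threshold and wait's noisy utility. Midpoint quadrature after the
// substitution v = F_respond(x), which maps the domain to (F_r(UT), 1).
static double p_false_start_cycle(double u_wait, double u_resp, double ut, double s) {
  if (s <= 0.0) return (u_resp >= ut && u_resp > u_wait) ? 1.0 : 0.0;
  const int K = 64;
  double v0 = plogis1((ut - u_resp) / s);
  double width = 1.0 - v0;
  if (width <= 0.0) return 0.0;
  double acc = 0.0;
  for (int i = 0; i < K; ++i) {
    double v = v0 + width * (i + 0.5) / K;
    double x = u_resp + s * std::log(v / (1.0 - v));
    acc += plogis1((x - u_wait) / s);
  }
  return acc * width / K;
}

struct TrialResult {
  double rt_ms;   // NA for false starts and sleep attacks
  int type;
  int ml_this;
  double elapsed_end;
  double zeta;
};

// One PVT trial starting at session time `trial_start` (s) with the given ISI.
// Pre-stimulus candidates {wait, respond - mismatch}: respond firing is a
// false start; failed cycles advance time silently. Post-stimulus candidates
// {attend, wait} at the shared utility, then {respond}; a cycle where nothing
// clears the threshold is a microlapse (phi + t_ml). The lambda^N penalty
// uses the microlapses accumulated since this trial's stimulus processing
// began (utilities are restored once a response completes); `n_ml` keeps the
// session-cumulative bookkeeping count.
static TrialResult run_trial(const Params &p, int &n_ml, double trial_start,
                             double isi, double timeout, double zeta) {
  TrialResult out;
  out.zeta = zeta;
  out.ml_this = 0;

  double t_min = trial_start / 60.0;
  double U = utility(p, 0, t_min, zeta);
  double UT = threshold(p, t_min);

  // pre-stimulus phase: utilities held at phase-start t
  int n_pre = (int)std::floor(isi / p.phi);
  if (n_pre > 0) {
    double pfs = p_false_start_cycle(U, U - p.mismatch, UT, p.s);
    if (pfs >= 1.0) {
      out.type = TYPE_FALSE_START;
      out.rt_ms = NA_REAL;
      out.elapsed_end = trial_start + p.phi + p.t_motor;
      return out;
    }
    if (pfs > 0.0) {
      double u = unif_rand();
      double p_any = 1.0 - std::pow(1.0 - pfs, (double)n_pre);
      if (u < p_any) {
        int k = (int)std::ceil(std::log1p(-u) / std::log1p(-pfs));
        if (k < 1) k = 1;
        if (k > n_pre) k = n_pre;
        out.type = TYPE_FALSE_START;
        out.rt_ms = NA_REAL;
        out.elapsed_end = trial_start + k * p.phi + p.t_motor;
        return out;
      }
    }
  }

  // stimulus onset
  double onset = trial_start + isi;
  double tso = 0.0; // time since onset
  bool attended = false;
  while (true) {
    t_min = (onset + tso) / 60.0;
    U = utility(p, out.ml_this, t_min, zeta);
    UT = threshold(p, t_min);
    int outcome; // 0 microlapse, 1 advance (attend/respond fires), 2 wait fires
    if (!attended) {
      if (p.s <= 0.0) {
        outcome = (U >= UT) ? 1 : 0; // tie-break favors the state-appropriate production
      } else {
        double Fm = plogis1((UT - U) / p.s);
        double p_ml = Fm * Fm;
        double u = unif_rand();
        if (u < p_ml) outcome = 0;
        else if (u < p_ml + (1.0 - p_ml) / 2.0) outcome = 1;
        else outcome = 2;
      }
    } else {
      if (p.s <= 0.0) {
        outcome = (U >= UT) ? 1 : 0;
      } else {
        double p_ml = plogis1((UT - U) / p.s);
        outcome = (unif_rand() < p_ml) ? 0 : 1;
      }
    }

    if (outcome == 0) {
      tso += p.phi + p.t_ml;
      n_ml += 1;
      out.ml_this += 1;
    } else if (outcome == 2) {
      tso += p.phi;
    } else if (!attended) {
      tso += p.phi;
      attended = true;
    } else {
      tso += p.phi;
      double rt_s = tso + p.t_motor;
      out.rt_ms = rt_s * 1000.0;
      if (out.rt_ms < 150.0) out.type = TYPE_FALSE_START;
      else if (out.rt_ms <= 500.0) out.type = TYPE_ALERT;
      else out.type = TYPE_LAPSE;
      out.elapsed_end = onset + rt_s;
      return out;
    }
    if (tso >= timeout) {
      out.type = TYPE_SLEEP_ATTACK;
      out.rt_ms = NA_REAL;
      out.elapsed_end = onset + tso;
      return out;
    }
  }
}

static Params make_params(List par, int variant) {
  Params p;
  p.upsilon = as<double>(par["upsilon"]);
  p.tau = as<double>(par["tau"]);
  p.lambda = as<double>(par["lambda"]);
  p.phi = as<double>(par["phi"]);
  p.rho = as<double>(par["rho"]);
  p.kappa = as<double>(par["kappa"]);
  p.s = as<double>(par["s"]);
  p.t_ml = as<double>(par["t_microlapse"]);
  p.t_motor = as<double>(par["t_motor"]);
  p.mismatch = as<double>(par["mismatch"]);
  p.variant = variant;
  return p;
}

// [[Rcpp::export]]
List cpp_simulate_trial(List par, int variant, double zeta, int n_ml0,
                        double elapsed0, double isi, double timeout) {
  Params p = make_params(par, variant);
  int n_ml = n_ml0;
  TrialResult tr = run_trial(p, n_ml, elapsed0, isi, timeout, zeta);
  return List::create(
    _["onset_s"] = elapsed0 + isi,
    _["rt_ms"] = tr.rt_ms,
    _["type"] = tr.type,
    _["n_ml_trial"] = tr.ml_this,
    _["n_ml"] = n_ml,
    _["elapsed_end"] = tr.elapsed_end,
    _["zeta"] = tr.zeta);
}

// [[Rcpp::export]]
List cpp_simulate_session(List par, int variant, NumericVector zeta,
                          double duration, double timeout,
                          IntegerVector isi_choices) {
  Params p = make_params(par, variant);
  int n_ml = 0;
  double elapsed = 0.0;
  int nz = zeta.size();
  int k_isi = isi_choices.size();

  std::vector<double> onset, isi_v, rt, zeta_v;
  std::vector<int> type, ml_trial, n_ml_cum;

  int trial = 0;
  while (true) {
    int idx = (int)std::floor(unif_rand() * k_isi);
    if (idx >= k_isi) idx = k_isi - 1;
    double isi = (double)isi_choices[idx];
    if (elapsed + isi >= duration) break;
    trial += 1;

    double z = 1.0;
    if (variant == 1) {
      int bin = (int)std::floor((elapsed + isi) / (duration / 5.0));
      if (bin > 4) bin = 4;
      if (bin >= nz) bin = nz - 1;
      z = zeta[bin];
    } else if (variant == 2) {
      int zi = trial - 1;
      if (zi >= nz) zi = nz - 1;
      z = zeta[zi];
    }

    TrialResult tr = run_trial(p, n_ml, elapsed, isi, timeout, z);
    onset.push_back(elapsed + isi);
    isi_v.push_back(isi);
    rt.push_back(tr.rt_ms);
    type.push_back(tr.type);
    ml_trial.push_back(tr.ml_this);
    zeta_v.push_back(tr.zeta);
    n_ml_cum.push_back(n_ml);
    elapsed = tr.elapsed_end;
  }

  return List::create(
    _["onset_s"] = wrap(onset),
    _["isi_s"] = wrap(isi_v),
    _["rt_ms"] = wrap(rt),
    _["type"] = wrap(type),
    _["n_ml_trial"] = wrap(ml_trial),
    _["zeta"] = wrap(zeta_v),
    _["n_ml_cum"] = wrap(n_ml_cum),
    _["final_n_ml"] = n_ml,
    _["final_elapsed"] = elapsed);
}

// Lean batch path for the simulated likelihood: n_sessions full sessions,
// returning only RTs and type codes.
// [[Rcpp::export]]
List cpp_simulate_trials(List par, int variant, NumericVector zeta,
                         double duration, double timeout,
                         IntegerVector isi_choices, int n_sessions) {
  Params p = make_params(par, variant);
  int nz = zeta.size();
  int k_isi = isi_choices.size();
  std::vector<double> rt, onset, zeta_v;
  std::vector<int> type;
  for (int s = 0; s < n_sessions; ++s) {
    int n_ml = 0;
    double elapsed = 0.0;
    int trial = 0;
    while (true) {
      int idx = (int)std::floor(unif_rand() * k_isi);
      if (idx >= k_isi) idx = k_isi - 1;
      double isi = (double)isi_choices[idx];
      if (elapsed + isi >= duration) break;
      trial += 1;
      double z = 1.0;
      if (variant == 1) {
        int bin = (int)std::floor((elapsed + isi) / (duration / 5.0));
        if (bin > 4) bin = 4;
        if (bin >= nz) bin = nz - 1;
        z = zeta[bin];
      } else if (variant == 2) {
        int zi = trial - 1;
        if (zi >= nz) zi = nz - 1;
        z = zeta[zi];
      }
      TrialResult tr = run_trial(p, n_ml, elapsed, isi, timeout, z);
      rt.push_back(tr.rt_ms);
      type.push_back(tr.type);
      onset.push_back(elapsed + isi);
      zeta_v.push_back(z);
      elapsed = tr.elapsed_end;
    }
  }
  return List::create(_["rt_ms"] = wrap(rt), _["type"] = wrap(type),
                      _["onset_s"] = wrap(onset), _["zeta"] = wrap(zeta_v));
}
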