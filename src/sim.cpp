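#include <Rcpp.h>
using namespace Rcpp;

// Coupled integration of a Tsodyks-Pawelzik-Markram synapse between two
// leaky integrate-and-fire neurons, with an optional online soft-bounded
// STDP rule.  Forward Euler on the membrane potentials; all first-order
// decays (x1, x2, u0, gE, STDP traces) advance by their exact exponential
// solutions, so the synaptic state variables carry no step-size error.
//
// Units: time ms, voltage mV, current pA, capacitance pF, conductance nS
// (1 nS * 1 mV = 1 pA; leak conductance = 1000/Rm[MOhm] nS).

struct TpmConst {
  double U, tau_in, tau_rec, tau_f;
  double e_in, e_rec, e_f;   // per-dt decay factors
  double a_coef;             // tau_rec/(tau_in - tau_rec), NaN when equal
  double dt;
};

static inline TpmConst tpm_const(double U, double tau_in, double tau_rec,
                                 double tau_f, double dt) {
  TpmConst c;
  c.U = U; c.tau_in = tau_in; c.tau_rec = tau_rec; c.tau_f = tau_f;
  c.dt = dt;
  c.e_in = std::exp(-dt / tau_in);
  c.e_rec = std::exp(-dt / tau_rec);
  c.e_f = std::exp(-dt / tau_f);
  c.a_coef = (std::abs(tau_in - tau_rec) > 1e-12)
                 ? tau_rec / (tau_in - tau_rec)
                 : std::numeric_limits<double>::quiet_NaN();
  return c;
}

// Exact inter-spike decay over one step; conservation kept by moving the
// balance into x0 incrementally.
static inline void tpm_decay(double &x0, double &x1, double &x2, double &u0,
                             const TpmConst &c) {
  double nx1 = x1 * c.e_in, nx2;
  if (!std::isfinite(c.a_coef)) {
    nx2 = (x2 + x1 * c.dt / c.tau_in) * c.e_rec;  // tau_in == tau_rec
  } else {
    double A = x1 * c.a_coef;
    nx2 = (x2 - A) * c.e_rec + A * c.e_in;
  }
  x0 += (x1 + x2) - (nx1 + nx2);
  x1 = nx1;
  x2 = nx2;
  u0 *= c.e_f;
}

// Rectangular pulse train: summed amplitude of all pulses active at t.
struct PulseTrain {
  const double *onset;
  int n;
  double width, amp;
  int lo;
  PulseTrain(const NumericVector &on, double width_, double amp_)
      : onset(on.begin()), n(on.size()), width(width_), amp(amp_), lo(0) {}
  double current(double t) {
    while (lo < n && onset[lo] + width <= t) ++lo;
    double I = 0.0;
    for (int j = lo; j < n && onset[j] <= t; ++j) I += amp;
    return I;
  }
};

struct SimResult {
  std::vector<double> pre_spikes, post_spikes;
  double w_final;
  NumericMatrix traces;  // optional
};

static SimResult run_sim(const NumericVector &pre_onsets,
                         const NumericVector &post_onsets,
                         double pre_width, double post_width, double A1,
                         double A2, double U, double tau_in, double tau_rec,
                         double tau_f, double Cm, double Rm, double EL,
                         double Vthre, double Vreset, double tau_ref,
                         double tau_syn, double EE, double w_init,
                         bool stdp_on, double lam, double tau_plus,
                         double tau_minus, double w_max, double dt,
                         double t_end, int record_every) {
  TpmConst tc = tpm_const(U, tau_in, tau_rec, tau_f, dt);
  double e_syn = std::exp(-dt / tau_syn);
  double e_plus = std::exp(-dt / tau_plus);
  double e_minus = std::exp(-dt / tau_minus);
  double gL = 1000.0 / Rm;  // nS

  double x0 = 1.0, x1 = 0.0, x2 = 0.0, u0 = 0.0;
  double V1 = EL, V2 = EL, gE = 0.0;
  double ref1_until = -1e30, ref2_until = -1e30;
  double w = w_init;
  double a_pre = 0.0, a_post = 0.0;  // STDP traces

  PulseTrain pre(pre_onsets, pre_width, A1);
  PulseTrain post(post_onsets, post_width, A2);

  int n_steps = (int)std::ceil(t_end / dt);
  SimResult res;
  int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 0;
  NumericMatrix tr(n_rec, 9);
  int rec_i = 0;
  if (record_every > 0) {
    tr(0, 0) = 0.0; tr(0, 1) = V1; tr(0, 2) = V2; tr(0, 3) = gE;
    tr(0, 4) = x0; tr(0, 5) = x1; tr(0, 6) = x2; tr(0, 7) = u0; tr(0, 8) = w;
    rec_i = 1;
  }

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    double I1 = pre.current(t);
    double I2 = post.current(t);

    // forward Euler on the membranes (held at Vreset while refractory)
    if (t >= ref1_until)
      V1 += dt * (-(V1 - EL) * gL + I1) / Cm;
    else
      V1 = Vreset;
    if (t >= ref2_until)
      V2 += dt * (-(V2 - EL) * gL + I2 + gE * (EE - V2)) / Cm;
    else
      V2 = Vreset;

    // exact exponential decays
    gE *= e_syn;
    tpm_decay(x0, x1, x2, u0, tc);
    a_pre *= e_plus;
    a_post *= e_minus;

    double t_next = (s + 1) * dt;
    bool pre_sp = (t >= ref1_until) && (V1 >= Vthre);
    bool post_sp = (t >= ref2_until) && (V2 >= Vthre);
    // snapshots so that exactly coincident spikes pair with weight 0
    double a_pre0 = a_pre, a_post0 = a_post;

    if (pre_sp) {
      res.pre_spikes.push_back(t_next);
      V1 = Vreset;
      ref1_until = t_next + tau_ref;
      // facilitation jump -> release -> conductance jump
      u0 += U * (1.0 - u0);
      double rel = u0 * x0;
      x0 -= rel;
      x1 += rel;
      gE += w * rel;
      if (stdp_on) {
        w -= lam * w * a_post0;
        a_pre += 1.0;
      }
    }
    if (post_sp) {
      res.post_spikes.push_back(t_next);
      V2 = Vreset;
      ref2_until = t_next + tau_ref;
      if (stdp_on) {
        w += lam * (w_max - w) * a_pre0;
        a_post += 1.0;
      }
    }
    if (stdp_on) {
      if (w < 0.0) w = 0.0;
      if (w > w_max) w = w_max;
    }

    if (record_every > 0 && ((s + 1) % record_every == 0) && rec_i < n_rec) {
      tr(rec_i, 0) = t_next; tr(rec_i, 1) = V1; tr(rec_i, 2) = V2; tr(rec_i, 3) = gE;
      tr(rec_i, 4) = x0; tr(rec_i, 5) = x1; tr(rec_i, 6) = x2;
      tr(rec_i, 7) = u0; tr(rec_i, 8) = w;
      ++rec_i;
    }
  }
  if (record_every > 0 && rec_i < n_rec)
    res.traces = tr(Range(0, rec_i - 1), Range(0, 8));
  else
    res.traces = tr;
  res.w_final = w;
  return res;
}

// [[Rcpp::export]]
List cpp_simulate_pair(NumericVector pre_onsets, NumericVector post_onsets,
                       double pre_width, double post_width, double A1,
                       double A2, double U, double tau_in, double tau_rec,
                       double tau_f, double Cm, double Rm, double EL,
                       double Vthre, double Vreset, double tau_ref,
                       double tau_syn, double EE, double w_init, bool stdp_on,
                       double lam, double tau_plus, double tau_minus,
                       double w_max, double dt, double t_end,
                       int record_every) {
  SimResult r = run_sim(pre_onsets, post_onsets, pre_width, post_width, A1,
                        A2, U, tau_in, tau_rec, tau_f, Cm, Rm, EL, Vthre,
                        Vreset, tau_ref, tau_syn, EE, w_init, stdp_on, lam,
                        tau_plus, tau_minus, w_max, dt, t_end, record_every);
  List out = List::create(
      _["pre_spikes"] = wrap(r.pre_spikes),
      _["post_spikes"] = wrap(r.post_spikes), _["w_final"] = r.w_final);
  if (record_every > 0) out["traces"] = r.traces;
  return out;
}

// Relative weight change (w_final - w0)/w0 for a batch of release
// probabilities under one stimulation geometry (a pairing-grid cell).
// [[Rcpp::export]]
NumericVector cpp_dw_batch(NumericVector U_values, NumericVector pre_onsets,
                           NumericVector post_onsets, double pre_width,
                           double post_width, double A1, double A2,
                           double tau_in, double tau_rec, double tau_f,
                           double Cm, double Rm, double EL, double Vthre,
                           double Vreset, double tau_ref, double tau_syn,
                           double EE, double w0, double lam, double tau_plus,
                           double tau_minus, double w_max, double dt,
                           double t_end) {
  int n = U_values.size();
  NumericVector dw(n);
  for (int i = 0; i < n; ++i) {
    SimResult r = run_sim(pre_onsets, post_onsets, pre_width, post_width, A1,
                          A2, U_values[i], tau_in, tau_rec, tau_f, Cm, Rm, EL,
                          Vthre, Vreset, tau_ref, tau_syn, EE, w0, true, lam,
                          tau_plus, tau_minus, w_max, dt, t_end, 0);
    dw[i] = (r.w_final - w0) / w0;
  }
  return dw;
}
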