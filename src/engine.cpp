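// Clock-driven simulation engine for the STN-GPe network.
//
// STN neurons: single-compartment conductance-based model (Otsuka-type),
// integrated with exponential Euler for gating variables and a forward
// update for V. GPe neurons: conductance-based leaky integrate-and-fire
// with exact exponential subthreshold updates. Synaptic kernels are
// realised as exponential state variables (beta = difference of two
// exponentials, alpha = critically damped pair). Delayed event delivery
// uses per-target ring buffers; short-term plasticity state is updated
// lazily at presynaptic event times.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xorshift-free 64-bit Mersenne-like stream. We use splitmix64 to seed
// and a small xoshiro256++ generator so that each noise consumer (cortex,
// GPe intrinsic, release/feedback) owns an independent reproducible stream.
// ---------------------------------------------------------------------------
struct RngStream {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit RngStream(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  bool bernoulli(double p) { return unif() < p; }
  int binomial(int n, double p) {
    int k = 0;
    for (int i = 0; i < n; ++i) if (unif() < p) ++k;
    return k;
  }
};

// ---------------------------------------------------------------------------
// STN membrane model
// ---------------------------------------------------------------------------
static const int N_GATE = 9; // m h n a b c d1 p q (voltage-gated)

struct StnKinetics {
  // per gate: th_inf, k_inf, tau0, tau1, th1, s1, th2, s2
  double th_inf[N_GATE], k_inf[N_GATE], tau0[N_GATE], tau1[N_GATE];
  double th1[N_GATE], s1[N_GATE], th2[N_GATE], s2[N_GATE];
  // calcium-dependent gates d2 (L inactivation) and r (Ca-K activation)
  double d2_th, d2_k, d2_tau, r_th, r_k, r_tau;
};

struct StnParams {
  double cm;            // uF/cm2
  double gna, gk, ga, glca, gt, gcak, gleak; // mS/cm2
  double vna, vk, vleak, vexc, vinh;         // mV
  double syn_scale;     // mS/cm2 per nS (1e-6 / membrane area in cm2)
  double alpha_ca;      // uM per (uA/cm2 * ms)
  double k_ca;          // 1/ms
  double ca_out;        // uM
  double spike_thr;     // mV, upward-crossing detection
  double spike_refr;    // ms, detection guard
};

struct StnState {
  double v, gate[N_GATE], d2, r, ca, last_spike;
};

static inline double sigm(double v, double th, double k) {
  return 1.0 / (1.0 + std::exp(-(v - th) / k));
}

static inline double gate_tau(const StnKinetics &kin, int g, double v) {
  double e1 = std::exp(-(v - kin.th1[g]) / kin.s1[g]);
  double e2 = std::exp(-(v - kin.th2[g]) / kin.s2[g]);
  return kin.tau0[g] + kin.tau1[g] / (e1 + e2);
}

static StnKinetics kinetics_from_list(const List &kl) {
  StnKinetics kin;
  NumericMatrix m = kl["vgates"]; // N_GATE x 8
  if (m.nrow() != N_GATE || m.ncol() != 8)
    stop("gating-kinetics table must be 9 x 8");
  for (int g = 0; g < N_GATE; ++g) {
    kin.th_inf[g] = m(g, 0); kin.k_inf[g] = m(g, 1);
    kin.tau0[g] = m(g, 2);   kin.tau1[g] = m(g, 3);
    kin.th1[g] = m(g, 4);    kin.s1[g] = m(g, 5);
    kin.th2[g] = m(g, 6);    kin.s2[g] = m(g, 7);
  }
  NumericVector cg = kl["cagates"]; // d2_th d2_k d2_tau r_th r_k r_tau
  kin.d2_th = cg[0]; kin.d2_k = cg[1]; kin.d2_tau = cg[2];
  kin.r_th = cg[3];  kin.r_k = cg[4];  kin.r_tau = cg[5];
  return kin;
}

static StnParams stn_params_from_list(const List &pl) {
  StnParams p;
  p.cm = pl["cm"]; p.gna = pl["g_na"]; p.gk = pl["g_k"]; p.ga = pl["g_a"];
  p.glca = pl["g_lca"]; p.gt = pl["g_t"]; p.gcak = pl["g_cak"];
  p.gleak = pl["g_leak"]; p.vna = pl["v_na"]; p.vk = pl["v_k"];
  p.vleak = pl["v_leak"]; p.vexc = pl["v_exc"]; p.vinh = pl["v_inh"];
  p.syn_scale = pl["syn_scale"]; p.alpha_ca = pl["alpha_ca"];
  p.k_ca = pl["k_ca"]; p.ca_out = pl["ca_out"];
  p.spike_thr = pl["spike_threshold"]; p.spike_refr = pl["spike_refractory"];
  return p;
}

// initialise gates at their steady state for the given voltage
static void stn_init(StnState &st, const StnParams &p, const StnKinetics &kin,
                     double v0, double ca0) {
  st.v = v0; st.ca = ca0; st.last_spike = -1e9;
  for (int g = 0; g < N_GATE; ++g) st.gate[g] = sigm(v0, kin.th_inf[g], kin.k_inf[g]);
  st.d2 = sigm(ca0, kin.d2_th, kin.d2_k);
  st.r = sigm(ca0, kin.r_th, kin.r_k);
}

// one exponential-Euler step; returns true when a spike is detected
static bool stn_step(StnState &st, const StnParams &p, const StnKinetics &kin,
                     double dt, double t, double g_ampa, double g_gaba,
                     double i_app, double *gt_out) {
  const double v = st.v;
  const double vca = 13.27 * std::log(p.ca_out / std::max(st.ca, 1e-9));
  const double m = st.gate[0], h = st.gate[1], n = st.gate[2];
  const double a = st.gate[3], b = st.gate[4], c = st.gate[5];
  const double d1 = st.gate[6], pp = st.gate[7], q = st.gate[8];

  const double ina = p.gna * m * m * m * h * (v - p.vna);
  const double ik = p.gk * n * n * n * n * (v - p.vk);
  const double ia = p.ga * a * a * b * (v - p.vk);
  const double ilca = p.glca * c * c * d1 * st.d2 * (v - vca);
  const double it = p.gt * pp * pp * q * (v - vca);
  const double icak = p.gcak * st.r * st.r * (v - p.vk);
  const double ileak = p.gleak * (v - p.vleak);
  const double isyn = p.syn_scale * (g_ampa * (v - p.vexc) + g_gaba * (v - p.vinh));
  if (gt_out) *gt_out = p.gt * pp * pp * q; // T-current conductance, mS/cm2

  const double dv = (-ina - ik - ia - ilca - it - icak - ileak - isyn + i_app) / p.cm;

  // gating: exponential Euler at the pre-step voltage
  for (int g = 0; g < N_GATE; ++g) {
    const double xinf = sigm(v, kin.th_inf[g], kin.k_inf[g]);
    const double tau = gate_tau(kin, g, v);
    double x = xinf + (st.gate[g] - xinf) * std::exp(-dt / tau);
    st.gate[g] = x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
  }
  {
    const double d2inf = sigm(st.ca, kin.d2_th, kin.d2_k);
    st.d2 = d2inf + (st.d2 - d2inf) * std::exp(-dt / kin.d2_tau);
    const double rinf = sigm(st.ca, kin.r_th, kin.r_k);
    st.r = rinf + (st.r - rinf) * std::exp(-dt / kin.r_tau);
  }
  // calcium relaxes exponentially toward the current-driven equilibrium
  {
    double ca_inf = -p.alpha_ca * (ilca + it) / p.k_ca;
    if (ca_inf < 0.0) ca_inf = 0.0;
    st.ca = ca_inf + (st.ca - ca_inf) * std::exp(-p.k_ca * dt);
  }

  const double v_new = v + dt * dv;
  if (!std::isfinite(v_new))
    stop("STN membrane potential diverged (non-finite) at t = %f ms", t);
  bool spike = false;
  if (v < p.spike_thr && v_new >= p.spike_thr && (t - st.last_spike) > p.spike_refr) {
    spike = true;
    st.last_spike = t;
  }
  st.v = v_new;
  return spike;
}

// ---------------------------------------------------------------------------
// Kernel amplitude normalisation
// ---------------------------------------------------------------------------
// beta kernel g(t) = k (exp(-t/tau_d) - exp(-t/tau_r)); unnormalised peak
// value is k * beta_peak_factor. With peak normalisation, a unit event
// reaches exactly the configured amplitude at its peak.
static double beta_peak_factor(double tau_r, double tau_d) {
  double tstar = tau_r * tau_d / (tau_d - tau_r) * std::log(tau_d / tau_r);
  return std::exp(-tstar / tau_d) - std::exp(-tstar / tau_r);
}

// ---------------------------------------------------------------------------
// Single-neuron trajectory helpers (used by calibration and tests)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_stn_trajectory(List params, List kinetics, double dt, int n_steps,
                        NumericVector i_app, NumericVector g_ampa,
                        NumericVector g_gaba, double v0, double ca0,
                        bool record) {
  StnParams p = stn_params_from_list(params);
  StnKinetics kin = kinetics_from_list(kinetics);
  StnState st;
  stn_init(st, p, kin, v0, ca0);
  std::vector<double> spikes, vtrace;
  if (record) vtrace.reserve(n_steps);
  auto at = [&](const NumericVector &x, int i) {
    return x.size() == 1 ? x[0] : x[i];
  };
  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    bool s = stn_step(st, p, kin, dt, t, at(g_ampa, i), at(g_gaba, i),
                      at(i_app, i), nullptr);
    if (s) spikes.push_back(t);
    if (record) vtrace.push_back(st.v);
  }
  List out = List::create(
    _["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
    _["v_final"] = st.v, _["ca_final"] = st.ca);
  if (record) out["v"] = NumericVector(vtrace.begin(), vtrace.end());
  return out;
}

// [[Rcpp::export]]
List cpp_gpe_trajectory(double cm, double g_leak, double v_leak, double v_exc,
                        double v_thr, double v_reset, double refr, double dt,
                        int n_steps, NumericVector g_exc, double v0) {
  double v = v0, refr_left = 0.0;
  std::vector<double> spikes, vtrace;
  vtrace.reserve(n_steps);
  for (int i = 0; i < n_steps; ++i) {
    double g = g_exc.size() == 1 ? g_exc[0] : g_exc[i];
    bool active = refr_left <= 0.0;
    if (!active) {
      // hold during the refractory period; resume on the step where it ends
      refr_left -= dt;
      if (refr_left <= 1e-12) { refr_left = 0.0; active = true; }
    }
    if (active) {
      double gtot = g_leak + g;
      double vinf = (g_leak * v_leak + g * v_exc) / gtot;
      // cm in nF, g in nS, dt in ms: tau_ms = 1000 * cm / gtot
      v = vinf + (v - vinf) * std::exp(-gtot * dt / (1000.0 * cm));
      if (v >= v_thr) {
        spikes.push_back(i * dt);
        v = v_reset;
        refr_left = refr;
      }
    }
    vtrace.push_back(v);
  }
  return List::create(_["spike_times"] = NumericVector(spikes.begin(), spikes.end()),
                      _["v"] = NumericVector(vtrace.begin(), vtrace.end()));
}

// ---------------------------------------------------------------------------
// Full network engine
// ---------------------------------------------------------------------------

struct Projection {
  int src, tgt, delay_steps;
  // depression (GPe->STN)
  int n_contact;
  // facilitation x depression (STN->GPe)
  double f_f, f_d_fac, tau_f, tau_d_fac;
  // shared plasticity state
  double P, F, D, last_t;
};

// [[Rcpp::export]]
List cpp_simulate(List cfg) {
  const double dt = cfg["dt"];
  const int n_steps = cfg["n_steps"];
  const int n_stn = cfg["n_stn"];
  const int n_gpe = cfg["n_gpe"];

  StnParams sp = stn_params_from_list(cfg["stn_params"]);
  StnKinetics kin = kinetics_from_list(cfg["stn_kinetics"]);

  List gp = cfg["gpe_params"];
  const double g_cm = gp["cm"], g_gl = gp["g_leak"], g_vl = gp["v_leak"];
  const double g_vexc = gp["v_exc"], g_thr = gp["threshold"];
  const double g_reset = gp["reset"], g_refr = gp["refractory"];

  // kernels
  List ker = cfg["kernels"];
  const double gaba_tr = ker["gaba_tau_rise"], gaba_td = ker["gaba_tau_decay"];
  const double gampa_tr = ker["gpe_ampa_tau_rise"], gampa_td = ker["gpe_ampa_tau_decay"];
  const double ctx_tau = ker["ctx_tau"];
  const bool normalize = ker["peak_normalize"];
  const double gaba_amp_scale = normalize ? 1.0 / beta_peak_factor(gaba_tr, gaba_td) : 1.0;
  const double gampa_amp_scale = normalize ? 1.0 / beta_peak_factor(gampa_tr, gampa_td) : 1.0;
  const double ctx_amp_scale = normalize ? std::exp(1.0) : 1.0;

  // precomputed per-step decay factors
  const double dec_gaba_r = std::exp(-dt / gaba_tr), dec_gaba_d = std::exp(-dt / gaba_td);
  const double dec_gampa_r = std::exp(-dt / gampa_tr), dec_gampa_d = std::exp(-dt / gampa_td);
  const double dec_ctx = std::exp(-dt / ctx_tau);

  // conductance amplitudes (nS)
  List amps = cfg["amplitudes"];
  const double a_gaba = amps["g_gaba_gpe_stn"];
  const double a_stn_gpe = amps["g_ampa_stn_gpe"];
  const double a_int = amps["g_ampa_gpe_int"];
  const double a_ctx = amps["g_ampa_ctx_stn"];

  // short-term plasticity constants
  List stp = cfg["stp"];
  const double dep_tau = stp["tau_d"], dep_fd = stp["f_d"];
  const double dep_pb = stp["p_bound"], dep_nb = stp["n_bound"];
  const double f_bound = stp["f_bound"];
  const bool per_contact = stp["per_contact"];

  // projections
  List net = cfg["network"];
  IntegerVector gs_src = net["gs_src"], gs_tgt = net["gs_tgt"],
                gs_nc = net["gs_n_contact"], gs_delay = net["gs_delay_steps"];
  IntegerVector sg_src = net["sg_src"], sg_tgt = net["sg_tgt"],
                sg_type = net["sg_type"], sg_delay = net["sg_delay_steps"];
  NumericMatrix stp_types = net["stp_type_params"]; // 3 x 4: fF fD tauF tauD

  const int n_gs = gs_src.size(), n_sg = sg_src.size();
  std::vector<Projection> proj_gs(n_gs), proj_sg(n_sg);
  int max_delay = 1;
  for (int i = 0; i < n_gs; ++i) {
    Projection &pr = proj_gs[i];
    pr.src = gs_src[i]; pr.tgt = gs_tgt[i]; pr.n_contact = gs_nc[i];
    pr.delay_steps = gs_delay[i]; pr.P = 1.0; pr.last_t = 0.0;
    if (pr.delay_steps > max_delay) max_delay = pr.delay_steps;
  }
  for (int i = 0; i < n_sg; ++i) {
    Projection &pr = proj_sg[i];
    pr.src = sg_src[i]; pr.tgt = sg_tgt[i]; pr.delay_steps = sg_delay[i];
    int ty = sg_type[i] - 1;
    pr.f_f = stp_types(ty, 0); pr.f_d_fac = stp_types(ty, 1);
    pr.tau_f = stp_types(ty, 2); pr.tau_d_fac = stp_types(ty, 3);
    pr.F = 1.0; pr.D = 1.0; pr.last_t = 0.0;
    if (pr.delay_steps > max_delay) max_delay = pr.delay_steps;
  }

  // adjacency: efferent projection indices by source neuron
  std::vector<std::vector<int> > eff_gpe(n_gpe), eff_stn(n_stn);
  for (int i = 0; i < n_gs; ++i) eff_gpe[proj_gs[i].src].push_back(i);
  for (int i = 0; i < n_sg; ++i) eff_stn[proj_sg[i].src].push_back(i);

  // feedback delay lines (STN -> STN via the external loop abstraction)
  List fb = cfg["feedback"];
  IntegerVector fb_src = fb["src"], fb_tgt = fb["tgt"], fb_delay = fb["delay_steps"];
  NumericVector fb_amp = fb["amp"];
  const double fb_p = fb["p_transmit"];
  const int n_fb = fb_src.size();
  std::vector<std::vector<int> > eff_fb(n_stn);
  for (int i = 0; i < n_fb; ++i) {
    eff_fb[fb_src[i]].push_back(i);
    if (fb_delay[i] > max_delay) max_delay = fb_delay[i];
  }

  // cortex drive: shared piecewise-constant rate profile (Hz), independent
  // event streams per STN neuron
  List ctx = cfg["cortex"];
  NumericVector ctx_break_step = ctx["break_steps"]; // sorted step indices
  NumericVector ctx_rates = ctx["rates"];            // length breaks + 1
  const double gpe_int_rate = cfg["gpe_int_rate"];   // Hz
  const bool gpe_int_deterministic = cfg["gpe_int_deterministic"];

  // seeds
  List seeds = cfg["seeds"];
  RngStream rng_ctx((uint64_t)(double)seeds["cortex"]);
  RngStream rng_noise((uint64_t)(double)seeds["noise"]);
  RngStream rng_rel((uint64_t)(double)seeds["release"]);

  // forced STN spikes (testing aid): list of step-index vectors per neuron
  List forced = cfg["forced_stn_spikes"];
  std::vector<std::vector<int> > forced_steps(n_stn);
  if (forced.size() > 0) {
    for (int i = 0; i < n_stn && i < forced.size(); ++i) {
      IntegerVector v = forced[i];
      forced_steps[i] = std::vector<int>(v.begin(), v.end());
    }
  }
  std::vector<size_t> forced_pos(n_stn, 0);

  // ring buffers for delayed increments (already amplitude-resolved, nS)
  const int ring = max_delay + 1;
  std::vector<double> ring_gaba((size_t)n_stn * ring, 0.0);
  std::vector<double> ring_gampa((size_t)n_gpe * ring, 0.0);
  std::vector<double> ring_ctx((size_t)n_stn * ring, 0.0);

  // neuron state
  std::vector<StnState> stn(n_stn);
  const double v0 = cfg["stn_v0"];
  for (int i = 0; i < n_stn; ++i) stn_init(stn[i], sp, kin, v0, 0.005);
  std::vector<double> gpe_v(n_gpe, g_vl), gpe_refr(n_gpe, 0.0);

  // synaptic state (nS): STN gaba beta pair, STN ctx alpha pair,
  // GPe ampa beta pair (shared by STN input and intrinsic noise)
  std::vector<double> st_gaba_r(n_stn, 0.0), st_gaba_d(n_stn, 0.0);
  std::vector<double> st_ctx_y(n_stn, 0.0), st_ctx_g(n_stn, 0.0);
  std::vector<double> gp_amp_r(n_gpe, 0.0), gp_amp_d(n_gpe, 0.0);

  // recording
  std::vector<std::vector<double> > stn_spk(n_stn), gpe_spk(n_gpe);
  IntegerVector rec_stn = cfg["record_stn"]; // 0-based neuron indices
  IntegerVector rec_gpe = cfg["record_gpe"];
  const int decim = cfg["trace_decim"];
  const int n_rec_steps = rec_stn.size() + rec_gpe.size() > 0 ? (n_steps / decim + 1) : 0;
  // traces: per recorded STN neuron: v, g_gaba, g_ampa, q, g_t, ca
  std::vector<std::vector<double> > tr_stn;
  tr_stn.resize((size_t)rec_stn.size() * 6);
  for (auto &v : tr_stn) v.reserve(n_rec_steps);
  std::vector<std::vector<double> > tr_gpe;  // v, g_ampa
  tr_gpe.resize((size_t)rec_gpe.size() * 2);
  for (auto &v : tr_gpe) v.reserve(n_rec_steps);

  const double p_scale = dt * 1e-3; // Hz -> probability per step
  int ctx_seg = 0;
  const int n_ctx_breaks = ctx_break_step.size();

  // depression helpers
  auto dep_decay = [&](double P, double dtms) {
    return 1.0 - (1.0 - P) * std::exp(-dtms / dep_tau);
  };
  auto dep_spike = [&](double P) {
    double frac = (P - dep_pb) / (1.0 - dep_pb);
    if (frac < 0.0) frac = 0.0;
    return P * (1.0 + (dep_fd - 1.0) * std::pow(frac, dep_nb));
  };

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const int slot = step % ring;

    // advance cortex rate segment
    while (ctx_seg < n_ctx_breaks && step >= ctx_break_step[ctx_seg]) ++ctx_seg;
    const double ctx_rate = ctx_rates[ctx_seg];
    const double p_ctx = ctx_rate * p_scale;

    // --- STN population -----------------------------------------------
    for (int i = 0; i < n_stn; ++i) {
      // deliver delayed events
      double inc_gaba = ring_gaba[(size_t)i * ring + slot];
      ring_gaba[(size_t)i * ring + slot] = 0.0;
      if (inc_gaba != 0.0) {
        st_gaba_r[i] += inc_gaba * gaba_amp_scale;
        st_gaba_d[i] += inc_gaba * gaba_amp_scale;
      }
      double inc_ctx = ring_ctx[(size_t)i * ring + slot];
      ring_ctx[(size_t)i * ring + slot] = 0.0;
      if (inc_ctx != 0.0) st_ctx_y[i] += inc_ctx * ctx_amp_scale;
      // background cortical drive (no delay: delays are folded into the
      // Poisson character of the drive)
      if (p_ctx > 0.0 && rng_ctx.bernoulli(p_ctx))
        st_ctx_y[i] += a_ctx * ctx_amp_scale;

      const double g_gaba = st_gaba_d[i] - st_gaba_r[i];
      const double g_ampa = st_ctx_g[i];

      double gt_now;
      bool spiked = stn_step(stn[i], sp, kin, dt, t, g_ampa,
                             g_gaba > 0.0 ? g_gaba : 0.0, 0.0, &gt_now);

      // forced spikes (testing)
      if (!forced_steps[i].empty() && forced_pos[i] < forced_steps[i].size() &&
          forced_steps[i][forced_pos[i]] == step) {
        spiked = true;
        ++forced_pos[i];
      }

      if (spiked) {
        stn_spk[i].push_back(t);
        // STN->GPe projections with facilitation x depression
        for (int pi : eff_stn[i]) {
          Projection &pr = proj_sg[pi];
          double dte = t - pr.last_t;
          pr.F = 1.0 + (pr.F - 1.0) * std::exp(-dte / pr.tau_f);
          pr.D = 1.0 + (pr.D - 1.0) * std::exp(-dte / pr.tau_d_fac);
          pr.last_t = t;
          double A = pr.F * pr.D;
          pr.F = pr.F * (1.0 + (pr.f_f - 1.0) * ((f_bound - pr.F) / f_bound));
          pr.D = pr.D * pr.f_d_fac;
          int dslot = (step + pr.delay_steps) % ring;
          ring_gampa[(size_t)pr.tgt * ring + dslot] += A * a_stn_gpe;
        }
        // feedback delay lines
        for (int fi : eff_fb[i]) {
          if (fb_p >= 1.0 || rng_rel.bernoulli(fb_p)) {
            int dslot = (step + fb_delay[fi]) % ring;
            ring_ctx[(size_t)fb_tgt[fi] * ring + dslot] += fb_amp[fi];
          }
        }
      }

      // decay synaptic states after the membrane update
      st_gaba_r[i] *= dec_gaba_r; st_gaba_d[i] *= dec_gaba_d;
      st_ctx_g[i] = st_ctx_g[i] * dec_ctx + st_ctx_y[i] * (dt / ctx_tau) * dec_ctx;
      st_ctx_y[i] *= dec_ctx;

      if (step % decim == 0) {
        for (int k = 0; k < rec_stn.size(); ++k) if (rec_stn[k] == i) {
          tr_stn[(size_t)k * 6 + 0].push_back(stn[i].v);
          tr_stn[(size_t)k * 6 + 1].push_back(g_gaba);
          tr_stn[(size_t)k * 6 + 2].push_back(g_ampa);
          tr_stn[(size_t)k * 6 + 3].push_back(stn[i].gate[8]);
          tr_stn[(size_t)k * 6 + 4].push_back(gt_now);
          tr_stn[(size_t)k * 6 + 5].push_back(stn[i].ca);
        }
      }
    }

    // --- GPe population -----------------------------------------------
    const double p_int = gpe_int_rate * p_scale;
    for (int j = 0; j < n_gpe; ++j) {
      double inc = ring_gampa[(size_t)j * ring + slot];
      ring_gampa[(size_t)j * ring + slot] = 0.0;
      if (inc != 0.0) {
        gp_amp_r[j] += inc * gampa_amp_scale;
        gp_amp_d[j] += inc * gampa_amp_scale;
      }
      if (!gpe_int_deterministic) {
        if (p_int > 0.0 && rng_noise.bernoulli(p_int)) {
          gp_amp_r[j] += a_int * gampa_amp_scale;
          gp_amp_d[j] += a_int * gampa_amp_scale;
        }
      }
      double g = gp_amp_d[j] - gp_amp_r[j];
      if (g < 0.0) g = 0.0;
      if (gpe_int_deterministic) {
        // constant-conductance control: mean of the Poisson-driven kernel
        g += a_int * gampa_amp_scale * (gpe_int_rate * 1e-3) * (gampa_td - gampa_tr);
      }

      bool spiked = false;
      bool active = gpe_refr[j] <= 0.0;
      if (!active) {
        gpe_refr[j] -= dt;
        if (gpe_refr[j] <= 1e-12) { gpe_refr[j] = 0.0; active = true; }
      }
      if (active) {
        double gtot = g_gl + g;
        double vinf = (g_gl * g_vl + g * g_vexc) / gtot;
        gpe_v[j] = vinf + (gpe_v[j] - vinf) * std::exp(-gtot * dt / (1000.0 * g_cm));
        if (!std::isfinite(gpe_v[j]))
          stop("GPe membrane potential diverged at t = %f ms (neuron %d)", t, j);
        if (gpe_v[j] >= g_thr) {
          spiked = true;
          gpe_v[j] = g_reset;
          gpe_refr[j] = g_refr;
        }
      }

      if (spiked) {
        gpe_spk[j].push_back(t);
        for (int pi : eff_gpe[j]) {
          Projection &pr = proj_gs[pi];
          pr.P = dep_decay(pr.P, t - pr.last_t);
          pr.last_t = t;
          int succ;
          if (per_contact) {
            double mu = 1.0 - std::pow(1.0 - pr.P, 1.0 / pr.n_contact);
            succ = rng_rel.binomial(pr.n_contact, mu);
          } else {
            succ = rng_rel.bernoulli(pr.P) ? 1 : 0;
          }
          pr.P = dep_spike(pr.P);
          if (succ > 0) {
            int dslot = (step + pr.delay_steps) % ring;
            ring_gaba[(size_t)pr.tgt * ring + dslot] += succ * a_gaba;
          }
        }
      }

      gp_amp_r[j] *= dec_gampa_r; gp_amp_d[j] *= dec_gampa_d;

      if (step % decim == 0) {
        for (int k = 0; k < rec_gpe.size(); ++k) if (rec_gpe[k] == j) {
          tr_gpe[(size_t)k * 2 + 0].push_back(gpe_v[j]);
          tr_gpe[(size_t)k * 2 + 1].push_back(g);
        }
      }
    }
  }

  // pack results
  List stn_out(n_stn), gpe_out(n_gpe);
  for (int i = 0; i < n_stn; ++i)
    stn_out[i] = NumericVector(stn_spk[i].begin(), stn_spk[i].end());
  for (int j = 0; j < n_gpe; ++j)
    gpe_out[j] = NumericVector(gpe_spk[j].begin(), gpe_spk[j].end());

  List traces = R_NilValue;
  if (rec_stn.size() + rec_gpe.size() > 0) {
    List ts(rec_stn.size()), tg(rec_gpe.size());
    CharacterVector stn_nm = CharacterVector::create("v", "g_gaba", "g_ampa",
                                                     "q", "g_t", "ca");
    for (int k = 0; k < rec_stn.size(); ++k) {
      List one(6);
      for (int c = 0; c < 6; ++c)
        one[c] = NumericVector(tr_stn[(size_t)k * 6 + c].begin(),
                               tr_stn[(size_t)k * 6 + c].end());
      one.attr("names") = stn_nm;
      ts[k] = one;
    }
    for (int k = 0; k < rec_gpe.size(); ++k) {
      List one(2);
      for (int c = 0; c < 2; ++c)
        one[c] = NumericVector(tr_gpe[(size_t)k * 2 + c].begin(),
                               tr_gpe[(size_t)k * 2 + c].end());
      one.attr("names") = CharacterVector::create("v", "g_ampa");
      tg[k] = one;
    }
    traces = List::create(_["stn"] = ts, _["gpe"] = tg);
  }

  return List::create(_["stn_spikes"] = stn_out, _["gpe_spikes"] = gpe_out,
                      _["traces"] = traces);
}
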