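// Compiled episode engine: per-millisecond spiking loop with event-driven
// eligibility-trace plasticity. The dense, per-step semantics that this
// code must reproduce exactly are defined by the pure-R reference
// functions (step_traces / accumulate_dw_* / step_synaptic_currents); see
// the methods vignette for the discretization conventions.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bernoulli(p) over n slots via geometric skipping; fills `hits` with the
// 0-based positions that fired. O(k) RNG draws instead of O(n).
static inline void sample_hits(int n, double p, std::vector<int> &hits) {
  hits.clear();
  if (p <= 0.0) return;
  if (p >= 1.0) { for (int i = 0; i < n; ++i) hits.push_back(i); return; }
  double log1mp = std::log1p(-p);
  double i = -1.0;
  for (;;) {
    double u = unif_rand();
    i += 1.0 + std::floor(std::log(u) / log1mp);
    if (i >= n) break;
    hits.push_back((int)i);
  }
}

// ---------------------------------------------------------------------
// Event-driven integrator for the per-synapse traces kappa (STDP window),
// z (eligibility) and dw (episode weight change), in "critic-sign" form
//   d(dw) = CF z - c V z + V f,   c = (tau_r - tau_z)/(tau_r tau_z),
// with CF z and V f impulsive and V z carrying dt. The actor rule is the
// exact negative and is obtained by negating dw at the end.
//
// Between events every synapse's kappa and z just decay exponentially, so
// per postsynaptic neuron j we keep the running epoch scalars
//   E_j = d_z^(t - t_last_spike(j)),  J_j = sum_k g_k d_z^(k - t_last),
// with g_k = CF_k - c V_k dt, and compose closed epochs lazily per
// synapse. kappa is kept lazily with a last-update step and a decay
// lookup table; it is reset for all synapses of j when j spikes (enforced
// by comparing the last kappa update against j's last spike step).
// ---------------------------------------------------------------------
struct PlasticTracer {
  int n_syn = 0, n_post = 0;
  double dz = 0.0, cc = 0.0, dt = 1.0;
  const int *post_of = nullptr;

  std::vector<double> kappa, z, dw;
  std::vector<int> kappa_last, z_epoch;
  std::vector<char> dirty;
  std::vector<double> E, J;
  std::vector<int> L;
  std::vector<std::vector<int>> dirty_list;
  std::vector<std::vector<double>> e_hist, J_hist;
  std::vector<double> Dk; // Dk[d] = exp(-d dt / tau_kappa)

  void init(int n_syn_, const int *post_of_, int n_post_, double dt_,
            double tau_kappa, double tau_z, double tau_r, int t_cap) {
    n_syn = n_syn_; n_post = n_post_; post_of = post_of_; dt = dt_;
    dz = std::exp(-dt / tau_z);
    cc = (tau_r - tau_z) / (tau_r * tau_z);
    kappa.assign(n_syn, 0.0); z.assign(n_syn, 0.0); dw.assign(n_syn, 0.0);
    kappa_last.assign(n_syn, 0); z_epoch.assign(n_syn, 0);
    dirty.assign(n_syn, 0);
    E.assign(n_post, 1.0); J.assign(n_post, 0.0);
    L.assign(n_post, 0);
    dirty_list.assign(n_post, {});
    e_hist.assign(n_post, {}); J_hist.assign(n_post, {});
    Dk.resize(t_cap + 2);
    double dk = std::exp(-dt / tau_kappa);
    Dk[0] = 1.0;
    for (int d = 1; d < (int)Dk.size(); ++d) Dk[d] = Dk[d - 1] * dk;
  }

  // advance the per-post epoch integrals for step t; g = CF - c V dt
  void step_update(double g) {
    for (int j = 0; j < n_post; ++j) {
      E[j] *= dz;
      J[j] += g * E[j];
    }
  }

  // presynaptic spike on synapse s at (plasticity) step t
  void pre_touch(int s, int t) {
    int j = post_of[s];
    if (kappa_last[s] <= L[j]) kappa[s] = 1.0; // was reset by j's spike
    else kappa[s] = kappa[s] * Dk[t - kappa_last[s]] + 1.0;
    kappa_last[s] = t;
    if (!dirty[s]) { dirty[s] = 1; dirty_list[j].push_back(s); }
  }

  // postsynaptic neuron j spikes at step t (after step_update for t)
  void post_spike(int j, int t, double V, double g) {
    int M = (int)e_hist[j].size();
    for (int s : dirty_list[j]) {
      double f = kappa[s] * Dk[t - kappa_last[s]];
      double acc = 0.0, prod = 1.0;
      const std::vector<double> &eh = e_hist[j], &Jh = J_hist[j];
      for (int m = z_epoch[s]; m < M; ++m) {
        acc += prod * Jh[m];
        prod *= eh[m];
      }
      acc += prod * J[j];
      dw[s] += z[s] * acc + (g + V) * f;
      z[s] = z[s] * prod * E[j] + f;
      z_epoch[s] = M + 1;
      kappa[s] = 0.0; kappa_last[s] = t;
      dirty[s] = 0;
    }
    dirty_list[j].clear();
    e_hist[j].push_back(E[j]);
    J_hist[j].push_back(J[j]);
    E[j] = 1.0; J[j] = 0.0; L[j] = t;
  }

  // flush all synapses to the end of the episode (final step t_end);
  // also advances z and kappa to their final values.
  void finish(int t_end) {
    std::vector<std::vector<double>> S(n_post), P(n_post);
    for (int j = 0; j < n_post; ++j) {
      int M = (int)e_hist[j].size();
      S[j].assign(M + 1, 0.0);
      P[j].assign(M + 1, 0.0);
      S[j][M] = J[j];
      P[j][M] = E[j];
      for (int m = M - 1; m >= 0; --m) {
        S[j][m] = J_hist[j][m] + e_hist[j][m] * S[j][m + 1];
        P[j][m] = e_hist[j][m] * P[j][m + 1];
      }
    }
    for (int s = 0; s < n_syn; ++s) {
      int j = post_of[s];
      if (z[s] != 0.0) {
        dw[s] += z[s] * S[j][z_epoch[s]];
        z[s] *= P[j][z_epoch[s]];
      }
      if (kappa_last[s] <= L[j]) kappa[s] = 0.0; // reset by j's last spike
      else kappa[s] *= Dk[t_end - kappa_last[s]];
    }
  }
};

// Standalone entry: run the event-driven tracer over explicit spike
// trains (unit-test pathway; the episode engine uses the same class).
// [[Rcpp::export]]
List cpp_traces_event(LogicalMatrix pre, LogicalMatrix post_neuron,
                      IntegerVector post_of, NumericVector cf_amp,
                      NumericVector V, double dt, double tau_kappa,
                      double tau_z, double tau_r) {
  int T = pre.nrow(), n = pre.ncol(), m = post_neuron.ncol();
  if (post_neuron.nrow() != T || cf_amp.size() != T || V.size() != T)
    stop("inconsistent fixture dimensions");
  PlasticTracer tr;
  tr.init(n, post_of.begin(), m, dt, tau_kappa, tau_z, tau_r, T);
  double cc = tr.cc;
  for (int t = 1; t <= T; ++t) {
    double g = cf_amp[t - 1] - cc * V[t - 1] * dt;
    tr.step_update(g);
    for (int s = 0; s < n; ++s)
      if (pre(t - 1, s)) tr.pre_touch(s, t);
    for (int j = 0; j < m; ++j)
      if (post_neuron(t - 1, j)) tr.post_spike(j, t, V[t - 1], g);
  }
  tr.finish(T);
  return List::create(_["dw"] = NumericVector(tr.dw.begin(), tr.dw.end()),
                      _["z"] = NumericVector(tr.z.begin(), tr.z.end()),
                      _["kappa"] = NumericVector(tr.kappa.begin(),
                                                 tr.kappa.end()));
}

// ---------------------------------------------------------------------
// Full episode engine
// ---------------------------------------------------------------------

struct Lif {
  int n = 0;
  double Cm, gL, EL, Uth, Ureset, Iext, zeta, tau_noise, d_noise, dt;
  std::vector<double> u, Inoise;
  std::vector<int> spikes; // indices spiking this step

  void init(int n_, const NumericVector &p, double dt_) {
    n = n_; dt = dt_;
    Cm = p[0]; gL = p[1]; EL = p[2]; Uth = p[3]; Ureset = p[4];
    Iext = p[5]; zeta = p[6]; tau_noise = p[7];
    d_noise = std::exp(-dt / tau_noise);
    u.assign(n, EL);
    Inoise.assign(n, 0.0);
    spikes.reserve(n);
  }

  void step(const std::vector<double> &Isyn) {
    spikes.clear();
    for (int i = 0; i < n; ++i) {
      Inoise[i] = Inoise[i] * d_noise +
                  zeta * (2.0 * unif_rand() - 1.0) * dt;
      double du = (-gL * (u[i] - EL) + Isyn[i] + Iext + Inoise[i]) *
                  dt / Cm;
      u[i] += du;
      if (!std::isfinite(u[i]))
        stop("LIF integration blow-up (non-finite membrane potential)");
      if (u[i] >= Uth) { u[i] = Ureset; spikes.push_back(i); }
    }
  }
};

// per-connection-type filtered current: one filter per postsynaptic
// neuron, decayed each step, incremented by the synaptic weight when a
// presynaptic spike arrives (so a spike at step t is felt from t+1 on)
struct CurrentGroup {
  const int *ptr = nullptr;
  const int *post_by_pre = nullptr; // non-plastic
  const int *slot = nullptr;        // plastic: CSR slot -> synapse id
  const int *post_canon = nullptr;  // plastic: canonical posts
  const double *w_syn = nullptr;    // plastic weights (canonical order)
  double w_fix = 1.0, sc = 0.0, decay = 1.0;
  bool plastic = false;
  std::vector<double> Jf;

  void init(const List &g, int n_post, double dt, const double *w_vec) {
    ptr = INTEGER(as<IntegerVector>(g["ptr"]));
    sc = as<double>(g["sc"]);
    decay = std::exp(-dt / as<double>(g["tau_c"]));
    plastic = as<bool>(g["plastic"]);
    if (plastic) {
      slot = INTEGER(as<IntegerVector>(g["slot"]));
      post_canon = INTEGER(as<IntegerVector>(g["post"]));
      w_syn = w_vec;
    } else {
      post_by_pre = INTEGER(as<IntegerVector>(g["post_by_pre"]));
      w_fix = as<double>(g["w"]);
    }
    Jf.assign(n_post, 0.0);
  }

  void decay_step() { for (double &x : Jf) x *= decay; }

  // inject one presynaptic spike; returns nothing. For plastic groups the
  // tracer (if learning) is touched by the caller via visit().
  void inject(int pre) {
    for (int e = ptr[pre]; e < ptr[pre + 1]; ++e) {
      if (plastic) {
        int s = slot[e];
        Jf[post_canon[s]] += w_syn[s];
      } else {
        Jf[post_by_pre[e]] += w_fix;
      }
    }
  }
};

static inline double group_mean(const std::vector<double> &x,
                                const int *grp, int g, int n) {
  double s = 0.0; int c = 0;
  for (int i = 0; i < n; ++i)
    if (grp[i] == g) { s += x[i]; ++c; }
  return c ? s / c : 0.0;
}

// [[Rcpp::export]]
List cpp_run_episode(List net, NumericVector w_pfsc, NumericVector w_pfpc,
                     List task, List ctrl) {
  // ---- unpack ---------------------------------------------------------
  List plane = net["plane"];
  int n_tiles = as<int>(plane["n_tiles"]);
  int npf_tile = as<int>(plane["npf_tile"]);
  NumericVector cx = plane["cx"], cy = plane["cy"];
  double sigma = as<double>(plane["sigma"]);
  double rho_pf = as<double>(plane["rho_pf"]);
  double nx = as<double>(plane["nx"]), ny = as<double>(plane["ny"]);
  double xmin = as<double>(plane["xmin"]), xmax = as<double>(plane["xmax"]);
  double ymin = as<double>(plane["ymin"]), ymax = as<double>(plane["ymax"]);
  double dsx = as<double>(plane["dsx"]), dsy = as<double>(plane["dsy"]);

  int n_sc = as<int>(net["n_sc"]), n_bc = as<int>(net["n_bc"]),
      n_pc = as<int>(net["n_pc"]), n_groups = as<int>(net["n_groups"]);
  IntegerVector pc_group = net["pc_group"];
  List params = net["params"], groups = net["groups"];

  double dt = as<double>(ctrl["dt"]);
  int pre_steps = as<int>(ctrl["pre_steps"]);
  int max_steps = as<int>(ctrl["max_steps"]);
  int post_steps = as<int>(ctrl["post_steps"]);
  bool learn_sc = as<bool>(ctrl["learn_sc"]);
  bool learn_pc = as<bool>(ctrl["learn_pc"]);
  bool record_spikes = as<bool>(ctrl["record_spikes"]);
  double tau_kappa = as<double>(ctrl["tau_kappa"]);
  double tau_z = as<double>(ctrl["tau_z"]);
  double tau_r = as<double>(ctrl["tau_r"]);
  double nu = as<double>(ctrl["nu"]), v0 = as<double>(ctrl["v0"]);
  double dcn_tau = as<double>(ctrl["dcn_tau"]);
  double dcn0 = as<double>(ctrl["dcn_baseline"]);
  double dcn_nu = as<double>(ctrl["dcn_nu"]);

  int type = as<int>(task["type"]); // 0 = mountain car, 1 = eyeblink
  double r_bar = as<double>(task["r_bar"]);
  double cf_amp_val = -r_bar;

  // ---- populations & currents ----------------------------------------
  Lif sc, bc, pc;
  sc.init(n_sc, params["SC"], dt);
  bc.init(n_bc, params["BC"], dt);
  pc.init(n_pc, params["PC"], dt);

  CurrentGroup g_pfsc, g_pfbc, g_pfpc, g_scpc, g_bcbc, g_bcpc, g_pcbc,
      g_pcpc;
  g_pfsc.init(groups["pf_sc"], n_sc, dt, REAL(w_pfsc));
  g_pfbc.init(groups["pf_bc"], n_bc, dt, nullptr);
  g_pfpc.init(groups["pf_pc"], n_pc, dt, REAL(w_pfpc));
  g_scpc.init(groups["sc_pc"], n_pc, dt, nullptr);
  g_bcbc.init(groups["bc_bc"], n_bc, dt, nullptr);
  g_bcpc.init(groups["bc_pc"], n_pc, dt, nullptr);
  g_pcbc.init(groups["pc_bc"], n_bc, dt, nullptr);
  g_pcpc.init(groups["pc_pc"], n_pc, dt, nullptr);

  // activity filter pairs (SC for the critic, PC for DCN drive)
  double sc_tr = as<double>(ctrl["sc_tau_rise"]);
  double sc_td = as<double>(ctrl["sc_tau_decay"]);
  double pc_tr = as<double>(ctrl["pc_tau_rise"]);
  double pc_td = as<double>(ctrl["pc_tau_decay"]);
  double d_scr = std::exp(-dt / sc_tr), d_scd = std::exp(-dt / sc_td);
  double d_pcr = std::exp(-dt / pc_tr), d_pcd = std::exp(-dt / pc_td);
  std::vector<double> scr(n_sc, 0.0), scd(n_sc, 0.0);
  std::vector<double> pcr(n_pc, 0.0), pcd(n_pc, 0.0);
  std::vector<double> pc_act(n_pc, 0.0);
  std::vector<double> dcn(n_pc, dcn0);
  double d_dcn = std::exp(-dt / dcn_tau);

  // plasticity tracers (critic-sign accumulation for both)
  int t_cap = max_steps + post_steps + 2;
  const int *sc_post = INTEGER(as<IntegerVector>(
      as<List>(groups["pf_sc"])["post"]));
  const int *pc_post = INTEGER(as<IntegerVector>(
      as<List>(groups["pf_pc"])["post"]));
  int n_syn_sc = w_pfsc.size(), n_syn_pc = w_pfpc.size();
  PlasticTracer tr_sc, tr_pc;
  if (learn_sc)
    tr_sc.init(n_syn_sc, sc_post, n_sc, dt, tau_kappa, tau_z, tau_r, t_cap);
  if (learn_pc)
    tr_pc.init(n_syn_pc, pc_post, n_pc, dt, tau_kappa, tau_z, tau_r, t_cap);
  double cc = (tau_r - tau_z) / (tau_r * tau_z);

  // CSR of plastic groups for pre-touching on PF spikes
  const int *pfsc_ptr = INTEGER(as<IntegerVector>(
      as<List>(groups["pf_sc"])["ptr"]));
  const int *pfsc_slot = INTEGER(as<IntegerVector>(
      as<List>(groups["pf_sc"])["slot"]));
  const int *pfpc_ptr = INTEGER(as<IntegerVector>(
      as<List>(groups["pf_pc"])["ptr"]));
  const int *pfpc_slot = INTEGER(as<IntegerVector>(
      as<List>(groups["pf_pc"])["slot"]));

  // ---- environment ----------------------------------------------------
  double px = 0, vx = 0, pe = 0;
  double F_bar = 0, grav = 0, p_goal = 0, p_wall = 0, v_max = 0,
         nu_bar = 0, x_lo = 0, x_hi = 0;
  bool literal_cf = false;
  double t_us = 0, cr_thr = 0, close_speed = 0;
  double pe_us = NA_REAL;
  if (type == 0) {
    NumericVector xr = task["x_range"], st = task["start"];
    x_lo = xr[0]; x_hi = xr[1];
    F_bar = as<double>(task["F_bar"]);
    grav = as<double>(task["g"]);
    p_goal = as<double>(task["p_goal"]);
    p_wall = as<double>(task["p_wall"]);
    v_max = as<double>(task["v_max"]);
    nu_bar = as<double>(task["nu_bar"]);
    literal_cf = as<std::string>(task["cf_rate_form"]) == "literal";
    px = st[0]; vx = st[1];
  } else {
    t_us = as<double>(task["t_us"]);
    cr_thr = as<double>(task["cr_threshold"]);
    close_speed = as<double>(task["close_speed"]);
    pe = as<double>(task["pe0"]);
  }

  double obs_x = (type == 0) ? px : 0.0;
  double obs_y = (type == 0) ? vx : pe;

  // ---- records --------------------------------------------------------
  std::vector<double> v_trace, sc_trace;
  std::vector<int> action_trace, cf_steps;
  std::vector<double> traj_x, traj_y;
  std::vector<int> sp_step, sp_id;
  v_trace.reserve(max_steps); sc_trace.reserve(max_steps);
  double first_close = NA_REAL, t_goal = NA_REAL;
  double close_onset = NA_REAL, close_cand = NA_REAL;
  bool success = false, done = false;
  // PC group spike counts in two main-phase windows: [100,300), [400,500) ms
  std::vector<double> win_counts(2 * n_groups, 0.0);

  std::vector<double> Isyn_sc(n_sc), Isyn_bc(n_bc), Isyn_pc(n_pc);
  std::vector<int> tile_hits;
  std::vector<int> pf_spikes;
  pf_spikes.reserve(64);
  double rate_scale = rho_pf / (2.0 * M_PI * sigma * sigma);
  double p_unit = dt / 1000.0;

  int t_pl = 0; // plasticity-phase step counter
  int n_main = 0;

  for (int phase = 1; phase <= 3; ++phase) {
    int steps = (phase == 1) ? pre_steps
                : (phase == 2) ? max_steps : post_steps;
    for (int k = 1; k <= steps; ++k) {
      bool plast = (phase >= 2) && (learn_sc || learn_pc);
      if (phase >= 2) ++t_pl;

      // --- PF sampling (silenced in the post phase) -------------------
      pf_spikes.clear();
      if (phase <= 2) {
        double ox = (obs_x - xmin) / dsx, oy = (obs_y - ymin) / dsy;
        ox = std::min(std::max(ox, 0.0), nx);
        oy = std::min(std::max(oy, 0.0), ny);
        for (int tile = 0; tile < n_tiles; ++tile) {
          double dx = cx[tile] - ox, dy = cy[tile] - oy;
          double rate = rate_scale *
              std::exp(-(dx * dx + dy * dy) / (2.0 * sigma * sigma));
          double p = rate * p_unit;
          if (p * npf_tile < 1e-12) continue;
          if (p > 1.0)
            stop("PF rate * dt exceeds 1; invalid configuration");
          sample_hits(npf_tile, p, tile_hits);
          for (int h : tile_hits)
            pf_spikes.push_back(tile * npf_tile + h);
        }
      }

      // --- plasticity: presynaptic touches (main phase only, since the
      //     post phase has no PF spikes) ------------------------------
      if (phase == 2 && !pf_spikes.empty()) {
        for (int pf : pf_spikes) {
          if (learn_sc)
            for (int e = pfsc_ptr[pf]; e < pfsc_ptr[pf + 1]; ++e)
              tr_sc.pre_touch(pfsc_slot[e], t_pl);
          if (learn_pc)
            for (int e = pfpc_ptr[pf]; e < pfpc_ptr[pf + 1]; ++e)
              tr_pc.pre_touch(pfpc_slot[e], t_pl);
        }
      }

      // --- synaptic currents (spikes up to the previous step) ---------
      g_pfsc.decay_step(); g_pfbc.decay_step(); g_pfpc.decay_step();
      g_scpc.decay_step(); g_bcbc.decay_step(); g_bcpc.decay_step();
      g_pcbc.decay_step(); g_pcpc.decay_step();
      for (int i = 0; i < n_sc; ++i)
        Isyn_sc[i] = g_pfsc.sc * g_pfsc.Jf[i];
      for (int i = 0; i < n_bc; ++i)
        Isyn_bc[i] = g_pfbc.sc * g_pfbc.Jf[i] + g_bcbc.sc * g_bcbc.Jf[i] +
                     g_pcbc.sc * g_pcbc.Jf[i];
      for (int i = 0; i < n_pc; ++i)
        Isyn_pc[i] = g_pfpc.sc * g_pfpc.Jf[i] + g_scpc.sc * g_scpc.Jf[i] +
                     g_bcpc.sc * g_bcpc.Jf[i] + g_pcpc.sc * g_pcpc.Jf[i];

      // --- membranes ---------------------------------------------------
      sc.step(Isyn_sc);
      bc.step(Isyn_bc);
      pc.step(Isyn_pc);

      // --- inject this step's spikes (felt from the next step) --------
      for (int pf : pf_spikes) {
        g_pfsc.inject(pf); g_pfbc.inject(pf); g_pfpc.inject(pf);
      }
      for (int i : sc.spikes) g_scpc.inject(i);
      for (int i : bc.spikes) { g_bcbc.inject(i); g_bcpc.inject(i); }
      for (int i : pc.spikes) { g_pcbc.inject(i); g_pcpc.inject(i); }

      // --- activity filters, value readout, DCN, action ---------------
      for (int i = 0; i < n_sc; ++i) { scr[i] *= d_scr; scd[i] *= d_scd; }
      for (int i : sc.spikes) { scr[i] += 1.0; scd[i] += 1.0; }
      for (int i = 0; i < n_pc; ++i) { pcr[i] *= d_pcr; pcd[i] *= d_pcd; }
      for (int i : pc.spikes) { pcr[i] += 1.0; pcd[i] += 1.0; }
      double sc_sum = 0.0;
      for (int i = 0; i < n_sc; ++i) sc_sum += scd[i] - scr[i];
      double sc_bar = sc_sum / ((sc_td - sc_tr) * n_sc);
      double V = v0 - nu * sc_bar;
      for (int i = 0; i < n_pc; ++i)
        pc_act[i] = (pcd[i] - pcr[i]) / (pc_td - pc_tr);
      for (int i = 0; i < n_pc; ++i) {
        dcn[i] = dcn0 + (dcn[i] - dcn0) * d_dcn - dcn_nu * pc_act[i] * dt;
        if (dcn[i] < 0.0) dcn[i] = 0.0;
      }
      int a_idx = 0;
      {
        double best = -1.0;
        for (int g = 0; g < n_groups; ++g) {
          double h = group_mean(dcn, INTEGER(pc_group), g, n_pc);
          if (h > best) { best = h; a_idx = g; }
        }
      }
      double a_val = (a_idx == 0) ? -1.0 : 1.0;

      // --- environment & climbing fiber (main phase only) -------------
      bool cf_spike = false;
      if (phase == 2) {
        if (type == 0) {
          vx += (F_bar * a_val - grav * std::cos(3.0 * px)) * dt;
          vx = std::min(std::max(vx, -v_max), v_max);
          px += vx * dt;
          if (px <= x_lo) { px = x_lo; vx = 0.0; }
          if (px >= x_hi) px = x_hi;
          if (px >= p_goal) {
            done = true; success = true; t_goal = k * dt;
          }
          double dfrac = (p_goal - px) / (p_goal - p_wall);
          double dterm = literal_cf ? (1.0 - dfrac) : dfrac;
          double rate = nu_bar * dterm * (1.0 - std::fabs(vx) / v_max);
          rate = std::min(std::max(rate, 0.0), nu_bar);
          cf_spike = unif_rand() < rate * p_unit;
          obs_x = px; obs_y = vx;
        } else {
          double pe_prev = pe;
          pe += close_speed * a_val * dt;
          pe = std::min(std::max(pe, 0.0), 1.0);
          // onset of the (latest) closed stretch before the US
          if (pe_prev > cr_thr && pe <= cr_thr && k * dt <= t_us)
            close_cand = k * dt;
          if (ISNA(pe_us) && k * dt >= t_us) {
            pe_us = pe;
            success = pe_us <= cr_thr;
            cf_spike = pe_us > cr_thr;
            if (success) close_onset = close_cand;
          }
          if (ISNA(first_close) && pe <= cr_thr) first_close = k * dt;
          obs_x = k * dt; obs_y = pe;
          if (k == steps) done = true;
        }
      }

      // --- plasticity epoch integrals and postsynaptic events ---------
      if (plast) {
        double g = (cf_spike ? cf_amp_val : 0.0) - cc * V * dt;
        if (learn_sc) {
          tr_sc.step_update(g);
          for (int j : sc.spikes) tr_sc.post_spike(j, t_pl, V, g);
        }
        if (learn_pc) {
          tr_pc.step_update(g);
          for (int j : pc.spikes) tr_pc.post_spike(j, t_pl, V, g);
        }
      }

      // --- records -----------------------------------------------------
      if (phase == 2) {
        ++n_main;
        v_trace.push_back(V);
        sc_trace.push_back(sc_bar);
        action_trace.push_back(a_idx + 1);
        traj_x.push_back(obs_x); traj_y.push_back(obs_y);
        if (cf_spike) cf_steps.push_back(k);
        double t_ms = k * dt;
        int win = (t_ms >= 100.0 && t_ms < 300.0) ? 0
                  : (t_ms >= 400.0 && t_ms < 500.0) ? 1 : -1;
        if (win >= 0)
          for (int i : pc.spikes) win_counts[win * n_groups + pc_group[i]] += 1.0;
        if (record_spikes) {
          for (int i : sc.spikes) { sp_step.push_back(k); sp_id.push_back(i); }
          for (int i : bc.spikes) { sp_step.push_back(k); sp_id.push_back(n_sc + i); }
          for (int i : pc.spikes) { sp_step.push_back(k); sp_id.push_back(n_sc + n_bc + i); }
        }
        if (done) break;
      }
    }
  }

  // ---- finalize plasticity -------------------------------------------
  NumericVector dw_sc_out(n_syn_sc), dw_pc_out(n_syn_pc);
  if (learn_sc) {
    tr_sc.finish(t_pl);
    std::copy(tr_sc.dw.begin(), tr_sc.dw.end(), dw_sc_out.begin());
  }
  if (learn_pc) {
    tr_pc.finish(t_pl);
    // the actor rule is the exact sign-flip of the critic rule
    for (int s = 0; s < n_syn_pc; ++s) dw_pc_out[s] = -tr_pc.dw[s];
  }

  // per-neuron rates (Hz) of the PC groups in the two windows
  NumericMatrix win_rates(n_groups, 2);
  int per_group = n_pc / n_groups;
  double w0_dur = 0.200, w1_dur = 0.100; // seconds
  for (int g = 0; g < n_groups; ++g) {
    win_rates(g, 0) = win_counts[g] / (per_group * w0_dur);
    win_rates(g, 1) = win_counts[n_groups + g] / (per_group * w1_dur);
  }

  NumericMatrix traj(n_main, 2);
  for (int i = 0; i < n_main; ++i) {
    traj(i, 0) = traj_x[i];
    traj(i, 1) = traj_y[i];
  }

  List out = List::create(
      _["success"] = success,
      _["n_main"] = n_main,
      _["dw_pfsc"] = dw_sc_out,
      _["dw_pfpc"] = dw_pc_out,
      _["v"] = NumericVector(v_trace.begin(), v_trace.end()),
      _["sc_activity"] = NumericVector(sc_trace.begin(), sc_trace.end()),
      _["action"] = IntegerVector(action_trace.begin(), action_trace.end()),
      _["traj"] = traj,
      _["cf_steps"] = IntegerVector(cf_steps.begin(), cf_steps.end()),
      _["pc_window_rates"] = win_rates,
      _["t_goal"] = t_goal,
      _["pe_us"] = pe_us,
      _["first_close"] = first_close,
      _["close_onset"] = close_onset);
  if (record_spikes) {
    IntegerMatrix spk(sp_step.size(), 2);
    for (int i = 0; i < (int)sp_step.size(); ++i) {
      spk(i, 0) = sp_step[i];
      spk(i, 1) = sp_id[i];
    }
    out["spikes"] = spk;
  }
  return out;
}
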