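// Batch simulator for coupled Potts attractor networks.
//
// Layout conventions (all 0-based internally):
//  - state arrays are trial-contiguous: sig[(i*S + k)*T + t] for unit i,
//    active state k, trial t; sig0[i*T + t] for the quiescent component.
//  - weight tensors are stored per (post unit, input slot) as S x S blocks
//    with the PRE state l as the major index:
//    J[((i*Cm + c)*S + l)*S + k] multiplies sig_pre[(adj(i,c)*S + l)*T + t]
//    and accumulates into h[(i*S + k)*T + t].
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

#if defined(__x86_64__) && defined(__GNUC__) && !defined(__clang__)
#define HOT_CLONES __attribute__((target_clones("avx2,fma", "default")))
#else
#define HOT_CLONES
#endif

// h += J * sig_pre over the diluted adjacency (restricted, hot kernel)
HOT_CLONES
static void accumulate_field(double *__restrict__ h,
                             const double *__restrict__ sig_pre,
                             const double *__restrict__ J,
                             const int *__restrict__ adj, int N, int Cm,
                             int S, int T) {
  for (int i = 0; i < N; ++i) {
    double *hb = h + (size_t)i * S * T;
    for (int c = 0; c < Cm; ++c) {
      const int j = adj[(size_t)i * Cm + c];
      const double *Jb = J + ((size_t)i * Cm + c) * S * S;
      const double *sj = sig_pre + (size_t)j * S * T;
      for (int l = 0; l < S; ++l) {
        const double *sl = sj + (size_t)l * T;
        for (int k = 0; k < S; ++k) {
          const double jv = Jb[(size_t)l * S + k];
          double *hk = hb + (size_t)k * T;
          for (int t = 0; t < T; ++t) hk[t] += jv * sl[t];
        }
      }
    }
  }
}

struct Net {
  int N, S, Cm;
  double a, w, beta, U, tau1, tauA, tauB, gA, dt, tauU;
  bool dyn_enabled;
  std::vector<int> adj;          // N*Cm, 0-based pre indices
  std::vector<double> J;         // N*Cm*S*S
  std::vector<double> tau2f, tau2s, g2f; // N*S (unit-state maps)
  std::vector<double> kick;      // N*S threshold kick (may be empty)
  std::vector<int> dyn_scope;    // per unit, 1..n_scopes (0 = none)
  std::vector<double> dyn_norm;  // per scope: a * N_scope
  int n_scopes;
  // hetero input (buffer only)
  bool has_het;
  int Cm_het;
  std::vector<int> het_adj;
  std::vector<double> het_J;
  // state (allocated at run time)
  std::vector<double> sig, sig0, r, thf, ths, thA, thB, h, Uhat;
};

static std::vector<double> expand_map(SEXP x, int N, int S) {
  NumericVector v(x);
  std::vector<double> out((size_t)N * S);
  if (v.size() == 1) {
    std::fill(out.begin(), out.end(), v[0]);
  } else if (v.size() == (R_xlen_t)N * S) {
    // R matrix N x S, column-major: entry (i,k) at i + k*N -> out[i*S+k]
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < S; ++k) out[(size_t)i * S + k] = v[i + (size_t)k * N];
  } else {
    stop("per-unit-state map has wrong length");
  }
  return out;
}

static Net parse_net(List nl) {
  Net n;
  n.N = as<int>(nl["N"]);
  n.S = as<int>(nl["S"]);
  n.a = as<double>(nl["a"]);
  n.w = as<double>(nl["w"]);
  n.beta = as<double>(nl["beta"]);
  n.U = as<double>(nl["U"]);
  n.tau1 = as<double>(nl["tau1"]);
  n.tauA = as<double>(nl["tau_A"]);
  n.tauB = as<double>(nl["tau_B"]);
  n.gA = as<double>(nl["gamma_A"]);
  n.dt = as<double>(nl["dt"]);
  n.tauU = as<double>(nl["tau_U"]);
  IntegerMatrix adj = nl["adj"]; // N x Cm, 1-based
  n.Cm = adj.ncol();
  n.adj.resize((size_t)n.N * n.Cm);
  for (int i = 0; i < n.N; ++i)
    for (int c = 0; c < n.Cm; ++c) n.adj[(size_t)i * n.Cm + c] = adj(i, c) - 1;
  NumericVector J = nl["J"];
  if ((R_xlen_t)J.size() != (R_xlen_t)n.N * n.Cm * n.S * n.S)
    stop("autoassociative weight vector has wrong length");
  n.J.assign(J.begin(), J.end());
  n.tau2f = expand_map(nl["tau2_fast"], n.N, n.S);
  n.tau2s = expand_map(nl["tau2_slow"], n.N, n.S);
  n.g2f = expand_map(nl["gamma2_fast"], n.N, n.S);
  if (nl.containsElementNamed("kick") && !Rf_isNull(nl["kick"]))
    n.kick = expand_map(nl["kick"], n.N, n.S);
  n.dyn_enabled = as<bool>(nl["dynamic_threshold"]);
  n.n_scopes = 0;
  if (n.dyn_enabled) {
    IntegerVector sc = nl["dyn_scope"];
    NumericVector nm = nl["dyn_norm"];
    n.dyn_scope.assign(sc.begin(), sc.end());
    n.dyn_norm.assign(nm.begin(), nm.end());
    n.n_scopes = nm.size();
  }
  n.has_het = nl.containsElementNamed("het") && !Rf_isNull(nl["het"]);
  if (n.has_het) {
    List het = nl["het"];
    IntegerMatrix ha = het["adj"];
    n.Cm_het = ha.ncol();
    n.het_adj.resize((size_t)n.N * n.Cm_het);
    for (int i = 0; i < n.N; ++i)
      for (int c = 0; c < n.Cm_het; ++c)
        n.het_adj[(size_t)i * n.Cm_het + c] = ha(i, c) - 1;
    NumericVector hJ = het["J"];
    n.het_J.assign(hJ.begin(), hJ.end());
  }
  return n;
}

static void init_state(Net &n, int T, double eps) {
  size_t ns = (size_t)n.N * n.S * T, n1 = (size_t)n.N * T;
  n.sig.assign(ns, eps / n.S);
  n.sig0.assign(n1, 1.0 - eps);
  // r consistent with the near-null activations under the softmax at theta=0,
  // so the network actually starts from the global null state
  const double r0 = n.U + std::log(eps / n.S / (1.0 - eps)) / n.beta;
  n.r.assign(ns, r0);
  n.thf.assign(ns, 0.0);
  n.ths.assign(ns, 0.0);
  n.thA.assign(n1, 0.0);
  n.thB.assign(n1, 0.0);
  n.h.assign(ns, 0.0);
  n.Uhat.assign((size_t)std::max(n.n_scopes, 1) * T, 0.0);
}

// local feedback term: h += w * (sig - mean_l sig)
HOT_CLONES
static void add_feedback(Net &n, int T) {
  const double w = n.w, invS = 1.0 / n.S;
  std::vector<double> mean(T);
  for (int i = 0; i < n.N; ++i) {
    double *sb = n.sig.data() + (size_t)i * n.S * T;
    std::fill(mean.begin(), mean.end(), 0.0);
    for (int k = 0; k < n.S; ++k)
      for (int t = 0; t < T; ++t) mean[t] += sb[(size_t)k * T + t];
    double *hb = n.h.data() + (size_t)i * n.S * T;
    for (int k = 0; k < n.S; ++k)
      for (int t = 0; t < T; ++t)
        hb[(size_t)k * T + t] += w * (sb[(size_t)k * T + t] - invS * mean[t]);
  }
}

// one Euler update of r and thresholds, then softmax refresh of sig
HOT_CLONES
static void update_net(Net &n, int T) {
  const int S = n.S;
  const double dt = n.dt;
  const double c1 = dt / n.tau1, cA = dt / n.tauA, cB = dt / n.tauB;
  const bool has_kick = !n.kick.empty();
  for (int i = 0; i < n.N; ++i) {
    const size_t ib = (size_t)i * S * T;
    for (int k = 0; k < S; ++k) {
      const size_t kb = ib + (size_t)k * T;
      const double c2f = dt / n.tau2f[(size_t)i * S + k];
      const double c2s = dt / n.tau2s[(size_t)i * S + k];
      const double gf = n.g2f[(size_t)i * S + k];
      const double kik = has_kick ? n.kick[(size_t)i * S + k] : 0.0;
      double *rk = n.r.data() + kb, *tf = n.thf.data() + kb,
             *ts = n.ths.data() + kb;
      const double *hk = n.h.data() + kb, *sk = n.sig.data() + kb;
      for (int t = 0; t < T; ++t) {
        rk[t] += c1 * (hk[t] - tf[t] - ts[t] - rk[t]);
        tf[t] += c2f * (gf * sk[t] - kik - tf[t]);
        ts[t] += c2s * ((1.0 - gf) * sk[t] - ts[t]);
      }
    }
    double *tA = n.thA.data() + (size_t)i * T, *tB = n.thB.data() + (size_t)i * T;
    for (int t = 0; t < T; ++t) {
      double stot = 0.0;
      for (int k = 0; k < S; ++k) stot += n.sig[ib + (size_t)k * T + t];
      tA[t] += cA * (n.gA * stot - tA[t]);
      tB[t] += cB * ((1.0 - n.gA) * stot - tB[t]);
    }
  }
  // dynamic threshold component(s)
  if (n.dyn_enabled) {
    const double cU = dt / n.tauU;
    std::vector<double> act((size_t)n.n_scopes * T, 0.0);
    for (int i = 0; i < n.N; ++i) {
      int s = n.dyn_scope[i];
      if (s <= 0) continue;
      const double *s0 = n.sig0.data() + (size_t)i * T;
      double *as = act.data() + (size_t)(s - 1) * T;
      for (int t = 0; t < T; ++t) as[t] += 1.0 - s0[t];
    }
    for (int s = 0; s < n.n_scopes; ++s) {
      const double inv = 1.0 / n.dyn_norm[s];
      double *us = n.Uhat.data() + (size_t)s * T;
      const double *as = act.data() + (size_t)s * T;
      for (int t = 0; t < T; ++t) us[t] += cU * (inv * as[t] - us[t]);
    }
  }
  // softmax refresh (max-subtraction stabilized)
  const double beta = n.beta;
  for (int i = 0; i < n.N; ++i) {
    const size_t ib = (size_t)i * S * T;
    const int sc = n.dyn_enabled ? n.dyn_scope[i] : 0;
    const double *us =
        (n.dyn_enabled && sc > 0) ? n.Uhat.data() + (size_t)(sc - 1) * T : NULL;
    for (int t = 0; t < T; ++t) {
      const double Ueff = n.U + (us ? us[t] : 0.0);
      const double q =
          beta * (n.thA[(size_t)i * T + t] + n.thB[(size_t)i * T + t] + Ueff);
      double m = q;
      for (int k = 0; k < S; ++k)
        m = std::max(m, beta * n.r[ib + (size_t)k * T + t]);
      // arguments clamped at -40: exp(-40) ~ 4e-18 is negligible against the
      // leading term (which is exp(0) after max-subtraction), and the clamp
      // keeps libm away from underflow slow paths
      double denom = std::exp(std::max(q - m, -40.0));
      const double e0 = denom;
      double ek[32];
      for (int k = 0; k < S; ++k) {
        ek[k] = std::exp(std::max(beta * n.r[ib + (size_t)k * T + t] - m, -40.0));
        denom += ek[k];
      }
      for (int k = 0; k < S; ++k) n.sig[ib + (size_t)k * T + t] = ek[k] / denom;
      n.sig0[(size_t)i * T + t] = e0 / denom;
    }
  }
}

struct PatternIndex {
  // per pattern: active units and their states, plus overlap normalization
  std::vector<std::vector<int>> unit, state;
  std::vector<double> norm, abar;
  std::vector<int> scope; // 0 = whole network, else cluster id (1-based)
};

static PatternIndex index_patterns(const IntegerMatrix &xi,
                                   const NumericVector &norm,
                                   const NumericVector &abar,
                                   const IntegerVector &scope) {
  PatternIndex px;
  int p = xi.nrow(), N = xi.ncol();
  px.unit.resize(p);
  px.state.resize(p);
  px.norm.assign(norm.begin(), norm.end());
  px.abar.assign(abar.begin(), abar.end());
  px.scope.assign(scope.begin(), scope.end());
  for (int m = 0; m < p; ++m)
    for (int i = 0; i < N; ++i)
      if (xi(m, i) > 0) {
        px.unit[m].push_back(i);
        px.state[m].push_back(xi(m, i) - 1);
      }
  return px;
}

// overlaps of all indexed patterns for every trial at the current step
static void record_overlaps(const Net &n, const PatternIndex &px,
                            const std::vector<int> &cluster_of_unit,
                            int n_clusters, int T, double *out) {
  const int S = n.S;
  // total active-state mass, globally and per cluster
  std::vector<double> tot_g(T, 0.0), tot_c((size_t)std::max(n_clusters, 1) * T, 0.0);
  for (int i = 0; i < n.N; ++i) {
    const double *sb = n.sig.data() + (size_t)i * S * T;
    const int cl = cluster_of_unit.empty() ? 0 : cluster_of_unit[i];
    for (int k = 0; k < S; ++k)
      for (int t = 0; t < T; ++t) {
        const double v = sb[(size_t)k * T + t];
        tot_g[t] += v;
        if (cl > 0) tot_c[(size_t)(cl - 1) * T + t] += v;
      }
  }
  const int p = px.unit.size();
  for (int m = 0; m < p; ++m) {
    const double *tot =
        px.scope[m] > 0 ? tot_c.data() + (size_t)(px.scope[m] - 1) * T
                        : tot_g.data();
    double *om = out + (size_t)m * T;
    for (int t = 0; t < T; ++t) om[t] = 0.0;
    const size_t nu = px.unit[m].size();
    for (size_t uu = 0; uu < nu; ++uu) {
      const double *sr =
          n.sig.data() + ((size_t)px.unit[m][uu] * S + px.state[m][uu]) * T;
      for (int t = 0; t < T; ++t) om[t] += sr[t];
    }
    for (int t = 0; t < T; ++t)
      om[t] = px.norm[m] * (om[t] - px.abar[m] * tot[t]);
  }
}

// [[Rcpp::export]]
List simulate_potts_batch_cpp(List buffer, SEXP source_, List cue_schedule,
                              IntegerMatrix xi_buf, List buf_measure,
                              SEXP xi_src_, List control) {
  Net pob = parse_net(buffer);
  bool has_src = !Rf_isNull(source_);
  Net pol;
  if (has_src) pol = parse_net(source_);
  if (pob.has_het && !has_src) stop("hetero weights given but no source network");

  const int T = as<int>(control["n_trials"]);
  const int T_max = as<int>(control["T_max"]);
  const int every = as<int>(control["record_every"]);
  const bool early_stop = as<bool>(control["early_stop"]);
  const double stop_level = as<double>(control["stop_level"]);
  const int stop_after = as<int>(control["stop_after"]);
  const int stop_window = as<int>(control["stop_window"]);
  const double eps = as<double>(control["init_eps"]);

  // cue schedule: one row per cue event
  IntegerVector cue_trial = cue_schedule["trial"];     // 1-based
  IntegerVector cue_pattern = cue_schedule["pattern"]; // 1-based row of cue xi
  IntegerVector cue_onset = cue_schedule["onset"];
  IntegerVector cue_dur = cue_schedule["duration"];
  NumericVector cue_strength = cue_schedule["strength"];
  const bool cue_on_source = has_src;
  IntegerMatrix xi_cue = cue_on_source ? IntegerMatrix(xi_src_) : xi_buf;

  // buffer overlap bookkeeping
  NumericVector m_norm = buf_measure["norm"], m_abar = buf_measure["abar"];
  IntegerVector m_scope = buf_measure["scope"];
  IntegerVector cl_unit = buf_measure["cluster_of_unit"]; // length N, 0 = none
  const int n_clusters = as<int>(buf_measure["n_clusters"]);
  PatternIndex px = index_patterns(xi_buf, m_norm, m_abar, m_scope);
  std::vector<int> cluster_of_unit(cl_unit.begin(), cl_unit.end());

  // watched buffer patterns (activity measures), per trial
  IntegerMatrix watch = buf_measure["watch"]; // n_watch x T, 0 = none
  const int n_watch = watch.nrow();
  // watched source patterns (overlap of cued items), per trial
  IntegerMatrix src_watch =
      has_src ? IntegerMatrix(as<IntegerMatrix>(buf_measure["src_watch"]))
              : IntegerMatrix(0, 0);
  const int n_src_watch = src_watch.nrow();
  PatternIndex spx;
  if (has_src && n_src_watch > 0) {
    IntegerMatrix xs(xi_src_);
    const int p_src = xs.nrow();
    NumericVector nn(p_src), ab(p_src);
    IntegerVector scc(p_src);
    const double norm = 1.0 / (pol.N * pol.a * (1.0 - pol.a / pol.S));
    for (int m = 0; m < p_src; ++m) {
      nn[m] = norm;
      ab[m] = pol.a / pol.S;
      scc[m] = 0;
    }
    spx = index_patterns(xs, nn, ab, scc);
  }

  const int n_rec = (T_max + every - 1) / every;
  const int p_buf = xi_buf.nrow();
  NumericVector rec_buf((R_xlen_t)p_buf * n_rec * T);
  NumericVector rec_src((R_xlen_t)std::max(n_src_watch, 0) * n_rec * T);
  NumericVector rec_act((R_xlen_t)n_watch * n_rec * T);
  NumericVector rec_wr((R_xlen_t)n_watch * n_rec * T);
  NumericVector rec_wth((R_xlen_t)n_watch * n_rec * T);
  const int n_scope_rec = pob.dyn_enabled ? pob.n_scopes : 0;
  NumericVector rec_uhat((R_xlen_t)n_scope_rec * n_rec * T);
  const int n_pairs = n_watch >= 2 ? n_watch * (n_watch - 1) / 2 : 0;
  NumericVector rec_shared((R_xlen_t)n_pairs * n_rec * T);
  IntegerVector rec_t(n_rec);

  // shared-support lists per trial for watched pattern pairs
  std::vector<std::vector<std::vector<int>>> shared(T);
  if (n_pairs > 0) {
    for (int t = 0; t < T; ++t) {
      for (int u = 0; u < n_watch; ++u)
        for (int v = u + 1; v < n_watch; ++v) {
          std::vector<int> sh;
          int pu = watch(u, t), pv = watch(v, t);
          if (pu > 0 && pv > 0) {
            for (int i = 0; i < pob.N; ++i)
              if (xi_buf(pu - 1, i) > 0 && xi_buf(pv - 1, i) > 0)
                sh.push_back(i);
          }
          shared[t].push_back(sh);
        }
    }
  }

  init_state(pob, T, eps);
  if (has_src) init_state(pol, T, eps);

  std::vector<double> scratch((size_t)p_buf * T);
  std::vector<double> s_scratch((size_t)std::max(n_src_watch, 1) * T);
  int quiet_rec = 0, steps_run = 0, rec_i = 0;

  for (int step = 0; step < T_max; ++step) {
    // fields from the current activations
    std::fill(pob.h.begin(), pob.h.end(), 0.0);
    accumulate_field(pob.h.data(), pob.sig.data(), pob.J.data(),
                     pob.adj.data(), pob.N, pob.Cm, pob.S, T);
    add_feedback(pob, T);
    if (has_src) {
      std::fill(pol.h.begin(), pol.h.end(), 0.0);
      accumulate_field(pol.h.data(), pol.sig.data(), pol.J.data(),
                       pol.adj.data(), pol.N, pol.Cm, pol.S, T);
      add_feedback(pol, T);
      if (pob.has_het)
        accumulate_field(pob.h.data(), pol.sig.data(), pob.het_J.data(),
                         pob.het_adj.data(), pob.N, pob.Cm_het, pob.S, T);
    }
    // external cue fields
    Net &cue_net = cue_on_source ? pol : pob;
    for (int e = 0; e < cue_trial.size(); ++e) {
      if (step < cue_onset[e] || step >= cue_onset[e] + cue_dur[e]) continue;
      const int tr = cue_trial[e] - 1, pm = cue_pattern[e] - 1;
      const double st = cue_strength[e];
      for (int i = 0; i < cue_net.N; ++i) {
        const int k0 = xi_cue(pm, i);
        if (k0 > 0) cue_net.h[((size_t)i * cue_net.S + (k0 - 1)) * T + tr] += st;
      }
    }
    update_net(pob, T);
    if (has_src) update_net(pol, T);
    steps_run = step + 1;

    if ((step + 1) % every == 0 || step == T_max - 1) {
      record_overlaps(pob, px, cluster_of_unit, n_clusters, T, scratch.data());
      double mx = 0.0;
      for (size_t z = 0; z < scratch.size(); ++z) mx = std::max(mx, scratch[z]);
      for (int m = 0; m < p_buf; ++m)
        for (int t = 0; t < T; ++t)
          rec_buf[((R_xlen_t)m * n_rec + rec_i) * T + t] = scratch[(size_t)m * T + t];
      if (has_src && n_src_watch > 0) {
        // overlap of each watched source pattern, per trial
        for (int uw = 0; uw < n_src_watch; ++uw)
          for (int t = 0; t < T; ++t) {
            const int pm = src_watch(uw, t);
            double o = 0.0;
            if (pm > 0) {
              const size_t nu = spx.unit[pm - 1].size();
              double tot = 0.0;
              for (int i = 0; i < pol.N; ++i)
                for (int k = 0; k < pol.S; ++k)
                  tot += pol.sig[((size_t)i * pol.S + k) * T + t];
              for (size_t uu = 0; uu < nu; ++uu)
                o += pol.sig[((size_t)spx.unit[pm - 1][uu] * pol.S +
                              spx.state[pm - 1][uu]) * T + t];
              o = spx.norm[pm - 1] * (o - spx.abar[pm - 1] * tot);
            }
            rec_src[((R_xlen_t)uw * n_rec + rec_i) * T + t] = o;
            mx = std::max(mx, o);
          }
      }
      for (int uw = 0; uw < n_watch; ++uw)
        for (int t = 0; t < T; ++t) {
          const int pm = watch(uw, t);
          double v = 0.0, vr = 0.0, vth = 0.0;
          if (pm > 0) {
            const std::vector<int> &un = px.unit[pm - 1];
            const std::vector<int> &st = px.state[pm - 1];
            for (size_t uu = 0; uu < un.size(); ++uu) {
              v += 1.0 - pob.sig0[(size_t)un[uu] * T + t];
              const size_t ik = ((size_t)un[uu] * pob.S + st[uu]) * T + t;
              vr += pob.r[ik];
              vth += pob.thf[ik] + pob.ths[ik];
            }
            v /= un.size();
            vr /= un.size();
            vth /= un.size();
          }
          rec_act[((R_xlen_t)uw * n_rec + rec_i) * T + t] = v;
          rec_wr[((R_xlen_t)uw * n_rec + rec_i) * T + t] = vr;
          rec_wth[((R_xlen_t)uw * n_rec + rec_i) * T + t] = vth;
        }
      for (int pr = 0; pr < n_pairs; ++pr)
        for (int t = 0; t < T; ++t) {
          const std::vector<int> &sh = shared[t][pr];
          double v = 0.0;
          if (!sh.empty()) {
            for (size_t uu = 0; uu < sh.size(); ++uu)
              v += 1.0 - pob.sig0[(size_t)sh[uu] * T + t];
            v /= sh.size();
          }
          rec_shared[((R_xlen_t)pr * n_rec + rec_i) * T + t] = v;
        }
      for (int s = 0; s < n_scope_rec; ++s)
        for (int t = 0; t < T; ++t)
          rec_uhat[((R_xlen_t)s * n_rec + rec_i) * T + t] =
              pob.Uhat[(size_t)s * T + t];
      rec_t[rec_i] = step + 1;
      ++rec_i;
      if (early_stop) {
        quiet_rec = (mx < stop_level) ? quiet_rec + 1 : 0;
        if (step + 1 >= stop_after && quiet_rec >= stop_window) break;
      }
    }
  }

  auto final_state = [&](Net &n) {
    return List::create(
        _["sigma"] = NumericVector(n.sig.begin(), n.sig.end()),
        _["sigma0"] = NumericVector(n.sig0.begin(), n.sig0.end()),
        _["r"] = NumericVector(n.r.begin(), n.r.end()),
        _["theta_fast"] = NumericVector(n.thf.begin(), n.thf.end()),
        _["theta_slow"] = NumericVector(n.ths.begin(), n.ths.end()),
        _["theta_A"] = NumericVector(n.thA.begin(), n.thA.end()),
        _["theta_B"] = NumericVector(n.thB.begin(), n.thB.end()),
        _["U_hat"] = NumericVector(n.Uhat.begin(), n.Uhat.end()));
  };

  List out = List::create(
      _["overlap_buffer"] = rec_buf, _["overlap_source"] = rec_src,
      _["watch_activity"] = rec_act, _["watch_shared"] = rec_shared,
      _["u_hat"] = rec_uhat, _["watch_r"] = rec_wr, _["watch_theta"] = rec_wth,
      _["t_rec"] = rec_t, _["n_rec_used"] = rec_i, _["steps_run"] = steps_run,
      _["dims"] = IntegerVector::create(p_buf, n_rec, T),
      _["final_buffer"] = final_state(pob));
  if (has_src) out["final_source"] = final_state(pol);
  return out;
}

// Autoassociative tensor weights (covariance rule) on a diluted adjacency.
// [[Rcpp::export]]
NumericVector build_auto_weights_cpp(IntegerMatrix adj, IntegerMatrix xi,
                                     double a, int S, double Cm_norm) {
  const int N = adj.nrow(), Cm = adj.ncol(), p = xi.nrow();
  const double abar = a / S;
  const double norm = 1.0 / (Cm_norm * a * (1.0 - abar));
  // n_k(i): number of patterns with xi_i = k
  std::vector<int> nk((size_t)N * S, 0);
  for (int m = 0; m < p; ++m)
    for (int i = 0; i < N; ++i)
      if (xi(m, i) > 0) ++nk[(size_t)i * S + (xi(m, i) - 1)];
  NumericVector out((R_xlen_t)N * Cm * S * S);
  std::vector<int> xcol((size_t)p * N);
  for (int m = 0; m < p; ++m)
    for (int i = 0; i < N; ++i) xcol[(size_t)i * p + m] = xi(m, i);
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < Cm; ++c) {
      const int j = adj(i, c) - 1;
      double *blk = REAL(out) + ((R_xlen_t)i * Cm + c) * S * S;
      // layout: blk[l*S + k]
      for (int l = 0; l < S; ++l)
        for (int k = 0; k < S; ++k)
          blk[(size_t)l * S + k] =
              abar * abar * p - abar * nk[(size_t)i * S + k] -
              abar * nk[(size_t)j * S + l];
      const int *xi_i = xcol.data() + (size_t)i * p;
      const int *xi_j = xcol.data() + (size_t)j * p;
      for (int m = 0; m < p; ++m)
        if (xi_i[m] > 0 && xi_j[m] > 0)
          blk[(size_t)(xi_j[m] - 1) * S + (xi_i[m] - 1)] += 1.0;
      for (int z = 0; z < S * S; ++z) blk[z] *= norm;
    }
  }
  return out;
}

// Heteroassociative weights from a list of (source pattern, target pattern,
// weight) associations; the weight carries G * lambda.
// [[Rcpp::export]]
NumericVector build_hetero_weights_cpp(IntegerMatrix adj, IntegerMatrix xi_post,
                                       IntegerMatrix xi_pre, IntegerVector mu,
                                       IntegerVector nu, NumericVector g,
                                       double a, int S, double Cm_norm) {
  const int N = adj.nrow(), Cm = adj.ncol(), Npre = xi_post.ncol() * 0 + xi_pre.ncol();
  const int ne = mu.size();
  const double abar = a / S;
  const double norm = 1.0 / (Cm_norm * a * (1.0 - abar));
  // B_i[k] = sum_e g_e delta(xi_post[nu_e, i] = k); A_j[l] likewise on pre side
  std::vector<double> B((size_t)N * S, 0.0), A((size_t)Npre * S, 0.0);
  double gtot = 0.0;
  for (int e = 0; e < ne; ++e) {
    gtot += g[e];
    for (int i = 0; i < N; ++i) {
      int k0 = xi_post(nu[e] - 1, i);
      if (k0 > 0) B[(size_t)i * S + (k0 - 1)] += g[e];
    }
    for (int j = 0; j < Npre; ++j) {
      int l0 = xi_pre(mu[e] - 1, j);
      if (l0 > 0) A[(size_t)j * S + (l0 - 1)] += g[e];
    }
  }
  // per-event state lookups, column-wise for cache friendliness
  std::vector<int> xpost((size_t)N * ne), xpre((size_t)Npre * ne);
  for (int e = 0; e < ne; ++e) {
    for (int i = 0; i < N; ++i) xpost[(size_t)i * ne + e] = xi_post(nu[e] - 1, i);
    for (int j = 0; j < Npre; ++j) xpre[(size_t)j * ne + e] = xi_pre(mu[e] - 1, j);
  }
  NumericVector out((R_xlen_t)N * Cm * S * S);
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < Cm; ++c) {
      const int j = adj(i, c) - 1;
      double *blk = REAL(out) + ((R_xlen_t)i * Cm + c) * S * S;
      for (int l = 0; l < S; ++l)
        for (int k = 0; k < S; ++k)
          blk[(size_t)l * S + k] = abar * abar * gtot -
                                   abar * B[(size_t)i * S + k] -
                                   abar * A[(size_t)j * S + l];
      const int *xi_i = xpost.data() + (size_t)i * ne;
      const int *xi_j = xpre.data() + (size_t)j * ne;
      for (int e = 0; e < ne; ++e)
        if (xi_i[e] > 0 && xi_j[e] > 0)
          blk[(size_t)(xi_j[e] - 1) * S + (xi_i[e] - 1)] += g[e];
      for (int z = 0; z < S * S; ++z) blk[z] *= norm;
    }
  }
  return out;
}
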