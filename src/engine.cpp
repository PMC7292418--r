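// Discrete-event trial engine.
//
// One call simulates one seeded trial of a whole Mouse: Body, Dose, and a
// vLiver of sampled lobule graphs.  Compound objects (APAP, G, S, ALT,
// Marker) percolate PV-to-CV through the Sinusoid-Segment graph; vHPC
// agents metabolize APAP, deplete a GSH counter, create and mitigate
// damage products, and externalize ALT under the configured release
// mechanism.
//
// Random numbers come from four named substreams (disposition, marker,
// damage, release) so that changing the release mechanism or its
// parameters leaves the disposition and damage trajectories bit-identical,
// and the Marker internal standard is invariant to everything except the
// structure and flow configuration.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---- xoshiro256++ with splitmix64 seeding -------------------------------

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed ^ (stream * 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline int unif_int(int n) {  // in [0, n)
    return (int)(next() % (uint64_t)n);  // modulo bias negligible for small n
  }
  // exact binomial: Bernoulli loop for small n, BINV inversion for small
  // n*p, halving recursion otherwise (keeps every draw exact).
  int binom(int n, double p) {
    if (n <= 0 || p <= 0.0) return 0;
    if (p >= 1.0) return n;
    if (p > 0.5) return n - binom(n, 1.0 - p);
    if (n < 16) {
      int k = 0;
      for (int i = 0; i < n; ++i) if (unif() < p) ++k;
      return k;
    }
    double np = n * p;
    if (np < 30.0) {
      double q = 1.0 - p, qn = std::pow(q, n);
      double r = p / q, g = r * (n + 1);
      while (true) {
        int ix = 0;
        double f = qn, u = unif();
        while (true) {
          if (u < f) return ix;
          if (ix > 110) break;
          u -= f;
          ++ix;
          f *= (g / ix - r);
        }
      }
    }
    int h = n / 2;
    return binom(h, p) + binom(n - h, p);
  }
};

// ---- engine -------------------------------------------------------------

enum Kind { K_APAP = 0, K_G = 1, K_S = 2, K_ALT = 3, K_MARKER = 4 };
enum Ev { E_GSH = 0, E_MIT = 1, E_LEAK = 2, E_SCHED = 3, E_REL = 4,
          E_NTRIG = 5, E_NECR = 6 };
enum Mode { M_NECROTIC = 0, M_MITOD = 1, M_NONMD = 2, M_DUAL = 3 };

struct Engine {
  // graph
  int n_nodes, nv;
  std::vector<int> layer, node_nvhpc, vhpc_off, node_band;
  std::vector<int> edge_ptr, edge_to;          // CV encoded as -1
  std::vector<int> entry_nodes;                // layer-1 nodes
  std::vector<int> order;                      // nodes, layer 3 first
  // per-vHPC
  std::vector<double> zone, gsh;
  std::vector<int> node_of, band_of;
  std::vector<int> apap_free, apap_bound, gq, sq, napqi, mitoD, nonMD;
  std::vector<int> alt_counter, npend;
  std::vector<int32_t> pend;                   // 5 slots per vHPC
  std::vector<uint8_t> active, ever_leak, leak_state, necr_trig, necrotic;
  std::vector<int32_t> necr_due, trig_cycle, necrotic_cycle, leak_cycle;
  // extracellular
  std::vector<int> ex;                         // n_nodes x 5
  std::vector<int> ec_bound, ec_cap;
  double body[5];
  // params
  double dose_frac, p_down, p_entry, p_exit, ec_bind, ec_rel, hb, hr;
  std::vector<double> pm_v, pn_v, mm_v, mn_v, gsh0_v;
  double p_mito;
  int mode; bool dual_sum;
  int leak_thr, necr_thr; double p_rm;
  int amp_min, amp_max, leak_min, leak_max, death_min, death_max, alt_init;
  // ledgers
  long long cum_met, cum_g, cum_s, cum_alt_created, initial_dose, initial_marker;
  long long cum_rel_leak, cum_rel_necr;
  // event counters [scope 0..3][event 0..6], scope 0 = whole liver
  long long cum_ev[4][7];
  Rng disp, mark, dmg, rel;

  Engine(uint64_t seed)
    : disp(seed, 1), mark(seed, 2), dmg(seed, 3), rel(seed, 4) {
    cum_met = cum_g = cum_s = cum_alt_created = 0;
    cum_rel_leak = cum_rel_necr = 0;
    for (int s = 0; s < 4; ++s) for (int e = 0; e < 7; ++e) cum_ev[s][e] = 0;
    for (int k = 0; k < 5; ++k) body[k] = 0;
  }

  inline double lin(double a, double b, double z) { return a + (b - a) * z; }

  inline void count_ev(int band, int e, int n = 1) {
    cum_ev[0][e] += n;
    if (band < 3) cum_ev[band + 1][e] += n;
  }

  inline Rng& kind_rng(int k) {
    if (k == K_MARKER) return mark;
    if (k == K_ALT) return rel;
    return disp;
  }

  void body_to_pv(int kind, Rng& r) {
    int n = (int)body[kind];
    int k = r.binom(n, dose_frac);
    body[kind] -= k;
    int ne = (int)entry_nodes.size();
    for (int i = 0; i < k; ++i)
      ex[entry_nodes[r.unif_int(ne)] * 5 + kind] += 1;
  }

  void percolate() {
    for (int oi = 0; oi < n_nodes; ++oi) {
      int nd = order[oi];
      for (int k = 0; k < 5; ++k) {
        int cnt = ex[nd * 5 + k];
        if (cnt == 0) continue;
        Rng& r = kind_rng(k);
        int mv = r.binom(cnt, p_down);
        if (mv == 0) continue;
        ex[nd * 5 + k] -= mv;
        int e0 = edge_ptr[nd], e1 = edge_ptr[nd + 1], ne = e1 - e0;
        for (int i = 0; i < mv; ++i) {
          int to = edge_to[e0 + (ne == 1 ? 0 : r.unif_int(ne))];
          if (to < 0) body[k] += 1.0;     // CV -> Mouse Body, same cycle
          else ex[to * 5 + k] += 1;
        }
      }
    }
  }

  void ec_binders() {
    for (int nd = 0; nd < n_nodes; ++nd) {
      int rls = disp.binom(ec_bound[nd], ec_rel);
      ec_bound[nd] -= rls; ex[nd * 5 + K_APAP] += rls;
      int cap = ec_cap[nd] - ec_bound[nd];
      int bnd = disp.binom(ex[nd * 5 + K_APAP], ec_bind);
      if (bnd > cap) bnd = cap;
      ec_bound[nd] += bnd; ex[nd * 5 + K_APAP] -= bnd;
    }
  }

  void cell_entry() {
    for (int nd = 0; nd < n_nodes; ++nd) {
      int cnt = ex[nd * 5 + K_APAP];
      if (cnt == 0) continue;
      int k = disp.binom(cnt, p_entry);
      int nvh = node_nvhpc[nd], off = vhpc_off[nd];
      for (int i = 0; i < k; ++i) {
        int v = off + disp.unif_int(nvh);
        if (necrotic[v]) continue;        // dead cells admit nothing
        ex[nd * 5 + K_APAP] -= 1;
        apap_free[v] += 1;
        active[v] = 1;
      }
    }
  }

  inline bool leak_test(int v) {
    switch (mode) {
      case M_MITOD: return mitoD[v] > leak_thr;
      case M_NONMD: return nonMD[v] > leak_thr;
      case M_DUAL:
        if (dual_sum) return mitoD[v] + nonMD[v] > leak_thr;
        return mitoD[v] > leak_thr && nonMD[v] > leak_thr;
      default: return false;
    }
  }

  void vhpc_cycle(int t) {
    for (int v = 0; v < nv; ++v) {
      if (!active[v]) continue;
      int nd = node_of[v], bd = band_of[v];

      // --- membrane exchange and binders (disposition stream)
      int k;
      if ((k = disp.binom(apap_free[v], p_exit))) {
        apap_free[v] -= k; ex[nd * 5 + K_APAP] += k;
      }
      if ((k = disp.binom(gq[v], p_exit))) { gq[v] -= k; ex[nd * 5 + K_G] += k; }
      if ((k = disp.binom(sq[v], p_exit))) { sq[v] -= k; ex[nd * 5 + K_S] += k; }
      if ((k = disp.binom(apap_bound[v], hr))) { apap_bound[v] -= k; apap_free[v] += k; }
      if ((k = disp.binom(apap_free[v], hb))) { apap_free[v] -= k; apap_bound[v] += k; }

      // --- metabolism (damage stream)
      int m = dmg.binom(apap_free[v], pm_v[v]);
      if (m) {
        apap_free[v] -= m; cum_met += m;
        int nn = dmg.binom(m, pn_v[v]);
        napqi[v] += nn;
        int gg = dmg.binom(m - nn, 0.5);
        gq[v] += gg; sq[v] += m - nn - gg;
        cum_g += gg; cum_s += m - nn - gg;
      }

      // --- NAPQI removal: GSH depletion then damage-product bursts
      int nr = dmg.binom(napqi[v], p_rm);
      for (int i = 0; i < nr; ++i) {
        napqi[v] -= 1;
        if (gsh[v] > 0.0) {
          gsh[v] -= 1.0;
          if (gsh[v] <= 0.0) { gsh[v] = 0.0; count_ev(bd, E_GSH); }
        } else {
          int amp = amp_min + (amp_max > amp_min ? dmg.unif_int(amp_max - amp_min + 1) : 0);
          int prod = amp + 1;
          if (dmg.unif() < p_mito) mitoD[v] += prod; else nonMD[v] += prod;
        }
      }

      // --- damage mitigation: at most one removal per type per cycle
      if (mitoD[v] > 0 && dmg.unif() < mm_v[v]) {
        mitoD[v] -= 1; count_ev(bd, E_MIT);
      }
      if (nonMD[v] > 0 && dmg.unif() < mn_v[v]) {
        nonMD[v] -= 1; count_ev(bd, E_MIT);
      }

      // --- Necrosis-Triggered -> Necrotic transition
      if (necr_trig[v] && !necrotic[v] && t >= necr_due[v]) {
        necrotic[v] = 1; necrotic_cycle[v] = t;
        int reln = alt_counter[v];
        alt_counter[v] = 0;
        if (reln) {
          ex[nd * 5 + K_ALT] += reln;
          cum_alt_created += reln; cum_rel_necr += reln;
          count_ev(bd, E_REL, reln);
        }
        count_ev(bd, E_NECR);
        active[v] = 0;                     // a Necrotic vHPC does nothing more
        continue;
      }

      // --- necrosis trigger (strict >)
      if (!necr_trig[v] && mitoD[v] > necr_thr) {
        necr_trig[v] = 1; trig_cycle[v] = t;
        necr_due[v] = t + death_min +
          (death_max > death_min ? dmg.unif_int(death_max - death_min) : 0);
        count_ev(bd, E_NTRIG);
      }

      // --- leakage: fire due releases, re-test trigger, schedule
      if (mode != M_NECROTIC) {
        if (npend[v]) {
          int32_t* p = &pend[(size_t)v * 5];
          for (int i = 0; i < npend[v]; ) {
            if (p[i] <= t) {
              if (alt_counter[v] > 0) {
                alt_counter[v] -= 1;
                ex[nd * 5 + K_ALT] += 1;
                cum_alt_created += 1; cum_rel_leak += 1;
                count_ev(bd, E_REL);
              }
              p[i] = p[--npend[v]];
            } else ++i;
          }
        }
        bool lt = leak_test(v);
        if (lt && !ever_leak[v]) {
          ever_leak[v] = 1; leak_cycle[v] = t; count_ev(bd, E_LEAK);
        }
        leak_state[v] = lt;
        if (lt && npend[v] < 5 && alt_counter[v] - npend[v] > 0) {
          int lag = leak_min +
            (leak_max > leak_min ? rel.unif_int(leak_max - leak_min) : 0);
          pend[(size_t)v * 5 + npend[v]] = t + lag;
          npend[v] += 1;
          count_ev(bd, E_SCHED);
        }
      }

      active[v] = (apap_free[v] | apap_bound[v] | napqi[v] | mitoD[v] |
                   nonMD[v] | gq[v] | sq[v]) != 0 ||
                  npend[v] > 0 || (necr_trig[v] && !necrotic[v]);
    }
  }

  void check_ledgers(int t) {
    long long ex_tot[5] = {0, 0, 0, 0, 0};
    for (int nd = 0; nd < n_nodes; ++nd)
      for (int k = 0; k < 5; ++k) ex_tot[k] += ex[nd * 5 + k];
    long long bound_tot = 0, cell_apap = 0, cell_g = 0, cell_s = 0, alt_ctr = 0;
    for (int nd = 0; nd < n_nodes; ++nd) bound_tot += ec_bound[nd];
    for (int v = 0; v < nv; ++v) {
      cell_apap += apap_free[v] + apap_bound[v];
      cell_g += gq[v]; cell_s += sq[v];
      alt_ctr += alt_counter[v];
    }
    long long apap_all = (long long)body[K_APAP] + ex_tot[K_APAP] + bound_tot +
                         cell_apap + cum_met;
    if (apap_all != initial_dose)
      stop("APAP ledger violated at cycle %d: %lld != %lld", t, apap_all,
           initial_dose);
    if ((long long)body[K_G] + ex_tot[K_G] + cell_g != cum_g)
      stop("G ledger violated at cycle %d", t);
    if ((long long)body[K_S] + ex_tot[K_S] + cell_s != cum_s)
      stop("S ledger violated at cycle %d", t);
    if ((long long)body[K_ALT] + ex_tot[K_ALT] != cum_alt_created)
      stop("ALT ledger violated at cycle %d", t);
    if (alt_ctr + cum_alt_created != (long long)alt_init * nv)
      stop("ALT counter identity violated at cycle %d", t);
    if ((long long)body[K_MARKER] + ex_tot[K_MARKER] != initial_marker)
      stop("Marker ledger violated at cycle %d", t);
  }
};

// [[Rcpp::export(name = ".run_trial_cpp")]]
List run_trial_cpp(List liver, List flow, List grad, List mech,
                   int dose_objects, int marker_objects,
                   int duration, double seed,
                   int thin = 60, int check_every = 600,
                   bool return_state = false) {
  Engine E((uint64_t)seed);

  // ---- liver layout
  IntegerVector layer = liver["layer"], nnv = liver["node_nvhpc"],
    voff = liver["vhpc_off"], nband = liver["node_band"],
    eptr = liver["edge_ptr"], eto = liver["edge_to"],
    entry = liver["entry_nodes"], vnode = liver["node_of"],
    vband = liver["band_of"], ecc = liver["ec_cap"];
  NumericVector vzone = liver["zone"];
  E.n_nodes = layer.size();
  E.nv = vzone.size();
  E.layer.assign(layer.begin(), layer.end());
  E.node_nvhpc.assign(nnv.begin(), nnv.end());
  E.vhpc_off.assign(voff.begin(), voff.end());
  E.node_band.assign(nband.begin(), nband.end());
  E.edge_ptr.assign(eptr.begin(), eptr.end());
  E.edge_to.assign(eto.begin(), eto.end());
  E.entry_nodes.assign(entry.begin(), entry.end());
  E.node_of.assign(vnode.begin(), vnode.end());
  E.band_of.assign(vband.begin(), vband.end());
  E.zone.assign(vzone.begin(), vzone.end());
  E.ec_cap.assign(ecc.begin(), ecc.end());
  E.order.resize(E.n_nodes);
  {
    int idx = 0;
    for (int ly = 3; ly >= 1; --ly)
      for (int nd = 0; nd < E.n_nodes; ++nd)
        if (E.layer[nd] == ly) E.order[idx++] = nd;
  }

  // ---- parameters
  E.dose_frac = flow["dose_transfer_fraction"];
  E.p_down = flow["downstream_prob"]; E.p_entry = flow["entry_prob"];
  E.p_exit = flow["exit_prob"];
  E.ec_bind = flow["ec_bind_prob"]; E.ec_rel = flow["ec_release_prob"];
  E.hb = flow["hpc_bind_prob"]; E.hr = flow["hpc_release_prob"];
  NumericVector pm = grad["p_metabolism"], pn = grad["p_napqi"],
    gt = grad["gsh_threshold"], mm = grad["p_mitigate_mitod"],
    mn = grad["p_mitigate_nonmd"];
  E.pm_v.assign(pm.begin(), pm.end());
  E.pn_v.assign(pn.begin(), pn.end());
  E.mm_v.assign(mm.begin(), mm.end());
  E.mn_v.assign(mn.begin(), mn.end());
  E.gsh0_v.assign(gt.begin(), gt.end());
  E.p_mito = grad["p_mito_fraction"];
  E.mode = mech["release_mode_id"];
  E.dual_sum = as<std::string>(mech["dual_semantics"]) == "sum";
  E.leak_thr = mech["leakage_threshold"];
  E.necr_thr = mech["necrosis_threshold"];
  E.p_rm = mech["napqi_removal_prob"];
  IntegerVector amp = mech["amplification_range"],
    ll = mech["leak_lag_cycles"], dd = mech["death_delay_cycles"];
  int shift = mech["exlt_shift_cycles"];
  E.amp_min = amp[0]; E.amp_max = amp[1];
  E.leak_min = ll[0] + shift; E.leak_max = ll[1] + shift;
  E.death_min = dd[0] + shift; E.death_max = dd[1] + shift;
  E.alt_init = mech["alt_initial"];

  // ---- state
  int nv = E.nv, nn = E.n_nodes;
  if ((int)E.pm_v.size() != nv) stop("gradient vectors must have one value per vHPC");
  E.gsh.resize(nv);
  for (int v = 0; v < nv; ++v) E.gsh[v] = E.gsh0_v[v];
  E.apap_free.assign(nv, 0); E.apap_bound.assign(nv, 0);
  E.gq.assign(nv, 0); E.sq.assign(nv, 0); E.napqi.assign(nv, 0);
  E.mitoD.assign(nv, 0); E.nonMD.assign(nv, 0);
  E.alt_counter.assign(nv, E.alt_init); E.npend.assign(nv, 0);
  E.pend.assign((size_t)nv * 5, 0);
  E.active.assign(nv, 0); E.ever_leak.assign(nv, 0);
  E.leak_state.assign(nv, 0); E.necr_trig.assign(nv, 0);
  E.necrotic.assign(nv, 0);
  E.necr_due.assign(nv, -1); E.trig_cycle.assign(nv, -1);
  E.necrotic_cycle.assign(nv, -1); E.leak_cycle.assign(nv, -1);
  E.ex.assign((size_t)nn * 5, 0); E.ec_bound.assign(nn, 0);
  if (dose_objects > 100000) stop("APAP Doses are <= 100,000 objects");
  E.body[K_APAP] = dose_objects;
  E.body[K_MARKER] = marker_objects;
  E.initial_dose = dose_objects;
  E.initial_marker = marker_objects;

  // ---- logs
  NumericMatrix body_log(duration, 5);
  IntegerMatrix ev_log(duration, 28);
  int nrec = duration / thin + 1;
  NumericMatrix amt_log(nrec, 24);
  IntegerVector rec_cycles(nrec);
  int irec = 0;

  for (int t = 0; t < duration; ++t) {
    E.body_to_pv(K_APAP, E.disp);
    E.body_to_pv(K_MARKER, E.mark);
    E.percolate();
    E.ec_binders();
    E.cell_entry();
    E.vhpc_cycle(t);

    for (int k = 0; k < 5; ++k) body_log(t, k) = E.body[k];
    for (int s = 0; s < 4; ++s)
      for (int e = 0; e < 7; ++e) ev_log(t, s * 7 + e) = (int)E.cum_ev[s][e];
    if (t % thin == 0 || t == duration - 1) {
      double a[4][6] = {{0}};
      for (int v = 0; v < nv; ++v) {
        int b = E.band_of[v];
        double vals[4] = {(double)(E.apap_free[v] + E.apap_bound[v]),
                          (double)E.napqi[v], (double)E.mitoD[v],
                          (double)E.nonMD[v]};
        for (int j = 0; j < 4; ++j) {
          a[0][j] += vals[j];
          if (b < 3) a[b + 1][j] += vals[j];
        }
      }
      for (int nd = 0; nd < nn; ++nd) {
        int b = E.node_band[nd];
        double exalt = E.ex[nd * 5 + K_ALT];
        double exapap = E.ex[nd * 5 + K_APAP] + E.ec_bound[nd];
        a[0][4] += exalt; a[0][5] += exapap;
        if (b < 3) { a[b + 1][4] += exalt; a[b + 1][5] += exapap; }
      }
      if (irec < nrec) {
        rec_cycles[irec] = t;
        for (int s = 0; s < 4; ++s)
          for (int j = 0; j < 6; ++j) amt_log(irec, s * 6 + j) = a[s][j];
        ++irec;
      }
    }
    if (check_every > 0 && (t % check_every == 0 || t == duration - 1))
      E.check_ledgers(t);
    if (t > 0 && body_log(t, K_ALT) < body_log(t - 1, K_ALT))
      stop("Body ALT decreased at cycle %d", t);
  }

  List out = List::create(
    _["body"] = body_log,
    _["events"] = ev_log,
    _["amounts"] = amt_log,
    _["amount_cycles"] = rec_cycles,
    _["trig_cycle"] = IntegerVector(E.trig_cycle.begin(), E.trig_cycle.end()),
    _["necrotic_cycle"] = IntegerVector(E.necrotic_cycle.begin(), E.necrotic_cycle.end()),
    _["leak_cycle"] = IntegerVector(E.leak_cycle.begin(), E.leak_cycle.end()),
    _["band_of"] = IntegerVector(E.band_of.begin(), E.band_of.end()),
    _["cum_metabolized"] = (double)E.cum_met,
    _["cum_released_leak"] = (double)E.cum_rel_leak,
    _["cum_released_necrotic"] = (double)E.cum_rel_necr);
  if (return_state) {
    out["state"] = List::create(
      _["gsh"] = NumericVector(E.gsh.begin(), E.gsh.end()),
      _["apap_free"] = IntegerVector(E.apap_free.begin(), E.apap_free.end()),
      _["apap_bound"] = IntegerVector(E.apap_bound.begin(), E.apap_bound.end()),
      _["napqi"] = IntegerVector(E.napqi.begin(), E.napqi.end()),
      _["mitoD"] = IntegerVector(E.mitoD.begin(), E.mitoD.end()),
      _["nonMD"] = IntegerVector(E.nonMD.begin(), E.nonMD.end()),
      _["alt_counter"] = IntegerVector(E.alt_counter.begin(), E.alt_counter.end()),
      _["ever_leak"] = IntegerVector(E.ever_leak.begin(), E.ever_leak.end()),
      _["necrotic"] = IntegerVector(E.necrotic.begin(), E.necrotic.end()));
  }
  return out;
}
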