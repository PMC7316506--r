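// Stochastic individual-based model of gene uptake on a toroidal lattice.
//
// Every site holds exactly one cell characterised by a gene flag (+ barcode),
// an SGE flag (+ barcode) and an individual uptake rate h.  A time step is a
// fixed sequence of sweeps: reproduction, gene loss, SGE loss, uptake (HGT),
// influx, mutation of h, mixing.  All per-event rates are scaled by dt.
// Sweeps whose events read the states of other cells (reproduction, HGT) are
// synchronous: decisions are taken against the pre-sweep state and applied
// atomically, so raster order never matters.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// xoshiro256++ with splitmix64 seeding: fast, seedable, compiler-independent.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
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
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }  // [0, 1)
  inline int below(int n) { return (int)(unif() * n); }
};

struct Cfg {
  int n, s, t, d;
  bool well_mixed;
  double l, c, u, m, f, b, sge_influx, beta, dt, hgt_plus;
  int f_start, f_stop, i_start, i_stop;
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.n = as<int>(cfg["n"]);
  c.s = as<int>(cfg["s"]);
  c.t = as<int>(cfg["t"]);
  c.d = as<int>(cfg["d"]);
  c.well_mixed = as<bool>(cfg["well_mixed"]);
  c.l = as<double>(cfg["l"]);
  c.c = as<double>(cfg["c"]);
  c.u = as<double>(cfg["u"]);
  c.m = as<double>(cfg["m"]);
  c.f = as<double>(cfg["f"]);
  c.b = as<double>(cfg["b"]);
  c.sge_influx = as<double>(cfg["sge_influx"]);
  c.beta = as<double>(cfg["beta"]);
  c.dt = as<double>(cfg["dt"]);
  c.hgt_plus = as<double>(cfg["hgt_plus"]);
  c.f_start = as<int>(cfg["f_start"]);
  c.f_stop = as<int>(cfg["f_stop"]);
  c.i_start = as<int>(cfg["i_start"]);
  c.i_stop = as<int>(cfg["i_stop"]);
  return c;
}

// Visit the sites of independent Bernoulli(p) trials by geometric skipping;
// exactly equivalent to drawing one uniform per site, but O(hits).
template <class F>
static inline void bernoulli_sites(Xoshiro& rng, int N, double p, F fn) {
  if (p <= 0) return;
  if (p >= 1) { for (int i = 0; i < N; i++) fn(i); return; }
  const double log1mp = std::log1p(-p);
  double idx = std::floor(std::log(1.0 - rng.unif()) / log1mp);
  while (idx < (double)N) {
    fn((int)idx);
    idx += 1.0 + std::floor(std::log(1.0 - rng.unif()) / log1mp);
  }
}

struct IBM {
  Cfg cfg;
  int n, N, maxrad;
  std::vector<int> gene, gbar, sge, sbar;
  std::vector<double> h;
  std::vector<int> wr;            // toroidal wrap lookup
  Xoshiro rng;
  long phase;                     // Margolus offset parity counter
  int gene_next, sge_next;        // barcode registry counters
  std::vector<int> gene_born, sge_born;
  // lineage store: one node per birth event
  bool track;
  long prune_limit;
  std::vector<int> node_id;       // per site; -1 = no recorded ancestry
  std::vector<int> par, ngen;
  std::vector<double> nphi;
  std::vector<double> phibuf;

  IBM(const List& grid, const Cfg& cfg_, uint64_t seed, bool track_,
      long prune_limit_, int gene_next_, int sge_next_, long phase_)
    : cfg(cfg_), n(cfg_.n), N(cfg_.n * cfg_.n), rng(seed), phase(phase_),
      gene_next(gene_next_), sge_next(sge_next_), track(track_),
      prune_limit(prune_limit_) {
    gene = as<std::vector<int>>(grid["gene"]);
    gbar = as<std::vector<int>>(grid["gene_barcode"]);
    sge  = as<std::vector<int>>(grid["sge"]);
    sbar = as<std::vector<int>>(grid["sge_barcode"]);
    h    = as<std::vector<double>>(grid["h"]);
    if ((int)gene.size() != N) stop("grid does not match config n");
    maxrad = std::max(cfg.s / 2, cfg.t / 2);
    wr.resize(n + 2 * maxrad);
    for (int i = 0; i < (int)wr.size(); i++) wr[i] = ((i - maxrad) % n + n) % n;
    node_id.assign(N, -1);
    phibuf.resize(N);
  }

  inline double phi_of(int i) const {
    double v = 1.0 + (gene[i] ? cfg.b : 0.0) - (sge[i] ? cfg.beta : 0.0)
      - cfg.c * h[i];
    return v > 0 ? v : 0.0;
  }

  // ---- sweeps -------------------------------------------------------------
  // The competitor that may reproduce into a focal site is drawn uniformly
  // from the other s*s - 1 cells of the competition block (the focal cell
  // itself competes for its neighbours' sites, not for its own): this makes
  // the well-mixed lattice reduce exactly to the mass-action dynamics.
  // Under well_mixed, competitor and donor are sampled uniformly from the
  // whole grid (minus self), which is distributionally identical to
  // re-assigning all positions at random every step.
  struct Rep { int site, g, gb, sg, sb, parent, gen; double h, phi; };
  std::vector<Rep> reps;

  inline int draw_other_global(int i) {
    int j = rng.below(N - 1);
    return j >= i ? j + 1 : j;
  }

  void reproduction() {
    const int s = cfg.s, rad = s / 2, ss = s * s, center = (s * s) / 2;
    const double dt = cfg.dt;
    const bool global = cfg.well_mixed;
    reps.clear();
    for (int r = 0; r < n; r++) {
      const int rbase = r + maxrad;
      for (int c0 = 0; c0 < n; c0++) {
        int src;
        if (global) {
          src = draw_other_global(r * n + c0);
        } else {
          int k = (int)(rng.unif() * (ss - 1));
          if (k >= center) k++;                   // exclude self
          src = wr[rbase + k / s - rad] * n + wr[c0 + maxrad + k % s - rad];
        }
        double phi = phi_of(src);
        if (rng.unif() < phi * dt) {
          Rep e;
          e.site = r * n + c0;
          e.g = gene[src]; e.gb = gbar[src];
          e.sg = sge[src]; e.sb = sbar[src];
          e.h = h[src];
          e.parent = node_id[src];
          e.gen = (e.parent >= 0 ? ngen[e.parent] + 1 : 1);
          e.phi = phi;
          reps.push_back(e);
        }
      }
    }
    for (const Rep& e : reps) {
      gene[e.site] = e.g; gbar[e.site] = e.gb;
      sge[e.site] = e.sg; sbar[e.site] = e.sb;
      h[e.site] = e.h;
      if (track) {
        par.push_back(e.parent);
        nphi.push_back(e.phi);
        ngen.push_back(e.gen);
        node_id[e.site] = (int)par.size() - 1;
      }
    }
  }

  void gene_loss() {
    bernoulli_sites(rng, N, cfg.l * cfg.dt, [&](int i) {
      if (gene[i]) { gene[i] = 0; gbar[i] = 0; }
    });
  }

  void sge_loss() {
    bernoulli_sites(rng, N, cfg.l * cfg.dt, [&](int i) {
      if (sge[i]) { sge[i] = 0; sbar[i] = 0; }
    });
  }

  struct Tr { int site, g, gb, sg, sb; };
  std::vector<Tr> trs;

  void hgt() {
    const int t = cfg.t, radt = t / 2, tt = t * t, center = tt / 2;
    const double dt = cfg.dt;
    const bool global = cfg.well_mixed;
    trs.clear();
    for (int i = 0; i < N; i++) {
      const double hi = h[i];
      if (hi <= 0) continue;
      double p = hi * dt;
      if (p > 1) p = 1;
      if (rng.unif() >= p) continue;
      int don;
      if (global) {
        don = draw_other_global(i);
      } else {
        int k = (int)(rng.unif() * (tt - 1));
        if (k >= center) k++;                     // exclude self
        int r = i / n, c0 = i % n;
        don = wr[r + maxrad + k / t - radt] * n
          + wr[c0 + maxrad + k % t - radt];
      }
      Tr e; e.site = i;
      e.g = gene[i]; e.gb = gbar[i]; e.sg = sge[i]; e.sb = sbar[i];
      bool got = false;
      if (!gene[i] && gene[don]) { e.g = 1; e.gb = gbar[don]; got = true; }
      if (!sge[i] && sge[don])   { e.sg = 1; e.sb = sbar[don]; got = true; }
      if (got) trs.push_back(e);
    }
    for (const Tr& e : trs) {
      gene[e.site] = e.g; gbar[e.site] = e.gb;
      sge[e.site] = e.sg; sbar[e.site] = e.sb;
    }
  }

  // influx rates are dt-scaled like the other rate-like processes; the
  // mutation probability u is per cell per step as given
  void influx(int step) {
    if (cfg.f > 0 && step >= cfg.f_start && step < cfg.f_stop) {
      bernoulli_sites(rng, N, cfg.f * cfg.dt, [&](int i) {
        if (!gene[i]) {
          gene[i] = 1; gbar[i] = gene_next++;
          gene_born.push_back(step);
        }
      });
    }
    if (cfg.sge_influx > 0 && step >= cfg.i_start && step < cfg.i_stop) {
      bernoulli_sites(rng, N, cfg.sge_influx * cfg.dt, [&](int i) {
        if (!sge[i]) {
          sge[i] = 1; sbar[i] = sge_next++;
          sge_born.push_back(step);
        }
      });
    }
  }

  void mutation() {
    bernoulli_sites(rng, N, cfg.u, [&](int i) {
      double nh = h[i] + (2.0 * rng.unif() - 1.0) * cfg.m;
      h[i] = nh > 0 ? nh : 0.0;
    });
  }

  inline void rot4(const int idx[4], bool cw) {
    // values move one position along the cycle (clockwise or back)
    auto cyc = [&](auto& v) {
      auto tmp = v[idx[3]];
      if (cw) {
        v[idx[3]] = v[idx[2]]; v[idx[2]] = v[idx[1]];
        v[idx[1]] = v[idx[0]]; v[idx[0]] = tmp;
      } else {
        v[idx[3]] = v[idx[0]]; v[idx[0]] = v[idx[1]];
        v[idx[1]] = v[idx[2]]; v[idx[2]] = tmp;
      }
    };
    cyc(gene); cyc(gbar); cyc(sge); cyc(sbar); cyc(h); cyc(node_id);
  }

  void margolus_once() {
    const int o = (int)(phase & 1);
    for (int bi = 0; bi < n / 2; bi++) {
      int r0 = (2 * bi + o) % n, r1 = (r0 + 1) % n;
      for (int bj = 0; bj < n / 2; bj++) {
        int c0 = (2 * bj + o) % n, c1 = (c0 + 1) % n;
        const int idx[4] = { r0 * n + c0, r0 * n + c1,
                             r1 * n + c1, r1 * n + c0 };
        rot4(idx, rng.unif() < 0.5);
      }
    }
    phase++;
  }

  void well_mix() {
    for (int i = N - 1; i > 0; i--) {
      int j = rng.below(i + 1);
      std::swap(gene[i], gene[j]); std::swap(gbar[i], gbar[j]);
      std::swap(sge[i], sge[j]);   std::swap(sbar[i], sbar[j]);
      std::swap(h[i], h[j]);       std::swap(node_id[i], node_id[j]);
    }
  }

  void mix() {
    // well_mixed needs no physical permutation: all interactions already
    // sample partners globally, so positions carry no information
    if (!cfg.well_mixed)
      for (int k = 0; k < cfg.d; k++) margolus_once();
  }

  void step(int step_idx) {
    reproduction();
    gene_loss();
    sge_loss();
    hgt();
    influx(step_idx);
    mutation();
    mix();
    if (track && (long)par.size() > prune_limit) prune();
  }

  // ---- lineage ------------------------------------------------------------
  static const int LOD_WINDOW = 250;

  double phi_lod() const {
    if (!track) return NA_REAL;
    double tot = 0; long cells = 0;
    for (int i = 0; i < N; i++) {
      int v = node_id[i];
      if (v < 0) continue;
      double s = 0; int c = 0;
      while (v >= 0 && c < LOD_WINDOW) { s += nphi[v]; c++; v = par[v]; }
      tot += s / c; cells++;
    }
    return cells ? tot / cells : NA_REAL;
  }

  void prune() {
    // keep, for every live cell, its last LOD_WINDOW ancestral birth events
    std::vector<int> rem(par.size(), -1);
    for (int i = 0; i < N; i++) {
      int v = node_id[i], need = LOD_WINDOW;
      while (v >= 0 && need > 0 && need > rem[v]) {
        rem[v] = need; v = par[v]; need--;
      }
    }
    std::vector<int> nid(par.size(), -1);
    std::vector<int> par2, ngen2; std::vector<double> nphi2;
    for (size_t v = 0; v < par.size(); v++) {
      if (rem[v] < 0) continue;
      nid[v] = (int)par2.size();
      int p = par[v];
      par2.push_back(p >= 0 && rem[p] >= 0 ? nid[p] : -1);
      ngen2.push_back(ngen[v]);
      nphi2.push_back(nphi[v]);
    }
    par.swap(par2); ngen.swap(ngen2); nphi.swap(nphi2);
    for (int i = 0; i < N; i++)
      if (node_id[i] >= 0) node_id[i] = nid[node_id[i]];
  }

  // ---- observables --------------------------------------------------------
  List report(int step_idx) {
    long ng = 0, ns = 0, nplus = 0;
    double sumh = 0, sumphi = 0;
    std::unordered_set<int> gset, sset;
    for (int i = 0; i < N; i++) {
      if (gene[i]) { ng++; gset.insert(gbar[i]); }
      if (sge[i])  { ns++; sset.insert(sbar[i]); }
      if (h[i] > cfg.hgt_plus) nplus++;
      sumh += h[i];
      phibuf[i] = phi_of(i);
      sumphi += phibuf[i];
    }
    // mean excess growth of carriers over their 8 Moore neighbours
    double sig = NA_REAL;
    if (ng > 0) {
      double acc = 0;
      for (int r = 0; r < n; r++) {
        for (int c0 = 0; c0 < n; c0++) {
          int i = r * n + c0;
          if (!gene[i]) continue;
          double nb = 0;
          for (int di = -1; di <= 1; di++)
            for (int dj = -1; dj <= 1; dj++) {
              if (di == 0 && dj == 0) continue;
              nb += phibuf[wr[r + maxrad + di] * n + wr[c0 + maxrad + dj]];
            }
          acc += phibuf[i] - nb / 8.0;
        }
      }
      sig = acc / ng;
    }
    return List::create(
      _["step"] = step_idx,
      _["carrier_freq"] = (double)ng / N,
      _["sge_freq"] = (double)ns / N,
      _["mean_h"] = sumh / N,
      _["frac_hgt_plus"] = (double)nplus / N,
      _["phi_pop"] = sumphi / N,
      _["sigma_c"] = sig,
      _["phi_lod"] = phi_lod(),
      _["gene_barcodes"] = (double)gset.size(),
      _["sge_barcodes"] = (double)sset.size());
  }

  List grid_out() const {
    IntegerMatrix g(n, n), gb(n, n), s(n, n), sb(n, n);
    NumericMatrix hh(n, n);
    std::copy(gene.begin(), gene.end(), g.begin());
    std::copy(gbar.begin(), gbar.end(), gb.begin());
    std::copy(sge.begin(), sge.end(), s.begin());
    std::copy(sbar.begin(), sbar.end(), sb.begin());
    std::copy(h.begin(), h.end(), hh.begin());
    return List::create(_["gene"] = g, _["gene_barcode"] = gb,
                        _["sge"] = s, _["sge_barcode"] = sb, _["h"] = hh);
  }
};

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ibm_run(List grid, List cfg, int steps, int step_offset,
                 int report_every, IntegerVector snapshot_steps,
                 bool track_lineage, double seed, int gene_next, int sge_next,
                 int phase, double prune_limit, bool return_lineage) {
  Cfg c = parse_cfg(cfg);
  IBM ibm(grid, c, (uint64_t)seed, track_lineage, (long)prune_limit,
          gene_next, sge_next, phase);
  std::vector<List> rows;
  rows.push_back(ibm.report(step_offset));
  List snaps;
  std::unordered_set<int> snapset(snapshot_steps.begin(), snapshot_steps.end());
  std::vector<int> snap_at;
  std::vector<List> snap_grids;
  for (int k = 1; k <= steps; k++) {
    int idx = step_offset + k - 1;       // 0-based index of executed step
    ibm.step(idx);
    int now = step_offset + k;
    if (now % report_every == 0 || k == steps) rows.push_back(ibm.report(now));
    if (snapset.count(now)) { snap_at.push_back(now); snap_grids.push_back(ibm.grid_out()); }
    if (k % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  // assemble time series
  int nr = (int)rows.size();
  NumericMatrix ts(nr, 10);
  CharacterVector nm = rows[0].names();
  for (int r = 0; r < nr; r++)
    for (int c2 = 0; c2 < 10; c2++)
      ts(r, c2) = as<double>(rows[r][c2]);
  List out = List::create(
    _["ts"] = ts, _["ts_names"] = nm,
    _["grid"] = ibm.grid_out(),
    _["gene_next"] = ibm.gene_next, _["sge_next"] = ibm.sge_next,
    _["gene_born"] = IntegerVector(ibm.gene_born.begin(), ibm.gene_born.end()),
    _["sge_born"] = IntegerVector(ibm.sge_born.begin(), ibm.sge_born.end()),
    _["phase"] = (double)ibm.phase,
    _["snapshot_steps"] = IntegerVector(snap_at.begin(), snap_at.end()),
    _["snapshots"] = List(snap_grids.begin(), snap_grids.end()));
  if (track_lineage && return_lineage) {
    out["lineage"] = List::create(
      _["parent"] = IntegerVector(ibm.par.begin(), ibm.par.end()),
      _["phi"] = NumericVector(ibm.nphi.begin(), ibm.nphi.end()),
      _["generation"] = IntegerVector(ibm.ngen.begin(), ibm.ngen.end()),
      _["site_node"] = IntegerVector(ibm.node_id.begin(), ibm.node_id.end()));
  }
  return out;
}

// Apply a single named sweep once (unit-test access to the update rules).
// [[Rcpp::export]]
List cpp_ibm_sweep(List grid, List cfg, std::string sweep, double seed,
                   int step_idx, int phase, int gene_next, int sge_next) {
  Cfg c = parse_cfg(cfg);
  IBM ibm(grid, c, (uint64_t)seed, false, 1e18, gene_next, sge_next, phase);
  if (sweep == "reproduction") ibm.reproduction();
  else if (sweep == "gene_loss") ibm.gene_loss();
  else if (sweep == "sge_loss") ibm.sge_loss();
  else if (sweep == "hgt") ibm.hgt();
  else if (sweep == "influx") ibm.influx(step_idx);
  else if (sweep == "mutation") ibm.mutation();
  else if (sweep == "margolus") { for (int k = 0; k < c.d; k++) ibm.margolus_once(); }
  else if (sweep == "well_mix") ibm.well_mix();
  else if (sweep == "step") ibm.step(step_idx);
  else stop("unknown sweep '%s'", sweep.c_str());
  return List::create(_["grid"] = ibm.grid_out(),
                      _["gene_next"] = ibm.gene_next,
                      _["sge_next"] = ibm.sge_next,
                      _["phase"] = (double)ibm.phase);
}
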