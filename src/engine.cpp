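// Event-driven individual-cell engine: tumour growth through a
// stem / transit / differentiating hierarchy and fractionated
// radiotherapy with OER-scaled linear-quadratic cell kill.
//
// Cells live in struct-of-arrays storage. The "next chronological cell
// due to divide" contract is implemented with a calendar queue: events
// (divisions for cycling cells, necrotic deaths for D3 and
// hypoxia-quiescent cells) are binned into one-hour buckets, and the
// current bucket is kept in a small binary min-heap ordered by
// (event_time, insertion sequence), so that event order -- and therefore
// the whole run -- is fully deterministic for a given R RNG seed.
// Cancelled events (cell killed or rescheduled) are invalidated lazily
// through a per-cell sequence stamp.
//
// All randomness is drawn from R's uniform generator (unif_rand), with
// exponential and normal deviates derived by inversion and Box-Muller,
// so set.seed() in R governs every draw.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <deque>
#include <algorithm>
#include <cmath>
#include <climits>
using namespace Rcpp;

enum CellType { TY_S = 0, TY_T = 1, TY_D1 = 2, TY_D2 = 3, TY_D3 = 4 };
enum CellState { ST_CYCLING = 0, ST_QUIESCENT = 2, ST_DEAD = 3 };

struct GrowPar {
  double spercent, split_transit;
  int transit_max_gen;
  double cct_mean, cct_sd, cct_min, g0_mean;
  double q_threshold, q_prob, q_half_life_h;
  double d3_lifespan_h;              // mean of exponential; <=0 => immortal
  double slow_A, slow_scale;
  double hypoxia_onset_cells, cell_total;
};

static GrowPar as_growpar(const List& g) {
  GrowPar p;
  p.spercent = g["spercent"];
  p.split_transit = g["asym_split_transit"];
  p.transit_max_gen = g["transit_max_generation"];
  p.cct_mean = g["cct_mean_h"]; p.cct_sd = g["cct_sd_h"];
  p.cct_min = g["cct_min_h"];  p.g0_mean = g["g0_mean_h"];
  p.q_threshold = g["quiescence_threshold"];
  p.q_prob = g["quiescence_entry_prob"];
  p.q_half_life_h = as<double>(g["quiescent_half_life_days"]) * 24.0;
  double d3d = g["d3_lifespan_days"];
  p.d3_lifespan_h = R_finite(d3d) ? d3d * 24.0 : -1.0;
  p.slow_A = g["cct_slowing_amplitude"];
  p.slow_scale = g["cct_slowing_scale_mmHg"];
  p.hypoxia_onset_cells = g["hypoxia_onset_cells"];
  p.cell_total = g["cell_total"];
  return p;
}

struct RbPar {
  double alpha, beta, c1, c2, k, norm_po2, noncycling;
  double leth_norm;
  double lethality(double p) const {
    double x = p / k;
    double o = (1.0 + c1 * x) / (1.0 + c2 * x);
    double f = o / leth_norm;
    return f > 1.0 ? 1.0 : f;
  }
};

static RbPar as_rbpar(const List& rb) {
  RbPar r;
  r.alpha = rb["alpha"]; r.beta = rb["beta"];
  List o = rb["oer"];
  r.c1 = o["c1"]; r.c2 = o["c2"]; r.k = o["k"]; r.norm_po2 = o["norm_po2"];
  r.noncycling = rb["noncycling_factor"];
  double x = r.norm_po2 / r.k;
  r.leth_norm = (1.0 + r.c1 * x) / (1.0 + r.c2 * x);
  return r;
}

struct Ev {
  double t;
  uint32_t s;
  int i;
};
struct EvGt {  // min-heap comparator: earliest time, then insertion order
  bool operator()(const Ev& a, const Ev& b) const {
    return a.t > b.t || (a.t == b.t && a.s > b.s);
  }
};
struct EvLt {  // ascending sort order
  bool operator()(const Ev& a, const Ev& b) const {
    return a.t < b.t || (a.t == b.t && a.s < b.s);
  }
};

static const double BUCKET_H = 1.0;  // calendar bucket width, hours

struct Engine {
  std::vector<double> tev, cycst, po2v;
  std::vector<uint8_t> type, gen, state;
  std::vector<uint32_t> seq;
  std::vector<int> freelist;
  std::vector<Ev> curv;                   // current bucket, sorted
  size_t curpos;
  std::vector<Ev> active;                 // side heap (intra-bucket inserts)
  std::deque<std::vector<Ev> > cal;       // future one-hour buckets
  long long cur_bucket;
  std::vector<std::pair<int, uint32_t> > qidx;  // quiescent cells
  long long live[5];   // non-quiescent live cells per type
  long long qlive[5];  // quiescent live cells per type
  double now;
  uint32_t seqc;
  bool hypoxic_config, hypoxia_applied;
  bool proliferation;  // divisions enabled (disabled for LQ-oracle runs)
  bool have_spare;     // Box-Muller spare
  double spare;
  std::vector<double> utab, qtab;  // hypoxic inverse-CDF table

  Engine() : curpos(0), cur_bucket(0), now(0), seqc(0), hypoxic_config(false),
             hypoxia_applied(false), proliferation(true),
             have_spare(false), spare(0) {
    for (int i = 0; i < 5; ++i) { live[i] = 0; qlive[i] = 0; }
  }

  long long n_store() const {
    return live[0] + live[1] + live[2] + live[3] + live[4];
  }
  long long n_quiescent() const {
    return qlive[0] + qlive[1] + qlive[2] + qlive[3] + qlive[4];
  }
  long long n_total() const { return n_store() + n_quiescent(); }
  long long n_stem() const { return live[0] + qlive[0]; }
  long long n_basal() const {
    return live[0] + live[1] + live[2] + qlive[0] + qlive[1] + qlive[2];
  }

  // ---- RNG (all from R's uniform stream) ----
  double rexp1() {
    double u;
    do { u = unif_rand(); } while (u <= 0.0);
    return -std::log(u);
  }
  double rnorm1() {
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = unif_rand(); } while (u1 <= 0.0);
    u2 = unif_rand();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }

  // ---- event calendar ----
  bool ev_valid(const Ev& e) const {
    return state[e.i] != ST_DEAD && seq[e.i] == e.s;
  }
  void push_event(double t, int i) {
    Ev e; e.t = t; e.s = seq[i]; e.i = i;
    long long h = (long long)std::floor(t / BUCKET_H);
    if (h <= cur_bucket) {
      active.push_back(e);
      std::push_heap(active.begin(), active.end(), EvGt());
    } else {
      size_t k = (size_t)(h - cur_bucket - 1);
      if (k >= cal.size()) cal.resize(k + 1);
      cal[k].push_back(e);
    }
  }
  // pop the earliest pending event with t <= tmax into `out`
  bool next_ev(double tmax, Ev& out) {
    for (;;) {
      while (curpos < curv.size() && !ev_valid(curv[curpos])) ++curpos;
      while (!active.empty() && !ev_valid(active.front())) {
        std::pop_heap(active.begin(), active.end(), EvGt());
        active.pop_back();
      }
      bool hc = curpos < curv.size(), ha = !active.empty();
      if (hc || ha) {
        bool use_c = hc && (!ha || !EvGt()(curv[curpos], active.front()));
        const Ev& e = use_c ? curv[curpos] : active.front();
        if (e.t > tmax) return false;
        out = e;
        if (use_c) ++curpos;
        else {
          std::pop_heap(active.begin(), active.end(), EvGt());
          active.pop_back();
        }
        return true;
      }
      if (cal.empty()) return false;
      ++cur_bucket;
      curv.clear();
      curpos = 0;
      std::vector<Ev>& b = cal.front();
      for (size_t j = 0; j < b.size(); ++j)
        if (ev_valid(b[j])) curv.push_back(b[j]);
      cal.pop_front();
      std::sort(curv.begin(), curv.end(), EvLt());
    }
  }
  bool no_pending() const {
    return curpos >= curv.size() && active.empty() && cal.empty();
  }

  // ---- storage ----
  int alloc() {
    int i;
    if (!freelist.empty()) { i = freelist.back(); freelist.pop_back(); }
    else {
      i = (int)tev.size();
      tev.push_back(0); cycst.push_back(0); po2v.push_back(0);
      type.push_back(0); gen.push_back(0); state.push_back(ST_DEAD);
      seq.push_back(0);
    }
    seq[i] = seqc++;
    return i;
  }
  void release(int i) { state[i] = ST_DEAD; freelist.push_back(i); }
  void reserve(size_t n) {
    tev.reserve(n); cycst.reserve(n); po2v.reserve(n);
    type.reserve(n); gen.reserve(n); state.reserve(n); seq.reserve(n);
  }

  // drop dead slots once they dominate (keeps radiation sweeps O(live))
  void compact() {
    int nsl = (int)tev.size();
    std::vector<int> remap(nsl, -1);
    int n = 0;
    for (int i = 0; i < nsl; ++i) if (state[i] != ST_DEAD) remap[i] = n++;
    // rewrite event containers first (validity needs the old arrays)
    size_t m = 0;
    for (size_t j = 0; j < active.size(); ++j) {
      if (ev_valid(active[j])) {
        active[m] = active[j];
        active[m].i = remap[active[m].i];
        ++m;
      }
    }
    active.resize(m);
    std::make_heap(active.begin(), active.end(), EvGt());
    m = 0;
    for (size_t j = curpos; j < curv.size(); ++j) {
      if (ev_valid(curv[j])) {
        curv[m] = curv[j];
        curv[m].i = remap[curv[m].i];
        ++m;
      }
    }
    curv.resize(m);
    curpos = 0;
    for (size_t k = 0; k < cal.size(); ++k) {
      m = 0;
      std::vector<Ev>& b = cal[k];
      for (size_t j = 0; j < b.size(); ++j) {
        if (ev_valid(b[j])) { b[m] = b[j]; b[m].i = remap[b[m].i]; ++m; }
      }
      b.resize(m);
    }
    m = 0;
    for (size_t j = 0; j < qidx.size(); ++j) {
      int i = qidx[j].first;
      if (state[i] == ST_QUIESCENT && seq[i] == qidx[j].second) {
        qidx[m] = qidx[j];
        qidx[m].first = remap[i];
        ++m;
      }
    }
    qidx.resize(m);
    for (int i = 0; i < nsl; ++i) {
      int r = remap[i];
      if (r < 0 || r == i) continue;
      tev[r] = tev[i]; cycst[r] = cycst[i]; po2v[r] = po2v[i];
      type[r] = type[i]; gen[r] = gen[i]; state[r] = state[i];
      seq[r] = seq[i];
    }
    tev.resize(n); cycst.resize(n); po2v.resize(n);
    type.resize(n); gen.resize(n); state.resize(n); seq.resize(n);
    freelist.clear();
  }

  // ---- oxygen ----
  double draw_po2() {
    double u = unif_rand();
    if (!hypoxia_applied || utab.empty()) return 5.0 + 95.0 * u;
    size_t lo = 0, hi = utab.size() - 1;
    if (u <= utab[0]) return qtab[0] * (u / utab[0]);
    if (u >= utab[hi]) return qtab[hi];
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (utab[mid] <= u) lo = mid; else hi = mid;
    }
    double w = (u - utab[lo]) / (utab[hi] - utab[lo]);
    return qtab[lo] + w * (qtab[hi] - qtab[lo]);
  }

  double draw_cct(double p, const GrowPar& g) {
    double x;
    do { x = g.cct_mean + g.cct_sd * rnorm1(); } while (x < g.cct_min);
    return x * (1.0 + g.slow_A * std::exp(-p / g.slow_scale));
  }

  void make_quiescent(int i, const GrowPar& g) {
    state[i] = ST_QUIESCENT;
    cycst[i] = R_PosInf;
    tev[i] = now + rexp1() * g.q_half_life_h / M_LN2;
    push_event(tev[i], i);
    qidx.push_back(std::make_pair(i, seq[i]));
  }

  // insert a newborn cell of a live type at the current clock
  void birth(int ty, int gn, double p, const GrowPar& g) {
    int i = alloc();
    type[i] = (uint8_t)ty; gen[i] = (uint8_t)gn; po2v[i] = p;
    // hypoxia-induced quiescence, decided when the pO2 is allocated
    if (ty != TY_D3 && p < g.q_threshold && unif_rand() < g.q_prob) {
      qlive[ty]++;
      make_quiescent(i, g);
      return;
    }
    state[i] = ST_CYCLING;
    if (ty == TY_D3) {
      cycst[i] = R_NegInf;
      if (g.d3_lifespan_h > 0) {
        tev[i] = now + rexp1() * g.d3_lifespan_h;
        push_event(tev[i], i);
      } else tev[i] = R_PosInf;     // immortal: no event
    } else {
      double g0 = rexp1() * g.g0_mean;
      cycst[i] = now + g0;
      tev[i] = now + g0 + draw_cct(p, g);
      push_event(tev[i], i);
    }
    live[ty]++;
  }

  void divide(int i, const GrowPar& g, double s_eff) {
    int mt = type[i], mg = gen[i];
    double mp = po2v[i];
    int ta, tb, ga = 0, gb = 0;
    if (mt == TY_S) {
      if (unif_rand() < s_eff) { ta = tb = TY_S; }
      else {
        ta = TY_S;
        if (unif_rand() < g.split_transit) { tb = TY_T; gb = 1; }
        else tb = TY_D1;
      }
    } else if (mt == TY_T) {
      if (mg < g.transit_max_gen) { ta = tb = TY_T; ga = gb = mg + 1; }
      else { ta = tb = TY_D2; }     // terminal transit division
    } else if (mt == TY_D1) { ta = tb = TY_D2; }
    else { ta = tb = TY_D3; }       // mt == TY_D2
    live[mt]--; release(i);
    double fresh = draw_po2();
    double pa = mp, pb = fresh;
    if (unif_rand() < 0.5) { pa = fresh; pb = mp; }
    birth(ta, ga, pa, g);
    birth(tb, gb, pb, g);
  }

  void apply_hypoxia_onset(const GrowPar& g) {
    hypoxia_applied = true;
    int nslots = (int)tev.size();
    for (int i = 0; i < nslots; ++i) {
      if (state[i] != ST_CYCLING) continue;
      double p = draw_po2();
      po2v[i] = p;
      if (type[i] != TY_D3 && p < g.q_threshold && unif_rand() < g.q_prob) {
        live[type[i]]--; qlive[type[i]]++;
        seq[i] = seqc++;            // cancel the pending division
        make_quiescent(i, g);
      }
    }
  }

  // process events with tev <= tmax; stop early once n_total >= stop_count.
  // Returns 1 when the event stream is exhausted, else 0.
  int process(double tmax, long long stop_count, const GrowPar& g,
              double s_eff, bool check_onset) {
    Ev e;
    while (next_ev(tmax, e)) {
      int i = e.i;
      now = e.t;
      if (state[i] == ST_QUIESCENT) {            // necrotic death
        qlive[type[i]]--; release(i);
      } else if (type[i] == TY_D3) {             // differentiated-cell loss
        live[TY_D3]--; release(i);
      } else if (!proliferation) {
        tev[i] = R_PosInf;  // division suspended; cell stays alive
      } else {
        divide(i, g, s_eff);
        if (check_onset && !hypoxia_applied && hypoxic_config &&
            n_total() >= (long long)g.hypoxia_onset_cells) {
          apply_hypoxia_onset(g);
        }
        if (n_total() >= stop_count) return 0;
      }
    }
    if (R_finite(tmax) && now < tmax) now = tmax;
    return no_pending() ? 1 : 0;
  }

  // one dose fraction: every living cell assessed independently
  void fraction(double dose, const RbPar& r, double* killed) {
    double kill_base = 1.0 - std::exp(-r.alpha * dose - r.beta * dose * dose);
    int nslots = (int)tev.size();
    for (int i = 0; i < nslots; ++i) {
      if (state[i] == ST_DEAD) continue;
      bool noncyc = type[i] == TY_D2 || type[i] == TY_D3 ||
                    state[i] == ST_QUIESCENT || now < cycst[i];
      double p = kill_base * r.lethality(po2v[i]);
      if (noncyc) p *= r.noncycling;
      if (unif_rand() < p) {
        if (state[i] == ST_QUIESCENT) {
          qlive[type[i]]--; if (killed) killed[5 + type[i]] += 1;
        } else {
          live[type[i]]--; if (killed) killed[type[i]] += 1;
        }
        release(i);
      }
    }
  }

  int draw_k(const std::vector<double>& cum) {
    double u = unif_rand();
    for (int k = 0; k < (int)cum.size(); ++k) if (u <= cum[k]) return k;
    return (int)cum.size() - 1;
  }

  // post-fraction reoxygenation: binomial pO2 increments for every cell,
  // retrieval of a random fraction of the quiescent pool
  double rox(const GrowPar& g, double increment, double retrieval,
             int kmax) {
    long long n = n_total();
    if (n < 1) return 0;
    std::vector<double> cum(kmax + 1, 0.0);
    double pinc = 1.0 / (double)n, tot = 0.0;
    for (int k = 0; k <= kmax; ++k) {
      cum[k] = R::dbinom((double)k, (double)n, pinc, 0);
      tot += cum[k];
    }
    double acc = 0.0;
    for (int k = 0; k <= kmax; ++k) { acc += cum[k] / tot; cum[k] = acc; }
    cum[kmax] = 1.0;
    int nslots = (int)tev.size();
    for (int i = 0; i < nslots; ++i) {
      if (state[i] != ST_CYCLING) continue;
      int k = draw_k(cum);
      if (k > 0) po2v[i] = std::min(po2v[i] + k * increment, 100.0);
    }
    double retrieved = 0;
    std::vector<std::pair<int, uint32_t> > keep;
    for (size_t j = 0; j < qidx.size(); ++j) {
      int i = qidx[j].first;
      if (seq[i] != qidx[j].second || state[i] != ST_QUIESCENT)
        continue;                    // stale entry (died or re-entered)
      if (unif_rand() < retrieval) {
        int k = draw_k(cum);
        po2v[i] = std::min(po2v[i] + k * increment, 100.0);
        if (po2v[i] >= g.q_threshold) {
          qlive[type[i]]--; live[type[i]]++;
          state[i] = ST_CYCLING;
          seq[i] = seqc++;           // cancel the pending necrotic death
          double g0 = rexp1() * g.g0_mean;
          cycst[i] = now + g0;
          tev[i] = now + g0 + draw_cct(po2v[i], g);
          push_event(tev[i], i);
          retrieved += 1;
          continue;
        }
      }
      keep.push_back(qidx[j]);
    }
    qidx.swap(keep);
    return retrieved;
  }
};

static Engine* eng(SEXP ptr) {
  Rcpp::XPtr<Engine> xp(ptr);
  return xp.get();
}

// [[Rcpp::export]]
SEXP cs_new(List dist, bool hypoxia_applied) {
  Engine* e = new Engine();
  int kind = as<int>(dist["kind_code"]);
  e->hypoxic_config = kind != 0;
  e->hypoxia_applied = hypoxia_applied && e->hypoxic_config;
  if (e->hypoxic_config) {
    e->utab = as<std::vector<double> >(dist["u"]);
    e->qtab = as<std::vector<double> >(dist["q"]);
  }
  return Rcpp::XPtr<Engine>(e, true);
}

// [[Rcpp::export]]
SEXP cs_clone(SEXP ptr) {
  Engine* c = new Engine(*eng(ptr));
  return Rcpp::XPtr<Engine>(c, true);
}

// [[Rcpp::export]]
void cs_reserve(SEXP ptr, double n) { eng(ptr)->reserve((size_t)n); }

// [[Rcpp::export]]
int cs_insert(SEXP ptr, int type, int state, double po2, int gen,
              double event_time, double cyc_start) {
  Engine* e = eng(ptr);
  if (!R_finite(event_time) && type != TY_D3)
    stop("event time must be finite for cycling and quiescent cells");
  if (po2 < 0 || !R_finite(po2)) stop("pO2 must be finite and non-negative");
  int i = e->alloc();
  e->type[i] = (uint8_t)type; e->gen[i] = (uint8_t)gen;
  e->po2v[i] = po2; e->state[i] = (uint8_t)state;
  e->cycst[i] = cyc_start;
  e->tev[i] = event_time;
  if (state == ST_QUIESCENT) {
    e->qlive[type]++;
    e->qidx.push_back(std::make_pair(i, e->seq[i]));
  } else {
    e->live[type]++;
  }
  if (R_finite(event_time)) e->push_event(event_time, i);
  return i;
}

// [[Rcpp::export]]
SEXP cs_pop_next_divider(SEXP ptr) {
  Engine* e = eng(ptr);
  Ev ev;
  while (e->next_ev(R_PosInf, ev)) {
    int i = ev.i;
    e->now = std::max(e->now, ev.t);
    if (e->state[i] == ST_QUIESCENT) {          // necrotic death en route
      e->qlive[e->type[i]]--; e->release(i);
    } else if (e->type[i] == TY_D3) {
      e->live[TY_D3]--; e->release(i);
    } else {
      List cell = List::create(
        _["type"] = (int)e->type[i], _["state"] = (int)e->state[i],
        _["po2"] = e->po2v[i], _["generation"] = (int)e->gen[i],
        _["next_division_time"] = e->tev[i], _["cycle_start"] = e->cycst[i]);
      e->live[e->type[i]]--; e->release(i);
      return cell;
    }
  }
  return R_NilValue;
}

// [[Rcpp::export]]
NumericMatrix cs_census(SEXP ptr) {
  Engine* e = eng(ptr);
  NumericMatrix m(5, 3);  // types x (CYCLING, G0, HYPOXIC_QUIESCENT)
  for (int i = 0; i < (int)e->tev.size(); ++i) {
    if (e->state[i] == ST_DEAD) continue;
    int col;
    if (e->state[i] == ST_QUIESCENT) col = 2;
    else if (e->type[i] != TY_D3 && e->now < e->cycst[i]) col = 1;
    else col = 0;
    m(e->type[i], col) += 1;
  }
  return m;
}

// [[Rcpp::export]]
NumericVector cs_counts(SEXP ptr) {
  Engine* e = eng(ptr);
  NumericVector v(11);
  for (int t = 0; t < 5; ++t) {
    v[t] = (double)e->live[t]; v[5 + t] = (double)e->qlive[t];
  }
  v[10] = (double)e->n_total();
  v.attr("names") = CharacterVector::create("S", "T", "D1", "D2", "D3",
    "q_S", "q_T", "q_D1", "q_D2", "q_D3", "total");
  return v;
}

// [[Rcpp::export]]
double cs_now(SEXP ptr) { return eng(ptr)->now; }

// [[Rcpp::export]]
bool cs_hypoxia_applied(SEXP ptr) { return eng(ptr)->hypoxia_applied; }

// [[Rcpp::export]]
NumericVector cs_po2_values(SEXP ptr, bool include_quiescent) {
  Engine* e = eng(ptr);
  std::vector<double> out;
  out.reserve((size_t)e->n_total());
  for (int i = 0; i < (int)e->tev.size(); ++i) {
    if (e->state[i] == ST_DEAD) continue;
    if (!include_quiescent && e->state[i] == ST_QUIESCENT) continue;
    out.push_back(e->po2v[i]);
  }
  return wrap(out);
}

// [[Rcpp::export]]
NumericVector cs_quiescent_po2(SEXP ptr) {
  Engine* e = eng(ptr);
  std::vector<double> out;
  for (int i = 0; i < (int)e->tev.size(); ++i)
    if (e->state[i] == ST_QUIESCENT) out.push_back(e->po2v[i]);
  return wrap(out);
}

// allocate fresh pO2 to every living cell from the hypoxic histogram,
// with quiescence evaluated for each (fires once, at the onset threshold)
// [[Rcpp::export]]
void cs_apply_onset(SEXP ptr, List growth) {
  Engine* e = eng(ptr);
  if (!e->hypoxic_config)
    stop("store was built with the oxic distribution; no hypoxia onset");
  if (e->hypoxia_applied) stop("hypoxia onset already applied");
  GrowPar g = as_growpar(growth);
  e->apply_hypoxia_onset(g);
}

// seed the tumour with a single oxic stem cell at time 0
// [[Rcpp::export]]
void cs_seed_stem(SEXP ptr, List growth) {
  Engine* e = eng(ptr);
  GrowPar g = as_growpar(growth);
  double p = 5.0 + 95.0 * unif_rand();
  e->now = 0;
  e->birth(TY_S, 0, p, g);
}

// [[Rcpp::export]]
List grow_cpp(SEXP ptr, List growth, double target, double s_eff,
              double record_factor) {
  Engine* e = eng(ptr);
  GrowPar g = as_growpar(growth);
  std::vector<double> rec;  // time, S,T,D1,D2,D3, quiescent
  long long next_cp = std::max(e->n_total(), 1LL);
  int status = 0;
  while (e->n_total() < (long long)target) {
    long long stop = std::min((long long)target, next_cp);
    int r = e->process(R_PosInf, stop, g, s_eff, true);
    if (r == 1) {
      status = e->n_total() == 0 ? 1 : 2;  // extinct / stalled
      break;
    }
    if (e->n_total() >= next_cp) {
      rec.push_back(e->now);
      for (int t = 0; t < 5; ++t)
        rec.push_back((double)(e->live[t] + e->qlive[t]));
      rec.push_back((double)e->n_quiescent());
      next_cp = std::max(next_cp + 1,
                         (long long)std::ceil(next_cp * record_factor));
    }
    Rcpp::checkUserInterrupt();
  }
  int ncol = 7, nrow = (int)rec.size() / ncol;
  NumericMatrix series(ncol, nrow);
  std::copy(rec.begin(), rec.end(), series.begin());
  return List::create(_["status"] = status, _["series"] = transpose(series),
                      _["time_h"] = e->now, _["total"] = (double)e->n_total());
}

// [[Rcpp::export]]
NumericVector apply_fraction_cpp(SEXP ptr, double dose, List rb) {
  Engine* e = eng(ptr);
  RbPar r = as_rbpar(rb);
  NumericVector killed(10);
  e->fraction(dose, r, killed.begin());
  killed.attr("names") = CharacterVector::create("S", "T", "D1", "D2", "D3",
    "q_S", "q_T", "q_D1", "q_D2", "q_D3");
  return killed;
}

// [[Rcpp::export]]
double rox_event_cpp(SEXP ptr, List growth, double increment_mmHg,
                     double retrieval_frac, int kmax) {
  Engine* e = eng(ptr);
  GrowPar g = as_growpar(growth);
  return e->rox(g, increment_mmHg, retrieval_frac, kmax);
}

// advance the clock (proliferation + necrosis) up to tmax
// [[Rcpp::export]]
int cs_advance(SEXP ptr, double tmax, List growth, double s_eff,
               bool proliferation) {
  Engine* e = eng(ptr);
  GrowPar g = as_growpar(growth);
  e->proliferation = proliferation;
  int r = e->process(tmax, LLONG_MAX, g, s_eff, true);
  e->proliferation = true;
  return r;
}

// full fractionated treatment course
// [[Rcpp::export]]
List treat_cpp(SEXP ptr, List growth, List rb, List sched) {
  Engine* e = eng(ptr);
  GrowPar g = as_growpar(growth);
  RbPar r = as_rbpar(rb);
  double dose = sched["dose_per_fraction"];
  int days_per_week = sched["treatment_days_per_week"];
  int max_weeks = sched["max_weeks"];
  double ar_onset_week = sched["ar_onset_week"];      // NA => disabled
  double ar_boost = sched["ar_boost_factor"];
  double rox_onset_week = sched["rox_onset_week"];    // NA => disabled
  double rox_delay = sched["rox_delay_h"];
  double rox_increment = sched["rox_increment_mmHg"];
  double rox_retrieval = sched["rox_quiescent_retrieval"];
  int rox_kmax = sched["rox_max_increments"];
  bool proliferation = sched["proliferation"];
  bool sf_scaling = sched["sf_scaling"];

  // increment size and quiescent retrieval scale linearly with (1 - SF),
  // referenced to the conventional 2 Gy fraction
  if (sf_scaling) {
    double ref = 1.0 - std::exp(-r.alpha * 2.0 - r.beta * 4.0);
    double cur = 1.0 - std::exp(-r.alpha * dose - r.beta * dose * dose);
    rox_increment *= cur / ref;
    rox_retrieval = std::min(rox_retrieval * cur / ref, 1.0);
  }

  double t0 = e->now;
  bool ar_on = R_finite(ar_onset_week);
  bool rox_on = R_finite(rox_onset_week);
  double t_ar = ar_on ? t0 + ar_onset_week * 168.0 : R_PosInf;
  double s_plain = g.spercent;
  double s_boost = ar_on ? std::min(g.spercent * ar_boost, 1.0) : g.spercent;

  e->proliferation = proliferation;
  std::vector<double> rec;
  int fx = 0, day = 0;
  int ep_stem = -1, ep_basal = -1, ep_total = -1;
  bool controlled = false;

  while (day < max_weeks * 7) {
    double day_start = t0 + day * 24.0;
    bool weekday = (day % 7) < days_per_week;
    if (weekday && e->n_total() > 0) {
      e->process(day_start, LLONG_MAX, g,
                 day_start >= t_ar ? s_boost : s_plain, true);
      ++fx;
      e->fraction(dose, r, 0);
      rec.push_back((double)fx); rec.push_back(day_start - t0);
      rec.push_back(dose);
      for (int t = 0; t < 5; ++t)
        rec.push_back((double)(e->live[t] + e->qlive[t]));
      rec.push_back((double)e->n_quiescent());
      if (rox_on && day_start - t0 >= rox_onset_week * 168.0 - 1e-9 &&
          e->n_total() > 0) {
        double t_rox = day_start + rox_delay;
        e->process(t_rox, LLONG_MAX, g, t_rox >= t_ar ? s_boost : s_plain,
                   true);
        e->rox(g, rox_increment, rox_retrieval, rox_kmax);
      }
    }
    double day_end = day_start + 24.0;
    e->process(day_end, LLONG_MAX, g, day_end >= t_ar ? s_boost : s_plain,
               true);
    if ((long long)e->tev.size() > std::max(4 * e->n_total(), 65536LL))
      e->compact();
    // endpoints: first fraction after which the population stays at zero
    if (e->n_stem() == 0) { if (ep_stem < 0) ep_stem = fx; }
    else ep_stem = -1;
    if (e->n_basal() == 0) { if (ep_basal < 0) ep_basal = fx; }
    else ep_basal = -1;
    if (e->n_total() == 0) {
      if (ep_total < 0) ep_total = fx;
      controlled = true;
      break;
    }
    ++day;
    Rcpp::checkUserInterrupt();
  }
  e->proliferation = true;
  int ncol = 9, nrow = (int)rec.size() / ncol;
  NumericMatrix m(ncol, nrow);
  std::copy(rec.begin(), rec.end(), m.begin());
  return List::create(
    _["per_fraction"] = transpose(m),
    _["fractions_delivered"] = fx,
    _["controlled"] = controlled,
    _["stem_endpoint"] = ep_stem,
    _["basal_endpoint"] = ep_basal,
    _["control_endpoint"] = ep_total);
}
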