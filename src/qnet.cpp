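// Discrete-event simulation of the closed GLUT4 recycling queuing network.
//
// Stations (cyclic routing): endosome store (infinite server, Exp(muS)) ->
// one of M microtubules chosen uniformly (capacity L, FIFO, transit
// Exp(muM), advancement increments Exp(L*muM)) -> associated fusion site
// (single server, zero buffer, Exp(muF), active/inactive per insulin
// phase) -> plasma membrane (infinite server, Exp(muP)) -> endosome.
//
// A vesicle finding its chosen microtubule full is blocked and redraws a
// full endosome service.  The head of a microtubule departs at
//   max(entry + transit, departure(predecessor) + increment, site free & active)
// evaluated lazily in FIFO order: the increment gating the new head is
// drawn at the instant its predecessor departs.  Inactive fusion sites
// accept nothing and hence stall their microtubule.
//
// All randomness comes from R's RNG so runs are reproducible under
// set.seed(); callers seed one sub-stream per run.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

enum Station { ST_ENDO = 0, ST_MT = 1, ST_FUS = 2, ST_MEM = 3 };

// Event types ordered by tie-break priority: membrane > fusion >
// microtubule > endosome.  Exponential clocks make ties measure-zero; the
// fixed order only serves determinism.
enum EvType { EV_MEM_DONE = 0, EV_FUS_DONE = 1, EV_MT_READY = 2, EV_ENDO_DONE = 3 };

struct Event {
  double t;
  int type;
  int id;  // vesicle id for endosome/membrane events, queue index otherwise
};

struct EventLater {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.type != b.type) return a.type > b.type;
    return a.id > b.id;
  }
};

// log codes, mapped to labels R-side
enum LogCode {
  LOG_ENDO_DEPART = 0, LOG_ENDO_BLOCKED = 1, LOG_MT_DEPART = 2,
  LOG_MT_HEAD_BLOCKED = 3, LOG_FUS_DONE = 4, LOG_MEM_DEPART = 5,
  LOG_PHASE_SWITCH = 6
};

class QNet {
public:
  int N, M, L;
  double muS, muM, muF, muP, pB, pI;
  bool insulin_phase;

  std::vector<int> station;
  std::vector<char> visited;
  std::vector<char> basal_active, insulin_active;
  std::vector<std::deque<std::pair<int, double> > > mtq;  // (vesicle, transit end)
  std::vector<char> head_waiting;
  std::vector<int> fus_occ;  // occupant vesicle or -1

  double now;
  int n_endo, n_mt, n_fus, n_mem;
  double acc[4];       // time-integrated occupancy per station
  long long n_events;

  bool logging;
  std::vector<double> log_t;
  std::vector<int> log_code, log_ves, log_station, log_q;

  std::priority_queue<Event, std::vector<Event>, EventLater> heap;

  QNet(NumericVector par, bool insulin, bool log_events) {
    N = (int)par["n_vesicles"];
    M = (int)par["n_microtubules"];
    L = (int)par["microtubule_capacity"];
    muS = par["rate_store"];
    muM = par["rate_microtubule"];
    muF = par["rate_fusion"];
    muP = par["rate_membrane"];
    pB = par["p_basal"];
    pI = par["p_insulin"];
    insulin_phase = insulin;
    logging = log_events;

    now = 0.0;
    n_events = 0;
    acc[0] = acc[1] = acc[2] = acc[3] = 0.0;
    station.assign(N, ST_ENDO);
    visited.assign(N, 0);
    mtq.assign(M, std::deque<std::pair<int, double> >());
    head_waiting.assign(M, 0);
    fus_occ.assign(M, -1);
    n_endo = N; n_mt = 0; n_fus = 0; n_mem = 0;

    // one persistent uniform per site couples the two activity states:
    // raising the active probability can only activate sites
    basal_active.resize(M);
    insulin_active.resize(M);
    for (int m = 0; m < M; ++m) {
      double u = unif_rand();
      basal_active[m] = (u < pB);
      insulin_active[m] = (u < pI);
    }
    for (int v = 0; v < N; ++v)
      push(draw_exp(muS), EV_ENDO_DONE, v);
  }

  double draw_exp(double rate) { return now + exp_rand() / rate; }

  void push(double t, int type, int id) {
    Event e; e.t = t; e.type = type; e.id = id;
    heap.push(e);
  }

  bool site_active(int m) const {
    return insulin_phase ? (insulin_active[m] != 0) : (basal_active[m] != 0);
  }

  void log_row(int code, int ves, int st, int q) {
    if (!logging) return;
    log_t.push_back(now); log_code.push_back(code);
    log_ves.push_back(ves); log_station.push_back(st); log_q.push_back(q);
  }

  void check_conservation() const {
    if (n_endo + n_mt + n_fus + n_mem != N)
      stop("internal simulator error: vesicle conservation violated at t=%f", now);
  }

  // move the head of microtubule m into its (active, idle) fusion site
  void transfer_head(int m) {
    std::pair<int, double> head = mtq[m].front();
    mtq[m].pop_front();
    int v = head.first;
    station[v] = ST_FUS; --n_mt; ++n_fus;
    fus_occ[m] = v;
    head_waiting[m] = 0;
    push(draw_exp(muF), EV_FUS_DONE, m);
    log_row(LOG_MT_DEPART, v, ST_FUS, m);
    if (!mtq[m].empty()) {
      // promotion: the advancement increment gating the new head is drawn
      // at the predecessor's departure epoch
      double gate = now + exp_rand() / (L * muM);
      double ready = std::max(mtq[m].front().second, gate);
      push(ready, EV_MT_READY, m);
    }
  }

  void handle(const Event& e) {
    switch (e.type) {
    case EV_ENDO_DONE: {
      int v = e.id;
      int j = (int)(unif_rand() * M);
      if (j >= M) j = M - 1;
      if ((int)mtq[j].size() >= L) {
        // entry blocking: redraw a full endosome service
        push(draw_exp(muS), EV_ENDO_DONE, v);
        log_row(LOG_ENDO_BLOCKED, v, ST_ENDO, j);
      } else {
        bool was_empty = mtq[j].empty();
        double transit_end = draw_exp(muM);
        mtq[j].push_back(std::make_pair(v, transit_end));
        station[v] = ST_MT; --n_endo; ++n_mt;
        log_row(LOG_ENDO_DEPART, v, ST_MT, j);
        if (was_empty)
          push(transit_end, EV_MT_READY, j);
      }
      break;
    }
    case EV_MT_READY: {
      int m = e.id;
      if (site_active(m) && fus_occ[m] < 0) {
        transfer_head(m);
      } else {
        head_waiting[m] = 1;
        log_row(LOG_MT_HEAD_BLOCKED, mtq[m].front().first, ST_MT, m);
      }
      break;
    }
    case EV_FUS_DONE: {
      int m = e.id;
      int v = fus_occ[m];
      fus_occ[m] = -1;
      station[v] = ST_MEM; --n_fus; ++n_mem;
      visited[v] = 1;
      push(draw_exp(muP), EV_MEM_DONE, v);
      log_row(LOG_FUS_DONE, v, ST_MEM, m);
      if (head_waiting[m] && site_active(m))
        transfer_head(m);
      break;
    }
    case EV_MEM_DONE: {
      int v = e.id;
      station[v] = ST_ENDO; --n_mem; ++n_endo;
      push(draw_exp(muS), EV_ENDO_DONE, v);
      log_row(LOG_MEM_DEPART, v, ST_ENDO, -1);
      break;
    }
    }
    ++n_events;
    check_conservation();
  }

  void accumulate(double t_new) {
    double dt = t_new - now;
    acc[0] += dt * n_endo; acc[1] += dt * n_mt;
    acc[2] += dt * n_fus;  acc[3] += dt * n_mem;
  }

  void advance_to(double t_end) {
    while (!heap.empty() && heap.top().t <= t_end) {
      Event e = heap.top();
      heap.pop();
      accumulate(e.t);
      now = e.t;
      handle(e);
    }
    accumulate(t_end);
    now = t_end;
  }

  // basal -> insulin: a superset of sites becomes active (coupled
  // uniforms), so only activations can occur; waiting heads on newly
  // active idle sites transfer immediately at the switch instant
  void switch_to_insulin() {
    insulin_phase = true;
    log_row(LOG_PHASE_SWITCH, -1, -1, -1);
    for (int m = 0; m < M; ++m)
      if (head_waiting[m] && site_active(m) && fus_occ[m] < 0)
        transfer_head(m);
  }

  void reset_visited() {
    for (int v = 0; v < N; ++v)
      visited[v] = (station[v] == ST_MEM);
  }

  int unique_visitors() const {
    int c = 0;
    for (size_t v = 0; v < visited.size(); ++v) c += visited[v];
    return c;
  }

  IntegerVector counts() const {
    IntegerVector out = IntegerVector::create(
      _["endosome"] = n_endo, _["microtubule"] = n_mt,
      _["fusion"] = n_fus, _["membrane"] = n_mem);
    return out;
  }

  List event_log() const {
    return List::create(_["time"] = log_t, _["code"] = log_code,
                        _["vesicle"] = log_ves, _["station"] = log_station,
                        _["queue_index"] = log_q);
  }
};

}  // namespace

// Run the full in-silico protocol suite within one simulation run:
// warm-up in basal phase, basal uptake, insulin switch + transition,
// equilibration, insulin uptake.  Returns the three measurement vectors.
// [[Rcpp::export(name = ".qnet_run_suite_cpp")]]
List qnet_run_suite_cpp(NumericVector par,
                        NumericVector transition_times,
                        NumericVector basal_uptake_times,
                        NumericVector insulin_uptake_times,
                        double warmup = 500.0,
                        double equilibration = 500.0) {
  QNet net(par, false, false);

  // basal warm-up
  net.advance_to(warmup);

  // basal uptake: visited flags restart from the current membrane occupants
  double t0 = net.now;
  net.reset_visited();
  int nb = basal_uptake_times.size();
  NumericVector basal_up(nb);
  for (int j = 0; j < nb; ++j) {
    net.advance_to(t0 + basal_uptake_times[j]);
    basal_up[j] = net.unique_visitors();
  }

  // transition: t = 0 sampled at the switch instant, before any
  // insulin-phase event fires
  double t1 = net.now;
  int nt = transition_times.size();
  NumericVector trans(nt);
  trans[0] = net.n_mem;
  net.switch_to_insulin();
  for (int j = 1; j < nt; ++j) {
    net.advance_to(t1 + transition_times[j]);
    trans[j] = net.n_mem;
  }

  // equilibrate to the insulin steady state, then insulin uptake
  net.advance_to(t1 + equilibration);
  double t2 = net.now;
  net.reset_visited();
  int ni = insulin_uptake_times.size();
  NumericVector insulin_up(ni);
  for (int j = 0; j < ni; ++j) {
    net.advance_to(t2 + insulin_uptake_times[j]);
    insulin_up[j] = net.unique_visitors();
  }

  return List::create(
    _["transition"] = trans,
    _["basal_uptake"] = basal_up,
    _["insulin_uptake"] = insulin_up,
    _["n_events"] = (double)net.n_events,
    _["final_counts"] = net.counts());
}

// Advance a freshly initialised network (all vesicles at the endosome)
// in a fixed activity phase.  Used for unit-level checks: occupancy time
// fractions, conservation, event logs, plasma-membrane traces.
// [[Rcpp::export(name = ".qnet_advance_cpp")]]
List qnet_advance_cpp(NumericVector par,
                      bool insulin,
                      double t_end,
                      NumericVector sample_times,
                      bool log_events = false) {
  QNet net(par, insulin, log_events);
  net.reset_visited();  // none visited: membrane starts empty

  int ns = sample_times.size();
  NumericVector pm(ns), uv(ns);
  for (int j = 0; j < ns; ++j) {
    net.advance_to(sample_times[j]);
    pm[j] = net.n_mem;
    uv[j] = net.unique_visitors();
  }
  net.advance_to(t_end);

  NumericVector frac(4);
  if (t_end > 0)
    for (int s = 0; s < 4; ++s) frac[s] = net.acc[s] / t_end;
  else
    frac[0] = 1.0;  // zero-length interval: everything still at the endosome
  frac.names() = CharacterVector::create("endosome", "microtubule",
                                         "fusion", "membrane");

  LogicalVector ba(net.M), ia(net.M);
  for (int m = 0; m < net.M; ++m) {
    ba[m] = net.basal_active[m] != 0;
    ia[m] = net.insulin_active[m] != 0;
  }

  return List::create(
    _["time"] = net.now,
    _["counts"] = net.counts(),
    _["pm_levels"] = pm,
    _["unique_visitors"] = uv,
    _["occupancy_fractions"] = frac,
    _["n_visited"] = net.unique_visitors(),
    _["n_events"] = (double)net.n_events,
    _["basal_active"] = ba,
    _["insulin_active"] = ia,
    _["event_log"] = net.event_log());
}
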