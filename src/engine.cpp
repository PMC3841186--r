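// Discrete-event core: neurons accumulate charge delivered along delayed
// synapses; a neuron fires when its charge reaches threshold outside its
// refractory period.  Periodic "tick" events measure the windowed firing
// rate and let the affective controller broadcast a threshold change.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int EV_CHARGE = 0;   // charge addition (input pulses carry syn = -1)
const int EV_TICK = 2;     // rate measurement / threshold adjustment
const int EV_DCHANGE = 3;  // desired-firing-rate change

struct Ev {
  double time;
  int prio;   // 0 = ordinary event, 1 = tick (ticks run after same-time events)
  long long seq;
  int type;
  int neuron;
  int syn;
  double amount;
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.time != b.time) return a.time > b.time;
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.seq > b.seq;
  }
};

inline double clamp1(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return -1.0;
  return x;
}

// 20 bins over [-1, 1]: [x, x+0.1) except the last, which is closed.
inline int wbin(double w) {
  int b = (int)std::floor((w + 1.0) * 10.0 + 1e-9);
  if (b < 0) b = 0;
  if (b > 19) b = 19;
  return b;
}

class Simulator {
 public:
  int n;
  std::vector<double> thr, chg, last_fire, refr;
  std::vector<int> s_pre, s_post;
  std::vector<double> s_w, s_dist, s_lastpl;
  std::vector<int> out_start, out_idx;

  bool plast_on;
  double plast_step, plast_refr;
  int ctrl_mode;  // 0 none, 1 simple (uses e), 2 complex (uses ebar)
  double alpha, lambda, wwin, d, ebar;
  double pulse_amp;

  double now;
  long long seq, win_count, events_done;
  double next_snap, snap_every;
  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;

  // per-run recorders
  std::vector<double> fire_t;
  std::vector<int> fire_id;
  std::vector<double> tick_t, tick_thr, tick_d, tick_rate;
  std::vector<double> snap_t;
  std::vector<std::vector<int> > snaps;

  Simulator(NumericVector threshold, NumericVector refractory,
            IntegerVector pre, IntegerVector post,
            NumericVector weight, NumericVector dist,
            bool plasticity_on, double step, double p_refr,
            int mode, double a, double l, double w, double d0,
            double pulse)
      : n(threshold.size()),
        thr(threshold.begin(), threshold.end()),
        chg(n, 0.0),
        last_fire(n, R_NegInf),
        refr(refractory.begin(), refractory.end()),
        s_pre(pre.begin(), pre.end()),
        s_post(post.begin(), post.end()),
        s_w(weight.begin(), weight.end()),
        s_dist(dist.begin(), dist.end()),
        s_lastpl(weight.size(), R_NegInf),
        plast_on(plasticity_on), plast_step(step), plast_refr(p_refr),
        ctrl_mode(mode), alpha(a), lambda(l), wwin(w), d(d0), ebar(0.0),
        pulse_amp(pulse),
        now(0.0), seq(0), win_count(0), events_done(0),
        next_snap(0.0), snap_every(0.0) {
    int m = (int)s_pre.size();
    out_start.assign(n + 1, 0);
    for (int s = 0; s < m; ++s) out_start[s_pre[s] + 1]++;
    for (int i = 0; i < n; ++i) out_start[i + 1] += out_start[i];
    out_idx.assign(m, 0);
    std::vector<int> cur(out_start.begin(), out_start.end() - 1);
    for (int s = 0; s < m; ++s) out_idx[cur[s_pre[s]]++] = s;
  }

  void push_ev(double t, int prio, int type, int neuron, int syn, double amt) {
    Ev e;
    e.time = t; e.prio = prio; e.seq = seq++;
    e.type = type; e.neuron = neuron; e.syn = syn; e.amount = amt;
    q.push(e);
  }

  bool plast_eligible(int s, double t) const {
    return s_lastpl[s] == R_NegInf || t - s_lastpl[s] >= plast_refr;
  }

  double mean_thr() const {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += thr[i];
    return m / n;
  }

  void take_snapshot(double t) {
    std::vector<int> h(20, 0);
    for (size_t s = 0; s < s_w.size(); ++s) h[wbin(s_w[s])]++;
    snap_t.push_back(t);
    snaps.push_back(h);
  }

  void handle(const Ev& ev) {
    const double t = ev.time;
    events_done++;
    if (ev.type == EV_CHARGE) {
      int i = ev.neuron;
      double c = clamp1(chg[i] + ev.amount);
      bool refractory = last_fire[i] > R_NegInf && t - last_fire[i] < refr[i];
      if (refractory) {
        // charge accumulates but the neuron cannot fire; an arrival during
        // the refractory period depresses the carrying synapse (LTD)
        chg[i] = c;
        if (plast_on && ev.syn >= 0 && plast_eligible(ev.syn, t)) {
          s_w[ev.syn] = clamp1(s_w[ev.syn] - plast_step);
          s_lastpl[ev.syn] = t;
        }
      } else if (c >= thr[i]) {
        chg[i] = 0.0;
        last_fire[i] = t;
        fire_t.push_back(t);
        fire_id.push_back(i);
        win_count++;
        for (int k = out_start[i]; k < out_start[i + 1]; ++k) {
          int s = out_idx[k];
          push_ev(t + s_dist[s], 0, EV_CHARGE, s_post[s], s, s_w[s]);
        }
        // the arrival that pushed charge over threshold potentiates its synapse
        if (plast_on && ev.syn >= 0 && plast_eligible(ev.syn, t)) {
          s_w[ev.syn] = clamp1(s_w[ev.syn] + plast_step);
          s_lastpl[ev.syn] = t;
        }
      } else {
        chg[i] = c;
      }
    } else if (ev.type == EV_TICK) {
      // firing rate in firings per unit time: windowed count / window
      // length, so the network-wide maximum is the neuron count
      double f = (double)win_count / wwin;
      win_count = 0;
      double e = f - d;
      ebar = lambda * ebar + (1.0 - lambda) * e;
      if (ctrl_mode > 0) {
        double err = (ctrl_mode == 1) ? e : ebar;
        double delta = alpha * err;
        for (int i = 0; i < n; ++i) {
          double nt = thr[i] + delta;
          // the broadcast has no effect on a neuron it would push out of [-1,1]
          if (nt >= -1.0 && nt <= 1.0) thr[i] = nt;
        }
      }
      tick_t.push_back(t);
      tick_rate.push_back(f);
      tick_thr.push_back(mean_thr());
      tick_d.push_back(d);
      if (snap_every > 0 && t + 1e-9 >= next_snap) {
        take_snapshot(t);
        while (next_snap <= t + 1e-9) next_snap += snap_every;
      }
    } else if (ev.type == EV_DCHANGE) {
      d = ev.amount;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP sim_create(NumericVector threshold, NumericVector refractory,
                IntegerVector pre, IntegerVector post,
                NumericVector weight, NumericVector dist,
                bool plasticity_on, double plasticity_step,
                double plasticity_refractory,
                int controller_mode, double alpha, double lambda,
                double window, double desired, double pulse_amplitude) {
  Simulator* sim = new Simulator(threshold, refractory, pre, post, weight,
                                 dist, plasticity_on, plasticity_step,
                                 plasticity_refractory, controller_mode,
                                 alpha, lambda, window, desired,
                                 pulse_amplitude);
  XPtr<Simulator> p(sim, true);
  return p;
}

// [[Rcpp::export]]
List sim_run(SEXP ptr, double t_end, NumericVector pulse_time,
             IntegerVector pulse_neuron, NumericVector d_time,
             NumericVector d_value, double snapshot_every) {
  XPtr<Simulator> sim(ptr);
  if (t_end < sim->now) stop("t_end precedes current simulation time");

  sim->fire_t.clear(); sim->fire_id.clear();
  sim->tick_t.clear(); sim->tick_rate.clear();
  sim->tick_thr.clear(); sim->tick_d.clear();
  sim->snap_t.clear(); sim->snaps.clear();
  sim->snap_every = snapshot_every;
  if (snapshot_every > 0) {
    double k = std::floor(sim->now / snapshot_every + 1e-9) + 1.0;
    sim->next_snap = k * snapshot_every;
  }

  // ticks at exact multiples of the window, strictly after `now`
  double w = sim->wwin;
  for (double k = std::floor(sim->now / w + 1e-9) + 1.0;
       k * w <= t_end + 1e-9; k += 1.0) {
    sim->push_ev(k * w, 1, EV_TICK, -1, -1, 0.0);
  }
  for (int i = 0; i < d_time.size(); ++i) {
    if (d_time[i] < sim->now) stop("desired-rate change scheduled in the past");
    sim->push_ev(d_time[i], 0, EV_DCHANGE, -1, -1, d_value[i]);
  }
  for (int i = 0; i < pulse_time.size(); ++i) {
    if (pulse_time[i] < sim->now) stop("input pulse scheduled in the past");
    sim->push_ev(pulse_time[i], 0, EV_CHARGE, pulse_neuron[i], -1,
                 sim->pulse_amp);
  }

  while (!sim->q.empty() && sim->q.top().time <= t_end + 1e-9) {
    Ev ev = sim->q.top();
    sim->q.pop();
    sim->handle(ev);
  }
  sim->now = t_end;

  IntegerMatrix hist(20, (int)sim->snaps.size());
  for (size_t j = 0; j < sim->snaps.size(); ++j)
    for (int b = 0; b < 20; ++b) hist(b, (int)j) = sim->snaps[j][b];

  return List::create(
      _["firing_time"] = wrap(sim->fire_t),
      _["firing_neuron"] = wrap(sim->fire_id),
      _["tick_time"] = wrap(sim->tick_t),
      _["tick_rate"] = wrap(sim->tick_rate),
      _["tick_threshold"] = wrap(sim->tick_thr),
      _["tick_desired"] = wrap(sim->tick_d),
      _["snapshot_time"] = wrap(sim->snap_t),
      _["snapshot_hist"] = hist,
      _["events_processed"] = (double)sim->events_done);
}

// [[Rcpp::export]]
List sim_state(SEXP ptr) {
  XPtr<Simulator> sim(ptr);
  return List::create(
      _["time"] = sim->now,
      _["charge"] = wrap(sim->chg),
      _["threshold"] = wrap(sim->thr),
      _["weight"] = wrap(sim->s_w),
      _["last_fire"] = wrap(sim->last_fire),
      _["smoothed_error"] = sim->ebar,
      _["desired"] = sim->d,
      _["pending_events"] = (double)sim->q.size());
}

// ---- standalone event queue (time, insertion-order tie-break) ----

typedef std::priority_queue<Ev, std::vector<Ev>, EvCmp> EvQueue;

struct TaggedQueue {
  EvQueue q;
  long long seq;
  TaggedQueue() : seq(0) {}
};

// [[Rcpp::export]]
SEXP eq_create() {
  XPtr<TaggedQueue> p(new TaggedQueue(), true);
  return p;
}

// [[Rcpp::export]]
void eq_push(SEXP ptr, double time, int id) {
  XPtr<TaggedQueue> tq(ptr);
  Ev e;
  e.time = time; e.prio = 0; e.seq = tq->seq++;
  e.type = 0; e.neuron = id; e.syn = -1; e.amount = 0.0;
  tq->q.push(e);
}

// [[Rcpp::export]]
List eq_pop(SEXP ptr) {
  XPtr<TaggedQueue> tq(ptr);
  if (tq->q.empty())
    return List::create(_["exhausted"] = true);
  Ev e = tq->q.top();
  tq->q.pop();
  return List::create(_["exhausted"] = false, _["time"] = e.time,
                      _["id"] = e.neuron);
}

// [[Rcpp::export]]
int eq_size(SEXP ptr) {
  XPtr<TaggedQueue> tq(ptr);
  return (int)tq->q.size();
}
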