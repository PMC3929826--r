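#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>

// Event-calendar core of the clinic simulation.
//
// All randomness (arrival times, routes, service durations) is sampled in R
// beforehand; this function is a deterministic replay of a FIFO multi-server
// network with scheduled stations. Event ordering at equal times:
// station_open < queue_join < service_end, then by patient id, so the FIFO
// order within a station is (queue_join time, patient id).

namespace {

enum EvKind { EV_OPEN = 0, EV_JOIN = 1, EV_END = 2 };

struct Event {
  double t;
  int kind;
  int id;  // patient index for JOIN/END, station index for OPEN
};

struct EventLater {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.kind != b.kind) return a.kind > b.kind;
    return a.id > b.id;
  }
};

}  // namespace

// [[Rcpp::export(name = ".des_core")]]
Rcpp::List des_core(Rcpp::NumericVector arrival,
                    Rcpp::IntegerVector route,      // 0-based station index
                    Rcpp::IntegerVector route_off,  // 0-based offset per patient
                    Rcpp::IntegerVector route_len,
                    Rcpp::NumericVector service,    // parallel to route
                    Rcpp::NumericVector open_time,
                    Rcpp::NumericVector close_time,
                    Rcpp::IntegerVector n_servers,
                    Rcpp::LogicalVector overtime) {
  const int n_pat = arrival.size();
  const int n_st = open_time.size();
  const int n_vis = route.size();

  Rcpp::NumericVector queue_join(n_vis, NA_REAL);
  Rcpp::NumericVector service_start(n_vis, NA_REAL);
  Rcpp::NumericVector service_end(n_vis, NA_REAL);

  std::vector<int> step(n_pat, 0);          // current position on own route
  std::vector<bool> is_open(n_st, false);
  std::vector<int> busy(n_st, 0);
  std::vector<std::deque<int> > q(n_st);

  std::priority_queue<Event, std::vector<Event>, EventLater> cal;
  for (int s = 0; s < n_st; ++s) cal.push(Event{open_time[s], EV_OPEN, s});
  for (int p = 0; p < n_pat; ++p)
    if (route_len[p] > 0) cal.push(Event{arrival[p], EV_JOIN, p});

  // Start services at `st` while a server is free and starting is allowed.
  auto try_start = [&](int st, double t) {
    if (!is_open[st]) return;
    if (!overtime[st] && t > close_time[st]) return;  // hard cutoff
    while (busy[st] < n_servers[st] && !q[st].empty()) {
      int p = q[st].front();
      q[st].pop_front();
      int idx = route_off[p] + step[p];
      service_start[idx] = t;
      service_end[idx] = t + service[idx];  // provisional; confirmed at EV_END
      ++busy[st];
      cal.push(Event{t + service[idx], EV_END, p});
    }
  };

  while (!cal.empty()) {
    Event ev = cal.top();
    cal.pop();
    if (ev.kind == EV_OPEN) {
      is_open[ev.id] = true;
      try_start(ev.id, ev.t);
    } else if (ev.kind == EV_JOIN) {
      int p = ev.id;
      int idx = route_off[p] + step[p];
      int st = route[idx];
      queue_join[idx] = ev.t;
      q[st].push_back(p);
      try_start(st, ev.t);
    } else {  // EV_END
      int p = ev.id;
      int idx = route_off[p] + step[p];
      int st = route[idx];
      --busy[st];
      ++step[p];
      if (step[p] < route_len[p]) cal.push(Event{ev.t, EV_JOIN, p});
      try_start(st, ev.t);
    }
  }

  return Rcpp::List::create(Rcpp::Named("queue_join") = queue_join,
                            Rcpp::Named("service_start") = service_start,
                            Rcpp::Named("service_end") = service_end);
}
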