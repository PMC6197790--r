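// Production risk-plot engine: per-beat token projection onto stairs,
// per-stair spring drainage into the valley, absorbing stuck stairs, and
// window resets. The naive token-by-token reference simulator lives in R
// (rp_reference) as an independent code path.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// record_level: 0 = window summaries only, 1 = post-drain snapshot per beat,
// 2 = post-projection and post-drain snapshots per beat.
// [[Rcpp::export(name = ".rp_engine")]]
List rp_engine(NumericVector rri, LogicalVector flagged, NumericVector edges,
               int drain, int capacity, int window_beats, bool clamp_oor,
               int record_level) {
  const int n = rri.size();
  const int K = edges.size() - 1;
  const double lo = edges[0], hi = edges[K];

  std::vector<int> occ(K, 0);
  std::vector<bool> stuck(K, false);
  long valley = 0, projected = 0, dropped = 0;
  int wbeat = 0, window = 1, stuck_beats = 0;
  int win_start = -1;

  // window accumulators
  std::vector<long> counts(K, 0);

  // window summary storage
  std::vector<int> w_id, w_start, w_end, w_nbeats, w_stuckbeats, w_nstuck;
  std::vector<long> w_projected, w_valley, w_dropped;
  std::vector<int> w_partial;
  std::vector<long> w_counts, w_occ;  // row-major K columns per window

  // per-beat storage
  std::vector<int> b_beat, b_window, b_stair, b_anystuck;
  std::vector<long> b_valley, b_projected, b_dropped;
  std::vector<int> b_occ;
  std::vector<std::string> b_phase;

  auto snapshot = [&](int beat, int stair, const char *phase) {
    b_beat.push_back(beat + 1);
    b_window.push_back(window);
    b_stair.push_back(stair);  // 1-based, NA_INTEGER when dropped
    b_valley.push_back(valley);
    b_projected.push_back(projected);
    b_dropped.push_back(dropped);
    bool any = false;
    for (int k = 0; k < K; ++k) any = any || stuck[k];
    b_anystuck.push_back(any ? 1 : 0);
    b_phase.push_back(phase);
    for (int k = 0; k < K; ++k) b_occ.push_back(occ[k]);
  };

  auto flush_window = [&](int end_beat, bool partial) {
    w_id.push_back(window);
    w_start.push_back(win_start + 1);
    w_end.push_back(end_beat + 1);
    w_nbeats.push_back(wbeat);
    w_stuckbeats.push_back(stuck_beats);
    int ns = 0;
    for (int k = 0; k < K; ++k) ns += stuck[k] ? 1 : 0;
    w_nstuck.push_back(ns);
    w_projected.push_back(projected);
    w_valley.push_back(valley);
    w_dropped.push_back(dropped);
    w_partial.push_back(partial ? 1 : 0);
    for (int k = 0; k < K; ++k) w_counts.push_back(counts[k]);
    for (int k = 0; k < K; ++k) w_occ.push_back(occ[k]);
    // reset state for the next window
    std::fill(occ.begin(), occ.end(), 0);
    std::fill(stuck.begin(), stuck.end(), false);
    std::fill(counts.begin(), counts.end(), 0L);
    valley = projected = dropped = 0;
    wbeat = 0;
    stuck_beats = 0;
    win_start = -1;
    ++window;
  };

  int last_proc = -1;
  for (int i = 0; i < n; ++i) {
    if (flagged[i]) continue;
    last_proc = i;
    double x = rri[i];
    if (!(x > 0)) stop("RR interval at position %d is not positive", i + 1);
    if (win_start < 0) win_start = i;

    // --- projectile assignment ---
    int stair;  // 0-based; -1 = dropped
    if (x < lo) {
      stair = clamp_oor ? 0 : -1;
    } else if (x >= hi) {
      // the last stair is closed at its right edge
      stair = (x == hi || clamp_oor) ? K - 1 : -1;
    } else {
      stair = int(std::upper_bound(edges.begin(), edges.end(), x) -
                  edges.begin()) - 1;
      if (stair >= K) stair = K - 1;
    }

    projected++;
    if (stair < 0) {
      dropped++;
    } else {
      occ[stair]++;
      counts[stair]++;
      if (occ[stair] >= capacity) stuck[stair] = true;
    }
    if (record_level == 2)
      snapshot(i, stair < 0 ? NA_INTEGER : stair + 1, "project");

    // --- spring drainage (stuck stairs drain nothing) ---
    for (int k = 0; k < K; ++k) {
      if (stuck[k]) continue;
      int moved = std::min(drain, occ[k]);
      occ[k] -= moved;
      valley += moved;
    }
    for (int k = 0; k < K; ++k) stuck[k] = occ[k] >= capacity;

    bool any = false;
    for (int k = 0; k < K; ++k) any = any || stuck[k];
    if (any) stuck_beats++;
    if (record_level >= 1)
      snapshot(i, stair < 0 ? NA_INTEGER : stair + 1, "drain");

    if (++wbeat == window_beats) flush_window(i, false);
  }
  if (wbeat > 0) flush_window(last_proc, true);  // terminal partial window

  int nw = w_id.size();
  IntegerMatrix cm(nw, K), om(nw, K);
  for (int i = 0; i < nw; ++i)
    for (int k = 0; k < K; ++k) {
      cm(i, k) = (int)w_counts[(size_t)i * K + k];
      om(i, k) = (int)w_occ[(size_t)i * K + k];
    }

  List windows = List::create(
      _["window"] = wrap(w_id), _["start_beat"] = wrap(w_start),
      _["end_beat"] = wrap(w_end), _["n_beats"] = wrap(w_nbeats),
      _["stuck_beats"] = wrap(w_stuckbeats), _["n_stuck"] = wrap(w_nstuck),
      _["projected"] = wrap(w_projected), _["valley"] = wrap(w_valley),
      _["dropped"] = wrap(w_dropped), _["partial"] = wrap(w_partial),
      _["counts"] = cm, _["occupancy"] = om);

  if (record_level == 0)
    return List::create(_["windows"] = windows, _["beats"] = R_NilValue);

  int nb = b_beat.size();
  IntegerMatrix bo(nb, K);
  for (int i = 0; i < nb; ++i)
    for (int k = 0; k < K; ++k) bo(i, k) = b_occ[(size_t)i * K + k];
  List beats = List::create(
      _["beat"] = wrap(b_beat), _["window"] = wrap(b_window),
      _["phase"] = wrap(b_phase), _["stair"] = wrap(b_stair),
      _["valley"] = wrap(b_valley), _["projected"] = wrap(b_projected),
      _["dropped"] = wrap(b_dropped), _["any_stuck"] = wrap(b_anystuck),
      _["occupancy"] = bo);
  return List::create(_["windows"] = windows, _["beats"] = beats);
}
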