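// Greedy longest-overlap one-to-one interval matching, shared by the
// evaluation metrics and the threshold search so both optimize the same
// objective.

#include <Rcpp.h>
using namespace Rcpp;

struct Cand { int overlap, ti, pi; };

// Single-class greedy longest-overlap matching plus silence agreement;
// returns total correctly recognized frames (note overlaps + frames covered
// by neither annotation).
static long long correct_frames_1class(const std::vector<int>& t_on,
                                       const std::vector<int>& t_off,
                                       const std::vector<int>& p_on,
                                       const std::vector<int>& p_off,
                                       int timeline) {
  const int nt = t_on.size(), np = p_on.size();
  std::vector<Cand> cands;
  int j0 = 0;
  for (int i = 0; i < nt; ++i) {
    while (j0 < np && p_off[j0] <= t_on[i]) ++j0;
    for (int j = j0; j < np && p_on[j] < t_off[i]; ++j) {
      int ov = std::min(t_off[i], p_off[j]) - std::max(t_on[i], p_on[j]);
      if (ov > 0) cands.push_back({ov, i, j});
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.overlap != b.overlap) return a.overlap > b.overlap;
    if (a.ti != b.ti) return a.ti < b.ti;
    return a.pi < b.pi;
  });
  std::vector<bool> t_used(nt, false), p_used(np, false);
  long long frames = 0;
  for (const Cand& c : cands) {
    if (t_used[c.ti] || p_used[c.pi]) continue;
    t_used[c.ti] = true; p_used[c.pi] = true;
    frames += c.overlap;
  }
  // silence agreement via merged-union sweep (both lists sorted)
  std::vector<std::pair<int, int>> iv;
  iv.reserve(nt + np);
  for (int i = 0; i < nt; ++i) iv.push_back({t_on[i], t_off[i]});
  for (int j = 0; j < np; ++j) iv.push_back({p_on[j], p_off[j]});
  std::sort(iv.begin(), iv.end());
  long long covered = 0; int cur_on = 0, cur_off = -1; bool open = false;
  for (const auto& ab : iv) {
    if (!open) { cur_on = ab.first; cur_off = ab.second; open = true; }
    else if (ab.first <= cur_off) cur_off = std::max(cur_off, ab.second);
    else { covered += cur_off - cur_on; cur_on = ab.first; cur_off = ab.second; }
  }
  if (open) covered += cur_off - cur_on;
  return frames + (long long)timeline - covered;
}

// Grid evaluation for the threshold search: given the non-background
// intervals detected at one amplitude threshold and the true note intervals
// of one sequence, return the correctly recognized frame count (timing-ER
// numerator) for every (gap threshold, duration threshold) combination.
// Gaps strictly shorter than gap_thr are merged, intervals strictly shorter
// than dur_thr are discarded, in that order.
// [[Rcpp::export]]
NumericMatrix cpp_threshold_grid(IntegerVector iv_on, IntegerVector iv_off,
                                 IntegerVector t_on, IntegerVector t_off,
                                 int timeline, IntegerVector gap_grid,
                                 IntegerVector dur_grid) {
  const int n = iv_on.size();
  std::vector<int> tt_on(t_on.begin(), t_on.end());
  std::vector<int> tt_off(t_off.begin(), t_off.end());
  NumericMatrix out(gap_grid.size(), dur_grid.size());
  for (int gi = 0; gi < gap_grid.size(); ++gi) {
    int gap = gap_grid[gi];
    std::vector<int> m_on, m_off;
    for (int i = 0; i < n; ++i) {
      if (!m_on.empty() && iv_on[i] - m_off.back() < gap)
        m_off.back() = iv_off[i];
      else { m_on.push_back(iv_on[i]); m_off.push_back(iv_off[i]); }
    }
    for (int di = 0; di < dur_grid.size(); ++di) {
      int dur = dur_grid[di];
      std::vector<int> f_on, f_off;
      for (size_t i = 0; i < m_on.size(); ++i)
        if (m_off[i] - m_on[i] >= dur) {
          f_on.push_back(m_on[i]); f_off.push_back(m_off[i]);
        }
      out(gi, di) = (double)correct_frames_1class(tt_on, tt_off, f_on, f_off,
                                                  timeline);
    }
  }
  return out;
}

// Intervals are half-open [on, off) on a common frame grid, sorted by onset,
// non-overlapping within each annotation. Classes are integer codes; with
// ignore_class = true all notes are treated as one class.
// Matching: candidate (true, pred) pairs with positive overlap and equal
// class are taken in order of descending overlap (ties: earlier true note,
// then earlier output note), each true and each output note used at most
// once. Returns matched pair indices (1-based), their overlaps, the total
// correctly recognized note length, and the correctly recognized silent
// length (frames covered by neither annotation).
// [[Rcpp::export]]
List cpp_match_intervals(IntegerVector t_on, IntegerVector t_off,
                         IntegerVector t_cls, IntegerVector p_on,
                         IntegerVector p_off, IntegerVector p_cls,
                         int timeline, bool ignore_class) {
  const int nt = t_on.size(), np = p_on.size();
  std::vector<Cand> cands;
  int j0 = 0;
  for (int i = 0; i < nt; ++i) {
    while (j0 < np && p_off[j0] <= t_on[i]) ++j0;
    for (int j = j0; j < np && p_on[j] < t_off[i]; ++j) {
      if (!ignore_class && t_cls[i] != p_cls[j]) continue;
      int ov = std::min(t_off[i], p_off[j]) - std::max(t_on[i], p_on[j]);
      if (ov > 0) cands.push_back({ov, i, j});
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.overlap != b.overlap) return a.overlap > b.overlap;
    if (a.ti != b.ti) return a.ti < b.ti;
    return a.pi < b.pi;
  });
  std::vector<bool> t_used(nt, false), p_used(np, false);
  std::vector<int> mti, mpi, mov;
  long long note_frames = 0;
  for (const Cand& c : cands) {
    if (t_used[c.ti] || p_used[c.pi]) continue;
    t_used[c.ti] = true; p_used[c.pi] = true;
    mti.push_back(c.ti + 1); mpi.push_back(c.pi + 1); mov.push_back(c.overlap);
    note_frames += c.overlap;
  }

  // silent agreement: frames covered by neither annotation
  std::vector<std::pair<int, int>> iv;
  iv.reserve(nt + np);
  for (int i = 0; i < nt; ++i) iv.push_back({t_on[i], t_off[i]});
  for (int j = 0; j < np; ++j) iv.push_back({p_on[j], p_off[j]});
  std::sort(iv.begin(), iv.end());
  long long covered = 0; int cur_on = 0, cur_off = -1; bool open = false;
  for (const auto& ab : iv) {
    if (!open) { cur_on = ab.first; cur_off = ab.second; open = true; }
    else if (ab.first <= cur_off) cur_off = std::max(cur_off, ab.second);
    else { covered += cur_off - cur_on; cur_on = ab.first; cur_off = ab.second; }
  }
  if (open) covered += cur_off - cur_on;
  long long silent_frames = (long long)timeline - covered;

  return List::create(_["true_idx"] = wrap(mti), _["pred_idx"] = wrap(mpi),
                      _["overlap"] = wrap(mov),
                      _["note_frames"] = (double)note_frames,
                      _["silent_frames"] = (double)silent_frames);
}
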