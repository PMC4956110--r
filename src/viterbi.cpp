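// Sparse-transition Viterbi decoding in the log domain.

#include <Rcpp.h>
using namespace Rcpp;

// init_log: S starting log-probabilities (-Inf where a start is not allowed).
// edges: E x 2 integer matrix (from, to), 1-based; edge_logp: E log-probs.
// emis_log: (n_emission_rows x T) log emission table; state_emit: length S,
// 1-based row of emis_log each state emits.
// Ties are broken toward the lower state (and lower predecessor) index.
// [[Rcpp::export]]
List cpp_viterbi(NumericVector init_log, IntegerMatrix edges,
                 NumericVector edge_logp, NumericMatrix emis_log,
                 IntegerVector state_emit) {
  const int S = init_log.size();
  const int T = emis_log.ncol();
  const int E = edges.nrow();
  if (T == 0) stop("degenerate-emissions: no frames");

  // group incoming edges by target state, predecessors in ascending order
  std::vector<std::vector<std::pair<int, double>>> inc(S);
  for (int e = 0; e < E; ++e) {
    int from = edges(e, 0) - 1, to = edges(e, 1) - 1;
    if (from < 0 || from >= S || to < 0 || to >= S) stop("edge out of range");
    inc[to].push_back({from, edge_logp[e]});
  }
  for (int s = 0; s < S; ++s)
    std::sort(inc[s].begin(), inc[s].end());

  std::vector<double> delta(S), ndelta(S);
  IntegerMatrix psi(S, T);
  for (int s = 0; s < S; ++s)
    delta[s] = init_log[s] + emis_log(state_emit[s] - 1, 0);

  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = R_NegInf; int arg = -1;
      for (const auto& pr : inc[s]) {
        double v = delta[pr.first] + pr.second;
        if (v > best) { best = v; arg = pr.first; }
      }
      ndelta[s] = best + emis_log(state_emit[s] - 1, t);
      psi(s, t) = arg;
    }
    std::swap(delta, ndelta);
  }

  int last = 0; double best = delta[0];
  for (int s = 1; s < S; ++s)
    if (delta[s] > best) { best = delta[s]; last = s; }
  if (!R_finite(best))
    stop("degenerate-emissions: no path with finite log score");

  IntegerVector path(T);
  path[T - 1] = last + 1;
  for (int t = T - 1; t > 0; --t) {
    last = psi(last, t);
    path[t - 1] = last + 1;
  }
  return List::create(_["path"] = path, _["logp"] = best);
}
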