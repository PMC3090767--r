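// Greedy maximum-weight connected-subnetwork search on an edge-weighted
// metabolic graph. Edges are reactions; two edges are adjacent when they
// share a compound endpoint (subgraph mode), or must form a simple,
// direction-compatible path of compounds (chain mode). The aggregate score
// of k edges with weights w_1..w_k is sum(w)/sqrt(k). Free-size growth is
// a greedy ascent: each step adds the highest-weight extension and stops
// as soon as that extension would not improve the aggregate score.
// Fixed-size growth adds the highest-weight extension unconditionally
// until exactly k edges are reached. Called once per observed search and
// B times per structural null, hence compiled.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Cand {
  bool valid = false;
  double score = R_NegInf;
  int k = 0;
  std::vector<int> edges;      // addition order
  std::vector<int> lex_sorted; // sorted lexicographic ranks, for tie-breaks
};

// deterministic ordering: higher score, then fewer edges, then smaller
// sorted reaction-id sequence
bool better(const Cand &a, const Cand &b) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.score != b.score) return a.score > b.score;
  if (a.k != b.k) return a.k < b.k;
  return a.lex_sorted < b.lex_sorted;
}

} // namespace

// [[Rcpp::export]]
List greedy_core(IntegerVector src, IntegerVector tgt, LogicalVector rev,
                 NumericVector w, IntegerVector lexr, int n_comp, int mode,
                 int k_fixed, int size_cap, IntegerVector seeds,
                 bool both_ends) {
  const int m = src.size();
  std::vector<std::vector<int>> inc(n_comp);
  for (int e = 0; e < m; ++e) {
    inc[src[e]].push_back(e);
    if (tgt[e] != src[e]) inc[tgt[e]].push_back(e);
  }

  Cand best;
  std::vector<char> in_set(m, 0), in_front(m, 0);
  std::vector<char> used_comp(n_comp, 0);
  std::vector<int> chosen, frontier;
  double cum = 0.0;

  auto agg_of = [](double s, int k) { return s / std::sqrt((double)k); };

  // stop rule of the free-size greedy ascent: adding weight `we` must
  // improve the aggregate score of the current `k`-edge subnetwork
  auto improves = [&](double we, int k) {
    return agg_of(cum + we, k + 1) > agg_of(cum, k);
  };

  auto consider = [&](void) {
    int k = (int)chosen.size();
    if (k_fixed > 0 && k != k_fixed) return;
    Cand c;
    c.valid = true;
    c.score = agg_of(cum, k);
    c.k = k;
    c.edges = chosen;
    c.lex_sorted.resize(k);
    for (int i = 0; i < k; ++i) c.lex_sorted[i] = lexr[c.edges[i]];
    std::sort(c.lex_sorted.begin(), c.lex_sorted.end());
    if (better(c, best)) best = std::move(c);
  };

  if (mode == 0) { // arbitrary connected subgraph
    for (int si = 0; si < seeds.size(); ++si) {
      const int s = seeds[si];
      chosen.clear();
      frontier.clear();
      cum = 0.0;
      auto add_edge = [&](int e) {
        in_set[e] = 1;
        chosen.push_back(e);
        cum += w[e];
        int cc[2] = {src[e], tgt[e]};
        int ncc = (cc[0] == cc[1]) ? 1 : 2;
        for (int ci = 0; ci < ncc; ++ci)
          for (int f : inc[cc[ci]])
            if (!in_set[f] && !in_front[f]) {
              in_front[f] = 1;
              frontier.push_back(f);
            }
      };
      add_edge(s);
      while ((int)chosen.size() < size_cap &&
             (k_fixed <= 0 || (int)chosen.size() < k_fixed)) {
        int bi = -1;
        for (int i = 0; i < (int)frontier.size(); ++i) {
          int f = frontier[i];
          if (bi < 0 || w[f] > w[frontier[bi]] ||
              (w[f] == w[frontier[bi]] && lexr[f] < lexr[frontier[bi]]))
            bi = i;
        }
        if (bi < 0) break;
        if (k_fixed <= 0 && !improves(w[frontier[bi]], (int)chosen.size()))
          break;
        int e = frontier[bi];
        frontier[bi] = frontier.back();
        frontier.pop_back();
        in_front[e] = 0;
        add_edge(e);
      }
      consider();
      for (int e : chosen) in_set[e] = 0;
      for (int f : frontier) in_front[f] = 0;
    }
  } else { // chain: simple direction-compatible path of compounds
    auto run_chain = [&](int s, bool forward) {
      if (src[s] == tgt[s]) return; // self-loops never form chains
      if (!forward && !rev[s]) return;
      int a = forward ? src[s] : tgt[s]; // path entry compound
      int b = forward ? tgt[s] : src[s]; // path exit compound
      chosen.clear();
      std::vector<int> usedc = {a, b};
      used_comp[a] = 1;
      used_comp[b] = 1;
      in_set[s] = 1;
      chosen.push_back(s);
      cum = w[s];
      while ((int)chosen.size() < size_cap &&
             (k_fixed <= 0 || (int)chosen.size() < k_fixed)) {
        int beste = -1, bestother = -1;
        bool at_tail = true;
        for (int f : inc[b]) { // extend forward, leaving b
          if (in_set[f] || src[f] == tgt[f]) continue;
          bool ok = (src[f] == b) || (rev[f] && tgt[f] == b);
          if (!ok) continue;
          int other = (src[f] == b) ? tgt[f] : src[f];
          if (used_comp[other]) continue;
          if (beste < 0 || w[f] > w[beste] ||
              (w[f] == w[beste] && lexr[f] < lexr[beste])) {
            beste = f;
            bestother = other;
            at_tail = true;
          }
        }
        if (both_ends) {
          for (int f : inc[a]) { // extend backward, entering a
            if (in_set[f] || src[f] == tgt[f]) continue;
            bool ok = (tgt[f] == a) || (rev[f] && src[f] == a);
            if (!ok) continue;
            int other = (tgt[f] == a) ? src[f] : tgt[f];
            if (used_comp[other]) continue;
            if (beste < 0 || w[f] > w[beste] ||
                (w[f] == w[beste] && lexr[f] < lexr[beste])) {
              beste = f;
              bestother = other;
              at_tail = false;
            }
          }
        }
        if (beste < 0) break;
        if (k_fixed <= 0 && !improves(w[beste], (int)chosen.size())) break;
        in_set[beste] = 1;
        used_comp[bestother] = 1;
        usedc.push_back(bestother);
        if (at_tail) b = bestother; else a = bestother;
        chosen.push_back(beste);
        cum += w[beste];
      }
      consider();
      for (int e : chosen) in_set[e] = 0;
      for (int c : usedc) used_comp[c] = 0;
    };
    for (int si = 0; si < seeds.size(); ++si) {
      run_chain(seeds[si], true);
      if (rev[seeds[si]]) run_chain(seeds[si], false);
    }
  }

  if (!best.valid) {
    return List::create(Named("edges") = IntegerVector(0),
                        Named("score") = R_NegInf);
  }
  IntegerVector out(best.edges.begin(), best.edges.end());
  return List::create(Named("edges") = out + 1, // 1-based for R
                      Named("score") = best.score);
}
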