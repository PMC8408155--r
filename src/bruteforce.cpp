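#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Union-find over the nodes that survive a removal set. Returns true when
// every connected component of the residual graph has size <= t.
static bool residual_ok(int n, const std::vector<int>& eu,
                        const std::vector<int>& ev,
                        const std::vector<char>& removed, int t,
                        std::vector<int>& parent, std::vector<int>& csize) {
  for (int i = 0; i < n; ++i) {
    parent[i] = i;
    csize[i] = removed[i] ? 0 : 1;
  }
  const int m = (int) eu.size();
  for (int e = 0; e < m; ++e) {
    int a = eu[e], b = ev[e];
    if (removed[a] || removed[b]) continue;
    while (parent[a] != a) a = parent[a] = parent[parent[a]];
    while (parent[b] != b) b = parent[b] = parent[parent[b]];
    if (a == b) continue;
    if (csize[a] < csize[b]) std::swap(a, b);
    parent[b] = a;
    csize[a] += csize[b];
    if (csize[a] > t) return false;
  }
  return true;
}

// All node subsets of minimum cardinality whose removal leaves every
// component of the graph with at most t nodes. Edges are 0-based pairs.
// Subsets are enumerated in lexicographic order by increasing cardinality,
// so the returned sets are already sorted. kmax guards the search depth.
// [[Rcpp::export]]
List cpp_optimal_sets(int n, IntegerMatrix edges, int t, int kmax) {
  std::vector<int> eu, ev;
  eu.reserve(edges.nrow());
  ev.reserve(edges.nrow());
  for (int i = 0; i < edges.nrow(); ++i) {
    eu.push_back(edges(i, 0));
    ev.push_back(edges(i, 1));
  }
  std::vector<int> parent(n), csize(n);
  std::vector<char> removed(n, 0);

  // k = 0: the graph may already satisfy the target
  if (residual_ok(n, eu, ev, removed, t, parent, csize)) {
    return List::create(_["k"] = 0, _["sets"] = List::create(IntegerVector(0)));
  }

  for (int k = 1; k <= kmax; ++k) {
    List hits;
    std::vector<int> comb(k);
    for (int i = 0; i < k; ++i) comb[i] = i;
    long long counter = 0;
    for (;;) {
      std::fill(removed.begin(), removed.end(), 0);
      for (int i = 0; i < k; ++i) removed[comb[i]] = 1;
      if (residual_ok(n, eu, ev, removed, t, parent, csize)) {
        IntegerVector s(k);
        for (int i = 0; i < k; ++i) s[i] = comb[i] + 1;  // 1-based for R
        hits.push_back(s);
      }
      if (++counter % 100000 == 0) Rcpp::checkUserInterrupt();
      // next combination in lexicographic order
      int i = k - 1;
      while (i >= 0 && comb[i] == n - k + i) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
    }
    if (hits.size() > 0) {
      return List::create(_["k"] = k, _["sets"] = hits);
    }
  }
  stop("no dismantling set of size <= kmax found");
}

// Size of the largest connected component after removing `removed` (1-based
// node indices). Shared fast path for attack replay on small graphs.
// [[Rcpp::export]]
IntegerVector cpp_lcc_after_removal(int n, IntegerMatrix edges,
                                    IntegerVector removedIdx) {
  std::vector<int> eu, ev;
  for (int i = 0; i < edges.nrow(); ++i) {
    eu.push_back(edges(i, 0));
    ev.push_back(edges(i, 1));
  }
  std::vector<char> removed(n, 0);
  for (int i = 0; i < removedIdx.size(); ++i) removed[removedIdx[i] - 1] = 1;
  std::vector<int> parent(n), csize(n);
  for (int i = 0; i < n; ++i) {
    parent[i] = i;
    csize[i] = removed[i] ? 0 : 1;
  }
  for (size_t e = 0; e < eu.size(); ++e) {
    int a = eu[e], b = ev[e];
    if (removed[a] || removed[b]) continue;
    while (parent[a] != a) a = parent[a] = parent[parent[a]];
    while (parent[b] != b) b = parent[b] = parent[parent[b]];
    if (a == b) continue;
    if (csize[a] < csize[b]) std::swap(a, b);
    parent[b] = a;
    csize[a] += csize[b];
  }
  int best = 0, second = 0;
  for (int i = 0; i < n; ++i) {
    if (!removed[i] && parent[i] == i) {
      if (csize[i] > best) { second = best; best = csize[i]; }
      else if (csize[i] > second) second = csize[i];
    }
  }
  return IntegerVector::create(best, second);
}
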