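#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Pair state between two nodes of a mixed graph: 0 none, 1 forward single
// arc, 2 backward single arc, 3 mutual (a PPI edge, or two opposing arcs).

static inline int flipState(int s) {
  return s == 1 ? 2 : (s == 2 ? 1 : s);
}

// Canonical code of a 3-node pattern: minimum over the 6 vertex orderings of
// the base-4 number s(x,y)*16 + s(x,z)*4 + s(y,z).
static int canonicalCode(int s01, int s02, int s12) {
  int st[3][3] = {{0, s01, s02},
                  {flipState(s01), 0, s12},
                  {flipState(s02), flipState(s12), 0}};
  static const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  int best = 1000;
  for (int p = 0; p < 6; ++p) {
    int x = perms[p][0], y = perms[p][1], z = perms[p][2];
    int code = st[x][y] * 16 + st[x][z] * 4 + st[y][z];
    if (code < best) best = code;
  }
  return best;
}

// [[Rcpp::export]]
int cpp_canonical_code(int s01, int s02, int s12) {
  return canonicalCode(s01, s02, s12);
}

// [[Rcpp::export]]
List cpp_triad_census(IntegerVector ea, IntegerVector eb,
                      IntegerVector at, IntegerVector ah, int n) {
  // out-connection sets: outs[u] contains v when u->v (PPI gives both)
  std::vector<std::unordered_set<int>> outs(n), any(n);
  for (int i = 0; i < ea.size(); ++i) {
    int u = ea[i] - 1, v = eb[i] - 1;
    outs[u].insert(v); outs[v].insert(u);
    any[u].insert(v); any[v].insert(u);
  }
  for (int i = 0; i < at.size(); ++i) {
    int u = at[i] - 1, v = ah[i] - 1;
    outs[u].insert(v);
    any[u].insert(v); any[v].insert(u);
  }
  std::vector<std::vector<int>> nb(n);
  for (int u = 0; u < n; ++u) {
    nb[u].assign(any[u].begin(), any[u].end());
    std::sort(nb[u].begin(), nb[u].end());
  }
  auto state = [&](int u, int v) -> int {
    bool f = outs[u].count(v) > 0, b = outs[v].count(u) > 0;
    return f && b ? 3 : (f ? 1 : (b ? 2 : 0));
  };
  std::unordered_map<int, double> counts;
  for (int v = 0; v < n; ++v) {
    const std::vector<int>& nbv = nb[v];
    for (size_t i = 0; i < nbv.size(); ++i) {
      for (size_t j = i + 1; j < nbv.size(); ++j) {
        int u = nbv[i], w = nbv[j];
        bool uw = any[u].count(w) > 0;
        // each path counted at its centre; each triangle at its least node
        if (uw && !(v < u && v < w)) continue;
        counts[canonicalCode(state(u, v), state(u, w), state(v, w))] += 1;
      }
    }
  }
  IntegerVector codes(counts.size());
  NumericVector cnt(counts.size());
  int k = 0;
  for (auto& kv : counts) { codes[k] = kv.first; cnt[k] = kv.second; ++k; }
  return List::create(_["code"] = codes, _["count"] = cnt);
}

// Nodes participating in at least one triad of the target canonical codes.
// [[Rcpp::export]]
IntegerVector cpp_triad_members(IntegerVector ea, IntegerVector eb,
                                IntegerVector at, IntegerVector ah,
                                int n, IntegerVector targetCodes) {
  std::vector<std::unordered_set<int>> outs(n), any(n);
  for (int i = 0; i < ea.size(); ++i) {
    int u = ea[i] - 1, v = eb[i] - 1;
    outs[u].insert(v); outs[v].insert(u);
    any[u].insert(v); any[v].insert(u);
  }
  for (int i = 0; i < at.size(); ++i) {
    int u = at[i] - 1, v = ah[i] - 1;
    outs[u].insert(v);
    any[u].insert(v); any[v].insert(u);
  }
  std::unordered_set<int> targets(targetCodes.begin(), targetCodes.end());
  std::vector<std::vector<int>> nb(n);
  for (int u = 0; u < n; ++u) {
    nb[u].assign(any[u].begin(), any[u].end());
    std::sort(nb[u].begin(), nb[u].end());
  }
  auto state = [&](int u, int v) -> int {
    bool f = outs[u].count(v) > 0, b = outs[v].count(u) > 0;
    return f && b ? 3 : (f ? 1 : (b ? 2 : 0));
  };
  std::vector<bool> hit(n, false);
  for (int v = 0; v < n; ++v) {
    const std::vector<int>& nbv = nb[v];
    for (size_t i = 0; i < nbv.size(); ++i) {
      for (size_t j = i + 1; j < nbv.size(); ++j) {
        int u = nbv[i], w = nbv[j];
        bool uw = any[u].count(w) > 0;
        if (uw && !(v < u && v < w)) continue;
        int code = canonicalCode(state(u, v), state(u, w), state(v, w));
        if (targets.count(code)) { hit[u] = hit[v] = hit[w] = true; }
      }
    }
  }
  std::vector<int> res;
  for (int u = 0; u < n; ++u) if (hit[u]) res.push_back(u + 1);
  return wrap(res);
}

static inline long long pairKey(int u, int v, int n) {
  if (u > v) std::swap(u, v);
  return (long long)u * n + v;
}

// Degree-preserving switching of a mixed graph: single arcs are swapped only
// with single arcs (preserving every node's single in- and out-degree) and
// mutual PPI edges only with mutual edges (preserving mutual degree). A
// proposed swap is rejected when it would create a self-loop, a duplicate,
// or any connection on a pair that is already connected in either layer --
// so singles never merge into mutuals and vice versa.
// [[Rcpp::export]]
List cpp_rewire_mixed(IntegerVector ea, IntegerVector eb,
                      IntegerVector at, IntegerVector ah,
                      int n, int nAttempts) {
  std::vector<int> EA(ea.begin(), ea.end()), EB(eb.begin(), eb.end());
  std::vector<int> AT(at.begin(), at.end()), AH(ah.begin(), ah.end());
  int nE = EA.size(), nA = AT.size();
  // flat adjacency bitmap when it fits (fast path), hash set otherwise
  long long span = (long long)(n + 1) * (n + 1);
  bool flat = span <= (64LL << 20);
  std::vector<uint8_t> conFlat;
  std::unordered_set<long long> conSet;
  if (flat) conFlat.assign(span, 0);
  auto has = [&](long long k) -> bool {
    return flat ? conFlat[k] != 0 : conSet.count(k) > 0;
  };
  auto ins = [&](long long k) { if (flat) conFlat[k] = 1; else conSet.insert(k); };
  auto del = [&](long long k) { if (flat) conFlat[k] = 0; else conSet.erase(k); };
  for (int i = 0; i < nE; ++i) ins(pairKey(EA[i], EB[i], n + 1));
  for (int i = 0; i < nA; ++i) ins(pairKey(AT[i], AH[i], n + 1));
  int total = nE + nA;
  if (total < 2) return List::create(_["ea"] = ea, _["eb"] = eb,
                                     _["at"] = at, _["ah"] = ah);
  GetRNGstate();
  for (int it = 0; it < nAttempts; ++it) {
    int pick = (int)(unif_rand() * total);
    if (pick >= total) pick = total - 1;
    if (pick < nE) {                       // mutual-edge swap
      if (nE < 2) continue;
      int i = (int)(unif_rand() * nE), j = (int)(unif_rand() * nE);
      if (i == j) continue;
      int a = EA[i], b = EB[i], c = EA[j], d = EB[j];
      if (unif_rand() < 0.5) std::swap(c, d);
      // propose {a,d} and {c,b}
      if (a == d || c == b) continue;
      long long k1 = pairKey(a, d, n + 1), k2 = pairKey(c, b, n + 1);
      if (k1 == k2 || has(k1) || has(k2)) continue;
      del(pairKey(a, b, n + 1));
      del(pairKey(EA[j], EB[j], n + 1));
      ins(k1); ins(k2);
      EA[i] = a; EB[i] = d; EA[j] = c; EB[j] = b;
    } else {                               // single-arc swap
      if (nA < 2) continue;
      int i = (int)(unif_rand() * nA), j = (int)(unif_rand() * nA);
      if (i == j) continue;
      int a = AT[i], b = AH[i], c = AT[j], d = AH[j];
      // propose a->d and c->b
      if (a == d || c == b) continue;
      long long k1 = pairKey(a, d, n + 1), k2 = pairKey(c, b, n + 1);
      if (k1 == k2 || has(k1) || has(k2)) continue;
      del(pairKey(a, b, n + 1));
      del(pairKey(c, d, n + 1));
      ins(k1); ins(k2);
      AH[i] = d; AH[j] = b;
    }
  }
  PutRNGstate();
  return List::create(_["ea"] = wrap(EA), _["eb"] = wrap(EB),
                      _["at"] = wrap(AT), _["ah"] = wrap(AH));
}
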