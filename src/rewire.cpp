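#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving double-edge swaps (Maslov-Sneppen). Edge k keeps its
// weight throughout: a swap of (x1,y1),(x2,y2) into (x1,y2),(x2,y1) moves
// the two weights with their edge slots, so the weight multiset and every
// node degree are preserved exactly. Uses R's RNG so results follow
// set.seed().
// [[Rcpp::export]]
List ms_rewire(IntegerVector ei, IntegerVector ej, int n_nodes,
               int target_swaps, int max_tries) {
  int m = ei.size();
  std::vector<int> a(ei.begin(), ei.end()), b(ej.begin(), ej.end());
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  auto at = [&](int i, int j) -> char& {
    return adj[(size_t)(i - 1) * n_nodes + (j - 1)];
  };
  for (int e = 0; e < m; ++e) {
    at(a[e], b[e]) = 1;
    at(b[e], a[e]) = 1;
  }
  int accepted = 0, tries = 0;
  while (accepted < target_swaps && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
    if (unif_rand() < 0.5) std::swap(x2, y2);
    if (x1 == x2 || x1 == y2 || y1 == x2 || y1 == y2) continue;
    if (at(x1, y2) || at(x2, y1)) continue;
    at(x1, y1) = at(y1, x1) = 0;
    at(x2, y2) = at(y2, x2) = 0;
    at(x1, y2) = at(y2, x1) = 1;
    at(x2, y1) = at(y1, x2) = 1;
    b[e1] = y2;
    a[e2] = x2;
    b[e2] = y1;
    ++accepted;
  }
  return List::create(_["i"] = IntegerVector(a.begin(), a.end()),
                      _["j"] = IntegerVector(b.begin(), b.end()),
                      _["accepted"] = accepted,
                      _["tries"] = tries);
}
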