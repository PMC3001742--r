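#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving checkerboard rewiring of a simple bipartite graph.
// Edges are (d[i], g[i]) with 1-based indices. Each attempt picks two
// edges (d1,g1),(d2,g2); if d1 != d2, g1 != g2 and neither (d1,g2) nor
// (d2,g1) exists, the pair is swapped to (d1,g2),(d2,g1). Every node's
// degree is invariant; the graph stays simple. Randomness comes from R's
// RNG stream (unif_rand), so set.seed() governs the result.
//
// [[Rcpp::export]]
List checkerboard_rewire_cpp(IntegerVector d, IntegerVector g,
                             int n_diseases, int n_genes,
                             double n_attempts) {
  int m = d.size();
  IntegerVector dd = clone(d), gg = clone(g);
  std::vector<char> present((size_t)n_diseases * n_genes, 0);
  for (int i = 0; i < m; ++i)
    present[(size_t)(dd[i] - 1) * n_genes + (gg[i] - 1)] = 1;

  double accepted = 0;
  if (m >= 2) {
    for (double a = 0; a < n_attempts; ++a) {
      int e1 = (int)(unif_rand() * m);
      int e2 = (int)(unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int d1 = dd[e1], g1 = gg[e1], d2 = dd[e2], g2 = gg[e2];
      if (d1 == d2 || g1 == g2) continue;
      size_t p12 = (size_t)(d1 - 1) * n_genes + (g2 - 1);
      size_t p21 = (size_t)(d2 - 1) * n_genes + (g1 - 1);
      if (present[p12] || present[p21]) continue;
      present[(size_t)(d1 - 1) * n_genes + (g1 - 1)] = 0;
      present[(size_t)(d2 - 1) * n_genes + (g2 - 1)] = 0;
      present[p12] = 1;
      present[p21] = 1;
      gg[e1] = g2;
      gg[e2] = g1;
      accepted += 1;
    }
  }
  return List::create(_["disease"] = dd, _["gene"] = gg,
                      _["accepted"] = accepted);
}
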