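#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fruchterman-Reingold force-directed layout in 2 or 3 dimensions.
//
// Optimal distance k = C * (volume / n)^(1/dims) with unit volume.
// Repulsion k^2/d between all node pairs, attraction d^2/k along edges,
// maximum per-node displacement cooled linearly from t0 to 0 over the
// iteration budget. Initial positions are uniform in the unit box, drawn
// from R's RNG stream, so set.seed() makes the layout reproducible.
// Coordinates are returned unscaled (the R wrapper normalizes).
//
// [[Rcpp::export]]
NumericMatrix fr_layout_cpp(int n, IntegerVector ei, IntegerVector ej,
                            int dims, int iterations, double C, double t0) {
  NumericMatrix pos(n, dims);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < dims; ++c)
      pos(i, c) = unif_rand();

  int m = ei.size();
  double k = C * std::pow(1.0 / n, 1.0 / dims);
  double k2 = k * k;
  const double eps2 = 1e-12;
  std::vector<double> disp((size_t)n * dims);
  double delta[3];

  for (int it = 0; it < iterations; ++it) {
    std::fill(disp.begin(), disp.end(), 0.0);

    // all-pairs repulsion: displacement += delta * k^2 / d^2
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double d2 = 0.0;
        for (int c = 0; c < dims; ++c) {
          delta[c] = pos(i, c) - pos(j, c);
          d2 += delta[c] * delta[c];
        }
        if (d2 < eps2) d2 = eps2;
        double coef = k2 / d2;
        for (int c = 0; c < dims; ++c) {
          double v = delta[c] * coef;
          disp[(size_t)i * dims + c] += v;
          disp[(size_t)j * dims + c] -= v;
        }
      }
    }

    // edge attraction: displacement -= delta * d / k
    for (int e = 0; e < m; ++e) {
      int i = ei[e] - 1, j = ej[e] - 1;
      double d2 = 0.0;
      for (int c = 0; c < dims; ++c) {
        delta[c] = pos(i, c) - pos(j, c);
        d2 += delta[c] * delta[c];
      }
      double dlen = std::sqrt(d2);
      double coef = dlen / k;
      for (int c = 0; c < dims; ++c) {
        double v = delta[c] * coef;
        disp[(size_t)i * dims + c] -= v;
        disp[(size_t)j * dims + c] += v;
      }
    }

    // move, capped at the current temperature (linear cooling to 0)
    double t = t0 * (1.0 - (double)it / iterations);
    for (int i = 0; i < n; ++i) {
      double len2 = 0.0;
      for (int c = 0; c < dims; ++c) {
        double v = disp[(size_t)i * dims + c];
        len2 += v * v;
      }
      double len = std::sqrt(len2);
      if (len > 0) {
        double scale = (len > t) ? t / len : 1.0;
        for (int c = 0; c < dims; ++c)
          pos(i, c) += disp[(size_t)i * dims + c] * scale;
      }
    }
  }
  return pos;
}
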