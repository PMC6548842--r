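#include <Rcpp.h>
using namespace Rcpp;

// Summed-area-table rectangle sum with clipping; cum is (V+1) x (U+1),
// rectangle is the half-open [x1, x2) x [y1, y2) in 0-based pixel units.
static inline double rect_sum_sat(const NumericMatrix &cum, int U, int V,
                                  long x1, long x2, long y1, long y2) {
  if (x1 < 0) x1 = 0; if (y1 < 0) y1 = 0;
  if (x2 > U) x2 = U; if (y2 > V) y2 = V;
  if (x1 >= x2 || y1 >= y2) return 0.0;
  return cum(y2, x2) - cum(y1, x2) - cum(y2, x1) + cum(y1, x1);
}

// Batch grid cost (exp of negated mean net cell energy) for K candidate
// displacement fields. X is N x K with N = 2*M; rows 1..M hold du (cells in
// column-major grid order), rows M+1..N hold dv. Cell rectangles are
// discretised with half-away-from-zero rounding of the left/top edge and
// span round(W) x round(H) pixels, matching the R reference path.
// [[Rcpp::export]]
NumericVector cost_batch_cpp(NumericMatrix cum,
                             NumericVector u, NumericVector v,
                             NumericVector W, NumericVector H,
                             IntegerMatrix edges, NumericMatrix X,
                             bool intra_only) {
  const int M = u.size();
  const int K = X.ncol();
  const int V = cum.nrow() - 1;
  const int U = cum.ncol() - 1;
  const int E = edges.nrow();
  if (X.nrow() != 2 * M) stop("position matrix must have 2 * n_cells rows");

  std::vector<long> Wi(M), Hi(M);
  std::vector<double> area(M);
  for (int i = 0; i < M; ++i) {
    Wi[i] = (long)std::floor(W[i] + 0.5);
    Hi[i] = (long)std::floor(H[i] + 0.5);
    area[i] = W[i] * H[i];
    if (area[i] <= 0) stop("cell area must be positive");
  }

  NumericVector cost(K);
  std::vector<double> d(M), g(M);
  std::vector<long> x1(M), y1(M);

  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < M; ++i) {
      double du = X(i, k), dv = X(M + i, k);
      x1[i] = (long)std::floor(u[i] + du - W[i] / 2.0 + 0.5);
      y1[i] = (long)std::floor(v[i] + dv - H[i] / 2.0 + 0.5);
      d[i] = rect_sum_sat(cum, U, V, x1[i], x1[i] + Wi[i], y1[i], y1[i] + Hi[i]);
      g[i] = 0.0;
    }
    if (!intra_only) {
      for (int e = 0; e < E; ++e) {
        int a = edges(e, 0), b = edges(e, 1);
        long ox1 = std::max(x1[a], x1[b]);
        long ox2 = std::min(x1[a] + Wi[a], x1[b] + Wi[b]);
        long oy1 = std::max(y1[a], y1[b]);
        long oy2 = std::min(y1[a] + Hi[a], y1[b] + Hi[b]);
        if (ox1 >= ox2 || oy1 >= oy2) continue;
        double den = d[a] + d[b];
        if (den == 0.0) continue;
        double os = rect_sum_sat(cum, U, V, ox1, ox2, oy1, oy2);
        g[a] += d[b] / den * os;  // share of the pair's overlap mass
        g[b] += d[a] / den * os;
      }
    }
    double fsum = 0.0;
    for (int i = 0; i < M; ++i) fsum += (d[i] - g[i]) / area[i];
    cost[k] = std::exp(-fsum / M);
  }
  return cost;
}
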