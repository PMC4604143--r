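#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>
using namespace Rcpp;

// Lloyd iterations for k-means with Euclidean distance.
// X: n x d; centroids: k x d initial positions. Converges when assignments
// stop changing or after max_iter iterations. An emptied cluster is
// re-seeded to the row farthest from its assigned centroid.

// [[Rcpp::export(name = ".lloyd_cpp")]]
List lloyd_cpp(NumericMatrix X, NumericMatrix centroids, int max_iter) {
  const int n = X.nrow(), d = X.ncol(), k = centroids.nrow();
  const double *xp = REAL(X);
  std::vector<double> cen(k * d); // row-major k x d
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) cen[j * d + c] = centroids(j, c);
  IntegerVector assign(n, -1);
  std::vector<double> dist_to_own(n, 0.0);
  std::vector<double> xi(d);
  std::vector<double> sums(k * d);
  std::vector<int> cnt(k);
  int iter = 0;
  bool changed = true;
  while (changed && iter < max_iter) {
    ++iter;
    changed = false;
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < d; ++c) xi[c] = xp[i + (size_t)c * n];
      double best = std::numeric_limits<double>::infinity();
      int bj = 0;
      const double *cj = cen.data();
      for (int j = 0; j < k; ++j, cj += d) {
        double s = 0.0;
        for (int c = 0; c < d; ++c) {
          const double diff = xi[c] - cj[c];
          s += diff * diff;
          if (s >= best) break;
        }
        if (s < best) { best = s; bj = j; }
      }
      if (assign[i] != bj) { assign[i] = bj; changed = true; }
      dist_to_own[i] = best;
    }
    std::fill(sums.begin(), sums.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) {
      ++cnt[assign[i]];
      double *sj = sums.data() + (size_t)assign[i] * d;
      for (int c = 0; c < d; ++c) sj[c] += xp[i + (size_t)c * n];
    }
    for (int j = 0; j < k; ++j) {
      if (cnt[j] == 0) {
        // re-seed to the farthest row from its assigned centroid
        int far = 0;
        double mx = -1.0;
        for (int i = 0; i < n; ++i)
          if (dist_to_own[i] > mx) { mx = dist_to_own[i]; far = i; }
        for (int c = 0; c < d; ++c) cen[j * d + c] = xp[far + (size_t)c * n];
        assign[far] = j;
        dist_to_own[far] = 0.0;
        changed = true;
      } else {
        for (int c = 0; c < d; ++c)
          cen[j * d + c] = sums[j * d + c] / cnt[j];
      }
    }
  }
  NumericMatrix out(k, d);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < d; ++c) out(j, c) = cen[j * d + c];
  return List::create(_["centroids"] = out,
                      _["assignment"] = assign + 1, // 1-based
                      _["iterations"] = iter);
}
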