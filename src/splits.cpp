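#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exhaustive univariate split search for the classification tree.
//
// X: n x p feature matrix; y: 0 (SVB) / 1 (VB); criterion: 0 = deviance
// (entropy), 1 = gini, 2 = twoing; priors: (pi1, pi2).
//
// Class counts are reweighted to the prior ratio at the node: observation
// of class j carries weight priors[j] / n_j so the node's effective class
// proportions equal the priors and the total node mass is 1. Candidate
// thresholds are the midpoints between adjacent distinct sorted values of
// each feature; rows go left iff x < threshold. Deviance/gini maximise the
// impurity decrease, twoing maximises the twoing index. Ties resolve to the
// lowest feature index, then the lowest threshold (scan order).

static inline double entropy2(double p1) {
  double h = 0.0;
  if (p1 > 0.0) h -= p1 * std::log(p1);
  double p2 = 1.0 - p1;
  if (p2 > 0.0) h -= p2 * std::log(p2);
  return h;
}

static inline double gini2(double p1) {
  return 2.0 * p1 * (1.0 - p1);
}

// [[Rcpp::export(name = ".best_split_cpp")]]
List best_split_cpp(NumericMatrix X, IntegerVector y, int criterion,
                    NumericVector priors) {
  int n = X.nrow(), p = X.ncol();
  double n1 = 0.0, n2 = 0.0;
  for (int i = 0; i < n; ++i) (y[i] == 0 ? n1 : n2) += 1.0;
  if (n1 == 0.0 || n2 == 0.0 || n < 2)
    return List::create(_["feature"] = -1, _["threshold"] = NA_REAL,
                        _["goodness"] = NA_REAL);
  double w1 = priors[0] / n1; // per-observation class weights
  double w2 = priors[1] / n2;
  double parent_imp;
  double p1_parent = priors[0]; // reweighted parent proportions = priors
  if (criterion == 0) parent_imp = entropy2(p1_parent);
  else if (criterion == 1) parent_imp = gini2(p1_parent);
  else parent_imp = 0.0; // twoing evaluated on splits only

  int best_feat = -1;
  double best_thr = NA_REAL, best_good = -1.0;

  std::vector<int> ord(n);
  std::vector<double> vals(n);
  std::vector<int> cls(n);

  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    NumericMatrix::Column col = X(_, j);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    for (int i = 0; i < n; ++i) {
      vals[i] = col[ord[i]];
      cls[i] = y[ord[i]];
    }
    double m1L = 0.0, m2L = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      if (cls[i] == 0) m1L += w1; else m2L += w2;
      if (vals[i + 1] <= vals[i]) continue; // not a boundary between distinct values
      double thr = 0.5 * (vals[i] + vals[i + 1]);
      double mL = m1L + m2L;
      double m1R = priors[0] - m1L, m2R = priors[1] - m2L;
      double mR = m1R + m2R;
      if (mL <= 0.0 || mR <= 0.0) continue;
      double good;
      if (criterion == 2) {
        double p1L = m1L / mL, p2L = m2L / mL;
        double p1R = m1R / mR, p2R = m2R / mR;
        double s = std::fabs(p1L - p1R) + std::fabs(p2L - p2R);
        good = mL * mR / 4.0 * s * s;
      } else {
        double iL = (criterion == 0) ? entropy2(m1L / mL) : gini2(m1L / mL);
        double iR = (criterion == 0) ? entropy2(m1R / mR) : gini2(m1R / mR);
        good = parent_imp - mL * iL - mR * iR;
      }
      if (good > best_good + 1e-12) {
        best_good = good;
        best_feat = j + 1; // 1-based for R
        best_thr = thr;
      }
    }
  }
  // sentinel only when no candidate threshold exists (identical rows);
  // zero-gain splits are legal and resolve by the scan-order tie-break
  if (best_feat < 0)
    return List::create(_["feature"] = -1, _["threshold"] = NA_REAL,
                        _["goodness"] = NA_REAL);
  return List::create(_["feature"] = best_feat, _["threshold"] = best_thr,
                      _["goodness"] = best_good);
}
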