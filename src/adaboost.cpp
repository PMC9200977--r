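#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Discrete AdaBoost with depth-1 threshold stumps.
//
// A stump h(x) = polarity * sign(x_j > threshold ? +1 : -1). Each round
// picks the (feature, threshold, polarity) minimising the weighted 0-1
// error; thresholds are midpoints between consecutive distinct sorted
// values (plus one below the minimum). Ties are broken deterministically
// by lowest feature index, then lowest threshold. Training stops early
// when the best weighted error reaches 0 (after keeping the stump) or
// 0.5 (before keeping it).

// [[Rcpp::export(name = ".cpp_adaboost_train")]]
List cpp_adaboost_train(NumericMatrix X, IntegerVector y, int T) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> y1(n);
  for (int i = 0; i < n; ++i) y1[i] = y[i] == 1 ? 1.0 : -1.0;

  // pre-sort each column once
  std::vector<std::vector<int> > ord(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::iota(ord[j].begin(), ord[j].end(), 0);
    const double* col = &X(0, j);
    std::stable_sort(ord[j].begin(), ord[j].end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  std::vector<double> w(n, 1.0 / n);
  std::vector<int> feat;
  std::vector<double> thr, pol, alpha;

  for (int t = 0; t < T; ++t) {
    double bestErr = R_PosInf, bestThr = 0.0;
    int bestJ = -1, bestPol = 1;

    for (int j = 0; j < p; ++j) {
      const std::vector<int>& o = ord[j];
      const double* col = &X(0, j);
      double totPos = 0.0, totNeg = 0.0;
      for (int i = 0; i < n; ++i) {
        if (y1[i] > 0) totPos += w[i]; else totNeg += w[i];
      }
      // boundary below all values: polarity +1 predicts everything +1
      double cpos = 0.0, cneg = 0.0;
      double candThr = col[o[0]] - 1.0;
      for (int k = -1; k < n - 1; ++k) {
        if (k >= 0) {
          int i = o[k];
          if (y1[i] > 0) cpos += w[i]; else cneg += w[i];
          if (col[o[k + 1]] == col[o[k]]) continue;  // not a boundary
          candThr = 0.5 * (col[o[k]] + col[o[k + 1]]);
        }
        // polarity +1: predict +1 if x > thr
        double e1 = cpos + (totNeg - cneg);
        double e2 = 1.0 - e1;                       // polarity -1
        double e = std::min(e1, e2);
        if (e < bestErr - 1e-12) {
          bestErr = e; bestJ = j; bestThr = candThr;
          bestPol = (e1 <= e2) ? 1 : -1;
        }
      }
    }

    if (bestJ < 0 || bestErr >= 0.5 - 1e-12) break;
    double eps = std::max(bestErr, 1e-12);
    double a = 0.5 * std::log((1.0 - eps) / eps);
    feat.push_back(bestJ + 1);
    thr.push_back(bestThr);
    pol.push_back(bestPol);
    alpha.push_back(a);

    double wsum = 0.0;
    for (int i = 0; i < n; ++i) {
      double h = (X(i, bestJ) > bestThr) ? bestPol : -bestPol;
      w[i] *= std::exp(-a * y1[i] * h);
      wsum += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= wsum;

    if (bestErr <= 1e-12) break;  // perfect separation: stop after keeping
  }

  return List::create(_["feature"] = wrap(feat), _["threshold"] = wrap(thr),
                      _["polarity"] = wrap(pol), _["alpha"] = wrap(alpha));
}

// signed ensemble margin sum(alpha_t * h_t(x))
// [[Rcpp::export(name = ".cpp_adaboost_score")]]
NumericVector cpp_adaboost_score(NumericMatrix X, IntegerVector feature,
                                 NumericVector threshold,
                                 NumericVector polarity,
                                 NumericVector alpha) {
  int n = X.nrow(), s = feature.size();
  NumericVector out(n);
  for (int t = 0; t < s; ++t) {
    int j = feature[t] - 1;
    for (int i = 0; i < n; ++i) {
      double h = (X(i, j) > threshold[t]) ? polarity[t] : -polarity[t];
      out[i] += alpha[t] * h;
    }
  }
  return out;
}
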