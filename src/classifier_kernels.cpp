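#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Summed per-feature Gaussian-kernel log densities of test rows under the
// kernel density estimate built from the training rows of one class.
// Per-feature density floored at 1e-300 so a single far-out feature cannot
// collapse the 4125-term log sum to -Inf.
// [[Rcpp::export(name = ".nb_class_loglik")]]
NumericVector nb_class_loglik(NumericMatrix Xtest, NumericMatrix Xtrain,
                              NumericVector h) {
  const int n = Xtest.nrow(), p = Xtest.ncol(), m = Xtrain.nrow();
  if (Xtrain.ncol() != p || h.size() != p)
    stop("dimension mismatch in kernel density evaluation");
  const double log2pi_half = 0.5 * std::log(2.0 * M_PI);
  const double floor_dens = 1e-300;
  NumericVector ll(n);
  for (int f = 0; f < p; ++f) {
    const double hf = h[f];
    const double inv_h = 1.0 / hf;
    const double log_norm = -std::log((double)m) - std::log(hf) - log2pi_half;
    const double *xt = &Xtest(0, f);
    const double *tr = &Xtrain(0, f);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const double xi = xt[i];
      for (int j = 0; j < m; ++j) {
        const double z = (xi - tr[j]) * inv_h;
        if (z < 37.0 && z > -37.0) s += std::exp(-0.5 * z * z);
      }
      double dens = std::exp(log_norm) * s;
      if (dens < floor_dens) dens = floor_dens;
      ll[i] += std::log(dens);
    }
  }
  return ll;
}

// Column-wise sort orders (0-based), computed once per training matrix and
// reused across boosting rounds.
// [[Rcpp::export(name = ".column_orders")]]
IntegerMatrix column_orders(NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  IntegerMatrix ord(n, p);
  std::vector<int> idx(n);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    const double *col = &X(0, f);
    std::stable_sort(idx.begin(), idx.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
    for (int i = 0; i < n; ++i) ord(i, f) = idx[i];
  }
  return ord;
}

struct BestSplit {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

// Best weighted-least-squares split of one leaf: scan every feature in
// presorted order, thresholds midway between consecutive distinct member
// values; gain is the weighted SSE reduction. Ties resolve to the first
// (lowest feature index, lowest threshold) candidate via strict >.
static BestSplit best_split_for_leaf(const NumericMatrix &X,
                                     const NumericVector &y,
                                     const NumericVector &w,
                                     const IntegerMatrix &ord,
                                     const std::vector<int> &node_of,
                                     int leaf, double sw, double swy) {
  const int n = X.nrow(), p = X.ncol();
  BestSplit best;
  const double base = (sw > 0.0) ? swy * swy / sw : 0.0;
  for (int f = 0; f < p; ++f) {
    double swL = 0.0, swyL = 0.0, last_x = 0.0;
    bool have_prev = false;
    const double *col = &X(0, f);
    const int *of = &ord(0, f);
    for (int k = 0; k < n; ++k) {
      const int i = of[k];
      if (node_of[i] != leaf) continue;
      const double x = col[i];
      if (have_prev && x > last_x) {
        const double swR = sw - swL, swyR = swy - swyL;
        if (swL > 0.0 && swR > 0.0) {
          const double gain = swyL * swyL / swL + swyR * swyR / swR - base;
          if (gain > best.gain) {
            best.gain = gain;
            best.feature = f;
            best.threshold = 0.5 * (last_x + x);
          }
        }
      }
      swL += w[i];
      swyL += w[i] * y[i];
      last_x = x;
      have_prev = true;
    }
  }
  return best;
}

// Greedy best-first weighted least-squares regression tree with at most
// max_split internal splits. Nodes are returned as parallel arrays
// (feature = -1 marks a leaf; child indices are 1-based for R).
// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_split, IntegerMatrix ord) {
  const int n = X.nrow();
  if (y.size() != n || w.size() != n) stop("y/w length mismatch");
  double sw_all = 0.0, swy_all = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w[i] < 0) stop("weights must be non-negative");
    sw_all += w[i];
    swy_all += w[i] * y[i];
  }
  if (sw_all <= 0) stop("sum of weights must be positive");

  std::vector<int> feature{-1};
  std::vector<double> threshold{0.0};
  std::vector<int> left{-1}, right{-1};
  std::vector<double> value{swy_all / sw_all};
  std::vector<double> node_sw{sw_all}, node_swy{swy_all};
  std::vector<BestSplit> cand;
  std::vector<int> node_of(n, 0);

  cand.push_back(best_split_for_leaf(X, y, w, ord, node_of, 0,
                                     sw_all, swy_all));
  const double min_gain = 1e-12;
  int splits = 0;
  while (splits < max_split) {
    int pick = -1;
    double best_gain = min_gain;
    for (size_t t = 0; t < cand.size(); ++t) {
      if (feature[t] == -1 && cand[t].feature >= 0 &&
          cand[t].gain > best_gain) {
        best_gain = cand[t].gain;
        pick = (int)t;
      }
    }
    if (pick < 0) break;
    const int f = cand[pick].feature;
    const double thr = cand[pick].threshold;
    const int id_left = (int)feature.size();
    const int id_right = id_left + 1;
    double swL = 0.0, swyL = 0.0;
    for (int i = 0; i < n; ++i) {
      if (node_of[i] != pick) continue;
      if (X(i, f) <= thr) {
        node_of[i] = id_left;
        swL += w[i];
        swyL += w[i] * y[i];
      } else {
        node_of[i] = id_right;
      }
    }
    const double swR = node_sw[pick] - swL;
    const double swyR = node_swy[pick] - swyL;
    feature[pick] = f;
    threshold[pick] = thr;
    left[pick] = id_left;
    right[pick] = id_right;
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(swL > 0 ? swyL / swL : value[pick]);
    node_sw.push_back(swL);
    node_swy.push_back(swyL);
    feature.push_back(-1);
    threshold.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(swR > 0 ? swyR / swR : value[pick]);
    node_sw.push_back(swR);
    node_swy.push_back(swyR);
    cand.push_back(best_split_for_leaf(X, y, w, ord, node_of, id_left,
                                       swL, swyL));
    cand.push_back(best_split_for_leaf(X, y, w, ord, node_of, id_right,
                                       swR, swyR));
    cand[pick] = BestSplit();
    ++splits;
  }
  IntegerVector feat(feature.begin(), feature.end());
  IntegerVector lft(left.begin(), left.end());
  IntegerVector rgt(right.begin(), right.end());
  for (int t = 0; t < feat.size(); ++t) {
    if (feat[t] >= 0) feat[t] += 1;   // 1-based feature index for R
    if (lft[t] >= 0) lft[t] += 1;
    if (rgt[t] >= 0) rgt[t] += 1;
  }
  return List::create(_["feature"] = feat,
                      _["threshold"] = NumericVector(threshold.begin(),
                                                     threshold.end()),
                      _["left"] = lft, _["right"] = rgt,
                      _["value"] = NumericVector(value.begin(), value.end()),
                      _["n_splits"] = splits);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector value, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] > 0) {
      const int f = feature[node] - 1;
      if (f >= X.ncol()) stop("tree references feature beyond matrix");
      node = (X(i, f) <= threshold[node]) ? left[node] - 1 : right[node] - 1;
    }
    out[i] = value[node];
  }
  return out;
}
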