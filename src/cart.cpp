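// Weighted CART regression core.
//
// Greedy binary recursive partitioning minimizing weighted squared error,
// with the tuning knobs exposed by the training grid: maximum depth,
// minimum weight fraction per child node (relative to the total training
// weight), number of candidate features per node, and best vs random
// split strategy (random = one uniformly drawn threshold per candidate
// feature, best threshold among those candidates kept). Randomness is
// drawn from R's RNG so set.seed() on the R side governs reproducibility.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct NodeRec {
  int feature;       // -1 for leaf
  double threshold;
  int left, right;   // node indices, -1 for leaf
  double value;      // weighted mean of y
  double weight;     // total weight in node
  double improvement; // weighted SSE reduction achieved by the split
  int n;
  int depth;
};

struct Builder {
  const NumericMatrix& X;
  const NumericVector& y;
  const NumericVector& w;
  int max_depth;
  double min_child_weight; // absolute weight threshold per child
  int max_features;
  bool random_split;
  double total_weight;
  std::vector<NodeRec> nodes;

  Builder(const NumericMatrix& X_, const NumericVector& y_,
          const NumericVector& w_, int max_depth_, double mwf,
          int max_features_, bool random_split_)
      : X(X_), y(y_), w(w_), max_depth(max_depth_),
        max_features(max_features_), random_split(random_split_) {
    total_weight = 0.0;
    for (int i = 0; i < w.size(); ++i) total_weight += w[i];
    min_child_weight = mwf * total_weight;
  }

  // Fisher-Yates draw of k distinct column indices using R's RNG
  std::vector<int> sample_features(int p, int k) {
    std::vector<int> idx(p);
    for (int j = 0; j < p; ++j) idx[j] = j;
    for (int j = 0; j < k; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(idx[j], idx[r]);
    }
    idx.resize(k);
    return idx;
  }

  int build(std::vector<int>& rows, int depth) {
    double W = 0.0, Swy = 0.0, Swyy = 0.0;
    for (int i : rows) {
      W += w[i];
      Swy += w[i] * y[i];
      Swyy += w[i] * y[i] * y[i];
    }
    double pred = Swy / W;
    double sse = Swyy - Swy * Swy / W;

    NodeRec node{-1, NA_REAL, -1, -1, pred, W, 0.0, (int)rows.size(), depth};
    int id = (int)nodes.size();
    nodes.push_back(node);

    if (depth >= max_depth || (int)rows.size() < 2 || sse <= 1e-12)
      return id;

    std::vector<int> feats = sample_features(X.ncol(), max_features);
    int best_f = -1;
    double best_thr = 0.0, best_gain = 0.0;

    std::vector<std::pair<double, int>> xv;
    xv.reserve(rows.size());
    for (int f : feats) {
      xv.clear();
      for (int i : rows) xv.push_back({X(i, f), i});
      double xmin = xv[0].first, xmax = xv[0].first;
      for (auto& p_ : xv) {
        if (p_.first < xmin) xmin = p_.first;
        if (p_.first > xmax) xmax = p_.first;
      }
      if (xmax <= xmin) continue;

      if (random_split) {
        double thr = xmin + unif_rand() * (xmax - xmin);
        if (thr >= xmax) thr = xmax - 1e-12 * std::max(1.0, std::abs(xmax));
        double WL = 0, SL = 0, QL = 0;
        for (auto& p_ : xv) {
          int i = p_.second;
          if (p_.first <= thr) { WL += w[i]; SL += w[i]*y[i]; QL += w[i]*y[i]*y[i]; }
        }
        double WR = W - WL, SR = Swy - SL, QR = Swyy - QL;
        if (WL < min_child_weight || WR < min_child_weight || WL <= 0 || WR <= 0)
          continue;
        double gain = sse - ((QL - SL*SL/WL) + (QR - SR*SR/WR));
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_f = f; best_thr = thr;
        }
      } else {
        std::sort(xv.begin(), xv.end());
        double WL = 0, SL = 0, QL = 0;
        for (size_t s = 0; s + 1 < xv.size(); ++s) {
          int i = xv[s].second;
          WL += w[i]; SL += w[i]*y[i]; QL += w[i]*y[i]*y[i];
          if (xv[s + 1].first <= xv[s].first) continue; // tie, no cut here
          double WR = W - WL, SR = Swy - SL, QR = Swyy - QL;
          if (WL < min_child_weight || WR < min_child_weight || WR <= 0)
            continue;
          double gain = sse - ((QL - SL*SL/WL) + (QR - SR*SR/WR));
          if (gain > best_gain + 1e-12) {
            best_gain = gain; best_f = f;
            best_thr = xv[s].first + 0.5 * (xv[s + 1].first - xv[s].first);
          }
        }
      }
    }

    if (best_f < 0) return id;

    std::vector<int> left_rows, right_rows;
    for (int i : rows) {
      if (X(i, best_f) <= best_thr) left_rows.push_back(i);
      else right_rows.push_back(i);
    }
    if (left_rows.empty() || right_rows.empty()) return id;

    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].improvement = best_gain;
    int lid = build(left_rows, depth + 1);
    int rid = build(right_rows, depth + 1);
    nodes[id].left = lid;
    nodes[id].right = rid;
    return id;
  }
};

// [[Rcpp::export]]
List cart_fit_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth, double min_weight_fraction,
                  int max_features, bool random_split) {
  if (X.nrow() == 0) stop("empty training data");
  if (X.nrow() != y.size() || X.nrow() != w.size())
    stop("X, y, w sizes differ");
  RNGScope scope;
  Builder b(X, y, w, max_depth, min_weight_fraction, max_features,
            random_split);
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  b.build(rows, 0);

  int m = (int)b.nodes.size();
  IntegerVector feature(m), left(m), right(m), nn(m), depth(m);
  NumericVector threshold(m), value(m), weight(m), improvement(m);
  for (int i = 0; i < m; ++i) {
    const NodeRec& nd = b.nodes[i];
    feature[i] = nd.feature;
    threshold[i] = nd.threshold;
    left[i] = nd.left;
    right[i] = nd.right;
    value[i] = nd.value;
    weight[i] = nd.weight;
    improvement[i] = nd.improvement;
    nn[i] = nd.n;
    depth[i] = nd.depth;
  }
  return List::create(
    _["feature"] = feature, _["threshold"] = threshold,
    _["left"] = left, _["right"] = right, _["value"] = value,
    _["weight"] = weight, _["improvement"] = improvement,
    _["n"] = nn, _["depth"] = depth,
    _["total_weight"] = b.total_weight);
}

// [[Rcpp::export]]
NumericVector cart_predict_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
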