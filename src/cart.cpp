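// Weighted classification CART (Gini impurity) used by the random forest,
// AdaBoost stumps and the single-tree classifier.  Trees are grown with R's
// RNG (for mtry feature subsampling), so fits are reproducible under
// set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feature;        // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<std::vector<double>> prob;
};

static int grow(const NumericMatrix &X, const IntegerVector &y,
                const NumericVector &w, int K, int mtry, int min_split,
                int max_depth, std::vector<int> &idx, int depth, TreeBuf &buf) {
  const int n = idx.size();
  const int p = X.ncol();

  // weighted class counts
  std::vector<double> cnt(K, 0.0);
  double wtot = 0.0;
  for (int i = 0; i < n; ++i) {
    cnt[y[idx[i]] - 1] += w[idx[i]];
    wtot += w[idx[i]];
  }
  int nonzero = 0;
  for (int k = 0; k < K; ++k) if (cnt[k] > 0) ++nonzero;

  auto make_leaf = [&]() {
    int id = buf.feature.size();
    buf.feature.push_back(-1);
    buf.threshold.push_back(0.0);
    buf.left.push_back(-1);
    buf.right.push_back(-1);
    std::vector<double> pr(K, wtot > 0 ? 0.0 : 1.0 / K);
    if (wtot > 0) for (int k = 0; k < K; ++k) pr[k] = cnt[k] / wtot;
    buf.prob.push_back(pr);
    return id;
  };

  if (n < min_split || depth >= max_depth || nonzero <= 1) return make_leaf();

  // sample mtry features without replacement (R RNG)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = mtry < p ? mtry : p;
  if (m < p) {
    for (int j = 0; j < m; ++j) {
      int pick = j + (int)(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(feats[j], feats[pick]);
    }
    feats.resize(m);
    std::sort(feats.begin(), feats.end());   // deterministic tie order
  }

  double best_crit = R_PosInf;
  int best_f = -1;
  double best_t = 0.0;
  std::vector<std::pair<double, int>> sx(n);
  std::vector<double> cumk(K);

  for (int pass = 0; pass < 2 && best_f < 0; ++pass) {
    std::vector<int> fl = feats;
    if (pass == 1) {   // fallback: sampled features were all constant
      if ((int)feats.size() == p) break;
      fl.resize(p);
      for (int j = 0; j < p; ++j) fl[j] = j;
    }
    for (size_t fj = 0; fj < fl.size(); ++fj) {
      int f = fl[fj];
      for (int i = 0; i < n; ++i) sx[i] = {X(idx[i], f), idx[i]};
      std::sort(sx.begin(), sx.end());
      if (sx[0].first == sx[n - 1].first) continue;
      std::fill(cumk.begin(), cumk.end(), 0.0);
      double wl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        int yi = y[sx[i].second] - 1;
        double wi = w[sx[i].second];
        cumk[yi] += wi;
        wl += wi;
        if (sx[i].first >= sx[i + 1].first) continue;
        double sl = 0.0, sr = 0.0, wr = wtot - wl;
        for (int k = 0; k < K; ++k) {
          sl += cumk[k] * cumk[k];
          double rk = cnt[k] - cumk[k];
          sr += rk * rk;
        }
        double crit = (wl - sl / std::max(wl, 1e-300)) +
                      (wr - sr / std::max(wr, 1e-300));
        if (crit < best_crit - 1e-12) {
          best_crit = crit;
          best_f = f;
          best_t = 0.5 * (sx[i].first + sx[i + 1].first);
        }
      }
    }
  }
  if (best_f < 0) return make_leaf();

  std::vector<int> li, ri;
  li.reserve(n); ri.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(idx[i], best_f) <= best_t) li.push_back(idx[i]);
    else ri.push_back(idx[i]);
  }
  if (li.empty() || ri.empty()) return make_leaf();

  int id = buf.feature.size();
  buf.feature.push_back(best_f);
  buf.threshold.push_back(best_t);
  buf.left.push_back(-2);
  buf.right.push_back(-2);
  buf.prob.push_back(std::vector<double>());
  int lid = grow(X, y, w, K, mtry, min_split, max_depth, li, depth + 1, buf);
  int rid = grow(X, y, w, K, mtry, min_split, max_depth, ri, depth + 1, buf);
  buf.left[id] = lid;
  buf.right[id] = rid;
  return id;
}

// [[Rcpp::export]]
List cart_grow_class(NumericMatrix X, IntegerVector y, NumericVector w,
                     int K, int mtry, int min_split, int max_depth) {
  TreeBuf buf;
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  int md = max_depth < 0 ? INT_MAX : max_depth;
  grow(X, y, w, K, mtry, min_split, md, idx, 0, buf);
  int nn = buf.feature.size();
  NumericMatrix pr(nn, K);
  for (int i = 0; i < nn; ++i)
    if (!buf.prob[i].empty())
      for (int k = 0; k < K; ++k) pr(i, k) = buf.prob[i][k];
  return List::create(_["feature"] = wrap(buf.feature),
                      _["threshold"] = wrap(buf.threshold),
                      _["left"] = wrap(buf.left),
                      _["right"] = wrap(buf.right),
                      _["prob"] = pr);
}

// [[Rcpp::export]]
NumericMatrix cart_predict_class(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  NumericMatrix prob = tree["prob"];
  int n = X.nrow(), K = prob.ncol();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
    for (int k = 0; k < K; ++k) out(i, k) = prob(node, k);
  }
  return out;
}
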