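// Classification trees for the bagged ensemble: CART with Gini impurity,
// grown best-first under an explicit split budget (MaxNumSplits semantics)
// and a minimum weighted leaf size. Bootstrap resamples enter as per-row
// weights drawn from R's RNG, so the whole ensemble is reproducible from R.
//
// Split search walks a per-feature presorted order with incremental
// left/right class-weight sums, so each node costs O(p * n) with no
// allocation in the inner loop.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct SplitChoice {
  int feature;      // -1 if no valid split
  double threshold;
  double gain;      // weighted impurity decrease
};

struct Node {
  int feature;           // split feature (-1 leaf), 0-based
  double threshold;
  int left, right;       // child node ids (-1 for leaf)
  std::vector<double> dist;   // weighted class frequencies, normalized
  std::vector<int> rows;      // in-bag rows (kept only while a leaf)
  SplitChoice pending;
};

class TreeGrower {
 public:
  TreeGrower(const NumericMatrix &X, const IntegerVector &y, int K,
             const NumericVector &w, double min_leaf)
      : n_(X.nrow()), p_(X.ncol()), K_(K), y_(y), w_(w), min_leaf_(min_leaf),
        in_node_(n_, 0), left_cnt_(K), tot_cnt_(K) {
    cols_.resize(p_);
    order_.resize(p_);
    std::vector<int> base;
    base.reserve(n_);
    for (int i = 0; i < n_; ++i)
      if (w[i] > 0.0) base.push_back(i);
    inbag_ = base;
    for (int f = 0; f < p_; ++f) {
      cols_[f].resize(n_);
      for (int i = 0; i < n_; ++i) cols_[f][i] = X(i, f);
      order_[f] = base;
      const std::vector<double> &col = cols_[f];
      std::stable_sort(order_[f].begin(), order_[f].end(),
                       [&col](int a, int b) { return col[a] < col[b]; });
    }
  }

  const std::vector<int> &inbag() const { return inbag_; }

  // Best split over all features for the given in-bag rows.
  SplitChoice best_split(const std::vector<int> &rows) {
    SplitChoice best = {-1, 0.0, 0.0};
    std::fill(tot_cnt_.begin(), tot_cnt_.end(), 0.0);
    double n_tot = 0.0, s_tot = 0.0;
    for (int r : rows) {
      double &c = tot_cnt_[y_[r]];
      s_tot += w_[r] * w_[r] + 2.0 * w_[r] * c;
      c += w_[r];
      n_tot += w_[r];
    }
    if (n_tot < 2.0 * min_leaf_) return best;
    const double imp_parent = n_tot - s_tot / n_tot;
    if (imp_parent <= 1e-12) return best;

    for (int r : rows) in_node_[r] = 1;
    for (int f = 0; f < p_; ++f) {
      const std::vector<double> &col = cols_[f];
      std::fill(left_cnt_.begin(), left_cnt_.end(), 0.0);
      double n_left = 0.0, s_left = 0.0, s_right = s_tot;
      double prev_val = 0.0;
      bool seen = false;
      for (int r : order_[f]) {
        if (!in_node_[r]) continue;
        const double v = col[r];
        if (seen && v > prev_val) {
          const double n_right = n_tot - n_left;
          if (n_left >= min_leaf_ && n_right >= min_leaf_) {
            const double gain = imp_parent - (n_left - s_left / n_left) -
                                (n_right - s_right / n_right);
            // strict >: first feature / lowest threshold wins ties
            if (gain > best.gain + 1e-12) {
              best.feature = f;
              best.threshold = 0.5 * (prev_val + v);
              best.gain = gain;
            }
          }
        }
        const double wr = w_[r];
        double &cl = left_cnt_[y_[r]];
        s_left += wr * wr + 2.0 * wr * cl;
        s_right += wr * wr - 2.0 * wr * (tot_cnt_[y_[r]] - cl);
        cl += wr;
        n_left += wr;
        prev_val = v;
        seen = true;
      }
    }
    for (int r : rows) in_node_[r] = 0;
    if (best.gain <= 1e-12) best.feature = -1;
    return best;
  }

  std::vector<double> class_dist(const std::vector<int> &rows) const {
    std::vector<double> d(K_, 0.0);
    double tot = 0.0;
    for (int r : rows) {
      d[y_[r]] += w_[r];
      tot += w_[r];
    }
    for (double &v : d) v /= tot;
    return d;
  }

  double col(int f, int r) const { return cols_[f][r]; }

 private:
  int n_, p_, K_;
  const IntegerVector &y_;
  const NumericVector &w_;
  double min_leaf_;
  std::vector<std::vector<double>> cols_;
  std::vector<std::vector<int>> order_;
  std::vector<int> inbag_;
  std::vector<char> in_node_;
  std::vector<double> left_cnt_, tot_cnt_;
};

}  // namespace

// Grow one tree. Returns node arrays plus per-feature summed impurity decrease.
// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                   NumericVector w, int max_splits, double min_leaf) {
  TreeGrower tg(X, y, n_classes, w, min_leaf);
  if (tg.inbag().empty()) stop("no in-bag observations");

  std::vector<Node> nodes;
  std::vector<double> importance(X.ncol(), 0.0);

  auto make_node = [&](std::vector<int> rows) {
    Node nd;
    nd.feature = -1;
    nd.threshold = 0.0;
    nd.left = nd.right = -1;
    nd.dist = tg.class_dist(rows);
    nd.pending = tg.best_split(rows);
    nd.rows = std::move(rows);
    nodes.push_back(std::move(nd));
    return (int)nodes.size() - 1;
  };

  make_node(tg.inbag());
  int splits_used = 0;
  std::vector<int> open = {0};  // leaves with a pending split candidate

  while (splits_used < max_splits) {
    // best-first: expand the open leaf with the largest gain (earliest on ties)
    int pick = -1;
    double best_gain = 1e-12;
    for (int id : open) {
      const SplitChoice &s = nodes[id].pending;
      if (s.feature >= 0 && s.gain > best_gain) {
        best_gain = s.gain;
        pick = id;
      }
    }
    if (pick < 0) break;

    const int f = nodes[pick].pending.feature;
    const double thr = nodes[pick].pending.threshold;
    std::vector<int> lt, ge;
    for (int r : nodes[pick].rows) {
      if (tg.col(f, r) < thr) lt.push_back(r); else ge.push_back(r);
    }
    nodes[pick].feature = f;
    nodes[pick].threshold = thr;
    nodes[pick].rows.clear();
    importance[f] += nodes[pick].pending.gain;
    const int lid = make_node(std::move(lt));   // may reallocate `nodes`
    const int rid = make_node(std::move(ge));
    nodes[pick].left = lid;
    nodes[pick].right = rid;
    open.erase(std::remove(open.begin(), open.end(), pick), open.end());
    open.push_back(lid);
    open.push_back(rid);
    ++splits_used;
  }

  const int nn = (int)nodes.size();
  IntegerVector feature(nn), left(nn), right(nn);
  NumericVector threshold(nn);
  NumericMatrix dist(nn, n_classes);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    for (int k = 0; k < n_classes; ++k) dist(i, k) = nodes[i].dist[k];
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["dist"] = dist,
                      _["importance"] = NumericVector(importance.begin(),
                                                      importance.end()),
                      _["n_splits"] = splits_used);
}

// Leaf class distributions for new rows under one tree, accumulated into
// `acc` (n x K), so ensemble averaging needs no per-tree allocation in R.
// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericMatrix predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  NumericMatrix dist = tree["dist"];
  const int n = X.nrow(), K = dist.ncol();
  NumericMatrix out(n, K);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) < threshold[node]) ? left[node] : right[node];
    }
    for (int k = 0; k < K; ++k) out(i, k) = dist(node, k);
  }
  return out;
}

// Average leaf class distributions over a list of trees.
// [[Rcpp::export(name = ".predict_ensemble_cpp")]]
NumericMatrix predict_ensemble_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericMatrix first = predict_tree_cpp(trees[0], X);
  const int K = first.ncol();
  NumericMatrix acc(n, K);
  for (int i = 0; i < n * K; ++i) acc[i] = first[i];
  for (int t = 1; t < T; ++t) {
    NumericMatrix pt = predict_tree_cpp(trees[t], X);
    for (int i = 0; i < n * K; ++i) acc[i] += pt[i];
  }
  for (int i = 0; i < n * K; ++i) acc[i] /= T;
  return acc;
}
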