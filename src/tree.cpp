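// CART decision tree with Gini impurity: split search and prediction.
// Shared core for the decision-tree classifier and the random forest
// (which passes bootstrap row indices and mtry < p). Uses R's RNG for
// feature subsampling so results are reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // child indices, -1 for leaf
  int pred;         // majority class (0-based)
};

static double gini_from_counts(const std::vector<double>& cnt, double n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (double c : cnt) s += c * c;
  return 1.0 - s / (n * n);
}

static int majority(const std::vector<double>& cnt) {
  int best = 0;
  for (size_t k = 1; k < cnt.size(); ++k) if (cnt[k] > cnt[best]) best = (int)k;
  return best;
}

// [[Rcpp::export(name = ".cpp_grow_tree")]]
List cpp_grow_tree(NumericMatrix X, IntegerVector y, IntegerVector rows,
                   int n_classes, int mtry, int max_depth, int min_node) {
  const int p = X.ncol();
  std::vector<Node> nodes;
  // work stack: (node index, depth) with row subsets held per pending node
  struct Job { int node; int depth; std::vector<int> idx; };
  std::vector<Job> stack;

  std::vector<int> root_idx(rows.begin(), rows.end());
  nodes.push_back(Node{-1, 0.0, -1, -1, 0});
  stack.push_back(Job{0, 0, std::move(root_idx)});

  std::vector<int> feat_pool(p);
  for (int j = 0; j < p; ++j) feat_pool[j] = j;

  while (!stack.empty()) {
    Job job = std::move(stack.back());
    stack.pop_back();
    std::vector<int>& idx = job.idx;
    const int n = (int)idx.size();

    std::vector<double> cnt(n_classes, 0.0);
    for (int i : idx) cnt[y[i]] += 1.0;
    int pred = majority(cnt);
    nodes[job.node].pred = pred;

    double node_gini = gini_from_counts(cnt, (double)n);
    if (n < 2 * min_node || job.depth >= max_depth || node_gini <= 1e-12) {
      continue; // leaf
    }

    // sample mtry features without replacement via partial Fisher-Yates
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int r = j + (int)(unif_rand() * (p - j));
      if (r >= p) r = p - 1;
      std::swap(feat_pool[j], feat_pool[r]);
    }

    double best_gain = 1e-12;
    int best_feat = -1;
    double best_thr = 0.0;

    std::vector<std::pair<double, int>> vals(n);
    std::vector<double> lc(n_classes);
    for (int jj = 0; jj < m; ++jj) {
      int f = feat_pool[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(lc.begin(), lc.end(), 0.0);
      double nl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second] += 1.0;
        nl += 1.0;
        if (vals[i].first == vals[i + 1].first) continue;
        if (nl < min_node || (n - nl) < min_node) continue;
        double gl = gini_from_counts(lc, nl);
        std::vector<double> rc(n_classes);
        for (int k = 0; k < n_classes; ++k) rc[k] = cnt[k] - lc[k];
        double gr = gini_from_counts(rc, (double)n - nl);
        double gain = node_gini - (nl * gl + (n - nl) * gr) / (double)n;
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_feat < 0) continue; // no useful split -> leaf

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx) {
      if (X(i, best_feat) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) continue;

    int l_id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, pred});
    int r_id = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, pred});
    nodes[job.node].feature = best_feat;
    nodes[job.node].threshold = best_thr;
    nodes[job.node].left = l_id;
    nodes[job.node].right = r_id;
    stack.push_back(Job{l_id, job.depth + 1, std::move(li)});
    stack.push_back(Job{r_id, job.depth + 1, std::move(ri)});
  }

  const int nn = (int)nodes.size();
  IntegerVector feature(nn), left(nn), right(nn), pred(nn);
  NumericVector threshold(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    pred[i] = nodes[i].pred;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["pred"] = pred);
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
IntegerVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"],
                pred = tree["pred"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
    out[i] = pred[node];
  }
  return out;
}
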