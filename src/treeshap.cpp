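// Path-dependent TreeSHAP for regression-tree ensembles, plus node-cover
// accounting. Trees arrive as flat arrays (ranger treeInfo layout): for
// node j, left[j]/right[j] are 0-based child ids (-1 at leaves),
// feature[j] the 0-based split variable, threshold[j] the split value
// (x <= threshold goes left, matching ranger), value[j] the leaf
// prediction and cover[j] the number of in-bag training rows reaching j.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

void extend_path(PathElement *unique_path, int unique_depth,
                 double zero_fraction, double one_fraction,
                 int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight +=
        one_fraction * unique_path[i].pweight * (i + 1) /
        static_cast<double>(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) /
                             static_cast<double>(unique_depth + 1);
  }
}

void unwind_path(PathElement *unique_path, int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                                   (unique_depth - i) /
                                   static_cast<double>(unique_depth + 1);
    } else {
      unique_path[i].pweight =
          (unique_path[i].pweight * (unique_depth + 1)) /
          static_cast<double>(zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement *unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
                         static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight -
                         tmp * zero_fraction * (unique_depth - i) /
                             static_cast<double>(unique_depth + 1);
    } else {
      total += (unique_path[i].pweight / zero_fraction) /
               ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

void tree_shap_recursive(const Tree &tree, const double *x, double *phi,
                         double scale, int node_index, int unique_depth,
                         PathElement *parent_unique_path,
                         double parent_zero_fraction,
                         double parent_one_fraction,
                         int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tree.left[node_index] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * tree.value[node_index] *
          scale;
    }
    return;
  }

  const int split_feature = tree.feature[node_index];
  int hot_index, cold_index;
  if (x[split_feature] <= tree.threshold[node_index]) {
    hot_index = tree.left[node_index];
    cold_index = tree.right[node_index];
  } else {
    hot_index = tree.right[node_index];
    cold_index = tree.left[node_index];
  }
  const double w = tree.cover[node_index];
  const double hot_zero_fraction = tree.cover[hot_index] / w;
  const double cold_zero_fraction = tree.cover[cold_index] / w;
  double incoming_zero_fraction = 1.0;
  double incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, scale, hot_index, unique_depth + 1,
                      unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(tree, x, phi, scale, cold_index, unique_depth + 1,
                      unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split_feature);
}

int tree_depth(const IntegerVector &left, const IntegerVector &right,
               int node, int depth) {
  if (left[node] < 0) return depth;
  int dl = tree_depth(left, right, left[node], depth + 1);
  int dr = tree_depth(left, right, right[node], depth + 1);
  return dl > dr ? dl : dr;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix treeshap_values(List trees, NumericMatrix X,
                              NumericVector tree_weights) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  if (tree_weights.size() != T) stop("one weight per tree required");
  NumericMatrix phi(n, p);
  std::vector<double> xrow(p);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector left = tr["left"], right = tr["right"],
                  feature = tr["feature"];
    NumericVector threshold = tr["threshold"], value = tr["value"],
                  cover = tr["cover"];
    Tree tree{left.begin(), right.begin(),    feature.begin(),
              threshold.begin(), value.begin(), cover.begin()};
    const double wt = tree_weights[t];
    if (wt == 0) continue;
    const int maxd = tree_depth(left, right, 0, 0) + 2;
    std::vector<PathElement> paths((maxd + 1) * (maxd + 2) / 2 + maxd + 2);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      std::vector<double> phirow(p, 0.0);
      tree_shap_recursive(tree, xrow.data(), phirow.data(), wt, 0, 0,
                          paths.data(), 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += phirow[j];
    }
  }
  return phi;
}

// Expected value of each tree (cover-weighted mean of leaf values),
// combined with the same per-tree weights: the SHAP base value.
// [[Rcpp::export]]
double treeshap_base(List trees, NumericVector tree_weights) {
  const int T = trees.size();
  double base = 0;
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector left = tr["left"];
    NumericVector value = tr["value"], cover = tr["cover"];
    double num = 0, den = 0;
    for (int j = 0; j < left.size(); ++j) {
      if (left[j] < 0) {
        num += value[j] * cover[j];
        den += cover[j];
      }
    }
    if (den > 0) base += tree_weights[t] * num / den;
  }
  return base;
}

// Count in-bag training rows reaching every node of one tree.
// [[Rcpp::export]]
NumericVector tree_node_cover(IntegerVector left, IntegerVector right,
                              IntegerVector feature, NumericVector threshold,
                              NumericMatrix X_train,
                              NumericVector inbag_counts) {
  const int n = X_train.nrow();
  NumericVector cover(left.size());
  for (int i = 0; i < n; ++i) {
    const double w = inbag_counts[i];
    if (w <= 0) continue;
    int node = 0;
    for (;;) {
      cover[node] += w;
      if (left[node] < 0) break;
      node = (X_train(i, feature[node]) <= threshold[node]) ? left[node]
                                                            : right[node];
    }
  }
  return cover;
}
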