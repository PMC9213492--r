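#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Stochastic gradient boosting with squared-error loss and depth-limited
// exhaustive-search regression trees. Each tree is grown on a random subset
// of the sites; the held-out sites score the tree's contribution to the
// deviance (the basis of the cross-validated R^2) before the update is
// applied. Split improvements (reductions in sum of squares) are accumulated
// per predictor per tree; these are the raw material of the variable
// importance scores.

struct Node {
  int var;        // 0-based predictor index, -1 for leaf
  double split;   // x <= split goes left
  int left, right;
  double pred;    // node mean of the working response
  double improve; // SS reduction achieved by the split (0 for leaves)
};

struct TreeGrower {
  const NumericMatrix& X;
  const std::vector<double>& r;
  int max_depth, min_obs;
  std::vector<Node> nodes;
  std::vector<double> var_improve; // per-predictor, this tree

  TreeGrower(const NumericMatrix& X_, const std::vector<double>& r_,
             int max_depth_, int min_obs_)
    : X(X_), r(r_), max_depth(max_depth_), min_obs(min_obs_),
      var_improve(X_.ncol(), 0.0) {}

  int grow(std::vector<int>& rows, int depth) {
    int n = rows.size();
    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += r[rows[i]];
    double mean = sum / n;

    Node nd; nd.var = -1; nd.split = 0.0; nd.left = -1; nd.right = -1;
    nd.pred = mean; nd.improve = 0.0;
    int self = nodes.size();
    nodes.push_back(nd);

    if (depth >= max_depth || n < 2 * min_obs) return self;

    int p = X.ncol();
    double best_gain = 0.0, best_split = 0.0;
    int best_var = -1;
    std::vector<std::pair<double,double> > xv(n);

    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i)
        xv[i] = std::make_pair(X(rows[i], j), r[rows[i]]);
      std::sort(xv.begin(), xv.end());
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xv[i].second;
        if (xv[i].first == xv[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        if (nl < min_obs || nr < min_obs) continue;
        double sr = sum - sl;
        double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
        if (gain > best_gain) {
          best_gain = gain;
          best_var = j;
          best_split = 0.5 * (xv[i].first + xv[i + 1].first);
        }
      }
    }

    if (best_var < 0 || best_gain <= 0.0) return self;

    std::vector<int> lrows, rrows;
    lrows.reserve(n); rrows.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(rows[i], best_var) <= best_split) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    if ((int)lrows.size() < min_obs || (int)rrows.size() < min_obs) return self;

    nodes[self].var = best_var;
    nodes[self].split = best_split;
    nodes[self].improve = best_gain;
    var_improve[best_var] += best_gain;
    int li = grow(lrows, depth + 1);
    nodes[self].left = li;
    int ri = grow(rrows, depth + 1);
    nodes[self].right = ri;
    return self;
  }
};

static double tree_predict_row(const NumericMatrix& tree,
                               const NumericMatrix& X, int row) {
  int node = 0;
  while (true) {
    int var = (int)tree(node, 0);
    if (var < 0) return tree(node, 4);
    node = (X(row, var) <= tree(node, 1)) ? (int)tree(node, 2)
                                          : (int)tree(node, 3);
  }
}

// [[Rcpp::export(name = ".gbm_fit_cpp")]]
List gbm_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                 double shrinkage, int max_depth, double holdout_frac,
                 int min_obs) {
  RNGScope scope; // bagging uses R's RNG: set.seed() in R reproduces the fit
  int n = X.nrow(), p = X.ncol();
  int n_train = (int)std::floor(n * (1.0 - holdout_frac) + 0.5);
  if (n_train < 2 * min_obs) n_train = std::min(n, 2 * min_obs);
  if (n_train > n) n_train = n;

  double init = mean(y);
  std::vector<double> F(n, init), resid(n);
  NumericVector oob_improve(n_trees);
  NumericMatrix var_imp(p, n_trees);
  List trees(n_trees);
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  for (int t = 0; t < n_trees; ++t) {
    // Fisher-Yates permutation from R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    std::vector<int> train(perm.begin(), perm.begin() + n_train);

    for (int i = 0; i < n; ++i) resid[i] = y[i] - F[i];
    TreeGrower g(X, resid, max_depth, min_obs);
    g.grow(train, 0);

    int nn = g.nodes.size();
    NumericMatrix tm(nn, 6);
    for (int k = 0; k < nn; ++k) {
      tm(k, 0) = g.nodes[k].var;
      tm(k, 1) = g.nodes[k].split;
      tm(k, 2) = g.nodes[k].left;
      tm(k, 3) = g.nodes[k].right;
      tm(k, 4) = g.nodes[k].pred;
      tm(k, 5) = g.nodes[k].improve;
    }
    trees[t] = tm;
    for (int j = 0; j < p; ++j) var_imp(j, t) = g.var_improve[j];

    // held-out deviance improvement of this tree, then commit the update
    double before = 0.0, after = 0.0;
    for (int i = n_train; i < n; ++i) {
      int row = perm[i];
      double e0 = y[row] - F[row];
      double step = shrinkage * tree_predict_row(tm, X, row);
      before += e0 * e0;
      after += (e0 - step) * (e0 - step);
    }
    int n_oob = n - n_train;
    oob_improve[t] = n_oob > 0 ? (before - after) / n_oob : NA_REAL;

    for (int i = 0; i < n; ++i)
      F[i] += shrinkage * tree_predict_row(tm, X, i);
  }

  return List::create(_["init"] = init, _["trees"] = trees,
                      _["oob_improve"] = oob_improve,
                      _["var_imp"] = var_imp,
                      _["fitted_all"] = NumericVector(F.begin(), F.end()));
}

// [[Rcpp::export(name = ".gbm_predict_cpp")]]
NumericVector gbm_predict_cpp(List trees, double init, double shrinkage,
                              NumericMatrix X, int n_use) {
  int n = X.nrow();
  NumericVector out(n, init);
  int nt = std::min((int)trees.size(), n_use);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i)
      out[i] += shrinkage * tree_predict_row(tm, X, i);
  }
  return out;
}
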