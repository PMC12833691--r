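#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Path-dependent SHAP for ensembles of binary regression trees, following
// the polynomial-time dynamic-programming algorithm of Lundberg et al.
// Trees are passed as flat arrays (0-based node ids, -1 for "no child"):
//   feature[j]   : split variable (0-based) or -1 at leaves
//   threshold[j] : x[feature] <= threshold goes left
//   value[j]     : prediction at leaves
//   cover[j]     : training/background weight reaching the node
// tree_start gives the first node index of each tree; nodes of a tree are
// contiguous, root first.

struct PathElement {
  int d;        // feature index
  double z;     // fraction of zero (not-conditioned) paths
  double o;     // fraction of one (conditioned) paths
  double w;     // permutation weight
};

static void extend_path(PathElement* m, int depth, double pz, double po,
                        int pi) {
  m[depth].d = pi;
  m[depth].z = pz;
  m[depth].o = po;
  m[depth].w = (depth == 0) ? 1.0 : 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1.0) / (depth + 1.0);
    m[i].w = pz * m[i].w * (depth - i) / (depth + 1.0);
  }
}

static void unwind_path(PathElement* m, int depth, int idx) {
  const double o = m[idx].o, z = m[idx].z;
  double nxt = m[depth].w;
  for (int i = depth - 1; i >= 0; --i) {
    if (o != 0.0) {
      const double tmp = m[i].w;
      m[i].w = nxt * (depth + 1.0) / ((i + 1.0) * o);
      nxt = tmp - m[i].w * z * (depth - i) / (depth + 1.0);
    } else {
      m[i].w = m[i].w * (depth + 1.0) / (z * (depth - i));
    }
  }
  for (int i = idx; i < depth; ++i) {
    m[i].d = m[i + 1].d;
    m[i].z = m[i + 1].z;
    m[i].o = m[i + 1].o;
  }
}

static double unwound_path_sum(const PathElement* m, int depth, int idx) {
  const double o = m[idx].o, z = m[idx].z;
  double nxt = m[depth].w, total = 0.0;
  for (int i = depth - 1; i >= 0; --i) {
    if (o != 0.0) {
      const double tmp = nxt * (depth + 1.0) / ((i + 1.0) * o);
      total += tmp;
      nxt = m[i].w - tmp * z * (depth - i) / (depth + 1.0);
    } else {
      total += m[i].w / z * (depth + 1.0) / (depth - i);
    }
  }
  return total;
}

struct FlatTrees {
  const int* feature;
  const double* threshold;
  const int* left;
  const int* right;
  const double* value;
  const double* cover;
};

static void shap_recurse(const FlatTrees& t, const double* x, double* phi,
                         int node, int depth, PathElement* parent_path,
                         double pz, double po, int pi) {
  PathElement* path = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth + 1, path);
  extend_path(path, depth, pz, po, pi);
  if (t.feature[node] < 0) {  // leaf
    for (int i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      phi[path[i].d] += w * (path[i].o - path[i].z) * t.value[node];
    }
  } else {
    const int f = t.feature[node];
    int hot, cold;
    if (x[f] <= t.threshold[node]) {
      hot = t.left[node]; cold = t.right[node];
    } else {
      hot = t.right[node]; cold = t.left[node];
    }
    const double cw = t.cover[node];
    const double hot_z = t.cover[hot] / cw;
    const double cold_z = t.cover[cold] / cw;
    double iz = 1.0, io = 1.0;
    int idx = 0;
    for (; idx <= depth; ++idx)
      if (path[idx].d == f) break;
    if (idx <= depth) {
      iz = path[idx].z;
      io = path[idx].o;
      unwind_path(path, depth, idx);
      depth -= 1;
    }
    shap_recurse(t, x, phi, hot, depth + 1, path, hot_z * iz, io, f);
    shap_recurse(t, x, phi, cold, depth + 1, path, cold_z * iz, 0.0, f);
  }
}

static int tree_depth(const FlatTrees& t, int node) {
  if (t.feature[node] < 0) return 0;
  return 1 + std::max(tree_depth(t, t.left[node]),
                      tree_depth(t, t.right[node]));
}

// Average per-observation SHAP attributions over an ensemble whose
// prediction is the mean of per-tree predictions. Returns an n x k matrix
// plus the ensemble base value (mean of cover-weighted leaf values).
// [[Rcpp::export]]
List treeshap_cpp(IntegerVector feature, NumericVector threshold,
                  IntegerVector left, IntegerVector right,
                  NumericVector value, NumericVector cover,
                  IntegerVector tree_start, NumericMatrix X) {
  const int n = X.nrow(), k = X.ncol(), T = tree_start.size();
  FlatTrees t{feature.begin(), threshold.begin(), left.begin(),
              right.begin(), value.begin(), cover.begin()};
  NumericMatrix phi(n, k);
  double base = 0.0;
  std::vector<double> row(k);
  std::vector<double> phirow(k);
  for (int tr = 0; tr < T; ++tr) {
    const int root = tree_start[tr];
    // base value of this tree
    const int end = (tr + 1 < T) ? tree_start[tr + 1] : feature.size();
    double b = 0.0;
    for (int j = root; j < end; ++j)
      if (feature[j] < 0) b += value[j] * cover[j];
    base += b / cover[root];
    const int D = tree_depth(t, root);
    std::vector<PathElement> buf((D + 2) * (D + 3) / 2 + 2);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < k; ++j) row[j] = X(i, j);
      std::fill(phirow.begin(), phirow.end(), 0.0);
      shap_recurse(t, row.data(), phirow.data(), root, 0, buf.data(), 1.0,
                   1.0, -1);
      for (int j = 0; j < k; ++j) phi(i, j) += phirow[j];
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < k; ++j) phi(i, j) /= T;
  base /= T;
  return List::create(_["phi"] = phi, _["base"] = base);
}

// Background covers: number of rows of X reaching each node.
// [[Rcpp::export]]
NumericVector tree_cover_cpp(IntegerVector feature, NumericVector threshold,
                             IntegerVector left, IntegerVector right,
                             IntegerVector tree_start, NumericMatrix X) {
  const int n = X.nrow(), T = tree_start.size();
  NumericVector cover(feature.size());
  for (int tr = 0; tr < T; ++tr) {
    const int root = tree_start[tr];
    for (int i = 0; i < n; ++i) {
      int node = root;
      for (;;) {
        cover[node] += 1.0;
        const int f = feature[node];
        if (f < 0) break;
        node = (X(i, f) <= threshold[node]) ? left[node] : right[node];
      }
    }
  }
  return cover;
}

// Ensemble prediction (mean over trees) from the flat representation.
// [[Rcpp::export]]
NumericVector tree_predict_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector value, IntegerVector tree_start,
                               NumericMatrix X) {
  const int n = X.nrow(), T = tree_start.size();
  NumericVector out(n);
  for (int tr = 0; tr < T; ++tr) {
    const int root = tree_start[tr];
    for (int i = 0; i < n; ++i) {
      int node = root;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      out[i] += value[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
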