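// Path-dependent TreeSHAP: polynomial-time Shapley values for decision-tree
// ensembles with the conditional-expectation (cover-weighted) value function.
// Trees arrive as flat node arrays; children/feature indices are 0-based with
// -1 marking "none". The `le` flag selects the split convention:
// le = true  -> x <= split goes left (ranger)
// le = false -> x <  split goes left (xgboost)

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct PathElem {
  int d;        // feature index of the split that created this path element
  double z;     // fraction of zero (cold) paths flowing through
  double o;     // fraction of one (hot) paths flowing through
  double w;     // permutation weight
};

struct Tree {
  std::vector<int> left, right, var;
  std::vector<double> split, value, cover;
  bool le;   // x <= split goes left (ranger) vs x < split (xgboost)
  bool f32;  // compare in single precision (xgboost stores float32 thresholds)
};

bool goes_left(const Tree& tr, double xv, int node) {
  if (tr.f32) {
    float x = static_cast<float>(xv), s = static_cast<float>(tr.split[node]);
    return tr.le ? (x <= s) : (x < s);
  }
  return tr.le ? (xv <= tr.split[node]) : (xv < tr.split[node]);
}

void extend(std::vector<PathElem>& m, double pz, double po, int pi) {
  int l = static_cast<int>(m.size());
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (l + 1);
    m[i].w = pz * m[i].w * (l - i) / (l + 1);
  }
}

std::vector<PathElem> unwind(const std::vector<PathElem>& min, int i) {
  std::vector<PathElem> m = min;
  int l = static_cast<int>(m.size()) - 1;
  double n = m[l].w;
  for (int j = l - 1; j >= 0; --j) {
    if (m[i].o != 0) {
      double t = m[j].w;
      m[j].w = n * (l + 1) / ((j + 1) * m[i].o);
      n = t - m[j].w * m[i].z * (l - j) / (l + 1);
    } else {
      m[j].w = m[j].w * (l + 1) / (m[i].z * (l - j));
    }
  }
  for (int j = i; j < l; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
  return m;
}

void recurse(const Tree& tr, const double* x, std::vector<double>& phi,
             int node, std::vector<PathElem> m, double pz, double po, int pi) {
  extend(m, pz, po, pi);
  if (tr.left[node] < 0) {  // leaf
    double v = tr.value[node];
    for (int i = 1; i < static_cast<int>(m.size()); ++i) {
      std::vector<PathElem> mu = unwind(m, i);
      double w = 0;
      for (const PathElem& e : mu) w += e.w;
      phi[m[i].d] += w * (m[i].o - m[i].z) * v;
    }
    return;
  }
  int f = tr.var[node];
  bool gl = goes_left(tr, x[f], node);
  int hot = gl ? tr.left[node] : tr.right[node];
  int cold = gl ? tr.right[node] : tr.left[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < static_cast<int>(m.size()); ++i)
    if (m[i].d == f) { k = i; break; }
  if (k >= 0) {
    iz = m[k].z;
    io = m[k].o;
    m = unwind(m, k);
  }
  double cj = tr.cover[node];
  recurse(tr, x, phi, hot, m, iz * tr.cover[hot] / cj, io, f);
  recurse(tr, x, phi, cold, m, iz * tr.cover[cold] / cj, 0.0, f);
}

Tree tree_from_list(const List& tl) {
  Tree tr;
  IntegerVector left = tl["left"], right = tl["right"], var = tl["var"];
  NumericVector split = tl["split"], value = tl["value"], cover = tl["cover"];
  tr.left = std::vector<int>(left.begin(), left.end());
  tr.right = std::vector<int>(right.begin(), right.end());
  tr.var = std::vector<int>(var.begin(), var.end());
  tr.split = std::vector<double>(split.begin(), split.end());
  tr.value = std::vector<double>(value.begin(), value.end());
  tr.cover = std::vector<double>(cover.begin(), cover.end());
  tr.le = as<bool>(tl["le"]);
  tr.f32 = as<bool>(tl["f32"]);
  return tr;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix treeshap_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix phi(n, p);
  std::vector<double> xrow(p);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int s = 0; s < n; ++s) {
      for (int j = 0; j < p; ++j) xrow[j] = X(s, j);
      std::vector<double> ph(p, 0.0);
      recurse(tr, xrow.data(), ph, 0, {}, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(s, j) += ph[j];
    }
  }
  return phi;
}

// Weighted number of training observations reaching each node; used to build
// the cover arrays for forests whose export lacks them (ranger).
// [[Rcpp::export]]
NumericVector tree_covers_cpp(IntegerVector left, IntegerVector right,
                              IntegerVector var, NumericVector split,
                              bool le, NumericMatrix X, NumericVector w) {
  int nodes = left.size();
  NumericVector cover(nodes);
  for (int s = 0; s < X.nrow(); ++s) {
    double ws = w[s];
    if (ws == 0) continue;
    int node = 0;
    while (true) {
      cover[node] += ws;
      if (left[node] < 0) break;
      double xv = X(s, var[node]);
      bool goes_left = le ? (xv <= split[node]) : (xv < split[node]);
      node = goes_left ? left[node] : right[node];
    }
  }
  return cover;
}

// Evaluate the ensemble on X by plain tree traversal (internal consistency
// checks between the extracted representation and the source model).
// [[Rcpp::export]]
NumericVector tree_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int s = 0; s < n; ++s) {
      int node = 0;
      while (tr.left[node] >= 0) {
        node = goes_left(tr, X(s, tr.var[node]), node) ? tr.left[node]
                                                       : tr.right[node];
      }
      out[s] += tr.value[node];
    }
  }
  return out;
}
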