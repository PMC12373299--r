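// Path-dependent TreeSHAP for a single decision tree.
//
// Nodes are 0-based; feature[i] == -1 marks a leaf. For internal nodes the
// "yes" child is taken when x < threshold (strict_lt = true) or
// x <= threshold (strict_lt = false). Covers are the number of training
// rows reaching each node and must be internally consistent
// (cover[parent] == cover[yes] + cover[no]), which guarantees local
// accuracy: base + sum(phi) == the tree's output for the row.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct PathElement {
  int d;
  double z;  // fraction of zero (feature-absent) paths flowing through
  double o;  // fraction of one (feature-present) paths flowing through
  double w;  // permutation weight
};

void extend_path(PathElement *m, int ud, double pz, double po, int pi) {
  m[ud].d = pi;
  m[ud].z = pz;
  m[ud].o = po;
  m[ud].w = (ud == 0) ? 1.0 : 0.0;
  for (int i = ud - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(ud + 1);
    m[i].w = pz * m[i].w * (ud - i) / static_cast<double>(ud + 1);
  }
}

void unwind_path(PathElement *m, int ud, int path_index) {
  const double o = m[path_index].o;
  const double z = m[path_index].z;
  double next_one = m[ud].w;
  for (int i = ud - 1; i >= 0; --i) {
    if (o != 0.0) {
      const double tmp = m[i].w;
      m[i].w = next_one * (ud + 1) / static_cast<double>((i + 1) * o);
      next_one = tmp - m[i].w * z * (ud - i) / static_cast<double>(ud + 1);
    } else {
      m[i].w = m[i].w * (ud + 1) / static_cast<double>(z * (ud - i));
    }
  }
  for (int i = path_index; i < ud; ++i) {
    m[i].d = m[i + 1].d;
    m[i].z = m[i + 1].z;
    m[i].o = m[i + 1].o;
  }
}

double unwound_path_sum(const PathElement *m, int ud, int path_index) {
  const double o = m[path_index].o;
  const double z = m[path_index].z;
  double next_one = m[ud].w;
  double total = 0.0;
  if (o != 0.0) {
    for (int i = ud - 1; i >= 0; --i) {
      const double tmp = next_one / static_cast<double>((i + 1) * o);
      total += tmp;
      next_one = m[i].w - tmp * z * (ud - i);
    }
  } else {
    for (int i = ud - 1; i >= 0; --i) {
      total += m[i].w / (z * (ud - i));
    }
  }
  return total * (ud + 1);
}

struct Tree {
  const int *feature;
  const double *threshold;
  const int *yes;
  const int *no;
  const double *cover;
  const double *value;
  bool strict_lt;
};

void recurse(const Tree &tree, const double *x, double *phi, int node,
             std::vector<PathElement> m, double pz, double po, int pi) {
  const int ud = static_cast<int>(m.size());
  m.resize(ud + 1);
  extend_path(m.data(), ud, pz, po, pi);
  const int f = tree.feature[node];
  if (f < 0) {  // leaf
    for (int i = 1; i <= ud; ++i) {
      const double w = unwound_path_sum(m.data(), ud, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * tree.value[node];
    }
    return;
  }
  const double xv = x[f];
  const bool go_yes = tree.strict_lt ? (xv < tree.threshold[node])
                                     : (xv <= tree.threshold[node]);
  const int hot = go_yes ? tree.yes[node] : tree.no[node];
  const int cold = go_yes ? tree.no[node] : tree.yes[node];
  const double w = tree.cover[node];
  const double hot_z = tree.cover[hot] / w;
  const double cold_z = tree.cover[cold] / w;
  double iz = 1.0, io = 1.0;
  int path_index = -1;
  for (int i = 0; i <= ud; ++i) {
    if (m[i].d == f) { path_index = i; break; }
  }
  if (path_index >= 0) {
    iz = m[path_index].z;
    io = m[path_index].o;
    unwind_path(m.data(), ud, path_index);
    m.resize(ud);
  }
  recurse(tree, x, phi, hot, m, hot_z * iz, io, f);
  recurse(tree, x, phi, cold, m, cold_z * iz, 0.0, f);
}

}  // namespace

// [[Rcpp::export]]
List treeshap_tree(IntegerVector feature, NumericVector threshold,
                   IntegerVector yes, IntegerVector no,
                   NumericVector cover, NumericVector value,
                   NumericMatrix X, bool strict_lt) {
  const int n = X.nrow(), p = X.ncol();
  Tree tree{feature.begin(), threshold.begin(), yes.begin(), no.begin(),
            cover.begin(), value.begin(), strict_lt};
  NumericMatrix phi(n, p);
  // expected value of the tree under the cover measure
  double base = 0.0;
  const int n_nodes = feature.size();
  std::vector<double> reach(n_nodes, 0.0);
  reach[0] = 1.0;
  for (int j = 0; j < n_nodes; ++j) {
    if (feature[j] < 0) {
      base += reach[j] * value[j];
    } else {
      reach[yes[j]] += reach[j] * cover[yes[j]] / cover[j];
      reach[no[j]] += reach[j] * cover[no[j]] / cover[j];
    }
  }
  std::vector<double> xrow(p);
  std::vector<double> phirow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(phirow.begin(), phirow.end(), 0.0);
    std::vector<PathElement> m;
    m.reserve(64);
    recurse(tree, xrow.data(), phirow.data(), 0, m, 1.0, 1.0, -1);
    for (int j = 0; j < p; ++j) phi(i, j) = phirow[j];
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}
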