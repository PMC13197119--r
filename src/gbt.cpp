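// Gradient-boosted decision trees with a second-order logistic objective.
// Exact greedy split search on presorted features, bernoulli row subsampling,
// per-tree column subsampling, hessian-based min_child_weight, L2 (lambda)
// leaf regularization, and optional early stopping on validation AUPR.
// All randomness comes from R's RNG so set.seed() on the R side makes
// training fully deterministic.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Average precision (step-wise PR integration) with tied scores grouped.
// Must stay in sync with pr_curve() on the R side.
static double aupr_margin(const std::vector<double>& score,
                          const std::vector<int>& y) {
  const int n = (int)score.size();
  int npos = 0;
  for (int i = 0; i < n; ++i) npos += y[i];
  if (npos == 0 || npos == n) return NA_REAL;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return score[a] > score[b];
  });
  double ap = 0.0;
  int tp = 0, fp = 0, i = 0;
  while (i < n) {
    int j = i, tp_add = 0, fp_add = 0;
    while (j < n && score[ord[j]] == score[ord[i]]) {
      if (y[ord[j]]) ++tp_add; else ++fp_add;
      ++j;
    }
    tp += tp_add; fp += fp_add;
    double prec = (double)tp / (double)(tp + fp);
    ap += ((double)tp_add / (double)npos) * prec;
    i = j;
  }
  return ap;
}

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x < threshold
  std::vector<int> left, right;
  std::vector<double> value;     // leaf weight (eta already applied)
  std::vector<double> gain;      // split gain
  std::vector<double> cover;     // hessian sum at node
  int add_node() {
    feature.push_back(-1); threshold.push_back(0.0);
    left.push_back(-1); right.push_back(-1);
    value.push_back(0.0); gain.push_back(0.0); cover.push_back(0.0);
    return (int)feature.size() - 1;
  }
  double predict_row(const NumericMatrix& X, int i) const {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) < threshold[node]) ? left[node] : right[node];
    }
    return value[node];
  }
};

static List tree_to_list(const Tree& t) {
  return List::create(
    _["feature"]   = IntegerVector(t.feature.begin(), t.feature.end()),
    _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
    _["left"]      = IntegerVector(t.left.begin(), t.left.end()),
    _["right"]     = IntegerVector(t.right.begin(), t.right.end()),
    _["value"]     = NumericVector(t.value.begin(), t.value.end()),
    _["gain"]      = NumericVector(t.gain.begin(), t.gain.end()),
    _["cover"]     = NumericVector(t.cover.begin(), t.cover.end()));
}

static Tree tree_from_list(const List& l) {
  Tree t;
  IntegerVector f = l["feature"], le = l["left"], ri = l["right"];
  NumericVector th = l["threshold"], va = l["value"], ga = l["gain"], co = l["cover"];
  t.feature.assign(f.begin(), f.end());
  t.threshold.assign(th.begin(), th.end());
  t.left.assign(le.begin(), le.end());
  t.right.assign(ri.begin(), ri.end());
  t.value.assign(va.begin(), va.end());
  t.gain.assign(ga.begin(), ga.end());
  t.cover.assign(co.begin(), co.end());
  return t;
}

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, IntegerVector y,
                   int nrounds, double eta, int max_depth,
                   double subsample, double colsample,
                   double min_child_weight, double lambda,
                   double base_score,
                   Nullable<NumericMatrix> Xval_, Nullable<IntegerVector> yval_,
                   int early_stopping_rounds) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 1 || p < 1) stop("empty training matrix");

  const double base_margin = std::log(base_score / (1.0 - base_score));

  bool has_val = false;
  NumericMatrix Xval;
  std::vector<int> yval;
  if (Xval_.isNotNull() && yval_.isNotNull()) {
    Xval = NumericMatrix(Xval_);
    IntegerVector yv(yval_);
    yval.assign(yv.begin(), yv.end());
    int pos = 0;
    for (size_t i = 0; i < yval.size(); ++i) pos += yval[i];
    has_val = yval.size() > 0 && pos > 0 && pos < (int)yval.size();
  }

  // presort each feature once
  std::vector<std::vector<int>> ord(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[j][i] = i;
    std::stable_sort(ord[j].begin(), ord[j].end(), [&](int a, int b) {
      return X(a, j) < X(b, j);
    });
  }

  std::vector<double> margin(n, base_margin);
  std::vector<double> val_margin(has_val ? Xval.nrow() : 0, base_margin);

  std::vector<Tree> trees;
  std::vector<double> imp_gain(p, 0.0);
  std::vector<double> imp_freq(p, 0.0);
  // per-tree importance kept so truncation at best_iter stays consistent
  std::vector<std::vector<double>> tree_gain, tree_freq;

  int best_iter = -1;
  double best_score = -1.0;
  std::vector<double> eval_log;

  std::vector<double> g(n), h(n);
  std::vector<int> node_of(n);

  const int ncols_used = std::max(1, (int)std::lround(colsample * p));

  for (int round = 0; round < nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pr = sigmoid(margin[i]);
      g[i] = pr - y[i];
      h[i] = pr * (1.0 - pr);
    }

    // bernoulli row subsample (R RNG)
    int n_samp = 0;
    if (subsample >= 1.0) {
      std::fill(node_of.begin(), node_of.end(), 0);
      n_samp = n;
    } else {
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < subsample) { node_of[i] = 0; ++n_samp; }
        else node_of[i] = -1;
      }
      if (n_samp == 0) { std::fill(node_of.begin(), node_of.end(), 0); n_samp = n; }
    }

    // column subsample without replacement (partial Fisher-Yates, R RNG)
    std::vector<int> cols(p);
    for (int j = 0; j < p; ++j) cols[j] = j;
    if (ncols_used < p) {
      for (int j = 0; j < ncols_used; ++j) {
        int k = j + (int)std::floor(unif_rand() * (p - j));
        if (k >= p) k = p - 1;
        std::swap(cols[j], cols[k]);
      }
      cols.resize(ncols_used);
      std::sort(cols.begin(), cols.end());
    }

    Tree tree;
    tree.add_node(); // root
    std::vector<double> t_gain(p, 0.0), t_freq(p, 0.0);

    // active nodes at current depth
    std::vector<int> active; active.push_back(0);
    // aggregate stats per tree node id
    std::vector<double> node_G(1, 0.0), node_H(1, 0.0);
    for (int i = 0; i < n; ++i) {
      if (node_of[i] == 0) { node_G[0] += g[i]; node_H[0] += h[i]; }
    }

    for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
      const int n_act = (int)active.size();
      std::vector<int> slot((int)tree.feature.size(), -1);
      for (int s = 0; s < n_act; ++s) slot[active[s]] = s;

      std::vector<int> best_feat(n_act, -1);
      std::vector<double> best_gain(n_act, 0.0), best_thr(n_act, 0.0);
      std::vector<double> best_GL(n_act, 0.0), best_HL(n_act, 0.0);

      std::vector<double> run_GL(n_act), run_HL(n_act), last_val(n_act);
      std::vector<int> run_cnt(n_act);

      for (int cj : cols) {
        std::fill(run_GL.begin(), run_GL.end(), 0.0);
        std::fill(run_HL.begin(), run_HL.end(), 0.0);
        std::fill(run_cnt.begin(), run_cnt.end(), 0);
        const std::vector<int>& oj = ord[cj];
        for (int t = 0; t < n; ++t) {
          int i = oj[t];
          int nid = node_of[i];
          if (nid < 0 || nid >= (int)slot.size()) continue;
          int s = slot[nid];
          if (s < 0) continue;
          double xv = X(i, cj);
          if (run_cnt[s] > 0 && xv > last_val[s]) {
            double GL = run_GL[s], HL = run_HL[s];
            double GR = node_G[nid] - GL, HR = node_H[nid] - HL;
            if (HL >= min_child_weight && HR >= min_child_weight) {
              double gain = 0.5 * (GL * GL / (HL + lambda) +
                                   GR * GR / (HR + lambda) -
                                   node_G[nid] * node_G[nid] / (node_H[nid] + lambda));
              if (gain > best_gain[s]) {
                best_gain[s] = gain;
                best_feat[s] = cj;
                best_thr[s] = 0.5 * (last_val[s] + xv);
                best_GL[s] = GL; best_HL[s] = HL;
              }
            }
          }
          run_GL[s] += g[i];
          run_HL[s] += h[i];
          last_val[s] = xv;
          ++run_cnt[s];
        }
      }

      // apply best splits, spawn children
      std::vector<int> next_active;
      std::vector<double> next_G, next_H;
      for (int s = 0; s < n_act; ++s) {
        int nid = active[s];
        tree.cover[nid] = node_H[nid];
        if (best_feat[s] >= 0 && best_gain[s] > 1e-12) {
          int lc = tree.add_node();
          int rc = tree.add_node();
          tree.feature[nid] = best_feat[s];
          tree.threshold[nid] = best_thr[s];
          tree.left[nid] = lc; tree.right[nid] = rc;
          tree.gain[nid] = best_gain[s];
          t_gain[best_feat[s]] += best_gain[s];
          t_freq[best_feat[s]] += 1.0;
          next_active.push_back(lc);
          next_G.push_back(best_GL[s]); next_H.push_back(best_HL[s]);
          next_active.push_back(rc);
          next_G.push_back(node_G[nid] - best_GL[s]);
          next_H.push_back(node_H[nid] - best_HL[s]);
        } else {
          tree.value[nid] = -eta * node_G[nid] / (node_H[nid] + lambda);
        }
      }
      if (next_active.empty()) break;

      node_G.resize(tree.feature.size(), 0.0);
      node_H.resize(tree.feature.size(), 0.0);
      for (size_t k = 0; k < next_active.size(); ++k) {
        node_G[next_active[k]] = next_G[k];
        node_H[next_active[k]] = next_H[k];
      }
      // route sampled rows to children
      for (int i = 0; i < n; ++i) {
        int nid = node_of[i];
        if (nid < 0) continue;
        if (tree.feature[nid] >= 0) {
          node_of[i] = (X(i, tree.feature[nid]) < tree.threshold[nid])
                         ? tree.left[nid] : tree.right[nid];
        } else {
          node_of[i] = -2 - nid; // finished at a leaf; park it
        }
      }
      // finalize leaves at max depth
      if (depth == max_depth - 1) {
        for (size_t k = 0; k < next_active.size(); ++k) {
          int nid = next_active[k];
          tree.cover[nid] = node_H[nid];
          tree.value[nid] = -eta * node_G[nid] / (node_H[nid] + lambda);
        }
      }
      active = next_active;
    }

    // update margins for every row (sampled or not)
    for (int i = 0; i < n; ++i) margin[i] += tree.predict_row(X, i);
    if (has_val) {
      for (int i = 0; i < (int)val_margin.size(); ++i)
        val_margin[i] += tree.predict_row(Xval, i);
    }

    trees.push_back(tree);
    tree_gain.push_back(t_gain);
    tree_freq.push_back(t_freq);

    if (has_val && early_stopping_rounds > 0) {
      double sc = aupr_margin(val_margin, yval);
      eval_log.push_back(sc);
      if (sc > best_score) { best_score = sc; best_iter = round; }
      if (round - best_iter >= early_stopping_rounds) break;
    }
  }

  int keep = (int)trees.size();
  if (has_val && early_stopping_rounds > 0 && best_iter >= 0) keep = best_iter + 1;

  List tree_list(keep);
  for (int t = 0; t < keep; ++t) {
    tree_list[t] = tree_to_list(trees[t]);
    for (int j = 0; j < p; ++j) {
      imp_gain[j] += tree_gain[t][j];
      imp_freq[j] += tree_freq[t][j];
    }
  }

  return List::create(
    _["trees"] = tree_list,
    _["n_trees"] = keep,
    _["best_iteration"] = (has_val && early_stopping_rounds > 0) ? best_iter + 1 : keep,
    _["best_score"] = (has_val && early_stopping_rounds > 0) ? best_score : NA_REAL,
    _["eval_log"] = NumericVector(eval_log.begin(), eval_log.end()),
    _["base_score"] = base_score,
    _["importance_gain"] = NumericVector(imp_gain.begin(), imp_gain.end()),
    _["importance_frequency"] = NumericVector(imp_freq.begin(), imp_freq.end()));
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List trees, NumericMatrix X, double base_score,
                              bool output_margin) {
  const int n = X.nrow();
  const double base_margin = std::log(base_score / (1.0 - base_score));
  NumericVector out(n, base_margin);
  for (int t = 0; t < trees.size(); ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += tr.predict_row(X, i);
  }
  if (!output_margin) for (int i = 0; i < n; ++i) out[i] = sigmoid(out[i]);
  return out;
}
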