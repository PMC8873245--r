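// Classification random forest: CART trees with Gini splits, bootstrap
// resampling, out-of-bag (OOB) voting and unscaled permutation importance.
// Uses R's RNG throughout so set.seed() governs reproducibility.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Forest {
  // flat node arrays, one block per tree delimited by tree_offset
  std::vector<int> feature;    // split variable, -1 => leaf
  std::vector<double> thresh;  // x[f] <= thresh goes left
  std::vector<int> left, right, pred;
  std::vector<int> tree_offset;  // root index of each tree
};

inline double gini_from_counts(const std::vector<int>& cnt, int n) {
  if (n == 0) return 0.0;
  double s = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k) {
    double p = (double)cnt[k] / n;
    s += p * p;
  }
  return 1.0 - s;
}

inline int sample_int(int n) {  // 0..n-1 using R's RNG
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

class TreeBuilder {
public:
  TreeBuilder(const NumericMatrix& X, const IntegerVector& y, int nclass,
              int mtry, int min_node, Forest& out)
    : X_(X), y_(y), nclass_(nclass), mtry_(mtry), min_node_(min_node),
      out_(out), p_(X.ncol()) {}

  // idx: bootstrap sample indices (with repeats); returns node id
  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    std::vector<int> cnt(nclass_, 0);
    for (int i = lo; i < hi; ++i) cnt[y_[idx[i]]]++;
    int maj = majority(cnt);
    double g0 = gini_from_counts(cnt, n);
    if (n < 2 * min_node_ || g0 <= 0.0) return leaf(maj);

    // draw mtry candidate features without replacement
    std::vector<int> feats(p_);
    for (int j = 0; j < p_; ++j) feats[j] = j;
    int m = std::min(mtry_, p_);
    for (int j = 0; j < m; ++j) std::swap(feats[j], feats[j + sample_int(p_ - j)]);

    int best_f = -1;
    double best_gain = 0.0, best_thr = 0.0;
    std::vector<std::pair<double,int>> vals(n);
    std::vector<int> lc(nclass_);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X_(idx[lo + i], f), (int)y_[idx[lo + i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(lc.begin(), lc.end(), 0);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second]++; nl++;
        if (vals[i].first == vals[i + 1].first) continue;
        if (nl < min_node_ || (n - nl) < min_node_) continue;
        double gl = 0.0, gr = 0.0;
        {
          double sl = 0.0, sr = 0.0;
          for (int k = 0; k < nclass_; ++k) {
            double pl = (double)lc[k] / nl;
            double pr = (double)(cnt[k] - lc[k]) / (n - nl);
            sl += pl * pl; sr += pr * pr;
          }
          gl = 1.0 - sl; gr = 1.0 - sr;
        }
        double gain = g0 - ((double)nl / n) * gl - ((double)(n - nl) / n) * gr;
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return leaf(maj);

    // partition idx[lo,hi) in place around the split
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X_(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    if (mid == lo || mid == hi) return leaf(maj);  // numeric degeneracy guard

    int node = new_node();
    out_.feature[node] = best_f;
    out_.thresh[node] = best_thr;
    out_.pred[node] = maj;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    out_.left[node] = l;
    out_.right[node] = r;
    return node;
  }

private:
  int leaf(int maj) {
    int node = new_node();
    out_.pred[node] = maj;
    return node;
  }
  int new_node() {
    out_.feature.push_back(-1);
    out_.thresh.push_back(0.0);
    out_.left.push_back(-1);
    out_.right.push_back(-1);
    out_.pred.push_back(-1);
    return (int)out_.feature.size() - 1;
  }
  int majority(const std::vector<int>& cnt) {
    int best = 0;
    for (int k = 1; k < nclass_; ++k) if (cnt[k] > cnt[best]) best = k;
    return best;  // ties -> lowest class index (canonical order)
  }
  const NumericMatrix& X_;
  const IntegerVector& y_;
  int nclass_, mtry_, min_node_;
  Forest& out_;
  int p_;
};

inline int predict_row_buf(const Forest& fo, int root, const double* x) {
  int node = root;
  while (fo.feature[node] >= 0)
    node = (x[fo.feature[node]] <= fo.thresh[node]) ? fo.left[node] : fo.right[node];
  return fo.pred[node];
}

Forest forest_from_list(const List& model) {
  Forest fo;
  IntegerVector feature = model["feature"], left = model["left"],
                right = model["right"], pred = model["pred"],
                offs = model["tree_offset"];
  NumericVector thresh = model["thresh"];
  fo.feature.assign(feature.begin(), feature.end());
  fo.thresh.assign(thresh.begin(), thresh.end());
  fo.left.assign(left.begin(), left.end());
  fo.right.assign(right.begin(), right.end());
  fo.pred.assign(pred.begin(), pred.end());
  fo.tree_offset.assign(offs.begin(), offs.end());
  return fo;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int min_node, bool importance) {
  int n = X.nrow(), p = X.ncol();
  RNGScope scope;
  Forest fo;
  fo.tree_offset.reserve(ntree);
  IntegerMatrix oob_votes(n, nclass);
  NumericVector imp(p), imp_sq(p);
  std::vector<int> imp_n(p, 0);
  std::vector<int> boot(n), oob;
  std::vector<char> inbag(n);
  std::vector<double> xbuf(p), xperm;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      boot[i] = sample_int(n);
      inbag[boot[i]] = 1;
    }
    TreeBuilder tb(X, y, nclass, mtry, min_node, fo);
    std::vector<int> idx = boot;
    int root = tb.build(idx, 0, n);
    fo.tree_offset.push_back(root);

    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    int correct = 0;
    std::vector<int> oob_pred(oob.size());
    for (size_t k = 0; k < oob.size(); ++k) {
      int i = oob[k];
      for (int j = 0; j < p; ++j) xbuf[j] = X(i, j);
      int pr = predict_row_buf(fo, root, xbuf.data());
      oob_pred[k] = pr;
      oob_votes(i, pr)++;
      if (pr == y[i]) correct++;
    }
    if (importance) {
      double acc = (double)correct / oob.size();
      xperm.resize(oob.size());
      for (int f = 0; f < p; ++f) {
        // permute feature f among the OOB cases
        for (size_t k = 0; k < oob.size(); ++k) xperm[k] = X(oob[k], f);
        for (size_t k = oob.size(); k > 1; --k)
          std::swap(xperm[k - 1], xperm[sample_int((int)k)]);
        int corr_p = 0;
        for (size_t k = 0; k < oob.size(); ++k) {
          int i = oob[k];
          for (int j = 0; j < p; ++j) xbuf[j] = X(i, j);
          xbuf[f] = xperm[k];
          if (predict_row_buf(fo, root, xbuf.data()) == y[i]) corr_p++;
        }
        double d = acc - (double)corr_p / oob.size();
        imp[f] += d; imp_sq[f] += d * d; imp_n[f]++;
      }
    }
  }

  // overall OOB accuracy from aggregated votes (samples with >=1 OOB vote)
  int used = 0, correct = 0;
  IntegerVector oob_pred_all(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int best = -1, bestv = 0, tot = 0;
    for (int k = 0; k < nclass; ++k) {
      tot += oob_votes(i, k);
      if (oob_votes(i, k) > bestv) { bestv = oob_votes(i, k); best = k; }
    }
    if (tot > 0) {
      used++;
      oob_pred_all[i] = best;
      if (best == y[i]) correct++;
    }
  }
  double oob_acc = used > 0 ? (double)correct / used : NA_REAL;

  NumericVector imp_mean(p), imp_sd(p);
  for (int f = 0; f < p; ++f) {
    if (imp_n[f] > 0) {
      imp_mean[f] = imp[f] / imp_n[f];
      double v = imp_sq[f] / imp_n[f] - imp_mean[f] * imp_mean[f];
      imp_sd[f] = v > 0 ? std::sqrt(v) : 0.0;
    } else {
      imp_mean[f] = NA_REAL; imp_sd[f] = NA_REAL;
    }
  }

  return List::create(
    _["feature"] = IntegerVector(fo.feature.begin(), fo.feature.end()),
    _["thresh"] = NumericVector(fo.thresh.begin(), fo.thresh.end()),
    _["left"] = IntegerVector(fo.left.begin(), fo.left.end()),
    _["right"] = IntegerVector(fo.right.begin(), fo.right.end()),
    _["pred"] = IntegerVector(fo.pred.begin(), fo.pred.end()),
    _["tree_offset"] = IntegerVector(fo.tree_offset.begin(), fo.tree_offset.end()),
    _["oob_votes"] = oob_votes,
    _["oob_pred"] = oob_pred_all,
    _["oob_accuracy"] = oob_acc,
    _["importance_mean"] = imp_mean,
    _["importance_sd"] = imp_sd);
}

// [[Rcpp::export]]
IntegerMatrix rf_votes_cpp(List model, NumericMatrix X, int nclass) {
  Forest fo = forest_from_list(model);
  int n = X.nrow(), p = X.ncol(), K = nclass;
  IntegerMatrix votes(n, K);
  std::vector<double> xbuf(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xbuf[j] = X(i, j);
    for (size_t t = 0; t < fo.tree_offset.size(); ++t)
      votes(i, predict_row_buf(fo, fo.tree_offset[t], xbuf.data()))++;
  }
  return votes;
}
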