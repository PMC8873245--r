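// Pseudo-F statistics for PERMANOVA over a set of label permutations.
// Anderson's one-way partitioning of a squared-distance matrix:
//   SS_total  = sum_{i<j} d2_ij / N
//   SS_within = sum_g sum_{i<j in g} d2_ij / n_g
//   F = (SS_among / (a-1)) / (SS_within / (N-a))
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector permanova_f_cpp(NumericMatrix d2, IntegerMatrix perms, int ngroups) {
  int n = d2.nrow(), nperm = perms.ncol();
  double ss_tot = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) ss_tot += d2(i, j);
  ss_tot /= n;

  NumericVector out(nperm);
  std::vector<double> ssw_g(ngroups);
  std::vector<int> cnt(ngroups);
  for (int t = 0; t < nperm; ++t) {
    std::fill(ssw_g.begin(), ssw_g.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = 0; i < n; ++i) cnt[perms(i, t)]++;
    for (int i = 0; i < n; ++i) {
      int gi = perms(i, t);
      for (int j = i + 1; j < n; ++j)
        if (perms(j, t) == gi) ssw_g[gi] += d2(i, j);
    }
    double ssw = 0.0;
    for (int g = 0; g < ngroups; ++g)
      if (cnt[g] > 0) ssw += ssw_g[g] / cnt[g];
    double ssa = ss_tot - ssw;
    out[t] = (ssa / (ngroups - 1)) / (ssw / (n - ngroups));
  }
  return out;
}
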