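#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Exact null distribution of the Spearman rank-sum statistic
// S = sum_i i * p(i) over all permutations p of 1..n. Returns a count
// vector c where c[s] is the number of permutations with S = s (0-based
// index; entries below the minimal attainable S are zero). Feasible for
// n <= 10 (10! = 3,628,800 permutations).
// [[Rcpp::export]]
Rcpp::NumericVector spearman_null_counts(int n) {
  if (n < 1 || n > 10)
    Rcpp::stop("exact enumeration supported for 1 <= n <= 10");
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i + 1;
  int smax = 0;
  for (int i = 1; i <= n; ++i) smax += i * i;
  Rcpp::NumericVector counts(smax + 1);
  do {
    int s = 0;
    for (int i = 0; i < n; ++i) s += (i + 1) * p[i];
    counts[s] += 1.0;
  } while (std::next_permutation(p.begin(), p.end()));
  return counts;
}
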