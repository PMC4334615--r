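#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree over compressed CV ranks.
static inline void fen_add(std::vector<int>& t, int i) {
  for (; i < (int)t.size(); i += i & -i) t[i]++;
}
static inline int fen_sum(const std::vector<int>& t, int i) {
  int s = 0;
  for (; i > 0; i -= i & -i) s += t[i];
  return s;
}

// Self-inclusive dominance counts within one regime:
//   out[i] = #{ j : m[j] >= m[i] (upper) or m[j] <= m[i] (lower),
//               and cv[j] <= cv[i] }
// Counting is inclusive of ties on both coordinates (point i counts itself).
// O(N log N): sweep m in decreasing (upper) / increasing (lower) order,
// inserting whole tie-groups before querying their members.
// [[Rcpp::export(name = ".quadrantSelfCounts")]]
IntegerVector quadrantSelfCounts(NumericVector m, NumericVector cv, bool upper) {
  int n = m.size();
  IntegerVector out(n);
  if (n == 0) return out;

  // compress cv: rank = index of value in sorted unique cv (1-based);
  // querying prefix sum at that rank counts all cv' <= cv.
  std::vector<double> cvs(cv.begin(), cv.end());
  std::sort(cvs.begin(), cvs.end());
  cvs.erase(std::unique(cvs.begin(), cvs.end()), cvs.end());
  std::vector<int> crank(n);
  for (int i = 0; i < n; ++i)
    crank[i] = (int)(std::upper_bound(cvs.begin(), cvs.end(), cv[i]) - cvs.begin());

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  if (upper)
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return m[a] > m[b]; });
  else
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return m[a] < m[b]; });

  std::vector<int> tree(cvs.size() + 1, 0);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && m[ord[j + 1]] == m[ord[i]]) ++j;
    for (int k = i; k <= j; ++k) fen_add(tree, crank[ord[k]]);
    for (int k = i; k <= j; ++k) out[ord[k]] = fen_sum(tree, crank[ord[k]]);
    i = j + 1;
  }
  return out;
}

// Joint-tail counts of observed (mean, cv) pairs against a null sample.
// Regime is chosen per observation: mean >= 1 counts null pairs with
// mean at least as large, mean < 1 counts null pairs with mean at most as
// small; in both regimes the null CV must not exceed the observed CV.
// [[Rcpp::export(name = ".quadrantQueryCounts")]]
IntegerVector quadrantQueryCounts(NumericVector mObs, NumericVector cvObs,
                                  NumericVector mNull, NumericVector cvNull) {
  int nO = mObs.size(), nN = mNull.size();
  IntegerVector out(nO);
  for (int i = 0; i < nO; ++i) {
    double mo = mObs[i], co = cvObs[i];
    int cnt = 0;
    if (mo >= 1.0) {
      for (int j = 0; j < nN; ++j)
        if (mNull[j] >= mo && cvNull[j] <= co) ++cnt;
    } else {
      for (int j = 0; j < nN; ++j)
        if (mNull[j] <= mo && cvNull[j] <= co) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}
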