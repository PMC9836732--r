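#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of a query against a reference
// consensus string, linear gap penalty. Traceback ties are broken
// deterministically: diagonal first, then up (consume query), then left
// (consume reference). Returns the optimal score and, for every query
// position, the 1-based reference column it aligns to (NA when the query
// position falls in a reference gap).
// [[Rcpp::export]]
List nw_align_map(std::string query, std::string ref,
                  double match, double mismatch, double gap) {
  const int n = query.size(), m = ref.size();
  NumericMatrix F(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) F(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) F(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      double d = F(i - 1, j - 1) + s;
      double up = F(i - 1, j) + gap;
      double lf = F(i, j - 1) + gap;
      F(i, j) = std::max(d, std::max(up, lf));
    }
  }
  IntegerVector qmap(n, NA_INTEGER);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      if (F(i, j) == F(i - 1, j - 1) + s) {
        qmap[i - 1] = j;
        --i; --j;
        continue;
      }
    }
    if (i > 0 && F(i, j) == F(i - 1, j) + gap) {
      --i;  // query position unaligned (gap in reference)
      continue;
    }
    --j;  // reference column skipped (deletion in query)
  }
  return List::create(_["score"] = F(n, m), _["map"] = qmap);
}
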