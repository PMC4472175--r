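#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Ungapped nucleotide-space rescoring of seed diagonals: for each candidate
// (read, target, diagonal) find the maximal-scoring contiguous segment under
// +1 match / -1 mismatch (Kadane). Coordinates are 0-based; the returned
// target interval is half-open. 'N' in the read never counts as a match.
// [[Rcpp::export]]
DataFrame rescore_diagonals(CharacterVector reads, IntegerVector read_idx,
                            CharacterVector targets, IntegerVector target_idx,
                            IntegerVector diag_nt) {
  const int n = read_idx.size();
  IntegerVector score(n), t_start(n), t_end(n), r_start(n),
      matches(n), mismatches(n);
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, read_idx[i] - 1));
    const char *t = CHAR(STRING_ELT(targets, target_idx[i] - 1));
    const int rl = (int)std::strlen(r), tl = (int)std::strlen(t), d = diag_nt[i];
    int lo = d < 0 ? -d : 0;
    int hi = rl < tl - d ? rl : tl - d;
    int best = 0, bs = lo, be = lo, cur = 0, cs = lo;
    for (int p = lo; p < hi; ++p) {
      const int sc = (r[p] == t[p + d] && r[p] != 'N') ? 1 : -1;
      if (cur <= 0) { cur = sc; cs = p; } else cur += sc;
      if (cur > best) { best = cur; bs = cs; be = p + 1; }
    }
    int ma = 0;
    for (int p = bs; p < be; ++p)
      if (r[p] == t[p + d] && r[p] != 'N') ++ma;
    score[i] = best;
    r_start[i] = bs;
    t_start[i] = bs + d;
    t_end[i] = be + d;
    matches[i] = ma;
    mismatches[i] = (be - bs) - ma;
  }
  return DataFrame::create(_["score"] = score, _["r_start"] = r_start,
                           _["t_start"] = t_start, _["t_end"] = t_end,
                           _["matches"] = matches, _["mismatches"] = mismatches);
}
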