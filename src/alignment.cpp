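#include <Rcpp.h>
#include <vector>
#include <string>

// Global (Needleman-Wunsch) alignment with linear gap penalty.
//
// Returns c(score, identities) where `identities` is the maximum number of
// identical aligned residue pairs over all optimal-score alignments: the DP
// optimises (score, identities) lexicographically, which is valid because
// both objectives are additive over the same edit transitions.
// [[Rcpp::export(name = ".nw_align")]]
Rcpp::IntegerVector nw_align(const std::string& a, const std::string& b,
                             int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  std::vector<int> sc(m + 1), id(m + 1), sc_prev(m + 1), id_prev(m + 1);

  for (int j = 0; j <= m; ++j) { sc_prev[j] = j * gap; id_prev[j] = 0; }
  for (int i = 1; i <= n; ++i) {
    sc[0] = i * gap; id[0] = 0;
    for (int j = 1; j <= m; ++j) {
      const bool eq = a[i - 1] == b[j - 1];
      int s_diag = sc_prev[j - 1] + (eq ? match : mismatch);
      int i_diag = id_prev[j - 1] + (eq ? 1 : 0);
      int s_up = sc_prev[j] + gap, i_up = id_prev[j];
      int s_left = sc[j - 1] + gap, i_left = id[j - 1];

      int s = s_diag, d = i_diag;
      if (s_up > s || (s_up == s && i_up > d)) { s = s_up; d = i_up; }
      if (s_left > s || (s_left == s && i_left > d)) { s = s_left; d = i_left; }
      sc[j] = s; id[j] = d;
    }
    std::swap(sc, sc_prev);
    std::swap(id, id_prev);
  }
  return Rcpp::IntegerVector::create(sc_prev[m], id_prev[m]);
}
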