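#include <Rcpp.h>
using namespace Rcpp;

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Greedy left-to-right perfect-repeat scan. At each position, periods are
// tried in increasing order; the first maximal run meeting its copy-number
// threshold (with a minimal-period motif) is emitted, truncated to whole
// motif copies, and scanning resumes immediately after its end. Runs never
// cross a non-ACGT character. Coordinates are 1-based inclusive.
// [[Rcpp::export(name = ".scan_seq_cpp")]]
DataFrame scan_seq_cpp(const std::string& seq, IntegerVector min_repeats,
                       int max_period) {
  const int n = (int) seq.size();
  std::vector<int> starts, periods, copies;
  int i = 0;
  while (i < n) {
    if (!valid_base(seq[i])) { ++i; continue; }
    bool emitted = false;
    for (int p = 1; p <= max_period && i + p <= n; ++p) {
      bool motif_ok = true;
      for (int j = i; j < i + p; ++j) {
        if (!valid_base(seq[j])) { motif_ok = false; break; }
      }
      if (!motif_ok) break;  // larger periods include the same character
      int j = i + p;
      while (j < n && valid_base(seq[j]) && seq[j] == seq[j - p]) ++j;
      int cp = (j - i) / p;
      if (cp < min_repeats[p - 1]) continue;
      bool minimal = true;
      for (int d = 1; d < p && minimal; ++d) {
        if (p % d) continue;
        bool rep = true;
        for (int k = d; k < p; ++k) {
          if (seq[i + k] != seq[i + k - d]) { rep = false; break; }
        }
        if (rep) minimal = false;
      }
      if (!minimal) continue;
      starts.push_back(i + 1);
      periods.push_back(p);
      copies.push_back(cp);
      i += p * cp;
      emitted = true;
      break;
    }
    if (!emitted) ++i;
  }
  const int m = (int) starts.size();
  IntegerVector s(m), e(m), pd(m), cc(m);
  for (int k = 0; k < m; ++k) {
    s[k] = starts[k];
    pd[k] = periods[k];
    cc[k] = copies[k];
    e[k] = starts[k] + periods[k] * copies[k] - 1;
  }
  return DataFrame::create(_["start"] = s, _["end"] = e,
                           _["period"] = pd, _["copies"] = cc);
}
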