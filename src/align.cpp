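#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Traceback is deterministic: diagonal beats a gap in the second sequence
// (vertical move) which beats a gap in the first (horizontal move).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) S(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up   = S(i - 1, j) + gap;
      double left = S(i, j - 1) + gap;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      S(i, j) = best;
    }
  }
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S(i, j) == S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = S(n, m));
}

// 1-based start position of the leftmost acceptable adapter occurrence in
// each sequence, or 0 when none is found. An occurrence is the full adapter
// anywhere, or a 3'-truncated adapter prefix (>= ceil(len/2) bases) ending
// exactly at the read end; mismatches <= ceil(max_mismatch_fraction * matched
// length) in either case.
// [[Rcpp::export]]
IntegerVector adapter_scan_cpp(CharacterVector seqs, std::string adapter,
                               double max_mismatch_fraction) {
  const int alen = adapter.size();
  const int min_trunc = (alen + 1) / 2;
  IntegerVector out(seqs.size());
  for (R_xlen_t k = 0; k < seqs.size(); ++k) {
    std::string s = as<std::string>(seqs[k]);
    const int L = s.size();
    int found = 0;
    for (int i = 0; i < L && !found; ++i) {
      const int mlen = std::min(alen, L - i);
      if (mlen < alen && mlen < min_trunc) break;  // tail too short from here on
      const int allowed = (int)std::ceil(max_mismatch_fraction * mlen - 1e-9);
      int mm = 0;
      for (int p = 0; p < mlen; ++p) {
        if (s[i + p] != adapter[p] && ++mm > allowed) break;
      }
      if (mm <= allowed) found = i + 1;
    }
    out[k] = found;
  }
  return out;
}
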