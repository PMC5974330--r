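#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>
using namespace Rcpp;

// Sorted unique 2-bit k-mer codes of a sequence (k <= 15); windows
// containing non-ACGT characters are skipped.

// [[Rcpp::export]]
IntegerVector kmer_codes_cpp(std::string s, int k) {
  int n = s.size();
  std::vector<int> out;
  if (n < k) return IntegerVector(0);
  int code = 0, valid = 0;
  const int mask = (1 << (2 * k)) - 1;
  for (int i = 0; i < n; ++i) {
    int b;
    switch (s[i]) {
      case 'A': b = 0; break;
      case 'C': b = 1; break;
      case 'G': b = 2; break;
      case 'T': b = 3; break;
      default: b = -1;
    }
    if (b < 0) { valid = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++valid >= k) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return IntegerVector(out.begin(), out.end());
}

// Number of shared codes between two sorted unique vectors.

// [[Rcpp::export]]
int shared_codes_cpp(IntegerVector a, IntegerVector b) {
  int i = 0, j = 0, n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}
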