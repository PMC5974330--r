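#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Semi-global alignment: free end gaps on the reference, query aligned
// end-to-end. Affine gaps: the first gapped base in a run costs `open`,
// each further base `ext`. Gap-to-gap switches (X<->Y) are disallowed.
//
// Layers: M = query base vs ref base (diagonal), X = query base vs gap
// (consumes query), Y = ref base vs gap (consumes ref).
//
// Identity is BLAST-like: matches / columns between the first and last
// aligned (diagonal) column, so terminal overhangs lower the score and
// the query coverage but not the identity. Coverage = (matches +
// mismatches) / query length.

static const double NEG = -1e15;

// [[Rcpp::export]]
List sg_align_cpp(std::string q, std::string r,
                  double match = 1.0, double mismatch = -1.0,
                  double open = -2.0, double ext = -1.0) {
  const int n = q.size(), m = r.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["matches"] = 0,
                        _["mismatches"] = 0, _["aligned_cols"] = 0,
                        _["ref_start"] = 0, _["ref_end"] = 0);
  const int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG), X((n + 1) * w, NEG),
      Y((n + 1) * w, NEG);
  std::vector<signed char> bM((n + 1) * w, 0), bX((n + 1) * w, 0),
      bY((n + 1) * w, 0);
  // back codes: 1=M, 2=X, 3=Y, 0=start row
  // row 1: entry from the free start row
  {
    double* Mi = &M[w];
    double* Xi = &X[w];
    double* Yi = &Y[w];
    signed char* bYi = &bY[w];
    char qc = q[0];
    Xi[0] = open; // query base 1 vs gap before the reference
    for (int j = 1; j <= m; ++j) {
      Mi[j] = ((qc == r[j - 1] && qc != 'N') ? match : mismatch);
      Xi[j] = open;
      double fm = Mi[j - 1] + open, fy = Yi[j - 1] + ext;
      if (fm >= fy) { Yi[j] = fm; bYi[j] = 1; }
      else          { Yi[j] = fy; bYi[j] = 3; }
    }
  }
  for (int i = 2; i <= n; ++i) {
    const double* Mp = &M[(i - 1) * w];
    const double* Xp = &X[(i - 1) * w];
    const double* Yp = &Y[(i - 1) * w];
    double* Mi = &M[i * w];
    double* Xi = &X[i * w];
    double* Yi = &Y[i * w];
    signed char* bMi = &bM[i * w];
    signed char* bXi = &bX[i * w];
    signed char* bYi = &bY[i * w];
    const char qc = q[i - 1];
    // j = 0 column: only X possible (query prefix vs nothing)
    {
      double fm = Mp[0] + open, fx = Xp[0] + ext;
      if (fm >= fx) { Xi[0] = fm; bXi[0] = 1; }
      else          { Xi[0] = fx; bXi[0] = 2; }
    }
    for (int j = 1; j <= m; ++j) {
      // M from diagonal
      double best = Mp[j - 1]; signed char bb = 1;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; bb = 2; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; bb = 3; }
      Mi[j] = best + ((qc == r[j - 1] && qc != 'N') ? match : mismatch);
      bMi[j] = bb;
      // X vertical
      double fm = Mp[j] + open, fx = Xp[j] + ext;
      if (fm >= fx) { Xi[j] = fm; bXi[j] = 1; }
      else          { Xi[j] = fx; bXi[j] = 2; }
      // Y horizontal
      double gm = Mi[j - 1] + open, gy = Yi[j - 1] + ext;
      if (gm >= gy) { Yi[j] = gm; bYi[j] = 1; }
      else          { Yi[j] = gy; bYi[j] = 3; }
    }
  }
  // free reference suffix: best over j of row n, layers M and X
  double best = NEG;
  int bj = 0, blayer = 1;
  const double* Mn = &M[n * w];
  const double* Xn = &X[n * w];
  for (int j = 0; j <= m; ++j) {
    if (Mn[j] > best) { best = Mn[j]; bj = j; blayer = 1; }
    if (Xn[j] > best) { best = Xn[j]; bj = j; blayer = 2; }
  }
  // traceback
  int i = n, j = bj, layer = blayer;
  int matches = 0, mismatches = 0;
  std::vector<signed char> cols; // 1=diag 2=x 3=y, end-to-start order
  cols.reserve(n + m);
  int ref_end = bj;
  while (i > 0) {
    signed char back;
    if (layer == 1) {
      back = bM[i * w + j];
      char qc = q[i - 1], rc = r[j - 1];
      if (qc == rc && qc != 'N') ++matches; else ++mismatches;
      cols.push_back(1);
      --i; --j;
      if (i == 0) break;
    } else if (layer == 2) {
      back = bX[i * w + j];
      cols.push_back(2);
      --i;
      if (i == 0) break;
    } else {
      back = bY[i * w + j];
      cols.push_back(3);
      --j;
    }
    layer = back;
  }
  int ref_start = j;
  // identity region: between first and last diagonal column
  int nc = cols.size(), lo = -1, hi = -1;
  for (int k = 0; k < nc; ++k)
    if (cols[k] == 1) { if (lo < 0) lo = k; hi = k; }
  int core_cols = (lo >= 0) ? (hi - lo + 1) : 0;
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["mismatches"] = mismatches,
                      _["aligned_cols"] = core_cols,
                      _["ref_start"] = ref_start, _["ref_end"] = ref_end);
}
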