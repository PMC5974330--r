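#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Glocal Viterbi decode of a small Plan7-like DNA profile: the full model
// (match/insert/delete; begin enters only at M1/D1, exit only from ML/DL)
// is aligned to the best-scoring substring of the sequence. Sequence
// positions outside the hit emit at background, so they contribute zero
// log-odds and the hit score is independent of its context.
//
// Inputs are log2-odds emissions (lm: L x 4 match rows, li: insert
// 4-vector) and log2 transition probabilities (vectors indexed by source
// column j = 1..L-1). x: sequence as 0..3 ints, -1 for N (emitted at
// background: 0 bits).
//
// Returns the best score in bits with the 0-based half-open hit span;
// paths emitting no symbol are excluded.

static const double NEG = -1e15;

// [[Rcpp::export]]
List viterbi_glocal_cpp(NumericMatrix lm, NumericVector li,
                        double tBM, double tBD,
                        NumericVector tMM, NumericVector tMI, NumericVector tMD,
                        NumericVector tIM, NumericVector tII,
                        NumericVector tDM, NumericVector tDD,
                        IntegerVector x) {
  const int L = lm.nrow(), n = x.size();
  const int w = L + 1;
  // flatten emissions: em[j*4 + b] for column j (1-based)
  std::vector<double> em(w * 4, 0.0), ei(4);
  for (int j = 1; j <= L; ++j)
    for (int b = 0; b < 4; ++b) em[j * 4 + b] = lm(j - 1, b);
  for (int b = 0; b < 4; ++b) ei[b] = li[b];
  std::vector<double> VM((n + 1) * w, NEG), VI((n + 1) * w, NEG),
      VD((n + 1) * w, NEG);
  std::vector<int> SM((n + 1) * w, -1), SI((n + 1) * w, -1),
      SD((n + 1) * w, -1);
  double best = NEG;
  int bs = -1, be = -1;
  for (int i = 0; i <= n; ++i) {
    double* VDi = &VD[i * w];
    double* VMi = &VM[i * w];
    double* VIi = &VI[i * w];
    int* SDi = &SD[i * w];
    int* SMi = &SM[i * w];
    int* SIi = &SI[i * w];
    // delete chain at boundary i (consumes nothing)
    VDi[1] = tBD;
    SDi[1] = i;
    for (int j = 2; j <= L; ++j) {
      double fm = VMi[j - 1] + tMD[j - 2];
      double fd = VDi[j - 1] + tDD[j - 2];
      if (fm >= fd) { VDi[j] = fm; SDi[j] = SMi[j - 1]; }
      else          { VDi[j] = fd; SDi[j] = SDi[j - 1]; }
    }
    // exit at boundary i (require >= 1 emitted symbol)
    if (VMi[L] > best && SMi[L] >= 0 && SMi[L] < i) {
      best = VMi[L]; bs = SMi[L]; be = i;
    }
    if (VDi[L] > best && SDi[L] >= 0 && SDi[L] < i) {
      best = VDi[L]; bs = SDi[L]; be = i;
    }
    if (i == n) break;
    // advance: emit symbol i+1
    const int xi = x[i];
    double* VMn = &VM[(i + 1) * w];
    double* VIn = &VI[(i + 1) * w];
    int* SMn = &SM[(i + 1) * w];
    int* SIn = &SI[(i + 1) * w];
    // j = 1: entry from begin
    VMn[1] = tBM + ((xi < 0) ? 0.0 : em[4 + xi]);
    SMn[1] = i;
    for (int j = 2; j <= L; ++j) {
      double fm = VMi[j - 1] + tMM[j - 2];
      double fi = VIi[j - 1] + tIM[j - 2];
      double fd = VDi[j - 1] + tDM[j - 2];
      double bb = fm; int org = SMi[j - 1];
      if (fi > bb) { bb = fi; org = SIi[j - 1]; }
      if (fd > bb) { bb = fd; org = SDi[j - 1]; }
      VMn[j] = bb + ((xi < 0) ? 0.0 : em[j * 4 + xi]);
      SMn[j] = org;
    }
    const double e_ins = (xi < 0) ? 0.0 : ei[xi];
    for (int j = 1; j <= L - 1; ++j) {
      double fm = VMi[j] + tMI[j - 1];
      double fi = VIi[j] + tII[j - 1];
      if (fm >= fi) { VIn[j] = fm + e_ins; SIn[j] = SMi[j]; }
      else          { VIn[j] = fi + e_ins; SIn[j] = SIi[j]; }
    }
  }
  if (bs < 0 || best < NEG / 2)
    return List::create(_["score"] = R_NegInf, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER);
  return List::create(_["score"] = best, _["start"] = bs, _["end"] = be);
}
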