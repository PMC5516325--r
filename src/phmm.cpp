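// Forward and Viterbi recursions for the profile HMM, in log space.
// States per node k = 0..M: match (node 0 = begin), insert I0..IM,
// delete D1..DM; end state reached from node M. No I<->D transitions.
// Sequences are passed as 0-based residue codes; code 20 (X) emits with
// log-probability 0 in every emitting state (and in the null model).

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

static inline double emit(const NumericMatrix& lem, int row, int code) {
  return code >= 20 ? 0.0 : lem(row, code);
}

// [[Rcpp::export(name = ".phmm_forward")]]
double phmm_forward(IntegerVector seq, NumericMatrix lmatch,
                    NumericMatrix linsert, NumericVector tMM,
                    NumericVector tMI, NumericVector tMD,
                    NumericVector tIM, NumericVector tII,
                    NumericVector tDM, NumericVector tDD) {
  const int L = seq.size();
  const int M = lmatch.nrow();
  const double NEG = R_NegInf;
  // FM[k], k = 0..M (0 = begin); FI[k], k = 0..M; FD[k], k = 1..M.
  std::vector<double> FM(M + 1, NEG), FI(M + 1, NEG), FD(M + 1, NEG);
  std::vector<double> pM(M + 1), pI(M + 1), pD(M + 1);
  FM[0] = 0.0;
  // Deletion chain reachable before any emission.
  FD[1] = FM[0] + tMD[0];
  for (int k = 2; k <= M; ++k) FD[k] = FD[k - 1] + tDD[k - 1];
  for (int i = 1; i <= L; ++i) {
    pM = FM; pI = FI; pD = FD;
    std::fill(FM.begin(), FM.end(), NEG);
    std::fill(FI.begin(), FI.end(), NEG);
    std::fill(FD.begin(), FD.end(), NEG);
    const int c = seq[i - 1];
    for (int k = 1; k <= M; ++k) {
      double prevD = (k >= 2) ? pD[k - 1] + tDM[k - 1] : NEG;
      FM[k] = emit(lmatch, k - 1, c) +
              lse3(pM[k - 1] + tMM[k - 1], pI[k - 1] + tIM[k - 1], prevD);
    }
    for (int k = 0; k <= M; ++k) {
      FI[k] = emit(linsert, k, c) +
              lse2(pM[k] + tMI[k], pI[k] + tII[k]);
    }
    // D states are silent: D_k at position i comes from M_{k-1} or D_{k-1}
    // at the same i. D_1 is only reachable from the begin state (i = 0).
    for (int k = 1; k <= M; ++k) {
      double fromM = (k >= 2) ? FM[k - 1] + tMD[k - 1]
                              : FM[0] + tMD[0];
      double fromD = (k >= 2) ? FD[k - 1] + tDD[k - 1] : NEG;
      FD[k] = lse2(fromM, fromD);
    }
  }
  return lse3(FM[M] + tMM[M], FI[M] + tIM[M], FD[M] + tDM[M]);
}

// [[Rcpp::export(name = ".phmm_viterbi")]]
List phmm_viterbi(IntegerVector seq, NumericMatrix lmatch,
                  NumericMatrix linsert, NumericVector tMM,
                  NumericVector tMI, NumericVector tMD,
                  NumericVector tIM, NumericVector tII,
                  NumericVector tDM, NumericVector tDD) {
  const int L = seq.size();
  const int M = lmatch.nrow();
  const double NEG = R_NegInf;
  // Full DP tables with backpointers (0 = from M, 1 = from I, 2 = from D).
  NumericMatrix VM(L + 1, M + 1), VI(L + 1, M + 1), VD(L + 1, M + 1);
  IntegerMatrix BM(L + 1, M + 1), BI(L + 1, M + 1), BD(L + 1, M + 1);
  std::fill(VM.begin(), VM.end(), NEG);
  std::fill(VI.begin(), VI.end(), NEG);
  std::fill(VD.begin(), VD.end(), NEG);
  VM(0, 0) = 0.0;
  for (int k = 1; k <= M; ++k) {
    double fromM = (k >= 2) ? VM(0, k - 1) + tMD[k - 1] : VM(0, 0) + tMD[0];
    double fromD = (k >= 2) ? VD(0, k - 1) + tDD[k - 1] : NEG;
    if (fromM >= fromD) { VD(0, k) = fromM; BD(0, k) = 0; }
    else { VD(0, k) = fromD; BD(0, k) = 2; }
  }
  for (int i = 1; i <= L; ++i) {
    const int c = seq[i - 1];
    for (int k = 1; k <= M; ++k) {
      double a = VM(i - 1, k - 1) + tMM[k - 1];
      double b = VI(i - 1, k - 1) + tIM[k - 1];
      double d = (k >= 2) ? VD(i - 1, k - 1) + tDM[k - 1] : NEG;
      double best = a; int arg = 0;
      if (b > best) { best = b; arg = 1; }
      if (d > best) { best = d; arg = 2; }
      VM(i, k) = emit(lmatch, k - 1, c) + best;
      BM(i, k) = arg;
    }
    for (int k = 0; k <= M; ++k) {
      double a = VM(i - 1, k) + tMI[k];
      double b = VI(i - 1, k) + tII[k];
      if (a >= b) { VI(i, k) = emit(linsert, k, c) + a; BI(i, k) = 0; }
      else { VI(i, k) = emit(linsert, k, c) + b; BI(i, k) = 1; }
    }
    for (int k = 1; k <= M; ++k) {
      double fromM = (k >= 2) ? VM(i, k - 1) + tMD[k - 1] : VM(i, 0) + tMD[0];
      double fromD = (k >= 2) ? VD(i, k - 1) + tDD[k - 1] : NEG;
      if (fromM >= fromD) { VD(i, k) = fromM; BD(i, k) = 0; }
      else { VD(i, k) = fromD; BD(i, k) = 2; }
    }
  }
  double a = VM(L, M) + tMM[M];
  double b = VI(L, M) + tIM[M];
  double d = VD(L, M) + tDM[M];
  double best = a; int st = 0;
  if (b > best) { best = b; st = 1; }
  if (d > best) { best = d; st = 2; }
  // Traceback: state codes 0 = M, 1 = I, 2 = D.
  std::vector<int> states, nodes, positions;
  int i = L, k = M;
  while (!(st == 0 && k == 0)) {
    states.push_back(st);
    nodes.push_back(k);
    positions.push_back(st == 2 ? NA_INTEGER : i);
    int prev;
    if (st == 0) { prev = BM(i, k); --i; --k; }
    else if (st == 1) { prev = BI(i, k); --i; }
    else { prev = BD(i, k); --k; }
    st = prev;
    if (i < 0 || k < 0) stop("viterbi traceback out of bounds");
  }
  std::reverse(states.begin(), states.end());
  std::reverse(nodes.begin(), nodes.end());
  std::reverse(positions.begin(), positions.end());
  return List::create(_["logp"] = best,
                      _["state"] = wrap(states),
                      _["node"] = wrap(nodes),
                      _["seq_pos"] = wrap(positions));
}
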