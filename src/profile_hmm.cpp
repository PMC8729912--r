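#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local (free-endpoint) profile-HMM alignment in log-odds space.
//
// lom : L x M matrix, match-state emission log-odds per residue (X rows are 0)
// loi : length-L vector, insert-state emission log-odds per residue
// lt  : M x 7 matrix of log transition probabilities, columns
//       0 MM  1 MI  2 MD  3 IM  4 II  5 DM  6 DD  (source state = row)
//
// A path starts in any match state at any residue (free entry), moves through
// match/insert/delete states, and exits from any match state (free exit).
// Residues outside the hit score as background (log-odds 0), so the total
// path score is just the sum of emission log-odds and transitions inside it.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".viterbi_local_cpp")]]
List viterbi_local_cpp(NumericMatrix lom, NumericVector loi, NumericMatrix lt) {
  const int L = lom.nrow(), M = lom.ncol();
  NumericMatrix VM(L, M), VI(L, M), VD(L, M);
  IntegerMatrix SM(L, M), SI(L, M), SD(L, M); // 1-based start of best path
  double best = NEG_INF;
  int bstart = -1, bend = -1;

  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < M; ++j) {
      // --- match state j consuming residue i ---
      double sc = 0.0;            // free entry
      int st = i + 1;
      if (i > 0 && j > 0) {
        double c = VM(i - 1, j - 1) + lt(j - 1, 0);
        if (c > sc || (c == sc && SM(i - 1, j - 1) < st)) { sc = c; st = SM(i - 1, j - 1); }
        c = VI(i - 1, j - 1) + lt(j - 1, 3);
        if (c > sc || (c == sc && SI(i - 1, j - 1) < st)) { sc = c; st = SI(i - 1, j - 1); }
        c = VD(i - 1, j - 1) + lt(j - 1, 5);
        if (c > sc || (c == sc && SD(i - 1, j - 1) < st)) { sc = c; st = SD(i - 1, j - 1); }
      }
      VM(i, j) = sc + lom(i, j);
      SM(i, j) = st;

      // --- insert state j consuming residue i ---
      double si = NEG_INF; int sti = i + 1;
      if (i > 0) {
        double c = VM(i - 1, j) + lt(j, 1);
        if (c > si) { si = c; sti = SM(i - 1, j); }
        c = VI(i - 1, j) + lt(j, 4);
        if (c > si || (c == si && SI(i - 1, j) < sti)) { si = c; sti = SI(i - 1, j); }
      }
      VI(i, j) = (si == NEG_INF) ? NEG_INF : si + loi[i];
      SI(i, j) = sti;

      // --- delete state j (no residue consumed) ---
      double sd = NEG_INF; int std_ = i + 1;
      if (j > 0) {
        double c = VM(i, j - 1) + lt(j - 1, 2);
        if (c > sd) { sd = c; std_ = SM(i, j - 1); }
        c = VD(i, j - 1) + lt(j - 1, 6);
        if (c > sd || (c == sd && SD(i, j - 1) < std_)) { sd = c; std_ = SD(i, j - 1); }
      }
      VD(i, j) = sd;
      SD(i, j) = std_;
    }
  }

  // free exit from any match cell; tie-break smallest start, then smallest end
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < M; ++j) {
      double sc = VM(i, j);
      int st = SM(i, j), en = i + 1;
      if (sc > best ||
          (sc == best && (st < bstart || (st == bstart && en < bend)))) {
        best = sc; bstart = st; bend = en;
      }
    }
  }
  return List::create(_["score"] = best, _["start"] = bstart, _["end"] = bend);
}

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export(name = ".forward_local_cpp")]]
double forward_local_cpp(NumericMatrix lom, NumericVector loi, NumericMatrix lt) {
  const int L = lom.nrow(), M = lom.ncol();
  NumericMatrix FM(L, M), FI(L, M), FD(L, M);
  double total = NEG_INF;
  for (int i = 0; i < L; ++i) {
    for (int j = 0; j < M; ++j) {
      double sm = 0.0; // free entry contributes probability 1
      if (i > 0 && j > 0) {
        sm = lse2(sm, FM(i - 1, j - 1) + lt(j - 1, 0));
        sm = lse2(sm, FI(i - 1, j - 1) + lt(j - 1, 3));
        sm = lse2(sm, FD(i - 1, j - 1) + lt(j - 1, 5));
      }
      FM(i, j) = sm + lom(i, j);

      double si = NEG_INF;
      if (i > 0) {
        si = lse2(FM(i - 1, j) + lt(j, 1), FI(i - 1, j) + lt(j, 4));
      }
      FI(i, j) = (si == NEG_INF) ? NEG_INF : si + loi[i];

      double sd = NEG_INF;
      if (j > 0) {
        sd = lse2(FM(i, j - 1) + lt(j - 1, 2), FD(i, j - 1) + lt(j - 1, 6));
      }
      FD(i, j) = sd;

      total = lse2(total, FM(i, j)); // free exit
    }
  }
  return total;
}
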