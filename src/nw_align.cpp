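#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine-style gap penalties in the
// pairwise2.globalds convention: a gap run of length L costs
// open + (L-1) * extend (the opening position is charged `open` only).
// Deterministic traceback with fixed preference diagonal > up > left and,
// within a state, match-state predecessors preferred; ties resolved by the
// first-listed option so the optimum reported is unique and stable.
//
// States: M = both consumed, X = gap in the second sequence (consume a only),
// Y = gap in the first sequence (consume b only).

static inline double subScore(char a, char b, double match, double mismatch) {
  // N mismatches everything, including N
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gapOpen, double gapExtend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // flattened (n+1) x (m+1) matrices
  std::vector<double> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<unsigned char> tbM(M.size(), 0), tbX(M.size(), 0), tbY(M.size(), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gapOpen + (i - 1) * gapExtend;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;  // from M at first, then X
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gapOpen + (j - 1) * gapExtend;
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = subScore(a[i - 1], b[j - 1], match, mismatch);
      // M: predecessors M, X, Y at (i-1, j-1); prefer M > X > Y on ties
      {
        double best = M[at(i - 1, j - 1)];
        unsigned char tb = 0;
        if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; tb = 1; }
        if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; tb = 2; }
        M[at(i, j)] = best + s;
        tbM[at(i, j)] = tb;
      }
      // X: gap in b, consume a[i-1]; open from M/Y, extend from X
      {
        double best = M[at(i - 1, j)] + gapOpen;
        unsigned char tb = 0;
        if (X[at(i - 1, j)] + gapExtend > best) { best = X[at(i - 1, j)] + gapExtend; tb = 1; }
        if (Y[at(i - 1, j)] + gapOpen > best) { best = Y[at(i - 1, j)] + gapOpen; tb = 2; }
        X[at(i, j)] = best;
        tbX[at(i, j)] = tb;
      }
      // Y: gap in a, consume b[j-1]
      {
        double best = M[at(i, j - 1)] + gapOpen;
        unsigned char tb = 0;
        if (X[at(i, j - 1)] + gapOpen > best) { best = X[at(i, j - 1)] + gapOpen; tb = 1; }
        if (Y[at(i, j - 1)] + gapExtend > best) { best = Y[at(i, j - 1)] + gapExtend; tb = 2; }
        Y[at(i, j)] = best;
        tbY[at(i, j)] = tb;
      }
    }
  }

  // terminal state: prefer M > X > Y on ties
  unsigned char state = 0;
  double score = M[at(n, m)];
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {  // M
      unsigned char prev = tbM[at(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {  // X: a aligned to gap
      unsigned char prev = tbX[at(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      state = prev;
    } else {  // Y: gap aligned to b
      unsigned char prev = tbY[at(i, j)];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["refRow"] = ra, _["ancRow"] = rb, _["score"] = score);
}
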