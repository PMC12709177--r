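#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap costs over a
// precomputed column-pair score matrix S (nA x nB).  A gap of length L
// costs open + (L-1)*extend.  Traceback ties resolve diagonal > up > left,
// where "up" consumes a row of S (a residue/column of sequence A) and
// "left" consumes a column of S (sequence B).
//
// Returns list(score, ops) where ops is an integer vector over
// {0 = diagonal, 1 = up/consume-A, 2 = left/consume-B}, in alignment order.
//
// The same routine serves residue-vs-residue alignment (S indexed by the
// substitution matrix) and profile-vs-profile alignment (S = t(PA) %*% M
// %*% PB computed by the caller).
// [[Rcpp::export(name = ".affine_dp")]]
List affine_dp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // H, E (gap in A: last move left), F (gap in B: last move up)
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // pointer codes: for H: 0 diag, 1 from F (up), 2 from E (left)
  IntegerMatrix PH(n + 1, m + 1), PE(n + 1, m + 1), PF(n + 1, m + 1);

  H(0, 0) = 0.0;
  E(0, 0) = F(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -(gap_open + (j - 1) * gap_extend);
    H(0, j) = E(0, j);
    F(0, j) = NEG;
    PH(0, j) = 2;
    PE(0, j) = 1; // extend
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -(gap_open + (i - 1) * gap_extend);
    H(i, 0) = F(i, 0);
    E(i, 0) = NEG;
    PH(i, 0) = 1;
    PF(i, 0) = 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // E: gap in A (move left). Open from H(i, j-1) or extend E(i, j-1).
      double e_open = H(i, j - 1) - gap_open;
      double e_ext = E(i, j - 1) - gap_extend;
      if (e_open >= e_ext) { E(i, j) = e_open; PE(i, j) = 0; }
      else { E(i, j) = e_ext; PE(i, j) = 1; }
      // F: gap in B (move up).
      double f_open = H(i - 1, j) - gap_open;
      double f_ext = F(i - 1, j) - gap_extend;
      if (f_open >= f_ext) { F(i, j) = f_open; PF(i, j) = 0; }
      else { F(i, j) = f_ext; PF(i, j) = 1; }
      // H: tie order diagonal > up (F) > left (E)
      double diag = H(i - 1, j - 1) + S(i - 1, j - 1);
      double best = diag; int ptr = 0;
      if (F(i, j) > best) { best = F(i, j); ptr = 1; }
      if (E(i, j) > best) { best = E(i, j); ptr = 2; }
      H(i, j) = best;
      PH(i, j) = ptr;
    }
  }

  // traceback
  std::vector<int> ops;
  ops.reserve(n + m);
  int i = n, j = m, state = 0; // 0=H, 1=F, 2=E
  while (i > 0 || j > 0) {
    if (state == 0) {
      int p = PH(i, j);
      if (p == 0 && i > 0 && j > 0) {
        ops.push_back(0); --i; --j;
      } else if (p == 1) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // in F: consume A (up)
      int p = PF(i, j);
      ops.push_back(1); --i;
      state = (p == 0) ? 0 : 1;
    } else { // in E: consume B (left)
      int p = PE(i, j);
      ops.push_back(2); --j;
      state = (p == 0) ? 0 : 2;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = H(n, m),
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
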