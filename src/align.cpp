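#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming over a precomputed similarity matrix.
// sim(i, j) scores pairing row-unit i of A with column-unit j of B; the
// caller builds it from a substitution matrix (residues) or from profile
// column cross-scores (progressive MSA merges), so one kernel serves
// pairwise, local and profile-profile alignment.
//
// Gap model: a gap of length k costs gap_open + k * gap_ext.
// Traceback ties are broken diagonal > up (gap in B) > left (gap in A),
// which makes the reported alignment deterministic.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".align_dp")]]
List align_dp(NumericMatrix sim, double gap_open, double gap_ext,
              bool local) {
  const int n = sim.nrow(), m = sim.ncol();
  // state 0 = M (match), 1 = X (gap in B, consumes A), 2 = Y (gap in A)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }

  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    X(i, 0) = local ? NEG_INF : -(gap_open + i * gap_ext);
    tbX(i, 0) = 1;
    if (local) M(i, 0) = 0.0;
  }
  for (int j = 1; j <= m; ++j) {
    Y(0, j) = local ? NEG_INF : -(gap_open + j * gap_ext);
    tbY(0, j) = 2;
    if (local) M(0, j) = 0.0;
  }
  if (local)
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= m; ++j) M(i, j) = std::max(M(i, j), 0.0);

  double best = NEG_INF;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: from M/X/Y at (i-1, j-1); tie order M > X > Y
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double mprev = dM; int mfrom = 0;
      if (dX > mprev) { mprev = dX; mfrom = 1; }
      if (dY > mprev) { mprev = dY; mfrom = 2; }
      double mval = mprev + sim(i - 1, j - 1);
      if (local && mval < 0.0) { mval = 0.0; mfrom = -1; }
      M(i, j) = mval; tbM(i, j) = mfrom;

      // X: gap in B (move down); open from M, extend from X
      double xo = M(i - 1, j) - gap_open - gap_ext;
      double xe = X(i - 1, j) - gap_ext;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 0; }
      else          { X(i, j) = xe; tbX(i, j) = 1; }

      // Y: gap in A (move right); open from M, extend from Y
      double yo = M(i, j - 1) - gap_open - gap_ext;
      double ye = Y(i, j - 1) - gap_ext;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 0; }
      else          { Y(i, j) = ye; tbY(i, j) = 2; }

      if (local && M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  int si, sj, state;
  double score;
  if (local) {
    score = best <= 0.0 ? 0.0 : best;
    si = bi; sj = bj; state = 0;
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0),
                          _["a_range"] = IntegerVector::create(0, 0),
                          _["b_range"] = IntegerVector::create(0, 0));
    }
  } else {
    double fM = M(n, m), fX = X(n, m), fY = Y(n, m);
    state = 0; score = fM;
    if (fX > score) { score = fX; state = 1; }
    if (fY > score) { score = fY; state = 2; }
    si = n; sj = m;
  }

  // traceback
  std::vector<int> ai, bi_;
  int i = si, j = sj, st = state;
  while (i > 0 || j > 0) {
    if (st == 0) {
      if (local && (M(i, j) == 0.0 || tbM(i, j) == -1)) break;
      if (i == 0 || j == 0) break;
      int from = tbM(i, j);
      ai.push_back(i); bi_.push_back(j);
      --i; --j; st = from;
      if (local && st == -1) break;
    } else if (st == 1) {
      int from = tbX(i, j);
      ai.push_back(i); bi_.push_back(0);
      --i; st = from;
    } else {
      int from = tbY(i, j);
      ai.push_back(0); bi_.push_back(j);
      --j; st = from;
    }
    if (local && i == 0 && j == 0) break;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_.begin(), bi_.end());

  int a_lo = 0, a_hi = 0, b_lo = 0, b_hi = 0;
  for (size_t k = 0; k < ai.size(); ++k) {
    if (ai[k] > 0) { if (a_lo == 0) a_lo = ai[k]; a_hi = ai[k]; }
    if (bi_[k] > 0) { if (b_lo == 0) b_lo = bi_[k]; b_hi = bi_[k]; }
  }

  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi_),
                      _["a_range"] = IntegerVector::create(a_lo, a_hi),
                      _["b_range"] = IntegerVector::create(b_lo, b_hi));
}
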