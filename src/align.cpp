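#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh). A gap run of length k costs
// open + k * extend. Tie-break in traceback: diagonal > up > left,
// so alignments are deterministic.
//
// States: 0 = M (match/mismatch), 1 = Ix (residue of a vs gap, "up"),
// 2 = Iy (gap vs residue of b, "left").

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix submat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // DP matrices, (n+1) x (m+1), row-major index i*(m+1)+j
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix(M), Iy(M);
  // traceback: predecessor state for each cell/state
  std::vector<signed char> tbM(M.size(), -1), tbIx(M.size(), -1), tbIy(M.size(), -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[i * (m + 1)] = -(gap_open + i * gap_extend);
    tbIx[i * (m + 1)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = -(gap_open + j * gap_extend);
    tbIy[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = i * (m + 1) + j;
      const int di = (i - 1) * (m + 1) + (j - 1);
      const int up = (i - 1) * (m + 1) + j;
      const int lf = i * (m + 1) + (j - 1);
      const double s = submat(a[i - 1] - 1, b[j - 1] - 1);
      // M: best predecessor, prefer M > Ix > Iy on ties
      double best = M[di]; signed char st = 0;
      if (Ix[di] > best) { best = Ix[di]; st = 1; }
      if (Iy[di] > best) { best = Iy[di]; st = 2; }
      M[ij] = best + s; tbM[ij] = st;
      // Ix: open from M or extend, prefer open on ties
      double op = M[up] - (gap_open + gap_extend);
      double ex = Ix[up] - gap_extend;
      if (op >= ex) { Ix[ij] = op; tbIx[ij] = 0; } else { Ix[ij] = ex; tbIx[ij] = 1; }
      op = M[lf] - (gap_open + gap_extend);
      ex = Iy[lf] - gap_extend;
      if (op >= ex) { Iy[ij] = op; tbIy[ij] = 0; } else { Iy[ij] = ex; tbIy[ij] = 2; }
    }
  }

  const int end = n * (m + 1) + m;
  double score = M[end]; signed char state = 0;
  if (Ix[end] > score) { score = Ix[end]; state = 1; }
  if (Iy[end] > score) { score = Iy[end]; state = 2; }

  // traceback: moves 1 = diagonal, 2 = up (a vs gap), 3 = left (gap vs b)
  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int ij = i * (m + 1) + j;
    if (state == 0) {
      moves.push_back(1); state = tbM[ij]; --i; --j;
    } else if (state == 1) {
      moves.push_back(2); state = tbIx[ij]; --i;
    } else {
      moves.push_back(3); state = tbIy[ij]; --j;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score, _["moves"] = wrap(moves));
}

// Profile-profile affine alignment for progressive MSA. Profiles are
// integer matrices (rows = sequences, columns = alignment columns),
// 0 = gap, otherwise 1-based residue codes into submat. Column pair
// score is the average substitution score over all residue pairs;
// anything paired with a gap contributes 0. Gap penalties are the
// same unscaled affine penalties as the pairwise aligner.
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(IntegerMatrix A, IntegerMatrix B, NumericMatrix submat,
                       double gap_open, double gap_extend) {
  const int nA = A.nrow(), LA = A.ncol();
  const int nB = B.nrow(), LB = B.ncol();
  const int K = submat.nrow();

  // residue counts per column (K x L), gaps excluded
  NumericMatrix cntA(K, LA), SB(K, LB);
  for (int c = 0; c < LA; ++c)
    for (int r = 0; r < nA; ++r)
      if (A(r, c) > 0) cntA(A(r, c) - 1, c) += 1.0;
  {
    NumericMatrix cntB(K, LB);
    for (int c = 0; c < LB; ++c)
      for (int r = 0; r < nB; ++r)
        if (B(r, c) > 0) cntB(B(r, c) - 1, c) += 1.0;
    for (int c = 0; c < LB; ++c)
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int l = 0; l < K; ++l) acc += submat(k, l) * cntB(l, c);
        SB(k, c) = acc;
      }
  }
  const double denom = (double)nA * (double)nB;

  std::vector<double> M((LA + 1) * (LB + 1), NEG_INF), Ix(M), Iy(M);
  std::vector<signed char> tbM(M.size(), -1), tbIx(M.size(), -1), tbIy(M.size(), -1);
  M[0] = 0.0;
  for (int i = 1; i <= LA; ++i) {
    Ix[i * (LB + 1)] = -(gap_open + i * gap_extend);
    tbIx[i * (LB + 1)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= LB; ++j) {
    Iy[j] = -(gap_open + j * gap_extend);
    tbIy[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= LA; ++i) {
    for (int j = 1; j <= LB; ++j) {
      const int ij = i * (LB + 1) + j;
      const int di = (i - 1) * (LB + 1) + (j - 1);
      const int up = (i - 1) * (LB + 1) + j;
      const int lf = i * (LB + 1) + (j - 1);
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        if (cntA(k, i - 1) > 0) s += cntA(k, i - 1) * SB(k, j - 1);
      s /= denom;
      double best = M[di]; signed char st = 0;
      if (Ix[di] > best) { best = Ix[di]; st = 1; }
      if (Iy[di] > best) { best = Iy[di]; st = 2; }
      M[ij] = best + s; tbM[ij] = st;
      double op = M[up] - (gap_open + gap_extend);
      double ex = Ix[up] - gap_extend;
      if (op >= ex) { Ix[ij] = op; tbIx[ij] = 0; } else { Ix[ij] = ex; tbIx[ij] = 1; }
      op = M[lf] - (gap_open + gap_extend);
      ex = Iy[lf] - gap_extend;
      if (op >= ex) { Iy[ij] = op; tbIy[ij] = 0; } else { Iy[ij] = ex; tbIy[ij] = 2; }
    }
  }
  const int end = LA * (LB + 1) + LB;
  double score = M[end]; signed char state = 0;
  if (Ix[end] > score) { score = Ix[end]; state = 1; }
  if (Iy[end] > score) { score = Iy[end]; state = 2; }
  std::vector<int> moves;
  int i = LA, j = LB;
  while (i > 0 || j > 0) {
    const int ij = i * (LB + 1) + j;
    if (state == 0) { moves.push_back(1); state = tbM[ij]; --i; --j; }
    else if (state == 1) { moves.push_back(2); state = tbIx[ij]; --i; }
    else { moves.push_back(3); state = tbIy[ij]; --j; }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score, _["moves"] = wrap(moves));
}
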