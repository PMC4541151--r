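#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-programming cores for the alignment stages. Sequences arrive as
// integer codes (nucleotides: A=0 C=1 G=2 T=3 N=4). Gap of length L costs
// gap_open + L * gap_extend throughout.

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// Local affine-gap alignment (Smith-Waterman/Gotoh) between two nucleotide
// integer vectors. N (code 4) scores as a mismatch against everything,
// including itself. Returns the single best-scoring local alignment with
// coordinates (1-based, inclusive) and column statistics.
// [[Rcpp::export(name = ".C_sw_affine")]]
List C_sw_affine(IntegerVector a, IntegerVector b,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // H, E (gap in a: consumes b), F (gap in b: consumes a)
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  // traceback pointers: tbH 0=stop 1=diag 2=E(left) 3=F(up); tbE/tbF 0=open 1=extend
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t off = (size_t)i * (m + 1) + j;
      const double e_open = Hcur[j - 1] - gap_open - gap_extend;
      const double e_ext  = Ecur[j - 1] - gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[off] = 0; }
      else                 { Ecur[j] = e_ext;  tbE[off] = 1; }
      const double f_open = Hprev[j] - gap_open - gap_extend;
      const double f_ext  = Fprev[j] - gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[off] = 0; }
      else                 { Fcur[j] = f_ext;  tbF[off] = 1; }
      const double s = (ai == b[j - 1] && ai < 4) ? match : mismatch;
      const double diag = Hprev[j - 1] + s;
      double h = 0.0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; p = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; p = 3; }
      Hcur[j] = h; tbH[off] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  // traceback from (bi,bj)
  int i = bi, j = bj, state = 0; // 0=H
  int matches = 0, mismatches = 0, gapopens = 0, gaps = 0, alnlen = 0;
  int qend = bi, send = bj, qstart = bi + 1, sstart = bj + 1;
  bool in_gap_e = false, in_gap_f = false;
  while (i > 0 && j > 0) {
    const size_t off = (size_t)i * (m + 1) + j;
    if (state == 0) {
      const unsigned char p = tbH[off];
      if (p == 0) break;
      if (p == 1) {
        ++alnlen;
        if (a[i - 1] == b[j - 1] && a[i - 1] < 4) ++matches; else ++mismatches;
        qstart = i; sstart = j; --i; --j;
        in_gap_e = in_gap_f = false;
      } else if (p == 2) { state = 2; }
      else { state = 3; }
    } else if (state == 2) { // E: gap in a, consume b
      ++alnlen; ++gaps;
      if (!in_gap_e) { ++gapopens; in_gap_e = true; }
      sstart = j;
      const unsigned char p = tbE[off];
      --j;
      if (p == 0) { state = 0; in_gap_e = false; }
    } else { // F: gap in b, consume a
      ++alnlen; ++gaps;
      if (!in_gap_f) { ++gapopens; in_gap_f = true; }
      qstart = i;
      const unsigned char p = tbF[off];
      --i;
      if (p == 0) { state = 0; in_gap_f = false; }
    }
  }
  return List::create(_["score"] = best,
                      _["q_start"] = qstart, _["q_end"] = qend,
                      _["s_start"] = sstart, _["s_end"] = send,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gap_opens"] = gapopens, _["gaps"] = gaps,
                      _["align_len"] = alnlen);
}

// Global affine-gap alignment (Needleman-Wunsch/Gotoh) over a precomputed
// column-score matrix S (rows index positions of A, columns positions of B).
// Works for residue-vs-residue scoring (S from a substitution matrix) and for
// profile-vs-profile scoring (S from expected sum-of-pairs scores).
// Traceback tie-break: diagonal, then up (gap in B), then left (gap in A).
// Returns the optimal score and the aligned path as two integer vectors of
// equal length; 0 marks a gap, otherwise 1-based positions.
// [[Rcpp::export(name = ".C_nw_affine")]]
List C_nw_affine(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in B (consumes A, "up"); Y: gap in A (consumes B, "left")
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG; X(i, j) = NEG; Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  // pointer matrices: predecessor state (0=M, 1=X, 2=Y) for each cell/state
  std::vector<unsigned char> ptrM((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> ptrX((size_t)(n + 1) * (m + 1), 1);
  std::vector<unsigned char> ptrY((size_t)(n + 1) * (m + 1), 2);
  for (int i = 1; i <= n; ++i) {
    X(i, 0) = -gap_open - i * gap_extend;
    ptrX[(size_t)i * (m + 1)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y(0, j) = -gap_open - j * gap_extend;
    ptrY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t off = (size_t)i * (m + 1) + j;
      // M: preference M > X > Y on ties
      double best = M(i - 1, j - 1); unsigned char p = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); p = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); p = 2; }
      M(i, j) = S(i - 1, j - 1) + best;
      ptrM[off] = p;
      // X (gap in B, consumes A)
      best = M(i - 1, j) - gap_open - gap_extend; p = 0;
      if (X(i - 1, j) - gap_extend > best) {
        best = X(i - 1, j) - gap_extend; p = 1;
      }
      if (Y(i - 1, j) - gap_open - gap_extend > best) {
        best = Y(i - 1, j) - gap_open - gap_extend; p = 2;
      }
      X(i, j) = best;
      ptrX[off] = p;
      // Y (gap in A, consumes B)
      best = M(i, j - 1) - gap_open - gap_extend; p = 0;
      if (X(i, j - 1) - gap_open - gap_extend > best) {
        best = X(i, j - 1) - gap_open - gap_extend; p = 1;
      }
      if (Y(i, j - 1) - gap_extend > best) {
        best = Y(i, j - 1) - gap_extend; p = 2;
      }
      Y(i, j) = best;
      ptrY[off] = p;
    }
  }
  const double score = max3(M(n, m), X(n, m), Y(n, m));
  // traceback via pointers stored in the forward pass; preference M > X > Y
  std::vector<int> pa, pb;
  int i = n, j = m;
  int state; // 0=M 1=X 2=Y
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 0;
  else if (X(n, m) >= Y(n, m)) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    const size_t off = (size_t)i * (m + 1) + j;
    if (state == 0) {
      pa.push_back(i); pb.push_back(j);
      state = ptrM[off];
      --i; --j;
    } else if (state == 1) {
      pa.push_back(i); pb.push_back(0);
      state = ptrX[off];
      --i;
    } else {
      pa.push_back(0); pb.push_back(j);
      state = ptrY[off];
      --j;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
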