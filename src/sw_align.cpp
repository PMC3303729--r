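#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Gotoh local alignment (affine gaps) over integer-coded sequences with an
// arbitrary substitution matrix.  A gap of length L costs gap_open +
// L * gap_extend (the open penalty is charged once, at the first gap
// residue, in addition to its extend penalty).
//
// Determinism contract (the R-level oracle in the test suite implements the
// same rule independently):
//   * the alignment endpoint is the first cell, scanning rows (query) then
//     columns (subject), that attains the maximal score;
//   * on ties while filling a cell, the preference order is
//     diagonal > gap-in-subject (consumes query) > gap-in-query > restart;
//   * gap states prefer opening a new gap over extending on a tie.
// This yields, among co-optimal alignments, the one with the smallest query
// start and then the smallest subject start reachable under the preference.
//
// Returns 1-based inclusive coordinates; score 0 means no local alignment.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix smat,
                  double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int nsym = smat.nrow();
  for (int i = 0; i < n; ++i)
    if (q[i] < 1 || q[i] > nsym) stop("query symbol code out of range");
  for (int j = 0; j < m; ++j)
    if (s[j] < 1 || s[j] > nsym) stop("subject symbol code out of range");

  const double go = gap_open, ge = gap_extend;
  const size_t W = (size_t)m + 1;
  // Rolling value rows; full pointer matrices for traceback.
  std::vector<float> Hprev(W, 0.0f), Hcur(W, 0.0f);
  // gap-in-subject state is unreachable in row 0
  std::vector<float> Fprev(W, -1e30f), Fcur(W, 0.0f);
  // pointers: pH 0=stop 1=diag 2=fromF 3=fromE ; pF/pE 0=open(from H) 1=extend
  std::vector<uint8_t> pH((size_t)(n + 1) * W, 0), pF((size_t)(n + 1) * W, 0),
      pE((size_t)(n + 1) * W, 0);
  const double NEG = -1e30;
  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    double Ecur = NEG; // gap in query (horizontal), within this row
    Hcur[0] = 0.0f;
    Fcur[0] = (float)NEG;
    const double *srow = &smat(q[i - 1] - 1, 0); // column-major: use smat(a,b)
    (void)srow;
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t)i * W + j;
      // F: gap in subject, consumes query (from row i-1, same column)
      double f_open = (double)Hprev[j] - go - ge;
      double f_ext = (double)Fprev[j] - ge;
      double F;
      if (f_open >= f_ext) { F = f_open; pF[idx] = 0; }
      else                 { F = f_ext;  pF[idx] = 1; }
      Fcur[j] = (float)F;
      // E: gap in query, consumes subject (same row, column j-1)
      double e_open = (double)Hcur[j - 1] - go - ge;
      double e_ext = Ecur - ge;
      double E;
      if (e_open >= e_ext) { E = e_open; pE[idx] = 0; }
      else                 { E = e_ext;  pE[idx] = 1; }
      Ecur = E;
      // H
      double diag = (double)Hprev[j - 1] + smat(q[i - 1] - 1, s[j - 1] - 1);
      double h = diag;
      uint8_t ptr = 1;
      if (F > h) { h = F; ptr = 2; }
      if (E > h) { h = E; ptr = 3; }
      if (h <= 0.0) { h = 0.0; ptr = 0; }
      Hcur[j] = (float)h;
      pH[idx] = ptr;
      if (h > best + 1e-12) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["matches"] = 0,
                        _["aln_len"] = 0);
  }

  // Traceback from (bi, bj) following stored pointers.
  int i = bi, j = bj, matches = 0, aln_len = 0;
  int state = 0; // 0 = H, 1 = F, 2 = E
  while (true) {
    const size_t idx = (size_t)i * W + j;
    if (state == 0) {
      uint8_t p = pH[idx];
      if (p == 0) break;
      if (p == 1) {
        if (q[i - 1] == s[j - 1]) ++matches;
        ++aln_len; --i; --j;
      } else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) { // F: consumes query
      uint8_t p = pF[idx];
      ++aln_len; --i;
      if (p == 0) state = 0;
    } else { // E: consumes subject
      uint8_t p = pE[idx];
      ++aln_len; --j;
      if (p == 0) state = 0;
    }
  }
  return List::create(_["score"] = best, _["q_start"] = i + 1,
                      _["q_end"] = bi, _["s_start"] = j + 1,
                      _["s_end"] = bj, _["matches"] = matches,
                      _["aln_len"] = aln_len);
}
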