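#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>

using namespace Rcpp;

static inline int bcode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N: mismatches everything
  }
}

// Smith-Waterman local alignment of read vs one reference, affine gaps.
// A gap of length L costs gap_open + L * gap_extend. The subject start
// column of the optimal local alignment is propagated through the DP so
// ties resolve to the smallest subject start, then smallest subject end.
// Returns (score, start, end) with 1-based subject coordinates; score 0
// means no positive-scoring alignment.
// [[Rcpp::export]]
List cpp_sw(std::string read, std::string ref, double match, double mismatch,
            double gap_open, double gap_extend) {
  const int m = (int) read.size(), n = (int) ref.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER);
  std::vector<int> rd(m), rf(n);
  for (int i = 0; i < m; ++i) rd[i] = bcode(read[i]);
  for (int j = 0; j < n; ++j) rf[j] = bcode(ref[j]);

  const double GO = gap_open + gap_extend;  // cost of a length-1 gap
  const double NEG = -1e18;
  // rolling rows over the subject dimension
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);  // gap in read
  std::vector<double> Fcur(n + 1, NEG);                     // gap in subject
  std::vector<int> HOprev(n + 1, 0), HOcur(n + 1, 0);
  std::vector<int> EOprev(n + 1, 0), EOcur(n + 1, 0);
  std::vector<int> FOcur(n + 1, 0);

  double best = 0.0;
  int best_start = NA_INTEGER, best_end = NA_INTEGER;

  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    HOcur[0] = 0; EOcur[0] = 0; FOcur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      // E: gap in the read (subject consumed horizontally)
      double e_open = Hcur[j - 1] - GO, e_ext = Ecur[j - 1] - gap_extend;
      if (e_open >= e_ext) {
        Ecur[j] = e_open; EOcur[j] = HOcur[j - 1];
        if (e_open == e_ext && EOcur[j - 1] < EOcur[j]) EOcur[j] = EOcur[j - 1];
      } else { Ecur[j] = e_ext; EOcur[j] = EOcur[j - 1]; }
      // F: gap in the subject (read consumed vertically)
      double f_open = Hprev[j] - GO, f_ext = Fcur[j] - gap_extend;
      int fo_prev = FOcur[j];
      if (f_open >= f_ext) {
        Fcur[j] = f_open; FOcur[j] = HOprev[j];
        if (f_open == f_ext && fo_prev < FOcur[j]) FOcur[j] = fo_prev;
      } else { Fcur[j] = f_ext; FOcur[j] = fo_prev; }
      // H: best of {0, diagonal, E, F}; equal positive scores resolve to the
      // smaller subject origin
      bool is_match = (rd[i - 1] < 4 && rd[i - 1] == rf[j - 1]);
      double diag = Hprev[j - 1] + (is_match ? match : mismatch);
      int diag_o = (Hprev[j - 1] > 0.0) ? HOprev[j - 1] : j;
      double h = 0.0; int ho = 0;
      if (diag > h || (diag == h && diag > 0.0 && diag_o < ho)) {
        h = diag; ho = diag_o;
      }
      if (Ecur[j] > h || (Ecur[j] == h && h > 0.0 && EOcur[j] < ho)) {
        h = Ecur[j]; ho = EOcur[j];
      }
      if (Fcur[j] > h || (Fcur[j] == h && h > 0.0 && FOcur[j] < ho)) {
        h = Fcur[j]; ho = FOcur[j];
      }
      if (h <= 0.0) { h = 0.0; ho = 0; }
      Hcur[j] = h; HOcur[j] = ho;
      if (h > best ||
          (h == best && h > 0.0 &&
           (ho < best_start || (ho == best_start && j < best_end)))) {
        best = h; best_start = ho; best_end = j;
      }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
    std::swap(HOprev, HOcur); std::swap(EOprev, EOcur);
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["start"] = NA_INTEGER,
                        _["end"] = NA_INTEGER);
  return List::create(_["score"] = best, _["start"] = best_start,
                      _["end"] = best_end);
}
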