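#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local alignment of a text against tandem copies of a cyclic pattern
// (wraparound dynamic programming). Scoring is TRF-style linear:
// match +ma, mismatch -mm, indel -gp per base; N matches nothing.
//
// The column index runs over the pattern and wraps, so an alignment may
// traverse the monomer any number of times; the row recurrence is swept
// repeatedly until stable to resolve the cyclic horizontal dependency
// (gap costs are positive, so convergence is fast).
//
// Returns the best local score, the text interval it covers (0-based
// half-open) and the match/mismatch/indel counts along the best path.
// [[Rcpp::export]]
List wrap_align(std::string text, std::string pat,
                int ma, int mm, int gp) {
  int n = (int) text.size(), p = (int) pat.size();
  if (p < 1 || n < 1) stop("empty text or pattern");

  std::vector<int> Ps(p, 0), Pb(p, 0), Pm(p, 0), Px(p, 0), Pi(p, 0);
  std::vector<int> Cs(p), Cb(p), Cm(p), Cx(p), Ci(p);
  // row 0: empty-text cells all start fresh at the next position
  for (int j = 0; j < p; ++j) Pb[j] = 0;

  int best = 0, bestEnd = 0, bestB = 0, bestM = 0, bestX = 0, bestI = 0;

  for (int i = 1; i <= n; ++i) {
    char tc = text[i - 1];
    for (int j = 0; j < p; ++j) {
      int jm = (j == 0) ? p - 1 : j - 1;
      char pc = pat[j];
      bool isMatch = (tc == pc) && tc != 'N';
      int sub = isMatch ? ma : -mm;
      // diagonal from previous row
      int sc = Ps[jm] + sub;
      int b = Pb[jm], m = Pm[jm] + (isMatch ? 1 : 0),
          x = Px[jm] + (isMatch ? 0 : 1), in = Pi[jm];
      // fresh local start consuming this char
      int fresh = sub;
      if (fresh > sc || (fresh == sc && i - 1 > b)) {
        sc = fresh; b = i - 1; m = isMatch ? 1 : 0; x = isMatch ? 0 : 1; in = 0;
      }
      // vertical: text char against a gap
      int up = Ps[j] - gp;
      if (up > sc) { sc = up; b = Pb[j]; m = Pm[j]; x = Px[j]; in = Pi[j] + 1; }
      if (sc < 0) { sc = 0; b = i; m = 0; x = 0; in = 0; }
      Cs[j] = sc; Cb[j] = b; Cm[j] = m; Cx[j] = x; Ci[j] = in;
    }
    // horizontal (pattern char against a gap) with wraparound: sweep until
    // stable; each wrap costs at least gp so a few sweeps suffice
    bool changed = true;
    int sweeps = 0;
    while (changed && sweeps < 4) {
      changed = false;
      ++sweeps;
      for (int j = 0; j < p; ++j) {
        int jm = (j == 0) ? p - 1 : j - 1;
        int left = Cs[jm] - gp;
        if (left > Cs[j]) {
          Cs[j] = left; Cb[j] = Cb[jm]; Cm[j] = Cm[jm]; Cx[j] = Cx[jm];
          Ci[j] = Ci[jm] + 1;
          changed = true;
        }
      }
    }
    for (int j = 0; j < p; ++j) {
      if (Cs[j] > best) {
        best = Cs[j]; bestEnd = i; bestB = Cb[j];
        bestM = Cm[j]; bestX = Cx[j]; bestI = Ci[j];
      }
    }
    std::swap(Ps, Cs); std::swap(Pb, Cb); std::swap(Pm, Cm);
    std::swap(Px, Cx); std::swap(Pi, Ci);
  }

  return List::create(
    _["score"] = best, _["start"] = bestB, _["end"] = bestEnd,
    _["matches"] = bestM, _["mismatches"] = bestX, _["indels"] = bestI);
}

// Positions (0-based) where the sequence matches itself at the given lag:
// m[i] = (s[i] == s[i + d]), N never matches. Returned as a logical vector
// of length n - d.
// [[Rcpp::export]]
LogicalVector lag_matches(std::string s, int d) {
  int n = (int) s.size();
  if (d >= n) return LogicalVector(0);
  LogicalVector out(n - d);
  for (int i = 0; i < n - d; ++i)
    out[i] = (s[i] == s[i + d]) && s[i] != 'N';
  return out;
}
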