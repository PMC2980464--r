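#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Exact affine-gap local alignment (Gotoh).  A gap of length k costs
// gap_open + (k - 1) * gap_extend, i.e. gap_open is charged for the first
// gapped position.  Scores are looked up in a 128 x 128 integer table
// indexed by ASCII code, built on the R side from a ScoringScheme.

static const int NEG_INF = -1073741824;  // safely below any reachable score

// Score-only DP with rolling rows.  Returns the best local score (>= 0).
static int sw_score_one(const std::string& a, const std::string& b,
                        const IntegerMatrix& lut, int go, int ge) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) return 0;
  const int* L = INTEGER(lut);  // column-major 128 x 128
  std::vector<int> brow(n);
  for (int j = 0; j < n; ++j) brow[j] = 128 * ((unsigned char)b[j] & 127);
  std::vector<int> H(n + 1, 0), E(n + 1, NEG_INF);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    const int ai = (unsigned char)a[i - 1] & 127;
    int Hdiag = 0;             // H[i-1][0]
    int Fprev = NEG_INF;       // F[i][j] carried along the row
    int Hleft = 0;             // H[i][j-1]
    for (int j = 1; j <= n; ++j) {
      int e = H[j] - go, eext = E[j] - ge;        // vertical gap
      if (eext > e) e = eext;
      E[j] = e;
      int f = Hleft - go, fext = Fprev - ge;      // horizontal gap
      if (fext > f) f = fext;
      Fprev = f;
      int h = Hdiag + L[ai + brow[j - 1]];
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (f > h) h = f;
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// NOTE on the rolling recurrence above: by the time column j is processed,
// H[j] still holds row i-1 (used for E, the gap consuming query rows) while
// H[j-1] already holds row i (used for F, the gap consuming subject cols).
// E therefore extends vertically and F horizontally, which together with the
// symmetric costs gives the same optimum as the full Gotoh matrices (checked
// against a naive three-matrix oracle in the test suite).

//' @noRd
// [[Rcpp::export]]
int sw_score_cpp(std::string a, std::string b, IntegerMatrix lut,
                 int gap_open, int gap_extend) {
  return sw_score_one(a, b, lut, gap_open, gap_extend);
}

//' @noRd
// [[Rcpp::export]]
IntegerVector sw_score_vec_cpp(std::string query, CharacterVector db,
                               IntegerMatrix lut, int gap_open, int gap_extend) {
  const int N = db.size();
  IntegerVector out(N);
  for (int k = 0; k < N; ++k) {
    std::string s = as<std::string>(db[k]);
    out[k] = sw_score_one(query, s, lut, gap_open, gap_extend);
  }
  return out;
}

// All pairwise scores between two sets of peptides (frame translations);
// returns a length(as) x length(bs) matrix.  Used by the translated modes.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix sw_score_cross_cpp(CharacterVector xs, CharacterVector ys,
                                 IntegerMatrix lut, int gap_open, int gap_extend) {
  IntegerMatrix out(xs.size(), ys.size());
  for (int i = 0; i < xs.size(); ++i) {
    std::string a = as<std::string>(xs[i]);
    for (int j = 0; j < ys.size(); ++j) {
      std::string b = as<std::string>(ys[j]);
      out(i, j) = sw_score_one(a, b, lut, gap_open, gap_extend);
    }
  }
  return out;
}

// Full DP with traceback.  Tie-breaks in H are resolved diagonal > up
// (gap in subject) > left (gap in query) so one reproducible optimal
// alignment is reported.  Coordinates returned are 1-based inclusive.
//' @noRd
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix lut,
                  int gap_open, int gap_extend) {
  const int m = a.size(), n = b.size();
  // traceback codes for H: 0 stop, 1 diag, 2 up (consume a), 3 left (consume b)
  std::vector<signed char> tbH((m + 1) * (n + 1), 0);
  std::vector<signed char> tbE((m + 1) * (n + 1), 0);  // 1 = extend
  std::vector<signed char> tbF((m + 1) * (n + 1), 0);
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> Ev((m + 1) * (n + 1), NEG_INF);
  std::vector<int> Fv((m + 1) * (n + 1), NEG_INF);
  const int* L = INTEGER(lut);  // column-major 128 x 128
  std::vector<int> brow(n);
  for (int j = 0; j < n; ++j) brow[j] = 128 * ((unsigned char)b[j] & 127);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ai = (unsigned char)a[i - 1] & 127;
    const size_t row = (size_t)i * (n + 1);
    const size_t prow = row - (n + 1);
    for (int j = 1; j <= n; ++j) {
      const size_t id = row + j;
      const size_t up = prow + j;
      const size_t lf = id - 1;
      // "up" gap consumes a[i]: extends vertically
      int e_open = H[up] - gap_open, e_ext = Ev[up] - gap_extend;
      Ev[id] = (e_ext > e_open) ? e_ext : e_open;
      tbE[id] = (e_ext > e_open) ? 1 : 0;
      // "left" gap consumes b[j]: extends horizontally
      int f_open = H[lf] - gap_open, f_ext = Fv[lf] - gap_extend;
      Fv[id] = (f_ext > f_open) ? f_ext : f_open;
      tbF[id] = (f_ext > f_open) ? 1 : 0;
      int d = H[up - 1] + L[ai + brow[j - 1]];
      int h = 0; signed char p = 0;
      if (d > h) { h = d; p = 1; }
      if (Ev[id] > h) { h = Ev[id]; p = 2; }
      if (Fv[id] > h) { h = Fv[id]; p = 3; }
      H[id] = h; tbH[id] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0);
  // traceback
  std::string qa, sa;
  int i = bi, j = bj;
  // state: 0 in H, 1 in E (up-gap run), 2 in F (left-gap run)
  int state = 0;
  while (i > 0 && j > 0) {
    const size_t id = (size_t)i * (n + 1) + j;
    if (state == 0) {
      signed char p = tbH[id];
      if (p == 0) break;
      if (p == 1) { qa += a[i - 1]; sa += b[j - 1]; --i; --j; }
      else if (p == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      qa += a[i - 1]; sa += '-';
      signed char ext = tbE[id];
      --i;
      if (!ext) state = 0;
    } else {
      qa += '-'; sa += b[j - 1];
      signed char ext = tbF[id];
      --j;
      if (!ext) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  int ident = 0;
  for (size_t k = 0; k < qa.size(); ++k)
    if (qa[k] == sa[k] && qa[k] != '-') ++ident;
  return List::create(
    _["score"] = best,
    _["q_start"] = i + 1, _["q_end"] = bi,
    _["s_start"] = j + 1, _["s_end"] = bj,
    _["aligned_query"] = qa, _["aligned_subject"] = sa,
    _["n_ident"] = ident, _["n_cols"] = (int)qa.size());
}

// Count mismatches of a primer laid on the template at each feasible
// offset; returns 0-based offsets where mismatches <= max_mm and the last
// three_prime_exact bases match exactly.  N in the template never matches.
//' @noRd
// [[Rcpp::export]]
IntegerVector primer_sites_cpp(std::string tmpl, std::string primer,
                               int max_mm, int three_prime_exact) {
  const int L = tmpl.size(), P = primer.size();
  std::vector<int> hits;
  for (int off = 0; off + P <= L; ++off) {
    int mm = 0; bool ok = true;
    for (int k = 0; k < P; ++k) {
      char t = tmpl[off + k], p = primer[k];
      bool match = (t == p) && t != 'N';
      if (!match) {
        if (k >= P - three_prime_exact) { ok = false; break; }
        if (++mm > max_mm) { ok = false; break; }
      }
    }
    if (ok) hits.push_back(off);
  }
  return wrap(hits);
}
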