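#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// Gap convention: the first base of a gap costs `gap_open`, each further
// base `gap_ext` (so a gap of length g costs gap_open + (g-1)*gap_ext).
// Costs are passed as positive magnitudes.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap_open = 2.0, double gap_ext = 1.0) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("sw_align: empty sequence");
  const double NEG = -1e18;
  // H: best ending in match/mismatch or any state; E: gap in a (consume b); F: gap in b
  std::vector<std::vector<double>> H(m + 1, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<double>> E(m + 1, std::vector<double>(n + 1, NEG));
  std::vector<std::vector<double>> F(m + 1, std::vector<double>(n + 1, NEG));
  // traceback pointers: for H 0=stop,1=diag,2=E,3=F; for E/F 1=open(from H),2=extend
  std::vector<std::vector<unsigned char>> pH(m + 1, std::vector<unsigned char>(n + 1, 0));
  std::vector<std::vector<unsigned char>> pE(m + 1, std::vector<unsigned char>(n + 1, 0));
  std::vector<std::vector<unsigned char>> pF(m + 1, std::vector<unsigned char>(n + 1, 0));
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double eo = H[i][j - 1] - gap_open, ee = E[i][j - 1] - gap_ext;
      E[i][j] = (eo >= ee) ? eo : ee;
      pE[i][j] = (eo >= ee) ? 1 : 2;
      double fo = H[i - 1][j] - gap_open, fe = F[i - 1][j] - gap_ext;
      F[i][j] = (fo >= fe) ? fo : fe;
      pF[i][j] = (fo >= fe) ? 1 : 2;
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double diag = H[i - 1][j - 1] + s;
      double h = 0.0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E[i][j] > h) { h = E[i][j]; p = 2; }
      if (F[i][j] > h) { h = F[i][j]; p = 3; }
      H[i][j] = h; pH[i][j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback from the best cell
  int matches = 0, cols = 0;
  int i = bi, j = bj;
  int a_end = bi, b_end = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      unsigned char p = pH[i][j];
      if (p == 0) break;
      if (p == 1) {
        ++cols;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (p == 2) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      ++cols;
      unsigned char p = pE[i][j];
      --j;
      if (p == 1) state = 'H';
    } else { // F
      ++cols;
      unsigned char p = pF[i][j];
      --i;
      if (p == 1) state = 'H';
    }
  }
  double identity = cols > 0 ? (double)matches / (double)cols : 0.0;
  return List::create(
    _["score"] = best,
    _["identity"] = identity,
    _["aln_len"] = cols,
    _["a_start"] = i, _["a_end"] = a_end,
    _["b_start"] = j, _["b_end"] = b_end,
    _["matches"] = matches);
}

// batch scoring used by reciprocal_best_hits: aligns paired vectors
// [[Rcpp::export(name = ".sw_align_batch_cpp")]]
DataFrame sw_align_batch_cpp(CharacterVector a, CharacterVector b,
                             double match = 1.0, double mismatch = -1.0,
                             double gap_open = 2.0, double gap_ext = 1.0) {
  const int n = a.size();
  if (b.size() != n) stop("sw_align_batch: length mismatch");
  NumericVector score(n), identity(n);
  IntegerVector aln_len(n);
  for (int k = 0; k < n; ++k) {
    List r = sw_align_cpp(as<std::string>(a[k]), as<std::string>(b[k]),
                          match, mismatch, gap_open, gap_ext);
    score[k] = as<double>(r["score"]);
    identity[k] = as<double>(r["identity"]);
    aln_len[k] = as<int>(r["aln_len"]);
  }
  return DataFrame::create(_["score"] = score, _["identity"] = identity,
                           _["aln_len"] = aln_len);
}
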