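#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Global pairwise alignment (Gotoh three-state DP) with affine gaps.
// A gap of length L costs gap_open + (L - 1) * gap_extend.
// States: M = last column was a substitution/match,
//         X = last column consumed a ref base against a gap in alt ("up"),
//         Y = last column consumed an alt base against a gap in ref ("left").
// Tie-breaking everywhere prefers M over X over Y, so the traceback prefers
// diagonal over up over left and the output is deterministic.
// [[Rcpp::export]]
List nw_align_cpp(std::string ref, std::string alt,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int)ref.size();
  const int m = (int)alt.size();
  const size_t w = (size_t)m + 1;
  auto at = [w](int i, int j) { return (size_t)i * w + (size_t)j; };

  std::vector<double> M((size_t)(n + 1) * w, NEG_INF);
  std::vector<double> X((size_t)(n + 1) * w, NEG_INF);
  std::vector<double> Y((size_t)(n + 1) * w, NEG_INF);
  // predecessor state codes: 0 = M, 1 = X, 2 = Y
  std::vector<unsigned char> tbM((size_t)(n + 1) * w, 0);
  std::vector<unsigned char> tbX((size_t)(n + 1) * w, 0);
  std::vector<unsigned char> tbY((size_t)(n + 1) * w, 0);

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // X: consume ref[i-1] against a gap
      {
        double fm = M[at(i - 1, j)] + gap_open;
        double fx = X[at(i - 1, j)] + gap_extend;
        double fy = Y[at(i - 1, j)] + gap_open;
        double best = fm;
        unsigned char st = 0;
        if (fx > best) { best = fx; st = 1; }
        if (fy > best) { best = fy; st = 2; }
        X[at(i, j)] = best;
        tbX[at(i, j)] = st;
      }
      // Y: consume alt[j-1] against a gap
      {
        double fm = M[at(i, j - 1)] + gap_open;
        double fx = X[at(i, j - 1)] + gap_open;
        double fy = Y[at(i, j - 1)] + gap_extend;
        double best = fm;
        unsigned char st = 0;
        if (fx > best) { best = fx; st = 1; }
        if (fy > best) { best = fy; st = 2; }
        Y[at(i, j)] = best;
        tbY[at(i, j)] = st;
      }
      // M: substitution column
      {
        double s = (ref[i - 1] == alt[j - 1]) ? match : mismatch;
        double fm = M[at(i - 1, j - 1)];
        double fx = X[at(i - 1, j - 1)];
        double fy = Y[at(i - 1, j - 1)];
        double best = fm;
        unsigned char st = 0;
        if (fx > best) { best = fx; st = 1; }
        if (fy > best) { best = fy; st = 2; }
        M[at(i, j)] = best + s;
        tbM[at(i, j)] = st;
      }
    }
  }

  double best = M[at(n, m)];
  unsigned char state = 0;
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }

  std::string ra, aa;
  ra.reserve(n + m);
  aa.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = tbM[at(i, j)];
      ra.push_back(ref[i - 1]);
      aa.push_back(alt[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      unsigned char prev = tbX[at(i, j)];
      ra.push_back(ref[i - 1]);
      aa.push_back('-');
      --i;
      state = prev;
    } else {
      unsigned char prev = tbY[at(i, j)];
      ra.push_back('-');
      aa.push_back(alt[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(aa.begin(), aa.end());

  return List::create(_["ref_aln"] = ra, _["alt_aln"] = aa, _["score"] = best);
}

// Exhaustive enumeration of every global alignment (monotone lattice path),
// tracking the previous column type so affine gap runs are costed exactly.
// No dynamic programming and no memoisation: this is the independent oracle
// for small inputs, exponential on purpose.
static double enum_best(const std::string &a, const std::string &b,
                        int i, int j, int last,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (i == n && j == m) return 0.0;
  double best = NEG_INF;
  if (i < n && j < m) {
    double s = (a[i] == b[j]) ? match : mismatch;
    double rest = enum_best(a, b, i + 1, j + 1, 0, match, mismatch, gap_open, gap_extend);
    if (s + rest > best) best = s + rest;
  }
  if (i < n) {
    double s = (last == 1) ? gap_extend : gap_open;
    double rest = enum_best(a, b, i + 1, j, 1, match, mismatch, gap_open, gap_extend);
    if (s + rest > best) best = s + rest;
  }
  if (j < m) {
    double s = (last == 2) ? gap_extend : gap_open;
    double rest = enum_best(a, b, i, j + 1, 2, match, mismatch, gap_open, gap_extend);
    if (s + rest > best) best = s + rest;
  }
  return best;
}

// [[Rcpp::export]]
double nw_enum_score_cpp(std::string ref, std::string alt,
                         double match, double mismatch,
                         double gap_open, double gap_extend) {
  if (ref.size() > 14 || alt.size() > 14)
    stop("enumeration oracle is restricted to sequences of length <= 14");
  return enum_best(ref, alt, 0, 0, -1, match, mismatch, gap_open, gap_extend);
}
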