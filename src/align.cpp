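#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// A gap of length k costs gap_open + k * gap_extend (penalties passed as
// negative numbers).  Ties are broken deterministically: diagonal (match
// state) is preferred over up (gap in b) over left (gap in a), both when
// choosing the predecessor of each state and at the final cell.

// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // predecessor state: 0 = M, 1 = X, 2 = Y, -1 = origin
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
      tY((n + 1) * W, -1);
  auto at = [W](int i, int j) { return i * W + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + i * gap_extend;
    tX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + j * gap_extend;
    tY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M from (i-1, j-1); strict > keeps earlier (preferred) state on tie
      {
        double best = M[at(i - 1, j - 1)];
        signed char st = 0;
        if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; st = 1; }
        if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; st = 2; }
        M[at(i, j)] = best + s;
        tM[at(i, j)] = st;
      }
      // X (gap in b, consume a) from (i-1, j)
      {
        double best = M[at(i - 1, j)] + gap_open + gap_extend;
        signed char st = 0;
        double v = X[at(i - 1, j)] + gap_extend;
        if (v > best) { best = v; st = 1; }
        v = Y[at(i - 1, j)] + gap_open + gap_extend;
        if (v > best) { best = v; st = 2; }
        X[at(i, j)] = best;
        tX[at(i, j)] = st;
      }
      // Y (gap in a, consume b) from (i, j-1)
      {
        double best = M[at(i, j - 1)] + gap_open + gap_extend;
        signed char st = 0;
        double v = X[at(i, j - 1)] + gap_open + gap_extend;
        if (v > best) { best = v; st = 1; }
        v = Y[at(i, j - 1)] + gap_extend;
        if (v > best) { best = v; st = 2; }
        Y[at(i, j)] = best;
        tY[at(i, j)] = st;
      }
    }
  }

  signed char s = 0;
  double score = M[at(n, m)];
  if (X[at(n, m)] > score) { score = X[at(n, m)]; s = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; s = 2; }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (s == 0) {
      signed char prev = tM[at(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
      s = prev;
    } else if (s == 1) {
      signed char prev = tX[at(i, j)];
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
      s = prev;
    } else {
      signed char prev = tY[at(i, j)];
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
      s = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}
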