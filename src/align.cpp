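#include <Rcpp.h>
#include <cstring>
#include <limits>
#include <vector>

using namespace Rcpp;

// Affine-gap (Gotoh) global alignment over arbitrary character strings.
// Gap of length L costs gap_open + (L - 1) * gap_extend (first gapped column
// pays gap_open). Three-state DP with full traceback; deterministic
// tie-breaking: match/mismatch state preferred over gap-in-b (char of a over
// '-') over gap-in-a ('-' over char of b), both when choosing the final state
// and within each state's predecessor.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a)

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  // rolling score rows, full byte traceback
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  // tb[i*(m+1)+j]: bits 0-1 pred-state of M, 2-3 of X, 4-5 of Y
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);

  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF; Xprev[j] = NEG_INF;
    Yprev[j] = (j == 1) ? gap_open : Yprev[j - 1] + gap_extend;
    tb[j] |= (unsigned char)((j == 1 ? 0 : 2) << 4);
  }
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * (m + 1);
    Mcur[0] = NEG_INF; Ycur[0] = NEG_INF;
    Xcur[0] = (i == 1) ? gap_open : Xprev[0] + gap_extend;
    tb[row] |= (unsigned char)((i == 1 ? 0 : 1) << 2);
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M from best of (M, X, Y)[i-1][j-1], prefer M > X > Y
      double mm = Mprev[j - 1], mx = Xprev[j - 1], my = Yprev[j - 1];
      int pm = 0; double best = mm;
      if (mx > best) { best = mx; pm = 1; }
      if (my > best) { best = my; pm = 2; }
      Mcur[j] = best + s;
      // X (consume a_i): from row i-1, same j
      double xm = Mprev[j] + gap_open, xx = Xprev[j] + gap_extend,
             xy = Yprev[j] + gap_open;
      int px = 0; best = xm;
      if (xx > best) { best = xx; px = 1; }
      if (xy > best) { best = xy; px = 2; }
      Xcur[j] = best;
      // Y (consume b_j): from same row i, j-1
      double ym = Mcur[j - 1] + gap_open, yx = Xcur[j - 1] + gap_open,
             yy = Ycur[j - 1] + gap_extend;
      int py = 0; best = ym;
      if (yx > best) { best = yx; py = 1; }
      if (yy > best) { best = yy; py = 2; }
      Ycur[j] = best;
      tb[row + j] = (unsigned char)(pm | (px << 2) | (py << 4));
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  double sM = Mprev[m], sX = Xprev[m], sY = Yprev[m];
  int state = 0; double score = sM;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = t & 3; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = (t >> 2) & 3; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = (t >> 4) & 3; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}

// Score-only variant (same DP, no traceback) for bulk homology scoring.
// [[Rcpp::export(name = ".gotoh_score")]]
double gotoh_score(std::string a, std::string b,
                   double match, double mismatch,
                   double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF; Xprev[j] = NEG_INF;
    Yprev[j] = (j == 1) ? gap_open : Yprev[j - 1] + gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG_INF; Ycur[0] = NEG_INF;
    Xcur[0] = (i == 1) ? gap_open : Xprev[0] + gap_extend;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double d = std::max(Mprev[j - 1], std::max(Xprev[j - 1], Yprev[j - 1]));
      Mcur[j] = d + s;
      Xcur[j] = std::max(Mprev[j] + gap_open,
                std::max(Xprev[j] + gap_extend, Yprev[j] + gap_open));
      Ycur[j] = std::max(Mcur[j - 1] + gap_open,
                std::max(Xcur[j - 1] + gap_open, Ycur[j - 1] + gap_extend));
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  return std::max(Mprev[m], std::max(Xprev[m], Yprev[m]));
}
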