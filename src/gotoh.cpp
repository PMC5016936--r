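#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state DP) over {A,C,G,T,N}.
// A gap of length k costs |gap_open| + k * |gap_extend|; N matches any base
// at score 0.  Deterministic tie-breaking: diagonal (match/mismatch) is
// preferred over a gap in the query (reference consumed), which is preferred
// over a gap in the reference.
//
// An optional diagonal band restricts query offsets j - i to
// [band_low, band_high]; the full DP corresponds to [-n, m].  The band is a
// speed device for reference projection, where the optimal path's offset is
// bracketed by the net length difference plus a margin.
//
// Traceback is one byte per cell: bits 0-1 predecessor state of M,
// bits 2-3 of X (gap in query), bits 4-5 of Y (gap in reference).

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string qry,
                 double match, double mismatch,
                 double gap_open, double gap_extend,
                 int band_low, int band_high) {
  const int n = (int) ref.size();   // rows: reference
  const int m = (int) qry.size();   // cols: query
  const double go = -std::abs(gap_open);
  const double ge = -std::abs(gap_extend);
  if (band_low > 0) band_low = 0;
  if (band_high < m - n) band_high = m - n;   // end cell must be reachable

  std::vector<double> Mprev(m + 2, NEG_INF), Xprev(m + 2, NEG_INF),
      Yprev(m + 2, NEG_INF);
  std::vector<double> Mcur(m + 2, NEG_INF), Xcur(m + 2, NEG_INF),
      Ycur(m + 2, NEG_INF);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);

  Mprev[0] = 0.0;
  {
    const int jhi0 = std::min(m, band_high);
    for (int j = 1; j <= jhi0; ++j) {
      Yprev[j] = go + ge * j;
      tb[j] |= (uint8_t)((j == 1 ? 0 : 2) << 4);
    }
  }

  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(1, i + band_low);
    const int jhi = std::min(m, i + band_high);
    if (jlo > jhi) stop("empty alignment band");
    // cells bordering the band are unreachable
    Mcur[jlo - 1] = Xcur[jlo - 1] = Ycur[jlo - 1] = NEG_INF;
    if (jhi < m) Mcur[jhi + 1] = Xcur[jhi + 1] = Ycur[jhi + 1] = NEG_INF;
    if (jlo == 1) {
      Xcur[0] = go + ge * i;
      Mcur[0] = Ycur[0] = NEG_INF;
      tb[(size_t)i * (m + 1)] |= (uint8_t)((i == 1 ? 0 : 1) << 2);
    }
    const char rc = ref[i - 1];
    const bool rN = (rc == 'N');
    uint8_t *tbrow = &tb[(size_t)i * (m + 1)];
    double mdiag = Mprev[jlo - 1], xdiag = Xprev[jlo - 1],
           ydiag = Yprev[jlo - 1];
    double mleft = Mcur[jlo - 1], xleft = Xcur[jlo - 1], yleft = Ycur[jlo - 1];
    for (int j = jlo; j <= jhi; ++j) {
      const char qc = qry[j - 1];
      const double s = (rN || qc == 'N') ? 0.0 : (rc == qc ? match : mismatch);
      const double mup = Mprev[j], xup = Xprev[j], yup = Yprev[j];
      uint8_t cell = 0;
      // M: diagonal predecessors, preference M > X > Y
      double best = mdiag; uint8_t from = 0;
      if (xdiag > best) { best = xdiag; from = 1; }
      if (ydiag > best) { best = ydiag; from = 2; }
      const double Mv = best + s;
      cell |= from;
      // X: gap in query (consume reference base i)
      double xo = mup + go + ge; uint8_t xf = 0;
      if (xup + ge > xo) { xo = xup + ge; xf = 1; }
      if (yup + go + ge > xo) { xo = yup + go + ge; xf = 2; }
      cell |= (uint8_t)(xf << 2);
      // Y: gap in reference (consume query base j)
      double yo = mleft + go + ge; uint8_t yf = 0;
      if (xleft + go + ge > yo) { yo = xleft + go + ge; yf = 1; }
      if (yleft + ge > yo) { yo = yleft + ge; yf = 2; }
      cell |= (uint8_t)(yf << 4);
      Mcur[j] = Mv; Xcur[j] = xo; Ycur[j] = yo;
      tbrow[j] = cell;
      mdiag = mup; xdiag = xup; ydiag = yup;
      mleft = Mv; xleft = xo; yleft = yo;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  double score = Mprev[m]; int state = 0;
  if (Xprev[m] > score) { score = Xprev[m]; state = 1; }
  if (Yprev[m] > score) { score = Yprev[m]; state = 2; }
  if (score <= NEG_INF / 2) stop("alignment band excludes the end cell");

  std::string ra, qa;
  ra.reserve(n + m); qa.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const uint8_t cell = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      const uint8_t from = cell & 3;
      ra.push_back(ref[i - 1]); qa.push_back(qry[j - 1]);
      --i; --j; state = from;
    } else if (state == 1) {
      const uint8_t from = (cell >> 2) & 3;
      ra.push_back(ref[i - 1]); qa.push_back('-');
      --i; state = from;
    } else {
      const uint8_t from = (cell >> 4) & 3;
      ra.push_back('-'); qa.push_back(qry[j - 1]);
      --j; state = from;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  return List::create(_["ref_aligned"] = ra, _["qry_aligned"] = qa,
                      _["score"] = score);
}
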