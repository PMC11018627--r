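#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps.
// A gap run of length L costs open + L * ext.
// Three-state DP: M (residue-residue), U (query residue over gap, "up"),
// L (gap over reference residue, "left"). Transitions between the two gap
// states re-open (pay open + ext), so every maximal gap run pays exactly
// open + L * ext regardless of its neighbours.
//
// The forward pass keeps only two rows of scores and records packed
// traceback pointers (2 bits per state per cell), so memory traffic stays
// low even for ~1000-residue chains. Traceback tie-break is fixed as
// diagonal > up > left (state preference M > U > L) for determinism.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string query, std::string ref,
                  NumericVector submat, double gap_open, double gap_ext) {
  const int n = query.size();   // rows: query
  const int m = ref.size();     // cols: reference
  const double oe = gap_open + gap_ext;

  std::vector<int> qc(n), rc(m);
  for (int i = 0; i < n; ++i) qc[i] = query[i] - 'A';
  for (int j = 0; j < m; ++j) rc[j] = ref[j] - 'A';
  const double* S = REAL(submat);

  // tb[i*(m+1)+j]: bits 0-1 predecessor state of M, 2-3 of U, 4-5 of L
  // (0 = M, 1 = U, 2 = L)
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  std::vector<double> M0(m + 1), U0(m + 1), L0(m + 1),
      M1(m + 1), U1(m + 1), L1(m + 1);

  // row 0
  M0[0] = 0.0; U0[0] = L0[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M0[j] = U0[j] = NEG_INF;
    L0[j] = -(gap_open + j * gap_ext);
    tb[j] |= (uint8_t)((j == 1 ? 0 : 2) << 4);  // L from M at j=1, else L
  }

  std::vector<double> sbuf(m);
  for (int i = 1; i <= n; ++i) {
    uint8_t* tbrow = &tb[(size_t)i * (m + 1)];
    const double* srow = S + qc[i - 1];
    for (int j = 0; j < m; ++j) sbuf[j] = srow[26 * rc[j]];

    M1[0] = L1[0] = NEG_INF;
    U1[0] = -(gap_open + i * gap_ext);
    tbrow[0] = (uint8_t)((i == 1 ? 0 : 1) << 2);  // U from M at i=1, else U

    for (int j = 1; j <= m; ++j) {
      // M: diagonal predecessors, prefer M > U > L on ties
      double best = M0[j - 1];
      int pm = 0;
      if (U0[j - 1] > best) { best = U0[j - 1]; pm = 1; }
      if (L0[j - 1] > best) { best = L0[j - 1]; pm = 2; }
      M1[j] = best + sbuf[j - 1];

      // U: consume query residue (from row above)
      double u = M0[j] - oe;
      int pu = 0;
      if (U0[j] - gap_ext > u) { u = U0[j] - gap_ext; pu = 1; }
      if (L0[j] - oe > u) { u = L0[j] - oe; pu = 2; }
      U1[j] = u;

      // L: consume reference residue (from the left)
      double l = M1[j - 1] - oe;
      int pl = 0;
      if (U1[j - 1] - oe > l) { l = U1[j - 1] - oe; pl = 1; }
      if (L1[j - 1] - gap_ext > l) { l = L1[j - 1] - gap_ext; pl = 2; }
      L1[j] = l;

      tbrow[j] = (uint8_t)(pm | (pu << 2) | (pl << 4));
    }
    M0.swap(M1); U0.swap(U1); L0.swap(L1);
  }

  // final state: prefer M > U > L on ties (diagonal > up > left)
  double score = M0[m];
  int state = 0;
  if (U0[m] > score) { score = U0[m]; state = 1; }
  if (L0[m] > score) { score = L0[m]; state = 2; }

  IntegerVector cmap(m, 0);  // reference position -> query position, 0 = gap
  std::string aq, ar;        // aligned strings, built backwards
  aq.reserve(n + m); ar.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    const uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {            // residue-residue column
      cmap[j - 1] = i;
      aq.push_back(query[i - 1]); ar.push_back(ref[j - 1]);
      state = t & 3;
      --i; --j;
    } else if (state == 1) {     // query residue over gap
      aq.push_back(query[i - 1]); ar.push_back('-');
      state = (t >> 2) & 3;
      --i;
    } else {                     // gap over reference residue
      aq.push_back('-'); ar.push_back(ref[j - 1]);
      state = (t >> 4) & 3;
      --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  return List::create(_["score"] = score, _["column_map"] = cmap,
                      _["aligned_query"] = aq, _["aligned_ref"] = ar);
}
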