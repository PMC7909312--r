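#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) DP over a precomputed column-column score
// matrix S (n x m), linear gap penalty. Traceback tie-break: diagonal,
// then up (gap in the second sequence), then left. Returns the optimal
// score and the aligned index paths (1-based positions, 0 = gap).
// Used both for residue-level pairwise alignment (S from an outer
// match/mismatch comparison) and for profile-profile merges in the
// progressive MSA (S = expected pair score between columns).
// [[Rcpp::export(name = ".nw_dp")]]
List nw_dp(NumericMatrix S, double gap) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix F(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) F(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) F(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = F(i - 1, j - 1) + S(i - 1, j - 1);
      double u = F(i - 1, j) + gap;
      double l = F(i, j - 1) + gap;
      F(i, j) = std::max(d, std::max(u, l));
    }
  }
  std::vector<int> ai, bi;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(F(i, j) - (F(i - 1, j - 1) + S(i - 1, j - 1))) < eps) {
      ai.push_back(i); bi.push_back(j); --i; --j;
    } else if (i > 0 && std::abs(F(i, j) - (F(i - 1, j) + gap)) < eps) {
      ai.push_back(i); bi.push_back(0); --i;
    } else {
      ai.push_back(0); bi.push_back(j); --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = F(n, m),
                      _["ai"] = wrap(ai), _["bi"] = wrap(bi));
}

// Spliced-mapping DP for exact exon chains. cds and gen are integer-coded
// bases (1-based values irrelevant, only equality is used). donor_ok[j]
// (1-based genomic position j) says an intron STARTING at j begins with
// "GT"; acc_ok[j] says an intron ENDING at j ends with "AG".
//
// F(i, j) = minimal cost of mapping cds[1..i] with cds[i] placed at
// genomic position j, where each intron costs BIG and each non-GT..AG
// intron costs an extra 1. Infeasible cells are +Inf. An intron between
// an exon ending at genomic j' and the next exon starting at j spans
// j'+1 .. j-1 (length >= 1, so j' <= j - 2).
// The matrix is stored transposed (genomic position j in rows, CDS
// position i in columns) so the j-sweep for each CDS position runs down
// contiguous memory.
// [[Rcpp::export(name = ".spliced_cost")]]
NumericMatrix spliced_cost(IntegerVector cds, IntegerVector gen,
                           IntegerVector donor_ok, IntegerVector acc_ok,
                           double BIG) {
  int n = cds.size(), m = gen.size();
  const double INF = R_PosInf;
  NumericMatrix F(m, n); // F(j, i)
  double *cur = REAL(F), *prev = nullptr;
  for (int j = 0; j < m; ++j)
    cur[j] = (cds[0] == gen[j]) ? 0.0 : INF;
  for (int i = 1; i < n; ++i) {
    prev = REAL(F) + (R_xlen_t)(i - 1) * m;
    cur = REAL(F) + (R_xlen_t)i * m;
    // prefix minima over the previous column: all donors, and GT donors
    // (donor position is j' + 1 for an exon ending at j').
    double mAll = INF, mGT = INF;
    for (int j = 0; j < m; ++j) {
      if (j >= 2) { // exon may end at j' = j - 2 (0-based), intron len >= 1
        int jp = j - 2;
        double v = prev[jp];
        if (v < mAll) mAll = v;
        if (jp + 1 < m && donor_ok[jp + 1] == 1 && v < mGT) mGT = v;
      }
      if (cds[i] != gen[j]) { cur[j] = INF; continue; }
      double best = (j >= 1) ? prev[j - 1] : INF; // same exon
      double viaIntron = INF;
      if (mAll < INF) {
        bool accAG = (j >= 1 && acc_ok[j - 1] == 1);
        viaIntron = mAll + BIG + 1.0;
        if (accAG && mGT < INF) {
          double cCan = mGT + BIG;
          if (cCan < viaIntron) viaIntron = cCan;
        }
      }
      cur[j] = std::min(best, viaIntron);
    }
  }
  return F;
}
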