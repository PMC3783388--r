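#include <Rcpp.h>
using namespace Rcpp;

// Alignment kernels shared by the profile scanner, the pairwise aligners and
// the progressive aligner.  Peptides arrive as 0-based integer codes:
// 0..19 = amino acids in alphabet order, 20 = '*' (stop), 21 = 'X' (ambiguous).
// Gap model everywhere: a gap of length g costs gap_open + g * gap_extend
// (both supplied as negative numbers).

static const double NEG_INF = -1e30;

// Emission score of peptide code `c` against profile column `j`.
// Stops carry a fixed penalty; X is neutral by design so ambiguity from
// N-containing codons neither creates nor destroys hits.
static inline double emit_score(const NumericMatrix &pssm, int c, int j,
                                double stop_pen) {
  if (c == 20) return stop_pen;
  if (c == 21) return 0.0;
  return pssm(c, j);
}

// Smith-Waterman of a peptide against a position score matrix with affine
// gaps, reporting all non-overlapping local optima with score >= threshold,
// greedily from the best score with aligned-region masking (the matched
// peptide stretch is blanked and the DP re-run).
// Returns a matrix with one row per hit:
//   pep_start, pep_end (0-based half-open), score, aligned_cols,
//   prof_start, prof_end (0-based half-open)
// [[Rcpp::export]]
NumericMatrix cpp_pssm_scan(IntegerVector pep, NumericMatrix pssm,
                            double gap_open, double gap_extend,
                            double stop_pen, double threshold) {
  const int n = pep.size();
  const int m = pssm.ncol();
  std::vector<bool> masked(n, false);
  std::vector<std::array<double, 6> > hits;

  if (n == 0 || m == 0) return NumericMatrix(0, 6);

  // traceback codes: 0 none, 1 diag(H), 2 from E, 3 from F
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0); // 1 open,0 extend
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  std::vector<double> H((size_t)(n + 1) * (m + 1));
  std::vector<double> E((size_t)(n + 1) * (m + 1));
  std::vector<double> F((size_t)(n + 1) * (m + 1));
  const size_t W = (size_t)m + 1;

  for (;;) {
    // full DP pass with current mask
    for (int j = 0; j <= m; ++j) {
      H[j] = 0.0; E[j] = NEG_INF; F[j] = NEG_INF;
    }
    double best = 0.0; int bi = -1, bj = -1;
    for (int i = 1; i <= n; ++i) {
      H[i * W] = 0.0; E[i * W] = NEG_INF; F[i * W] = NEG_INF;
      const bool mk = masked[i - 1];
      const int c = pep[i - 1];
      for (int j = 1; j <= m; ++j) {
        const size_t here = i * W + j, up = (i - 1) * W + j, left = i * W + j - 1,
                     diag = (i - 1) * W + j - 1;
        // E: gap in peptide (profile column j consumed without a residue)
        double eo = H[left] + gap_open + gap_extend, ee = E[left] + gap_extend;
        if (eo >= ee) { E[here] = eo; tbE[here] = 1; } else { E[here] = ee; tbE[here] = 0; }
        // F: peptide residue consumed against a profile gap
        double fo = H[up] + gap_open + gap_extend, fe = F[up] + gap_extend;
        if (fo >= fe) { F[here] = fo; tbF[here] = 1; } else { F[here] = fe; tbF[here] = 0; }
        if (mk) { F[here] = NEG_INF; }
        // H
        double sc = mk ? NEG_INF : emit_score(pssm, c, j - 1, stop_pen);
        double hd = H[diag] + sc;
        double h = 0.0; unsigned char tb = 0;
        if (hd > h) { h = hd; tb = 1; }
        if (E[here] > h) { h = E[here]; tb = 2; }
        if (F[here] > h) { h = F[here]; tb = 3; }
        H[here] = h; tbH[here] = tb;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best < threshold || bi < 0) break;

    // traceback from (bi, bj)
    int i = bi, j = bj, state = 0; // 0=H,1=E,2=F
    int pep_end = bi, prof_end = bj;
    int aligned = 0;
    while (true) {
      size_t here = (size_t)i * W + j;
      if (state == 0) {
        unsigned char tb = tbH[here];
        if (tb == 0) break;
        if (tb == 1) { ++aligned; --i; --j; }
        else if (tb == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        unsigned char tb = tbE[here];
        --j;
        if (tb == 1) state = 0;
      } else {
        unsigned char tb = tbF[here];
        --i;
        if (tb == 1) state = 0;
      }
    }
    int pep_start = i, prof_start = j; // 0-based starts
    std::array<double, 6> row = {(double)pep_start, (double)pep_end, best,
                                 (double)aligned, (double)prof_start,
                                 (double)prof_end};
    hits.push_back(row);
    for (int k = pep_start; k < pep_end; ++k) masked[k] = true;
    if (pep_end <= pep_start) break; // safety against zero-length masks
  }

  NumericMatrix out(hits.size(), 6);
  for (size_t r = 0; r < hits.size(); ++r)
    for (int cix = 0; cix < 6; ++cix) out(r, cix) = hits[r][cix];
  colnames(out) = CharacterVector::create("pep_start", "pep_end", "score",
                                          "aligned_cols", "prof_start",
                                          "prof_end");
  return out;
}

// Best local (Smith-Waterman) score of a peptide against a PSSM; score only.
// Used for shuffle nulls and motif scoring where no coordinates are needed.
// [[Rcpp::export]]
double cpp_pssm_best_score(IntegerVector pep, NumericMatrix pssm,
                           double gap_open, double gap_extend,
                           double stop_pen) {
  const int n = pep.size(), m = pssm.ncol();
  if (n == 0 || m == 0) return 0.0;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG_INF), F(m + 1, NEG_INF);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diagH = 0.0; // H[i-1][j-1]
    H[0] = 0.0; E[0] = NEG_INF; F[0] = NEG_INF;
    const int c = pep[i - 1];
    for (int j = 1; j <= m; ++j) {
      double upH = H[j];
      E[j] = std::max(H[j - 1] + gap_open + gap_extend, E[j - 1] + gap_extend);
      F[j] = std::max(upH + gap_open + gap_extend, F[j] + gap_extend);
      double h = std::max(0.0, diagH + emit_score(pssm, c, j - 1, stop_pen));
      h = std::max(h, std::max(E[j], F[j]));
      diagH = upH;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// Generic affine-gap alignment over a precomputed position score matrix S
// (rows = sequence/profile 1 positions, cols = sequence/profile 2 positions).
// mode: 0 = global (Needleman-Wunsch), 1 = local (Smith-Waterman).
// Returns list(score, i_start, j_start, ops) where ops is the edit path from
// the start, 0 = diagonal, 1 = row position consumed (gap in 2),
// 2 = column position consumed (gap in 1); starts are 0-based.
// [[Rcpp::export]]
List cpp_align_matrix(NumericMatrix S, double gap_open, double gap_extend,
                      int mode) {
  const int n = S.nrow(), m = S.ncol();
  const size_t W = (size_t)m + 1;
  std::vector<double> H((size_t)(n + 1) * W), E((size_t)(n + 1) * W),
      F((size_t)(n + 1) * W);
  std::vector<unsigned char> tbH((size_t)(n + 1) * W, 0),
      tbE((size_t)(n + 1) * W, 0), tbF((size_t)(n + 1) * W, 0);
  const bool local = (mode == 1);

  H[0] = 0.0; E[0] = NEG_INF; F[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    E[j] = local ? NEG_INF : gap_open + gap_extend * j;
    H[j] = local ? 0.0 : E[j];
    F[j] = NEG_INF;
    tbH[j] = local ? 0 : 2;
    tbE[j] = (j == 1) ? 1 : 0;
  }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    size_t r0 = (size_t)i * W;
    F[r0] = local ? NEG_INF : gap_open + gap_extend * i;
    H[r0] = local ? 0.0 : F[r0];
    E[r0] = NEG_INF;
    tbH[r0] = local ? 0 : 3;
    tbF[r0] = (i == 1) ? 1 : 0;
    for (int j = 1; j <= m; ++j) {
      size_t here = r0 + j, up = here - W, left = here - 1, diag = up - 1;
      double eo = H[left] + gap_open + gap_extend, ee = E[left] + gap_extend;
      if (eo >= ee) { E[here] = eo; tbE[here] = 1; } else { E[here] = ee; tbE[here] = 0; }
      double fo = H[up] + gap_open + gap_extend, fe = F[up] + gap_extend;
      if (fo >= fe) { F[here] = fo; tbF[here] = 1; } else { F[here] = fe; tbF[here] = 0; }
      double hd = H[diag] + S(i - 1, j - 1);
      double h = hd; unsigned char tb = 1;
      if (E[here] > h) { h = E[here]; tb = 2; }
      if (F[here] > h) { h = F[here]; tb = 3; }
      if (local && 0.0 >= h) { h = 0.0; tb = 0; }
      H[here] = h; tbH[here] = tb;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (!local) { best = H[(size_t)n * W + m]; bi = n; bj = m; }

  // traceback
  std::vector<int> ops;
  int i = bi, j = bj, state = 0;
  while (true) {
    size_t here = (size_t)i * W + j;
    if (state == 0) {
      unsigned char tb = tbH[here];
      if (local && tb == 0) break;
      if (!local && i == 0 && j == 0) break;
      if (tb == 1) { ops.push_back(0); --i; --j; }
      else if (tb == 2) state = 1;
      else if (tb == 3) state = 2;
      else break;
    } else if (state == 1) {
      unsigned char tb = tbE[here];
      ops.push_back(2); --j;
      if (tb == 1) state = 0;
    } else {
      unsigned char tb = tbF[here];
      ops.push_back(1); --i;
      if (tb == 1) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["i_start"] = i, _["j_start"] = j,
                      _["ops"] = wrap(ops));
}

// Score-only global/local alignment over a score matrix (linear memory).
// [[Rcpp::export]]
double cpp_align_score(NumericMatrix S, double gap_open, double gap_extend,
                       int mode) {
  const int n = S.nrow(), m = S.ncol();
  const bool local = (mode == 1);
  std::vector<double> H(m + 1), E(m + 1), F(m + 1, NEG_INF);
  H[0] = 0.0; E[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    E[j] = local ? NEG_INF : gap_open + gap_extend * j;
    H[j] = local ? 0.0 : E[j];
    F[j] = NEG_INF;
  }
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diagH = H[0];
    H[0] = local ? 0.0 : gap_open + gap_extend * i;
    F[0] = local ? NEG_INF : H[0];
    E[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double upH = H[j];
      E[j] = std::max(H[j - 1] + gap_open + gap_extend, E[j - 1] + gap_extend);
      F[j] = std::max(upH + gap_open + gap_extend, F[j] + gap_extend);
      double h = diagH + S(i - 1, j - 1);
      h = std::max(h, std::max(E[j], F[j]));
      if (local) h = std::max(h, 0.0);
      diagH = upH;
      H[j] = h;
      if (local && h > best) best = h;
    }
  }
  return local ? best : H[m];
}
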