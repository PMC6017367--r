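#include <Rcpp.h>
using namespace Rcpp;

// Alignment kernels shared by the profile scanner and the pairwise
// similarity/identity routines. Sequences arrive as 0-based integer
// vectors indexing the 20-letter amino-acid alphabet; -1 marks an
// unknown residue (scored as the column minimum so it never creates
// spurious matches).

static inline double col_score(const NumericMatrix& prof, int col, int aa) {
  if (aa < 0) {
    double m = prof(0, col);
    for (int r = 1; r < prof.nrow(); ++r) m = std::min(m, prof(r, col));
    return m;
  }
  return prof(aa, col);
}

// Affine-gap local alignment of a sequence against a position-specific
// scoring matrix (20 x W, bit scores). Returns the best score, the spans
// on target and profile (1-based inclusive) and, when traceback is on,
// the matched (profile column, target position) pairs.
// [[Rcpp::export(name = ".profile_sw")]]
List profile_sw(IntegerVector seq, NumericMatrix prof,
                double gap_open, double gap_extend, bool traceback) {
  const int n = seq.size();        // target length
  const int W = prof.ncol();       // profile length
  const double NEG = -1e30;

  // H: match state, E: gap in profile (consume target), F: gap in target
  std::vector<double> Hprev(W + 1, 0.0), Hcur(W + 1, 0.0);
  std::vector<double> Eprev(W + 1, NEG), Ecur(W + 1, NEG);
  std::vector<double> Fcur(W + 1, NEG);

  // traceback pointers: 0 none, 1 diag(H), 2 from E, 3 from F
  // for E: 0 open (from H), 1 extend; same for F
  std::vector<unsigned char> ptrH, ptrE, ptrF;
  if (traceback) {
    ptrH.assign((size_t)(n + 1) * (W + 1), 0);
    ptrE.assign((size_t)(n + 1) * (W + 1), 0);
    ptrF.assign((size_t)(n + 1) * (W + 1), 0);
  }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= W; ++j) {
      const size_t at = (size_t)i * (W + 1) + j;
      // E: gap in profile (target residue i unaligned), vertical move
      double eOpen = Hprev[j] - gap_open, eExt = Eprev[j] - gap_extend;
      Ecur[j] = std::max(eOpen, eExt);
      if (traceback) ptrE[at] = (eExt > eOpen) ? 1 : 0;
      // F: gap in target (profile column j skipped), horizontal move
      double fOpen = Hcur[j - 1] - gap_open, fExt = Fcur[j - 1] - gap_extend;
      Fcur[j] = std::max(fOpen, fExt);
      if (traceback) ptrF[at] = (fExt > fOpen) ? 1 : 0;
      // H: align target i to column j
      double diag = Hprev[j - 1] + col_score(prof, j - 1, seq[i - 1]);
      double h = 0.0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; p = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; p = 3; }
      Hcur[j] = h;
      if (traceback) ptrH[at] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
  }

  int tstart = 0, tend = 0, pstart = 0, pend = 0;
  IntegerMatrix pairs(0, 2);
  if (traceback && best > 0) {
    std::vector<int> pc, tp;
    int i = bi, j = bj, state = 1; // start in H
    tend = bi; pend = bj;
    while (i > 0 && j > 0) {
      const size_t at = (size_t)i * (W + 1) + j;
      if (state == 1) {
        unsigned char p = ptrH[at];
        if (p == 0) break;
        if (p == 1) { pc.push_back(j); tp.push_back(i); --i; --j; }
        else if (p == 2) state = 2;
        else state = 3;
      } else if (state == 2) {
        unsigned char p = ptrE[at];
        --i;
        state = (p == 1) ? 2 : 1;
      } else {
        unsigned char p = ptrF[at];
        --j;
        state = (p == 1) ? 3 : 1;
      }
    }
    tstart = i + 1; pstart = j + 1;
    const int m = pc.size();
    pairs = IntegerMatrix(m, 2);
    for (int k = 0; k < m; ++k) { // reverse into 5'->3' order
      pairs(k, 0) = pc[m - 1 - k];
      pairs(k, 1) = tp[m - 1 - k];
    }
  } else if (best > 0) {
    tend = bi; pend = bj; // spans unknown without traceback
  }

  return List::create(_["score"] = best,
                      _["t_start"] = tstart, _["t_end"] = tend,
                      _["p_start"] = pstart, _["p_end"] = pend,
                      _["pairs"] = pairs);
}

// Scores only, for many sequences (E-value calibration hot loop).
// [[Rcpp::export(name = ".profile_sw_scores")]]
NumericVector profile_sw_scores(List seqs, NumericMatrix prof,
                                double gap_open, double gap_extend) {
  const int W = prof.ncol();
  const double NEG = -1e30;
  const int nseq = seqs.size();
  NumericVector out(nseq);
  std::vector<double> Hprev(W + 1), Hcur(W + 1), Eprev(W + 1), Ecur(W + 1), Fcur(W + 1);
  for (int s = 0; s < nseq; ++s) {
    IntegerVector seq = seqs[s];
    const int n = seq.size();
    std::fill(Hprev.begin(), Hprev.end(), 0.0);
    std::fill(Eprev.begin(), Eprev.end(), NEG);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
      Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
      const int aa = seq[i - 1];
      for (int j = 1; j <= W; ++j) {
        Ecur[j] = std::max(Hprev[j] - gap_open, Eprev[j] - gap_extend);
        Fcur[j] = std::max(Hcur[j - 1] - gap_open, Fcur[j - 1] - gap_extend);
        double h = Hprev[j - 1] + col_score(prof, j - 1, aa);
        h = std::max(0.0, std::max(h, std::max(Ecur[j], Fcur[j])));
        Hcur[j] = h;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
    }
    out[s] = best;
  }
  return out;
}

// Affine-gap local alignment of two sequences under a substitution
// matrix. Reports score, spans, identical-pair count and alignment
// length (gapped columns included) for identity/coverage filters.
// [[Rcpp::export(name = ".pair_sw")]]
List pair_sw(IntegerVector a, IntegerVector b, NumericMatrix subst,
             double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG), Fcur(m + 1, NEG);
  std::vector<unsigned char> ptrH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> ptrE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> ptrF((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      const size_t at = (size_t)i * (m + 1) + j;
      double eOpen = Hprev[j] - gap_open, eExt = Eprev[j] - gap_extend;
      Ecur[j] = std::max(eOpen, eExt); ptrE[at] = (eExt > eOpen) ? 1 : 0;
      double fOpen = Hcur[j - 1] - gap_open, fExt = Fcur[j - 1] - gap_extend;
      Fcur[j] = std::max(fOpen, fExt); ptrF[at] = (fExt > fOpen) ? 1 : 0;
      double sc;
      if (a[i - 1] < 0 || b[j - 1] < 0) sc = -4.0;
      else sc = subst(a[i - 1], b[j - 1]);
      double diag = Hprev[j - 1] + sc;
      double h = 0.0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; p = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; p = 3; }
      Hcur[j] = h; ptrH[at] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
  }

  int ident = 0, alnlen = 0, astart = 0, aend = 0, bstart = 0, bend = 0;
  if (best > 0) {
    int i = bi, j = bj, state = 1;
    aend = bi; bend = bj;
    while (i > 0 && j > 0) {
      const size_t at = (size_t)i * (m + 1) + j;
      if (state == 1) {
        unsigned char p = ptrH[at];
        if (p == 0) break;
        if (p == 1) {
          if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++ident;
          ++alnlen; --i; --j;
        } else if (p == 2) state = 2;
        else state = 3;
      } else if (state == 2) {
        unsigned char p = ptrE[at];
        ++alnlen; --i;
        state = (p == 1) ? 2 : 1;
      } else {
        unsigned char p = ptrF[at];
        ++alnlen; --j;
        state = (p == 1) ? 3 : 1;
      }
    }
    astart = i + 1; bstart = j + 1;
  }
  return List::create(_["score"] = best,
                      _["a_start"] = astart, _["a_end"] = aend,
                      _["b_start"] = bstart, _["b_end"] = bend,
                      _["identical"] = ident, _["aln_len"] = alnlen);
}

// Global (Needleman-Wunsch) path over a precomputed cell-score matrix,
// linear gap penalty; used by the convenience progressive aligner.
// Returns a step matrix: 1 = diagonal, 2 = gap in B (consume A), 3 = gap in A.
// [[Rcpp::export(name = ".nw_steps")]]
IntegerVector nw_steps(NumericMatrix cell, double gap) {
  const int n = cell.nrow(), m = cell.ncol();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) { H(i, 0) = -gap * i; P(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { H(0, j) = -gap * j; P(0, j) = 3; }
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double d = H(i - 1, j - 1) + cell(i - 1, j - 1);
      double u = H(i - 1, j) - gap;
      double l = H(i, j - 1) - gap;
      double h = d; int p = 1;
      if (u > h) { h = u; p = 2; }
      if (l > h) { h = l; p = 3; }
      H(i, j) = h; P(i, j) = p;
    }
  std::vector<int> steps;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = P(i, j);
    steps.push_back(p);
    if (p == 1) { --i; --j; }
    else if (p == 2) --i;
    else --j;
  }
  std::reverse(steps.begin(), steps.end());
  return wrap(steps);
}
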