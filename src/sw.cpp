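#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman over integer-encoded residues.
//
// q, s are 1-based indices into the rows/columns of `mat` (a square
// substitution matrix). A gap of length L costs gap_open + L * gap_extend
// (NCBI-style: the first gapped position pays open + extend).
//
// Tie-breaks are fully deterministic: the traceback starts at the
// highest-scoring cell, ties resolved by the smallest (row, col) in
// row-major order; within the traceback, diagonal moves are preferred over
// gaps in the subject, which are preferred over gaps in the query.
//
// Returns 0-based half-open coordinates. A best score <= 0 is the no-hit
// sentinel: score 0 and empty coordinates.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix mat,
                  double gap_open, double gap_extend, bool traceback) {
  const int m = q.size(), n = s.size();
  List nohit = List::create(
    _["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
    _["s_start"] = 0, _["s_end"] = 0, _["n_ident"] = 0, _["align_len"] = 0);
  if (m == 0 || n == 0) return nohit;

  const double gi = gap_open + gap_extend;  // cost of the first gap position
  std::vector<double> H(n + 1, 0.0), E(n + 1, R_NegInf);
  // Pointer codes per cell, packed: 0 = stop, 1 = diag, 2 = from E (gap in
  // query consumes subject), 3 = from F (gap in subject consumes query).
  // For E/F we also record whether the gap was opened (vs extended).
  std::vector<unsigned char> ptrH, ptrE, ptrF;
  if (traceback) {
    ptrH.assign((size_t)(m + 1) * (n + 1), 0);
    ptrE.assign((size_t)(m + 1) * (n + 1), 0);
    ptrF.assign((size_t)(m + 1) * (n + 1), 0);
  }
  std::vector<double> Fcol(n + 1, R_NegInf), Hprev(n + 1, 0.0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= m; ++i) {
    std::swap(Hprev, H);
    H[0] = 0.0;
    E[0] = R_NegInf;
    double diag = 0.0;  // Hprev[j-1] before overwrite
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (moving along subject)
      double e_open = H[j - 1] - gi, e_ext = E[j - 1] - gap_extend;
      E[j] = (e_open >= e_ext) ? e_open : e_ext;
      // F: gap in subject (moving along query)
      double f_open = Hprev[j] - gi, f_ext = Fcol[j] - gap_extend;
      Fcol[j] = (f_open >= f_ext) ? f_open : f_ext;
      double sub = Hprev[j - 1] + mat(q[i - 1] - 1, s[j - 1] - 1);
      double h = 0.0;
      unsigned char p = 0;
      if (sub >= h) { h = sub; p = 1; }
      if (E[j] > h) { h = E[j]; p = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; p = 3; }
      if (sub <= 0.0 && p == 1) { h = 0.0; p = 0; }
      H[j] = h;
      if (traceback) {
        size_t idx = (size_t)i * (n + 1) + j;
        ptrH[idx] = p;
        ptrE[idx] = (e_open >= e_ext) ? 1 : 0;  // 1 = opened here
        ptrF[idx] = (f_open >= f_ext) ? 1 : 0;
      }
      if (h > best) { best = h; bi = i; bj = j; }
      (void)diag;
    }
  }

  if (best <= 0.0) return nohit;

  int qs = bi, qe = bi, ss = bj, se = bj, nid = 0, alen = 0;
  if (traceback) {
    int i = bi, j = bj;
    int state = 0;  // 0 = in H, 2 = in E, 3 = in F
    while (i > 0 && j > 0) {
      size_t idx = (size_t)i * (n + 1) + j;
      if (state == 0) {
        unsigned char p = ptrH[idx];
        if (p == 0) break;
        if (p == 1) {
          ++alen;
          if (q[i - 1] == s[j - 1]) ++nid;
          --i; --j;
        } else {
          state = p;
        }
      } else if (state == 2) {
        ++alen;
        unsigned char opened = ptrE[idx];
        --j;
        if (opened) state = 0;
      } else {
        ++alen;
        unsigned char opened = ptrF[idx];
        --i;
        if (opened) state = 0;
      }
    }
    qs = i; ss = j;
  } else {
    qs = bi - 1; ss = bj - 1;  // unknown without traceback; degenerate span
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = qs, _["q_end"] = qe,      // 0-based half-open: [qs, qe)
    _["s_start"] = ss, _["s_end"] = se,
    _["n_ident"] = nid, _["align_len"] = alen);
}

// Score-only variant against many subjects; returns a numeric vector of
// optimal local scores. Used by the search layer after k-mer prefiltering.

// [[Rcpp::export]]
NumericVector sw_score_many_cpp(IntegerVector q, List subjects,
                                NumericMatrix mat, double gap_open,
                                double gap_extend) {
  const int m = q.size(), nsub = subjects.size();
  const int nrow = mat.nrow();
  NumericVector out(nsub);
  const double gi = gap_open + gap_extend;
  std::vector<double> matv(mat.begin(), mat.end());  // column-major
  for (int k = 0; k < nsub; ++k) {
    IntegerVector s = subjects[k];
    const int n = s.size();
    if (m == 0 || n == 0) { out[k] = 0.0; continue; }
    std::vector<double> H(n + 1, 0.0), Fcol(n + 1, R_NegInf),
        Hprev(n + 1, 0.0);
    std::vector<int> sv(n);
    for (int j = 0; j < n; ++j) sv[j] = s[j] - 1;
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
      std::swap(Hprev, H);
      H[0] = 0.0;
      const int qi = q[i - 1] - 1;
      double e_prev = R_NegInf, h_left = 0.0;
      for (int j = 1; j <= n; ++j) {
        double e = std::max(h_left - gi, e_prev - gap_extend);
        double f = std::max(Hprev[j] - gi, Fcol[j] - gap_extend);
        Fcol[j] = f;
        double h = Hprev[j - 1] + matv[(size_t)sv[j - 1] * nrow + qi];
        if (e > h) h = e;
        if (f > h) h = f;
        if (h < 0.0) h = 0.0;
        H[j] = h;
        h_left = h;
        e_prev = e;
        if (h > best) best = h;
      }
    }
    out[k] = best;
  }
  return out;
}
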