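#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Plan7-lite local Viterbi in bit space.
//
// States: M_1..M_M, I_1..I_{M-1}, D_2..D_M, with uniform local entry
// (B -> M_k, 0 bits, any k) and uniform local exit (M_k -> E, 0 bits).
// trans row k (0-based) holds log2 transition scores out of node k+1:
//   [0] M->M  [1] M->I  [2] M->D  [3] I->M  [4] I->I  [5] D->M  [6] D->D
// match emission column index r < 0 (unknown residue such as X or *)
// emits 0 bits; insert states emit background (0 bits) by construction.
//
// Ties resolve toward the earliest end position, then the earliest model
// state, and within a cell toward fresh entry, then the M, I, D
// predecessors in that order; only the envelope, never the score, can
// depend on this.
// [[Rcpp::export]]
List viterbi_local_cpp(NumericMatrix match_bits, NumericMatrix trans_bits,
                       IntegerVector pep) {
  const int M = match_bits.nrow();
  const int L = pep.size();
  const double NEG = -1e300;

  if (L == 0 || M == 0)
    return List::create(_["score"] = R_NegInf,
                        _["aa_start"] = NA_INTEGER,
                        _["aa_end"] = NA_INTEGER,
                        _["k_end"] = NA_INTEGER);

  // vm/vi/vd: best score of a path ending in that state having consumed
  // residues up to the current column; sm/si/sd track the 0-based index of
  // the first consumed residue (local alignment start).
  std::vector<double> vm(M, NEG), vi(M, NEG), vd(M, NEG);
  std::vector<double> pm(M), pi(M), pd(M);
  std::vector<int> sm(M, -1), si(M, -1), sd(M, -1), qm(M), qi(M), qd(M);

  double best = NEG;
  int best_end = -1, best_k = -1, best_start = -1;

  for (int j = 0; j < L; ++j) {
    pm = vm; pi = vi; pd = vd;
    qm = sm; qi = si; qd = sd;
    const int r = pep[j];
    for (int k = 0; k < M; ++k) {
      const double e = (r >= 0) ? match_bits(k, r) : 0.0;

      // M_k+1: fresh entry or extend from node k's M/I/D (previous column)
      double v = 0.0;
      int s = j;
      if (k > 0) {
        double c = pm[k - 1] + trans_bits(k - 1, 0);
        if (c > v) { v = c; s = qm[k - 1]; }
        c = pi[k - 1] + trans_bits(k - 1, 3);
        if (c > v) { v = c; s = qi[k - 1]; }
        c = pd[k - 1] + trans_bits(k - 1, 5);
        if (c > v) { v = c; s = qd[k - 1]; }
      }
      vm[k] = e + v;
      sm[k] = s;

      // I_k+1 consumes a residue at 0 bits
      const double a = pm[k] + trans_bits(k, 1);
      const double b = pi[k] + trans_bits(k, 4);
      if (a >= b) { vi[k] = a; si[k] = qm[k]; }
      else        { vi[k] = b; si[k] = qi[k]; }

      // D_k+1 consumes nothing: current column of node k
      if (k > 0) {
        const double dm = vm[k - 1] + trans_bits(k - 1, 2);
        const double dd = vd[k - 1] + trans_bits(k - 1, 6);
        if (dm >= dd) { vd[k] = dm; sd[k] = sm[k - 1]; }
        else          { vd[k] = dd; sd[k] = sd[k - 1]; }
      } else {
        vd[k] = NEG;
        sd[k] = -1;
      }

      if (vm[k] > best) {
        best = vm[k];
        best_end = j;
        best_k = k;
        best_start = sm[k];
      }
    }
  }

  return List::create(_["score"] = best,
                      _["aa_start"] = best_start,
                      _["aa_end"] = best_end + 1,
                      _["k_end"] = best_k + 1);
}
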