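#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Scan a read for the best occurrence of the bisulfite-converted hairpin
// linker. Marked positions (unmethylated linker Cs) match C or T; all other
// positions must match exactly. Returns the best start (1-based), its
// mismatch count and how many starts attain that count.
// [[Rcpp::export(name = ".cpp_linker_scan")]]
IntegerVector cpp_linker_scan(std::string read, std::string linker,
                              LogicalVector marked) {
  const int n = read.size(), L = linker.size();
  int best_start = -1, best_mm = L + 1, n_best = 0;
  if (n < L) return IntegerVector::create(-1, L + 1, 0);
  for (int s = 0; s + L <= n; ++s) {
    int mm = 0;
    for (int k = 0; k < L && mm < best_mm + 1; ++k) {
      const char r = read[s + k], l = linker[k];
      bool ok = marked[k] ? (r == 'C' || r == 'T') : (r == l);
      if (!ok) ++mm;
    }
    if (mm < best_mm) { best_mm = mm; best_start = s + 1; n_best = 1; }
    else if (mm == best_mm) ++n_best;
  }
  return IntegerVector::create(best_start, best_mm, n_best);
}

// Global (Needleman-Wunsch/Gotoh) alignment of a bisulfite read arm against
// its strand-local reference. Asymmetric substitution: reference C against
// read T scores as a match (conversion), identical bases match, everything
// else is a mismatch. Affine gaps: a gap of length k costs
// gap_open + (k-1) * gap_extend. Traceback ties are broken
// substitution > gap-in-read > gap-in-reference, for determinism.
// [[Rcpp::export(name = ".cpp_bisulfite_align")]]
List cpp_bisulfite_align(std::string ref, std::string read,
                         double match, double mismatch,
                         double gap_open, double gap_extend) {
  const int n = ref.size(), m = read.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state 0 = M (diagonal), 1 = X (ref base vs gap), 2 = Y (read base vs gap)
  std::vector<double> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<signed char> pM(M.size(), -1), pX(M.size(), -1), pY(M.size(), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char rc = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char qc = read[j - 1];
      const double s =
        (rc == qc || (rc == 'C' && qc == 'T')) ? match : mismatch;
      // M: best predecessor of the diagonal move, preference M > X > Y
      {
        const int d = at(i - 1, j - 1);
        double best = M[d]; signed char p = 0;
        if (X[d] > best) { best = X[d]; p = 1; }
        if (Y[d] > best) { best = Y[d]; p = 2; }
        M[at(i, j)] = best + s; pM[at(i, j)] = p;
      }
      // X: consume ref[i], gap in read
      {
        const int u = at(i - 1, j);
        double best = M[u] + gap_open; signed char p = 0;
        if (X[u] + gap_extend > best) { best = X[u] + gap_extend; p = 1; }
        if (Y[u] + gap_open > best) { best = Y[u] + gap_open; p = 2; }
        X[at(i, j)] = best; pX[at(i, j)] = p;
      }
      // Y: consume read[j], gap in ref
      {
        const int l = at(i, j - 1);
        double best = M[l] + gap_open; signed char p = 0;
        if (X[l] + gap_open > best) { best = X[l] + gap_open; p = 1; }
        if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; p = 2; }
        Y[at(i, j)] = best; pY[at(i, j)] = p;
      }
    }
  }

  int i = n, j = m, state = 0;
  double score = M[at(n, m)];
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::string ar, aq;
  while (i > 0 || j > 0) {
    if (state == 0) {
      const signed char p = pM[at(i, j)];
      ar.push_back(ref[i - 1]); aq.push_back(read[j - 1]);
      --i; --j; state = p;
    } else if (state == 1) {
      const signed char p = pX[at(i, j)];
      ar.push_back(ref[i - 1]); aq.push_back('-');
      --i; state = p;
    } else {
      const signed char p = pY[at(i, j)];
      ar.push_back('-'); aq.push_back(read[j - 1]);
      --j; state = p;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(aq.begin(), aq.end());
  return List::create(_["ref"] = ar, _["read"] = aq, _["score"] = score);
}
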