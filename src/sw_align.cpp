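#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) with explicit traceback pointers.
// Gap of length g costs gap_open + (g - 1) * gap_extend.
// Deterministic tie-breaking: at equal score prefer the alignment with
// the smaller (query start, subject start), realised by preferring
// diagonal > gap-in-query > gap-in-subject moves and by comparing
// propagated origins.
//
// q, s: 0-based residue indices into the substitution matrix.

static inline long enc(int i, int j, int n) {
  return (long)i * (n + 2) + j;
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  const int NEG = -100000000;
  const long W = n + 1;
  std::vector<int> H((m + 1) * W, 0), E((m + 1) * W, NEG),
      F((m + 1) * W, NEG);
  std::vector<long> oH((m + 1) * W, 0), oE((m + 1) * W, 0),
      oF((m + 1) * W, 0);
  std::vector<unsigned char> tbH((m + 1) * W, 0), tbE((m + 1) * W, 0),
      tbF((m + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  long bestOrigin = enc(m + 1, n + 1, n);

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const long c = i * W + j, up = (i - 1) * W + j, lf = i * W + (j - 1),
                 dg = (i - 1) * W + (j - 1);
      // E: gap in query, consumes subject residue j
      int eOpen = H[lf] - gap_open, eExt = E[lf] - gap_extend;
      if (eOpen >= eExt) {
        E[c] = eOpen; tbE[c] = 1; oE[c] = oH[lf];
      } else {
        E[c] = eExt; tbE[c] = 2; oE[c] = oE[lf];
      }
      // F: gap in subject, consumes query residue i
      int fOpen = H[up] - gap_open, fExt = F[up] - gap_extend;
      if (fOpen >= fExt) {
        F[c] = fOpen; tbF[c] = 1; oF[c] = oH[up];
      } else {
        F[c] = fExt; tbF[c] = 2; oF[c] = oF[up];
      }
      // H: best of restart / diagonal / E / F
      int diag = H[dg] + sub(q[i - 1], s[j - 1]);
      long diagO = (H[dg] > 0) ? oH[dg] : enc(i, j, n);
      int hBest = diag; unsigned char hTb = 1; long hO = diagO;
      if (E[c] > hBest || (E[c] == hBest && oE[c] < hO)) {
        hBest = E[c]; hTb = 2; hO = oE[c];
      }
      if (F[c] > hBest || (F[c] == hBest && oF[c] < hO)) {
        hBest = F[c]; hTb = 3; hO = oF[c];
      }
      if (hBest <= 0) {
        H[c] = 0; tbH[c] = 0; oH[c] = 0;
      } else {
        H[c] = hBest; tbH[c] = hTb; oH[c] = hO;
        if (hBest > best || (hBest == best && hO < bestOrigin)) {
          best = hBest; bi = i; bj = j; bestOrigin = hO;
        }
      }
    }
  }

  if (best == 0) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER, _["n_columns"] = 0,
                        _["n_matches"] = 0, _["n_gapcols"] = 0);
  }

  // traceback
  int i = bi, j = bj, ncol = 0, nmatch = 0, ngap = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    const long c = i * W + j;
    if (state == 0) {
      if (tbH[c] == 0) break;
      if (tbH[c] == 1) {
        ++ncol;
        if (q[i - 1] == s[j - 1]) ++nmatch;
        --i; --j;
      } else if (tbH[c] == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      ++ncol; ++ngap;
      state = (tbE[c] == 1) ? 0 : 1;
      --j;
    } else {
      ++ncol; ++ngap;
      state = (tbF[c] == 1) ? 0 : 2;
      --i;
    }
  }

  return List::create(_["score"] = best, _["qstart"] = i + 1,
                      _["qend"] = bi, _["sstart"] = j + 1,
                      _["send"] = bj, _["n_columns"] = ncol,
                      _["n_matches"] = nmatch, _["n_gapcols"] = ngap);
}
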