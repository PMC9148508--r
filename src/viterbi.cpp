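// Viterbi decoding over the 29 dynamic-programming rows of the 49-state
// gene model. Row order (0-based) matches R/states.R exactly:
//   0      R (noncoding)
//   1..6   M1+..M6+    7..12  I1+..I6+    13 S+   14 E+
//   15..20 M1-..M6-   21..26  I1-..I6-    27 S-   28 E-
// Boundary composites consume three input positions atomically; deletion
// states are the implicit skip arcs M_p -> M_{p+2}. The DP is traversed
// position-outer / row-inner and stored position-major so that all row
// scores of one position are contiguous.
//
// Tie-breaking: predecessor lists are kept sorted by row index and a
// candidate replaces the incumbent only when strictly greater, so equal
// scores resolve to the lowest-numbered row. The final row is likewise the
// lowest row attaining the maximum.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

const int NROWS = 29;
// transition vector layout (see R/viterbi.R): NN NSF NER MM MI MD II IM GE
enum { tNN, tNSF, tNER, tMM, tMI, tMD, tII, tIM, tGE };

struct Arc { int from; double logw; };

inline int wrap6(int p) { return ((p - 1) % 6 + 6) % 6 + 1; }

// Build the incoming-arc table from the macro transitions; sorted by
// predecessor row so the tie-break rule is positional.
std::vector<std::vector<Arc>> buildArcs(const NumericVector& tr) {
  std::vector<std::vector<Arc>> arcs(NROWS);
  // attachment costs split evenly across entry/exit arcs so that
  // edge-truncated segments score strand-symmetrically (see R/states.R)
  const double mio = (tr[tMI] + tr[tIM]) / 2;
  const double rside = (tr[tNSF] + tr[tNER]) / 4;
  const double gside = tr[tGE] / 2;
  auto add = [&](int to, int from, double w) {
    arcs[to].push_back({from, w});
  };
  add(0, 0, tr[tNN]); add(0, 14, rside); add(0, 27, rside);
  for (int p = 1; p <= 6; ++p) {
    int pm1 = wrap6(p - 1), pm2 = wrap6(p - 2);
    int mf = p, ifr = 6 + p, mr = 14 + p, irr = 20 + p;
    add(mf, pm1, tr[tMM]); add(mf, pm2, tr[tMD]); add(mf, 6 + pm1, mio);
    if (p == 1) add(mf, 13, gside);
    add(ifr, mf, mio); add(ifr, ifr, tr[tII]);
    add(mr, 14 + pm1, tr[tMM]); add(mr, 14 + pm2, tr[tMD]);
    add(mr, 20 + pm1, mio);
    if (p == 1) add(mr, 28, gside);
    add(irr, mr, mio); add(irr, irr, tr[tII]);
  }
  add(13, 0, rside);
  add(14, 3, gside); add(14, 6, gside);
  add(27, 17, gside); add(27, 20, gside);
  add(28, 0, rside);
  for (auto& a : arcs)
    std::sort(a.begin(), a.end(),
              [](const Arc& x, const Arc& y) { return x.from < y.from; });
  return arcs;
}

} // namespace

// [[Rcpp::export(name = ".viterbiCore")]]
List viterbiCore(IntegerVector seq, NumericVector matchF, NumericVector matchR,
                 NumericVector noncod, NumericVector matchFMarg,
                 NumericVector matchRMarg, NumericVector ncMarg,
                 NumericVector pwmFlat, NumericMatrix adjust, int W,
                 NumericVector trans, double prior, double logUnif) {
  const int n = seq.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<std::vector<Arc>> arcs = buildArcs(trans);

  // emission of a single-consume row whose table is `tab` (16 contexts x
  // 4); `marg` is the context-marginal row used when the preceding
  // dinucleotide is unavailable or ambiguous
  auto emitTab = [&](const double* tab, const double* marg, int i) -> double {
    int b = seq[i];
    if (b > 3) return logUnif;
    if (i < 2 || seq[i - 1] > 3 || seq[i - 2] > 3) return marg[b];
    return tab[(seq[i - 2] * 4 + seq[i - 1]) * 4 + b];
  };
  // boundary composite ending at position i (0-based): codon occupies
  // i-2..i, window of length W centred on the middle base i-1. Offsets
  // outside the sequence are skipped (edge rule); ambiguous bases score
  // log(1/4). Summation order (ascending offset) matches R/viterbi.R.
  auto bscore = [&](int kind, int i) -> double {
    int c = i - 1, half = (W - 1) / 2;
    double s = 0.0;
    for (int j = 0; j < W; ++j) {
      int q = c + j - half;
      if (q < 0 || q >= n) continue;
      double lp = seq[q] > 3 ? logUnif : pwmFlat[(kind * W + j) * 4 + seq[q]];
      s += (double(W) * adjust(kind, j)) * lp;
    }
    return s;
  };

  std::vector<double> V((size_t)n * NROWS, NEG);
  std::vector<int> bpFrom((size_t)n * NROWS, -1);
  double ops = 0.0;
  const double* mF = matchF.begin();
  const double* mR = matchR.begin();
  const double* nc = noncod.begin();

  for (int i = 0; i < n; ++i) {
    double* col = &V[(size_t)i * NROWS];
    int* bcol = &bpFrom[(size_t)i * NROWS];
    const double* prev = i > 0 ? &V[(size_t)(i - 1) * NROWS] : nullptr;
    const double* prev3 = i >= 3 ? &V[(size_t)(i - 3) * NROWS] : nullptr;
    for (int r = 0; r < NROWS; ++r) {
      bool composite = (r == 13 || r == 14 || r == 27 || r == 28);
      double best = NEG;
      int bestFrom = -1;
      if (!composite) {
        if (i == 0) {
          best = prior;
        } else {
          for (const Arc& a : arcs[r]) {
            ++ops;
            double cand = prev[a.from] + a.logw;
            if (cand > best) { best = cand; bestFrom = a.from; }
          }
        }
      } else {
        if (i == 2) {
          best = prior;
        } else if (i >= 3) {
          for (const Arc& a : arcs[r]) {
            ++ops;
            double cand = prev3[a.from] + a.logw;
            if (cand > best) { best = cand; bestFrom = a.from; }
          }
        }
      }
      if (best == NEG) continue;
      double e;
      switch (r) {
        case 0:  e = emitTab(nc, ncMarg.begin(), i); break;
        case 13: e = bscore(0, i); break;
        case 14: e = bscore(1, i); break;
        case 27: e = bscore(2, i); break;
        case 28: e = bscore(3, i); break;
        default:
          if (r >= 1 && r <= 6)
            e = emitTab(mF + (r - 1) * 64, matchFMarg.begin() + (r - 1) * 4, i);
          else if (r >= 7 && r <= 12)  e = logUnif;
          else if (r >= 15 && r <= 20)
            e = emitTab(mR + (r - 15) * 64, matchRMarg.begin() + (r - 15) * 4, i);
          else                         e = logUnif;
      }
      col[r] = best + e;
      bcol[r] = bestFrom;
    }
  }

  const double* last = &V[(size_t)(n - 1) * NROWS];
  double bestScore = NEG;
  int bestRow = -1;
  for (int r = 0; r < NROWS; ++r) {
    if (last[r] > bestScore) { bestScore = last[r]; bestRow = r; }
  }
  if (bestRow < 0) stop("no admissible path");  // cannot happen: R row is total

  IntegerVector path(n);
  int pos = n - 1, row = bestRow;
  while (pos >= 0) {
    bool composite = (row == 13 || row == 14 || row == 27 || row == 28);
    int k = composite ? 3 : 1;
    for (int t = 0; t < k; ++t) path[pos - t] = row + 1;
    int from = bpFrom[(size_t)pos * NROWS + row];
    pos -= k;
    row = from;
  }

  return List::create(_["path"] = path, _["logScore"] = bestScore,
                      _["opCount"] = ops);
}
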