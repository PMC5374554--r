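#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static const double INF = 1e9;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': case 'U': return 3;
    default: return -1;
  }
}

// Pair types indexing the 6x6 stack table: AU UA CG GC GU UG
// (first base on the miRNA strand, second on the target strand; T == U).
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;  // A:U
  if (a == 3 && b == 0) return 1;  // U:A
  if (a == 1 && b == 2) return 2;  // C:G
  if (a == 2 && b == 1) return 3;  // G:C
  if (a == 2 && b == 3) return 4;  // G:U
  if (a == 3 && b == 2) return 5;  // U:G
  return -1;
}

// Intermolecular duplex MFE by nearest-neighbor dynamic programming.
// Structures are antiparallel non-crossing sets of base pairs (i on x, j on y;
// i increasing implies j decreasing). Adjacent pairs score the stack table;
// consecutive pairs separated by unpaired bases score an affine interior
// loop/bulge penalty; a lone pair and the empty structure score 0, so the
// MFE is always <= 0. No intramolecular pairs, pseudoknots, or dangling ends.
// [[Rcpp::export]]
List duplex_dp_cpp(std::string x, std::string y, NumericMatrix stack,
                   double loop_open, double loop_ext, int max_loop) {
  const int m = (int) x.size(), n = (int) y.size();
  std::vector<int> xb(m), yb(n);
  for (int i = 0; i < m; ++i) xb[i] = base_code(x[i]);
  for (int j = 0; j < n; ++j) yb[j] = base_code(y[j]);

  // H(i,j): best energy of a structure whose last pair (largest i,
  // smallest j) is (i,j). 0-based here.
  std::vector<std::vector<double> > H(m, std::vector<double>(n, INF));
  std::vector<std::vector<int> > PI(m, std::vector<int>(n, -1)),
      PJ(m, std::vector<int>(n, -1));

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < m; ++i) {
    for (int j = n - 1; j >= 0; --j) {
      int t = pair_type(xb[i], yb[j]);
      if (t < 0) continue;
      double e = 0.0;  // (i,j) as the first (and so far only) pair
      int pi = -1, pj = -1;
      for (int ip = 0; ip < i; ++ip) {
        for (int jp = n - 1; jp > j; --jp) {
          if (H[ip][jp] >= INF) continue;
          int tp = pair_type(xb[ip], yb[jp]);
          int gx = i - ip - 1, gy = jp - j - 1;
          double cost;
          if (gx == 0 && gy == 0) cost = stack(tp, t);
          else if (gx + gy <= max_loop)
            cost = loop_open + loop_ext * (gx + gy);
          else continue;
          double cand = H[ip][jp] + cost;
          if (cand < e) { e = cand; pi = ip; pj = jp; }
        }
      }
      H[i][j] = e;
      PI[i][j] = pi;
      PJ[i][j] = pj;
      if (e < best) { best = e; bi = i; bj = j; }
    }
  }

  std::vector<int> pis, pjs;
  std::vector<bool> wob;
  int ci = bi, cj = bj;
  while (ci >= 0) {
    pis.push_back(ci + 1);
    pjs.push_back(cj + 1);
    wob.push_back(pair_type(xb[ci], yb[cj]) >= 4);
    int ni = PI[ci][cj], nj = PJ[ci][cj];
    ci = ni; cj = nj;
  }
  const int np = (int) pis.size();
  IntegerVector pi_out(np), pj_out(np);
  LogicalVector wob_out(np);
  for (int r = 0; r < np; ++r) {  // reverse into ascending miRNA position
    pi_out[r] = pis[np - 1 - r];
    pj_out[r] = pjs[np - 1 - r];
    wob_out[r] = wob[np - 1 - r];
  }
  return List::create(_["mfe"] = best, _["i"] = pi_out, _["j"] = pj_out,
                      _["wobble"] = wob_out);
}
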