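#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// miRanda-style local duplex alignment (Gotoh affine gaps) of a miRNA
// (aligned 3'->5') against a target window (5'->3'), with pair scores of
// positions falling in the miRNA seed multiplied by a weight. Gap runs cost
// gap_open for the first gapped position and gap_ext for each further one.

static inline int pair_class(char a, char b) {
  // 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
      (a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
  return 2;
}

// [[Rcpp::export(name = ".duplex_align_cpp")]]
List duplex_align_cpp(std::string mirna, std::string window,
                      double match, double wobble, double mismatch,
                      double gap_open, double gap_ext,
                      double seed_weight, int seed_from, int seed_to) {
  const int M = mirna.size(), N = window.size();
  // q = reversed miRNA; row a (1..M) corresponds to miRNA position M - a + 1
  std::string q(mirna.rbegin(), mirna.rend());

  const double NEG = -1e18;
  std::vector<double> H((M + 1) * (N + 1), 0.0), E((M + 1) * (N + 1), NEG),
      F((M + 1) * (N + 1), NEG);
  // traceback: tbH 0=stop,1=diag,2=fromE,3=fromF ; tbE/tbF 0=open,1=extend
  std::vector<signed char> tbH((M + 1) * (N + 1), 0),
      tbE((M + 1) * (N + 1), 0), tbF((M + 1) * (N + 1), 0);
  auto at = [N](int a, int j) { return a * (N + 1) + j; };

  double best = 0.0; int ba = 0, bj = 0;
  for (int a = 1; a <= M; ++a) {
    int mpos = M - a + 1;  // 1-based miRNA position
    double w = (mpos >= seed_from && mpos <= seed_to) ? seed_weight : 1.0;
    for (int j = 1; j <= N; ++j) {
      // E: gap in miRNA (window base consumed)
      double eo = H[at(a, j - 1)] + gap_open;
      double ee = E[at(a, j - 1)] + gap_ext;
      if (eo >= ee) { E[at(a, j)] = eo; tbE[at(a, j)] = 0; }
      else          { E[at(a, j)] = ee; tbE[at(a, j)] = 1; }
      // F: gap in window (miRNA base consumed)
      double fo = H[at(a - 1, j)] + gap_open;
      double fe = F[at(a - 1, j)] + gap_ext;
      if (fo >= fe) { F[at(a, j)] = fo; tbF[at(a, j)] = 0; }
      else          { F[at(a, j)] = fe; tbF[at(a, j)] = 1; }
      int pc = pair_class(q[a - 1], window[j - 1]);
      double ps = (pc == 0 ? match : (pc == 1 ? wobble : mismatch)) * w;
      double diag = H[at(a - 1, j - 1)] + ps;
      double h = 0.0; signed char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[at(a, j)] > h) { h = E[at(a, j)]; tb = 2; }
      if (F[at(a, j)] > h) { h = F[at(a, j)]; tb = 3; }
      H[at(a, j)] = h; tbH[at(a, j)] = tb;
      if (h > best) { best = h; ba = a; bj = j; }
    }
  }

  // traceback from (ba, bj) in state H until score source is the 0 floor
  std::vector<int> col_a, col_j, col_kind;  // kind 0 pair, 1 gap-in-miRNA, 2 gap-in-window
  int a = ba, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  while (a > 0 && j > 0) {
    if (state == 0) {
      signed char tb = tbH[at(a, j)];
      if (tb == 0) break;
      if (tb == 1) {
        col_a.push_back(a); col_j.push_back(j); col_kind.push_back(0);
        --a; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      col_a.push_back(0); col_j.push_back(j); col_kind.push_back(1);
      signed char tb = tbE[at(a, j)];
      --j;
      if (tb == 0) state = 0;
    } else {
      col_a.push_back(a); col_j.push_back(0); col_kind.push_back(2);
      signed char tb = tbF[at(a, j)];
      --a;
      if (tb == 0) state = 0;
    }
  }
  const int L = col_a.size();
  IntegerMatrix cols(L, 3);
  for (int k = 0; k < L; ++k) {  // reverse into 5'->3' window order
    cols(k, 0) = col_a[L - 1 - k];
    cols(k, 1) = col_j[L - 1 - k];
    cols(k, 2) = col_kind[L - 1 - k];
  }
  return List::create(_["score"] = best, _["columns"] = cols);
}
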