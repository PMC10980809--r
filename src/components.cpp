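#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labeling of a 3D binary mask.
// mask: 0/1 integer vector in column-major order with dims `dims`;
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns component labels (1..k) in the same layout, 0 outside the mask.
// [[Rcpp::export]]
IntegerVector cc_label_3d(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1)
          continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int nn = (int)di.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++current;
    lab[s] = current;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)n1 * n2));
      int rem = (int)(v % ((R_xlen_t)n1 * n2));
      int j = rem / n1;
      int i = rem % n1;
      for (int m = 0; m < nn; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        R_xlen_t w = (R_xlen_t)kk * n1 * n2 + (R_xlen_t)jj * n1 + ii;
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}
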