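#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary mask.
// Labels are 1..n in first-encounter (column-major scan) order; background is 0.
// connectivity: 4 or 8.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nn = connectivity;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr[k], c2 = cc2 + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Binary erosion with a 3x3 (8-connected) structuring element, iterated.
// Pixels beyond the image border count as foreground, so the mask is never
// eroded from the image edge itself (the chest-wall edge stays intact).
// [[Rcpp::export(name = ".binary_erode")]]
LogicalMatrix binary_erode(LogicalMatrix mask, int iterations) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalMatrix nxt(nr, nc);
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        bool keep = cur(r, c);
        if (keep) {
          for (int dc2 = -1; dc2 <= 1 && keep; ++dc2) {
            for (int dr2 = -1; dr2 <= 1 && keep; ++dr2) {
              int r2 = r + dr2, c2 = c + dc2;
              if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
              if (!cur(r2, c2)) keep = false;
            }
          }
        }
        nxt(r, c) = keep;
      }
    }
    cur = nxt;
  }
  return cur;
}
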