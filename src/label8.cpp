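// 8-connected component labeling by breadth-first flood fill.
#include <Rcpp.h>
#include <vector>

// [[Rcpp::export]]
Rcpp::IntegerMatrix label_components8(const Rcpp::LogicalMatrix& m) {
  const int h = m.nrow(), w = m.ncol();
  Rcpp::IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      if (!m(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * h);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int rr = idx % h, cc = idx / h;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            const int nr = rr + dr, nc = cc + dc;
            if (nr < 0 || nr >= h || nc < 0 || nc >= w) continue;
            if (m(nr, nc) && !lab(nr, nc)) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * h);
            }
          }
        }
      }
    }
  }
  return lab;
}
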