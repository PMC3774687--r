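#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-connected neighbour offsets (row, col)
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  // column-major scan so labels are assigned in R's linear-index order
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = cr + DR[k], c2 = cc + DC[k];
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

struct FloodEntry {
  double value;
  long long order;
  int idx;
};

struct FloodCmp {
  bool operator()(const FloodEntry& a, const FloodEntry& b) const {
    if (a.value != b.value) return a.value > b.value;  // min-heap on relief
    return a.order > b.order;                          // FIFO tie-break
  }
};

// Marker-controlled watershed by priority flooding (Meyer-style): pixels of
// `mask` are claimed in increasing `relief` order starting from the labelled
// seed pixels; each newly claimed pixel inherits the label of the front that
// reached it first. Flooding never leaves `mask`.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_seeded_flood(const NumericMatrix& relief,
                               const IntegerMatrix& seeds,
                               const LogicalMatrix& mask) {
  const int nr = relief.nrow(), nc = relief.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc || mask.nrow() != nr ||
      mask.ncol() != nc)
    stop("relief, seeds and mask must share dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<FloodEntry, std::vector<FloodEntry>, FloodCmp> pq;
  long long ord = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) && seeds(r, c) > 0) {
        lab(r, c) = seeds(r, c);
        pq.push(FloodEntry{relief(r, c), ord++, r + c * nr});
      }
  while (!pq.empty()) {
    FloodEntry e = pq.top();
    pq.pop();
    int cr = e.idx % nr, cc = e.idx / nr;
    int l = lab(cr, cc);
    for (int k = 0; k < 8; ++k) {
      int r2 = cr + DR[k], c2 = cc + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && lab(r2, c2) == 0) {
        lab(r2, c2) = l;
        pq.push(FloodEntry{relief(r2, c2), ord++, r2 + c2 * nr});
      }
    }
  }
  return lab;
}
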