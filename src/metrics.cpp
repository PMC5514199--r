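#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of same-class cells.  Connectivity 8 (queen,
// the patch rule used throughout) or 4 (rook), selectable.  Cells whose value
// is not in `classes` (nodata or unknown) get label 0.  Labels are assigned
// in column-major scan order, so output is deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_label_patches(IntegerMatrix grid, IntegerVector classes,
                                int connectivity) {
  int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix lab(nr, nc);
  std::set<int> cls(classes.begin(), classes.end());
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int v = grid(i, j);
      if (lab(i, j) != 0 || cls.find(v) == cls.end()) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int ci = cur % nr, cj = cur / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            if (connectivity == 4 && di != 0 && dj != 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (lab(ni, nj) == 0 && grid(ni, nj) == v) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Per-cell rook side counts for substantive-class cells:
//  - unlike:  sides shared with a cell of a DIFFERENT substantive class
//  - outside: sides facing nodata/unknown cells or the grid boundary
// Cells not in `classes` get 0 in both.  Patch perimeter (in sides) is
// unlike + outside summed over the patch; default edge density uses unlike
// only, the boundary flag adds outside.
// [[Rcpp::export]]
List cpp_cell_sides(IntegerMatrix grid, IntegerVector classes) {
  int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix unlike(nr, nc), outside(nr, nc);
  std::set<int> cls(classes.begin(), classes.end());
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int v = grid(i, j);
      if (cls.find(v) == cls.end()) continue;
      for (int d = 0; d < 4; ++d) {
        int ni = i + di[d], nj = j + dj[d];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) {
          outside(i, j)++;
        } else {
          int w = grid(ni, nj);
          if (cls.find(w) == cls.end()) outside(i, j)++;
          else if (w != v) unlike(i, j)++;
        }
      }
    }
  }
  return List::create(_["unlike"] = unlike, _["outside"] = outside);
}

// Directed rook adjacency tallies g[i,k] among substantive classes: one tally
// per ordered (cell, neighbour) pair, so like adjacencies g[i,i] follow the
// double-count convention and g[i,k] + g[k,i] double-counts unlike sides.
// Pairs involving nodata/unknown cells or the grid boundary are excluded.
// [[Rcpp::export]]
IntegerMatrix cpp_adjacency(IntegerMatrix grid, IntegerVector classes) {
  int nr = grid.nrow(), nc = grid.ncol();
  int K = classes.size();
  std::map<int, int> idx;
  for (int k = 0; k < K; ++k) idx[classes[k]] = k;
  IntegerMatrix g(K, K);
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      std::map<int, int>::iterator a = idx.find(grid(i, j));
      if (a == idx.end()) continue;
      for (int d = 0; d < 4; ++d) {
        int ni = i + di[d], nj = j + dj[d];
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        std::map<int, int>::iterator b = idx.find(grid(ni, nj));
        if (b == idx.end()) continue;
        g(a->second, b->second)++;
      }
    }
  }
  return g;
}
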