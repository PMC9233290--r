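#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' Label connected components of equal non-zero values.
//'
//' Two pixels belong to the same component iff they hold the same non-zero
//' value and are adjacent under the requested connectivity (4 or 8).
//' Returns an integer matrix of component ids, 0 for zero-valued pixels;
//' ids are compact, 1..n, in raster (column-major) order of first occurrence.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const IntegerMatrix& m, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  parent.push_back(0); // index 0 unused

  // first pass: provisional labels, merging with already-visited neighbours
  // (column-major scan: previous column fully visited, current column above)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int v = m(r, c);
      if (v == 0) continue;
      int lbl = 0;
      // neighbour offsets: (r-1,c), (r,c-1), and diagonals for 8-connectivity
      const int dr[4] = {-1, 0, -1, 1};
      const int dc[4] = {0, -1, -1, -1};
      const int nn = (connectivity == 8) ? 4 : 2;
      for (int k = 0; k < nn; ++k) {
        const int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (m(rr, cc) != v) continue;
        const int nl = lab(rr, cc);
        if (nl == 0) continue;
        if (lbl == 0) lbl = nl;
        else uf_union(parent, lbl, nl);
      }
      if (lbl == 0) {
        lbl = (int)parent.size();
        parent.push_back(lbl);
      }
      lab(r, c) = lbl;
    }
  }

  // second pass: compact root labels in order of first occurrence
  std::vector<int> remap(parent.size(), 0);
  int next_id = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (remap[root] == 0) remap[root] = ++next_id;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
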