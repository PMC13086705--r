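#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find.
// mask: integer matrix, nonzero = foreground. connectivity: 4 or 8.
// Returns an integer matrix with components labeled 1..K in raster order
// of first appearance, background 0.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];  // path halving
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // dummy so labels start at 1
  int next = 1;

  // column-major scan; neighbors already visited: up (r-1,c), left (r,c-1),
  // and for 8-connectivity the diagonals (r-1,c-1) and (r+1,c-1)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      int lup = (r > 0 && mask(r - 1, c)) ? lab(r - 1, c) : 0;
      int lleft = (c > 0 && mask(r, c - 1)) ? lab(r, c - 1) : 0;
      int lul = 0, ldl = 0;
      if (connectivity == 8) {
        if (r > 0 && c > 0 && mask(r - 1, c - 1)) lul = lab(r - 1, c - 1);
        if (r + 1 < nr && c > 0 && mask(r + 1, c - 1)) ldl = lab(r + 1, c - 1);
      }
      int lmin = 0;
      int cand[4] = {lup, lleft, lul, ldl};
      for (int k = 0; k < 4; ++k)
        if (cand[k] && (lmin == 0 || cand[k] < lmin)) lmin = cand[k];
      if (lmin == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = lmin;
        for (int k = 0; k < 4; ++k)
          if (cand[k]) unite(parent, lmin, cand[k]);
      }
    }
  }

  // resolve and relabel consecutively in order of first appearance
  std::vector<int> newlab(next, 0);
  int K = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c)) {
        int root = find_root(parent, lab(r, c));
        if (newlab[root] == 0) newlab[root] = ++K;
        lab(r, c) = newlab[root];
      }
  return lab;
}
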