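#include <Rcpp.h>
using namespace Rcpp;

// Refined incompatibility score for a pair of sites: E - V + Cc over the
// bipartite state graph built from sequences unambiguous at both sites
// (x, y coded 1..4, 0 = missing). Equals the minimum number of extra
// mutations any tree must invoke beyond the parsimony floor.
// Returns -1 when either site is monomorphic after pairwise deletion.
static int pair_score(const int* x, const int* y, int n) {
  bool joint[16];            // distinct (state_x, state_y) pairs
  bool sx[4], sy[4];
  for (int k = 0; k < 16; ++k) joint[k] = false;
  for (int k = 0; k < 4; ++k) { sx[k] = false; sy[k] = false; }
  for (int i = 0; i < n; ++i) {
    if (x[i] > 0 && y[i] > 0) {
      sx[x[i] - 1] = true;
      sy[y[i] - 1] = true;
      joint[(x[i] - 1) * 4 + (y[i] - 1)] = true;
    }
  }
  int vx = 0, vy = 0, e = 0;
  for (int k = 0; k < 4; ++k) { if (sx[k]) ++vx; if (sy[k]) ++vy; }
  if (vx < 2 || vy < 2) return -1;
  // union-find over 8 nodes: x-states 0..3, y-states 4..7
  int par[8];
  for (int k = 0; k < 8; ++k) par[k] = k;
  for (int a = 0; a < 4; ++a) {
    for (int b = 0; b < 4; ++b) {
      if (!joint[a * 4 + b]) continue;
      ++e;
      int ra = a, rb = b + 4;
      while (par[ra] != ra) ra = par[ra];
      while (par[rb] != rb) rb = par[rb];
      if (ra != rb) par[ra] = rb;
    }
  }
  int cc = 0;
  for (int k = 0; k < 8; ++k) {
    bool present = (k < 4) ? sx[k] : sy[k - 4];
    if (present) {
      int r = k;
      while (par[r] != r) r = par[r];
      if (r == k) ++cc;           // count roots of occupied components
      else {
        // root may itself be unoccupied only if path compression skipped;
        // roots are always occupied nodes here because unions only involve
        // occupied nodes.
      }
    }
  }
  return e - (vx + vy) + cc;
}

// [[Rcpp::export]]
IntegerMatrix incompat_matrix_cpp(IntegerMatrix enc) {
  const int n = enc.nrow();   // taxa
  const int m = enc.ncol();   // sites
  IntegerMatrix out(m, m);
  std::vector<int> cols(static_cast<size_t>(n) * m);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) cols[static_cast<size_t>(j) * n + i] = enc(i, j);
  for (int a = 0; a < m; ++a) {
    out(a, a) = NA_INTEGER;
    for (int b = a + 1; b < m; ++b) {
      int s = pair_score(&cols[static_cast<size_t>(a) * n],
                         &cols[static_cast<size_t>(b) * n], n);
      out(a, b) = (s < 0) ? NA_INTEGER : s;
      out(b, a) = out(a, b);
    }
  }
  return out;
}

// [[Rcpp::export]]
int pair_score_cpp(IntegerVector x, IntegerVector y) {
  if (x.size() != y.size()) stop("columns differ in length");
  return pair_score(x.begin(), y.begin(), x.size());
}
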