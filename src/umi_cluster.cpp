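#include <Rcpp.h>
using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Connected-component UMI clustering within groups.
//
// `group` must be non-decreasing; entries i, j in the same group are
// joined when the Hamming distance between umi[i] and umi[j] is at most
// max_mismatch. Returns a 0-based cluster id per entry, globally unique
// and assigned in order of each cluster's first (lexicographically
// smallest-index) member, which makes the labelling deterministic for a
// fixed input order.
// [[Rcpp::export]]
IntegerVector cluster_umis_cpp(IntegerVector group, CharacterVector umi,
                               int max_mismatch) {
  int n = group.size();
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  int gstart = 0;
  R_xlen_t len0 = LENGTH(STRING_ELT(umi, 0));
  for (int i = 0; i < n; ++i) {
    if (LENGTH(STRING_ELT(umi, i)) != len0)
      stop("all UMIs must have the same length");
    if (i > 0 && group[i] < group[i - 1])
      stop("group ids must be sorted");
    if (i == n - 1 || group[i + 1] != group[i]) {
      // close group [gstart, i]
      for (int a = gstart; a <= i; ++a) {
        const char* sa = CHAR(STRING_ELT(umi, a));
        for (int b = a + 1; b <= i; ++b) {
          if (uf_find(parent, a) == uf_find(parent, b)) continue;
          const char* sb = CHAR(STRING_ELT(umi, b));
          int d = 0;
          for (int p = 0; p < len0 && d <= max_mismatch; ++p)
            if (sa[p] != sb[p]) ++d;
          if (d <= max_mismatch) uf_union(parent, a, b);
        }
      }
      gstart = i + 1;
    }
  }
  // relabel roots to consecutive ids in first-member order
  std::vector<int> label(n, -1);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    if (label[r] < 0) label[r] = next++;
    out[i] = label[r];
  }
  return out;
}
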