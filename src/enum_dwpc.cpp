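#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive simple-path DWPC by depth-first traversal.
//
// steps: list with one element per metapath step; each element is a list
//   with CSR slots p (row pointers, length nrow+1), j (0-based column
//   indices) and x (damped edge weights) of that step's matrix.
// typeIds: 0-based metanode id per node position (length = steps + 1);
//   positions sharing a metanode id may not revisit the same node.
// typeSizes: node count per metanode id.
// budget: maximum number of edge extensions before aborting.
//
// Returns the (n_source x n_target) DWPC matrix.  Used both as the
// independent oracle for the matrix routines and as the exact fallback for
// complex repeat patterns.
// [[Rcpp::export(name = ".cppEnumDwpc")]]
NumericMatrix cppEnumDwpc(List steps, IntegerVector typeIds,
                          IntegerVector typeSizes, double budget) {
  const int L = steps.size();
  std::vector<const int*> pp(L), jj(L);
  std::vector<const double*> xx(L);
  std::vector<IntegerVector> pKeep(L), jKeep(L);
  std::vector<NumericVector> xKeep(L);
  for (int k = 0; k < L; ++k) {
    List s = steps[k];
    pKeep[k] = s["p"]; jKeep[k] = s["j"]; xKeep[k] = s["x"];
    pp[k] = INTEGER(pKeep[k]); jj[k] = INTEGER(jKeep[k]);
    xx[k] = REAL(xKeep[k]);
  }
  List s0 = steps[0];
  IntegerVector p0 = s0["p"];
  const int nSrc = p0.size() - 1;
  const int nTgt = typeSizes[typeIds[L]];
  NumericMatrix out(nSrc, nTgt);

  std::vector<std::vector<char> > visited(typeSizes.size());
  for (int t = 0; t < typeSizes.size(); ++t) visited[t].assign(typeSizes[t], 0);

  double used = 0.0;
  // iterative DFS with an explicit stack of (position, node, weight, edge idx)
  struct Frame { int pos; int node; double w; int e; int eEnd; };
  std::vector<Frame> stack(L + 1);

  for (int src = 0; src < nSrc; ++src) {
    int top = 0;
    stack[0] = Frame{0, src, 1.0, pp[0][src], pp[0][src + 1]};
    visited[typeIds[0]][src] = 1;
    while (top >= 0) {
      Frame &f = stack[top];
      if (f.pos == L || f.e >= f.eEnd) {
        visited[typeIds[f.pos]][f.node] = 0;
        --top;
        continue;
      }
      int nxt = jj[f.pos][f.e];
      double wgt = f.w * xx[f.pos][f.e];
      ++f.e;
      if (++used > budget)
        stop("path enumeration budget exceeded (budget = %.0f extensions)", budget);
      if (visited[typeIds[f.pos + 1]][nxt]) continue;
      if (f.pos + 1 == L) {
        out(src, nxt) += wgt;
      } else {
        ++top;
        stack[top] = Frame{f.pos + 1, nxt, wgt,
                           pp[f.pos + 1][nxt], pp[f.pos + 1][nxt + 1]};
        visited[typeIds[f.pos + 1]][nxt] = 1;
      }
    }
  }
  return out;
}
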