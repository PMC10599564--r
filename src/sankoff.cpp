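// Sankoff parsimony DP for a binary character on a rooted tree, plus the
// Maddison-Slatkin permutation null (tip states shuffled preserving counts).
//
// The tree arrives as an ape edge matrix already in postorder (children
// before parents), tips numbered 1..nTip, root = nTip + 1.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static double sankoff_score(const IntegerVector &parent,
                            const IntegerVector &child,
                            int nTip, int nNode,
                            const int *tipState,
                            const double *cost /* 2x2 row-major */) {
  const double INF = 1e300;
  int total = nTip + nNode;
  std::vector<double> S(2 * (size_t)total);
  for (int v = 0; v < nTip; ++v) {
    int st = tipState[v];
    S[2 * (size_t)v] = (st == 0) ? 0.0 : INF;
    S[2 * (size_t)v + 1] = (st == 1) ? 0.0 : INF;
  }
  for (int v = nTip; v < total; ++v) {
    S[2 * (size_t)v] = 0.0;
    S[2 * (size_t)v + 1] = 0.0;
  }
  int nEdge = parent.size();
  for (int e = 0; e < nEdge; ++e) {
    int p = parent[e] - 1, c = child[e] - 1;
    double c0 = S[2 * (size_t)c], c1 = S[2 * (size_t)c + 1];
    double m0 = std::min(cost[0] + c0, cost[1] + c1); // parent state 0
    double m1 = std::min(cost[2] + c0, cost[3] + c1); // parent state 1
    S[2 * (size_t)p] += m0;
    S[2 * (size_t)p + 1] += m1;
  }
  int root = nTip; // node nTip+1, 0-based nTip
  return std::min(S[2 * (size_t)root], S[2 * (size_t)root + 1]);
}

// [[Rcpp::export]]
double cpp_sankoff(IntegerVector parent, IntegerVector child,
                   int nTip, int nNode, IntegerVector tipStates,
                   NumericMatrix costMat) {
  if (tipStates.size() != nTip) stop("tip state vector length mismatch");
  double cost[4] = {costMat(0, 0), costMat(0, 1), costMat(1, 0), costMat(1, 1)};
  std::vector<int> st(nTip);
  for (int i = 0; i < nTip; ++i) st[i] = tipStates[i];
  return sankoff_score(parent, child, nTip, nNode, st.data(), cost);
}

// [[Rcpp::export]]
NumericVector cpp_ms_null(IntegerVector parent, IntegerVector child,
                          int nTip, int nNode, IntegerVector tipStates,
                          NumericMatrix costMat, int nPerm) {
  if (tipStates.size() != nTip) stop("tip state vector length mismatch");
  double cost[4] = {costMat(0, 0), costMat(0, 1), costMat(1, 0), costMat(1, 1)};
  std::vector<int> st(nTip);
  for (int i = 0; i < nTip; ++i) st[i] = tipStates[i];
  NumericVector out(nPerm);
  GetRNGstate();
  for (int r = 0; r < nPerm; ++r) {
    // Fisher-Yates shuffle preserving state counts
    for (int i = nTip - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(st[i], st[j]);
    }
    out[r] = sankoff_score(parent, child, nTip, nNode, st.data(), cost);
  }
  PutRNGstate();
  return out;
}
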