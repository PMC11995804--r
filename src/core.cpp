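// Hot loops: TFCE enhancement over a node graph, dwPLI accumulation over
// time samples, and pairwise affine-invariant Riemannian distances.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct UnionFind {
  std::vector<int> parent, size;
  UnionFind(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a; size[a] += size[b];
  }
};

} // namespace

// TFCE(p) = sum_h extent(cluster(p, h))^E * h^H * dh over height steps.
// values: nonnegative statistic per node; edges: 0-based m x 2 matrix of
// undirected graph edges; nSteps height steps of dh = max/nSteps.
// [[Rcpp::export]]
NumericVector tfce_enhance_cpp(NumericVector values, IntegerMatrix edges,
                               double E, double H, int nSteps) {
  const int n = values.size();
  NumericVector out(n, 0.0);
  double vmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (values[i] > vmax) vmax = values[i];
  if (vmax <= 0.0 || nSteps < 1) return out;
  const double dh = vmax / nSteps;
  const int m = edges.nrow();
  for (int s = 1; s <= nSteps; ++s) {
    const double h = s * dh;
    UnionFind uf(n);
    for (int e = 0; e < m; ++e) {
      const int a = edges(e, 0), b = edges(e, 1);
      if (values[a] >= h && values[b] >= h) uf.unite(a, b);
    }
    // cluster extents among supra-threshold nodes
    std::vector<int> extent(n, 0);
    for (int i = 0; i < n; ++i)
      if (values[i] >= h) extent[uf.find(i)]++;
    const double hH = std::pow(h, H);
    for (int i = 0; i < n; ++i) {
      if (values[i] < h) continue;
      const double ext = static_cast<double>(extent[uf.find(i)]);
      out[i] += std::pow(ext, E) * hH * dh;
    }
  }
  return out;
}

// dwPLI accumulators over valid time samples. X = complex coefficients
// (samples x sensors). Returns sum(I), sum(I^2), sum(|I|) with
// I_j(a,b) = Im(X_ja * conj(X_jb)).
// [[Rcpp::export]]
List dwpli_accumulate_cpp(arma::cx_mat X) {
  const arma::uword p = X.n_cols, nt = X.n_rows;
  arma::mat sumI(p, p, arma::fill::zeros);
  arma::mat sumI2(p, p, arma::fill::zeros);
  arma::mat sumAbsI(p, p, arma::fill::zeros);
  for (arma::uword j = 0; j < nt; ++j) {
    for (arma::uword a = 0; a < p; ++a) {
      const double ra = X(j, a).real(), ia = X(j, a).imag();
      for (arma::uword b = a + 1; b < p; ++b) {
        // Im(X_a conj(X_b)) = ia*rb - ra*ib
        const double I = ia * X(j, b).real() - ra * X(j, b).imag();
        sumI(a, b) += I;
        sumI2(a, b) += I * I;
        sumAbsI(a, b) += std::fabs(I);
      }
    }
  }
  sumI = sumI + sumI.t();
  sumI2 = sumI2 + sumI2.t();
  sumAbsI = sumAbsI + sumAbsI.t();
  return List::create(_["sumI"] = sumI, _["sumI2"] = sumI2,
                      _["sumAbsI"] = sumAbsI);
}

// Pairwise AIRM distances d(A,B) = ||logm(A^-1/2 B A^-1/2)||_F for a cube
// of SPD matrices (r x r x n).
// [[Rcpp::export]]
arma::mat pairwise_airm_cpp(arma::cube M) {
  const arma::uword n = M.n_slices, r = M.n_rows;
  std::vector<arma::mat> invsqrt(n);
  for (arma::uword i = 0; i < n; ++i) {
    arma::vec eval; arma::mat evec;
    if (!arma::eig_sym(eval, evec, M.slice(i)))
      stop("eigendecomposition failed");
    if (eval.min() <= 0) stop("matrix %d is not positive definite", (int)i + 1);
    invsqrt[i] = evec * arma::diagmat(1.0 / arma::sqrt(eval)) * evec.t();
  }
  arma::mat D(n, n, arma::fill::zeros);
  arma::vec eval(r);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = i + 1; j < n; ++j) {
      arma::mat W = invsqrt[i] * M.slice(j) * invsqrt[i];
      W = 0.5 * (W + W.t());
      if (!arma::eig_sym(eval, W)) stop("eigendecomposition failed");
      if (eval.min() <= 0) stop("non-SPD product encountered");
      const double d = arma::norm(arma::log(eval), 2);
      D(i, j) = d; D(j, i) = d;
    }
  }
  return D;
}
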