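// Pruning (Felsenstein) likelihood machinery for K-state Mk models.
// Trees arrive as ape edge matrices in postorder; transition matrices are
// cached per unique branch length since Q is shared across edges.
#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// Transition kernels P(t) for every unique branch length. When Q has a
// well-conditioned eigendecomposition, P(t) = V exp(diag(lambda) t) V^-1 is
// far cheaper than a Pade exponential per edge; the decomposition is
// verified by reconstruction and the scaling-and-squaring Pade route is the
// fallback (non-reversible structures can be defective).
static std::map<double, arma::mat>
edge_kernels(const arma::mat& Q, const arma::vec& lens) {
  std::map<double, arma::mat> cache;
  const int K = Q.n_rows;
  arma::cx_vec lam;
  arma::cx_mat V;
  bool eig_ok = false;
  arma::cx_mat Vinv;
  if (arma::eig_gen(lam, V, Q)) {
    if (arma::inv(Vinv, V)) {
      arma::mat rec = arma::real(V * arma::diagmat(lam) * Vinv);
      double scale = arma::norm(Q, "fro") + 1.0;
      eig_ok = arma::norm(rec - Q, "fro") / scale < 1e-12;
    }
  }
  for (arma::uword i = 0; i < lens.n_elem; ++i) {
    double t = lens(i);
    if (cache.find(t) != cache.end()) continue;
    arma::mat P;
    if (eig_ok) {
      P = arma::real(V * arma::diagmat(arma::exp(lam * t)) * Vinv);
      P.clamp(0.0, arma::datum::inf);
      for (int r = 0; r < K; ++r) {
        double s = arma::accu(P.row(r));
        if (s > 0) P.row(r) /= s;
      }
    } else {
      P = arma::expmat(Q * t);
    }
    cache[t] = P;
  }
  return cache;
}

// Post-order conditional likelihoods. edge is the ape edge matrix (1-based,
// postorder: every child row precedes its parent's own child row), tip_part
// is n_tip x K. Returns the root partial (rescaled), the accumulated log
// scaling factor, and optionally the per-node partials for two-pass
// algorithms (each row rescaled to sum 1).
// [[Rcpp::export]]
List cpp_mk_partials(const arma::imat& edge, const arma::vec& edge_length,
                     int n_tip, const arma::mat& tip_part, const arma::mat& Q,
                     bool return_all = false) {
  const int K = Q.n_rows;
  const int n_node = edge.max();
  arma::mat part(n_node, K, arma::fill::ones);
  part.rows(0, n_tip - 1) = tip_part;
  std::map<double, arma::mat> P = edge_kernels(Q, edge_length);
  double logscale = 0.0;
  bool impossible = false;

  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int parent = edge(e, 0) - 1;
    int child = edge(e, 1) - 1;
    arma::rowvec ch = part.row(child);
    double m = ch.max();
    if (m <= 0.0) { impossible = true; break; }
    ch /= m;
    logscale += std::log(m);
    part.row(child) = ch;  // store rescaled for return_all consumers
    const arma::mat& Pt = P[edge_length(e)];
    part.row(parent) %= (Pt * ch.t()).t();
  }

  int root = n_tip;  // ape convention: root is node n_tip + 1 (1-based)
  List out;
  if (impossible) {
    out["root"] = NumericVector(K, 0.0);
    out["logscale"] = R_NegInf;
    out["impossible"] = true;
  } else {
    arma::rowvec rp = part.row(root);
    double m = rp.max();
    if (m <= 0.0) {
      out["root"] = NumericVector(K, 0.0);
      out["logscale"] = R_NegInf;
      out["impossible"] = true;
    } else {
      rp /= m;
      logscale += std::log(m);
      part.row(root) = rp;
      out["root"] = NumericVector(rp.begin(), rp.end());
      out["logscale"] = logscale;
      out["impossible"] = false;
    }
  }
  if (return_all) out["partials"] = wrap(part);
  return out;
}

// Log-likelihood with an explicit root prior vector (uniform/stationary/
// fixed priors resolve to a vector in R; the FitzJohn weighting is applied
// in R from the returned root partial).
// [[Rcpp::export]]
double cpp_mk_loglik(const arma::imat& edge, const arma::vec& edge_length,
                     int n_tip, const arma::mat& tip_part, const arma::mat& Q,
                     const arma::vec& root_prior) {
  List res = cpp_mk_partials(edge, edge_length, n_tip, tip_part, Q, false);
  if (as<bool>(res["impossible"])) return R_NegInf;
  NumericVector root = res["root"];
  double logscale = as<double>(res["logscale"]);
  double s = 0.0;
  for (int k = 0; k < root.size(); ++k) s += root[k] * root_prior(k);
  if (s <= 0.0) return R_NegInf;
  return std::log(s) + logscale;
}
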