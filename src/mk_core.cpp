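// Felsenstein pruning for k-state continuous-time Markov models.
// The generator is eigendecomposed once per call; per-edge transition
// matrices are then a diagonal exponential, with a scaling-and-squaring
// fallback when the eigenbasis is ill-conditioned.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct QExp {
  bool use_eig;
  cx_vec eigval;
  cx_mat eigvec;
  cx_mat eiginv;
  mat Q;

  explicit QExp(const mat& Qin) : Q(Qin) {
    use_eig = eig_gen(eigval, eigvec, Qin);
    if (use_eig) {
      cx_mat inv_try;
      use_eig = inv(inv_try, eigvec);
      if (use_eig && rcond(abs(eigvec)) > 1e-12) {
        eiginv = inv_try;
      } else {
        use_eig = false;
      }
    }
  }

  mat P(double t) const {
    if (t <= 0.0) return eye(Q.n_rows, Q.n_rows);
    mat out;
    if (use_eig) {
      out = real(eigvec * diagmat(exp(eigval * t)) * eiginv);
    } else {
      out = expmat(Q * t);
    }
    out.transform([](double v) { return v < 0.0 ? 0.0 : v; });
    return out;
  }
};

} // namespace

// Lower conditional likelihoods by pruning. `edge` is the 2-column ape edge
// matrix in postorder (1-based node ids, tips 1..ntip), `tipL` the ntip x k
// tip likelihood matrix (rows of ones encode missing data).
// [[Rcpp::export]]
Rcpp::List cpp_mk_conditionals(const arma::imat& edge,
                               const arma::vec& elen,
                               const arma::mat& Q,
                               const arma::mat& tipL,
                               const arma::vec& prior,
                               int n_node) {
  const int ntip = tipL.n_rows;
  const int k = Q.n_rows;
  const int ntot = ntip + n_node;
  QExp qe(Q);

  mat L(ntot, k, fill::ones);
  L.rows(0, ntip - 1) = tipL;
  double logscale = 0.0;

  for (uword i = 0; i < edge.n_rows; ++i) {
    const int p = edge(i, 0) - 1;
    const int c = edge(i, 1) - 1;
    const rowvec lc = (qe.P(elen(i)) * L.row(c).t()).t();
    const double s = accu(lc);
    if (s <= 0.0 || !std::isfinite(s)) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                                Rcpp::Named("L") = L,
                                Rcpp::Named("logscale") = logscale);
    }
    L.row(p) %= lc / s;
    logscale += std::log(s);
  }

  const int root = edge(edge.n_rows - 1, 0) - 1;
  const double rootlik = dot(prior, L.row(root).t());
  double loglik = (rootlik > 0.0) ? std::log(rootlik) + logscale : R_NegInf;
  return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("L") = L,
                            Rcpp::Named("logscale") = logscale);
}

// [[Rcpp::export]]
double cpp_mk_loglik(const arma::imat& edge,
                     const arma::vec& elen,
                     const arma::mat& Q,
                     const arma::mat& tipL,
                     const arma::vec& prior,
                     int n_node) {
  const int ntip = tipL.n_rows;
  const int k = Q.n_rows;
  QExp qe(Q);

  mat L(ntip + n_node, k, fill::ones);
  L.rows(0, ntip - 1) = tipL;
  double logscale = 0.0;

  for (uword i = 0; i < edge.n_rows; ++i) {
    const int p = edge(i, 0) - 1;
    const int c = edge(i, 1) - 1;
    const rowvec lc = (qe.P(elen(i)) * L.row(c).t()).t();
    const double s = accu(lc);
    if (s <= 0.0 || !std::isfinite(s)) return R_NegInf;
    L.row(p) %= lc / s;
    logscale += std::log(s);
  }

  const int root = edge(edge.n_rows - 1, 0) - 1;
  const double rootlik = dot(prior, L.row(root).t());
  return (rootlik > 0.0) ? std::log(rootlik) + logscale : R_NegInf;
}

// Transition matrices for a set of branch lengths, stacked as a k x (k*n)
// matrix (column blocks), sharing one eigendecomposition.
// [[Rcpp::export]]
arma::mat cpp_transition_stack(const arma::mat& Q, const arma::vec& times) {
  const int k = Q.n_rows;
  QExp qe(Q);
  mat out(k, k * times.n_elem);
  for (uword i = 0; i < times.n_elem; ++i) {
    out.cols(i * k, (i + 1) * k - 1) = qe.P(times(i));
  }
  return out;
}
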