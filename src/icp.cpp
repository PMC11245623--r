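// Point-to-point ICP core: brute-force nearest neighbours + Kabsch update.
// Kept in C++ because the classifier builds all-pairs similarity matrices,
// making registration the hot path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// index (0-based) of nearest target row for each source row; ties keep the
// lowest index (strict < comparison while scanning in order)
static arma::uvec nearest_idx(const arma::mat& src, const arma::mat& tgt,
                              arma::vec& d2_out) {
  const arma::uword n = src.n_rows, m = tgt.n_rows;
  arma::uvec idx(n);
  d2_out.set_size(n);
  for (arma::uword i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    arma::uword bj = 0;
    const double sx = src(i, 0), sy = src(i, 1), sz = src(i, 2);
    for (arma::uword j = 0; j < m; ++j) {
      const double dx = sx - tgt(j, 0), dy = sy - tgt(j, 1),
                   dz = sz - tgt(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx(i) = bj;
    d2_out(i) = best;
  }
  return idx;
}

// [[Rcpp::export]]
IntegerVector cpp_nearest_indices(const arma::mat& src,
                                  const arma::mat& tgt) {
  arma::vec d2;
  arma::uvec idx = nearest_idx(src, tgt, d2);
  IntegerVector out(idx.n_elem);
  for (arma::uword i = 0; i < idx.n_elem; ++i) out[i] = idx(i) + 1; // 1-based
  return out;
}

// least-squares rigid transform (Kabsch, reflection-corrected):
// y ~ R x + t for paired rows of src/tgt
static void kabsch(const arma::mat& src, const arma::mat& tgt,
                   arma::mat& R, arma::vec& t) {
  arma::rowvec cs = arma::mean(src, 0), ct = arma::mean(tgt, 0);
  arma::mat Xc = src.each_row() - cs;
  arma::mat Yc = tgt.each_row() - ct;
  arma::mat H = Xc.t() * Yc;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  R = V * D * U.t();
  t = ct.t() - R * cs.t();
}

// [[Rcpp::export]]
List cpp_best_rigid(const arma::mat& src, const arma::mat& tgt) {
  arma::mat R;
  arma::vec t;
  kabsch(src, tgt, R, t);
  return List::create(_["rotation"] = R, _["translation"] = t);
}

// [[Rcpp::export]]
List cpp_icp(const arma::mat& src, const arma::mat& tgt,
             const int max_iterations, const double tolerance) {
  arma::mat R = arma::eye(3, 3);
  arma::vec t = arma::zeros(3);
  std::vector<double> trace;
  double prev = std::numeric_limits<double>::infinity();
  bool converged = false;
  int iter = 0;
  arma::vec d2;
  for (iter = 1; iter <= max_iterations; ++iter) {
    arma::mat moved = src * R.t();
    moved.each_row() += t.t();
    arma::uvec idx = nearest_idx(moved, tgt, d2);
    const double mse = arma::mean(d2);
    trace.push_back(mse);
    // relative change, with an absolute floor so exact alignment terminates
    if (std::fabs(prev - mse) <= tolerance * std::max(mse, 1e-12)) {
      converged = true;
      break;
    }
    prev = mse;
    if (iter == max_iterations) break;
    arma::mat matched = tgt.rows(idx);
    arma::mat Rs;
    arma::vec ts;
    kabsch(moved, matched, Rs, ts);
    R = Rs * R;
    t = Rs * t + ts;
  }
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["mse"] = trace.back(),
                      _["mse_trace"] = NumericVector(trace.begin(),
                                                     trace.end()),
                      _["n_iterations"] = (int)trace.size(),
                      _["converged"] = converged);
}
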