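// Core numerical kernels: 3x3 matrix exponential (scaling-and-squaring Pade,
// via Armadillo) and the panel-observed CTMC log-likelihood. The likelihood
// loop is the hot path of fitting: one generator build per covariate pattern
// and one matrix exponential per distinct (pattern, interval length).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Off-diagonal transition order, fixed package-wide:
// (1,2),(1,3),(2,1),(2,3),(3,1),(3,2)
static const arma::uword TR_FROM[6] = {0, 0, 1, 1, 2, 2};
static const arma::uword TR_TO[6]   = {1, 2, 0, 2, 0, 1};

static arma::mat build_generator(const arma::vec& rates) {
  arma::mat Q(3, 3, arma::fill::zeros);
  for (arma::uword k = 0; k < 6; ++k) Q(TR_FROM[k], TR_TO[k]) = rates(k);
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

//' @noRd
// [[Rcpp::export(name = ".expm_cpp")]]
arma::mat expm_cpp(const arma::mat& m) {
  return arma::expmat(m);
}

// Per-record log-likelihood contributions wt * log P_{from,to}(dt; Q(x_grp)).
// log_rates: 6-vector of log baseline intensities (-Inf allowed => rate 0).
// beta: 6 x p matrix of log hazard ratios; X: ngrp x p centered covariates.
// grp/from/to are 1-based; records must be sorted by grp (dt order free but
// grouping identical dt together avoids recomputing the exponential).
// [[Rcpp::export(name = ".panel_loglik_terms_cpp")]]
arma::vec panel_loglik_terms_cpp(const arma::vec& log_rates,
                                 const arma::mat& beta,
                                 const arma::mat& X,
                                 const arma::uvec& grp,
                                 const arma::uvec& from,
                                 const arma::uvec& to,
                                 const arma::vec& dt,
                                 const arma::vec& wt) {
  const arma::uword m = from.n_elem;
  arma::vec out(m, arma::fill::zeros);
  arma::uword cur_grp = arma::uword(-1);
  double cur_dt = -1.0;
  arma::mat Q, P;
  const double neg_inf = -std::numeric_limits<double>::infinity();

  for (arma::uword r = 0; r < m; ++r) {
    const arma::uword g = grp(r) - 1;
    if (g != cur_grp) {
      arma::vec eta = log_rates;
      if (beta.n_cols > 0) eta += beta * X.row(g).t();
      Q = build_generator(arma::exp(eta));
      cur_grp = g;
      cur_dt = -1.0;
    }
    if (dt(r) != cur_dt) {
      // guard against the extreme generators a line search can visit:
      // exp(Q dt) is then numerically meaningless, treat as zero likelihood
      const arma::mat A = Q * dt(r);
      if (!A.is_finite() || arma::abs(A).max() > 1e4) {
        P.set_size(3, 3);
        P.fill(arma::datum::nan);
      } else {
        try {
          P = arma::expmat(A);
        } catch (...) {
          P.set_size(3, 3);
          P.fill(arma::datum::nan);
        }
      }
      cur_dt = dt(r);
    }
    const double p = P(from(r) - 1, to(r) - 1);
    if (!std::isfinite(p) || p <= 0.0) {
      out(r) = neg_inf;
    } else {
      out(r) = wt(r) * std::log(p);
    }
  }
  return out;
}
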