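#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Random-walk Kalman filter / RTS smoother for the gas-exchange
// decomposition. State x = [rest_vo2, rest_vco2, cost_vo2, cost_vco2],
// identity dynamics with diagonal process noise q. Observations
//   vo2(k)  = rest_vo2(k)  + cost_vo2(k)  * a(k) + e1,
//   vco2(k) = rest_vco2(k) + cost_vco2(k) * a(k) + e2,
// with diagonal observation noise r. Missing samples are predicted through
// (no update), so state variance inflates naturally across gaps.
// [[Rcpp::export]]
List kalman_rw_cpp(const arma::mat& y,        // n x 2 (NA allowed when miss)
                   const arma::vec& a,        // activity, length n
                   const LogicalVector& miss, // skip update where true
                   const arma::vec& q,        // process noise variances (4)
                   const arma::vec& r,        // obs noise variances (2)
                   const arma::vec& x0,
                   const arma::vec& p0,       // prior variances (4)
                   const bool do_smooth) {
  const arma::uword n = y.n_rows;
  arma::mat xf(4, n);          // filtered means
  arma::cube Pf(4, 4, n);      // filtered covariances
  arma::mat Q = arma::diagmat(q);
  arma::mat R = arma::diagmat(r);

  arma::vec x = x0;
  arma::mat P = arma::diagmat(p0);

  for (arma::uword k = 0; k < n; ++k) {
    // predict (F = I)
    if (k > 0) P += Q;
    bool use = !miss[k] && std::isfinite(y(k, 0)) && std::isfinite(y(k, 1));
    if (use) {
      arma::mat H(2, 4, arma::fill::zeros);
      H(0, 0) = 1.0; H(0, 2) = a[k];
      H(1, 1) = 1.0; H(1, 3) = a[k];
      arma::mat S = H * P * H.t() + R;
      arma::mat K = P * H.t() * arma::inv_sympd(S);
      x += K * (y.row(k).t() - H * x);
      arma::mat IKH = arma::eye(4, 4) - K * H;
      P = IKH * P * IKH.t() + K * R * K.t();  // Joseph form
    }
    xf.col(k) = x;
    Pf.slice(k) = P;
  }

  arma::mat xs = xf;
  arma::mat vs(4, n);
  if (do_smooth && n > 1) {
    arma::cube Ps(4, 4, 1);
    arma::mat Psk = Pf.slice(n - 1);
    vs.col(n - 1) = Psk.diag();
    for (arma::uword k = n - 1; k-- > 0;) {
      arma::mat Ppred = Pf.slice(k) + Q;        // predicted cov at k+1 (F = I)
      arma::mat G = Pf.slice(k) * arma::inv_sympd(Ppred);
      xs.col(k) = xf.col(k) + G * (xs.col(k + 1) - xf.col(k));
      Psk = Pf.slice(k) + G * (Psk - Ppred) * G.t();
      vs.col(k) = Psk.diag();
    }
  } else {
    for (arma::uword k = 0; k < n; ++k) vs.col(k) = Pf.slice(k).diag();
  }

  arma::mat vf(4, n);
  for (arma::uword k = 0; k < n; ++k) vf.col(k) = Pf.slice(k).diag();

  return List::create(_["state"] = xs.t(),
                      _["state_var"] = vs.t(),
                      _["filtered"] = xf.t(),
                      _["filtered_var"] = vf.t());
}
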