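// Single-layer, single-direction LSTM forward and backward passes.
// Layer stacking, direction reversal and dropout are orchestrated from R;
// keeping the time recursion in C++ is what makes CPU training viable.
//
// Gate layout in the 4H rows of Wx / Wh / b: [input; forget; cell; output].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigm(const arma::vec& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// [[Rcpp::export]]
List lstm_cell_forward(const arma::mat& X, const arma::mat& Wx,
                       const arma::mat& Wh, const arma::vec& b) {
  const int n = X.n_rows;
  const int H = Wh.n_cols;
  arma::mat G(n, 4 * H), Hs(n, H), Cs(n, H), Tc(n, H);
  arma::vec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
  for (int t = 0; t < n; ++t) {
    arma::vec a = Wx * X.row(t).t() + Wh * h + b;
    arma::vec i = sigm(a.subvec(0, H - 1));
    arma::vec f = sigm(a.subvec(H, 2 * H - 1));
    arma::vec g = arma::tanh(a.subvec(2 * H, 3 * H - 1));
    arma::vec o = sigm(a.subvec(3 * H, 4 * H - 1));
    c = f % c + i % g;
    arma::vec tc = arma::tanh(c);
    h = o % tc;
    G(t, arma::span(0, H - 1)) = i.t();
    G(t, arma::span(H, 2 * H - 1)) = f.t();
    G(t, arma::span(2 * H, 3 * H - 1)) = g.t();
    G(t, arma::span(3 * H, 4 * H - 1)) = o.t();
    Cs.row(t) = c.t();
    Tc.row(t) = tc.t();
    Hs.row(t) = h.t();
  }
  return List::create(_["H"] = Hs, _["G"] = G, _["C"] = Cs, _["Tc"] = Tc);
}

// [[Rcpp::export]]
List lstm_cell_backward(const arma::mat& X, const arma::mat& Wx,
                        const arma::mat& Wh, const List& cache,
                        const arma::mat& dH) {
  const int n = X.n_rows;
  const int H = Wh.n_cols;
  const arma::mat Hs = cache["H"], G = cache["G"], Cs = cache["C"], Tc = cache["Tc"];
  arma::mat dX(n, X.n_cols, arma::fill::zeros);
  arma::mat dWx(arma::size(Wx), arma::fill::zeros);
  arma::mat dWh(arma::size(Wh), arma::fill::zeros);
  arma::vec db(4 * H, arma::fill::zeros);
  arma::vec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
  for (int t = n - 1; t >= 0; --t) {
    arma::vec i = G(t, arma::span(0, H - 1)).t();
    arma::vec f = G(t, arma::span(H, 2 * H - 1)).t();
    arma::vec g = G(t, arma::span(2 * H, 3 * H - 1)).t();
    arma::vec o = G(t, arma::span(3 * H, 4 * H - 1)).t();
    arma::vec tc = Tc.row(t).t();
    arma::vec c_prev = (t > 0) ? arma::vec(Cs.row(t - 1).t())
                               : arma::vec(H, arma::fill::zeros);
    arma::vec h_prev = (t > 0) ? arma::vec(Hs.row(t - 1).t())
                               : arma::vec(H, arma::fill::zeros);
    arma::vec dh = dH.row(t).t() + dh_next;
    arma::vec dc = dc_next + dh % o % (1.0 - tc % tc);
    arma::vec da(4 * H);
    da.subvec(0, H - 1) = dc % g % i % (1.0 - i);
    da.subvec(H, 2 * H - 1) = dc % c_prev % f % (1.0 - f);
    da.subvec(2 * H, 3 * H - 1) = dc % i % (1.0 - g % g);
    da.subvec(3 * H, 4 * H - 1) = dh % tc % o % (1.0 - o);
    dWx += da * X.row(t);
    dWh += da * h_prev.t();
    db += da;
    dX.row(t) = (Wx.t() * da).t();
    dh_next = Wh.t() * da;
    dc_next = dc % f;
  }
  return List::create(_["dX"] = dX, _["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db);
}
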