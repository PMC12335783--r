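// Recurrent sequence kernels (LSTM / GRU) with hand-derived backward passes.
// Layout: X is a (batch x channels x time) cube; hidden states are
// (batch x units x time). Gate order: LSTM [i, f, g, o]; GRU [r, z, n].
// `reverse = true` runs the cell backwards in time (for the backward
// direction of a bidirectional layer) without any data reshuffling.
// Inner loops write through slice references to avoid per-step allocation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword phys(arma::uword s, arma::uword T, bool rev) {
  return rev ? (T - 1 - s) : s;
}

// [[Rcpp::export(name = ".lstm_forward_cpp")]]
List lstm_forward_cpp(const arma::cube& X, const arma::mat& W,
                      const arma::mat& U, const arma::rowvec& b,
                      const bool reverse) {
  const arma::uword B = X.n_rows, T = X.n_slices, H = U.n_rows;
  arma::cube Hs(B, H, T), Cs(B, H, T), G(B, 4 * H, T);
  arma::mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  arma::mat A(B, 4 * H);
  // batch the input projection X_t * W over all timesteps in one GEMM
  arma::mat S(B * T, X.n_cols);
  for (arma::uword t = 0; t < T; ++t) S.rows(t * B, t * B + B - 1) = X.slice(t);
  const arma::mat XW = S * W;
  for (arma::uword s = 0; s < T; ++s) {
    const arma::uword t = phys(s, T, reverse);
    A = XW.rows(t * B, t * B + B - 1);
    A += h * U;
    A.each_row() += b;
    arma::mat& Gs = G.slice(t);
    Gs.cols(0, 2 * H - 1) = 1.0 / (1.0 + arma::exp(-A.cols(0, 2 * H - 1)));
    Gs.cols(2 * H, 3 * H - 1) = arma::tanh(A.cols(2 * H, 3 * H - 1));
    Gs.cols(3 * H, 4 * H - 1) =
        1.0 / (1.0 + arma::exp(-A.cols(3 * H, 4 * H - 1)));
    c = Gs.cols(H, 2 * H - 1) % c + Gs.cols(0, H - 1) % Gs.cols(2 * H, 3 * H - 1);
    h = Gs.cols(3 * H, 4 * H - 1) % arma::tanh(c);
    Cs.slice(t) = c;
    Hs.slice(t) = h;
  }
  return List::create(_["H"] = Hs, _["C"] = Cs, _["G"] = G);
}

// [[Rcpp::export(name = ".lstm_backward_cpp")]]
List lstm_backward_cpp(const arma::cube& X, const arma::cube& dH,
                       const arma::cube& Hs, const arma::cube& Cs,
                       const arma::cube& G, const arma::mat& W,
                       const arma::mat& U, const bool reverse) {
  const arma::uword B = X.n_rows, C = X.n_cols, T = X.n_slices, H = U.n_rows;
  arma::cube dX(B, C, T);
  arma::mat dU(H, 4 * H, arma::fill::zeros);
  arma::rowvec db(4 * H, arma::fill::zeros);
  arma::mat dh_next(B, H, arma::fill::zeros), dc_next(B, H, arma::fill::zeros);
  const arma::mat zeros(B, H, arma::fill::zeros);
  arma::mat dA(B, 4 * H), dh(B, H), dc(B, H), tc(B, H);
  arma::mat dAall(B * T, 4 * H); // gate grads stacked for batched GEMMs
  for (arma::uword s = T; s-- > 0;) { // logical time, latest first
    const arma::uword t = phys(s, T, reverse);
    const arma::mat& Gs = G.slice(t);
    const auto i = Gs.cols(0, H - 1);
    const auto f = Gs.cols(H, 2 * H - 1);
    const auto g = Gs.cols(2 * H, 3 * H - 1);
    const auto o = Gs.cols(3 * H, 4 * H - 1);
    const arma::mat& c_prev = (s > 0) ? Cs.slice(phys(s - 1, T, reverse))
                                      : zeros;
    const arma::mat& h_prev = (s > 0) ? Hs.slice(phys(s - 1, T, reverse))
                                      : zeros;
    tc = arma::tanh(Cs.slice(t));
    dh = dH.slice(t) + dh_next;
    dc = dc_next + dh % o % (1.0 - tc % tc);
    dA.cols(0, H - 1) = (dc % g) % i % (1.0 - i);
    dA.cols(H, 2 * H - 1) = (dc % c_prev) % f % (1.0 - f);
    dA.cols(2 * H, 3 * H - 1) = (dc % i) % (1.0 - g % g);
    dA.cols(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);
    dc_next = dc % f;
    dAall.rows(t * B, t * B + B - 1) = dA;
    dU += h_prev.t() * dA;
    db += arma::sum(dA, 0);
    dh_next = dA * U.t();
  }
  // batched: dX_t = dA_t W', dW = sum_t X_t' dA_t
  arma::mat S(B * T, C);
  for (arma::uword t = 0; t < T; ++t) S.rows(t * B, t * B + B - 1) = X.slice(t);
  const arma::mat dXall = dAall * W.t();
  const arma::mat dW = S.t() * dAall;
  for (arma::uword t = 0; t < T; ++t) {
    dX.slice(t) = dXall.rows(t * B, t * B + B - 1);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["dU"] = dU,
                      _["db"] = db);
}

// GRU: r = s(xWr + hUr + br), z = s(xWz + hUz + bz),
//      n = tanh(xWn + bn + r % (hUn)), h' = (1-z) % n + z % h.
// Cached: G = [r, z, n] post-activation, HU = h_{t-1} * Un.

// [[Rcpp::export(name = ".gru_forward_cpp")]]
List gru_forward_cpp(const arma::cube& X, const arma::mat& W,
                     const arma::mat& U, const arma::rowvec& b,
                     const bool reverse) {
  const arma::uword B = X.n_rows, T = X.n_slices, H = U.n_rows;
  arma::cube Hs(B, H, T), G(B, 3 * H, T), HU(B, H, T);
  arma::mat h(B, H, arma::fill::zeros);
  arma::mat A(B, 3 * H), hU(B, 3 * H);
  arma::mat S(B * T, X.n_cols);
  for (arma::uword t = 0; t < T; ++t) S.rows(t * B, t * B + B - 1) = X.slice(t);
  const arma::mat XW = S * W;
  for (arma::uword s = 0; s < T; ++s) {
    const arma::uword t = phys(s, T, reverse);
    A = XW.rows(t * B, t * B + B - 1);
    A.each_row() += b;
    hU = h * U;
    arma::mat& Gs = G.slice(t);
    Gs.cols(0, 2 * H - 1) = 1.0 / (1.0 + arma::exp(-(A.cols(0, 2 * H - 1) +
                                                     hU.cols(0, 2 * H - 1))));
    HU.slice(t) = hU.cols(2 * H, 3 * H - 1);
    Gs.cols(2 * H, 3 * H - 1) =
        arma::tanh(A.cols(2 * H, 3 * H - 1) +
                   Gs.cols(0, H - 1) % hU.cols(2 * H, 3 * H - 1));
    h = (1.0 - Gs.cols(H, 2 * H - 1)) % Gs.cols(2 * H, 3 * H - 1) +
        Gs.cols(H, 2 * H - 1) % h;
    Hs.slice(t) = h;
  }
  return List::create(_["H"] = Hs, _["G"] = G, _["HU"] = HU);
}

// [[Rcpp::export(name = ".gru_backward_cpp")]]
List gru_backward_cpp(const arma::cube& X, const arma::cube& dH,
                      const arma::cube& Hs, const arma::cube& G,
                      const arma::cube& HU, const arma::mat& W,
                      const arma::mat& U, const bool reverse) {
  const arma::uword B = X.n_rows, C = X.n_cols, T = X.n_slices, H = U.n_rows;
  arma::cube dX(B, C, T);
  arma::mat dU(H, 3 * H, arma::fill::zeros);
  arma::rowvec db(3 * H, arma::fill::zeros);
  arma::mat dh_next(B, H, arma::fill::zeros);
  const arma::mat zeros(B, H, arma::fill::zeros);
  arma::mat dA(B, 3 * H), dHUm(B, 3 * H), dh(B, H), dan(B, H);
  arma::mat dAall(B * T, 3 * H);
  for (arma::uword s = T; s-- > 0;) {
    const arma::uword t = phys(s, T, reverse);
    const arma::mat& Gs = G.slice(t);
    const auto r = Gs.cols(0, H - 1);
    const auto z = Gs.cols(H, 2 * H - 1);
    const auto n = Gs.cols(2 * H, 3 * H - 1);
    const arma::mat& h_prev = (s > 0) ? Hs.slice(phys(s - 1, T, reverse))
                                      : zeros;
    dh = dH.slice(t) + dh_next;
    dan = (dh % (1.0 - z)) % (1.0 - n % n);     // pre-activation of n
    dA.cols(0, H - 1) = (dan % HU.slice(t)) % r % (1.0 - r);   // dar
    dA.cols(H, 2 * H - 1) = (dh % (h_prev - n)) % z % (1.0 - z); // daz
    dA.cols(2 * H, 3 * H - 1) = dan;
    dAall.rows(t * B, t * B + B - 1) = dA;
    db += arma::sum(dA, 0);
    // hidden-side weights: r,z parts share dA; n part flows through r % hUn
    dHUm.cols(0, 2 * H - 1) = dA.cols(0, 2 * H - 1);
    dHUm.cols(2 * H, 3 * H - 1) = dan % r;
    dU += h_prev.t() * dHUm;
    dh_next = dh % z + dHUm * U.t();
  }
  arma::mat S(B * T, C);
  for (arma::uword t = 0; t < T; ++t) S.rows(t * B, t * B + B - 1) = X.slice(t);
  const arma::mat dXall = dAall * W.t();
  const arma::mat dW = S.t() * dAall;
  for (arma::uword t = 0; t < T; ++t) {
    dX.slice(t) = dXall.rows(t * B, t * B + B - 1);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["dU"] = dU,
                      _["db"] = db);
}
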