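// Batched LSTM forward / backward pass.
//
// Parameter layout: per layer one fused weight matrix W (4*H x (H + I_l)) and
// bias vector B (4*H), row blocks ordered forget, input, candidate, output.
// Each gate sees the concatenation [h_{t-1}, x_t] (hidden part first).
// Sequences are packed in a cube X of dimension (I x B x T): slice t holds the
// inputs of all B sequences at time t.  All sequences in a batch share T.
//
// The backward pass is exact reverse-mode differentiation of the forward
// recursion with a linear readout and mean-squared-error loss over all
// (t, b) cells; it is checked against central finite differences in the
// test suite.
//
// The concatenated inputs A_t and the gate activations are cached per time
// step during the forward sweep so the backward sweep reuses them without
// re-allocating.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List lstm_pass_cpp(const Rcpp::List& W_list,
                         const Rcpp::List& B_list,
                         const arma::vec& w_y,
                         const double b_y,
                         const arma::cube& X,
                         const arma::mat& Y,
                         const bool grad) {
  const uword L  = W_list.size();
  const uword H  = w_y.n_elem;
  const uword Bn = X.n_cols;
  const uword T  = X.n_slices;

  std::vector<mat> W(L);
  std::vector<vec> Bv(L);
  for (uword l = 0; l < L; ++l) {
    W[l]  = Rcpp::as<mat>(W_list[l]);
    Bv[l] = Rcpp::as<vec>(B_list[l]);
  }

  // caches per layer: concatenated inputs A (H+I x B x T), gate block
  // Z -> activations (4H x B x T), cell states and tanh(c) (H x B x T)
  std::vector<cube> AS(L), GS(L), cS(L), tcS(L);
  cube top(H, Bn, T);  // hidden states of the top layer

  cube cur = X;  // input to the current layer
  for (uword l = 0; l < L; ++l) {
    const uword I = W[l].n_cols - H;
    AS[l].set_size(H + I, Bn, T);
    GS[l].set_size(4 * H, Bn, T);
    cS[l].set_size(H, Bn, T);
    tcS[l].set_size(H, Bn, T);

    mat h(H, Bn, fill::zeros), c(H, Bn, fill::zeros);
    cube out(H, Bn, T);
    for (uword t = 0; t < T; ++t) {
      mat& A = AS[l].slice(t);
      A.rows(0, H - 1) = h;
      A.rows(H, H + I - 1) = cur.slice(t);
      mat& G = GS[l].slice(t);
      G = W[l] * A;
      G.each_col() += Bv[l];
      // f, i sigmoid; candidate tanh; o sigmoid
      G.rows(0, 2 * H - 1) = 1.0 / (1.0 + exp(-G.rows(0, 2 * H - 1)));
      G.rows(2 * H, 3 * H - 1) = tanh(G.rows(2 * H, 3 * H - 1));
      G.rows(3 * H, 4 * H - 1) =
        1.0 / (1.0 + exp(-G.rows(3 * H, 4 * H - 1)));
      c = G.rows(0, H - 1) % c + G.rows(H, 2 * H - 1) % G.rows(2 * H, 3 * H - 1);
      cS[l].slice(t) = c;
      tcS[l].slice(t) = tanh(c);
      h = G.rows(3 * H, 4 * H - 1) % tcS[l].slice(t);
      out.slice(t) = h;
    }
    cur = out;
    if (l == L - 1) top = out;
  }

  // linear readout per time step
  mat P(T, Bn);
  for (uword t = 0; t < T; ++t) {
    P.row(t) = w_y.t() * top.slice(t) + b_y;
  }
  const double n = static_cast<double>(T) * static_cast<double>(Bn);
  const double loss = accu(square(P - Y)) / n;

  if (!grad) {
    return Rcpp::List::create(Rcpp::Named("loss")  = loss,
                              Rcpp::Named("preds") = P);
  }

  mat dY = 2.0 * (P - Y) / n;  // T x Bn

  vec dwy(H, fill::zeros);
  double dby = 0.0;
  cube dhext(H, Bn, T);
  for (uword t = 0; t < T; ++t) {
    dhext.slice(t) = w_y * dY.row(t);
    dwy += top.slice(t) * dY.row(t).t();
    dby += accu(dY.row(t));
  }

  Rcpp::List dW_out(L), dB_out(L);
  mat dz(4 * H, Bn);
  for (uword l = L; l-- > 0; ) {
    const uword I = W[l].n_cols - H;
    mat dW(4 * H, H + I, fill::zeros);
    vec dB(4 * H, fill::zeros);
    mat dhn(H, Bn, fill::zeros), dcn(H, Bn, fill::zeros);
    cube dX(I, Bn, T);

    for (uword t = T; t-- > 0; ) {
      const mat& G  = GS[l].slice(t);
      const mat& tc = tcS[l].slice(t);
      auto f  = G.rows(0, H - 1);
      auto ig = G.rows(H, 2 * H - 1);
      auto g  = G.rows(2 * H, 3 * H - 1);
      auto o  = G.rows(3 * H, 4 * H - 1);

      mat dh = dhext.slice(t) + dhn;
      mat dc = dcn + dh % o % (1.0 - tc % tc);
      if (t > 0) {
        dz.rows(0, H - 1) = (dc % cS[l].slice(t - 1)) % f % (1.0 - f);
      } else {
        dz.rows(0, H - 1).zeros();  // c_{-1} = 0
      }
      dz.rows(H, 2 * H - 1) = (dc % g) % ig % (1.0 - ig);
      dz.rows(2 * H, 3 * H - 1) = (dc % ig) % (1.0 - g % g);
      dz.rows(3 * H, 4 * H - 1) = (dh % tc) % o % (1.0 - o);

      const mat& A = AS[l].slice(t);
      dW += dz * A.t();
      dB += sum(dz, 1);
      mat dA = W[l].t() * dz;
      dhn = dA.rows(0, H - 1);
      dX.slice(t) = dA.rows(H, H + I - 1);
      dcn = dc % f;
    }
    dW_out[l] = dW;
    dB_out[l] = dB;
    if (l > 0) dhext = dX;
  }

  return Rcpp::List::create(Rcpp::Named("loss")  = loss,
                            Rcpp::Named("preds") = P,
                            Rcpp::Named("dW")    = dW_out,
                            Rcpp::Named("dB")    = dB_out,
                            Rcpp::Named("dwy")   = dwy,
                            Rcpp::Named("dby")   = dby);
}
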