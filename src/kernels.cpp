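// Compute kernels for the dual-path network: causal dilated 1-d convolution,
// LSTM, gated activations and temporal average pooling, forward and
// backward.
//
// Layouts: signal batches are cubes (channels x time x batch); conv weights
// are cubes (filters x in_channels x kernel) with slice k holding the tap
// applied to the sample lagged by (kernel - 1 - k) * dilation, so the last
// slice acts on the current sample.  LSTM caches use (units x batch x time)
// so each time step is one contiguous slice.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// A cube (C, T, B) viewed as the matrix (C, T*B) without copying.
static inline mat flat_view(const cube& X) {
  return mat(const_cast<double*>(X.memptr()), X.n_rows,
             X.n_cols * X.n_slices, false, true);
}

// [[Rcpp::export]]
arma::cube conv_causal_fw(const arma::cube& X, const arma::cube& W,
                          const arma::vec& b, const int dilation) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword F = W.n_rows, K = W.n_slices;
  if (W.n_cols != C) Rcpp::stop("conv weight in-channels mismatch");
  cube Y(F, T, B);
  mat Yf = flat_view(Y);
  const mat Xf = flat_view(X);
  // current-sample tap plus bias in one pass over the flattened batch
  Yf = W.slice(K - 1) * Xf;
  Yf.each_col() += b;
  mat Z;
  for (uword k = 0; k + 1 < K; ++k) {
    const uword s = (K - 1 - k) * (uword)dilation;
    if (s >= T) continue;
    Z = W.slice(k) * Xf;  // (F, T*B); add shifted within each slice
    for (uword bi = 0; bi < B; ++bi)
      Y.slice(bi).cols(s, T - 1) += Z.cols(bi * T, bi * T + T - 1 - s);
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv_causal_bw(const arma::cube& X, const arma::cube& W,
                          const arma::cube& dY, const int dilation,
                          const bool need_dx) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword F = W.n_rows, K = W.n_slices;
  cube dW(F, C, K, fill::zeros);
  vec db(F, fill::zeros);
  cube dX;
  const mat Xf = flat_view(X);
  const mat dYf = flat_view(dY);
  db = sum(dYf, 1);
  dW.slice(K - 1) = dYf * Xf.t();
  if (need_dx) {
    dX.zeros(C, T, B);
    flat_view(dX) = W.slice(K - 1).t() * dYf;
  }
  mat Xs, dYs, Z;
  for (uword k = 0; k + 1 < K; ++k) {
    const uword s = (K - 1 - k) * (uword)dilation;
    if (s >= T) continue;
    const uword L = T - s;
    Xs.set_size(C, L * B);
    dYs.set_size(F, L * B);
    for (uword bi = 0; bi < B; ++bi) {
      Xs.cols(bi * L, bi * L + L - 1) = X.slice(bi).cols(0, L - 1);
      dYs.cols(bi * L, bi * L + L - 1) = dY.slice(bi).cols(s, T - 1);
    }
    dW.slice(k) = dYs * Xs.t();
    if (need_dx) {
      Z = W.slice(k).t() * dYs;
      for (uword bi = 0; bi < B; ++bi)
        dX.slice(bi).cols(0, L - 1) += Z.cols(bi * L, bi * L + L - 1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// gated = tanh(f) * sigmoid(g), with both activations returned for backward
// [[Rcpp::export]]
Rcpp::List gated_act_fw(const arma::cube& f, const arma::cube& g) {
  cube tf = tanh(f);
  cube sg = 1.0 / (1.0 + exp(-g));
  cube gated = tf % sg;
  return Rcpp::List::create(Rcpp::Named("gated") = gated,
                            Rcpp::Named("tf") = tf,
                            Rcpp::Named("sg") = sg);
}

// [[Rcpp::export]]
Rcpp::List gated_act_bw(const arma::cube& d_gated, const arma::cube& tf,
                        const arma::cube& sg) {
  cube df = d_gated % sg % (1.0 - tf % tf);
  cube dg = d_gated % tf % sg % (1.0 - sg);
  return Rcpp::List::create(Rcpp::Named("df") = df, Rcpp::Named("dg") = dg);
}

static inline mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Gate order along the 4U axis: input, forget, cell candidate, output.
// Single bias vector (4U entries).  Returns the final hidden state and the
// caches needed by lstm_bw: gate activations G (4U, B, T), cell states
// Cs (U, B, T) and hidden states H (U, B, T).
// [[Rcpp::export]]
Rcpp::List lstm_fw(const arma::cube& X, const arma::mat& Wx,
                   const arma::mat& Wh, const arma::vec& b) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword U4 = Wx.n_rows, U = U4 / 4;
  if (Wx.n_cols != C || Wh.n_rows != U4 || Wh.n_cols != U || b.n_elem != U4)
    Rcpp::stop("lstm weight shape mismatch");
  // input projections for all steps at once
  cube P(U4, T, B);
  flat_view(P) = Wx * flat_view(X);
  cube G(U4, B, T), Cs(U, B, T), H(U, B, T);
  mat h(U, B, fill::zeros), c(U, B, fill::zeros);
  mat At(U4, B);
  for (uword t = 0; t < T; ++t) {
    for (uword bi = 0; bi < B; ++bi) At.col(bi) = P.slice(bi).col(t) + b;
    At += Wh * h;
    At.rows(0, 2 * U - 1) = sigmoid_m(At.rows(0, 2 * U - 1));
    At.rows(2 * U, 3 * U - 1) = tanh(At.rows(2 * U, 3 * U - 1));
    At.rows(3 * U, 4 * U - 1) = sigmoid_m(At.rows(3 * U, 4 * U - 1));
    c = At.rows(U, 2 * U - 1) % c + At.rows(0, U - 1) % At.rows(2 * U, 3 * U - 1);
    h = At.rows(3 * U, 4 * U - 1) % tanh(c);
    G.slice(t) = At;
    Cs.slice(t) = c;
    H.slice(t) = h;
  }
  return Rcpp::List::create(Rcpp::Named("h_last") = h,
                            Rcpp::Named("G") = G,
                            Rcpp::Named("C") = Cs,
                            Rcpp::Named("H") = H);
}

// [[Rcpp::export]]
Rcpp::List lstm_bw(const arma::cube& X, const arma::mat& Wx,
                   const arma::mat& Wh, const arma::cube& G,
                   const arma::cube& Cs, const arma::cube& H,
                   const arma::mat& dh_last, const bool need_dx) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword U4 = Wx.n_rows, U = U4 / 4;
  mat dWx(U4, C, fill::zeros), dWh(U4, U, fill::zeros);
  vec db(U4, fill::zeros);
  cube dX;
  if (need_dx) dX.zeros(C, T, B);
  // accumulate dA over time, then one big gemm against X for dWx
  cube dAall(U4, B, T);
  mat dh = dh_last, dc(U, B, fill::zeros);
  mat xt(C, B), dA(U4, B);
  for (uword ti = T; ti-- > 0;) {
    const mat& At = G.slice(ti);
    const mat gi = At.rows(0, U - 1);
    const mat gf = At.rows(U, 2 * U - 1);
    const mat gg = At.rows(2 * U, 3 * U - 1);
    const mat go = At.rows(3 * U, 4 * U - 1);
    mat tc = tanh(Cs.slice(ti));
    mat dgo = dh % tc % go % (1.0 - go);
    dc += dh % go % (1.0 - tc % tc);
    mat dgi = dc % gg % gi % (1.0 - gi);
    mat dgg = dc % gi % (1.0 - gg % gg);
    mat dgf(U, B);
    if (ti > 0) dgf = dc % Cs.slice(ti - 1) % gf % (1.0 - gf);
    else dgf.zeros();
    dA = join_cols(join_cols(dgi, dgf), join_cols(dgg, dgo));
    dAall.slice(ti) = dA;
    if (ti > 0) dWh += dA * H.slice(ti - 1).t();
    db += sum(dA, 1);
    dh = Wh.t() * dA;
    dc %= gf;
  }
  // dWx = sum_t dA_t x_t' : reorder dA to (U4, T*B) matching X's layout
  cube dAr(U4, T, B);
  for (uword t = 0; t < T; ++t)
    for (uword bi = 0; bi < B; ++bi)
      dAr.slice(bi).col(t) = dAall.slice(t).col(bi);
  dWx = flat_view(dAr) * flat_view(X).t();
  if (need_dx) flat_view(dX) = Wx.t() * flat_view(dAr);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh,
                            Rcpp::Named("db") = db);
}

// Non-overlapping temporal average pooling; trailing remainder dropped.
// [[Rcpp::export]]
arma::cube avgpool_fw(const arma::cube& X, const int p) {
  const uword C = X.n_rows, T = X.n_cols, B = X.n_slices;
  const uword Tp = T / (uword)p;
  cube Y(C, Tp, B, fill::zeros);
  for (uword bi = 0; bi < B; ++bi)
    for (uword t = 0; t < Tp; ++t)
      Y.slice(bi).col(t) =
        mean(X.slice(bi).cols(t * (uword)p, (t + 1) * (uword)p - 1), 1);
  return Y;
}

// [[Rcpp::export]]
arma::cube avgpool_bw(const arma::cube& dY, const int p, const int T_in) {
  const uword Tp = dY.n_cols, B = dY.n_slices;
  cube dX(dY.n_rows, (uword)T_in, B, fill::zeros);
  for (uword bi = 0; bi < B; ++bi)
    for (uword t = 0; t < Tp; ++t)
      dX.slice(bi).cols(t * (uword)p, (t + 1) * (uword)p - 1) =
        repmat(dY.slice(bi).col(t) / (double)p, 1, (uword)p);
  return dX;
}

// Direct-form II transposed IIR filtering with initial state zi
// (length max(len(a), len(b)) - 1); coefficients normalized by a[0].
// [[Rcpp::export]]
arma::vec iir_filter(const arma::vec& b, const arma::vec& a,
                     const arma::vec& x, const arma::vec& zi) {
  const uword nb = b.n_elem, na = a.n_elem;
  const uword nf = std::max(nb, na);
  vec bb(nf, fill::zeros), aa(nf, fill::zeros);
  bb.head(nb) = b / a(0);
  aa.head(na) = a / a(0);
  vec z(nf - 1, fill::zeros);
  if (zi.n_elem == nf - 1) z = zi;
  const uword n = x.n_elem;
  vec y(n);
  for (uword i = 0; i < n; ++i) {
    const double xi = x(i);
    const double yi = bb(0) * xi + z(0);
    for (uword j = 1; j < nf - 1; ++j)
      z(j - 1) = bb(j) * xi + z(j) - aa(j) * yi;
    z(nf - 2) = bb(nf - 1) * xi - aa(nf - 1) * yi;
    y(i) = yi;
  }
  return y;
}
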