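// Attention-LSTM sequence classifier: forward pass, class-weighted
// cross-entropy and full backpropagation-through-time, shared by training
// and inference. Input epochs arrive as samples x channels x trials arrays.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigmoidm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  cube G;   // B x 4H x T gate activations (i, f, g, o)
  cube C;   // B x H x T cell states
  cube H;   // B x H x T hidden states
};

static void lstm_forward(const cube& In, const mat& W, const mat& U,
                         const rowvec& b, LstmCache& cache) {
  const int B = In.n_rows, T = In.n_slices, H = U.n_rows;
  cache.G.set_size(B, 4 * H, T);
  cache.C.set_size(B, H, T);
  cache.H.set_size(B, H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat A = In.slice(t) * W + h * U;
    A.each_row() += b;
    mat i = sigmoidm(A.cols(0, H - 1));
    mat f = sigmoidm(A.cols(H, 2 * H - 1));
    mat g = tanh(A.cols(2 * H, 3 * H - 1));
    mat o = sigmoidm(A.cols(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    cache.G.slice(t) = join_rows(join_rows(i, f), join_rows(g, o));
    cache.C.slice(t) = c;
    cache.H.slice(t) = h;
  }
}

static void lstm_backward(const cube& In, const mat& W, const mat& U,
                          const LstmCache& cache, const cube& dH,
                          mat& dW, mat& dU, rowvec& db, cube& dIn,
                          bool needInputGrad) {
  const int B = In.n_rows, D = In.n_cols, T = In.n_slices;
  const int H = cache.H.n_cols;
  dW.zeros(D, 4 * H); dU.zeros(H, 4 * H); db.zeros(4 * H);
  if (needInputGrad) dIn.set_size(B, D, T);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const mat i = cache.G.slice(t).cols(0, H - 1);
    const mat f = cache.G.slice(t).cols(H, 2 * H - 1);
    const mat g = cache.G.slice(t).cols(2 * H, 3 * H - 1);
    const mat o = cache.G.slice(t).cols(3 * H, 4 * H - 1);
    const mat tc = tanh(cache.C.slice(t));
    const mat cprev = (t == 0) ? mat(B, H, fill::zeros) : cache.C.slice(t - 1);
    const mat hprev = (t == 0) ? mat(B, H, fill::zeros) : cache.H.slice(t - 1);
    mat dh = dH.slice(t) + dh_next;
    mat dc = dc_next + dh % o % (1.0 - tc % tc);
    mat dA = join_rows(
        join_rows((dc % g) % i % (1.0 - i), (dc % cprev) % f % (1.0 - f)),
        join_rows((dc % i) % (1.0 - g % g), (dh % tc) % o % (1.0 - o)));
    dW += In.slice(t).t() * dA;
    dU += hprev.t() * dA;
    db += sum(dA, 0);
    if (needInputGrad) dIn.slice(t) = dA * W.t();
    dh_next = dA * U.t();
    dc_next = dc % f;
  }
}

static cube dropout_mask(int B, int H, int T, double keep) {
  cube m(B, H, T);
  double* p = m.memptr();
  const uword n = m.n_elem;
  for (uword k = 0; k < n; ++k)
    p[k] = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

// Forward (and optionally backward) pass over a batch of epochs.
// X: samples x channels x trials; y: 0-based labels (empty => no loss);
// w: per-sample loss weights; keep1/keep2: dropout keep probabilities.
// [[Rcpp::export]]
Rcpp::List attlstm_run(const arma::cube& X, const Rcpp::List& params,
                       const arma::ivec& y, const arma::vec& w,
                       const bool training, const double keep1,
                       const double keep2, const bool wantGrad,
                       const bool wantAttention) {
  const int T = X.n_rows, C = X.n_cols, B = X.n_slices;
  const mat W1 = params["W1"], U1 = params["U1"];
  const mat W2 = params["W2"], U2 = params["U2"];
  const rowvec b1 = params["b1"], b2 = params["b2"];
  const mat Wa = params["Wa"];
  const rowvec ba = params["ba"];
  const vec va = params["va"];
  const mat Wd = params["Wd"];
  const rowvec bd = params["bd"];
  const int H1 = U1.n_rows, H2 = U2.n_rows, K = Wd.n_cols, AU = Wa.n_cols;

  // time-major batch layout: B x C x T
  cube In1(B, C, T);
  for (int t = 0; t < T; ++t)
    for (int c = 0; c < C; ++c)
      for (int b = 0; b < B; ++b) In1(b, c, t) = X(t, c, b);

  LstmCache c1, c2;
  lstm_forward(In1, W1, U1, b1, c1);
  cube m1, m2;
  cube H1d = c1.H;
  if (training && keep1 < 1.0) {
    m1 = dropout_mask(B, H1, T, keep1);
    H1d %= m1;
  }
  lstm_forward(H1d, W2, U2, b2, c2);
  cube H2d = c2.H;
  if (training && keep2 < 1.0) {
    m2 = dropout_mask(B, H2, T, keep2);
    H2d %= m2;
  }

  // additive temporal attention: e_t = va . tanh(h_t Wa + ba)
  cube TA(B, AU, T);
  mat E(B, T);
  for (int t = 0; t < T; ++t) {
    mat Z = H2d.slice(t) * Wa;
    Z.each_row() += ba;
    TA.slice(t) = tanh(Z);
    E.col(t) = TA.slice(t) * va;
  }
  mat alpha = exp(E.each_col() - max(E, 1));
  alpha.each_col() /= sum(alpha, 1);
  mat context(B, H2, fill::zeros);
  for (int t = 0; t < T; ++t)
    context += H2d.slice(t).each_col() % alpha.col(t);

  mat logits = context * Wd;
  logits.each_row() += bd;
  mat P = exp(logits.each_col() - max(logits, 1));
  P.each_col() /= sum(P, 1);

  double loss = NA_REAL;
  if (y.n_elem == (uword)B) {
    loss = 0.0;
    for (int b = 0; b < B; ++b)
      loss += -w(b) * std::log(std::max(P(b, y(b)), 1e-12));
    loss /= B;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("probs") = P, Rcpp::Named("loss") = loss);
  if (wantAttention) out["attention"] = alpha;
  if (!wantGrad) return out;

  // ---- backward ----
  mat dlogits = P;
  for (int b = 0; b < B; ++b) {
    dlogits(b, y(b)) -= 1.0;
    dlogits.row(b) *= w(b) / B;
  }
  mat dWd = context.t() * dlogits;
  rowvec dbd = sum(dlogits, 0);
  mat dcontext = dlogits * Wd.t();

  mat dalpha(B, T);
  cube dH2d(B, H2, T, fill::zeros);
  for (int t = 0; t < T; ++t) {
    dalpha.col(t) = sum(dcontext % H2d.slice(t), 1);
    dH2d.slice(t) = dcontext.each_col() % alpha.col(t);
  }
  vec rowDot = sum(alpha % dalpha, 1);
  mat dE = alpha % (dalpha.each_col() - rowDot);
  mat dWa(H2, AU, fill::zeros);
  rowvec dba(AU, fill::zeros);
  vec dva(AU, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat dS = dE.col(t) * va.t();                 // B x AU
    mat dZ = dS % (1.0 - TA.slice(t) % TA.slice(t));
    dva += TA.slice(t).t() * dE.col(t);
    dWa += H2d.slice(t).t() * dZ;
    dba += sum(dZ, 0);
    dH2d.slice(t) += dZ * Wa.t();
  }
  if (training && keep2 < 1.0) dH2d %= m2;

  mat dW2, dU2; rowvec db2; cube dH1d;
  lstm_backward(H1d, W2, U2, c2, dH2d, dW2, dU2, db2, dH1d, true);
  if (training && keep1 < 1.0) dH1d %= m1;
  mat dW1, dU1; rowvec db1; cube dIn;
  lstm_backward(In1, W1, U1, c1, dH1d, dW1, dU1, db1, dIn, false);

  out["grads"] = Rcpp::List::create(
      Rcpp::Named("W1") = dW1, Rcpp::Named("U1") = dU1, Rcpp::Named("b1") = db1,
      Rcpp::Named("W2") = dW2, Rcpp::Named("U2") = dU2, Rcpp::Named("b2") = db2,
      Rcpp::Named("Wa") = dWa, Rcpp::Named("ba") = dba, Rcpp::Named("va") = dva,
      Rcpp::Named("Wd") = dWd, Rcpp::Named("bd") = dbd);
  return out;
}
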