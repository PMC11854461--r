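// Convolution-transformer EEG encoder: factorized temporal+spatial
// convolution front end, average-pooled token sequence, stacked pre-LN
// multi-head self-attention blocks, dense softmax head. Forward and full
// backward passes, per-sample within the batch loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat eluf(const mat& x) {
  mat y = x;
  y.transform([](double v) { return v > 0 ? v : std::expm1(v); });
  return y;
}
// derivative from pre-activation x and activation a = elu(x)
static inline mat elud(const mat& x, const mat& a) {
  mat d(size(x));
  for (uword i = 0; i < x.n_elem; ++i) d(i) = x(i) > 0 ? 1.0 : a(i) + 1.0;
  return d;
}

static mat softmax_rows(const mat& s) {
  mat p = exp(s.each_col() - max(s, 1));
  p.each_col() /= sum(p, 1);
  return p;
}

struct LNCache { mat xhat; vec inv; };

static mat ln_forward(const mat& x, const rowvec& g, const rowvec& b,
                      LNCache& c) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = mean(xc % xc, 1);
  c.inv = 1.0 / sqrt(v + 1e-5);
  c.xhat = xc.each_col() % c.inv;
  mat y = c.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat ln_backward(const mat& dy, const rowvec& g, const LNCache& c,
                       mat& dg, rowvec& db) {
  dg += sum(dy % c.xhat, 0);
  db += sum(dy, 0);
  mat dxhat = dy.each_row() % g;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % c.xhat, 1);
  mat dx = dxhat.each_col() - m1;
  dx -= c.xhat.each_col() % m2;
  return dx.each_col() % c.inv;
}

struct BlockParams {
  rowvec ln1g, ln1b, ln2g, ln2b, bq, bk, bv, bo, bf1, bf2;
  mat Wq, Wk, Wv, Wo, Wf1, Wf2;
};
struct BlockGrads {
  rowvec ln1g, ln1b, ln2g, ln2b, bq, bk, bv, bo, bf1, bf2;
  mat Wq, Wk, Wv, Wo, Wf1, Wf2;
};
struct BlockCache {
  mat tokIn, x1, Q, K, V, AO, tokMid, x2, f1pre, f1act;
  cube At;
  LNCache ln1, ln2;
};

static mat dropout_mat(int r, int c, double keep) {
  mat m(r, c);
  for (uword i = 0; i < m.n_elem; ++i)
    m(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

// [[Rcpp::export]]
Rcpp::List conformer_run(const arma::cube& X, const Rcpp::List& params,
                         const arma::ivec& y, const arma::vec& w,
                         const bool training, const bool wantGrad,
                         const int poolLen, const int poolStride,
                         const int nHeads, const int nBlocks,
                         const double keepPool,
                         const double keepFc1, const double keepFc2) {
  const int T = X.n_rows, C = X.n_cols, B = X.n_slices;
  const mat Wt = params["Wt"];          // F x KT
  const mat Wsp = params["Wsp"];        // F x (F*C)
  const rowvec bsp = params["bsp"];
  const mat Wproj = params["Wproj"];    // F x D
  const rowvec bproj = params["bproj"];
  const mat Wh1 = params["Wh1"], Wh2 = params["Wh2"], Wh3 = params["Wh3"];
  const rowvec bh1 = params["bh1"], bh2 = params["bh2"], bh3 = params["bh3"];
  const int F = Wt.n_rows, KT = Wt.n_cols, D = Wproj.n_cols;
  const int K = Wh3.n_cols;
  const int NT = (T - poolLen) / poolStride + 1;
  const int DH = D / nHeads;
  const double scl = 1.0 / std::sqrt((double)DH);
  const int pad = KT / 2;
  const int L = nBlocks;

  std::vector<BlockParams> bp(L);
  for (int l = 0; l < L; ++l) {
    std::string p = "b" + std::to_string(l + 1) + "_";
    BlockParams& q = bp[l];
    q.ln1g = Rcpp::as<rowvec>(params[p + "ln1g"]);
    q.ln1b = Rcpp::as<rowvec>(params[p + "ln1b"]);
    q.ln2g = Rcpp::as<rowvec>(params[p + "ln2g"]);
    q.ln2b = Rcpp::as<rowvec>(params[p + "ln2b"]);
    q.Wq = Rcpp::as<mat>(params[p + "Wq"]); q.bq = Rcpp::as<rowvec>(params[p + "bq"]);
    q.Wk = Rcpp::as<mat>(params[p + "Wk"]); q.bk = Rcpp::as<rowvec>(params[p + "bk"]);
    q.Wv = Rcpp::as<mat>(params[p + "Wv"]); q.bv = Rcpp::as<rowvec>(params[p + "bv"]);
    q.Wo = Rcpp::as<mat>(params[p + "Wo"]); q.bo = Rcpp::as<rowvec>(params[p + "bo"]);
    q.Wf1 = Rcpp::as<mat>(params[p + "Wf1"]); q.bf1 = Rcpp::as<rowvec>(params[p + "bf1"]);
    q.Wf2 = Rcpp::as<mat>(params[p + "Wf2"]); q.bf2 = Rcpp::as<rowvec>(params[p + "bf2"]);
  }

  // factorized spatio-temporal kernel: Keff(f, c*KT+k) = sum_g Wsp(f,g*C+c) Wt(g,k)
  mat Keff(F, C * KT);
  std::vector<mat> Sc(C);
  for (int c = 0; c < C; ++c) {
    mat S(F, F);
    for (int g = 0; g < F; ++g) S.col(g) = Wsp.col(g * C + c);
    Sc[c] = S;
    Keff.cols(c * KT, c * KT + KT - 1) = S * Wt;
  }

  // grad accumulators
  mat dKeff, dWproj, dWh1, dWh2, dWh3;
  rowvec dbsp, dbproj, dbh1, dbh2, dbh3;
  std::vector<BlockGrads> bg(L);
  if (wantGrad) {
    dKeff.zeros(F, C * KT); dWproj.zeros(F, D);
    dWh1.zeros(Wh1.n_rows, Wh1.n_cols); dWh2.zeros(Wh2.n_rows, Wh2.n_cols);
    dWh3.zeros(Wh3.n_rows, Wh3.n_cols);
    dbsp.zeros(F); dbproj.zeros(D);
    dbh1.zeros(bh1.n_elem); dbh2.zeros(bh2.n_elem); dbh3.zeros(bh3.n_elem);
    for (int l = 0; l < L; ++l) {
      BlockGrads& q = bg[l];
      q.ln1g.zeros(D); q.ln1b.zeros(D); q.ln2g.zeros(D); q.ln2b.zeros(D);
      q.bq.zeros(D); q.bk.zeros(D); q.bv.zeros(D); q.bo.zeros(D);
      q.bf1.zeros(bp[l].bf1.n_elem); q.bf2.zeros(D);
      q.Wq.zeros(D, D); q.Wk.zeros(D, D); q.Wv.zeros(D, D); q.Wo.zeros(D, D);
      q.Wf1.zeros(bp[l].Wf1.n_rows, bp[l].Wf1.n_cols);
      q.Wf2.zeros(bp[l].Wf2.n_rows, bp[l].Wf2.n_cols);
    }
  }

  mat P(B, K);
  double loss = 0.0;
  const bool haveY = (y.n_elem == (uword)B);

  for (int b = 0; b < B; ++b) {
    // ---- convolutional front end ----
    mat M(T, C * KT, fill::zeros);
    for (int c = 0; c < C; ++c)
      for (int k = 0; k < KT; ++k) {
        const int sh = k - pad;
        const int t0 = std::max(0, -sh), t1 = std::min(T, T - sh);
        for (int t = t0; t < t1; ++t) M(t, c * KT + k) = X(t + sh, c, b);
      }
    mat E0 = M * Keff.t();
    E0.each_row() += bsp;
    mat E = eluf(E0);
    mat P0(NT, F);
    for (int j = 0; j < NT; ++j)
      P0.row(j) = mean(E.rows(j * poolStride, j * poolStride + poolLen - 1), 0);
    mat maskp;
    mat Pd = P0;
    if (training && keepPool < 1.0) {
      maskp = dropout_mat(NT, F, keepPool);
      Pd %= maskp;
    }
    mat tok = Pd * Wproj;
    tok.each_row() += bproj;

    // ---- transformer blocks ----
    std::vector<BlockCache> bc(L);
    for (int l = 0; l < L; ++l) {
      BlockCache& cc = bc[l];
      const BlockParams& q = bp[l];
      cc.tokIn = tok;
      cc.x1 = ln_forward(tok, q.ln1g, q.ln1b, cc.ln1);
      cc.Q = cc.x1 * q.Wq; cc.Q.each_row() += q.bq;
      cc.K = cc.x1 * q.Wk; cc.K.each_row() += q.bk;
      cc.V = cc.x1 * q.Wv; cc.V.each_row() += q.bv;
      cc.At.set_size(NT, NT, nHeads);
      cc.AO.set_size(NT, D);
      for (int h = 0; h < nHeads; ++h) {
        const int c0 = h * DH, c1 = (h + 1) * DH - 1;
        mat A = softmax_rows(cc.Q.cols(c0, c1) * cc.K.cols(c0, c1).t() * scl);
        cc.At.slice(h) = A;
        cc.AO.cols(c0, c1) = A * cc.V.cols(c0, c1);
      }
      mat O = cc.AO * q.Wo;
      O.each_row() += q.bo;
      cc.tokMid = cc.tokIn + O;
      cc.x2 = ln_forward(cc.tokMid, q.ln2g, q.ln2b, cc.ln2);
      cc.f1pre = cc.x2 * q.Wf1;
      cc.f1pre.each_row() += q.bf1;
      cc.f1act = eluf(cc.f1pre);
      mat F2 = cc.f1act * q.Wf2;
      F2.each_row() += q.bf2;
      tok = cc.tokMid + F2;
    }

    // ---- classification head ----
    mat h0 = vectorise(tok).t();            // 1 x NT*D
    mat z1 = h0 * Wh1; z1.each_row() += bh1;
    mat a1 = eluf(z1);
    mat mf1, mf2;
    mat d1 = a1;
    if (training && keepFc1 < 1.0) { mf1 = dropout_mat(1, a1.n_cols, keepFc1); d1 %= mf1; }
    mat z2 = d1 * Wh2; z2.each_row() += bh2;
    mat a2 = eluf(z2);
    mat d2 = a2;
    if (training && keepFc2 < 1.0) { mf2 = dropout_mat(1, a2.n_cols, keepFc2); d2 %= mf2; }
    mat lg = d2 * Wh3; lg.each_row() += bh3;
    mat pb = exp(lg - lg.max());
    pb /= accu(pb);
    P.row(b) = pb.row(0);
    if (haveY) loss += -w(b) * std::log(std::max(pb(0, y(b)), 1e-12));

    if (!wantGrad) continue;

    // ---- backward ----
    mat dlg = pb;
    dlg(0, y(b)) -= 1.0;
    dlg *= w(b) / B;
    dWh3 += d2.t() * dlg; dbh3 += dlg.row(0);
    mat dd2 = dlg * Wh3.t();
    if (training && keepFc2 < 1.0) dd2 %= mf2;
    mat dz2 = dd2 % elud(z2, a2);
    dWh2 += d1.t() * dz2; dbh2 += dz2.row(0);
    mat dd1 = dz2 * Wh2.t();
    if (training && keepFc1 < 1.0) dd1 %= mf1;
    mat dz1 = dd1 % elud(z1, a1);
    dWh1 += h0.t() * dz1; dbh1 += dz1.row(0);
    mat dh0 = dz1 * Wh1.t();
    mat dTok = reshape(dh0.t(), NT, D);

    for (int l = L - 1; l >= 0; --l) {
      const BlockParams& q = bp[l];
      BlockGrads& gq = bg[l];
      BlockCache& cc = bc[l];
      // FFN sublayer
      mat dF2 = dTok;
      mat dTokMid = dTok;
      gq.Wf2 += cc.f1act.t() * dF2; gq.bf2 += sum(dF2, 0);
      mat dF1 = dF2 * q.Wf2.t();
      mat dF1pre = dF1 % elud(cc.f1pre, cc.f1act);
      gq.Wf1 += cc.x2.t() * dF1pre; gq.bf1 += sum(dF1pre, 0);
      mat dX2 = dF1pre * q.Wf1.t();
      dTokMid += ln_backward(dX2, q.ln2g, cc.ln2, gq.ln2g, gq.ln2b);
      // attention sublayer
      mat dO = dTokMid;
      mat dTokIn = dTokMid;
      gq.Wo += cc.AO.t() * dO; gq.bo += sum(dO, 0);
      mat dAO = dO * q.Wo.t();
      mat dQ(NT, D), dKm(NT, D), dV(NT, D);
      for (int h = 0; h < nHeads; ++h) {
        const int c0 = h * DH, c1 = (h + 1) * DH - 1;
        const mat& A = cc.At.slice(h);
        mat dOh = dAO.cols(c0, c1);
        mat dA = dOh * cc.V.cols(c0, c1).t();
        dV.cols(c0, c1) = A.t() * dOh;
        vec rs = sum(dA % A, 1);
        mat dS = A % (dA.each_col() - rs);
        dQ.cols(c0, c1) = dS * cc.K.cols(c0, c1) * scl;
        dKm.cols(c0, c1) = dS.t() * cc.Q.cols(c0, c1) * scl;
      }
      gq.Wq += cc.x1.t() * dQ; gq.bq += sum(dQ, 0);
      gq.Wk += cc.x1.t() * dKm; gq.bk += sum(dKm, 0);
      gq.Wv += cc.x1.t() * dV; gq.bv += sum(dV, 0);
      mat dX1 = dQ * q.Wq.t() + dKm * q.Wk.t() + dV * q.Wv.t();
      dTokIn += ln_backward(dX1, q.ln1g, cc.ln1, gq.ln1g, gq.ln1b);
      dTok = dTokIn;
    }

    dWproj += Pd.t() * dTok; dbproj += sum(dTok, 0);
    mat dPd = dTok * Wproj.t();
    if (training && keepPool < 1.0) dPd %= maskp;
    mat dE(T, F, fill::zeros);
    for (int j = 0; j < NT; ++j)
      dE.rows(j * poolStride, j * poolStride + poolLen - 1) +=
          repmat(dPd.row(j) / poolLen, poolLen, 1);
    mat dE0 = dE % elud(E0, E);
    dKeff += dE0.t() * M;
    dbsp += sum(dE0, 0);
  }

  if (haveY) loss /= B;
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("probs") = P, Rcpp::Named("loss") = haveY ? loss : NA_REAL);
  if (!wantGrad) return out;

  // unfold dKeff into the factorized temporal/spatial parameters
  mat dWt(F, KT, fill::zeros);
  mat dWsp(F, F * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat dKc = dKeff.cols(c * KT, c * KT + KT - 1);
    dWt += Sc[c].t() * dKc;
    mat dS = dKc * Wt.t();
    for (int g = 0; g < F; ++g) dWsp.col(g * C + c) = dS.col(g);
  }

  Rcpp::List grads = Rcpp::List::create(
      Rcpp::Named("Wt") = dWt, Rcpp::Named("Wsp") = dWsp,
      Rcpp::Named("bsp") = dbsp, Rcpp::Named("Wproj") = dWproj,
      Rcpp::Named("bproj") = dbproj);
  for (int l = 0; l < L; ++l) {
    std::string p = "b" + std::to_string(l + 1) + "_";
    const BlockGrads& q = bg[l];
    grads[p + "ln1g"] = q.ln1g; grads[p + "ln1b"] = q.ln1b;
    grads[p + "Wq"] = q.Wq; grads[p + "bq"] = q.bq;
    grads[p + "Wk"] = q.Wk; grads[p + "bk"] = q.bk;
    grads[p + "Wv"] = q.Wv; grads[p + "bv"] = q.bv;
    grads[p + "Wo"] = q.Wo; grads[p + "bo"] = q.bo;
    grads[p + "ln2g"] = q.ln2g; grads[p + "ln2b"] = q.ln2b;
    grads[p + "Wf1"] = q.Wf1; grads[p + "bf1"] = q.bf1;
    grads[p + "Wf2"] = q.Wf2; grads[p + "bf2"] = q.bf2;
  }
  grads["Wh1"] = dWh1; grads["bh1"] = dbh1;
  grads["Wh2"] = dWh2; grads["bh2"] = dbh2;
  grads["Wh3"] = dWh3; grads["bh3"] = dbh3;
  out["grads"] = grads;
  return out;
}
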