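// Numeric core of the retention-time regressor: embedding -> bidirectional
// GRU -> attention pooling -> dense head, with analytic backpropagation.
// All dropout masks are generated on the R side (inverted-dropout scaled),
// so the C++ layer is fully deterministic.
//
// Conventions:
//  - X is a B x T integer matrix of residue indices, 0 = padding (right pad).
//  - GRU follows the reset-after-multiplication form:
//      z = s(x Wz + h Uz + bz), r = s(x Wr + h Ur + br),
//      n = tanh(x Wn + r * (h Un) + bn), h' = (1-z)*n + z*h
//    with masked steps carrying h through unchanged.
//  - Attention: score_t = h_t . v, masked softmax over positions, context =
//    sum_t alpha_t h_t.
//  - Dense head: ReLU hidden layers, linear scalar output; dropout after the
//    attention context and after every hidden dense activation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::uword;

static inline mat sigmoid(const mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

struct GruCache {
  std::vector<mat> hprev, z, r, n, hu, x;
  std::vector<vec> m;       // mask column per step
  std::vector<int> tidx;    // time index processed at each step
  std::vector<mat> h;       // hidden state after each step
};

// Run one GRU direction. order = sequence of time indices (0..T-1 for the
// forward pass, reversed for the backward direction).
static void gru_forward(const std::vector<mat>& xs, const mat& M,
                        const std::vector<int>& order,
                        const mat& Wz, const mat& Wr, const mat& Wn,
                        const mat& Uz, const mat& Ur, const mat& Un,
                        const rowvec& bz, const rowvec& br, const rowvec& bn,
                        GruCache& cache, std::vector<mat>& Hout) {
  const uword B = xs[0].n_rows, H = Wz.n_cols, T = order.size();
  mat h(B, H, arma::fill::zeros);
  for (uword s = 0; s < T; ++s) {
    int t = order[s];
    const mat& x = xs[t];
    vec m = M.col(t);
    mat z = sigmoid(x * Wz + h * Uz + arma::repmat(bz, B, 1));
    mat r = sigmoid(x * Wr + h * Ur + arma::repmat(br, B, 1));
    mat hu = h * Un;
    mat n = arma::tanh(x * Wn + r % hu + arma::repmat(bn, B, 1));
    mat hnew = (1.0 - z) % n + z % h;
    cache.hprev.push_back(h);
    cache.z.push_back(z);
    cache.r.push_back(r);
    cache.n.push_back(n);
    cache.hu.push_back(hu);
    cache.m.push_back(m);
    cache.tidx.push_back(t);
    h = hnew.each_col() % m + h.each_col() % (1.0 - m);
    cache.h.push_back(h);
    Hout[t] = h;
  }
}

struct GruGrads {
  mat dWz, dWr, dWn, dUz, dUr, dUn;
  rowvec dbz, dbr, dbn;
  std::vector<mat> dx;  // indexed by time t
};

static void gru_backward(const GruCache& cache, const std::vector<mat>& dHext,
                         const mat& Wz, const mat& Wr, const mat& Wn,
                         const mat& Uz, const mat& Ur, const mat& Un,
                         GruGrads& g, uword T, uword B, uword E, uword H) {
  g.dWz.zeros(E, H); g.dWr.zeros(E, H); g.dWn.zeros(E, H);
  g.dUz.zeros(H, H); g.dUr.zeros(H, H); g.dUn.zeros(H, H);
  g.dbz.zeros(H); g.dbr.zeros(H); g.dbn.zeros(H);
  g.dx.assign(T, mat());
  mat dh(B, H, arma::fill::zeros);
  for (int s = (int)T - 1; s >= 0; --s) {
    int t = cache.tidx[s];
    const mat& hprev = cache.hprev[s];
    const mat& z = cache.z[s];
    const mat& r = cache.r[s];
    const mat& n = cache.n[s];
    const mat& hu = cache.hu[s];
    const vec& m = cache.m[s];
    // x used at this step: recompute from caller-side store
    mat dh_total = dh + dHext[t];
    mat dhtilde = dh_total.each_col() % m;
    mat dhprev = dh_total.each_col() % (1.0 - m);
    mat dz = dhtilde % (hprev - n);
    mat dn = dhtilde % (1.0 - z);
    dhprev += dhtilde % z;
    mat dan = dn % (1.0 - n % n);
    mat dr = dan % hu;
    mat dhu = dan % r;
    g.dUn += hprev.t() * dhu;
    dhprev += dhu * Un.t();
    mat daz = dz % z % (1.0 - z);
    mat dar = dr % r % (1.0 - r);
    g.dUz += hprev.t() * daz;
    g.dUr += hprev.t() * dar;
    dhprev += daz * Uz.t() + dar * Ur.t();
    g.dbz += arma::sum(daz, 0);
    g.dbr += arma::sum(dar, 0);
    g.dbn += arma::sum(dan, 0);
    // accumulate weight grads wrt x and pass dx out
    const mat& x = cache.x[s];
    g.dWz += x.t() * daz;
    g.dWr += x.t() * dar;
    g.dWn += x.t() * dan;
    g.dx[t] = daz * Wz.t() + dar * Wr.t() + dan * Wn.t();
    dh = dhprev;
  }
}

// [[Rcpp::export]]
List rtnet_eval(const List& params, const arma::imat& X,
                const arma::vec& y, const arma::mat& dropCtx,
                const List& denseDrop, bool wantGrad) {
  const uword B = X.n_rows, T = X.n_cols;
  mat Emb = as<mat>(params["Emb"]);
  const uword E = Emb.n_cols;
  mat fWz = as<mat>(params["f_Wz"]), fWr = as<mat>(params["f_Wr"]),
      fWn = as<mat>(params["f_Wn"]);
  mat fUz = as<mat>(params["f_Uz"]), fUr = as<mat>(params["f_Ur"]),
      fUn = as<mat>(params["f_Un"]);
  rowvec fbz = as<rowvec>(params["f_bz"]), fbr = as<rowvec>(params["f_br"]),
         fbn = as<rowvec>(params["f_bn"]);
  mat bWz = as<mat>(params["b_Wz"]), bWr = as<mat>(params["b_Wr"]),
      bWn = as<mat>(params["b_Wn"]);
  mat bUz = as<mat>(params["b_Uz"]), bUr = as<mat>(params["b_Ur"]),
      bUn = as<mat>(params["b_Un"]);
  rowvec bbz = as<rowvec>(params["b_bz"]), bbr = as<rowvec>(params["b_br"]),
         bbn = as<rowvec>(params["b_bn"]);
  vec attn_v = as<vec>(params["attn_v"]);
  List denseW = params["denseW"], denseB = params["denseB"];
  const uword H = fWz.n_cols;
  const int nDense = denseW.size();

  // masks and embedded inputs
  mat M(B, T);
  std::vector<mat> xs(T);
  for (uword t = 0; t < T; ++t) {
    mat x(B, E);
    for (uword b = 0; b < B; ++b) {
      int idx = X(b, t);
      x.row(b) = Emb.row(idx);
      M(b, t) = idx > 0 ? 1.0 : 0.0;
    }
    xs[t] = x;
  }

  std::vector<int> fwd(T), bwd(T);
  for (uword t = 0; t < T; ++t) { fwd[t] = t; bwd[t] = T - 1 - t; }

  GruCache cf, cb;
  std::vector<mat> Hf(T), Hb(T);
  gru_forward(xs, M, fwd, fWz, fWr, fWn, fUz, fUr, fUn, fbz, fbr, fbn, cf, Hf);
  gru_forward(xs, M, bwd, bWz, bWr, bWn, bUz, bUr, bUn, bbz, bbr, bbn, cb, Hb);
  for (uword s = 0; s < T; ++s) { cf.x.push_back(xs[cf.tidx[s]]); }
  for (uword s = 0; s < T; ++s) { cb.x.push_back(xs[cb.tidx[s]]); }

  // attention over concatenated states
  mat S(B, T);
  for (uword t = 0; t < T; ++t) {
    S.col(t) = Hf[t] * attn_v.head(H) + Hb[t] * attn_v.tail(H);
  }
  S = S % M + (1.0 - M) * (-1e30);
  vec smax = arma::max(S, 1);
  mat eS = arma::exp(S.each_col() - smax);
  eS = eS % M;  // padded positions contribute exactly zero
  vec ssum = arma::sum(eS, 1);
  mat alpha = eS.each_col() / ssum;
  mat C(B, 2 * H, arma::fill::zeros);
  for (uword t = 0; t < T; ++t) {
    C.cols(0, H - 1) += Hf[t].each_col() % alpha.col(t);
    C.cols(H, 2 * H - 1) += Hb[t].each_col() % alpha.col(t);
  }

  // dense head
  mat a = C % dropCtx;
  std::vector<mat> acts;  // inputs to each dense layer
  std::vector<mat> zs;    // pre-activations of hidden layers
  acts.push_back(a);
  for (int i = 0; i < nDense - 1; ++i) {
    mat W = as<mat>(denseW[i]);
    rowvec b = as<rowvec>(denseB[i]);
    mat zi = a * W + arma::repmat(b, B, 1);
    zs.push_back(zi);
    a = arma::clamp(zi, 0.0, arma::datum::inf);
    a = a % as<mat>(denseDrop[i]);
    acts.push_back(a);
  }
  mat Wo = as<mat>(denseW[nDense - 1]);
  rowvec bo = as<rowvec>(denseB[nDense - 1]);
  vec pred = a * Wo + bo(0);

  List out;
  out["pred"] = pred;
  out["attention"] = alpha;
  double loss = NA_REAL;
  if (y.n_elem == B) {
    loss = arma::mean(arma::square(pred - y));
    out["loss"] = loss;
  }
  if (!wantGrad) return out;

  // ---- backward ----
  vec dpred = 2.0 * (pred - y) / (double)B;
  List grads;
  mat dWo = acts[nDense - 1].t() * dpred;
  rowvec dbo(1);
  dbo(0) = arma::accu(dpred);
  mat da = dpred * Wo.t();
  List gDenseW(nDense), gDenseB(nDense);
  gDenseW[nDense - 1] = dWo;
  gDenseB[nDense - 1] = dbo;
  for (int i = nDense - 2; i >= 0; --i) {
    da = da % as<mat>(denseDrop[i]);
    mat dz = da % arma::conv_to<mat>::from(zs[i] > 0);
    gDenseW[i] = acts[i].t() * dz;
    gDenseB[i] = rowvec(arma::sum(dz, 0));
    da = dz * as<mat>(denseW[i]).t();
  }
  mat dC = da % dropCtx;

  // attention backward
  mat dalpha(B, T, arma::fill::zeros);
  std::vector<mat> dHf(T), dHb(T);
  for (uword t = 0; t < T; ++t) {
    dHf[t] = dC.cols(0, H - 1).each_col() % alpha.col(t);
    dHb[t] = dC.cols(H, 2 * H - 1).each_col() % alpha.col(t);
    dalpha.col(t) = arma::sum(dC.cols(0, H - 1) % Hf[t], 1) +
                    arma::sum(dC.cols(H, 2 * H - 1) % Hb[t], 1);
  }
  vec rs = arma::sum(alpha % dalpha, 1);
  mat dS = alpha % (dalpha.each_col() - rs);
  vec dattn(2 * H, arma::fill::zeros);
  for (uword t = 0; t < T; ++t) {
    dHf[t] += dS.col(t) * attn_v.head(H).t();
    dHb[t] += dS.col(t) * attn_v.tail(H).t();
    dattn.head(H) += Hf[t].t() * dS.col(t);
    dattn.tail(H) += Hb[t].t() * dS.col(t);
  }

  GruGrads gf, gb;
  gru_backward(cf, dHf, fWz, fWr, fWn, fUz, fUr, fUn, gf, T, B, E, H);
  gru_backward(cb, dHb, bWz, bWr, bWn, bUz, bUr, bUn, gb, T, B, E, H);

  mat dEmb(Emb.n_rows, E, arma::fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat dx = gf.dx[t] + gb.dx[t];
    for (uword b = 0; b < B; ++b) {
      dEmb.row(X(b, t)) += dx.row(b);
    }
  }

  grads["Emb"] = dEmb;
  grads["f_Wz"] = gf.dWz; grads["f_Wr"] = gf.dWr; grads["f_Wn"] = gf.dWn;
  grads["f_Uz"] = gf.dUz; grads["f_Ur"] = gf.dUr; grads["f_Un"] = gf.dUn;
  grads["f_bz"] = gf.dbz; grads["f_br"] = gf.dbr; grads["f_bn"] = gf.dbn;
  grads["b_Wz"] = gb.dWz; grads["b_Wr"] = gb.dWr; grads["b_Wn"] = gb.dWn;
  grads["b_Uz"] = gb.dUz; grads["b_Ur"] = gb.dUr; grads["b_Un"] = gb.dUn;
  grads["b_bz"] = gb.dbz; grads["b_br"] = gb.dbr; grads["b_bn"] = gb.dbn;
  grads["attn_v"] = dattn;
  grads["denseW"] = gDenseW;
  grads["denseB"] = gDenseB;
  out["grads"] = grads;
  return out;
}
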