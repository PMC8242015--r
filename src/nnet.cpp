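// Core numerics for the multi-label LSTM-attention network.
//
// Layout conventions (column batches keep Armadillo gemm-friendly):
//   X      : cube(D, B, T)   slice t = input features at position t
//   hs, cs : cube(nH, B, T)  encoder hidden / cell states, nH = H (one
//            direction) or 2H (bidirectional: forward rows then backward)
//   gates  : cube(4H, B, T) per direction, activated gates [i; f; g; o]
//   ash    : cube(A, B, T)   shared attention pre-activation Wc*c + Wy*h
//   alpha  : cube(T, B, K)   attention weights, one slice per label
//   ctx    : cube(nH, B, K)  per-label context vectors
// The forward pass keeps its activation caches on the C++ side (returned to
// R as an external pointer) so a training step does not copy multi-megabyte
// cubes through R between the forward and backward calls.
// Dropout masks are inverted-dropout (0 or 1/(1-p)) drawn from R's RNG so
// training is reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct NNCache {
  cube hs, cs, tanhc, gates, gates_r, ash, alpha, ctx, us, mctx, mu;
  bool bidir;
};

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static cube drop_mask(uword r, uword c, uword s, double p) {
  cube m(r, c, s);
  if (p <= 0.0) { m.ones(); return m; }
  const double keep = 1.0 - p;
  for (uword k = 0; k < s; ++k)
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i)
        m(i, j, k) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

// one LSTM direction; writes hs/cs rows [row0, row0+H) and the direction's
// own 4H-row gate cube. reverse = read X right-to-left.
static void lstm_forward_dir(const mat& Wx, const mat& Wh, const vec& b,
                             const cube& X, bool reverse, uword row0,
                             cube& hs, cube& cs, cube& tanhc, cube& gates) {
  const uword H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  // input projection for every position in one gemm
  const mat X_flat(const_cast<double*>(X.memptr()), X.n_rows, B * T, false,
                   true);
  mat PX = Wx * X_flat;  // 4H x B*T
  mat hprev(H, B, fill::zeros), cprev(H, B, fill::zeros);
  for (uword step = 0; step < T; ++step) {
    const uword t = reverse ? (T - 1 - step) : step;
    mat z = PX.cols(t * B, (t + 1) * B - 1) + Wh * hprev;
    z.each_col() += b;
    mat gi = sigm(z.rows(0, H - 1));
    mat gf = sigm(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat go = sigm(z.rows(3 * H, 4 * H - 1));
    mat c = gf % cprev + gi % gg;
    mat tc = tanh(c);
    mat h = go % tc;
    gates.slice(t).rows(0, H - 1) = gi;
    gates.slice(t).rows(H, 2 * H - 1) = gf;
    gates.slice(t).rows(2 * H, 3 * H - 1) = gg;
    gates.slice(t).rows(3 * H, 4 * H - 1) = go;
    cs.slice(t).rows(row0, row0 + H - 1) = c;
    tanhc.slice(t).rows(row0, row0 + H - 1) = tc;
    hs.slice(t).rows(row0, row0 + H - 1) = h;
    hprev = h;
    cprev = c;
  }
}

// BPTT for one direction; dh_acc/dc_acc rows [row0, row0+H) hold upstream
// gradients; accumulates dWx/dWh/db and adds this direction's dX.
static void lstm_backward_dir(const mat& Wx, const mat& Wh,
                              const cube& X, bool reverse, uword row0,
                              const cube& hs, const cube& cs,
                              const cube& tanhc, const cube& gates,
                              const cube& dh_acc, const cube& dc_acc,
                              mat& dWx, mat& dWh, vec& db, cube& dX,
                              bool want_dx) {
  const uword H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  cube dz_all(4 * H, B, T);
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  for (uword step = T; step-- > 0;) {
    const uword t = reverse ? (T - 1 - step) : step;
    const uword tprev = reverse ? (t + 1) : (t - 1);
    const bool has_prev = reverse ? (t + 1 < T) : (t > 0);
    mat gi = gates.slice(t).rows(0, H - 1);
    mat gf = gates.slice(t).rows(H, 2 * H - 1);
    mat gg = gates.slice(t).rows(2 * H, 3 * H - 1);
    mat go = gates.slice(t).rows(3 * H, 4 * H - 1);
    mat cprev = has_prev ? mat(cs.slice(tprev).rows(row0, row0 + H - 1))
                         : mat(H, B, fill::zeros);
    mat hprev = has_prev ? mat(hs.slice(tprev).rows(row0, row0 + H - 1))
                         : mat(H, B, fill::zeros);
    mat th = tanhc.slice(t).rows(row0, row0 + H - 1);
    mat dh = dh_acc.slice(t).rows(row0, row0 + H - 1) + dh_next;
    mat dgo = dh % th;
    mat dct = dc_acc.slice(t).rows(row0, row0 + H - 1) + dc_next +
              dh % go % (1.0 - th % th);
    mat dgi = dct % gg, dgf = dct % cprev, dgg = dct % gi;
    mat& dz = dz_all.slice(t);
    dz.rows(0, H - 1) = dgi % gi % (1.0 - gi);
    dz.rows(H, 2 * H - 1) = dgf % gf % (1.0 - gf);
    dz.rows(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
    dz.rows(3 * H, 4 * H - 1) = dgo % go % (1.0 - go);
    dWh += dz * hprev.t();
    dh_next = Wh.t() * dz;
    dc_next = dct % gf;
  }
  // input-side gradients for all positions in single gemms
  const mat X_flat(const_cast<double*>(X.memptr()), X.n_rows, B * T, false,
                   true);
  const mat dz_flat(dz_all.memptr(), 4 * H, B * T, false, true);
  dWx += dz_flat * X_flat.t();
  db += sum(dz_flat, 1);
  if (want_dx) {
    mat dX_flat(dX.memptr(), dX.n_rows, B * T, false, true);
    dX_flat += Wx.t() * dz_flat;
  }
}

// [[Rcpp::export]]
List nn_forward_cpp(const List& params, const arma::cube& X,
                    bool training, double dropout) {
  mat Wx = params["Wx"], Wh = params["Wh"];
  vec b  = params["b"];
  mat Wc = params["Wc"], Wy = params["Wy"], Ba = params["Ba"], V = params["V"];
  cube W1 = params["W1"];
  mat b1 = params["b1"], W2 = params["W2"];
  vec b2 = params["b2"];
  const bool bidir = params.containsElementNamed("Wx_r");

  const uword H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  const uword nH = bidir ? 2 * H : H;
  const uword A = Wc.n_rows, K = V.n_cols, F = W2.n_rows;

  XPtr<NNCache> cache(new NNCache(), true);
  cache->bidir = bidir;
  cache->hs.set_size(nH, B, T);
  cache->cs.set_size(nH, B, T);
  cache->tanhc.set_size(nH, B, T);
  cache->gates.set_size(4 * H, B, T);
  lstm_forward_dir(Wx, Wh, b, X, false, 0, cache->hs, cache->cs,
                   cache->tanhc, cache->gates);
  if (bidir) {
    mat Wx_r = params["Wx_r"], Wh_r = params["Wh_r"];
    vec b_r = params["b_r"];
    cache->gates_r.set_size(4 * H, B, T);
    lstm_forward_dir(Wx_r, Wh_r, b_r, X, true, H, cache->hs, cache->cs,
                     cache->tanhc, cache->gates_r);
  }
  const cube& hs = cache->hs;
  const cube& cs = cache->cs;

  // shared attention pre-activation over all positions at once (A x B*T)
  cube& ash = cache->ash;
  ash.set_size(A, B, T);
  {
    const mat cs_flat(const_cast<double*>(cs.memptr()), nH, B * T, false, true);
    const mat hs_flat(const_cast<double*>(hs.memptr()), nH, B * T, false, true);
    mat ash_f(ash.memptr(), A, B * T, false, true);
    ash_f = Wc * cs_flat + Wy * hs_flat;
  }
  const mat ash_flat(const_cast<double*>(ash.memptr()), A, B * T, false, true);

  cube& alpha = cache->alpha;
  cube& ctx = cache->ctx;
  alpha.set_size(T, B, K);
  ctx.set_size(nH, B, K);
  for (uword j = 0; j < K; ++j) {
    mat s = ash_flat;              // A x B*T
    s.each_col() += Ba.col(j);
    s = tanh(s);
    rowvec ev = V.col(j).t() * s;  // 1 x B*T, position-major blocks of B
    mat e(T, B);
    for (uword t = 0; t < T; ++t)
      e.row(t) = ev.subvec(t * B, (t + 1) * B - 1);
    rowvec mx = max(e, 0);
    e.each_row() -= mx;
    mat ex = exp(e);
    rowvec den = sum(ex, 0);
    ex.each_row() /= den;
    alpha.slice(j) = ex;
    mat cj(nH, B, fill::zeros);
    for (uword t = 0; t < T; ++t)
      cj += hs.slice(t).each_row() % ex.row(t);
    ctx.slice(j) = cj;
  }

  const bool use_drop = training && dropout > 0.0;
  cache->mctx = use_drop ? drop_mask(nH, B, K, dropout)
                         : cube(nH, B, K, fill::ones);
  cache->mu = use_drop ? drop_mask(F, B, K, dropout)
                       : cube(F, B, K, fill::ones);

  cache->us.set_size(F, B, K);
  mat logits(K, B);
  for (uword j = 0; j < K; ++j) {
    mat cd = ctx.slice(j) % cache->mctx.slice(j);
    mat u = W1.slice(j) * cd;
    u.each_col() += b1.col(j);
    u.elem(find(u < 0)).zeros();
    cache->us.slice(j) = u;
    mat ud = u % cache->mu.slice(j);
    logits.row(j) = W2.col(j).t() * ud + b2(j);
  }
  mat probs = sigm(logits);

  return List::create(_["probs"] = probs, _["logits"] = logits,
                      _["alpha"] = alpha, _["cache"] = cache);
}

// [[Rcpp::export]]
List nn_backward_cpp(const List& params, SEXP cache_ptr,
                     const arma::cube& X, const arma::mat& dLogits,
                     bool want_dx = true) {
  XPtr<NNCache> cache(cache_ptr);
  mat Wx = params["Wx"], Wh = params["Wh"];
  mat Wc = params["Wc"], Wy = params["Wy"], Ba = params["Ba"], V = params["V"];
  cube W1 = params["W1"];
  mat W2 = params["W2"];
  const bool bidir = cache->bidir;

  const cube& hs = cache->hs;
  const cube& cs = cache->cs;
  const cube& ash = cache->ash;
  const cube& alpha = cache->alpha;
  const cube& ctx = cache->ctx;
  const cube& us = cache->us;
  const cube& mctx = cache->mctx;
  const cube& mu = cache->mu;

  const uword H = Wh.n_cols, B = X.n_cols, T = X.n_slices;
  const uword nH = bidir ? 2 * H : H;
  const uword A = Wc.n_rows, K = V.n_cols, F = W2.n_rows, D = Wx.n_cols;

  mat dWx(size(Wx), fill::zeros), dWh(size(Wh), fill::zeros);
  vec db(4 * H, fill::zeros);
  mat dWc(size(Wc), fill::zeros), dWy(size(Wy), fill::zeros);
  mat dBa(size(Ba), fill::zeros), dV(A, K, fill::zeros);
  cube dW1(size(W1), fill::zeros);
  mat db1(F, K, fill::zeros), dW2(F, K, fill::zeros);
  vec db2(K, fill::zeros);

  cube dh_acc(nH, B, T, fill::zeros), dc_acc(nH, B, T, fill::zeros);
  cube dash(A, B, T, fill::zeros);
  const mat ash_flat(const_cast<double*>(ash.memptr()), A, B * T, false, true);
  mat dash_flat(dash.memptr(), A, B * T, false, true);

  for (uword j = 0; j < K; ++j) {
    rowvec dl = dLogits.row(j);
    const mat& u = us.slice(j);
    mat ud = u % mu.slice(j);
    dW2.col(j) = ud * dl.t();
    db2(j) = accu(dl);
    mat dud = W2.col(j) * dl;
    mat du = dud % mu.slice(j);
    du.elem(find(u <= 0)).zeros();
    mat cd = ctx.slice(j) % mctx.slice(j);
    dW1.slice(j) = du * cd.t();
    db1.col(j) = sum(du, 1);
    mat dctx = (W1.slice(j).t() * du) % mctx.slice(j);

    const mat& a = alpha.slice(j);
    mat dalpha(T, B);
    for (uword t = 0; t < T; ++t) {
      dalpha.row(t) = sum(hs.slice(t) % dctx, 0);
      dh_acc.slice(t) += dctx.each_row() % a.row(t);
    }
    rowvec ssum = sum(a % dalpha, 0);
    mat de = a % (dalpha.each_row() - ssum);

    // flatten de to position-major 1 x B*T to mirror the forward layout
    rowvec de_flat(B * T);
    for (uword t = 0; t < T; ++t)
      de_flat.subvec(t * B, (t + 1) * B - 1) = de.row(t);
    mat s = ash_flat;
    s.each_col() += Ba.col(j);
    s = tanh(s);
    dV.col(j) = s * de_flat.t();
    mat da = (V.col(j) * de_flat) % (1.0 - s % s);
    dBa.col(j) = sum(da, 1);
    dash_flat += da;
  }

  {
    const mat cs_flat(const_cast<double*>(cs.memptr()), nH, B * T, false, true);
    const mat hs_flat(const_cast<double*>(hs.memptr()), nH, B * T, false, true);
    mat dc_flat(dc_acc.memptr(), nH, B * T, false, true);
    mat dh_flat(dh_acc.memptr(), nH, B * T, false, true);
    dWc = dash_flat * cs_flat.t();
    dWy = dash_flat * hs_flat.t();
    dc_flat += Wc.t() * dash_flat;
    dh_flat += Wy.t() * dash_flat;
  }

  cube dX(D, B, want_dx ? T : 0, fill::zeros);
  cube dX_dummy(0, 0, 0);
  cube& dX_ref = want_dx ? dX : dX_dummy;
  lstm_backward_dir(Wx, Wh, X, false, 0, hs, cs, cache->tanhc, cache->gates,
                    dh_acc, dc_acc, dWx, dWh, db, dX_ref, want_dx);

  List out = List::create(
    _["dWx"] = dWx, _["dWh"] = dWh, _["db"] = db,
    _["dWc"] = dWc, _["dWy"] = dWy, _["dBa"] = dBa, _["dV"] = dV,
    _["dW1"] = dW1, _["db1"] = db1, _["dW2"] = dW2, _["db2"] = db2);

  if (bidir) {
    mat Wx_r = params["Wx_r"], Wh_r = params["Wh_r"];
    mat dWx_r(size(Wx_r), fill::zeros), dWh_r(size(Wh_r), fill::zeros);
    vec db_r(4 * H, fill::zeros);
    lstm_backward_dir(Wx_r, Wh_r, X, true, H, hs, cs, cache->tanhc,
                      cache->gates_r, dh_acc, dc_acc, dWx_r, dWh_r, db_r,
                      dX_ref, want_dx);
    out["dWx_r"] = dWx_r;
    out["dWh_r"] = dWh_r;
    out["db_r"] = db_r;
  }
  if (want_dx) out["dX"] = dX;
  return out;
}

// 1-D convolution + ReLU + max-pool front-end for the one-hot pathway.
// X: cube(C, B, L); Wk: (Dout x C*wk); pool: width == stride.
// [[Rcpp::export]]
List conv_forward_cpp(const arma::mat& Wk, const arma::vec& bk,
                      const arma::cube& X, int pool) {
  const uword C = X.n_rows, B = X.n_cols, L = X.n_slices;
  const uword Dout = Wk.n_rows, wk = Wk.n_cols / C;
  if (L < wk) stop("sequence shorter than convolution width");
  const uword Lc = L - wk + 1;
  const uword T = Lc / (uword)pool;
  if (T == 0) stop("sequence too short after pooling");

  cube Zpre(Dout, B, Lc);
  mat col(C * wk, B);
  for (uword t = 0; t < Lc; ++t) {
    for (uword q = 0; q < wk; ++q)
      col.rows(q * C, (q + 1) * C - 1) = X.slice(t + q);
    mat z = Wk * col;
    z.each_col() += bk;
    Zpre.slice(t) = z;
  }

  cube P(Dout, B, T);
  cube amax(Dout, B, T);
  for (uword s = 0; s < T; ++s) {
    mat best = Zpre.slice(s * pool);
    mat arg(Dout, B);
    arg.fill((double)(s * pool));
    for (uword q = 1; q < (uword)pool; ++q) {
      const mat& cand = Zpre.slice(s * pool + q);
      for (uword jb = 0; jb < B; ++jb)
        for (uword id = 0; id < Dout; ++id)
          if (cand(id, jb) > best(id, jb)) {
            best(id, jb) = cand(id, jb);
            arg(id, jb) = (double)(s * pool + q);
          }
    }
    best.elem(find(best < 0)).zeros();  // relu-then-max == max-then-relu
    P.slice(s) = best;
    amax.slice(s) = arg;
  }
  return List::create(_["out"] = P, _["Zpre"] = Zpre, _["amax"] = amax,
                      _["pool"] = pool, _["wk"] = (int)wk);
}

// [[Rcpp::export]]
List conv_backward_cpp(const arma::mat& Wk, const List& cache,
                       const arma::cube& X, const arma::cube& dP) {
  const uword C = X.n_rows, B = X.n_cols, L = X.n_slices;
  const uword Dout = Wk.n_rows, wk = Wk.n_cols / C;
  cube Zpre = cache["Zpre"], amax = cache["amax"];
  const uword Lc = Zpre.n_slices, T = dP.n_slices;

  cube dZ(Dout, B, Lc, fill::zeros);
  for (uword s = 0; s < T; ++s)
    for (uword jb = 0; jb < B; ++jb)
      for (uword id = 0; id < Dout; ++id) {
        uword t = (uword)amax(id, jb, s);
        if (Zpre(id, jb, t) > 0) dZ(id, jb, t) += dP(id, jb, s);
      }

  mat dWk(size(Wk), fill::zeros);
  vec dbk(Dout, fill::zeros);
  cube dX(C, B, L, fill::zeros);
  mat col(C * wk, B);
  for (uword t = 0; t < Lc; ++t) {
    for (uword q = 0; q < wk; ++q)
      col.rows(q * C, (q + 1) * C - 1) = X.slice(t + q);
    const mat& dz = dZ.slice(t);
    dWk += dz * col.t();
    dbk += sum(dz, 1);
    mat dcol = Wk.t() * dz;
    for (uword q = 0; q < wk; ++q)
      dX.slice(t + q) += dcol.rows(q * C, (q + 1) * C - 1);
  }
  return List::create(_["dWk"] = dWk, _["dbk"] = dbk, _["dX"] = dX);
}
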