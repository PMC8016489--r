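// Pooled-timestep stacked bidirectional LSTM for base-wise sequence labeling.
//
// The network reads a one-hot (or fractional, for ambiguity codes) encoded
// DNA sequence of length L x 4, groups `pool` consecutive bases into one
// recurrent timestep (input dim 4*pool), runs n_layers bidirectional LSTM
// layers of `units` per direction with layer normalization on the
// concatenated output between consecutive layers, and maps each timestep
// through a shared dense head to pool*n_classes logits, i.e. an independent
// softmax over the classes at every base. No length-fixed layer exists, so
// any L divisible by pool is accepted at inference time.
//
// Parameters live in ONE flat vector; arma matrix views alias its memory.
// Layout (in order):
//   for l in 0..n_layers-1, for dir in {fwd, bwd}:
//       W (4U x D_l), R (4U x U), b (4U)        gate order [i, f, g, o]
//   for l in 0..n_layers-2:  ln_gamma (2U), ln_beta (2U)
//   Wo (pool*n_classes x 2U), bo (pool*n_classes)
// with D_0 = 4*pool and D_l = 2U for l > 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct NetCfg {
  int n_layers, units, pool, n_classes;
  int d0() const { return 4 * pool; }
  int dout() const { return n_classes * pool; }
};

NetCfg read_cfg(const List& cfg) {
  NetCfg c;
  c.n_layers  = as<int>(cfg["n_layers"]);
  c.units     = as<int>(cfg["units"]);
  c.pool      = as<int>(cfg["pool"]);
  c.n_classes = as<int>(cfg["n_classes"]);
  if (c.n_layers < 1 || c.units < 1 || c.pool < 1 || c.n_classes < 1)
    stop("invalid network configuration");
  return c;
}

std::vector<uword> in_dims(const NetCfg& c) {
  std::vector<uword> d(c.n_layers);
  d[0] = c.d0();
  for (int l = 1; l < c.n_layers; ++l) d[l] = 2 * (uword)c.units;
  return d;
}

uword count_params(const NetCfg& c) {
  uword U = c.units, n = 0;
  std::vector<uword> d = in_dims(c);
  for (int l = 0; l < c.n_layers; ++l)
    n += 2 * (4 * U * d[l] + 4 * U * U + 4 * U);
  n += (uword)(c.n_layers - 1) * 2 * (2 * U);
  n += (uword)c.dout() * 2 * U + c.dout();
  return n;
}

// Non-owning views into a flat parameter (or gradient) buffer.
struct Views {
  std::vector<mat> W, R;   // index l*2 + dir
  std::vector<vec> b;
  std::vector<vec> lng, lnb;
  mat Wo;
  vec bo;
};

Views make_views(double* p, const NetCfg& c) {
  Views v;
  uword U = c.units, off = 0;
  std::vector<uword> d = in_dims(c);
  v.W.reserve(2 * c.n_layers);
  v.R.reserve(2 * c.n_layers);
  v.b.reserve(2 * c.n_layers);
  v.lng.reserve(c.n_layers - 1);
  v.lnb.reserve(c.n_layers - 1);
  for (int l = 0; l < c.n_layers; ++l) {
    for (int dir = 0; dir < 2; ++dir) {
      v.W.emplace_back(p + off, 4 * U, d[l], false, true); off += 4 * U * d[l];
      v.R.emplace_back(p + off, 4 * U, U, false, true);    off += 4 * U * U;
      v.b.emplace_back(p + off, 4 * U, false, true);       off += 4 * U;
    }
  }
  for (int l = 0; l < c.n_layers - 1; ++l) {
    v.lng.emplace_back(p + off, 2 * U, false, true); off += 2 * U;
    v.lnb.emplace_back(p + off, 2 * U, false, true); off += 2 * U;
  }
  v.Wo = mat(p + off, c.dout(), 2 * U, false, true); off += (uword)c.dout() * 2 * U;
  v.bo = vec(p + off, c.dout(), false, true);        off += c.dout();
  return v;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct DirCache { cube I, F, G, O, C, TC, H; };

// One LSTM direction over a batch. Xin: (D x B x T). Fills H (U x B x T).
// `rmask` (U x B, or empty) is a variational recurrent-dropout mask: the
// same units are dropped from the recurrent path at every timestep.
void lstm_dir_fwd(const mat& W, const mat& Rm, const vec& b, const cube& Xin,
                  bool rev, DirCache& cc, bool keep,
                  const mat& rmask = mat()) {
  const uword U = Rm.n_cols, B = Xin.n_cols, T = Xin.n_slices;
  const bool use_mask = rmask.n_elem > 0;
  cc.H.set_size(U, B, T);
  if (keep) {
    cc.I.set_size(U, B, T); cc.F.set_size(U, B, T); cc.G.set_size(U, B, T);
    cc.O.set_size(U, B, T); cc.C.set_size(U, B, T); cc.TC.set_size(U, B, T);
  }
  mat h(U, B, fill::zeros), c(U, B, fill::zeros);
  for (uword s = 0; s < T; ++s) {
    const uword t = rev ? (T - 1 - s) : s;
    mat a = W * Xin.slice(t);
    if (use_mask) a += Rm * (h % rmask); else a += Rm * h;
    a.each_col() += b;
    mat i = sigm(a.rows(0, U - 1));
    mat f = sigm(a.rows(U, 2 * U - 1));
    mat g = tanh(a.rows(2 * U, 3 * U - 1));
    mat o = sigm(a.rows(3 * U, 4 * U - 1));
    c = f % c + i % g;
    mat tc = tanh(c);
    h = o % tc;
    cc.H.slice(t) = h;
    if (keep) {
      cc.I.slice(t) = i; cc.F.slice(t) = f; cc.G.slice(t) = g;
      cc.O.slice(t) = o; cc.C.slice(t) = c; cc.TC.slice(t) = tc;
    }
  }
}

// Backward through one direction; accumulates into dW, dR, db and dXin.
void lstm_dir_bwd(const mat& W, const mat& Rm, const cube& Xin, bool rev,
                  const DirCache& cc, const cube& dH, cube& dXin,
                  mat& dW, mat& dR, vec& db, const mat& rmask = mat()) {
  const uword U = Rm.n_cols, B = Xin.n_cols, T = Xin.n_slices;
  const bool use_mask = rmask.n_elem > 0;
  mat dh_next(U, B, fill::zeros), dc_next(U, B, fill::zeros);
  for (sword s = T - 1; s >= 0; --s) {
    const uword t = rev ? (T - 1 - s) : s;
    const uword tprev = rev ? (t + 1) : (t - 1);  // only used when s > 0
    const mat& i = cc.I.slice(t);
    const mat& f = cc.F.slice(t);
    const mat& g = cc.G.slice(t);
    const mat& o = cc.O.slice(t);
    const mat& tc = cc.TC.slice(t);
    mat dh = dH.slice(t) + dh_next;
    mat dop = dh % tc;
    mat dc = dh % o % (1.0 - square(tc)) + dc_next;
    mat di = dc % g;
    mat dg = dc % i;
    mat df;
    if (s > 0) df = dc % cc.C.slice(tprev);
    else       df = zeros<mat>(U, B);
    mat da(4 * U, B);
    da.rows(0, U - 1)         = di % i % (1.0 - i);
    da.rows(U, 2 * U - 1)     = df % f % (1.0 - f);
    da.rows(2 * U, 3 * U - 1) = dg % (1.0 - square(g));
    da.rows(3 * U, 4 * U - 1) = dop % o % (1.0 - o);
    dW += da * Xin.slice(t).t();
    if (s > 0) {
      if (use_mask) dR += da * (cc.H.slice(tprev) % rmask).t();
      else dR += da * cc.H.slice(tprev).t();
    }
    db += sum(da, 1);
    dXin.slice(t) += W.t() * da;
    dh_next = Rm.t() * da;
    if (use_mask) dh_next %= rmask;
    dc_next = dc % f;
  }
}

const double LN_EPS = 1e-5;

// Layer norm across features (rows) per sample-timestep column.
void ln_fwd(const vec& g, const vec& b, const cube& X, cube& Y,
            cube& XH, mat& ISTD, bool keep) {
  const uword F = X.n_rows, B = X.n_cols, T = X.n_slices;
  Y.set_size(F, B, T);
  if (keep) { XH.set_size(F, B, T); ISTD.set_size(B, T); }
  for (uword t = 0; t < T; ++t) {
    mat x = X.slice(t);
    rowvec mu = mean(x, 0);
    x.each_row() -= mu;
    rowvec istd = 1.0 / sqrt(mean(square(x), 0) + LN_EPS);
    x.each_row() %= istd;            // x is now xhat
    mat y = x;
    y.each_col() %= g;
    y.each_col() += b;
    Y.slice(t) = y;
    if (keep) { XH.slice(t) = x; ISTD.col(t) = istd.t(); }
  }
}

void ln_bwd(const vec& g, const cube& XH, const mat& ISTD, const cube& dY,
            cube& dX, vec& dg, vec& db) {
  const uword B = dY.n_cols, T = dY.n_slices;
  dX.set_size(size(dY));
  for (uword t = 0; t < T; ++t) {
    const mat& dy = dY.slice(t);
    const mat& xh = XH.slice(t);
    dg += sum(dy % xh, 1);
    db += sum(dy, 1);
    mat dxh = dy;
    dxh.each_col() %= g;
    rowvec m1 = mean(dxh, 0);
    rowvec m2 = mean(dxh % xh, 0);
    mat dx = dxh;
    dx.each_row() -= m1;
    mat t2 = xh;
    t2.each_row() %= m2;
    dx -= t2;
    rowvec istd = ISTD.col(t).t();
    dx.each_row() %= istd;
    dX.slice(t) = dx;
  }
  (void)B;
}

// Assemble the pooled-timestep input cube from L x 4 chunk matrices.
cube pool_inputs(const std::vector<NumericMatrix>& Xs, const NetCfg& c) {
  const uword B = Xs.size();
  const uword L = Xs[0].nrow();
  const uword T = L / c.pool;
  cube X0(c.d0(), B, T);
  for (uword b = 0; b < B; ++b) {
    const NumericMatrix& X = Xs[b];
    for (uword t = 0; t < T; ++t)
      for (int j = 0; j < c.pool; ++j)
        for (int k = 0; k < 4; ++k)
          X0(4 * j + k, b, t) = X(t * c.pool + j, k);
  }
  return X0;
}

struct FwdState {
  std::vector<cube> inputs;          // layer inputs: inputs[0] = pooled X
  std::vector<DirCache> dirs;        // index l*2 + dir
  std::vector<cube> hcat;            // concatenated output per layer
  std::vector<cube> ln_xh;           // per LN
  std::vector<mat> ln_istd;
  std::vector<cube> drop_mask;       // inverted-dropout masks per LN site
  std::vector<mat> rmasks;           // recurrent masks, index l*2 + dir
};

// Full forward pass; returns top hidden cube (2U x B x T) in st.hcat.back()
// (after LN for non-final layers the normalized version feeds the next layer;
// the head reads the final layer's raw concatenation).
// `dropout` > 0 (training only) applies inverted dropout to the normalized
// between-layer activations, using R's RNG (seeded from the R side).
void net_forward(const Views& v, const NetCfg& c, const cube& X0,
                 FwdState& st, bool keep, double dropout = 0.0,
                 double rdrop = 0.0) {
  const uword U = c.units, B = X0.n_cols, T = X0.n_slices;
  st.inputs.clear(); st.hcat.clear();
  st.dirs.assign(2 * c.n_layers, DirCache());
  st.ln_xh.assign(c.n_layers - 1, cube());
  st.ln_istd.assign(c.n_layers - 1, mat());
  st.drop_mask.assign(c.n_layers - 1, cube());
  st.rmasks.assign(2 * c.n_layers, mat());
  if (rdrop > 0.0) {
    const double scale = 1.0 / (1.0 - rdrop);
    for (int k = 0; k < 2 * c.n_layers; ++k) {
      st.rmasks[k].set_size(U, B);
      for (uword i = 0; i < st.rmasks[k].n_elem; ++i)
        st.rmasks[k](i) = (R::unif_rand() < rdrop) ? 0.0 : scale;
    }
  }
  st.inputs.push_back(X0);
  for (int l = 0; l < c.n_layers; ++l) {
    const cube& in = st.inputs[l];
    lstm_dir_fwd(v.W[2 * l], v.R[2 * l], v.b[2 * l], in, false,
                 st.dirs[2 * l], keep, st.rmasks[2 * l]);
    lstm_dir_fwd(v.W[2 * l + 1], v.R[2 * l + 1], v.b[2 * l + 1], in, true,
                 st.dirs[2 * l + 1], keep, st.rmasks[2 * l + 1]);
    cube hc(2 * U, B, T);
    for (uword t = 0; t < T; ++t)
      hc.slice(t) = join_cols(st.dirs[2 * l].H.slice(t),
                              st.dirs[2 * l + 1].H.slice(t));
    if (!keep) { st.dirs[2 * l].H.reset(); st.dirs[2 * l + 1].H.reset(); }
    st.hcat.push_back(hc);
    if (l < c.n_layers - 1) {
      cube y;
      ln_fwd(v.lng[l], v.lnb[l], hc, y, st.ln_xh[l], st.ln_istd[l], keep);
      if (dropout > 0.0) {
        cube& mk = st.drop_mask[l];
        mk.set_size(size(y));
        const double scale = 1.0 / (1.0 - dropout);
        for (uword i = 0; i < mk.n_elem; ++i)
          mk(i) = (R::unif_rand() < dropout) ? 0.0 : scale;
        y %= mk;
      }
      st.inputs.push_back(y);
    }
  }
}

// Per-base softmax probabilities for one batch member, from head logits.
// Z: (dout x T) for that member -> L x 4 matrix.
NumericMatrix logits_to_probs(const mat& Z, const NetCfg& c) {
  const uword T = Z.n_cols;
  const uword L = T * c.pool;
  NumericMatrix P(L, c.n_classes);
  for (uword t = 0; t < T; ++t) {
    for (int j = 0; j < c.pool; ++j) {
      vec z = Z.col(t).rows(c.n_classes * j, c.n_classes * (j + 1) - 1);
      z -= z.max();
      vec e = exp(z);
      e /= accu(e);
      for (int k = 0; k < c.n_classes; ++k)
        P(t * c.pool + j, k) = e(k);
    }
  }
  return P;
}

}  // namespace

// [[Rcpp::export]]
double nn_param_count_cpp(List cfg) {
  return (double)count_params(read_cfg(cfg));
}

// [[Rcpp::export]]
NumericVector nn_init_params_cpp(List cfg) {
  NetCfg c = read_cfg(cfg);
  const uword n = count_params(c);
  NumericVector out(n);
  std::vector<double> buf(n, 0.0);
  Views v = make_views(buf.data(), c);
  const uword U = c.units;
  std::vector<uword> d = in_dims(c);
  for (int l = 0; l < c.n_layers; ++l) {
    for (int dir = 0; dir < 2; ++dir) {
      double limW = std::sqrt(6.0 / (d[l] + 4.0 * U));
      double limR = std::sqrt(6.0 / (U + 4.0 * U));
      mat& W = v.W[2 * l + dir];
      mat& R = v.R[2 * l + dir];
      for (uword i = 0; i < W.n_elem; ++i) W(i) = R::runif(-limW, limW);
      for (uword i = 0; i < R.n_elem; ++i) R(i) = R::runif(-limR, limR);
      v.b[2 * l + dir].zeros();
      v.b[2 * l + dir].rows(U, 2 * U - 1).fill(1.0);  // forget-gate bias
    }
  }
  for (int l = 0; l < c.n_layers - 1; ++l) {
    v.lng[l].ones();
    v.lnb[l].zeros();
  }
  double limO = std::sqrt(6.0 / (2.0 * U + c.dout()));
  for (uword i = 0; i < v.Wo.n_elem; ++i) v.Wo(i) = R::runif(-limO, limO);
  v.bo.zeros();
  std::copy(buf.begin(), buf.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List nn_forward_cpp(NumericVector params, List cfg, List X_list) {
  NetCfg c = read_cfg(cfg);
  if ((uword)params.size() != count_params(c))
    stop("parameter vector length does not match configuration");
  std::vector<double> buf(params.begin(), params.end());
  Views v = make_views(buf.data(), c);
  const int n = X_list.size();
  List out(n);
  for (int idx = 0; idx < n; ++idx) {
    NumericMatrix X = X_list[idx];
    if (X.ncol() != 4) stop("input matrices must have 4 columns");
    if (X.nrow() % c.pool != 0)
      stop("input length must be divisible by the pool size");
    std::vector<NumericMatrix> Xs{X};
    cube X0 = pool_inputs(Xs, c);
    FwdState st;
    net_forward(v, c, X0, st, false);
    const cube& top = st.hcat.back();
    const uword T = top.n_slices;
    mat Z(c.dout(), T);
    for (uword t = 0; t < T; ++t) Z.col(t) = v.Wo * top.slice(t) + v.bo;
    out[idx] = logits_to_probs(Z, c);
  }
  return out;
}

// [[Rcpp::export]]
List nn_train_epoch_cpp(NumericVector params, NumericVector adam_m,
                        NumericVector adam_v, int adam_step, List cfg,
                        List X_list, List y_list, List w_list,
                        NumericVector class_weights, double lr,
                        IntegerVector batch_order, int batch_size,
                        double grad_clip, double dropout,
                        double input_mask_rate, double weight_decay,
                        double recurrent_dropout) {
  NetCfg c = read_cfg(cfg);
  const uword np = count_params(c);
  if ((uword)params.size() != np) stop("parameter length mismatch");
  std::vector<double> pbuf(params.begin(), params.end());
  std::vector<double> mbuf(adam_m.begin(), adam_m.end());
  std::vector<double> vbuf(adam_v.begin(), adam_v.end());
  Views v = make_views(pbuf.data(), c);
  vec cw(class_weights.begin(), class_weights.size());
  if ((int)cw.n_elem != c.n_classes) stop("need one class weight per class");

  const int n_chunks = batch_order.size();
  double loss_num = 0.0, loss_den = 0.0;
  const double b1 = 0.9, b2 = 0.999, adam_eps = 1e-8;
  int step = adam_step;

  for (int start = 0; start < n_chunks; start += batch_size) {
    const int B = std::min(batch_size, n_chunks - start);
    std::vector<NumericMatrix> Xs;
    std::vector<IntegerVector> ys;
    std::vector<NumericVector> ws;
    Xs.reserve(B); ys.reserve(B); ws.reserve(B);
    for (int b = 0; b < B; ++b) {
      int k = batch_order[start + b] - 1;
      Xs.push_back(as<NumericMatrix>(X_list[k]));
      ys.push_back(as<IntegerVector>(y_list[k]));
      ws.push_back(as<NumericVector>(w_list[k]));
    }
    const uword L = Xs[0].nrow();
    if (L % c.pool != 0) stop("chunk length must be divisible by pool size");
    for (int b = 1; b < B; ++b)
      if ((uword)Xs[b].nrow() != L)
        stop("all chunks in a batch must share one length");
    const uword T = L / c.pool;

    cube X0 = pool_inputs(Xs, c);
    // training-time base masking: random bases become the ambiguous
    // encoding [0.25 x4], forcing the model to lean on context
    if (input_mask_rate > 0) {
      for (uword b = 0; b < (uword)B; ++b)
        for (uword t = 0; t < T; ++t)
          for (int j = 0; j < c.pool; ++j)
            if (R::unif_rand() < input_mask_rate)
              for (int k = 0; k < 4; ++k) X0(4 * j + k, b, t) = 0.25;
    }
    FwdState st;
    net_forward(v, c, X0, st, true, dropout, recurrent_dropout);
    const cube& top = st.hcat.back();

    // head forward + loss gradient (dZ), normalized by total batch weight
    double wsum = 0.0;
    for (int b = 0; b < B; ++b)
      for (uword l = 0; l < L; ++l) {
        int y = ys[b][l];
        if (y >= 0 && ws[b][l] > 0) wsum += ws[b][l] * cw(y);
      }
    if (wsum <= 0) continue;  // fully masked batch: zero loss, no update

    std::vector<double> gbuf(np, 0.0);
    Views gv = make_views(gbuf.data(), c);
    cube dTop(2 * (uword)c.units, B, T, fill::zeros);
    double batch_loss = 0.0;
    for (uword t = 0; t < T; ++t) {
      mat Z = v.Wo * top.slice(t);
      Z.each_col() += v.bo;
      mat dZ(c.dout(), B, fill::zeros);
      for (int b = 0; b < B; ++b) {
        for (int j = 0; j < c.pool; ++j) {
          const uword l = t * c.pool + j;
          const int y = ys[b][l];
          const double sw = ws[b][l];
          vec z = Z.col(b).rows(c.n_classes * j, c.n_classes * (j + 1) - 1);
          z -= z.max();
          vec e = exp(z);
          e /= accu(e);
          if (y >= 0 && sw > 0) {
            const double wgt = sw * cw(y) / wsum;
            batch_loss += wgt * (-std::log(std::max(e(y), 1e-12)));
            vec d = e * wgt;
            d(y) -= wgt;
            dZ.col(b).rows(c.n_classes * j, c.n_classes * (j + 1) - 1) = d;
          }
        }
      }
      gv.Wo += dZ * top.slice(t).t();
      gv.bo += sum(dZ, 1);
      dTop.slice(t) = v.Wo.t() * dZ;
    }
    loss_num += batch_loss * wsum;
    loss_den += wsum;

    // backward through layers (head gradient dTop on final concatenation)
    cube dcur = dTop;
    for (int l = c.n_layers - 1; l >= 0; --l) {
      const uword U = c.units;
      cube dHf(U, B, T), dHb(U, B, T);
      for (uword t = 0; t < T; ++t) {
        dHf.slice(t) = dcur.slice(t).rows(0, U - 1);
        dHb.slice(t) = dcur.slice(t).rows(U, 2 * U - 1);
      }
      const cube& in = st.inputs[l];  // post-dropout input of layer l
      cube dIn(in.n_rows, B, T, fill::zeros);
      lstm_dir_bwd(v.W[2 * l], v.R[2 * l], in, false, st.dirs[2 * l], dHf,
                   dIn, gv.W[2 * l], gv.R[2 * l], gv.b[2 * l],
                   st.rmasks[2 * l]);
      lstm_dir_bwd(v.W[2 * l + 1], v.R[2 * l + 1], in, true,
                   st.dirs[2 * l + 1], dHb, dIn, gv.W[2 * l + 1],
                   gv.R[2 * l + 1], gv.b[2 * l + 1], st.rmasks[2 * l + 1]);
      if (l > 0) {
        // dIn is the gradient at the (dropped-out) LN(l-1) output
        if (dropout > 0.0) dIn %= st.drop_mask[l - 1];
        cube dpre;
        ln_bwd(v.lng[l - 1], st.ln_xh[l - 1], st.ln_istd[l - 1], dIn, dpre,
               gv.lng[l - 1], gv.lnb[l - 1]);
        dcur = dpre;
      }
    }

    // global gradient-norm clipping (LSTM gradients can spike)
    if (grad_clip > 0) {
      double nrm = 0.0;
      for (uword i = 0; i < np; ++i) nrm += gbuf[i] * gbuf[i];
      nrm = std::sqrt(nrm);
      if (nrm > grad_clip) {
        const double s = grad_clip / nrm;
        for (uword i = 0; i < np; ++i) gbuf[i] *= s;
      }
    }

    // Adam update
    ++step;
    const double bc1 = 1.0 - std::pow(b1, step);
    const double bc2 = 1.0 - std::pow(b2, step);
    for (uword i = 0; i < np; ++i) {
      const double g = gbuf[i];
      mbuf[i] = b1 * mbuf[i] + (1.0 - b1) * g;
      vbuf[i] = b2 * vbuf[i] + (1.0 - b2) * g * g;
      pbuf[i] -= lr * (mbuf[i] / bc1) / (std::sqrt(vbuf[i] / bc2) + adam_eps);
      if (weight_decay > 0) pbuf[i] -= lr * weight_decay * pbuf[i];
    }
    Rcpp::checkUserInterrupt();
  }

  NumericVector p_out(pbuf.begin(), pbuf.end());
  NumericVector m_out(mbuf.begin(), mbuf.end());
  NumericVector v_out(vbuf.begin(), vbuf.end());
  return List::create(_["params"] = p_out, _["adam_m"] = m_out,
                      _["adam_v"] = v_out, _["adam_step"] = step,
                      _["loss"] = loss_den > 0 ? loss_num / loss_den : 0.0);
}
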