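// Sequence regression network for peptide retention time:
//   one-hot input -> conv blocks -> bidirectional GRU (fixed width)
//   -> dense blocks -> linear output, trained by minibatch SGD variants
//   with early stopping on validation MSE.
//
// Forward, backprop (conv / batch-norm / max-pool / GRU) and the three
// optimizers are implemented here; gradients are covered by
// finite-difference tests on the R side.  Parameters live in one flat
// vector; every routine walks the blocks in the same canonical order:
//   conv layers (W-1, W0, W+1, bias[, gamma, beta]) ->
//   GRU forward then backward direction (Wz,Wr,Wh,Uz,Ur,Uh,bz,br,bh) ->
//   dense layers (W, bias[, gamma, beta]) -> output (w, b).
// Batch-norm running means/vars live in a second flat vector in the same
// layer order (mean then var per normalized layer).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstring>

using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double BN_EPS = 1e-3;
static const double BN_MOMENTUM = 0.9;
static const double LEAKY_ALPHA = 0.3;

// ---------------------------------------------------------------- spec

struct ConvSpec {
  int filters;
  int act;          // 0 relu, 1 tanh, 2 leaky relu
  double dropout;
  bool bn;
  bool pool;
};

struct DenseSpec {
  int units;
  int act;
  double dropout;
  bool bn;
};

struct NetSpec {
  int A;            // alphabet size (input channels)
  int L;            // fixed sequence length
  int H;            // GRU units per direction
  std::vector<ConvSpec> conv;
  std::vector<DenseSpec> dense;
  int optimizer;    // 0 adam, 1 rmsprop, 2 sgd+momentum

  std::vector<int> conv_in;   // input channels per conv layer
  std::vector<int> conv_T;    // time length entering each conv layer
  int T_gru;                  // time length entering the GRU
  int gru_in;                 // channels entering the GRU
  std::vector<int> dense_in;  // input width per dense layer
  int out_in;                 // input width of the output unit
  size_t n_weights;
  size_t n_bnstate;
};

static NetSpec parse_spec(const Rcpp::List& s) {
  NetSpec sp;
  sp.A = Rcpp::as<int>(s["alphabet_size"]);
  sp.L = Rcpp::as<int>(s["fixed_length"]);
  sp.H = Rcpp::as<int>(s["gru_units"]);
  sp.optimizer = Rcpp::as<int>(s["optimizer"]);
  Rcpp::List conv = s["conv"];
  for (int i = 0; i < conv.size(); ++i) {
    Rcpp::List g = conv[i];
    ConvSpec c;
    c.filters = Rcpp::as<int>(g["filters"]);
    c.act = Rcpp::as<int>(g["act"]);
    c.dropout = Rcpp::as<double>(g["dropout"]);
    c.bn = Rcpp::as<bool>(g["batch_norm"]);
    c.pool = Rcpp::as<bool>(g["max_pool"]);
    sp.conv.push_back(c);
  }
  Rcpp::List dense = s["dense"];
  for (int i = 0; i < dense.size(); ++i) {
    Rcpp::List g = dense[i];
    DenseSpec d;
    d.units = Rcpp::as<int>(g["units"]);
    d.act = Rcpp::as<int>(g["act"]);
    d.dropout = Rcpp::as<double>(g["dropout"]);
    d.bn = Rcpp::as<bool>(g["batch_norm"]);
    sp.dense.push_back(d);
  }
  int C = sp.A, T = sp.L;
  for (size_t l = 0; l < sp.conv.size(); ++l) {
    sp.conv_in.push_back(C);
    sp.conv_T.push_back(T);
    C = sp.conv[l].filters;
    if (sp.conv[l].pool && T >= 2) T /= 2;
  }
  sp.T_gru = T;
  sp.gru_in = C;
  int W = 2 * sp.H;
  for (size_t l = 0; l < sp.dense.size(); ++l) {
    sp.dense_in.push_back(W);
    W = sp.dense[l].units;
  }
  sp.out_in = W;
  size_t nw = 0, nb = 0;
  for (size_t l = 0; l < sp.conv.size(); ++l) {
    nw += 3u * (size_t)sp.conv_in[l] * sp.conv[l].filters + sp.conv[l].filters;
    if (sp.conv[l].bn) {
      nw += 2u * sp.conv[l].filters;
      nb += 2u * sp.conv[l].filters;
    }
  }
  for (int d = 0; d < 2; ++d)
    nw += 3u * ((size_t)sp.gru_in * sp.H + (size_t)sp.H * sp.H + sp.H);
  for (size_t l = 0; l < sp.dense.size(); ++l) {
    nw += (size_t)sp.dense_in[l] * sp.dense[l].units + sp.dense[l].units;
    if (sp.dense[l].bn) {
      nw += 2u * sp.dense[l].units;
      nb += 2u * sp.dense[l].units;
    }
  }
  nw += (size_t)sp.out_in + 1u;
  sp.n_weights = nw;
  sp.n_bnstate = nb;
  return sp;
}

// Sequential block cursor over a flat vector.
struct Cursor {
  double* p;
  size_t pos;
  explicit Cursor(double* ptr) : p(ptr), pos(0) {}
  double* take(size_t k) { double* q = p + pos; pos += k; return q; }
  mat read_mat(int r, int c) { return mat(take((size_t)r * c), r, c); }
  rowvec read_row(int k) { return rowvec(take(k), k); }
  void write(const mat& M) {
    std::memcpy(take(M.n_elem), M.memptr(), M.n_elem * sizeof(double));
  }
  void write(const rowvec& V) {
    std::memcpy(take(V.n_elem), V.memptr(), V.n_elem * sizeof(double));
  }
};

// ------------------------------------------------------------ helpers

static inline void activate(mat& x, int act) {
  if (act == 0) x.transform([](double v) { return v > 0 ? v : 0.0; });
  else if (act == 1) x = arma::tanh(x);
  else x.transform([](double v) { return v > 0 ? v : LEAKY_ALPHA * v; });
}

// derivative given pre-activation input z
static inline mat act_deriv(const mat& z, int act) {
  mat d(arma::size(z));
  if (act == 0) {
    for (arma::uword i = 0; i < z.n_elem; ++i) d(i) = z(i) > 0 ? 1.0 : 0.0;
  } else if (act == 1) {
    d = 1.0 - arma::square(arma::tanh(z));
  } else {
    for (arma::uword i = 0; i < z.n_elem; ++i)
      d(i) = z(i) > 0 ? 1.0 : LEAKY_ALPHA;
  }
  return d;
}

static inline mat sigmoid(const mat& x) {
  return 1.0 / (1.0 + arma::exp(-x));
}

// -------------------------------------------------------- batch-norm

struct BNCache {
  mat xhat;
  rowvec inv_std;
};

// Normalizes columns over rows (conv layers stack batch x time into rows).
// Running stats are updated in place through raw pointers.
static mat bn_forward(const mat& x, const rowvec& gamma, const rowvec& beta,
                      double* run_mean, double* run_var,
                      bool training, BNCache* cache) {
  int F = x.n_cols;
  rowvec mu(F), var(F);
  if (training) {
    mu = arma::mean(x, 0);
    var = arma::var(x, 1, 0);  // biased, as used for normalization
    for (int f = 0; f < F; ++f) {
      run_mean[f] = BN_MOMENTUM * run_mean[f] + (1 - BN_MOMENTUM) * mu(f);
      run_var[f] = BN_MOMENTUM * run_var[f] + (1 - BN_MOMENTUM) * var(f);
    }
  } else {
    for (int f = 0; f < F; ++f) { mu(f) = run_mean[f]; var(f) = run_var[f]; }
  }
  rowvec inv_std = 1.0 / arma::sqrt(var + BN_EPS);
  mat xhat = x.each_row() - mu;
  xhat.each_row() %= inv_std;
  mat y = xhat.each_row() % gamma;
  y.each_row() += beta;
  if (cache) { cache->xhat = xhat; cache->inv_std = inv_std; }
  return y;
}

static mat bn_backward(const mat& dy, const BNCache& cache,
                       const rowvec& gamma, rowvec& dgamma, rowvec& dbeta) {
  const mat& xhat = cache.xhat;
  double m = (double)dy.n_rows;
  dgamma += arma::sum(dy % xhat, 0);
  dbeta += arma::sum(dy, 0);
  mat dxhat = dy.each_row() % gamma;
  rowvec s1 = arma::sum(dxhat, 0);
  rowvec s2 = arma::sum(dxhat % xhat, 0);
  mat dx = dxhat * m;
  dx.each_row() -= s1;
  dx -= xhat.each_row() % s2;
  dx.each_row() %= (cache.inv_std / m);
  return dx;
}

// ---------------------------------------------------------- GRU cell

struct GRUWeights {
  mat Wz, Wr, Wh, Uz, Ur, Uh;
  rowvec bz, br, bh;
  void zeros(int in, int H) {
    Wz.zeros(in, H); Wr.zeros(in, H); Wh.zeros(in, H);
    Uz.zeros(H, H); Ur.zeros(H, H); Uh.zeros(H, H);
    bz.zeros(H); br.zeros(H); bh.zeros(H);
  }
};

static GRUWeights gru_read(Cursor& cur, int in, int H) {
  GRUWeights g;
  g.Wz = cur.read_mat(in, H);
  g.Wr = cur.read_mat(in, H);
  g.Wh = cur.read_mat(in, H);
  g.Uz = cur.read_mat(H, H);
  g.Ur = cur.read_mat(H, H);
  g.Uh = cur.read_mat(H, H);
  g.bz = cur.read_row(H);
  g.br = cur.read_row(H);
  g.bh = cur.read_row(H);
  return g;
}

static void gru_write(Cursor& cur, const GRUWeights& g) {
  cur.write(g.Wz); cur.write(g.Wr); cur.write(g.Wh);
  cur.write(g.Uz); cur.write(g.Ur); cur.write(g.Uh);
  cur.write(g.bz); cur.write(g.br); cur.write(g.bh);
}

struct GRUCache {
  std::vector<mat> z, r, hc, h_prev;
  mat Xall;  // inputs flattened (n*T x C), rows grouped by step index
};

// Runs a GRU over the slices of X in the order given by `order`;
// h_t = z_t.h_{t-1} + (1 - z_t).htilde_t.  Returns the final state.
// The input projections of all steps are computed as one large GEMM and
// the z/r recurrent projections are joined, which dominates runtime.
static mat gru_forward(const cube& X, const GRUWeights& w, int H,
                       const std::vector<int>& order, GRUCache* cache) {
  int n = X.n_rows, C = X.n_cols, T = (int)order.size();
  mat Wjoin(C, 3 * H);
  Wjoin.cols(0, H - 1) = w.Wz;
  Wjoin.cols(H, 2 * H - 1) = w.Wr;
  Wjoin.cols(2 * H, 3 * H - 1) = w.Wh;
  mat Uzr(H, 2 * H);
  Uzr.cols(0, H - 1) = w.Uz;
  Uzr.cols(H, 2 * H - 1) = w.Ur;
  mat Xall(n * T, C);
  for (int k = 0; k < T; ++k)
    Xall.rows(k * n, k * n + n - 1) = X.slice(order[k]);
  mat P = Xall * Wjoin;
  mat h(n, H, arma::fill::zeros);
  for (int k = 0; k < T; ++k) {
    mat hU = h * Uzr;
    mat z = P.submat(k * n, 0, k * n + n - 1, H - 1) + hU.cols(0, H - 1);
    z.each_row() += w.bz;
    z = sigmoid(z);
    mat r = P.submat(k * n, H, k * n + n - 1, 2 * H - 1) +
            hU.cols(H, 2 * H - 1);
    r.each_row() += w.br;
    r = sigmoid(r);
    mat hc = P.submat(k * n, 2 * H, k * n + n - 1, 3 * H - 1) +
             (r % h) * w.Uh;
    hc.each_row() += w.bh;
    hc = arma::tanh(hc);
    mat h_new = z % h + (1.0 - z) % hc;
    if (cache) {
      cache->z.push_back(z);
      cache->r.push_back(r);
      cache->hc.push_back(hc);
      cache->h_prev.push_back(h);
    }
    h = h_new;
  }
  if (cache) cache->Xall = std::move(Xall);
  return h;
}

// Backpropagates the gradient of the final state through the GRU;
// accumulates weight grads into `gw` and input grads into dX.  The
// per-step pre-activation gradients are collected and turned into the
// input-side gradients by two large GEMMs after the recurrence.
static void gru_backward(const GRUCache& cache, const GRUWeights& w,
                         GRUWeights& gw, const mat& dh_final,
                         cube& dX, const std::vector<int>& order) {
  int T = (int)order.size();
  int H = w.Uz.n_rows;
  int n = dh_final.n_rows;
  mat Uzr(H, 2 * H);
  Uzr.cols(0, H - 1) = w.Uz;
  Uzr.cols(H, 2 * H - 1) = w.Ur;
  mat dPall(n * T, 3 * H);
  mat dUzr(H, 2 * H, arma::fill::zeros);
  mat dh = dh_final;
  for (int k = T - 1; k >= 0; --k) {
    const mat& z = cache.z[k];
    const mat& r = cache.r[k];
    const mat& hc = cache.hc[k];
    const mat& hp = cache.h_prev[k];
    mat dz = dh % (hp - hc);
    mat dhc = dh % (1.0 - z);
    mat dh_prev = dh % z;
    mat dhc_pre = dhc % (1.0 - arma::square(hc));
    mat dz_pre = dz % (z % (1.0 - z));
    mat drh = dhc_pre * w.Uh.t();
    mat dr = drh % hp;
    dh_prev += drh % r;
    mat dr_pre = dr % (r % (1.0 - r));
    mat dZR = arma::join_rows(dz_pre, dr_pre);
    gw.Uh += (r % hp).t() * dhc_pre;
    dUzr += hp.t() * dZR;
    dh_prev += dZR * Uzr.t();
    dPall.submat(k * n, 0, k * n + n - 1, H - 1) = dz_pre;
    dPall.submat(k * n, H, k * n + n - 1, 2 * H - 1) = dr_pre;
    dPall.submat(k * n, 2 * H, k * n + n - 1, 3 * H - 1) = dhc_pre;
    dh = dh_prev;
  }
  gw.Uz += dUzr.cols(0, H - 1);
  gw.Ur += dUzr.cols(H, 2 * H - 1);
  mat dWjoin = cache.Xall.t() * dPall;
  gw.Wz += dWjoin.cols(0, H - 1);
  gw.Wr += dWjoin.cols(H, 2 * H - 1);
  gw.Wh += dWjoin.cols(2 * H, 3 * H - 1);
  rowvec bsum = arma::sum(dPall, 0);
  gw.bz += bsum.cols(0, H - 1);
  gw.br += bsum.cols(H, 2 * H - 1);
  gw.bh += bsum.cols(2 * H, 3 * H - 1);
  mat Wjoin(cache.Xall.n_cols, 3 * H);
  Wjoin.cols(0, H - 1) = w.Wz;
  Wjoin.cols(H, 2 * H - 1) = w.Wr;
  Wjoin.cols(2 * H, 3 * H - 1) = w.Wh;
  mat dXall = dPall * Wjoin.t();
  for (int k = 0; k < T; ++k)
    dX.slice(order[k]) += dXall.rows(k * n, k * n + n - 1);
}

// ------------------------------------------------------------ network

struct ConvCache {
  mat input;             // layer input, flattened (n*T x C) time-major
  cube preact;           // after conv (+bn), before activation
  BNCache bn;
  arma::ucube pool_from; // which of each pooled pair was the max
  cube drop_mask;
};

struct DenseCache {
  mat input;
  mat preact;            // after bn, before activation
  BNCache bn;
  mat drop_mask;
};

struct ForwardCache {
  std::vector<ConvCache> conv;
  GRUCache gru_f, gru_b;
  std::vector<DenseCache> dense;
  mat out_input;
};

// one-hot expansion of token indices (0 = padding); layout n x A x L
static cube onehot(const Rcpp::IntegerMatrix& tok, int A) {
  int n = tok.nrow(), L = tok.ncol();
  cube X(n, A, L, arma::fill::zeros);
  for (int t = 0; t < L; ++t)
    for (int i = 0; i < n; ++i) {
      int a = tok(i, t);
      if (a > 0) X(i, a - 1, t) = 1.0;
    }
  return X;
}

static vec net_forward(const NetSpec& sp, const double* wptr, double* bnptr,
                       const cube& X0, bool training,
                       std::mt19937_64* rng, ForwardCache* fc) {
  Cursor cur(const_cast<double*>(wptr));
  Cursor bncur(bnptr);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  cube X = X0;
  int n = X.n_rows;
  if (fc) fc->conv.resize(sp.conv.size());
  for (size_t l = 0; l < sp.conv.size(); ++l) {
    const ConvSpec& c = sp.conv[l];
    int Cin = sp.conv_in[l], F = c.filters, T = sp.conv_T[l];
    mat W0 = cur.read_mat(Cin, F);
    mat W1 = cur.read_mat(Cin, F);
    mat W2 = cur.read_mat(Cin, F);
    rowvec b = cur.read_row(F);
    mat Xall(n * T, Cin);
    for (int t = 0; t < T; ++t)
      Xall.rows(t * n, t * n + n - 1) = X.slice(t);
    if (fc) fc->conv[l].input = Xall;
    mat A0 = Xall * W0;
    mat A1 = Xall * W1;
    mat A2 = Xall * W2;
    cube P(n, F, T);
    for (int t = 0; t < T; ++t) {
      mat s = A1.rows(t * n, t * n + n - 1);
      if (t > 0) s += A0.rows((t - 1) * n, t * n - 1);
      if (t < T - 1) s += A2.rows((t + 1) * n, (t + 2) * n - 1);
      s.each_row() += b;
      P.slice(t) = s;
    }
    if (c.bn) {
      rowvec gamma = cur.read_row(F);
      rowvec beta = cur.read_row(F);
      double* rm = bncur.take(F);
      double* rv = bncur.take(F);
      mat stacked(n * T, F);
      for (int t = 0; t < T; ++t)
        stacked.rows(t * n, t * n + n - 1) = P.slice(t);
      mat y = bn_forward(stacked, gamma, beta, rm, rv, training,
                         fc ? &fc->conv[l].bn : nullptr);
      for (int t = 0; t < T; ++t)
        P.slice(t) = y.rows(t * n, t * n + n - 1);
    }
    if (fc) fc->conv[l].preact = P;
    for (int t = 0; t < T; ++t) {
      mat s = P.slice(t);
      activate(s, c.act);
      P.slice(t) = s;
    }
    if (c.pool && T >= 2) {
      int Tp = T / 2;
      cube Q(n, F, Tp);
      arma::ucube from(n, F, Tp);
      for (int t = 0; t < Tp; ++t) {
        const mat& a = P.slice(2 * t);
        const mat& bm = P.slice(2 * t + 1);
        for (int j = 0; j < F; ++j)
          for (int i = 0; i < n; ++i) {
            if (a(i, j) >= bm(i, j)) {
              Q(i, j, t) = a(i, j);
              from(i, j, t) = 0;
            } else {
              Q(i, j, t) = bm(i, j);
              from(i, j, t) = 1;
            }
          }
      }
      if (fc) fc->conv[l].pool_from = from;
      P = Q;
    }
    if (training && c.dropout > 0) {
      cube msk(arma::size(P));
      double keep = 1.0 - c.dropout;
      for (arma::uword i = 0; i < msk.n_elem; ++i)
        msk(i) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
      P %= msk;
      if (fc) fc->conv[l].drop_mask = msk;
    }
    X = P;
  }
  int T = sp.T_gru, H = sp.H;
  std::vector<int> fwd(T), bwd(T);
  for (int t = 0; t < T; ++t) { fwd[t] = t; bwd[t] = T - 1 - t; }
  GRUWeights gf = gru_read(cur, sp.gru_in, H);
  GRUWeights gb = gru_read(cur, sp.gru_in, H);
  mat hf = gru_forward(X, gf, H, fwd, fc ? &fc->gru_f : nullptr);
  mat hb = gru_forward(X, gb, H, bwd, fc ? &fc->gru_b : nullptr);
  mat Y = arma::join_rows(hf, hb);
  if (fc) fc->dense.resize(sp.dense.size());
  for (size_t l = 0; l < sp.dense.size(); ++l) {
    const DenseSpec& d = sp.dense[l];
    int in = sp.dense_in[l], U = d.units;
    mat W = cur.read_mat(in, U);
    rowvec b = cur.read_row(U);
    if (fc) fc->dense[l].input = Y;
    mat Z = Y * W;
    Z.each_row() += b;
    if (d.bn) {
      rowvec gamma = cur.read_row(U);
      rowvec beta = cur.read_row(U);
      double* rm = bncur.take(U);
      double* rv = bncur.take(U);
      Z = bn_forward(Z, gamma, beta, rm, rv, training,
                     fc ? &fc->dense[l].bn : nullptr);
    }
    if (fc) fc->dense[l].preact = Z;
    activate(Z, d.act);
    if (training && d.dropout > 0) {
      mat msk(arma::size(Z));
      double keep = 1.0 - d.dropout;
      for (arma::uword i = 0; i < msk.n_elem; ++i)
        msk(i) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
      Z %= msk;
      if (fc) fc->dense[l].drop_mask = msk;
    }
    Y = Z;
  }
  if (fc) fc->out_input = Y;
  mat Wo = cur.read_mat(sp.out_in, 1);
  double bo = *cur.take(1);
  vec yhat = Y * Wo + bo;
  return yhat;
}

// Backward pass; writes the gradient (same layout as the weights) into g.
static void net_backward(const NetSpec& sp, const double* wptr, double* gptr,
                         const ForwardCache& fc, const vec& dyhat) {
  // read weights (copies) in canonical order
  Cursor wcur(const_cast<double*>(wptr));
  struct ConvW { mat W0, W1, W2; rowvec gamma; };
  std::vector<ConvW> cw(sp.conv.size());
  for (size_t l = 0; l < sp.conv.size(); ++l) {
    int Cin = sp.conv_in[l], F = sp.conv[l].filters;
    cw[l].W0 = wcur.read_mat(Cin, F);
    cw[l].W1 = wcur.read_mat(Cin, F);
    cw[l].W2 = wcur.read_mat(Cin, F);
    wcur.take(F);                         // bias not needed for backward
    if (sp.conv[l].bn) {
      cw[l].gamma = wcur.read_row(F);
      wcur.take(F);                       // beta
    }
  }
  GRUWeights gfw = gru_read(wcur, sp.gru_in, sp.H);
  GRUWeights gbw = gru_read(wcur, sp.gru_in, sp.H);
  struct DenseW { mat W; rowvec gamma; };
  std::vector<DenseW> dw(sp.dense.size());
  for (size_t l = 0; l < sp.dense.size(); ++l) {
    int in = sp.dense_in[l], U = sp.dense[l].units;
    dw[l].W = wcur.read_mat(in, U);
    wcur.take(U);
    if (sp.dense[l].bn) {
      dw[l].gamma = wcur.read_row(U);
      wcur.take(U);
    }
  }
  mat Wo = wcur.read_mat(sp.out_in, 1);

  // local gradient accumulators
  int n = dyhat.n_elem;
  struct ConvG { mat gW0, gW1, gW2; rowvec gb, ggamma, gbeta; };
  std::vector<ConvG> cg(sp.conv.size());
  for (size_t l = 0; l < sp.conv.size(); ++l) {
    int Cin = sp.conv_in[l], F = sp.conv[l].filters;
    cg[l].gW0.zeros(Cin, F);
    cg[l].gW1.zeros(Cin, F);
    cg[l].gW2.zeros(Cin, F);
    cg[l].gb.zeros(F);
    cg[l].ggamma.zeros(F);
    cg[l].gbeta.zeros(F);
  }
  GRUWeights gfg, gbg;
  gfg.zeros(sp.gru_in, sp.H);
  gbg.zeros(sp.gru_in, sp.H);
  struct DenseG { mat gW; rowvec gb, ggamma, gbeta; };
  std::vector<DenseG> dg(sp.dense.size());
  for (size_t l = 0; l < sp.dense.size(); ++l) {
    int in = sp.dense_in[l], U = sp.dense[l].units;
    dg[l].gW.zeros(in, U);
    dg[l].gb.zeros(U);
    dg[l].ggamma.zeros(U);
    dg[l].gbeta.zeros(U);
  }
  mat gWo(sp.out_in, 1, arma::fill::zeros);
  double gbo = 0;

  // output layer
  gWo += fc.out_input.t() * dyhat;
  gbo += arma::accu(dyhat);
  mat dY = dyhat * Wo.t();
  // dense blocks
  for (int l = (int)sp.dense.size() - 1; l >= 0; --l) {
    const DenseSpec& d = sp.dense[l];
    const DenseCache& dc = fc.dense[l];
    if (d.dropout > 0 && dc.drop_mask.n_elem) dY %= dc.drop_mask;
    dY %= act_deriv(dc.preact, d.act);
    if (d.bn)
      dY = bn_backward(dY, dc.bn, dw[l].gamma, dg[l].ggamma, dg[l].gbeta);
    dg[l].gW += dc.input.t() * dY;
    dg[l].gb += arma::sum(dY, 0);
    dY = dY * dw[l].W.t();
  }
  // GRU
  int H = sp.H, T = sp.T_gru;
  mat dhf = dY.cols(0, H - 1);
  mat dhb = dY.cols(H, 2 * H - 1);
  cube dX(n, sp.gru_in, T, arma::fill::zeros);
  std::vector<int> fwd(T), bwd(T);
  for (int t = 0; t < T; ++t) { fwd[t] = t; bwd[t] = T - 1 - t; }
  gru_backward(fc.gru_f, gfw, gfg, dhf, dX, fwd);
  gru_backward(fc.gru_b, gbw, gbg, dhb, dX, bwd);
  // conv blocks
  cube d_out = dX;
  for (int l = (int)sp.conv.size() - 1; l >= 0; --l) {
    const ConvSpec& c = sp.conv[l];
    const ConvCache& cc = fc.conv[l];
    int F = c.filters, Tl = sp.conv_T[l];
    if (c.dropout > 0 && cc.drop_mask.n_elem) d_out %= cc.drop_mask;
    cube d_act(n, F, Tl, arma::fill::zeros);
    if (c.pool && Tl >= 2) {
      int Tp = Tl / 2;
      for (int t = 0; t < Tp; ++t)
        for (int j = 0; j < F; ++j)
          for (int i = 0; i < n; ++i) {
            int src = 2 * t + (int)cc.pool_from(i, j, t);
            d_act(i, j, src) += d_out(i, j, t);
          }
    } else {
      d_act = d_out;
    }
    cube dP(n, F, Tl);
    for (int t = 0; t < Tl; ++t)
      dP.slice(t) = d_act.slice(t) % act_deriv(cc.preact.slice(t), c.act);
    if (c.bn) {
      mat stacked(n * Tl, F);
      for (int t = 0; t < Tl; ++t)
        stacked.rows(t * n, t * n + n - 1) = dP.slice(t);
      mat dx = bn_backward(stacked, cc.bn, cw[l].gamma,
                           cg[l].ggamma, cg[l].gbeta);
      for (int t = 0; t < Tl; ++t)
        dP.slice(t) = dx.rows(t * n, t * n + n - 1);
    }
    const mat& Xall = cc.input;
    int Cin = sp.conv_in[l];
    mat dPall(n * Tl, F);
    for (int t = 0; t < Tl; ++t)
      dPall.rows(t * n, t * n + n - 1) = dP.slice(t);
    cg[l].gW1 += Xall.t() * dPall;
    cg[l].gb += arma::sum(dPall, 0);
    mat dXall = dPall * cw[l].W1.t();
    if (Tl > 1) {
      int m = (Tl - 1) * n;
      // P_t includes X_{t-1} W0 and X_{t+1} W2
      cg[l].gW0 += Xall.rows(0, m - 1).t() * dPall.rows(n, Tl * n - 1);
      cg[l].gW2 += Xall.rows(n, Tl * n - 1).t() * dPall.rows(0, m - 1);
      dXall.rows(0, m - 1) += dPall.rows(n, Tl * n - 1) * cw[l].W0.t();
      dXall.rows(n, Tl * n - 1) += dPall.rows(0, m - 1) * cw[l].W2.t();
    }
    cube dXin(n, Cin, Tl);
    for (int t = 0; t < Tl; ++t)
      dXin.slice(t) = dXall.rows(t * n, t * n + n - 1);
    d_out = dXin;
  }
  // write gradients out in canonical order
  Cursor gcur(gptr);
  for (size_t l = 0; l < sp.conv.size(); ++l) {
    gcur.write(cg[l].gW0);
    gcur.write(cg[l].gW1);
    gcur.write(cg[l].gW2);
    gcur.write(cg[l].gb);
    if (sp.conv[l].bn) {
      gcur.write(cg[l].ggamma);
      gcur.write(cg[l].gbeta);
    }
  }
  gru_write(gcur, gfg);
  gru_write(gcur, gbg);
  for (size_t l = 0; l < sp.dense.size(); ++l) {
    gcur.write(dg[l].gW);
    gcur.write(dg[l].gb);
    if (sp.dense[l].bn) {
      gcur.write(dg[l].ggamma);
      gcur.write(dg[l].gbeta);
    }
  }
  gcur.write(gWo);
  *gcur.take(1) = gbo;
}

// ------------------------------------------------------ initialization

static void glorot_fill(double* p, size_t k, int fan_in, int fan_out,
                        std::mt19937_64& rng) {
  double limit = std::sqrt(6.0 / (fan_in + fan_out));
  std::uniform_real_distribution<double> u(-limit, limit);
  for (size_t i = 0; i < k; ++i) p[i] = u(rng);
}

static vec init_weights(const NetSpec& sp, std::mt19937_64& rng) {
  vec w(sp.n_weights, arma::fill::zeros);
  Cursor cur(w.memptr());
  for (size_t l = 0; l < sp.conv.size(); ++l) {
    int Cin = sp.conv_in[l], F = sp.conv[l].filters;
    for (int k = 0; k < 3; ++k)
      glorot_fill(cur.take((size_t)Cin * F), (size_t)Cin * F,
                  3 * Cin, 3 * F, rng);
    cur.take(F);
    if (sp.conv[l].bn) {
      double* g = cur.take(F);
      for (int f = 0; f < F; ++f) g[f] = 1.0;
      cur.take(F);
    }
  }
  for (int d = 0; d < 2; ++d) {
    int in = sp.gru_in, H = sp.H;
    for (int k = 0; k < 3; ++k)
      glorot_fill(cur.take((size_t)in * H), (size_t)in * H, in, H, rng);
    for (int k = 0; k < 3; ++k)
      glorot_fill(cur.take((size_t)H * H), (size_t)H * H, H, H, rng);
    cur.take(3 * (size_t)H);
  }
  for (size_t l = 0; l < sp.dense.size(); ++l) {
    int in = sp.dense_in[l], U = sp.dense[l].units;
    glorot_fill(cur.take((size_t)in * U), (size_t)in * U, in, U, rng);
    cur.take(U);
    if (sp.dense[l].bn) {
      double* g = cur.take(U);
      for (int u = 0; u < U; ++u) g[u] = 1.0;
      cur.take(U);
    }
  }
  glorot_fill(cur.take(sp.out_in), sp.out_in, sp.out_in, 1, rng);
  cur.take(1);
  return w;
}

static vec init_bnstate(const NetSpec& sp) {
  vec s(std::max<size_t>(sp.n_bnstate, 1), arma::fill::zeros);
  Cursor cur(s.memptr());
  for (size_t l = 0; l < sp.conv.size(); ++l)
    if (sp.conv[l].bn) {
      cur.take(sp.conv[l].filters);
      double* v = cur.take(sp.conv[l].filters);
      for (int f = 0; f < sp.conv[l].filters; ++f) v[f] = 1.0;
    }
  for (size_t l = 0; l < sp.dense.size(); ++l)
    if (sp.dense[l].bn) {
      cur.take(sp.dense[l].units);
      double* v = cur.take(sp.dense[l].units);
      for (int u = 0; u < sp.dense[l].units; ++u) v[u] = 1.0;
    }
  return s;
}

// ---------------------------------------------------------- optimizers

struct Optimizer {
  int kind;
  double lr;
  vec m, v;
  long step = 0;
  Optimizer(int kind_, double lr_, size_t n) : kind(kind_), lr(lr_) {
    m.zeros(n);
    v.zeros(n);
  }
  void update(vec& w, const vec& g) {
    ++step;
    if (kind == 0) {                       // adam
      const double b1 = 0.9, b2 = 0.999, eps = 1e-7;
      m = b1 * m + (1 - b1) * g;
      v = b2 * v + (1 - b2) * arma::square(g);
      double c1 = 1 - std::pow(b1, (double)step);
      double c2 = 1 - std::pow(b2, (double)step);
      w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
    } else if (kind == 1) {                // rmsprop
      const double rho = 0.9, eps = 1e-7;
      v = rho * v + (1 - rho) * arma::square(g);
      w -= lr * g / (arma::sqrt(v) + eps);
    } else {                               // sgd + momentum
      const double mom = 0.9;
      m = mom * m - lr * g;
      w += m;
    }
  }
};

static double default_lr(int kind) {
  return kind == 2 ? 0.01 : 0.001;
}

// --------------------------------------------------------- entry points

static Rcpp::IntegerMatrix submatrix(const Rcpp::IntegerMatrix& x,
                                     int from, int to) {
  Rcpp::IntegerMatrix sub(to - from, x.ncol());
  for (int j = 0; j < x.ncol(); ++j)
    for (int i = from; i < to; ++i)
      sub(i - from, j) = x(i, j);
  return sub;
}

static double eval_mse(const NetSpec& sp, const double* w, double* bn,
                       const Rcpp::IntegerMatrix& tok, const vec& y) {
  int n = tok.nrow();
  double sse = 0;
  int chunk = 512;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    cube X = onehot(submatrix(tok, s, e), sp.A);
    vec yh = net_forward(sp, w, bn, X, false, nullptr, nullptr);
    sse += arma::accu(arma::square(yh - y.subvec(s, e - 1)));
  }
  return sse / n;
}

// [[Rcpp::export]]
Rcpp::List cpp_rtnet_sizes(Rcpp::List spec) {
  NetSpec sp = parse_spec(spec);
  return Rcpp::List::create(
      Rcpp::Named("n_weights") = (double)sp.n_weights,
      Rcpp::Named("n_bnstate") = (double)sp.n_bnstate,
      Rcpp::Named("t_gru") = sp.T_gru);
}

// [[Rcpp::export]]
Rcpp::List cpp_rtnet_init(Rcpp::List spec, int seed) {
  NetSpec sp = parse_spec(spec);
  std::mt19937_64 rng((unsigned long long)seed);
  vec w = init_weights(sp, rng);
  vec b = init_bnstate(sp);
  return Rcpp::List::create(
      Rcpp::Named("weights") = Rcpp::NumericVector(w.begin(), w.end()),
      Rcpp::Named("bn_state") = Rcpp::NumericVector(b.begin(), b.end()));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_rtnet_predict(Rcpp::List spec,
                                      Rcpp::NumericVector weights,
                                      Rcpp::NumericVector bn_state,
                                      Rcpp::IntegerMatrix tokens) {
  NetSpec sp = parse_spec(spec);
  if (weights.size() != (R_xlen_t)sp.n_weights)
    Rcpp::stop("weight vector has length %d, expected %d",
               (int)weights.size(), (int)sp.n_weights);
  vec w(weights.begin(), weights.size());
  vec bn(bn_state.begin(), bn_state.size());
  int n = tokens.nrow();
  Rcpp::NumericVector out(n);
  int chunk = 512;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    cube X = onehot(submatrix(tokens, s, e), sp.A);
    vec yh = net_forward(sp, w.memptr(), bn.memptr(), X, false,
                         nullptr, nullptr);
    for (int i = s; i < e; ++i) out[i] = yh(i - s);
  }
  return out;
}

// Loss and gradient on one batch (used by the finite-difference tests);
// dropout disabled, batch-norm uses batch statistics (deterministic),
// running stats updated on a throwaway copy.
// [[Rcpp::export]]
Rcpp::List cpp_rtnet_loss_grad(Rcpp::List spec,
                               Rcpp::NumericVector weights,
                               Rcpp::NumericVector bn_state,
                               Rcpp::IntegerMatrix tokens,
                               Rcpp::NumericVector y) {
  NetSpec sp = parse_spec(spec);
  for (auto& c : sp.conv) c.dropout = 0;
  for (auto& d : sp.dense) d.dropout = 0;
  vec w(weights.begin(), weights.size());
  vec bn(bn_state.begin(), bn_state.size());
  vec yy(y.begin(), y.size());
  cube X = onehot(tokens, sp.A);
  ForwardCache fc;
  vec yh = net_forward(sp, w.memptr(), bn.memptr(), X, true, nullptr, &fc);
  int n = yy.n_elem;
  double loss = arma::accu(arma::square(yh - yy)) / n;
  vec dy = 2.0 * (yh - yy) / n;
  vec g(sp.n_weights, arma::fill::zeros);
  net_backward(sp, w.memptr(), g.memptr(), fc, dy);
  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grad") = Rcpp::NumericVector(g.begin(), g.end()));
}

// [[Rcpp::export]]
Rcpp::List cpp_rtnet_train(Rcpp::List spec,
                           Rcpp::IntegerMatrix x_train,
                           Rcpp::NumericVector y_train,
                           Rcpp::IntegerMatrix x_valid,
                           Rcpp::NumericVector y_valid,
                           int max_epochs, int batch_size, int patience,
                           Rcpp::NumericVector init_w,
                           Rcpp::NumericVector init_bn,
                           int seed, double lr) {
  NetSpec sp = parse_spec(spec);
  std::mt19937_64 rng((unsigned long long)seed * 2654435761ULL + 1ULL);
  vec w, bn;
  if (init_w.size() > 0) {
    if (init_w.size() != (R_xlen_t)sp.n_weights)
      Rcpp::stop("initial weight vector has wrong length");
    w = vec(init_w.begin(), init_w.size());
    bn = init_bn.size() ? vec(init_bn.begin(), init_bn.size())
                        : init_bnstate(sp);
  } else {
    w = init_weights(sp, rng);
    bn = init_bnstate(sp);
  }
  if (lr <= 0) lr = default_lr(sp.optimizer);
  Optimizer opt(sp.optimizer, lr, sp.n_weights);
  int n = x_train.nrow();
  vec ytr(y_train.begin(), y_train.size());
  vec yva(y_valid.begin(), y_valid.size());
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  vec best_w = w, best_bn = bn;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1, since_best = 0;
  bool diverged = false;
  std::vector<double> hist_train, hist_val;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double sse = 0;
    for (int s = 0; s < n; s += batch_size) {
      int e = std::min(n, s + batch_size);
      int m = e - s;
      Rcpp::IntegerMatrix sub(m, x_train.ncol());
      vec yb(m);
      for (int i = 0; i < m; ++i) {
        int r = idx[s + i];
        for (int j = 0; j < x_train.ncol(); ++j) sub(i, j) = x_train(r, j);
        yb(i) = ytr(r);
      }
      cube X = onehot(sub, sp.A);
      ForwardCache fcache;
      vec yh = net_forward(sp, w.memptr(), bn.memptr(), X, true, &rng,
                           &fcache);
      double batch_sse = arma::accu(arma::square(yh - yb));
      if (!std::isfinite(batch_sse)) { diverged = true; break; }
      sse += batch_sse;
      vec dy = 2.0 * (yh - yb) / m;
      vec g(sp.n_weights, arma::fill::zeros);
      net_backward(sp, w.memptr(), g.memptr(), fcache, dy);
      opt.update(w, g);
    }
    if (diverged) break;
    double train_mse = sse / n;
    double val_mse = eval_mse(sp, w.memptr(), bn.memptr(), x_valid, yva);
    hist_train.push_back(train_mse);
    hist_val.push_back(val_mse);
    if (!std::isfinite(val_mse)) { diverged = true; break; }
    if (val_mse < best_val) {
      best_val = val_mse;
      best_w = w;
      best_bn = bn;
      best_epoch = epoch;
      since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") =
          Rcpp::NumericVector(best_w.begin(), best_w.end()),
      Rcpp::Named("bn_state") =
          Rcpp::NumericVector(best_bn.begin(), best_bn.end()),
      Rcpp::Named("best_val_mse") = best_val,
      Rcpp::Named("best_epoch") = best_epoch + 1,
      Rcpp::Named("epochs_run") = (int)hist_train.size(),
      Rcpp::Named("diverged") = diverged,
      Rcpp::Named("history_train") = hist_train,
      Rcpp::Named("history_val") = hist_val);
}
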