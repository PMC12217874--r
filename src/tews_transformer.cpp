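// Single-head transformer encoder for windowed clinical time series:
// forward pass, analytic backpropagation and input-gradient extraction.
//
// Architecture (pre-layer-norm residual blocks):
//   H0 = X * Win + bin + PE                               (T x d)
//   per layer: H += Drop(Attn(LN1(H)));  H += Drop(FFN(LN2(H)))
//   Hn = LNf(H); pooled h = last row of Hn (or masked mean)
//   u = relu(s * Ws + bs);  logit = [h, u] . w + b;  p = sigmoid(logit)
//
// Samples are processed one at a time so every intermediate stays
// cache-resident, with all large buffers preallocated once per batch call
// (per-sample allocation of the T x T attention matrix is what dominates a
// naive implementation). Attention is kept in transposed layout so softmax
// reductions run down contiguous columns. Gradients are verified against
// central finite differences in the test suite; dropout masks come from a
// dedicated seeded generator, independent of R's RNG.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LN_EPS = 1e-5;

struct LayerParams {
  vec ln1_g, ln1_b, ln2_g, ln2_b, b1, b2;
  mat Wq, Wk, Wv, Wo, W1, W2;
};

struct TewsParams {
  mat Win;
  vec bin;
  std::vector<LayerParams> layers;
  vec lnf_g, lnf_b;
  mat Ws;
  vec bs;
  vec head_w;
  double head_b;
};

static TewsParams unpack_params(const Rcpp::List& p, int n_layers) {
  TewsParams q;
  q.Win = Rcpp::as<mat>(p["Win"]);
  q.bin = Rcpp::as<vec>(p["bin"]);
  for (int l = 0; l < n_layers; ++l) {
    std::string pre = "l" + std::to_string(l + 1) + "_";
    LayerParams lp;
    lp.ln1_g = Rcpp::as<vec>(p[pre + "ln1_g"]);
    lp.ln1_b = Rcpp::as<vec>(p[pre + "ln1_b"]);
    lp.Wq = Rcpp::as<mat>(p[pre + "Wq"]);
    lp.Wk = Rcpp::as<mat>(p[pre + "Wk"]);
    lp.Wv = Rcpp::as<mat>(p[pre + "Wv"]);
    lp.Wo = Rcpp::as<mat>(p[pre + "Wo"]);
    lp.ln2_g = Rcpp::as<vec>(p[pre + "ln2_g"]);
    lp.ln2_b = Rcpp::as<vec>(p[pre + "ln2_b"]);
    lp.W1 = Rcpp::as<mat>(p[pre + "W1"]);
    lp.b1 = Rcpp::as<vec>(p[pre + "b1"]);
    lp.W2 = Rcpp::as<mat>(p[pre + "W2"]);
    lp.b2 = Rcpp::as<vec>(p[pre + "b2"]);
    q.layers.push_back(std::move(lp));
  }
  q.lnf_g = Rcpp::as<vec>(p["lnf_g"]);
  q.lnf_b = Rcpp::as<vec>(p["lnf_b"]);
  q.Ws = Rcpp::as<mat>(p["Ws"]);
  q.bs = Rcpp::as<vec>(p["bs"]);
  q.head_w = Rcpp::as<vec>(p["head_w"]);
  q.head_b = Rcpp::as<double>(p["head_b"]);
  return q;
}

struct TewsGrads {
  mat Win;
  vec bin;
  std::vector<LayerParams> layers;  // reused as gradient containers
  vec lnf_g, lnf_b;
  mat Ws;
  vec bs;
  vec head_w;
  double head_b;
  explicit TewsGrads(const TewsParams& p) {
    Win = zeros<mat>(size(p.Win));
    bin = zeros<vec>(size(p.bin));
    for (const auto& lp : p.layers) {
      LayerParams g;
      g.ln1_g = zeros<vec>(size(lp.ln1_g));
      g.ln1_b = zeros<vec>(size(lp.ln1_b));
      g.Wq = zeros<mat>(size(lp.Wq));
      g.Wk = zeros<mat>(size(lp.Wk));
      g.Wv = zeros<mat>(size(lp.Wv));
      g.Wo = zeros<mat>(size(lp.Wo));
      g.ln2_g = zeros<vec>(size(lp.ln2_g));
      g.ln2_b = zeros<vec>(size(lp.ln2_b));
      g.W1 = zeros<mat>(size(lp.W1));
      g.b1 = zeros<vec>(size(lp.b1));
      g.W2 = zeros<mat>(size(lp.W2));
      g.b2 = zeros<vec>(size(lp.b2));
      layers.push_back(std::move(g));
    }
    lnf_g = zeros<vec>(size(p.lnf_g));
    lnf_b = zeros<vec>(size(p.lnf_b));
    Ws = zeros<mat>(size(p.Ws));
    bs = zeros<vec>(size(p.bs));
    head_w = zeros<vec>(size(p.head_w));
    head_b = 0.0;
  }
};

// Row-wise layer norm into preallocated outputs.
static void layer_norm_fwd(const mat& x, const vec& g, const vec& b,
                           mat& y, mat& xhat, vec& sd) {
  vec mu = mean(x, 1);
  sd = sqrt(mean(square(x.each_col() - mu), 1) + LN_EPS);
  xhat = x;
  xhat.each_col() -= mu;
  xhat.each_col() /= sd;
  y = xhat;
  y.each_row() %= g.t();
  y.each_row() += b.t();
}

// dx written into `dx`; parameter gradients accumulated.
static void layer_norm_bwd(const mat& dy, const mat& xhat, const vec& sd,
                           const vec& g, vec& dg, vec& db, mat& dx) {
  dg += sum(dy % xhat, 0).t();
  db += sum(dy, 0).t();
  dx = dy;
  dx.each_row() %= g.t();
  vec m1 = mean(dx, 1);
  vec m2 = mean(dx % xhat, 1);
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() /= sd;
}

// Column-wise softmax in place (columns are contiguous in memory).
static void softmax_cols(mat& s) {
  const uword nr = s.n_rows;
  for (uword j = 0; j < s.n_cols; ++j) {
    double* c = s.colptr(j);
    double mx = c[0];
    for (uword i = 1; i < nr; ++i) mx = std::max(mx, c[i]);
    double sum = 0.0;
    for (uword i = 0; i < nr; ++i) { c[i] = std::exp(c[i] - mx); sum += c[i]; }
    const double inv = 1.0 / sum;
    for (uword i = 0; i < nr; ++i) c[i] *= inv;
  }
}

static void relu_into(const mat& x, mat& y) {
  y = x;
  y.elem(find(y < 0)).zeros();
}

static void fill_dropout_mask(mat& m, double keep, std::mt19937_64& rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double* p = m.memptr();
  const double inv = 1.0 / keep;
  for (uword i = 0; i < m.n_elem; ++i) p[i] = unif(rng) < keep ? inv : 0.0;
}

// Reusable per-sample buffers; allocated once per batch call.
struct LayerWS {
  mat Xn, xhat1, Q, K, V, At, Z, Xn2, xhat2, Pre, R, F, mask1, mask2;
  mat dAt, dSt, dQ, dK, dV;
  vec sd1, sd2;
};

struct Workspace {
  std::vector<LayerWS> L;
  mat H, Hn, xhatf, scratch, dH, dXn, dHn;
  vec sdf;
  rowvec pre_s, u;
  void init(uword T, uword d, uword dff, uword n_layers) {
    L.resize(n_layers);
    for (auto& w : L) {
      w.Xn.set_size(T, d); w.xhat1.set_size(T, d);
      w.Q.set_size(T, d); w.K.set_size(T, d); w.V.set_size(T, d);
      w.At.set_size(T, T); w.Z.set_size(T, d);
      w.Xn2.set_size(T, d); w.xhat2.set_size(T, d);
      w.Pre.set_size(T, dff); w.R.set_size(T, dff); w.F.set_size(T, d);
      w.mask1.set_size(T, d); w.mask2.set_size(T, d);
      w.dAt.set_size(T, T); w.dSt.set_size(T, T);
      w.dQ.set_size(T, d); w.dK.set_size(T, d); w.dV.set_size(T, d);
    }
    H.set_size(T, d); Hn.set_size(T, d); xhatf.set_size(T, d);
    scratch.set_size(T, d); dH.set_size(T, d); dXn.set_size(T, d);
    dHn.set_size(T, d);
  }
};

struct SampleOut {
  double logit, p;
  int pool_r0;
  vec pooled;
};

// Forward for one sample into the workspace.
static void forward_one(const TewsParams& P, const mat& pe, const mat& X,
                        const rowvec& s, int pooling, int first_bin,
                        double dropout, bool train, std::mt19937_64* rng,
                        Workspace& W, SampleOut& out) {
  const uword T = X.n_rows;
  const uword L = P.layers.size();
  const double keep = 1.0 - dropout;
  const bool drop = train && dropout > 0;
  const double scl = 1.0 / std::sqrt((double)P.Win.n_cols);
  const double emb = std::sqrt((double)P.Win.n_cols);  // standard embedding scale

  W.H = X * P.Win;
  W.H *= emb;
  W.H.each_row() += P.bin.t();
  W.H += pe;

  for (uword l = 0; l < L; ++l) {
    const LayerParams& lp = P.layers[l];
    LayerWS& w = W.L[l];
    layer_norm_fwd(W.H, lp.ln1_g, lp.ln1_b, w.Xn, w.xhat1, w.sd1);
    w.Q = w.Xn * lp.Wq;
    w.K = w.Xn * lp.Wk;
    w.V = w.Xn * lp.Wv;
    // transposed scores: At(j, i) = K_j . Q_i / sqrt(d); softmax over rows of
    // the original orientation = over contiguous columns here
    w.At = w.K * w.Q.t();
    w.At *= scl;
    softmax_cols(w.At);
    w.Z = w.At.t() * w.V;
    W.scratch = w.Z * lp.Wo;
    if (drop) {
      fill_dropout_mask(w.mask1, keep, *rng);
      W.scratch %= w.mask1;
    }
    W.H += W.scratch;
    layer_norm_fwd(W.H, lp.ln2_g, lp.ln2_b, w.Xn2, w.xhat2, w.sd2);
    w.Pre = w.Xn2 * lp.W1;
    w.Pre.each_row() += lp.b1.t();
    relu_into(w.Pre, w.R);
    w.F = w.R * lp.W2;
    w.F.each_row() += lp.b2.t();
    if (drop) {
      fill_dropout_mask(w.mask2, keep, *rng);
      w.F %= w.mask2;
    }
    W.H += w.F;
  }
  layer_norm_fwd(W.H, P.lnf_g, P.lnf_b, W.Hn, W.xhatf, W.sdf);

  if (pooling == 0) {
    out.pool_r0 = T - 1;
    out.pooled = W.Hn.row(T - 1).t();
  } else {
    int r0 = first_bin - 1;           // first_bin is 1-based from R
    if (r0 < 0 || r0 >= (int)T) r0 = 0;
    out.pool_r0 = r0;
    out.pooled = mean(W.Hn.rows(r0, T - 1), 0).t();
  }

  W.pre_s = s * P.Ws + P.bs.t();
  W.u = W.pre_s;
  W.u.elem(find(W.u < 0)).zeros();
  const uword d = out.pooled.n_elem;
  out.logit = dot(P.head_w.subvec(0, d - 1), out.pooled) +
              dot(P.head_w.subvec(d, d + W.u.n_elem - 1), W.u.t()) +
              P.head_b;
  out.p = 1.0 / (1.0 + std::exp(-out.logit));
}

// Backward for one sample given d(objective)/d(logit); accumulates into G.
static void backward_one(const TewsParams& P, const mat& X, const rowvec& s,
                         double dlogit, const SampleOut& out, Workspace& W,
                         TewsGrads& G, bool drop, mat* dX_out, mat* dHn_out) {
  const uword T = X.n_rows;
  const uword d = out.pooled.n_elem;
  const uword ds = W.u.n_elem;
  const uword L = P.layers.size();
  const double scl = 1.0 / std::sqrt((double)P.Win.n_cols);

  G.head_w.subvec(0, d - 1) += dlogit * out.pooled;
  G.head_w.subvec(d, d + ds - 1) += dlogit * W.u.t();
  G.head_b += dlogit;

  rowvec dpre_s = (dlogit * P.head_w.subvec(d, d + ds - 1).t()) %
                  conv_to<rowvec>::from(W.pre_s > 0);
  G.Ws += s.t() * dpre_s;
  G.bs += dpre_s.t();

  vec dh = dlogit * P.head_w.subvec(0, d - 1);
  W.dHn.zeros();
  if (out.pool_r0 == (int)T - 1) {
    W.dHn.row(T - 1) = dh.t();
  } else {
    const double cinv = 1.0 / (T - out.pool_r0);
    W.dHn.rows(out.pool_r0, T - 1).each_row() += cinv * dh.t();
  }
  if (dHn_out) *dHn_out = W.dHn;

  layer_norm_bwd(W.dHn, W.xhatf, W.sdf, P.lnf_g, G.lnf_g, G.lnf_b, W.dH);

  for (int l = (int)L - 1; l >= 0; --l) {
    const LayerParams& lp = P.layers[l];
    LayerWS& w = W.L[l];
    LayerParams& g = G.layers[l];

    // FFN block: H_out = H_in + Drop(relu(LN2(H_in) W1 + b1) W2 + b2)
    w.F = W.dH;                       // reuse as dF
    if (drop) w.F %= w.mask2;
    g.W2 += w.R.t() * w.F;
    g.b2 += sum(w.F, 0).t();
    w.R = w.F * lp.W2.t();            // reuse as dR -> dPre
    w.R %= conv_to<mat>::from(w.Pre > 0);
    g.W1 += w.Xn2.t() * w.R;
    g.b1 += sum(w.R, 0).t();
    layer_norm_bwd(w.R * lp.W1.t(), w.xhat2, w.sd2, lp.ln2_g,
                   g.ln2_g, g.ln2_b, W.dXn);
    W.dH += W.dXn;

    // attention block: H_out = H_in + Drop((softmax(QK'/sqrt(d)) V) Wo)
    W.scratch = W.dH;                 // dO
    if (drop) W.scratch %= w.mask1;
    g.Wo += w.Z.t() * W.scratch;
    w.Z = W.scratch * lp.Wo.t();      // reuse as dZ
    // transposed-layout softmax backward: dAt = V dZ', column reductions
    w.dAt = w.V * w.Z.t();
    rowvec rs = sum(w.dAt % w.At, 0);
    w.dSt = w.dAt;
    w.dSt.each_row() -= rs;
    w.dSt %= w.At;
    w.dQ = w.dSt.t() * w.K;
    w.dQ *= scl;
    w.dK = w.dSt * w.Q;
    w.dK *= scl;
    w.dV = w.At * w.Z;
    g.Wq += w.Xn.t() * w.dQ;
    g.Wk += w.Xn.t() * w.dK;
    g.Wv += w.Xn.t() * w.dV;
    W.dXn = w.dQ * lp.Wq.t();
    W.dXn += w.dK * lp.Wk.t();
    W.dXn += w.dV * lp.Wv.t();
    layer_norm_bwd(W.dXn, w.xhat1, w.sd1, lp.ln1_g, g.ln1_g, g.ln1_b,
                   W.scratch);
    W.dH += W.scratch;
  }

  const double emb = std::sqrt((double)P.Win.n_cols);
  G.Win += emb * (X.t() * W.dH);
  G.bin += sum(W.dH, 0).t();
  if (dX_out) *dX_out = emb * (W.dH * P.Win.t());
}

static Rcpp::List pack_grads(const TewsGrads& G) {
  Rcpp::List out;
  out["Win"] = G.Win;
  out["bin"] = G.bin;
  for (size_t l = 0; l < G.layers.size(); ++l) {
    std::string pre = "l" + std::to_string(l + 1) + "_";
    const LayerParams& g = G.layers[l];
    out[pre + "ln1_g"] = g.ln1_g;
    out[pre + "ln1_b"] = g.ln1_b;
    out[pre + "Wq"] = g.Wq;
    out[pre + "Wk"] = g.Wk;
    out[pre + "Wv"] = g.Wv;
    out[pre + "Wo"] = g.Wo;
    out[pre + "ln2_g"] = g.ln2_g;
    out[pre + "ln2_b"] = g.ln2_b;
    out[pre + "W1"] = g.W1;
    out[pre + "b1"] = g.b1;
    out[pre + "W2"] = g.W2;
    out[pre + "b2"] = g.b2;
  }
  out["lnf_g"] = G.lnf_g;
  out["lnf_b"] = G.lnf_b;
  out["Ws"] = G.Ws;
  out["bs"] = G.bs;
  out["head_w"] = G.head_w;
  out["head_b"] = G.head_b;
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_tews_train_batch(Rcpp::List params, arma::mat pe, arma::cube X,
                                arma::mat S, arma::vec y, double wpos,
                                double wneg, int n_layers, int pooling,
                                arma::ivec first_bin, double dropout,
                                double dropout_seed, double eps) {
  TewsParams P = unpack_params(params, n_layers);
  TewsGrads G(P);
  const uword B = X.n_slices;
  std::mt19937_64 rng((uint64_t)dropout_seed);
  Workspace W;
  W.init(X.n_rows, P.Win.n_cols, P.layers[0].b1.n_elem, n_layers);
  vec probs(B);
  double loss = 0.0;
  SampleOut out;
  for (uword b = 0; b < B; ++b) {
    forward_one(P, pe, X.slice(b), S.row(b), pooling, first_bin(b),
                dropout, true, &rng, W, out);
    probs(b) = out.p;
    const double pc = std::min(std::max(out.p, eps), 1.0 - eps);
    loss += -(wpos * y(b) * std::log(pc) +
              wneg * (1.0 - y(b)) * std::log(1.0 - pc));
    const double dlogit = (-wpos * y(b) * (1.0 - pc) +
                           wneg * (1.0 - y(b)) * pc) / B;
    backward_one(P, X.slice(b), S.row(b), dlogit, out, W, G,
                 dropout > 0, nullptr, nullptr);
  }
  loss /= B;
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("probs") = probs,
                            Rcpp::Named("grads") = pack_grads(G));
}

// [[Rcpp::export]]
arma::vec cpp_tews_predict(Rcpp::List params, arma::mat pe, arma::cube X,
                           arma::mat S, int n_layers, int pooling,
                           arma::ivec first_bin) {
  TewsParams P = unpack_params(params, n_layers);
  const uword B = X.n_slices;
  Workspace W;
  W.init(X.n_rows, P.Win.n_cols, P.layers[0].b1.n_elem, n_layers);
  vec probs(B);
  SampleOut out;
  for (uword b = 0; b < B; ++b) {
    forward_one(P, pe, X.slice(b), S.row(b), pooling, first_bin(b),
                0.0, false, nullptr, W, out);
    probs(b) = out.p;
  }
  return probs;
}

// Gradient of the pre-sigmoid logit with respect to the raw input window and
// the final encoder activations, for Grad-CAM-style attribution.
// [[Rcpp::export]]
Rcpp::List cpp_tews_input_grad(Rcpp::List params, arma::mat pe, arma::cube X,
                               arma::mat S, int n_layers, int pooling,
                               arma::ivec first_bin) {
  TewsParams P = unpack_params(params, n_layers);
  const uword T = X.n_rows, N = X.n_cols, B = X.n_slices;
  Workspace W;
  W.init(T, P.Win.n_cols, P.layers[0].b1.n_elem, n_layers);
  const uword d = P.lnf_g.n_elem;
  vec probs(B);
  cube dX(T, N, B), Hn(T, d, B), dHn(T, d, B);
  SampleOut out;
  for (uword b = 0; b < B; ++b) {
    forward_one(P, pe, X.slice(b), S.row(b), pooling, first_bin(b),
                0.0, false, nullptr, W, out);
    probs(b) = out.p;
    TewsGrads G(P);  // discarded; only input gradients are kept
    mat dx, dhn;
    backward_one(P, X.slice(b), S.row(b), 1.0, out, W, G, false, &dx, &dhn);
    dX.slice(b) = dx;
    Hn.slice(b) = W.Hn;
    dHn.slice(b) = dhn;
  }
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("dX") = dX,
                            Rcpp::Named("Hn") = Hn,
                            Rcpp::Named("dHn") = dHn);
}
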