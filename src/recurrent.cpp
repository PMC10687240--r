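// Recurrent network engine: multilayer RNN/GRU/LSTM classifiers trained by
// backpropagation through time with Adam, and a bidirectional recurrent
// imputer with per-feature temporal decay (BRITS-style, imputation-only).
//
// Data layout: cubes are participant x feature x time (slice t = n x d matrix).
// All randomness is driven by a std::mt19937 seeded from R, so results are
// reproducible across platforms independently of R's RNG state.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

typedef std::vector<arma::mat> WeightSet;

static int gate_count(const std::string& cell) {
  if (cell == "lstm") return 4;
  if (cell == "gru") return 3;
  return 1;
}

static WeightSet list_to_ws(List l) {
  WeightSet w;
  for (int i = 0; i < l.size(); ++i) w.push_back(as<arma::mat>(l[i]));
  return w;
}

static List ws_to_list(const WeightSet& w, const std::vector<std::string>& nm) {
  List out(w.size());
  CharacterVector names(w.size());
  for (size_t i = 0; i < w.size(); ++i) {
    out[i] = wrap(w[i]);
    names[i] = nm[i];
  }
  out.attr("names") = names;
  return out;
}

static std::vector<std::string> rnn_weight_names(int layers) {
  std::vector<std::string> nm;
  for (int l = 1; l <= layers; ++l) {
    nm.push_back("Wx" + std::to_string(l));
    nm.push_back("Wh" + std::to_string(l));
    nm.push_back("b" + std::to_string(l));
  }
  nm.push_back("w_out");
  nm.push_back("b_out");
  return nm;
}

static double runif_sym(std::mt19937& rng, double k) {
  std::uniform_real_distribution<double> u(-k, k);
  return u(rng);
}

static void fill_uniform(mat& m, std::mt19937& rng, double k) {
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = runif_sym(rng, k);
}

// [[Rcpp::export]]
List cpp_rnn_init(int input_size, int hidden, int layers, std::string cell,
                  int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int g = gate_count(cell);
  double k = 1.0 / std::sqrt((double)hidden);
  WeightSet W;
  for (int l = 0; l < layers; ++l) {
    int d = (l == 0) ? input_size : hidden;
    mat Wx(d, g * hidden), Wh(hidden, g * hidden), b(1, g * hidden);
    fill_uniform(Wx, rng, k);
    fill_uniform(Wh, rng, k);
    fill_uniform(b, rng, k);
    W.push_back(Wx); W.push_back(Wh); W.push_back(b);
  }
  mat w(hidden, 1), b0(1, 1);
  fill_uniform(w, rng, k);
  fill_uniform(b0, rng, k);
  W.push_back(w); W.push_back(b0);
  return ws_to_list(W, rnn_weight_names(layers));
}

static mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// Forward (and optionally backward) pass over one minibatch.
// If G != NULL, computes gradients of the BCE loss; dropout masks are drawn
// from rng when training (rng != NULL and dropout > 0).
static double rnn_fb(const WeightSet& W, const cube& Xb, const vec* y,
                     const std::string& cell, int hidden, int layers,
                     double dropout, std::mt19937* rng, double pos_weight,
                     WeightSet* G, vec* probs_out) {
  const int B = Xb.n_rows, T = Xb.n_slices;
  const int H = hidden;

  // caches per layer
  std::vector<std::vector<mat>> A(layers), Hc(layers), GT(layers), HHn(layers),
      Cc(layers), DM(layers);
  for (int l = 0; l < layers; ++l) {
    A[l].resize(T); Hc[l].resize(T);
    GT[l].resize(T);
    if (cell == "gru") HHn[l].resize(T);
    if (cell == "lstm") Cc[l].resize(T);
    if (l > 0 && dropout > 0 && rng) DM[l].resize(T);
  }

  std::uniform_real_distribution<double> unif01(0.0, 1.0);
  const double keep = 1.0 - dropout;

  for (int l = 0; l < layers; ++l) {
    const mat& Wx = W[3 * l], &Wh = W[3 * l + 1], &b = W[3 * l + 2];
    mat h(B, H, fill::zeros), c(B, H, fill::zeros);
    for (int t = 0; t < T; ++t) {
      mat a = (l == 0) ? mat(Xb.slice(t)) : Hc[l - 1][t];
      if (l > 0 && dropout > 0 && rng) {
        mat dm(B, H);
        for (uword j = 0; j < dm.n_cols; ++j)
          for (uword i = 0; i < dm.n_rows; ++i)
            dm(i, j) = (unif01(*rng) < keep) ? 1.0 / keep : 0.0;
        DM[l][t] = dm;
        a = a % dm;
      }
      A[l][t] = a;
      mat pre = a * Wx;
      pre.each_row() += b.row(0);
      if (cell == "rnn") {
        h = tanh(pre + h * Wh);
      } else if (cell == "gru") {
        mat hh = h * Wh;
        mat r = sigmoid_m(pre.cols(0, H - 1) + hh.cols(0, H - 1));
        mat z = sigmoid_m(pre.cols(H, 2 * H - 1) + hh.cols(H, 2 * H - 1));
        mat hhn = hh.cols(2 * H, 3 * H - 1);
        mat n = tanh(pre.cols(2 * H, 3 * H - 1) + r % hhn);
        mat gates(B, 3 * H);
        gates.cols(0, H - 1) = r;
        gates.cols(H, 2 * H - 1) = z;
        gates.cols(2 * H, 3 * H - 1) = n;
        GT[l][t] = gates;
        HHn[l][t] = hhn;
        h = (1.0 - z) % n + z % h;
      } else {  // lstm
        pre += h * Wh;
        mat i_ = sigmoid_m(pre.cols(0, H - 1));
        mat f_ = sigmoid_m(pre.cols(H, 2 * H - 1));
        mat g_ = tanh(pre.cols(2 * H, 3 * H - 1));
        mat o_ = sigmoid_m(pre.cols(3 * H, 4 * H - 1));
        mat gates(B, 4 * H);
        gates.cols(0, H - 1) = i_;
        gates.cols(H, 2 * H - 1) = f_;
        gates.cols(2 * H, 3 * H - 1) = g_;
        gates.cols(3 * H, 4 * H - 1) = o_;
        GT[l][t] = gates;
        c = f_ % c + i_ % g_;
        Cc[l][t] = c;
        h = o_ % tanh(c);
      }
      Hc[l][t] = h;
    }
  }

  const mat& w_out = W[3 * layers];
  const double b_out = W[3 * layers + 1](0, 0);
  mat hT = Hc[layers - 1][T - 1];
  vec zlin = hT * w_out + b_out;
  vec p = 1.0 / (1.0 + exp(-zlin));
  if (probs_out) *probs_out = p;
  if (!y) return NA_REAL;

  vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
  double loss = -mean(pos_weight * (*y) % log(pc) + (1.0 - *y) % log(1.0 - pc));
  if (!G) return loss;

  // backward
  WeightSet& Gr = *G;
  for (size_t i = 0; i < W.size(); ++i) Gr[i] = mat(size(W[i]), fill::zeros);

  vec dz = (-pos_weight * (*y) % (1.0 - p) + (1.0 - *y) % p) / (double)B;
  Gr[3 * layers] = hT.t() * dz;
  Gr[3 * layers + 1](0, 0) = accu(dz);

  std::vector<mat> dHabove(T);  // dL/d output of current layer at each t
  for (int t = 0; t < T; ++t) dHabove[t] = mat(B, H, fill::zeros);
  dHabove[T - 1] = dz * w_out.t();

  for (int l = layers - 1; l >= 0; --l) {
    const mat& Wx = W[3 * l], &Wh = W[3 * l + 1];
    mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
    int d_in = (l == 0) ? (int)Xb.n_cols : H;
    std::vector<mat> dA(T);
    for (int t = T - 1; t >= 0; --t) {
      dh += dHabove[t];
      mat hprev = (t == 0) ? mat(B, H, fill::zeros) : Hc[l][t - 1];
      const mat& a = A[l][t];
      mat da(B, d_in, fill::zeros);
      if (cell == "rnn") {
        mat dpre = dh % (1.0 - square(Hc[l][t]));
        Gr[3 * l] += a.t() * dpre;
        Gr[3 * l + 1] += hprev.t() * dpre;
        Gr[3 * l + 2] += sum(dpre, 0);
        da = dpre * Wx.t();
        dh = dpre * Wh.t();
      } else if (cell == "gru") {
        const mat& gates = GT[l][t];
        mat r = gates.cols(0, H - 1), z = gates.cols(H, 2 * H - 1),
            n = gates.cols(2 * H, 3 * H - 1);
        const mat& hhn = HHn[l][t];
        mat dn = dh % (1.0 - z);
        mat dzg = dh % (hprev - n);
        mat dh_prev = dh % z;
        mat dpre_n = dn % (1.0 - square(n));
        mat dr = dpre_n % hhn;
        mat dhh_n = dpre_n % r;
        mat dpre_z = dzg % z % (1.0 - z);
        mat dpre_r = dr % r % (1.0 - r);
        mat dpre_x(B, 3 * H), dhh(B, 3 * H);
        dpre_x.cols(0, H - 1) = dpre_r;
        dpre_x.cols(H, 2 * H - 1) = dpre_z;
        dpre_x.cols(2 * H, 3 * H - 1) = dpre_n;
        dhh.cols(0, H - 1) = dpre_r;
        dhh.cols(H, 2 * H - 1) = dpre_z;
        dhh.cols(2 * H, 3 * H - 1) = dhh_n;
        Gr[3 * l] += a.t() * dpre_x;
        Gr[3 * l + 1] += hprev.t() * dhh;
        Gr[3 * l + 2] += sum(dpre_x, 0);
        da = dpre_x * Wx.t();
        dh = dh_prev + dhh * Wh.t();
      } else {  // lstm
        const mat& gates = GT[l][t];
        mat i_ = gates.cols(0, H - 1), f_ = gates.cols(H, 2 * H - 1),
            g_ = gates.cols(2 * H, 3 * H - 1), o_ = gates.cols(3 * H, 4 * H - 1);
        mat cprev = (t == 0) ? mat(B, H, fill::zeros) : Cc[l][t - 1];
        mat tc = tanh(Cc[l][t]);
        mat do_ = dh % tc;
        dc += dh % o_ % (1.0 - square(tc));
        mat di = dc % g_, df = dc % cprev, dg = dc % i_;
        mat dc_prev = dc % f_;
        mat dpre(B, 4 * H);
        dpre.cols(0, H - 1) = di % i_ % (1.0 - i_);
        dpre.cols(H, 2 * H - 1) = df % f_ % (1.0 - f_);
        dpre.cols(2 * H, 3 * H - 1) = dg % (1.0 - square(g_));
        dpre.cols(3 * H, 4 * H - 1) = do_ % o_ % (1.0 - o_);
        Gr[3 * l] += a.t() * dpre;
        Gr[3 * l + 1] += hprev.t() * dpre;
        Gr[3 * l + 2] += sum(dpre, 0);
        da = dpre * Wx.t();
        dh = dpre * Wh.t();
        dc = dc_prev;
      }
      if (l > 0) {
        if (dropout > 0 && rng) da = da % DM[l][t];
        dA[t] = da;
      }
    }
    if (l > 0) dHabove = dA;
  }
  return loss;
}

// midrank-based AUC
static double auc_midrank(const vec& y, const vec& p) {
  const int n = y.n_elem;
  uvec ord = sort_index(p);
  vec ranks(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && p(ord(j + 1)) == p(ord(i))) ++j;
    double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) ranks(ord(k)) = r;
    i = j + 1;
  }
  double n1 = accu(y), n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  double s = accu(ranks % y);
  return (s - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// [[Rcpp::export]]
double cpp_auc(arma::vec y, arma::vec p) { return auc_midrank(y, p); }

// [[Rcpp::export]]
arma::vec cpp_rnn_predict(List weights, arma::cube X, std::string cell,
                          int hidden, int layers) {
  WeightSet W = list_to_ws(weights);
  vec p;
  rnn_fb(W, X, nullptr, cell, hidden, layers, 0.0, nullptr, 1.0, nullptr, &p);
  return p;
}

// [[Rcpp::export]]
List cpp_rnn_lossgrad(List weights, arma::cube X, arma::vec y, std::string cell,
                      int hidden, int layers, double pos_weight = 1.0) {
  WeightSet W = list_to_ws(weights);
  WeightSet G(W.size());
  double loss =
      rnn_fb(W, X, &y, cell, hidden, layers, 0.0, nullptr, pos_weight, &G, nullptr);
  return List::create(_["loss"] = loss,
                      _["grad"] = ws_to_list(G, rnn_weight_names(layers)));
}

static void adam_step(WeightSet& W, const WeightSet& G, WeightSet& M,
                      WeightSet& V, int t, double lr, double clip = 5.0) {
  double gn = 0.0;
  for (size_t i = 0; i < G.size(); ++i) gn += accu(square(G[i]));
  gn = std::sqrt(gn);
  double sc = (clip > 0 && gn > clip) ? clip / gn : 1.0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
  for (size_t i = 0; i < W.size(); ++i) {
    mat g = G[i] * sc;
    M[i] = b1 * M[i] + (1.0 - b1) * g;
    V[i] = b2 * V[i] + (1.0 - b2) * square(g);
    W[i] -= lr * (M[i] / bc1) / (sqrt(V[i] / bc2) + eps);
  }
}

// [[Rcpp::export]]
List cpp_rnn_train(arma::cube X, arma::vec y, arma::cube Xval, arma::vec yval,
                   List init, std::string cell, int hidden, int layers,
                   double dropout, int batch_size, int max_epochs, double lr,
                   int patience, int seed, double pos_weight = 1.0) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  WeightSet W;
  if (init.size() > 0) {
    W = list_to_ws(init);
  } else {
    W = list_to_ws(cpp_rnn_init(X.n_cols, hidden, layers, cell, seed));
  }
  WeightSet best = W, M(W.size()), V(W.size());
  for (size_t i = 0; i < W.size(); ++i) {
    M[i] = mat(size(W[i]), fill::zeros);
    V[i] = mat(size(W[i]), fill::zeros);
  }
  const int n = X.n_rows;
  int best_epoch = 0, stall = 0, adam_t = 0;
  double best_auc = NA_REAL;
  std::vector<double> log_loss, log_auc;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      uvec sel(end - start);
      for (int i = start; i < end; ++i) sel(i - start) = idx[i];
      cube Xb(sel.n_elem, X.n_cols, X.n_slices);
      for (uword t = 0; t < X.n_slices; ++t) Xb.slice(t) = X.slice(t).rows(sel);
      vec yb = y(sel);
      WeightSet G(W.size());
      double l = rnn_fb(W, Xb, &yb, cell, hidden, layers, dropout, &rng,
                        pos_weight, &G, nullptr);
      adam_step(W, G, M, V, ++adam_t, lr);
      ep_loss += l;
      ++nb;
    }
    ep_loss /= std::max(nb, 1);
    vec pv;
    rnn_fb(W, Xval, nullptr, cell, hidden, layers, 0.0, nullptr, 1.0, nullptr, &pv);
    double auc = auc_midrank(yval, pv);
    log_loss.push_back(ep_loss);
    log_auc.push_back(auc);
    if (!std::isnan(auc) && (std::isnan(best_auc) || auc > best_auc)) {
      best_auc = auc;
      best_epoch = epoch;
      best = W;
      stall = 0;
    } else {
      ++stall;
    }
    if (patience > 0 && stall >= patience) break;
  }
  int ne = log_loss.size();
  NumericMatrix logm(ne, 3);
  for (int i = 0; i < ne; ++i) {
    logm(i, 0) = i + 1;
    logm(i, 1) = log_loss[i];
    logm(i, 2) = log_auc[i];
  }
  colnames(logm) = CharacterVector::create("epoch", "train_loss", "val_auc");
  return List::create(_["weights"] = ws_to_list(best, rnn_weight_names(layers)),
                      _["best_epoch"] = best_epoch,
                      _["best_val_auc"] = best_auc, _["log"] = logm);
}

// ---------------------------------------------------------------------------
// Bidirectional recurrent imputer
// Per-direction parameters: Wg (d x H), bg (1 x H)  hidden decay from gaps
//                           Wout (H x d), bout (1 x d) regression to features
//                           Wx (d x H), Wh (H x H), bh (1 x H) recurrence
// ---------------------------------------------------------------------------

static std::vector<std::string> brits_weight_names() {
  return {"Wg", "bg", "Wout", "bout", "Wx", "Wh", "bh"};
}

// [[Rcpp::export]]
List cpp_brits_init(int d, int hidden, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  double k = 1.0 / std::sqrt((double)hidden);
  WeightSet W(7);
  W[0] = mat(d, hidden);  W[1] = mat(1, hidden);
  W[2] = mat(hidden, d);  W[3] = mat(1, d);
  W[4] = mat(d, hidden);  W[5] = mat(hidden, hidden); W[6] = mat(1, hidden);
  for (auto& m : W) fill_uniform(m, rng, k);
  return ws_to_list(W, brits_weight_names());
}

// per-feature gap matrices for one direction; ts is the visiting order
static std::vector<mat> make_deltas(const cube& M, const std::vector<int>& ts) {
  int n = M.n_rows, d = M.n_cols, T = ts.size();
  std::vector<mat> D(T);
  D[0] = mat(n, d, fill::zeros);
  for (int k = 1; k < T; ++k)
    D[k] = 1.0 + (1.0 - M.slice(ts[k - 1])) % D[k - 1];
  return D;
}

// forward pass of one direction, caching everything needed for BPTT
struct RitsCache {
  std::vector<mat> delta, gamma, u, htil, xhat, xc, h;
};

static void rits_forward(const WeightSet& W, const cube& X, const cube& M,
                         const std::vector<int>& ts, RitsCache& C) {
  int n = X.n_rows, H = W[1].n_cols, T = ts.size();
  C.delta = make_deltas(M, ts);
  C.gamma.resize(T); C.u.resize(T); C.htil.resize(T);
  C.xhat.resize(T); C.xc.resize(T); C.h.resize(T);
  mat h(n, H, fill::zeros);
  for (int k = 0; k < T; ++k) {
    int t = ts[k];
    mat u = C.delta[k] * W[0];
    u.each_row() += W[1].row(0);
    mat gamma = exp(-clamp(u, 0.0, datum::inf));
    mat htil = h % gamma;
    mat xhat = htil * W[2];
    xhat.each_row() += W[3].row(0);
    const mat& m = M.slice(t);
    mat xc = m % X.slice(t) + (1.0 - m) % xhat;
    mat hp = xc * W[4] + htil * W[5];
    hp.each_row() += W[6].row(0);
    h = tanh(hp);
    C.u[k] = u; C.gamma[k] = gamma; C.htil[k] = htil;
    C.xhat[k] = xhat; C.xc[k] = xc; C.h[k] = h;
  }
}

// backward pass; dxhat_ext[k] is the external loss gradient w.r.t. xhat at
// visiting position k; accumulates into G
static void rits_backward(const WeightSet& W, const cube& M,
                          const std::vector<int>& ts, const RitsCache& C,
                          const std::vector<mat>& dxhat_ext, WeightSet& G) {
  int n = M.n_rows, H = W[1].n_cols, T = ts.size();
  mat dh(n, H, fill::zeros);
  for (int k = T - 1; k >= 0; --k) {
    int t = ts[k];
    const mat& m = M.slice(t);
    mat hprev = (k == 0) ? mat(n, H, fill::zeros) : C.h[k - 1];
    mat da = dh % (1.0 - square(C.h[k]));
    G[4] += C.xc[k].t() * da;
    G[5] += C.htil[k].t() * da;
    G[6] += sum(da, 0);
    mat dxc = da * W[4].t();
    mat dhtil = da * W[5].t();
    mat dxhat = dxhat_ext[k] + dxc % (1.0 - m);
    G[2] += C.htil[k].t() * dxhat;
    G[3] += sum(dxhat, 0);
    dhtil += dxhat * W[2].t();
    mat dgamma = dhtil % hprev;
    mat dh_prev = dhtil % C.gamma[k];
    mat du = dgamma % (-C.gamma[k]) % conv_to<mat>::from(C.u[k] > 0.0);
    G[0] += C.delta[k].t() * du;
    G[1] += sum(du, 0);
    dh = dh_prev;
  }
}

// joint loss + gradients over both directions (recon on observed cells plus
// forward/backward consistency penalty)
static double brits_lossgrad(const WeightSet& Wf, const WeightSet& Wb,
                             const cube& X, const cube& M, double lambda,
                             WeightSet* Gf, WeightSet* Gb) {
  int T = X.n_slices;
  std::vector<int> tf(T), tb(T);
  for (int t = 0; t < T; ++t) { tf[t] = t; tb[t] = T - 1 - t; }
  RitsCache Cf, Cb;
  rits_forward(Wf, X, M, tf, Cf);
  rits_forward(Wb, X, M, tb, Cb);

  double nobs = accu(M);
  double ncell = (double)X.n_rows * X.n_cols * T;
  double loss = 0.0;
  // dxhat indexed by visiting position of each direction
  std::vector<mat> dxf(T), dxb(T);
  for (int k = 0; k < T; ++k) {
    int t_f = tf[k];
    const mat& m = M.slice(t_f);
    mat rf = X.slice(t_f) - Cf.xhat[k];
    loss += accu(m % square(rf)) / nobs;
    dxf[k] = -2.0 * (m % rf) / nobs;
  }
  for (int k = 0; k < T; ++k) {
    int t_b = tb[k];
    const mat& m = M.slice(t_b);
    mat rb = X.slice(t_b) - Cb.xhat[k];
    loss += accu(m % square(rb)) / nobs;
    dxb[k] = -2.0 * (m % rb) / nobs;
  }
  // consistency: compare estimates at the same absolute time step
  for (int t = 0; t < T; ++t) {
    int kf = t, kb = T - 1 - t;
    mat diff = Cf.xhat[kf] - Cb.xhat[kb];
    loss += lambda * accu(square(diff)) / ncell;
    dxf[kf] += 2.0 * lambda * diff / ncell;
    dxb[kb] += -2.0 * lambda * diff / ncell;
  }
  if (Gf && Gb) {
    for (size_t i = 0; i < Wf.size(); ++i) {
      (*Gf)[i] = mat(size(Wf[i]), fill::zeros);
      (*Gb)[i] = mat(size(Wb[i]), fill::zeros);
    }
    rits_backward(Wf, M, tf, Cf, dxf, *Gf);
    rits_backward(Wb, M, tb, Cb, dxb, *Gb);
  }
  return loss;
}

// [[Rcpp::export]]
List cpp_brits_lossgrad(List wf, List wb, arma::cube X, arma::cube M,
                        double lambda) {
  WeightSet Wf = list_to_ws(wf), Wb = list_to_ws(wb);
  WeightSet Gf(Wf.size()), Gb(Wb.size());
  double loss = brits_lossgrad(Wf, Wb, X, M, lambda, &Gf, &Gb);
  return List::create(_["loss"] = loss,
                      _["grad_f"] = ws_to_list(Gf, brits_weight_names()),
                      _["grad_b"] = ws_to_list(Gb, brits_weight_names()));
}

// [[Rcpp::export]]
List cpp_brits_train(arma::cube X, arma::cube M, int hidden, int max_epochs,
                     double lr, double lambda, int batch_size, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int d = X.n_cols, n = X.n_rows;
  WeightSet Wf = list_to_ws(cpp_brits_init(d, hidden, seed));
  WeightSet Wb = list_to_ws(cpp_brits_init(d, hidden, seed + 1));
  // single Adam state over the concatenation of both directions
  WeightSet W = Wf;
  W.insert(W.end(), Wb.begin(), Wb.end());
  WeightSet Ms(W.size()), Vs(W.size());
  for (size_t i = 0; i < W.size(); ++i) {
    Ms[i] = mat(size(W[i]), fill::zeros);
    Vs[i] = mat(size(W[i]), fill::zeros);
  }
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> losses;
  int adam_t = 0;
  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      uvec sel(end - start);
      for (int i = start; i < end; ++i) sel(i - start) = idx[i];
      cube Xb(sel.n_elem, X.n_cols, X.n_slices),
          Mb(sel.n_elem, X.n_cols, X.n_slices);
      for (uword t = 0; t < X.n_slices; ++t) {
        Xb.slice(t) = X.slice(t).rows(sel);
        Mb.slice(t) = M.slice(t).rows(sel);
      }
      WeightSet Wfc(W.begin(), W.begin() + 7), Wbc(W.begin() + 7, W.end());
      WeightSet Gf(7), Gb(7);
      double l = brits_lossgrad(Wfc, Wbc, Xb, Mb, lambda, &Gf, &Gb);
      WeightSet G = Gf;
      G.insert(G.end(), Gb.begin(), Gb.end());
      adam_step(W, G, Ms, Vs, ++adam_t, lr);
      ep += l;
      ++nb;
    }
    losses.push_back(ep / std::max(nb, 1));
  }
  WeightSet Wf2(W.begin(), W.begin() + 7), Wb2(W.begin() + 7, W.end());
  return List::create(_["wf"] = ws_to_list(Wf2, brits_weight_names()),
                      _["wb"] = ws_to_list(Wb2, brits_weight_names()),
                      _["loss"] = wrap(losses));
}

// [[Rcpp::export]]
List cpp_brits_impute(List wf, List wb, arma::cube X, arma::cube M) {
  WeightSet Wf = list_to_ws(wf), Wb = list_to_ws(wb);
  int T = X.n_slices;
  std::vector<int> tf(T), tb(T);
  for (int t = 0; t < T; ++t) { tf[t] = t; tb[t] = T - 1 - t; }
  RitsCache Cf, Cb;
  rits_forward(Wf, X, M, tf, Cf);
  rits_forward(Wb, X, M, tb, Cb);
  cube out = X, xf(size(X)), xb(size(X));
  for (int t = 0; t < T; ++t) {
    xf.slice(t) = Cf.xhat[t];
    xb.slice(t) = Cb.xhat[T - 1 - t];
    const mat& m = M.slice(t);
    out.slice(t) = m % X.slice(t) + (1.0 - m) % (0.5 * (xf.slice(t) + xb.slice(t)));
  }
  return List::create(_["imputed"] = out, _["est_forward"] = xf,
                      _["est_backward"] = xb);
}
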