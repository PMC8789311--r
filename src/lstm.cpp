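// Stacked LSTM with tanh activations, trained by backpropagation through
// time.  The sequence axis is the discretized time grid of the genealogy
// encoding (present -> past); inputs are the lineage-count channels.  Heads:
// 2-unit softmax (sweep/neutral classification, cross-entropy loss), linear
// scalar after the last timestep (selection-coefficient / onset regression,
// MSE), or linear scalar at every timestep (many-to-many allele-frequency
// trajectory, MSE).  Inverted dropout is applied to each stack's output on
// the upward (non-recurrent) connections; the same machinery run at
// inference time provides Monte Carlo dropout samples.  All randomness draws
// from R's RNG so results are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat sigm(const arma::mat &z) { return 1.0 / (1.0 + arma::exp(-z)); }

static arma::mat rand_mask(int nr, int nc, double p) {
  arma::mat m(nr, nc);
  for (arma::uword j = 0; j < m.n_elem; ++j)
    m(j) = (R::unif_rand() < p) ? 0.0 : 1.0 / (1.0 - p);
  return m;
}

struct LayerCache {
  arma::cube gi, gf, gg, go, c, h, hdrop;   // (B, U, K)
  arma::cube mask;                          // inverted-dropout mask on h
};

// forward through all stacks; returns per-layer caches; input X is (B, C, K)
static void lstm_forward(const List &layers, const arma::cube &X,
                         double dropout, bool use_dropout,
                         std::vector<LayerCache> &caches) {
  int K = X.n_slices, B = X.n_rows;
  arma::cube In = X;
  int nl = layers.size();
  caches.resize(nl);
  for (int l = 0; l < nl; ++l) {
    List lay = layers[l];
    arma::mat Wx = lay["Wx"], Wh = lay["Wh"], bmat = lay["b"];
    arma::rowvec b = bmat.row(0);
    int U = Wh.n_rows;
    LayerCache &cc = caches[l];
    cc.gi.set_size(B, U, K); cc.gf.set_size(B, U, K); cc.gg.set_size(B, U, K);
    cc.go.set_size(B, U, K); cc.c.set_size(B, U, K);  cc.h.set_size(B, U, K);
    cc.hdrop.set_size(B, U, K);
    cc.mask.set_size(B, U, K);
    arma::mat hprev(B, U, arma::fill::zeros), cprev(B, U, arma::fill::zeros);
    for (int t = 0; t < K; ++t) {
      arma::mat Z = In.slice(t) * Wx + hprev * Wh;
      Z.each_row() += b;
      arma::mat i = sigm(Z.cols(0, U - 1));
      arma::mat f = sigm(Z.cols(U, 2 * U - 1));
      arma::mat g = arma::tanh(Z.cols(2 * U, 3 * U - 1));
      arma::mat o = sigm(Z.cols(3 * U, 4 * U - 1));
      arma::mat c = f % cprev + i % g;
      arma::mat h = o % arma::tanh(c);
      arma::mat m = (use_dropout && dropout > 0.0)
                      ? rand_mask(B, U, dropout)
                      : arma::mat(B, U, arma::fill::ones);
      cc.gi.slice(t) = i; cc.gf.slice(t) = f; cc.gg.slice(t) = g;
      cc.go.slice(t) = o; cc.c.slice(t) = c;  cc.h.slice(t) = h;
      cc.mask.slice(t) = m;
      cc.hdrop.slice(t) = h % m;
      hprev = h;            // recurrent connection stays undropped
      cprev = c;
    }
    In = cc.hdrop;
  }
}

// [[Rcpp::export]]
arma::mat lstm_predict_cpp(List weights, arma::cube X, std::string task,
                           double dropout, bool use_dropout) {
  List layers = weights["layers"];
  arma::mat Wo = weights["Wo"], bomat = weights["bo"];
  arma::rowvec bo = bomat.row(0);
  std::vector<LayerCache> caches;
  lstm_forward(layers, X, dropout, use_dropout, caches);
  const arma::cube &H = caches.back().hdrop;
  int K = H.n_slices, B = H.n_rows;
  if (task == "trajectory") {
    arma::mat out(B, K);
    for (int t = 0; t < K; ++t) {
      arma::mat o = H.slice(t) * Wo;
      o.each_row() += bo;
      out.col(t) = o.col(0);
    }
    return out;
  }
  arma::mat out = H.slice(K - 1) * Wo;
  out.each_row() += bo;
  if (task == "classify") {
    out.each_col() -= arma::max(out, 1);
    out = arma::exp(out);
    out.each_col() /= arma::sum(out, 1);
  }
  return out;
}

// [[Rcpp::export]]
List lstm_grad_cpp(List weights, arma::cube X, arma::mat Y, std::string task,
                   double dropout) {
  List layers = weights["layers"];
  arma::mat Wo = weights["Wo"], bomat = weights["bo"];
  arma::rowvec bo = bomat.row(0);
  int nl = layers.size();
  std::vector<LayerCache> caches;
  lstm_forward(layers, X, dropout, true, caches);
  const arma::cube &H = caches.back().hdrop;
  int K = H.n_slices, B = H.n_rows;
  int U_top = H.n_cols;

  arma::mat dWo(arma::size(Wo), arma::fill::zeros);
  arma::rowvec dbo(arma::size(bo), arma::fill::zeros);
  arma::cube dOut(B, U_top, K, arma::fill::zeros);
  double loss = 0.0;

  if (task == "classify") {
    arma::mat logits = H.slice(K - 1) * Wo;
    logits.each_row() += bo;
    logits.each_col() -= arma::max(logits, 1);
    arma::mat p = arma::exp(logits);
    p.each_col() /= arma::sum(p, 1);
    arma::mat onehot(B, 2, arma::fill::zeros);
    for (int i = 0; i < B; ++i) {
      int cls = (int)Y(i, 0);
      onehot(i, cls) = 1.0;
      loss += -std::log(std::max(p(i, cls), 1e-12));
    }
    loss /= B;
    arma::mat dlog = (p - onehot) / B;
    dWo = H.slice(K - 1).t() * dlog;
    dbo = arma::sum(dlog, 0);
    dOut.slice(K - 1) = dlog * Wo.t();
  } else if (task == "trajectory") {
    for (int t = 0; t < K; ++t) {
      arma::mat o = H.slice(t) * Wo;
      o.each_row() += bo;
      arma::vec d = o.col(0) - Y.col(t);
      loss += arma::accu(d % d);
      arma::mat dout = 2.0 * d / (double)(B * K);
      dWo += H.slice(t).t() * dout;
      dbo += arma::sum(dout, 0);
      dOut.slice(t) = dout * Wo.t();
    }
    loss /= (double)(B * K);
  } else {                                  // scalar regression
    arma::mat o = H.slice(K - 1) * Wo;
    o.each_row() += bo;
    arma::vec d = o.col(0) - Y.col(0);
    loss = arma::accu(d % d) / B;
    arma::mat dout = 2.0 * d / (double)B;
    dWo = H.slice(K - 1).t() * dout;
    dbo = arma::sum(dout, 0);
    dOut.slice(K - 1) = dout * Wo.t();
  }

  // backprop through the stacks, top to bottom
  List glayers(nl);
  for (int l = nl - 1; l >= 0; --l) {
    List lay = layers[l];
    arma::mat Wx = lay["Wx"], Wh = lay["Wh"];
    int U = Wh.n_rows;
    const LayerCache &cc = caches[l];
    const arma::cube &In = (l == 0) ? X : caches[l - 1].hdrop;
    int Cin = In.n_cols;
    arma::mat dWx(Cin, 4 * U, arma::fill::zeros);
    arma::mat dWh(U, 4 * U, arma::fill::zeros);
    arma::rowvec db(4 * U, arma::fill::zeros);
    arma::cube dIn(B, Cin, K, arma::fill::zeros);
    arma::mat dh_fut(B, U, arma::fill::zeros), dc_fut(B, U, arma::fill::zeros);
    for (int t = K - 1; t >= 0; --t) {
      arma::mat dh = dOut.slice(t) % cc.mask.slice(t) + dh_fut;
      arma::mat tc = arma::tanh(cc.c.slice(t));
      arma::mat i = cc.gi.slice(t), f = cc.gf.slice(t),
                g = cc.gg.slice(t), o = cc.go.slice(t);
      arma::mat dopre = dh % tc % o % (1.0 - o);
      arma::mat dc = dh % o % (1.0 - tc % tc) + dc_fut;
      arma::mat cprev = (t > 0) ? cc.c.slice(t - 1)
                                : arma::mat(B, U, arma::fill::zeros);
      arma::mat dipre = dc % g % i % (1.0 - i);
      arma::mat dgpre = dc % i % (1.0 - g % g);
      arma::mat dfpre = dc % cprev % f % (1.0 - f);
      dc_fut = dc % f;
      arma::mat dZ = arma::join_rows(dipre, dfpre, dgpre, dopre);
      dWx += In.slice(t).t() * dZ;
      if (t > 0) dWh += cc.h.slice(t - 1).t() * dZ;
      db += arma::sum(dZ, 0);
      dIn.slice(t) = dZ * Wx.t();
      dh_fut = dZ * Wh.t();
    }
    glayers[l] = List::create(_["Wx"] = dWx, _["Wh"] = dWh, _["b"] = db);
    dOut = dIn;          // gradient w.r.t. the (dropped) output of layer l-1
  }
  return List::create(_["loss"] = loss,
                      _["layers"] = glayers,
                      _["Wo"] = dWo, _["bo"] = dbo);
}
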