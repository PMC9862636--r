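// Forward/backward kernels for the two small spectral classifiers:
// a seven-layer 1D CNN (conv -> ReLU -> maxpool -> FC -> softmax) and a
// single-layer LSTM with dropout on the final hidden state. The wavelength
// axis is the only convolution/sequence direction. Mini-batch loops live in
// R; these kernels compute one batch's loss, probabilities and gradients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat softmax_rows(const mat& logits) {
  mat z = logits.each_col() - max(logits, 1);
  mat e = exp(z);
  return e.each_col() / sum(e, 1);
}

static double xent_loss(const mat& probs, const mat& y) {
  return -accu(y % log(probs + 1e-12)) / probs.n_rows;
}

struct CnnCache {
  cube conv;      // B x P x nf (pre-ReLU)
  cube pooled;    // B x Pp x nf
  ucube argmax;   // winning in-window offset per pooled cell
  mat flat;       // B x (nf * Pp)
  mat h1;         // B x fcw (pre-ReLU)
  mat a1;         // B x fcw
  mat probs;      // B x 2
};

static CnnCache cnn_forward_impl(const mat& x, const mat& wc, const vec& bc,
                                 const mat& w1, const vec& b1,
                                 const mat& w2, const vec& b2, int pool_len,
                                 bool want_argmax) {
  const uword B = x.n_rows, F = x.n_cols;
  const uword K = wc.n_rows, nf = wc.n_cols;
  const uword P = F - K + 1;
  const uword Pp = P / pool_len;
  CnnCache c;
  c.conv.set_size(B, P, nf);
  for (uword f = 0; f < nf; ++f) {
    mat acc(B, P, fill::value(bc(f)));
    for (uword k = 0; k < K; ++k) {
      acc += x.cols(k, k + P - 1) * wc(k, f);
    }
    c.conv.slice(f) = acc;
  }
  cube relu = c.conv;
  relu.transform([](double v) { return v > 0.0 ? v : 0.0; });
  c.pooled.set_size(B, Pp, nf);
  if (want_argmax) c.argmax.set_size(B, Pp, nf);
  uvec stride(Pp);
  for (uword q = 0; q < Pp; ++q) stride(q) = q * pool_len;
  for (uword f = 0; f < nf; ++f) {
    mat best = relu.slice(f).cols(stride);
    umat amax;
    if (want_argmax) amax.zeros(B, Pp);
    for (int l = 1; l < pool_len; ++l) {
      mat cand = relu.slice(f).cols(stride + l);
      if (want_argmax) {
        umat better = cand > best;
        amax(find(better)).fill(uword(l));
      }
      best = arma::max(best, cand);
    }
    c.pooled.slice(f) = best;
    if (want_argmax) c.argmax.slice(f) = amax;
  }
  c.flat.set_size(B, nf * Pp);
  for (uword f = 0; f < nf; ++f) {
    c.flat.cols(f * Pp, (f + 1) * Pp - 1) = c.pooled.slice(f);
  }
  c.h1 = c.flat * w1;
  c.h1.each_row() += b1.t();
  c.a1 = c.h1;
  c.a1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  mat logits = c.a1 * w2;
  logits.each_row() += b2.t();
  c.probs = softmax_rows(logits);
  return c;
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(const arma::mat& x, const arma::mat& wc,
                          const arma::vec& bc, const arma::mat& w1,
                          const arma::vec& b1, const arma::mat& w2,
                          const arma::vec& b2, int pool_len) {
  return cnn_forward_impl(x, wc, bc, w1, b1, w2, b2, pool_len, false).probs;
}

// [[Rcpp::export]]
Rcpp::List cnn_batch_cpp(const arma::mat& x, const arma::mat& y,
                         const arma::mat& wc, const arma::vec& bc,
                         const arma::mat& w1, const arma::vec& b1,
                         const arma::mat& w2, const arma::vec& b2,
                         int pool_len) {
  const uword B = x.n_rows, F = x.n_cols;
  const uword K = wc.n_rows, nf = wc.n_cols;
  const uword P = F - K + 1;
  const uword Pp = P / pool_len;
  CnnCache c = cnn_forward_impl(x, wc, bc, w1, b1, w2, b2, pool_len, true);
  double loss = xent_loss(c.probs, y);

  mat dlogits = (c.probs - y) / double(B);
  mat dw2 = c.a1.t() * dlogits;
  vec db2 = sum(dlogits, 0).t();
  mat da1 = dlogits * w2.t();
  mat dh1 = da1 % (c.h1 > 0);
  mat dw1 = c.flat.t() * dh1;
  vec db1 = sum(dh1, 0).t();
  mat dflat = dh1 * w1.t();

  mat dwc(K, nf, fill::zeros);
  vec dbc(nf, fill::zeros);
  for (uword f = 0; f < nf; ++f) {
    // route pooled gradients back to the winning conv positions
    mat drelu(B, P, fill::zeros);
    const mat dpool = dflat.cols(f * Pp, (f + 1) * Pp - 1);
    const umat& am = c.argmax.slice(f);
    for (uword q = 0; q < Pp; ++q) {
      for (uword b = 0; b < B; ++b) {
        drelu(b, q * pool_len + am(b, q)) += dpool(b, q);
      }
    }
    mat dconv = drelu % (c.conv.slice(f) > 0);
    dbc(f) = accu(dconv);
    for (uword k = 0; k < K; ++k) {
      dwc(k, f) = accu(x.cols(k, k + P - 1) % dconv);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("probs") = c.probs,
    Rcpp::Named("gWc") = dwc, Rcpp::Named("gbc") = dbc,
    Rcpp::Named("gW1") = dw1, Rcpp::Named("gb1") = db1,
    Rcpp::Named("gW2") = dw2, Rcpp::Named("gb2") = db2);
}

static mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
arma::mat lstm_forward_cpp(const arma::mat& x, int n_steps, int d,
                           const arma::mat& wx, const arma::mat& wh,
                           const arma::vec& b, const arma::mat& wy,
                           const arma::vec& by, bool mean_pool) {
  const uword B = x.n_rows;
  const uword H = wh.n_rows;
  mat h(B, H, fill::zeros), cst(B, H, fill::zeros), hsum(B, H, fill::zeros);
  for (int t = 0; t < n_steps; ++t) {
    mat xt = x.cols(t * d, (t + 1) * d - 1);
    mat z = xt * wx + h * wh;
    z.each_row() += b.t();
    mat ig = sigmoid(z.cols(0, H - 1));
    mat fg = sigmoid(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat og = sigmoid(z.cols(3 * H, 4 * H - 1));
    cst = fg % cst + ig % gg;
    h = og % tanh(cst);
    if (mean_pool) hsum += h;
  }
  mat hout = mean_pool ? mat(hsum / double(n_steps)) : h;
  mat logits = hout * wy;
  logits.each_row() += by.t();
  return softmax_rows(logits);
}

// [[Rcpp::export]]
Rcpp::List lstm_batch_cpp(const arma::mat& x, const arma::mat& y,
                          int n_steps, int d,
                          const arma::mat& wx, const arma::mat& wh,
                          const arma::vec& b, const arma::mat& wy,
                          const arma::vec& by, const arma::mat& dropmask,
                          bool mean_pool) {
  const uword B = x.n_rows;
  const uword H = wh.n_rows;
  const int T = n_steps;
  cube I(B, H, T), Fg(B, H, T), G(B, H, T), O(B, H, T), C(B, H, T), Hs(B, H, T);
  mat h(B, H, fill::zeros), cst(B, H, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat xt = x.cols(t * d, (t + 1) * d - 1);
    mat z = xt * wx + h * wh;
    z.each_row() += b.t();
    mat ig = sigmoid(z.cols(0, H - 1));
    mat fg = sigmoid(z.cols(H, 2 * H - 1));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat og = sigmoid(z.cols(3 * H, 4 * H - 1));
    cst = fg % cst + ig % gg;
    h = og % tanh(cst);
    I.slice(t) = ig; Fg.slice(t) = fg; G.slice(t) = gg; O.slice(t) = og;
    C.slice(t) = cst; Hs.slice(t) = h;
  }
  mat hout = h;
  if (mean_pool) {
    hout.zeros();
    for (int t = 0; t < T; ++t) hout += Hs.slice(t);
    hout /= double(T);
  }
  mat hd = hout % dropmask;
  mat logits = hd * wy;
  logits.each_row() += by.t();
  mat probs = softmax_rows(logits);
  double loss = xent_loss(probs, y);

  mat dlogits = (probs - y) / double(B);
  mat dwy = hd.t() * dlogits;
  vec dby = sum(dlogits, 0).t();
  mat dhout = (dlogits * wy.t()) % dropmask;
  mat dh = mean_pool ? mat(dhout / double(T)) : dhout;
  mat dc(B, H, fill::zeros);
  mat dwx(wx.n_rows, wx.n_cols, fill::zeros);
  mat dwh(wh.n_rows, wh.n_cols, fill::zeros);
  vec db(b.n_elem, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat tc = tanh(C.slice(t));
    mat do_ = dh % tc;
    dc += dh % O.slice(t) % (1.0 - tc % tc);
    mat cprev = (t == 0) ? mat(B, H, fill::zeros) : C.slice(t - 1);
    mat di = dc % G.slice(t);
    mat dg = dc % I.slice(t);
    mat df = dc % cprev;
    mat dc_next = dc % Fg.slice(t);
    mat dz(B, 4 * H);
    dz.cols(0, H - 1) = di % I.slice(t) % (1.0 - I.slice(t));
    dz.cols(H, 2 * H - 1) = df % Fg.slice(t) % (1.0 - Fg.slice(t));
    dz.cols(2 * H, 3 * H - 1) = dg % (1.0 - G.slice(t) % G.slice(t));
    dz.cols(3 * H, 4 * H - 1) = do_ % O.slice(t) % (1.0 - O.slice(t));
    mat xt = x.cols(t * d, (t + 1) * d - 1);
    mat hprev = (t == 0) ? mat(B, H, fill::zeros) : Hs.slice(t - 1);
    dwx += xt.t() * dz;
    dwh += hprev.t() * dz;
    db += sum(dz, 0).t();
    dh = dz * wh.t();
    if (mean_pool && t > 0) dh += dhout / double(T);
    dc = dc_next;
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("probs") = probs,
    Rcpp::Named("gWx") = dwx, Rcpp::Named("gWh") = dwh,
    Rcpp::Named("gb") = db,
    Rcpp::Named("gWy") = dwy, Rcpp::Named("gby") = dby);
}
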