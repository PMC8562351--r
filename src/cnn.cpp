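// Compact 1D CNN (three strided convolutions, two max-pool stages, dense
// softmax head) with Adam and early stopping on the running training loss.
// Activations are stored as (n x C*L) matrices, channel-major columns
// (col = c*L + t). Convolutions are evaluated by im2col gathers so the inner
// products run through BLAS. All randomness (shuffling) uses the R RNG, so
// results are reproducible from set.seed() on the R side.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct ConvIdx {
  // flat gather table: idx[t * taps + q] = input column or -1 (zero pad)
  std::vector<long> idx;
  int n_out, taps;  // taps = kernel * in_channels
};

ConvIdx conv_index(int len_in, int in_ch, int kernel, int stride,
                   bool same_pad) {
  ConvIdx ci;
  int n_out, pad_left = 0;
  if (same_pad) {
    n_out = (len_in + stride - 1) / stride;
    int pad_total = std::max((n_out - 1) * stride + kernel - len_in, 0);
    pad_left = pad_total / 2;
  } else {
    n_out = (len_in - kernel) / stride + 1;
  }
  ci.n_out = n_out;
  ci.taps = kernel * in_ch;
  ci.idx.resize((size_t)n_out * ci.taps);
  for (int t = 0; t < n_out; ++t)
    for (int c = 0; c < in_ch; ++c)
      for (int j = 0; j < kernel; ++j) {
        int pos = t * stride - pad_left + j;
        ci.idx[(size_t)t * ci.taps + c * kernel + j] =
            (pos >= 0 && pos < len_in) ? (long)c * len_in + pos : -1;
      }
  return ci;
}

// gather activations (n x C*Lin) into im2col matrix (n*Lout x taps)
mat im2col(const mat& a, const ConvIdx& ci) {
  uword n = a.n_rows;
  mat g(n * ci.n_out, ci.taps, fill::zeros);
  for (int t = 0; t < ci.n_out; ++t)
    for (int q = 0; q < ci.taps; ++q) {
      long src = ci.idx[(size_t)t * ci.taps + q];
      if (src < 0) continue;
      for (uword i = 0; i < n; ++i)
        g(i * ci.n_out + t, q) = a(i, src);
    }
  return g;
}

// scatter-add gradient of im2col back onto the input layout
void col2im(const mat& dg, const ConvIdx& ci, mat& da) {
  uword n = da.n_rows;
  for (int t = 0; t < ci.n_out; ++t)
    for (int q = 0; q < ci.taps; ++q) {
      long dst = ci.idx[(size_t)t * ci.taps + q];
      if (dst < 0) continue;
      for (uword i = 0; i < n; ++i)
        da(i, dst) += dg(i * ci.n_out + t, q);
    }
}

// (n*Lout x F) conv output -> activation layout (n x F*Lout)
mat to_act(const mat& z, uword n, int n_out, int nf) {
  mat a(n, (uword)nf * n_out);
  for (int f = 0; f < nf; ++f)
    for (int t = 0; t < n_out; ++t)
      for (uword i = 0; i < n; ++i)
        a(i, (uword)f * n_out + t) = z(i * n_out + t, f);
  return a;
}

mat from_act(const mat& a, uword n, int n_out, int nf) {
  mat z(n * (uword)n_out, nf);
  for (int f = 0; f < nf; ++f)
    for (int t = 0; t < n_out; ++t)
      for (uword i = 0; i < n; ++i)
        z(i * n_out + t, f) = a(i, (uword)f * n_out + t);
  return z;
}

struct PoolCache { umat argmax; int n_out; };

mat maxpool(const mat& a, int len_in, int nch, PoolCache& pc) {
  uword n = a.n_rows;
  int n_out = len_in / 2;  // pool 2, stride 2, no padding
  pc.n_out = n_out;
  pc.argmax.set_size(n, (uword)nch * n_out);
  mat out(n, (uword)nch * n_out);
  for (int c = 0; c < nch; ++c)
    for (int t = 0; t < n_out; ++t) {
      uword i0 = (uword)c * len_in + 2 * t, oc = (uword)c * n_out + t;
      for (uword i = 0; i < n; ++i) {
        double v0 = a(i, i0), v1 = a(i, i0 + 1);
        bool first = v0 >= v1;
        out(i, oc) = first ? v0 : v1;
        pc.argmax(i, oc) = first ? i0 : i0 + 1;
      }
    }
  return out;
}

void maxpool_back(const mat& dout, const PoolCache& pc, mat& da) {
  for (uword j = 0; j < dout.n_cols; ++j)
    for (uword i = 0; i < dout.n_rows; ++i)
      da(i, pc.argmax(i, j)) += dout(i, j);
}

struct Net {
  mat w1, w2, w3, wd;
  rowvec b1, b2, b3, bd;
  ConvIdx c1, c2, c3;
  int len_in, l1, l2, p1, l3, p2, nflat, ncls;
  bool same_pad;

  void configure(int L, bool same) {
    len_in = L; same_pad = same;
    c1 = conv_index(L, 1, 5, 2, same);  l1 = c1.n_out;
    c2 = conv_index(l1, 3, 5, 2, same); l2 = c2.n_out;
    p1 = l2 / 2;
    c3 = conv_index(p1, 3, 5, 2, same); l3 = c3.n_out;
    p2 = l3 / 2;
    nflat = 3 * p2;
    if (l1 < 1 || l2 < 1 || p1 < 1 || l3 < 1 || p2 < 1)
      Rcpp::stop("input too short for the layer stack");
  }
};

struct Cache {
  mat g1, g2, g3;        // im2col inputs
  mat a1, a2, ap1, a3, ap2;  // post-ReLU / post-pool activations
  PoolCache pc1, pc2;
  mat probs;
};

// forward pass; if y provided (size>0) returns mean cross-entropy
double forward(Net& net, const mat& x, const ivec& y, Cache& cc) {
  uword n = x.n_rows;
  cc.g1 = im2col(x, net.c1);
  mat z1 = cc.g1 * net.w1; z1.each_row() += net.b1;
  z1.transform([](double v) { return v > 0 ? v : 0.0; });
  cc.a1 = to_act(z1, n, net.l1, 3);
  cc.g2 = im2col(cc.a1, net.c2);
  mat z2 = cc.g2 * net.w2; z2.each_row() += net.b2;
  z2.transform([](double v) { return v > 0 ? v : 0.0; });
  cc.a2 = to_act(z2, n, net.l2, 3);
  cc.ap1 = maxpool(cc.a2, net.l2, 3, cc.pc1);
  cc.g3 = im2col(cc.ap1, net.c3);
  mat z3 = cc.g3 * net.w3; z3.each_row() += net.b3;
  z3.transform([](double v) { return v > 0 ? v : 0.0; });
  cc.a3 = to_act(z3, n, net.l3, 3);
  cc.ap2 = maxpool(cc.a3, net.l3, 3, cc.pc2);
  mat logits = cc.ap2 * net.wd; logits.each_row() += net.bd;
  vec mx = max(logits, 1);
  logits.each_col() -= mx;
  mat ex = exp(logits);
  vec se = sum(ex, 1);
  cc.probs = ex.each_col() / se;
  if (y.n_elem == 0) return NA_REAL;
  double loss = 0;
  for (uword i = 0; i < n; ++i)
    loss += std::log(se(i)) - logits(i, y(i));
  return loss / n;
}

struct Grads { mat w1, w2, w3, wd; rowvec b1, b2, b3, bd; };

void backward(Net& net, const mat& x, const ivec& y, Cache& cc, Grads& gr) {
  uword n = x.n_rows;
  mat dlog = cc.probs;
  for (uword i = 0; i < n; ++i) dlog(i, y(i)) -= 1.0;
  dlog /= (double)n;
  gr.wd = cc.ap2.t() * dlog;
  gr.bd = sum(dlog, 0);
  mat dap2 = dlog * net.wd.t();
  mat da3(n, cc.a3.n_cols, fill::zeros);
  maxpool_back(dap2, cc.pc2, da3);
  da3 %= conv_to<mat>::from(cc.a3 > 0);
  mat dz3 = from_act(da3, n, net.l3, 3);
  gr.w3 = cc.g3.t() * dz3;
  gr.b3 = sum(dz3, 0);
  mat dap1(n, cc.ap1.n_cols, fill::zeros);
  col2im(dz3 * net.w3.t(), net.c3, dap1);
  mat da2(n, cc.a2.n_cols, fill::zeros);
  maxpool_back(dap1, cc.pc1, da2);
  da2 %= conv_to<mat>::from(cc.a2 > 0);
  mat dz2 = from_act(da2, n, net.l2, 3);
  gr.w2 = cc.g2.t() * dz2;
  gr.b2 = sum(dz2, 0);
  mat da1(n, cc.a1.n_cols, fill::zeros);
  col2im(dz2 * net.w2.t(), net.c2, da1);
  da1 %= conv_to<mat>::from(cc.a1 > 0);
  mat dz1 = from_act(da1, n, net.l1, 3);
  gr.w1 = cc.g1.t() * dz1;
  gr.b1 = sum(dz1, 0);
}

struct Adam {
  mat mw, vw; double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  void step(mat& w, const mat& g, double lr, double bc1, double bc2) {
    if (mw.n_elem == 0) { mw.zeros(size(w)); vw.zeros(size(w)); }
    mw = b1 * mw + (1 - b1) * g;
    vw = b2 * vw + (1 - b2) * square(g);
    w -= lr * (mw / bc1) / (sqrt(vw / bc2) + eps);
  }
};

Net net_from_r(const Rcpp::List& weights, int input_length, bool same_pad) {
  Net net;
  net.configure(input_length, same_pad);
  net.w1 = Rcpp::as<mat>(weights["w1"]);
  net.w2 = Rcpp::as<mat>(weights["w2"]);
  net.w3 = Rcpp::as<mat>(weights["w3"]);
  net.wd = Rcpp::as<mat>(weights["wd"]);
  net.b1 = Rcpp::as<rowvec>(weights["b1"]);
  net.b2 = Rcpp::as<rowvec>(weights["b2"]);
  net.b3 = Rcpp::as<rowvec>(weights["b3"]);
  net.bd = Rcpp::as<rowvec>(weights["bd"]);
  if ((int)net.wd.n_rows != net.nflat)
    Rcpp::stop("dense weights expect %d inputs but the stack produces %d",
               net.wd.n_rows, net.nflat);
  return net;
}

Rcpp::List weights_to_r(const Net& net) {
  return Rcpp::List::create(
      Rcpp::Named("w1") = net.w1, Rcpp::Named("b1") = net.b1,
      Rcpp::Named("w2") = net.w2, Rcpp::Named("b2") = net.b2,
      Rcpp::Named("w3") = net.w3, Rcpp::Named("b3") = net.b3,
      Rcpp::Named("wd") = net.wd, Rcpp::Named("bd") = net.bd);
}

}  // namespace

// [[Rcpp::export(name = ".cnn_predict")]]
arma::mat cnn_predict_cpp(Rcpp::List weights, arma::mat x, bool same_pad) {
  Net net = net_from_r(weights, x.n_cols, same_pad);
  Cache cc;
  ivec none;
  forward(net, x, none, cc);
  return cc.probs;
}

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, arma::mat x,
                         arma::ivec y,  // 0-based class indices
                         bool same_pad, double learning_rate,
                         double min_delta, int patience, int max_epochs,
                         int batch_size) {
  Net net = net_from_r(weights, x.n_cols, same_pad);
  uword n = x.n_rows;
  Adam aw1, ab1, aw2, ab2, aw3, ab3, awd, abd;
  long step = 0;
  double best_ckpt = datum::inf, best_mon = datum::inf;
  int wait = 0, best_epoch = 0;
  Net best = net;
  std::vector<double> history;
  Cache cc;
  Grads gr;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    Rcpp::IntegerVector perm =
        Rcpp::sample((int)n, (int)n, false);  // R RNG, 1-based
    double total = 0;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop = std::min(n, start + (uword)batch_size);
      uvec take(stop - start);
      for (uword i = start; i < stop; ++i) take(i - start) = perm[i] - 1;
      mat xb = x.rows(take);
      ivec yb = y.elem(take);
      double loss = forward(net, xb, yb, cc);
      backward(net, xb, yb, cc, gr);
      ++step;
      double bc1 = 1 - std::pow(0.9, (double)step);
      double bc2 = 1 - std::pow(0.999, (double)step);
      aw1.step(net.w1, gr.w1, learning_rate, bc1, bc2);
      aw2.step(net.w2, gr.w2, learning_rate, bc1, bc2);
      aw3.step(net.w3, gr.w3, learning_rate, bc1, bc2);
      awd.step(net.wd, gr.wd, learning_rate, bc1, bc2);
      mat t1 = net.b1, t2 = net.b2, t3 = net.b3, td = net.bd;
      ab1.step(t1, mat(gr.b1), learning_rate, bc1, bc2); net.b1 = t1;
      ab2.step(t2, mat(gr.b2), learning_rate, bc1, bc2); net.b2 = t2;
      ab3.step(t3, mat(gr.b3), learning_rate, bc1, bc2); net.b3 = t3;
      abd.step(td, mat(gr.bd), learning_rate, bc1, bc2); net.bd = td;
      total += loss * (stop - start);
    }
    double epoch_loss = total / n;
    history.push_back(epoch_loss);
    if (epoch_loss < best_ckpt) {  // checkpoint on any decrease
      best_ckpt = epoch_loss;
      best_epoch = epoch;
      best = net;
    }
    if (epoch_loss < best_mon - min_delta) {  // early-stopping monitor
      best_mon = epoch_loss;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights_to_r(best),
      Rcpp::Named("history") = history,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_loss") = best_ckpt,
      Rcpp::Named("epochs_run") = (int)history.size());
}
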