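// Minimal convolutional network for single-channel scanpath images:
// n_conv blocks of (3x3 same conv + ReLU + 2x2 max-pool + dropout), then a
// dense ReLU layer with dropout and a sigmoid output unit, trained with
// Adam on binary cross-entropy. All randomness (shuffling, dropout) comes
// from R's RNG so runs are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// im2col for a 3x3 kernel with zero padding 1: (C*9) x (H*W)
static mat im2col3(const cube& in) {
  int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  mat out(C * 9, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& ch = in.slice(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        int krow = c * 9 + (kj + 1) * 3 + (ki + 1);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + ki;
            if (si < 0 || si >= H) continue;
            out(krow, j * H + i) = ch(si, sj);
          }
        }
      }
    }
  }
  return out;
}

// transpose of im2col3: scatter-add columns back into an image cube
static cube col2im3(const mat& cols, int H, int W, int C) {
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& ch = out.slice(c);
    for (int kj = -1; kj <= 1; ++kj) {
      for (int ki = -1; ki <= 1; ++ki) {
        int krow = c * 9 + (kj + 1) * 3 + (ki + 1);
        for (int j = 0; j < W; ++j) {
          int sj = j + kj;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            int si = i + ki;
            if (si < 0 || si >= H) continue;
            ch(si, sj) += cols(krow, j * H + i);
          }
        }
      }
    }
  }
  return out;
}

static cube maxpool2(const cube& in, ucube& arg) {
  int H = in.n_rows / 2, W = in.n_cols / 2, C = in.n_slices;
  cube out(H, W, C);
  arg.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double best = in(2 * i, 2 * j, c);
        unsigned bi = 0;
        for (unsigned k = 1; k < 4; ++k) {
          double v = in(2 * i + (k & 1), 2 * j + (k >> 1), c);
          if (v > best) { best = v; bi = k; }
        }
        out(i, j, c) = best;
        arg(i, j, c) = bi;
      }
  return out;
}

static cube unpool2(const cube& grad, const ucube& arg, int H, int W) {
  int C = grad.n_slices;
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (unsigned j = 0; j < grad.n_cols; ++j)
      for (unsigned i = 0; i < grad.n_rows; ++i) {
        unsigned k = arg(i, j, c);
        out(2 * i + (k & 1), 2 * j + (k >> 1), c) = grad(i, j, c);
      }
  return out;
}

struct Net {
  std::vector<mat> Wc;  // conv weights: F x (C*9)
  std::vector<vec> bc;
  mat W1; vec b1;       // dense hidden
  mat W2; vec b2;       // output (1 x hidden)
};

static Net unpack(const Rcpp::List& weights) {
  Net net;
  Rcpp::List conv = weights["conv"];
  for (int i = 0; i < conv.size(); ++i) {
    Rcpp::List lyr = conv[i];
    net.Wc.push_back(Rcpp::as<mat>(lyr["W"]));
    net.bc.push_back(Rcpp::as<vec>(lyr["b"]));
  }
  net.W1 = Rcpp::as<mat>(weights["W1"]);
  net.b1 = Rcpp::as<vec>(weights["b1"]);
  net.W2 = Rcpp::as<mat>(weights["W2"]);
  net.b2 = Rcpp::as<vec>(weights["b2"]);
  return net;
}

static Rcpp::List pack(const Net& net) {
  Rcpp::List conv(net.Wc.size());
  for (size_t i = 0; i < net.Wc.size(); ++i)
    conv[i] = Rcpp::List::create(Rcpp::Named("W") = net.Wc[i],
                                 Rcpp::Named("b") = net.bc[i]);
  return Rcpp::List::create(Rcpp::Named("conv") = conv,
                            Rcpp::Named("W1") = net.W1,
                            Rcpp::Named("b1") = net.b1,
                            Rcpp::Named("W2") = net.W2,
                            Rcpp::Named("b2") = net.b2);
}

struct FwdState {
  std::vector<cube> act_in;    // input to each conv block
  std::vector<mat> cols;       // im2col of each conv input
  std::vector<cube> pre;       // conv pre-activation
  std::vector<ucube> argmax;
  std::vector<cube> drop_conv; // dropout masks (scaled), empty when off
  vec flat, h_pre, h, drop_fc;
};

static double fwd(const Net& net, const mat& img, FwdState* st,
                  double p_conv, double p_fc, bool train) {
  cube a(img.n_rows, img.n_cols, 1);
  a.slice(0) = img;
  size_t L = net.Wc.size();
  for (size_t l = 0; l < L; ++l) {
    mat cols = im2col3(a);
    mat z = net.Wc[l] * cols;
    z.each_col() += net.bc[l];
    int F = z.n_rows;
    cube zc(a.n_rows, a.n_cols, F);
    for (int f = 0; f < F; ++f)
      zc.slice(f) = reshape(z.row(f), a.n_rows, a.n_cols);
    cube r = clamp(zc, 0.0, datum::inf);
    ucube argm;
    cube p = maxpool2(r, argm);
    cube mask;
    if (train && p_conv > 0) {
      mask.set_size(p.n_rows, p.n_cols, p.n_slices);
      for (uword q = 0; q < mask.n_elem; ++q)
        mask(q) = (R::unif_rand() < p_conv) ? 0.0 : 1.0 / (1.0 - p_conv);
      p %= mask;
    }
    if (st) {
      st->act_in.push_back(a);
      st->cols.push_back(cols);
      st->pre.push_back(zc);
      st->argmax.push_back(argm);
      st->drop_conv.push_back(mask);
    }
    a = p;
  }
  vec flat = vectorise(a);
  vec h_pre = net.W1 * flat + net.b1;
  vec h = clamp(h_pre, 0.0, datum::inf);
  vec dmask;
  if (train && p_fc > 0) {
    dmask.set_size(h.n_elem);
    for (uword q = 0; q < h.n_elem; ++q)
      dmask(q) = (R::unif_rand() < p_fc) ? 0.0 : 1.0 / (1.0 - p_fc);
    h %= dmask;
  }
  double z = dot(net.W2.row(0).t(), h) + net.b2(0);
  double prob = 1.0 / (1.0 + std::exp(-z));
  if (st) {
    st->flat = flat; st->h_pre = h_pre; st->h = h; st->drop_fc = dmask;
  }
  return prob;
}

struct Grads {
  std::vector<mat> dWc; std::vector<vec> dbc;
  mat dW1; vec db1; mat dW2; vec db2;
  void init(const Net& net) {
    dWc.clear(); dbc.clear();
    for (size_t l = 0; l < net.Wc.size(); ++l) {
      dWc.push_back(zeros<mat>(net.Wc[l].n_rows, net.Wc[l].n_cols));
      dbc.push_back(zeros<vec>(net.bc[l].n_elem));
    }
    dW1 = zeros<mat>(net.W1.n_rows, net.W1.n_cols);
    db1 = zeros<vec>(net.b1.n_elem);
    dW2 = zeros<mat>(net.W2.n_rows, net.W2.n_cols);
    db2 = zeros<vec>(1);
  }
};

static void bwd(const Net& net, const FwdState& st, double prob, double y,
                double weight, Grads& g) {
  double dz = (prob - y) * weight;                  // BCE + sigmoid
  g.dW2.row(0) += dz * st.h.t();
  g.db2(0) += dz;
  vec dh = net.W2.row(0).t() * dz;
  if (st.drop_fc.n_elem) dh %= st.drop_fc;
  dh %= conv_to<vec>::from(st.h_pre > 0);
  g.dW1 += dh * st.flat.t();
  g.db1 += dh;
  vec dflat = net.W1.t() * dh;

  size_t L = net.Wc.size();
  // reshape flat gradient to the last pooled cube
  const cube& lastpre = st.pre[L - 1];
  int Hp = lastpre.n_rows / 2, Wp = lastpre.n_cols / 2, F = lastpre.n_slices;
  cube dp(Hp, Wp, F);
  std::copy(dflat.begin(), dflat.end(), dp.begin());
  for (int l = (int)L - 1; l >= 0; --l) {
    if (st.drop_conv[l].n_elem) dp %= st.drop_conv[l];
    cube dr = unpool2(dp, st.argmax[l], st.pre[l].n_rows, st.pre[l].n_cols);
    dr %= conv_to<cube>::from(st.pre[l] > 0);       // ReLU mask
    int Fl = dr.n_slices;
    mat dz_mat(Fl, dr.n_rows * dr.n_cols);
    for (int f = 0; f < Fl; ++f)
      dz_mat.row(f) = vectorise(dr.slice(f)).t();
    g.dWc[l] += dz_mat * st.cols[l].t();
    g.dbc[l] += sum(dz_mat, 1);
    if (l > 0) {
      mat dcols = net.Wc[l].t() * dz_mat;
      cube dx = col2im3(dcols, st.act_in[l].n_rows, st.act_in[l].n_cols,
                        st.act_in[l].n_slices);
      // through previous block's dropout handled at top of loop
      dp = dx;
    }
  }
}

struct Adam {
  std::vector<mat> mWc, vWc; std::vector<vec> mbc, vbc;
  mat mW1, vW1, mW2, vW2; vec mb1, vb1, mb2, vb2;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Net& net) {
    for (size_t l = 0; l < net.Wc.size(); ++l) {
      mWc.push_back(zeros<mat>(size(net.Wc[l])));
      vWc.push_back(zeros<mat>(size(net.Wc[l])));
      mbc.push_back(zeros<vec>(net.bc[l].n_elem));
      vbc.push_back(zeros<vec>(net.bc[l].n_elem));
    }
    mW1 = zeros<mat>(size(net.W1)); vW1 = mW1;
    mW2 = zeros<mat>(size(net.W2)); vW2 = mW2;
    mb1 = zeros<vec>(net.b1.n_elem); vb1 = mb1;
    mb2 = zeros<vec>(1); vb2 = mb2;
  }
  template <class T>
  void upd(T& w, T& m, T& v, const T& gr, double lr) {
    m = b1 * m + (1 - b1) * gr;
    v = b2 * v + (1 - b2) * (gr % gr);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
  void step(Net& net, const Grads& g, double lr) {
    ++t;
    for (size_t l = 0; l < net.Wc.size(); ++l) {
      upd(net.Wc[l], mWc[l], vWc[l], g.dWc[l], lr);
      upd(net.bc[l], mbc[l], vbc[l], g.dbc[l], lr);
    }
    upd(net.W1, mW1, vW1, g.dW1, lr);
    upd(net.b1, mb1, vb1, g.db1, lr);
    upd(net.W2, mW2, vW2, g.dW2, lr);
    upd(net.b2, mb2, vb2, g.db2, lr);
  }
};

static double bce(double p, double y) {
  double eps = 1e-12;
  return -(y * std::log(p + eps) + (1 - y) * std::log(1 - p + eps));
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::cube& X, const arma::vec& y,
                         const arma::cube& Xval, const arma::vec& yval,
                         Rcpp::List weights, int epochs, int batch,
                         double lr, double p_conv, double p_fc,
                         const arma::vec& class_w) {
  Rcpp::RNGScope rng;
  Net net = unpack(weights);
  Adam opt; opt.init(net);
  int n = X.n_slices;
  std::vector<double> tr_loss, va_loss;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch) {
      int end = std::min(n, start + batch);
      Grads g; g.init(net);
      for (int q = start; q < end; ++q) {
        int i = idx[q];
        FwdState st;
        double p = fwd(net, X.slice(i), &st, p_conv, p_fc, true);
        double w = class_w(y(i) > 0.5 ? 1 : 0);
        ep_loss += bce(p, y(i)) * w;
        bwd(net, st, p, y(i), w / (end - start), g);
      }
      opt.step(net, g, lr);
    }
    tr_loss.push_back(ep_loss / n);
    if (Xval.n_slices > 0) {
      double vl = 0.0;
      for (uword i = 0; i < Xval.n_slices; ++i)
        vl += bce(fwd(net, Xval.slice(i), nullptr, 0, 0, false), yval(i));
      va_loss.push_back(vl / Xval.n_slices);
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = pack(net),
      Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("val_loss") = va_loss);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::vec cnn_predict_cpp(const arma::cube& X, Rcpp::List weights) {
  Net net = unpack(weights);
  vec out(X.n_slices);
  for (uword i = 0; i < X.n_slices; ++i)
    out(i) = fwd(net, X.slice(i), nullptr, 0, 0, false);
  return out;
}
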