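// Small LSTM sequence classifier: 1-2 LSTM layers over the epoch's time
// steps, 1-2 fully connected hidden layers (ReLU/ELU), scalar tanh output,
// mean-squared-error loss against labels in {-1, +1}, Adam optimizer,
// optional L1/L2 weight regularization. Full backpropagation through time.
//
// The input projection x*W over all time steps and the weight-gradient
// accumulations are single large GEMMs over cached gate tensors; only the
// recurrent products remain per-step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LstmLayer {
  mat W, U;  // input->gates (in x 4H), recurrent (H x 4H)
  rowvec b;  // gate bias (4H)
};

struct FcLayer {
  mat W;
  rowvec b;
};

struct Net {
  std::vector<LstmLayer> lstm;
  std::vector<FcLayer> fc;   // hidden FC layers
  vec w_out;                 // last hidden -> scalar
  double b_out;
  int activation;            // 0 = ReLU, 1 = ELU
};

mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

mat act_fwd(const mat& x, int a) {
  if (a == 0) return clamp(x, 0.0, datum::inf);
  mat y = x;
  uvec neg = find(x < 0);
  y.elem(neg) = exp(x.elem(neg)) - 1.0;
  return y;
}

mat act_grad(const mat& pre, int a) {
  mat g(size(pre), fill::ones);
  if (a == 0) {
    g.elem(find(pre <= 0)).zeros();
  } else {
    uvec neg = find(pre < 0);
    g.elem(neg) = exp(pre.elem(neg));
  }
  return g;
}

double runif_sym(std::mt19937& rng, double r) {
  std::uniform_real_distribution<double> d(-r, r);
  return d(rng);
}

mat init_mat(int nr, int nc, std::mt19937& rng) {
  double r = std::sqrt(6.0 / (nr + nc));
  mat m(nr, nc);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = runif_sym(rng, r);
  return m;
}

Net build_net(const ivec& lstm_sizes, const ivec& fc_sizes, int n_inputs,
              int activation, std::mt19937& rng) {
  Net net;
  net.activation = activation;
  int in = n_inputs;
  for (uword l = 0; l < lstm_sizes.n_elem; ++l) {
    int H = lstm_sizes(l);
    LstmLayer L;
    L.W = init_mat(in, 4 * H, rng);
    L.U = init_mat(H, 4 * H, rng);
    L.b = rowvec(4 * H, fill::zeros);
    L.b.subvec(H, 2 * H - 1).fill(1.0);  // forget-gate bias init
    net.lstm.push_back(L);
    in = H;
  }
  for (uword l = 0; l < fc_sizes.n_elem; ++l) {
    FcLayer F;
    F.W = init_mat(in, fc_sizes(l), rng);
    F.b = rowvec(fc_sizes(l), fill::zeros);
    net.fc.push_back(F);
    in = fc_sizes(l);
  }
  net.w_out = vec(in);
  double r = std::sqrt(6.0 / (in + 1));
  for (uword i = 0; i < net.w_out.n_elem; ++i) net.w_out(i) = runif_sym(rng, r);
  net.b_out = 0.0;
  return net;
}

// Per-layer training caches, reused across batches of the same size.
// Row blocks of the flat (B*T x .) matrices are grouped by time step.
struct LayerCache {
  mat Xflat;                 // input, (B*T x in)
  mat Gact;                  // post-nonlinearity gates i|f|g|o, (B*T x 4H)
  mat C, TanhC, H;           // cell, tanh(cell), hidden, (B*T x H)
  mat dG;                    // gate gradients, (B*T x 4H)
};

struct Workspace {
  uword B = 0, T = 0;
  std::vector<LayerCache> layer;
  mat z;                           // FC input (B x H_top)
  std::vector<mat> fc_pre, fc_in;  // FC caches (B x .)
};

void ensure_workspace(Workspace& ws, const Net& net, uword B, uword T,
                      uword n_in) {
  if (ws.B == B && ws.T == T) return;
  ws.B = B; ws.T = T;
  ws.layer.assign(net.lstm.size(), LayerCache());
  uword in = n_in;
  for (uword l = 0; l < net.lstm.size(); ++l) {
    uword H = net.lstm[l].U.n_rows;
    LayerCache& c = ws.layer[l];
    c.Xflat.set_size(B * T, in);
    c.Gact.set_size(B * T, 4 * H);
    c.C.set_size(B * T, H);
    c.TanhC.set_size(B * T, H);
    c.H.set_size(B * T, H);
    c.dG.set_size(B * T, 4 * H);
    in = H;
  }
  ws.fc_pre.assign(net.fc.size(), mat());
  ws.fc_in.assign(net.fc.size() + 1, mat());
}

// Forward pass over a batch with full caching; returns tanh outputs.
vec forward_train(const Net& net, const cube& X, const uvec& idx,
                  Workspace& ws) {
  const uword B = idx.n_elem, T = X.n_cols, nl = net.lstm.size();
  ensure_workspace(ws, net, B, T, X.n_slices);
  // gather the batch into the first layer's flat input (time-major blocks)
  mat& X0 = ws.layer[0].Xflat;
  for (uword t = 0; t < T; ++t)
    for (uword ch = 0; ch < X.n_slices; ++ch)
      for (uword b = 0; b < B; ++b)
        X0(t * B + b, ch) = X(idx(b), t, ch);
  for (uword l = 0; l < nl; ++l) {
    const LstmLayer& L = net.lstm[l];
    const uword H = L.U.n_rows;
    LayerCache& c = ws.layer[l];
    mat XW = c.Xflat * L.W;          // input projection, one GEMM
    XW.each_row() += L.b;
    mat h(B, H, fill::zeros), cc(B, H, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      const uword r0 = t * B, r1 = t * B + B - 1;
      mat G = XW.rows(r0, r1) + h * L.U;
      mat gi = sigm(G.cols(0, H - 1));
      mat gf = sigm(G.cols(H, 2 * H - 1));
      mat gg = tanh(G.cols(2 * H, 3 * H - 1));
      mat go = sigm(G.cols(3 * H, 4 * H - 1));
      cc = gf % cc + gi % gg;
      mat tc = tanh(cc);
      h = go % tc;
      c.Gact.submat(r0, 0, r1, H - 1) = gi;
      c.Gact.submat(r0, H, r1, 2 * H - 1) = gf;
      c.Gact.submat(r0, 2 * H, r1, 3 * H - 1) = gg;
      c.Gact.submat(r0, 3 * H, r1, 4 * H - 1) = go;
      c.C.rows(r0, r1) = cc;
      c.TanhC.rows(r0, r1) = tc;
      c.H.rows(r0, r1) = h;
    }
    if (l + 1 < nl) ws.layer[l + 1].Xflat = c.H;
  }
  ws.z = ws.layer[nl - 1].H.rows((T - 1) * B, T * B - 1);
  mat z = ws.z;
  for (uword l = 0; l < net.fc.size(); ++l) {
    ws.fc_in[l] = z;
    mat pre = z * net.fc[l].W;
    pre.each_row() += net.fc[l].b;
    ws.fc_pre[l] = pre;
    z = act_fwd(pre, net.activation);
  }
  ws.fc_in[net.fc.size()] = z;
  return tanh(z * net.w_out + net.b_out);
}

// Light forward pass without caching (prediction).
vec forward_predict(const Net& net, const cube& X) {
  const uword B = X.n_rows, T = X.n_cols, nl = net.lstm.size();
  std::vector<mat> h(nl), c(nl);
  for (uword l = 0; l < nl; ++l) {
    h[l] = mat(B, net.lstm[l].U.n_rows, fill::zeros);
    c[l] = mat(B, net.lstm[l].U.n_rows, fill::zeros);
  }
  mat xt(B, X.n_slices);
  for (uword t = 0; t < T; ++t) {
    for (uword ch = 0; ch < X.n_slices; ++ch)
      for (uword b = 0; b < B; ++b) xt(b, ch) = X(b, t, ch);
    mat inp = xt;
    for (uword l = 0; l < nl; ++l) {
      const LstmLayer& L = net.lstm[l];
      const uword H = L.U.n_rows;
      mat G = inp * L.W + h[l] * L.U;
      G.each_row() += L.b;
      mat gi = sigm(G.cols(0, H - 1));
      mat gf = sigm(G.cols(H, 2 * H - 1));
      mat gg = tanh(G.cols(2 * H, 3 * H - 1));
      mat go = sigm(G.cols(3 * H, 4 * H - 1));
      c[l] = gf % c[l] + gi % gg;
      h[l] = go % tanh(c[l]);
      inp = h[l];
    }
  }
  mat z = h[nl - 1];
  for (uword l = 0; l < net.fc.size(); ++l) {
    mat pre = z * net.fc[l].W;
    pre.each_row() += net.fc[l].b;
    z = act_fwd(pre, net.activation);
  }
  return tanh(z * net.w_out + net.b_out);
}

struct Grads {
  std::vector<LstmLayer> lstm;
  std::vector<FcLayer> fc;
  vec w_out;
  double b_out;
};

Grads zero_like(const Net& net) {
  Grads g;
  for (const auto& L : net.lstm) {
    LstmLayer z;
    z.W = mat(size(L.W), fill::zeros);
    z.U = mat(size(L.U), fill::zeros);
    z.b = rowvec(L.b.n_elem, fill::zeros);
    g.lstm.push_back(z);
  }
  for (const auto& F : net.fc) {
    FcLayer z;
    z.W = mat(size(F.W), fill::zeros);
    z.b = rowvec(F.b.n_elem, fill::zeros);
    g.fc.push_back(z);
  }
  g.w_out = vec(net.w_out.n_elem, fill::zeros);
  g.b_out = 0.0;
  return g;
}

void backward(const Net& net, Workspace& ws, const vec& yhat, const vec& y,
              Grads& g) {
  const uword B = yhat.n_elem, T = ws.T, nl = net.lstm.size();
  vec dout = (2.0 / B) * (yhat - y) % (1.0 - yhat % yhat);
  g.w_out += ws.fc_in[net.fc.size()].t() * dout;
  g.b_out += accu(dout);
  mat dz = dout * net.w_out.t();
  for (int l = (int)net.fc.size() - 1; l >= 0; --l) {
    mat dpre = dz % act_grad(ws.fc_pre[l], net.activation);
    g.fc[l].W += ws.fc_in[l].t() * dpre;
    g.fc[l].b += sum(dpre, 0);
    dz = dpre * net.fc[l].W.t();
  }
  // BPTT layer by layer, top down; dXabove carries the lower layer's
  // incoming gradient across the whole time range
  mat dXabove;  // (B*T x H_below) for the layer below
  for (int l = nl - 1; l >= 0; --l) {
    const LstmLayer& L = net.lstm[l];
    const LayerCache& c = ws.layer[l];
    const uword H = L.U.n_rows;
    mat dh(B, H, fill::zeros), dc(B, H, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      const uword r0 = t * B, r1 = t * B + B - 1;
      mat dh_t = dh;
      if (l == (int)nl - 1 && t == (int)T - 1) dh_t += dz;
      if (l < (int)nl - 1) dh_t += dXabove.rows(r0, r1);
      mat gi = c.Gact.submat(r0, 0, r1, H - 1);
      mat gf = c.Gact.submat(r0, H, r1, 2 * H - 1);
      mat gg = c.Gact.submat(r0, 2 * H, r1, 3 * H - 1);
      mat go = c.Gact.submat(r0, 3 * H, r1, 4 * H - 1);
      mat tc = c.TanhC.rows(r0, r1);
      mat c_prev = (t > 0) ? c.C.rows(r0 - B, r1 - B)
                           : mat(B, H, fill::zeros);
      mat dct = dh_t % go % (1.0 - tc % tc) + dc;
      ws.layer[l].dG.submat(r0, 0, r1, H - 1) =
          dct % gg % gi % (1.0 - gi);
      ws.layer[l].dG.submat(r0, H, r1, 2 * H - 1) =
          dct % c_prev % gf % (1.0 - gf);
      ws.layer[l].dG.submat(r0, 2 * H, r1, 3 * H - 1) =
          dct % gi % (1.0 - gg % gg);
      ws.layer[l].dG.submat(r0, 3 * H, r1, 4 * H - 1) =
          dh_t % tc % go % (1.0 - go);
      dc = dct % gf;
      dh = ws.layer[l].dG.rows(r0, r1) * L.U.t();
    }
    // deferred weight gradients: single GEMMs over the cached tensors
    const mat& dG = ws.layer[l].dG;
    g.lstm[l].W += c.Xflat.t() * dG;
    g.lstm[l].b += sum(dG, 0);
    // h_prev rows: H shifted one step (zeros at t = 0)
    g.lstm[l].U += c.H.rows(0, (T - 1) * B - 1).t() * dG.rows(B, T * B - 1);
    if (l > 0) dXabove = dG * L.W.t();
  }
}

double reg_loss(const Net& net, int type, double lam) {
  if (type == 0 || lam == 0.0) return 0.0;
  double s = 0.0;
  auto add = [&](const mat& M) {
    s += (type == 1) ? accu(abs(M)) : accu(M % M);
  };
  for (const auto& L : net.lstm) { add(L.W); add(L.U); }
  for (const auto& F : net.fc) add(F.W);
  add(net.w_out);
  return lam * s;
}

void add_reg_grad(const Net& net, Grads& g, int type, double lam) {
  if (type == 0 || lam == 0.0) return;
  auto add = [&](const mat& M, mat& G) {
    if (type == 1) G += lam * sign(M); else G += 2.0 * lam * M;
  };
  for (uword l = 0; l < net.lstm.size(); ++l) {
    add(net.lstm[l].W, g.lstm[l].W);
    add(net.lstm[l].U, g.lstm[l].U);
  }
  for (uword l = 0; l < net.fc.size(); ++l) add(net.fc[l].W, g.fc[l].W);
  if (type == 1) g.w_out += lam * sign(net.w_out);
  else g.w_out += 2.0 * lam * net.w_out;
}

struct Adam {
  Grads m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
};

template <typename T>
void adam_update(T& w, T& gm, T& m, T& v, double lr, const Adam& a) {
  m = a.b1 * m + (1 - a.b1) * gm;
  v = a.b2 * v + (1 - a.b2) * (gm % gm);
  double c1 = 1 - std::pow(a.b1, a.step), c2 = 1 - std::pow(a.b2, a.step);
  w -= lr * (m / c1) / (sqrt(v / c2) + a.eps);
}

double grad_norm(const Grads& g) {
  double s = g.b_out * g.b_out + accu(g.w_out % g.w_out);
  for (const auto& L : g.lstm)
    s += accu(L.W % L.W) + accu(L.U % L.U) + accu(L.b % L.b);
  for (const auto& F : g.fc) s += accu(F.W % F.W) + accu(F.b % F.b);
  return std::sqrt(s);
}

void scale_grads(Grads& g, double f) {
  g.b_out *= f; g.w_out *= f;
  for (auto& L : g.lstm) { L.W *= f; L.U *= f; L.b *= f; }
  for (auto& F : g.fc) { F.W *= f; F.b *= f; }
}

double weight_l2(const Net& net) {
  double s = accu(net.w_out % net.w_out);
  for (const auto& L : net.lstm) s += accu(L.W % L.W) + accu(L.U % L.U);
  for (const auto& F : net.fc) s += accu(F.W % F.W);
  return std::sqrt(s);
}

Rcpp::List net_to_list(const Net& net) {
  Rcpp::List lstm, fc;
  for (const auto& L : net.lstm)
    lstm.push_back(Rcpp::List::create(
        Rcpp::Named("W") = L.W, Rcpp::Named("U") = L.U,
        Rcpp::Named("b") = L.b));
  for (const auto& F : net.fc)
    fc.push_back(Rcpp::List::create(
        Rcpp::Named("W") = F.W, Rcpp::Named("b") = F.b));
  return Rcpp::List::create(
      Rcpp::Named("lstm") = lstm, Rcpp::Named("fc") = fc,
      Rcpp::Named("w_out") = net.w_out, Rcpp::Named("b_out") = net.b_out,
      Rcpp::Named("activation") = net.activation);
}

Net net_from_list(const Rcpp::List& x) {
  Net net;
  net.activation = Rcpp::as<int>(x["activation"]);
  Rcpp::List lstm = x["lstm"], fc = x["fc"];
  for (int l = 0; l < lstm.size(); ++l) {
    Rcpp::List L = lstm[l];
    LstmLayer la;
    la.W = Rcpp::as<mat>(L["W"]);
    la.U = Rcpp::as<mat>(L["U"]);
    la.b = Rcpp::as<rowvec>(L["b"]);
    net.lstm.push_back(la);
  }
  for (int l = 0; l < fc.size(); ++l) {
    Rcpp::List F = fc[l];
    FcLayer fa;
    fa.W = Rcpp::as<mat>(F["W"]);
    fa.b = Rcpp::as<rowvec>(F["b"]);
    net.fc.push_back(fa);
  }
  net.w_out = Rcpp::as<vec>(x["w_out"]);
  net.b_out = Rcpp::as<double>(x["b_out"]);
  return net;
}

}  // namespace

// [[Rcpp::export(name = ".lstm_train_cpp")]]
Rcpp::List lstm_train_cpp(const arma::cube& X, const arma::vec& y,
                          const arma::ivec& lstm_sizes,
                          const arma::ivec& fc_sizes, int activation,
                          int reg_type, double reg_lambda, double lr,
                          int n_iter, int batch_size, int seed,
                          double clip_norm = 5.0) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  Net net = build_net(lstm_sizes, fc_sizes, X.n_slices, activation, rng);
  Adam ad;
  ad.m = zero_like(net); ad.v = zero_like(net);
  Workspace ws, ws_tail;   // full batches and the possible remainder batch
  const uword N = X.n_rows;
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;
  std::vector<double> iter_loss;
  for (int it = 0; it < n_iter; ++it) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    int n_batches = 0;
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, N);
      uvec idx(stop - start);
      for (uword i = start; i < stop; ++i) idx(i - start) = order[i];
      Workspace& w = (idx.n_elem == (uword)batch_size) ? ws : ws_tail;
      vec yhat = forward_train(net, X, idx, w);
      vec yb = y.elem(idx);
      loss_sum += mean(square(yhat - yb)) + reg_loss(net, reg_type, reg_lambda);
      ++n_batches;
      Grads g = zero_like(net);
      backward(net, w, yhat, yb, g);
      add_reg_grad(net, g, reg_type, reg_lambda);
      double gn = grad_norm(g);
      if (clip_norm > 0 && gn > clip_norm) scale_grads(g, clip_norm / gn);
      ++ad.step;
      for (uword l = 0; l < net.lstm.size(); ++l) {
        adam_update(net.lstm[l].W, g.lstm[l].W, ad.m.lstm[l].W,
                    ad.v.lstm[l].W, lr, ad);
        adam_update(net.lstm[l].U, g.lstm[l].U, ad.m.lstm[l].U,
                    ad.v.lstm[l].U, lr, ad);
        adam_update(net.lstm[l].b, g.lstm[l].b, ad.m.lstm[l].b,
                    ad.v.lstm[l].b, lr, ad);
      }
      for (uword l = 0; l < net.fc.size(); ++l) {
        adam_update(net.fc[l].W, g.fc[l].W, ad.m.fc[l].W, ad.v.fc[l].W,
                    lr, ad);
        adam_update(net.fc[l].b, g.fc[l].b, ad.m.fc[l].b, ad.v.fc[l].b,
                    lr, ad);
      }
      adam_update(net.w_out, g.w_out, ad.m.w_out, ad.v.w_out, lr, ad);
      {
        ad.m.b_out = ad.b1 * ad.m.b_out + (1 - ad.b1) * g.b_out;
        ad.v.b_out = ad.b2 * ad.v.b_out + (1 - ad.b2) * g.b_out * g.b_out;
        double c1 = 1 - std::pow(ad.b1, ad.step),
               c2 = 1 - std::pow(ad.b2, ad.step);
        net.b_out -= lr * (ad.m.b_out / c1) /
                     (std::sqrt(ad.v.b_out / c2) + ad.eps);
      }
    }
    iter_loss.push_back(loss_sum / n_batches);
  }
  return Rcpp::List::create(
      Rcpp::Named("net") = net_to_list(net),
      Rcpp::Named("iter_loss") = iter_loss,
      Rcpp::Named("weight_l2") = weight_l2(net));
}

// [[Rcpp::export(name = ".lstm_predict_cpp")]]
arma::vec lstm_predict_cpp(const Rcpp::List& net_list, const arma::cube& X) {
  return forward_predict(net_from_list(net_list), X);
}
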