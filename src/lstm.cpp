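// Character-level LSTM over amino-acid tokens: stacked layers, inverted
// dropout between layers, softmax output, Adam with global-norm clipping,
// full BPTT. All randomness (init, shuffling, dropout, sampling) draws from
// the R RNG so results are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double PROB_FLOOR = 1e-12;

struct Net {
  int L, H, D;                 // layers, hidden units, vocab size
  std::vector<mat> W, U;       // per layer: 4H x Din, 4H x H
  std::vector<vec> b;          // per layer: 4H
  mat V;                       // D x H output projection
  vec c;                       // D output bias
};

static Net net_from_list(const List &params) {
  Net nn;
  nn.L = as<int>(params["layers"]);
  nn.H = as<int>(params["hidden"]);
  nn.D = as<int>(params["vocab"]);
  List Wl = params["W"], Ul = params["U"], bl = params["b"];
  for (int l = 0; l < nn.L; ++l) {
    nn.W.push_back(as<mat>(Wl[l]));
    nn.U.push_back(as<mat>(Ul[l]));
    nn.b.push_back(as<vec>(bl[l]));
  }
  nn.V = as<mat>(params["V"]);
  nn.c = as<vec>(params["c"]);
  return nn;
}

static List net_to_list(const Net &nn) {
  List Wl(nn.L), Ul(nn.L), bl(nn.L);
  for (int l = 0; l < nn.L; ++l) {
    Wl[l] = nn.W[l]; Ul[l] = nn.U[l]; bl[l] = nn.b[l];
  }
  return List::create(_["layers"] = nn.L, _["hidden"] = nn.H,
                      _["vocab"] = nn.D, _["W"] = Wl, _["U"] = Ul,
                      _["b"] = bl, _["V"] = nn.V, _["c"] = nn.c);
}

// [[Rcpp::export]]
List cpp_lstm_init(int layers, int hidden, int vocab, double scale) {
  Net nn; nn.L = layers; nn.H = hidden; nn.D = vocab;
  for (int l = 0; l < layers; ++l) {
    int din = (l == 0) ? vocab : hidden;
    mat W(4 * hidden, din), U(4 * hidden, hidden);
    vec b(4 * hidden, fill::zeros);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = R::runif(-scale, scale);
    for (uword i = 0; i < U.n_elem; ++i) U(i) = R::runif(-scale, scale);
    // forget-gate bias starts at 1 to keep early memory open
    b.subvec(hidden, 2 * hidden - 1).fill(1.0);
    nn.W.push_back(W); nn.U.push_back(U); nn.b.push_back(b);
  }
  nn.V.set_size(vocab, hidden);
  for (uword i = 0; i < nn.V.n_elem; ++i) nn.V(i) = R::runif(-scale, scale);
  nn.c = vec(vocab, fill::zeros);
  return net_to_list(nn);
}

static inline mat sigm(const mat &x) { return 1.0 / (1.0 + exp(-x)); }

// softmax over columns
static mat softmax_cols(mat z) {
  z.each_row() -= max(z, 0);
  z = exp(z);
  z.each_row() /= sum(z, 0);
  return z;
}

// Forward pass without caches; accumulates per-sequence NLL.
// tokens: B columns of a (Tmax x n) token matrix subset; 0 = pad.
static vec forward_nll(const Net &nn, const imat &toks,
                       const ivec &lens, bool include_end) {
  const int B = toks.n_cols, H = nn.H;
  const int end_tok = nn.D - 1;  // pad = D, end = D-1, start = D-2
  const int Tmax = max(lens);
  std::vector<mat> h(nn.L, mat(H, B, fill::zeros));
  std::vector<mat> cst(nn.L, mat(H, B, fill::zeros));
  vec nll(B, fill::zeros);
  for (int t = 0; t < Tmax - 1; ++t) {
    mat x(nn.D, B, fill::zeros);
    for (int s = 0; s < B; ++s)
      if (t < lens[s]) x(toks(t, s) - 1, s) = 1.0;
    mat inp = x;
    for (int l = 0; l < nn.L; ++l) {
      mat z = nn.W[l] * inp + nn.U[l] * h[l];
      z.each_col() += nn.b[l];
      mat ig = sigm(z.rows(0, H - 1));
      mat fg = sigm(z.rows(H, 2 * H - 1));
      mat gg = tanh(z.rows(2 * H, 3 * H - 1));
      mat og = sigm(z.rows(3 * H, 4 * H - 1));
      cst[l] = fg % cst[l] + ig % gg;
      h[l] = og % tanh(cst[l]);
      inp = h[l];
    }
    mat logits = nn.V * inp;
    logits.each_col() += nn.c;
    mat p = softmax_cols(logits);
    for (int s = 0; s < B; ++s) {
      if (t + 1 >= lens[s]) continue;
      int tgt = toks(t + 1, s);
      if (!include_end && tgt == end_tok) continue;
      nll[s] += -std::log(std::max(p(tgt - 1, s), PROB_FLOOR));
    }
  }
  return nll;
}

// [[Rcpp::export]]
NumericVector cpp_lstm_nll(List params, IntegerMatrix tokens,
                           IntegerVector lengths, bool include_end,
                           int batch = 128) {
  Net nn = net_from_list(params);
  const int n = tokens.ncol();
  NumericVector out(n);
  for (int off = 0; off < n; off += batch) {
    int B = std::min(batch, n - off);
    ivec lens(B);
    for (int s = 0; s < B; ++s) lens[s] = lengths[off + s];
    imat toks(tokens.nrow(), B);
    for (int s = 0; s < B; ++s)
      for (int t = 0; t < tokens.nrow(); ++t) toks(t, s) = tokens(t, off + s);
    vec nll = forward_nll(nn, toks, lens, include_end);
    for (int s = 0; s < B; ++s) out[off + s] = nll[s];
  }
  return out;
}

struct Adam {
  std::vector<mat> mW, vW, mU, vU;
  std::vector<vec> mb, vb;
  mat mV, vV; vec mc, vc;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  explicit Adam(const Net &nn) {
    for (int l = 0; l < nn.L; ++l) {
      mW.push_back(zeros<mat>(size(nn.W[l]))); vW.push_back(zeros<mat>(size(nn.W[l])));
      mU.push_back(zeros<mat>(size(nn.U[l]))); vU.push_back(zeros<mat>(size(nn.U[l])));
      mb.push_back(zeros<vec>(nn.b[l].n_elem)); vb.push_back(zeros<vec>(nn.b[l].n_elem));
    }
    mV = zeros<mat>(size(nn.V)); vV = zeros<mat>(size(nn.V));
    mc = zeros<vec>(nn.c.n_elem); vc = zeros<vec>(nn.c.n_elem);
  }
  template <class T>
  void upd1(T &p, T &g, T &m, T &v, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    double bc1 = 1 - std::pow(b1, (double)step);
    double bc2 = 1 - std::pow(b2, (double)step);
    p -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
  }
};

struct Grads {
  std::vector<mat> W, U; std::vector<vec> b; mat V; vec c;
  explicit Grads(const Net &nn) {
    for (int l = 0; l < nn.L; ++l) {
      W.push_back(zeros<mat>(size(nn.W[l])));
      U.push_back(zeros<mat>(size(nn.U[l])));
      b.push_back(zeros<vec>(nn.b[l].n_elem));
    }
    V = zeros<mat>(size(nn.V)); c = zeros<vec>(nn.c.n_elem);
  }
  double sqnorm() const {
    double s = accu(V % V) + accu(c % c);
    for (size_t l = 0; l < W.size(); ++l)
      s += accu(W[l] % W[l]) + accu(U[l] % U[l]) + accu(b[l] % b[l]);
    return s;
  }
  void scale(double k) {
    V *= k; c *= k;
    for (size_t l = 0; l < W.size(); ++l) { W[l] *= k; U[l] *= k; b[l] *= k; }
  }
};

// One minibatch: forward with caches, weighted cross-entropy, BPTT.
// Returns summed weighted loss over target tokens; wsum accumulates weights.
static double train_batch(Net &nn, Adam &opt, const imat &toks,
                          const ivec &lens, const vec &w, double lr,
                          double dropout, double clip, double wd,
                          double &wsum_out) {
  const int B = toks.n_cols, H = nn.H, L = nn.L;
  const int Tmax = max(lens);
  const int steps = Tmax - 1;
  // caches [t][l]
  std::vector<std::vector<mat>> ig(steps, std::vector<mat>(L)),
      fg(steps, std::vector<mat>(L)), gg(steps, std::vector<mat>(L)),
      og(steps, std::vector<mat>(L)), cs(steps, std::vector<mat>(L)),
      hs(steps, std::vector<mat>(L)), hd(steps, std::vector<mat>(L)),
      msk(steps, std::vector<mat>(L)), xin(steps, std::vector<mat>(L));
  std::vector<mat> dlogits(steps);
  std::vector<mat> h(L, mat(H, B, fill::zeros)), cst(L, mat(H, B, fill::zeros));
  double loss = 0.0, wsum = 0.0;

  for (int t = 0; t < steps; ++t) {
    mat x(nn.D, B, fill::zeros);
    for (int s = 0; s < B; ++s)
      if (t < lens[s]) x(toks(t, s) - 1, s) = 1.0;
    mat inp = x;
    for (int l = 0; l < L; ++l) {
      xin[t][l] = inp;
      mat z = nn.W[l] * inp + nn.U[l] * h[l];
      z.each_col() += nn.b[l];
      ig[t][l] = sigm(z.rows(0, H - 1));
      fg[t][l] = sigm(z.rows(H, 2 * H - 1));
      gg[t][l] = tanh(z.rows(2 * H, 3 * H - 1));
      og[t][l] = sigm(z.rows(3 * H, 4 * H - 1));
      mat cprev = cst[l];
      cst[l] = fg[t][l] % cprev + ig[t][l] % gg[t][l];
      cs[t][l] = cst[l];
      h[l] = og[t][l] % tanh(cst[l]);
      hs[t][l] = h[l];
      if (dropout > 0) {
        mat m(H, B);
        for (uword i = 0; i < m.n_elem; ++i)
          m(i) = (R::unif_rand() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
        msk[t][l] = m;
        hd[t][l] = h[l] % m;
      } else {
        hd[t][l] = h[l];
      }
      inp = hd[t][l];
    }
    mat logits = nn.V * hd[t][L - 1];
    logits.each_col() += nn.c;
    mat p = softmax_cols(logits);
    mat dl(nn.D, B, fill::zeros);
    for (int s = 0; s < B; ++s) {
      if (t + 1 >= lens[s]) continue;
      int tgt = toks(t + 1, s) - 1;
      loss += -w[s] * std::log(std::max(p(tgt, s), PROB_FLOOR));
      wsum += w[s];
      dl.col(s) = w[s] * p.col(s);
      dl(tgt, s) -= w[s];
    }
    dlogits[t] = dl;
  }
  if (wsum <= 0) { wsum_out += 0; return 0.0; }

  Grads g(nn);
  std::vector<mat> dh_next(L, mat(H, B, fill::zeros)),
      dc_next(L, mat(H, B, fill::zeros));
  for (int t = steps - 1; t >= 0; --t) {
    mat dl = dlogits[t] / wsum;
    g.V += dl * hd[t][L - 1].t();
    g.c += sum(dl, 1);
    mat dtop = nn.V.t() * dl;  // grad wrt dropped h of top layer
    std::vector<mat> dh(L);
    for (int l = 0; l < L; ++l) dh[l] = dh_next[l];
    if (dropout > 0) dtop %= msk[t][L - 1];
    dh[L - 1] += dtop;
    for (int l = L - 1; l >= 0; --l) {
      mat tc = tanh(cs[t][l]);
      mat do_ = dh[l] % tc;
      mat dco = dc_next[l] + dh[l] % og[t][l] % (1.0 - tc % tc);
      mat di = dco % gg[t][l];
      mat dgg = dco % ig[t][l];
      mat cprev = (t > 0) ? cs[t - 1][l] : mat(H, B, fill::zeros);
      mat df = dco % cprev;
      dc_next[l] = dco % fg[t][l];
      mat dzi = di % ig[t][l] % (1.0 - ig[t][l]);
      mat dzf = df % fg[t][l] % (1.0 - fg[t][l]);
      mat dzg = dgg % (1.0 - gg[t][l] % gg[t][l]);
      mat dzo = do_ % og[t][l] % (1.0 - og[t][l]);
      mat dz = join_cols(join_cols(dzi, dzf), join_cols(dzg, dzo));
      g.W[l] += dz * xin[t][l].t();
      mat hprev = (t > 0) ? hs[t - 1][l] : mat(H, B, fill::zeros);
      g.U[l] += dz * hprev.t();
      g.b[l] += sum(dz, 1);
      dh_next[l] = nn.U[l].t() * dz;
      if (l > 0) {
        mat dx = nn.W[l].t() * dz;  // grad wrt dropped h of layer below
        if (dropout > 0) dx %= msk[t][l - 1];
        dh[l - 1] += dx;
      }
    }
  }
  double nrm = std::sqrt(g.sqnorm());
  if (clip > 0 && nrm > clip) g.scale(clip / nrm);
  opt.step += 1;
  for (int l = 0; l < L; ++l) {
    opt.upd1(nn.W[l], g.W[l], opt.mW[l], opt.vW[l], lr);
    opt.upd1(nn.U[l], g.U[l], opt.mU[l], opt.vU[l], lr);
    opt.upd1(nn.b[l], g.b[l], opt.mb[l], opt.vb[l], lr);
  }
  opt.upd1(nn.V, g.V, opt.mV, opt.vV, lr);
  opt.upd1(nn.c, g.c, opt.mc, opt.vc, lr);
  if (wd > 0) {  // decoupled weight decay on the weight matrices only
    for (int l = 0; l < L; ++l) {
      nn.W[l] *= (1.0 - lr * wd);
      nn.U[l] *= (1.0 - lr * wd);
    }
    nn.V *= (1.0 - lr * wd);
  }
  wsum_out += wsum;
  return loss;
}

// Fisher-Yates permutation using the R RNG (0-based indices)
static std::vector<int> r_permutation(int n) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

// [[Rcpp::export]]
List cpp_lstm_train(List params, IntegerMatrix tokens, IntegerVector lengths,
                    NumericVector weights, IntegerVector train_idx,
                    IntegerVector val_idx, int epochs, int batch, double lr,
                    double dropout, double clip, double weight_decay,
                    double ema_decay, bool lr_cosine) {
  Net nn = net_from_list(params);
  Adam opt(nn);
  Net ema = nn;
  const bool use_ema = ema_decay > 0 && ema_decay < 1;
  long ema_steps = 0;
  if (use_ema) {  // zero-init with bias correction at read-out
    for (int l = 0; l < nn.L; ++l) {
      ema.W[l].zeros(); ema.U[l].zeros(); ema.b[l].zeros();
    }
    ema.V.zeros(); ema.c.zeros();
  }
  auto ema_view = [&]() {
    Net out = ema;
    double corr = 1.0 - std::pow(ema_decay, (double)ema_steps);
    if (corr <= 0) return nn;
    for (int l = 0; l < out.L; ++l) {
      out.W[l] /= corr; out.U[l] /= corr; out.b[l] /= corr;
    }
    out.V /= corr; out.c /= corr;
    return out;
  };
  const int ntr = train_idx.size(), nval = val_idx.size();
  NumericVector train_loss(epochs), val_loss(epochs);
  imat all_toks(tokens.nrow(), tokens.ncol());
  for (int s = 0; s < tokens.ncol(); ++s)
    for (int t = 0; t < tokens.nrow(); ++t) all_toks(t, s) = tokens(t, s);

  for (int ep = 0; ep < epochs; ++ep) {
    double lr_ep = lr;
    if (lr_cosine && epochs > 1)
      lr_ep = lr * 0.5 * (1.0 + std::cos(M_PI * ep / (epochs - 1.0)));
    std::vector<int> perm = r_permutation(ntr);
    double lsum = 0.0, wsum = 0.0;
    for (int off = 0; off < ntr; off += batch) {
      int B = std::min(batch, ntr - off);
      ivec lens(B); vec w(B);
      int Tb = 0;
      for (int s = 0; s < B; ++s) {
        int gi = train_idx[perm[off + s]] - 1;
        lens[s] = lengths[gi];
        w[s] = weights[gi];
        Tb = std::max(Tb, (int)lens[s]);
      }
      imat toks(Tb, B);
      for (int s = 0; s < B; ++s) {
        int gi = train_idx[perm[off + s]] - 1;
        for (int t = 0; t < Tb; ++t)
          toks(t, s) = (t < tokens.nrow()) ? all_toks(t, gi) : 0;
      }
      lsum += train_batch(nn, opt, toks, lens, w, lr_ep, dropout, clip,
                          weight_decay, wsum);
      if (use_ema) {  // Polyak average of the weights
        for (int l = 0; l < nn.L; ++l) {
          ema.W[l] = ema_decay * ema.W[l] + (1 - ema_decay) * nn.W[l];
          ema.U[l] = ema_decay * ema.U[l] + (1 - ema_decay) * nn.U[l];
          ema.b[l] = ema_decay * ema.b[l] + (1 - ema_decay) * nn.b[l];
        }
        ema.V = ema_decay * ema.V + (1 - ema_decay) * nn.V;
        ema.c = ema_decay * ema.c + (1 - ema_decay) * nn.c;
        ema_steps += 1;
      }
    }
    train_loss[ep] = (wsum > 0) ? lsum / wsum : NA_REAL;
    if (nval > 0) {
      const Net evn = use_ema ? ema_view() : nn;
      double vs = 0.0, vw = 0.0;
      for (int off = 0; off < nval; off += 128) {
        int B = std::min(128, nval - off);
        ivec lens(B); vec w(B);
        for (int s = 0; s < B; ++s) {
          int gi = val_idx[off + s] - 1;
          lens[s] = lengths[gi]; w[s] = weights[gi];
        }
        imat toks(tokens.nrow(), B);
        for (int s = 0; s < B; ++s) {
          int gi = val_idx[off + s] - 1;
          for (int t = 0; t < tokens.nrow(); ++t) toks(t, s) = all_toks(t, gi);
        }
        vec nl = forward_nll(evn, toks, lens, true);
        for (int s = 0; s < B; ++s) {
          vs += w[s] * nl[s];
          vw += w[s] * (lens[s] - 1);
        }
      }
      val_loss[ep] = (vw > 0) ? vs / vw : NA_REAL;
    } else {
      val_loss[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = net_to_list(use_ema ? ema_view() : nn),
                      _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss);
}

// Autoregressive sampling. Returns residue tokens (1..20 expected), 0-padded;
// a row ends when the end token was emitted or max_steps was reached.
// start/pad tokens are excluded from the proposal distribution.
// [[Rcpp::export]]
IntegerMatrix cpp_lstm_sample(List params, int n, double temperature,
                              int max_steps) {
  Net nn = net_from_list(params);
  const int H = nn.H, L = nn.L;
  const int start_tok = nn.D - 2, end_tok = nn.D - 1, pad_tok = nn.D;
  IntegerMatrix out(n, max_steps);
  std::fill(out.begin(), out.end(), 0);
  for (int s = 0; s < n; ++s) {
    std::vector<vec> h(L, vec(H, fill::zeros)), cst(L, vec(H, fill::zeros));
    int tok = start_tok;
    for (int step = 0; step < max_steps; ++step) {
      vec x(nn.D, fill::zeros);
      x[tok - 1] = 1.0;
      vec inp = x;
      for (int l = 0; l < L; ++l) {
        vec z = nn.W[l] * inp + nn.U[l] * h[l] + nn.b[l];
        vec ig = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
        vec fg = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
        vec gg = tanh(z.subvec(2 * H, 3 * H - 1));
        vec og = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
        cst[l] = fg % cst[l] + ig % gg;
        h[l] = og % tanh(cst[l]);
        inp = h[l];
      }
      vec logits = nn.V * inp + nn.c;
      logits[start_tok - 1] = -1e30;
      logits[pad_tok - 1] = -1e30;
      int next;
      if (temperature <= 1e-8) {
        next = (int)logits.index_max() + 1;
      } else {
        vec z = logits / temperature;
        z -= z.max();
        vec p = exp(z);
        p /= accu(p);
        double u = R::unif_rand(), acc = 0.0;
        next = nn.D - 1;
        for (int k = 0; k < nn.D; ++k) {
          acc += p[k];
          if (u <= acc) { next = k + 1; break; }
        }
      }
      if (next == end_tok) break;
      out(s, step) = next;
      tok = next;
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
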