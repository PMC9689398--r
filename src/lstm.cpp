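// LSTM forecaster: forward pass, truncated BPTT over fixed-length windows,
// minibatch SGD with momentum and global-norm gradient clipping.
//
// Cell equations (scalar input x_t, hidden state y_t, cell state C_t):
//   i_t = sigmoid(x_t U^i + y_{t-1} W^i + b^i)
//   f_t = sigmoid(x_t U^f + y_{t-1} W^f + b^f)
//   g_t = tanh   (x_t U^g + y_{t-1} W^g + b^g)     (candidate cell state)
//   o_t = sigmoid(x_t U^o + y_{t-1} W^o + b^o)
//   C_t = f_t . C_{t-1} + i_t . g_t
//   y_t = o_t . tanh(C_t)
// The last hidden state feeds a stack of linear dense layers ending in a
// single output unit. Gate blocks are stored concatenated as [i | f | g | o].
//
// All randomness (init, shuffling, dropout) comes from a xorshift64* stream
// seeded from R, so training is bit-reproducible for a given seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    double u1 = std::max(unif(), 1e-300), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
};

struct Params {
  rowvec U;                 // 1 x 4H
  mat W;                    // H x 4H
  rowvec b;                 // 4H
  std::vector<mat> dW;      // dense weights
  std::vector<rowvec> db;   // dense biases
  int H;

  Params scaled_zero() const {
    Params z = *this;
    z.U.zeros(); z.W.zeros(); z.b.zeros();
    for (auto& m : z.dW) m.zeros();
    for (auto& v : z.db) v.zeros();
    return z;
  }
};

Params params_from_list(const List& lst) {
  Params p;
  p.U = as<rowvec>(lst["U"]);
  p.W = as<mat>(lst["W"]);
  p.b = as<rowvec>(lst["b"]);
  p.H = p.W.n_rows;
  List dW = lst["dense_W"], db = lst["dense_b"];
  for (int k = 0; k < dW.size(); ++k) {
    p.dW.push_back(as<mat>(dW[k]));
    p.db.push_back(as<rowvec>(db[k]));
  }
  return p;
}

List params_to_list(const Params& p) {
  List dW(p.dW.size()), db(p.db.size());
  for (size_t k = 0; k < p.dW.size(); ++k) {
    dW[k] = wrap(p.dW[k]);
    db[k] = wrap(p.db[k]);
  }
  return List::create(_["U"] = wrap(p.U), _["W"] = wrap(p.W),
                      _["b"] = wrap(p.b), _["dense_W"] = dW,
                      _["dense_b"] = db);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// Forward over a batch of windows X (B x L); optionally cache activations
// for backprop and apply a dropout mask (B x H, already inverted-scaled)
// to the final hidden state.
struct Cache {
  arma::cube I, F, G, O, TanhC, Cprev, Yprev; // each B x H x L
  mat h;                    // final hidden state, pre-dropout
  mat hd;                   // post-dropout
  std::vector<mat> z;       // dense activations (z[0] = hd)
};

vec forward(const Params& p, const mat& X, Cache* cache, const mat* dropmask) {
  const int B = X.n_rows, L = X.n_cols, H = p.H;
  mat Y(B, H, arma::fill::zeros), C(B, H, arma::fill::zeros);
  if (cache) {
    cache->I.set_size(B, H, L); cache->F.set_size(B, H, L);
    cache->G.set_size(B, H, L); cache->O.set_size(B, H, L);
    cache->TanhC.set_size(B, H, L); cache->Cprev.set_size(B, H, L);
    cache->Yprev.set_size(B, H, L);
  }
  for (int t = 0; t < L; ++t) {
    mat a = X.col(t) * p.U + Y * p.W;           // B x 4H
    a.each_row() += p.b;
    mat i = sigmoid(a.cols(0, H - 1));
    mat f = sigmoid(a.cols(H, 2 * H - 1));
    mat g = arma::tanh(a.cols(2 * H, 3 * H - 1));
    mat o = sigmoid(a.cols(3 * H, 4 * H - 1));
    if (cache) {
      cache->Cprev.slice(t) = C;
      cache->Yprev.slice(t) = Y;
    }
    C = f % C + i % g;
    mat tc = arma::tanh(C);
    Y = o % tc;
    if (cache) {
      cache->I.slice(t) = i; cache->F.slice(t) = f;
      cache->G.slice(t) = g; cache->O.slice(t) = o;
      cache->TanhC.slice(t) = tc;
    }
  }
  mat h = Y;
  mat hd = (dropmask != nullptr) ? mat(h % (*dropmask)) : h;
  if (cache) { cache->h = h; cache->hd = hd; cache->z.clear(); }
  mat z = hd;
  if (cache) cache->z.push_back(z);
  for (size_t k = 0; k < p.dW.size(); ++k) {
    z = z * p.dW[k];
    z.each_row() += p.db[k];
    if (cache) cache->z.push_back(z);
  }
  return z.col(0);
}

// Backprop the mean-squared-error loss; returns gradients in `grad`.
void backward(const Params& p, const mat& X, const vec& y, const Cache& cc,
              const mat* dropmask, Params& grad) {
  const int B = X.n_rows, L = X.n_cols, H = p.H;
  vec pred = cc.z.back().col(0);
  mat dz = mat(2.0 * (pred - y) / (double)B); // B x 1
  for (int k = (int)p.dW.size() - 1; k >= 0; --k) {
    grad.dW[k] = cc.z[k].t() * dz;
    grad.db[k] = arma::sum(dz, 0);
    dz = dz * p.dW[k].t();
  }
  mat dY = (dropmask != nullptr) ? mat(dz % (*dropmask)) : dz; // B x H
  mat dC(B, H, arma::fill::zeros);
  for (int t = L - 1; t >= 0; --t) {
    const mat& i = cc.I.slice(t); const mat& f = cc.F.slice(t);
    const mat& g = cc.G.slice(t); const mat& o = cc.O.slice(t);
    const mat& tc = cc.TanhC.slice(t);
    const mat& Cp = cc.Cprev.slice(t); const mat& Yp = cc.Yprev.slice(t);
    mat da_o = (dY % tc) % (o % (1.0 - o));
    dC += dY % o % (1.0 - tc % tc);
    mat da_i = (dC % g) % (i % (1.0 - i));
    mat da_g = (dC % i) % (1.0 - g % g);
    mat da_f = (dC % Cp) % (f % (1.0 - f));
    mat da = arma::join_rows(arma::join_rows(da_i, da_f),
                             arma::join_rows(da_g, da_o)); // B x 4H
    grad.U += X.col(t).t() * da;
    grad.W += Yp.t() * da;
    grad.b += arma::sum(da, 0);
    dY = da * p.W.t();
    dC = dC % f;
  }
}

double global_norm(const Params& g) {
  double s = arma::accu(g.U % g.U) + arma::accu(g.W % g.W) +
             arma::accu(g.b % g.b);
  for (const auto& m : g.dW) s += arma::accu(m % m);
  for (const auto& v : g.db) s += arma::accu(v % v);
  return std::sqrt(s);
}

void axpy(Params& acc, const Params& g, double a) {
  acc.U += a * g.U; acc.W += a * g.W; acc.b += a * g.b;
  for (size_t k = 0; k < acc.dW.size(); ++k) {
    acc.dW[k] += a * g.dW[k];
    acc.db[k] += a * g.db[k];
  }
}

void scale(Params& g, double a) {
  g.U *= a; g.W *= a; g.b *= a;
  for (auto& m : g.dW) m *= a;
  for (auto& v : g.db) v *= a;
}

} // namespace

// [[Rcpp::export]]
List cpp_lstm_init(int H, IntegerVector dense_widths, double seed) {
  Rng rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);
  Params p;
  p.H = H;
  double r = 1.0 / std::sqrt((double)H);
  p.U.set_size(4 * H);
  p.W.set_size(H, 4 * H);
  p.b.zeros(4 * H);
  for (int j = 0; j < 4 * H; ++j) p.U(j) = (2 * rng.unif() - 1) * r;
  for (int a = 0; a < H; ++a)
    for (int j = 0; j < 4 * H; ++j) p.W(a, j) = (2 * rng.unif() - 1) * r;
  for (int j = H; j < 2 * H; ++j) p.b(j) = 1.0;  // forget-gate bias
  int in = H;
  for (int k = 0; k < dense_widths.size(); ++k) {
    int out = dense_widths[k];
    double rd = std::sqrt(6.0 / (in + out));
    mat Wk(in, out);
    for (arma::uword a = 0; a < Wk.n_rows; ++a)
      for (arma::uword c = 0; c < Wk.n_cols; ++c)
        Wk(a, c) = (2 * rng.unif() - 1) * rd;
    p.dW.push_back(Wk);
    p.db.push_back(rowvec(out, arma::fill::zeros));
    in = out;
  }
  return params_to_list(p);
}

// [[Rcpp::export]]
NumericVector cpp_lstm_predict(List params, NumericMatrix X) {
  Params p = params_from_list(params);
  mat Xm = as<mat>(X);
  vec out(Xm.n_rows);
  const int chunk = 256;
  for (arma::uword a = 0; a < Xm.n_rows; a += chunk) {
    arma::uword b = std::min<arma::uword>(a + chunk, Xm.n_rows) - 1;
    out.subvec(a, b) = forward(p, Xm.rows(a, b), nullptr, nullptr);
  }
  return NumericVector(out.begin(), out.end());
}

// Recursive rollout from the window `start` (1 x L), `r` steps, compared to
// `target`: the monitored quantity when early stopping tracks multi-step
// stability rather than one-step loss.
static double recursive_mse(const Params& p, const rowvec& start,
                            const vec& target) {
  mat win(1, start.n_elem);
  win.row(0) = start;
  double acc = 0.0;
  for (arma::uword h = 0; h < target.n_elem; ++h) {
    vec pr = forward(p, win, nullptr, nullptr);
    double e = pr(0) - target(h);
    acc += e * e;
    win.cols(0, win.n_cols - 2) = win.cols(1, win.n_cols - 1);
    win(0, win.n_cols - 1) = pr(0);
  }
  return acc / target.n_elem;
}

// [[Rcpp::export]]
List cpp_lstm_train(List params, NumericMatrix X, NumericVector y,
                    NumericMatrix X_test, NumericVector y_test,
                    double lr, double momentum, double clip, int epochs,
                    int batch, int patience, double dropout, double seed,
                    int monitor_recursive = 0) {
  Params p = params_from_list(params);
  Params vel = p.scaled_zero();
  mat Xm = as<mat>(X);
  vec yv = as<vec>(y);
  mat Xte = as<mat>(X_test);
  vec yte = as<vec>(y_test);
  const int n = Xm.n_rows;
  const bool have_test = Xte.n_rows > 0;
  Rng rng((uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL);

  std::vector<double> train_hist, monitor_hist;
  Params best = p;
  double best_loss = std::numeric_limits<double>::infinity();
  int best_epoch = 0, bad = 0;

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int ep = 1; ep <= epochs; ++ep) {
    // Fisher-Yates shuffle from the package RNG stream
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(rng.unif() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch) {
      int end = std::min(start + batch, n);
      int B = end - start;
      arma::uvec idx(B);
      for (int i = 0; i < B; ++i) idx(i) = order[start + i];
      mat Xb = Xm.rows(idx);
      vec yb = yv.elem(idx);
      mat mask;
      const mat* maskp = nullptr;
      if (dropout > 0) {
        mask.set_size(B, p.H);
        for (arma::uword a = 0; a < mask.n_elem; ++a)
          mask(a) = (rng.unif() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
        maskp = &mask;
      }
      Cache cc;
      vec pred = forward(p, Xb, &cc, maskp);
      ep_loss += arma::accu(arma::square(pred - yb)) / B;
      ++nb;
      Params grad = p.scaled_zero();
      backward(p, Xb, yb, cc, maskp, grad);
      double gn = global_norm(grad);
      if (clip > 0 && gn > clip) scale(grad, clip / gn);
      if (!std::isfinite(gn))
        stop("train_forecaster: training diverged (non-finite gradient) at epoch %d", ep);
      // SGD with momentum
      scale(vel, momentum);
      axpy(vel, grad, -lr);
      axpy(p, vel, 1.0);
    }
    double tr = ep_loss / std::max(nb, 1);
    if (!std::isfinite(tr))
      stop("train_forecaster: loss became non-finite at epoch %d", ep);
    train_hist.push_back(tr);
    double mon = tr;
    if (have_test) {
      int r = std::min<int>(monitor_recursive, (int)yte.n_elem);
      if (r > 0) {
        arma::uword s0 = Xte.n_rows - r;
        mon = recursive_mse(p, Xte.row(s0), yte.subvec(s0, yte.n_elem - 1));
      } else {
        vec pte(yte.n_elem);
        const int chunk = 512;
        for (arma::uword a = 0; a < Xte.n_rows; a += chunk) {
          arma::uword b2 = std::min<arma::uword>(a + chunk, Xte.n_rows) - 1;
          pte.subvec(a, b2) = forward(p, Xte.rows(a, b2), nullptr, nullptr);
        }
        mon = arma::accu(arma::square(pte - yte)) / yte.n_elem;
      }
    }
    monitor_hist.push_back(mon);
    if (mon < best_loss - 1e-12) {
      best_loss = mon;
      best = p;
      best_epoch = ep;
      bad = 0;
    } else if (++bad >= patience && patience > 0) {
      break;
    }
  }
  return List::create(_["params"] = params_to_list(best),
                      _["train_loss"] = wrap(train_hist),
                      _["monitor_loss"] = wrap(monitor_hist),
                      _["best_epoch"] = best_epoch,
                      _["best_loss"] = best_loss);
}

// Activation trace of a single window: gate values, cell state and hidden
// output per time step (L x H matrices). Used by invariant tests.
// [[Rcpp::export]]
List cpp_lstm_trace(List params, NumericVector x) {
  Params p = params_from_list(params);
  const int L = x.size(), H = p.H;
  mat I(L, H), F(L, H), G(L, H), O(L, H), Cm(L, H), Ym(L, H);
  rowvec Y(H, arma::fill::zeros), C(H, arma::fill::zeros);
  for (int t = 0; t < L; ++t) {
    rowvec a = x[t] * p.U + Y * p.W + p.b;
    rowvec i = 1.0 / (1.0 + arma::exp(-a.subvec(0, H - 1)));
    rowvec f = 1.0 / (1.0 + arma::exp(-a.subvec(H, 2 * H - 1)));
    rowvec g = arma::tanh(a.subvec(2 * H, 3 * H - 1));
    rowvec o = 1.0 / (1.0 + arma::exp(-a.subvec(3 * H, 4 * H - 1)));
    C = f % C + i % g;
    Y = o % arma::tanh(C);
    I.row(t) = i; F.row(t) = f; G.row(t) = g; O.row(t) = o;
    Cm.row(t) = C; Ym.row(t) = Y;
  }
  return List::create(_["i"] = wrap(I), _["f"] = wrap(F), _["g"] = wrap(G),
                      _["o"] = wrap(O), _["C"] = wrap(Cm), _["y"] = wrap(Ym));
}
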