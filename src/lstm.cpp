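// Recurrent network for windowed grid-activation sequences: one LSTM layer
// (only the final-step output forwarded), four ReLU dense layers, and a
// softmax(2) classification head or a ReLU(1) regression head. Trained by
// backpropagation through time with Adam and early stopping on the
// validation loss. Windows are addressed as (start row, fixed length) into
// one stacked step matrix, so overlapping windows share storage.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  mat Wx, Wh;            // (4H x D), (4H x H); gate rows ordered i, f, g, o
  vec b;                 // (4H)
  std::vector<mat> Wd;   // dense weights
  std::vector<vec> bd;
  mat Wo;                // head weights (K x width)
  vec bo;
};

Net netFromList(const Rcpp::List& params) {
  Net n;
  n.Wx = Rcpp::as<mat>(params["Wx"]);
  n.Wh = Rcpp::as<mat>(params["Wh"]);
  n.b  = Rcpp::as<vec>(params["b"]);
  Rcpp::List Wd = params["Wd"], bd = params["bd"];
  for (int i = 0; i < Wd.size(); ++i) {
    n.Wd.push_back(Rcpp::as<mat>(Wd[i]));
    n.bd.push_back(Rcpp::as<vec>(bd[i]));
  }
  n.Wo = Rcpp::as<mat>(params["Wo"]);
  n.bo = Rcpp::as<vec>(params["bo"]);
  return n;
}

Rcpp::List netToList(const Net& n) {
  Rcpp::List Wd(n.Wd.size()), bd(n.bd.size());
  for (size_t i = 0; i < n.Wd.size(); ++i) { Wd[i] = n.Wd[i]; bd[i] = n.bd[i]; }
  return Rcpp::List::create(
    Rcpp::Named("Wx") = n.Wx, Rcpp::Named("Wh") = n.Wh, Rcpp::Named("b") = n.b,
    Rcpp::Named("Wd") = Wd, Rcpp::Named("bd") = bd,
    Rcpp::Named("Wo") = n.Wo, Rcpp::Named("bo") = n.bo);
}

Net zerosLike(const Net& n) {
  Net z;
  z.Wx = zeros<mat>(size(n.Wx)); z.Wh = zeros<mat>(size(n.Wh));
  z.b = zeros<vec>(size(n.b));
  for (size_t i = 0; i < n.Wd.size(); ++i) {
    z.Wd.push_back(zeros<mat>(size(n.Wd[i])));
    z.bd.push_back(zeros<vec>(size(n.bd[i])));
  }
  z.Wo = zeros<mat>(size(n.Wo)); z.bo = zeros<vec>(size(n.bo));
  return z;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cache {
  // per-timestep activations, each H x B
  std::vector<mat> gi, gf, gg, go, cc, hh;
  std::vector<mat> xs;               // D x B inputs per step
  std::vector<mat> za, aa;           // dense pre/post activations
  mat zo, out;                       // head pre-activation and output
};

// Forward pass for one minibatch of windows. XT is D x Nsteps (transposed
// stacked step matrix); cols(t) gathers the batch's step-t rows.
void forwardBatch(const Net& net, const mat& XT, const uvec& starts,
                  int T, int head, Cache& C) {
  const uword H = net.Wh.n_cols, B = starts.n_elem;
  mat h = zeros<mat>(H, B), c = zeros<mat>(H, B);
  C.gi.resize(T); C.gf.resize(T); C.gg.resize(T); C.go.resize(T);
  C.cc.resize(T); C.hh.resize(T); C.xs.resize(T);
  for (int t = 0; t < T; ++t) {
    uvec cols = starts + t;          // 0-based step rows
    mat Xt = XT.cols(cols);
    mat Z = net.Wx * Xt + net.Wh * h;
    Z.each_col() += net.b;
    mat i = sigm(Z.rows(0, H - 1));
    mat f = sigm(Z.rows(H, 2 * H - 1));
    mat g = tanh(Z.rows(2 * H, 3 * H - 1));
    mat o = sigm(Z.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % tanh(c);
    C.gi[t] = i; C.gf[t] = f; C.gg[t] = g; C.go[t] = o;
    C.cc[t] = c; C.hh[t] = h; C.xs[t] = Xt;
  }
  const size_t L = net.Wd.size();
  C.za.resize(L); C.aa.resize(L);
  mat a = h;
  for (size_t l = 0; l < L; ++l) {
    mat z = net.Wd[l] * a;
    z.each_col() += net.bd[l];
    a = clamp(z, 0.0, datum::inf);   // ReLU
    C.za[l] = z; C.aa[l] = a;
  }
  C.zo = net.Wo * a;
  C.zo.each_col() += net.bo;
  if (head == 0) {                   // softmax over K classes
    mat m = repmat(max(C.zo, 0), C.zo.n_rows, 1);
    mat e = exp(C.zo - m);
    C.out = e / repmat(sum(e, 0), C.zo.n_rows, 1);
  } else {                           // ReLU regression output
    C.out = clamp(C.zo, 0.0, datum::inf);
  }
}

// Loss over the batch (mean) given targets; y holds class indices for the
// classification head and real-valued targets for the regression head.
double batchLoss(const Cache& C, const vec& y, int head) {
  const uword B = C.out.n_cols;
  double loss = 0.0;
  if (head == 0) {
    for (uword j = 0; j < B; ++j)
      loss += -std::log(std::max(C.out((uword)y(j), j), 1e-12));
  } else {
    for (uword j = 0; j < B; ++j) {
      double d = C.out(0, j) - y(j);
      loss += d * d;
    }
  }
  return loss / B;
}

// Backward pass; fills grad (already zero-initialised).
void backwardBatch(const Net& net, const Cache& C, const vec& y, int head,
                   Net& grad) {
  const uword H = net.Wh.n_cols, B = C.out.n_cols;
  const int T = C.hh.size();
  mat dzo;
  if (head == 0) {
    dzo = C.out;
    for (uword j = 0; j < B; ++j) dzo((uword)y(j), j) -= 1.0;
    dzo /= (double)B;
  } else {
    dzo = zeros<mat>(1, B);
    for (uword j = 0; j < B; ++j)
      dzo(0, j) = 2.0 * (C.out(0, j) - y(j)) / (double)B;
    dzo %= conv_to<mat>::from(C.zo > 0);   // through the head ReLU
  }
  const size_t L = net.Wd.size();
  grad.Wo += dzo * C.aa[L - 1].t();
  grad.bo += sum(dzo, 1);
  mat da = net.Wo.t() * dzo;
  for (int l = (int)L - 1; l >= 0; --l) {
    mat dz = da % conv_to<mat>::from(C.za[l] > 0);
    const mat& ain = (l == 0) ? C.hh[T - 1] : C.aa[l - 1];
    grad.Wd[l] += dz * ain.t();
    grad.bd[l] += sum(dz, 1);
    da = net.Wd[l].t() * dz;
  }
  mat dh = da;                        // gradient into the final hidden state
  mat dc = zeros<mat>(H, B);
  for (int t = T - 1; t >= 0; --t) {
    mat tc = tanh(C.cc[t]);
    mat do_ = dh % tc % C.go[t] % (1.0 - C.go[t]);
    dc += dh % C.go[t] % (1.0 - tc % tc);
    const mat cPrev = (t > 0) ? C.cc[t - 1] : zeros<mat>(H, B);
    mat di = dc % C.gg[t] % C.gi[t] % (1.0 - C.gi[t]);
    mat df = dc % cPrev % C.gf[t] % (1.0 - C.gf[t]);
    mat dg = dc % C.gi[t] % (1.0 - C.gg[t] % C.gg[t]);
    mat dZ = join_cols(join_cols(di, df), join_cols(dg, do_));
    grad.Wx += dZ * C.xs[t].t();
    if (t > 0) grad.Wh += dZ * C.hh[t - 1].t();
    grad.b += sum(dZ, 1);
    dh = net.Wh.t() * dZ;
    dc = dc % C.gf[t];
  }
}

struct Adam {
  Net m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Net& n) : m(zerosLike(n)), v(zerosLike(n)) {}
  void stepOne(mat& w, mat& mm, mat& vv, const mat& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    mat mh = mm / (1 - std::pow(b1, (double)t));
    mat vh = vv / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
  void stepOne(vec& w, vec& mm, vec& vv, const vec& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    vec mh = mm / (1 - std::pow(b1, (double)t));
    vec vh = vv / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
  void update(Net& n, const Net& g, double lr) {
    ++t;
    stepOne(n.Wx, m.Wx, v.Wx, g.Wx, lr);
    stepOne(n.Wh, m.Wh, v.Wh, g.Wh, lr);
    stepOne(n.b, m.b, v.b, g.b, lr);
    for (size_t i = 0; i < n.Wd.size(); ++i) {
      stepOne(n.Wd[i], m.Wd[i], v.Wd[i], g.Wd[i], lr);
      stepOne(n.bd[i], m.bd[i], v.bd[i], g.bd[i], lr);
    }
    stepOne(n.Wo, m.Wo, v.Wo, g.Wo, lr);
    stepOne(n.bo, m.bo, v.bo, g.bo, lr);
  }
};

double datasetLoss(const Net& net, const mat& XT, const uvec& starts,
                   const vec& y, int T, int head, uword chunk = 512) {
  const uword N = starts.n_elem;
  double total = 0.0;
  Cache C;
  for (uword s = 0; s < N; s += chunk) {
    uword e = std::min(s + chunk, N) - 1;
    uvec sub = starts.subvec(s, e);
    forwardBatch(net, XT, sub, T, head, C);
    total += batchLoss(C, y.subvec(s, e), head) * sub.n_elem;
  }
  return total / N;
}

}  // namespace

// [[Rcpp::export(name = ".cg_forward")]]
arma::mat cg_forward(Rcpp::List params, const arma::mat& X,
                     const arma::uvec& starts1, int T, int head) {
  Net net = netFromList(params);
  mat XT = X.t();
  uvec starts = starts1 - 1;
  const uword N = starts.n_elem, chunk = 512;
  mat out(net.Wo.n_rows, N);
  Cache C;
  for (uword s = 0; s < N; s += chunk) {
    uword e = std::min(s + chunk, N) - 1;
    forwardBatch(net, XT, starts.subvec(s, e), T, head, C);
    out.cols(s, e) = C.out;
  }
  return out.t();
}

// [[Rcpp::export(name = ".cg_loss_grad")]]
Rcpp::List cg_loss_grad(Rcpp::List params, const arma::mat& X,
                        const arma::uvec& starts1, const arma::vec& y,
                        int T, int head) {
  Net net = netFromList(params);
  mat XT = X.t();
  uvec starts = starts1 - 1;
  Cache C;
  forwardBatch(net, XT, starts, T, head, C);
  double loss = batchLoss(C, y, head);
  Net grad = zerosLike(net);
  backwardBatch(net, C, y, head, grad);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = netToList(grad));
}

// [[Rcpp::export(name = ".cg_train")]]
Rcpp::List cg_train(Rcpp::List params, const arma::mat& X,
                    const arma::uvec& starts1, const arma::vec& y,
                    const arma::mat& Xval, const arma::uvec& vstarts1,
                    const arma::vec& yval, Rcpp::List opts) {
  Net net = netFromList(params);
  const int T = Rcpp::as<int>(opts["window"]);
  const int head = Rcpp::as<int>(opts["head"]);
  const int maxEpochs = Rcpp::as<int>(opts["maxEpochs"]);
  const int patience = Rcpp::as<int>(opts["patience"]);
  const double lr = Rcpp::as<double>(opts["learningRate"]);
  const uword batch = Rcpp::as<int>(opts["batchSize"]);
  const unsigned int seed = Rcpp::as<unsigned int>(opts["seed"]);

  mat XT = X.t();
  mat XTval = Xval.t();
  uvec starts = starts1 - 1;
  uvec vstarts = vstarts1 - 1;
  const uword N = starts.n_elem;
  if (N == 0) Rcpp::stop("insufficient data: empty training set");

  std::mt19937 rng(seed);
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  Adam adam(net);
  Net best = net;
  double bestVal = datum::inf;
  int bestEpoch = 0, wait = 0, epochsRun = 0;
  std::vector<double> trainHist, valHist;
  Cache C;

  for (int epoch = 1; epoch <= maxEpochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epochLoss = 0.0;
    uword seen = 0;
    for (uword s = 0; s < N; s += batch) {
      uword e = std::min(s + batch, N);
      uvec sub(e - s);
      vec ysub(e - s);
      for (uword j = s; j < e; ++j) {
        sub(j - s) = starts(order[j]);
        ysub(j - s) = y(order[j]);
      }
      forwardBatch(net, XT, sub, T, head, C);
      epochLoss += batchLoss(C, ysub, head) * sub.n_elem;
      seen += sub.n_elem;
      Net grad = zerosLike(net);
      backwardBatch(net, C, ysub, head, grad);
      adam.update(net, grad, lr);
    }
    double valLoss = datasetLoss(net, XTval, vstarts, yval, T, head);
    trainHist.push_back(epochLoss / seen);
    valHist.push_back(valLoss);
    epochsRun = epoch;
    if (valLoss < bestVal) {         // strict improvement resets patience
      bestVal = valLoss;
      best = net;
      bestEpoch = epoch;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = netToList(best),
    Rcpp::Named("trainLoss") = trainHist,
    Rcpp::Named("valLoss") = valHist,
    Rcpp::Named("bestEpoch") = bestEpoch,
    Rcpp::Named("epochsRun") = epochsRun,
    Rcpp::Named("bestValLoss") = bestVal);
}
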