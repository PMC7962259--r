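// Multi-label recurrent classifier over tokenised SMILES:
// embedding -> unidirectional LSTM -> dense(ReLU) -> dropout -> sigmoid,
// trained with binary cross-entropy via masked backpropagation through time
// and Adam.  Padding index 0 freezes the state (mask), so right-padded
// batches behave as if each sequence ended at its last real token.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Params {
  mat E;            // vocab x embed (row 0 = padding, kept at zero)
  mat Wx, Wh;       // embed x 4u, u x 4u ; gate order [i | f | o | g]
  rowvec b;         // 1 x 4u
  mat W1, W2;       // u x dense, dense x classes
  rowvec b1, b2;
};

static Params paramsFromList(const Rcpp::List& p) {
  Params P;
  P.E  = Rcpp::as<mat>(p["E"]);
  P.Wx = Rcpp::as<mat>(p["Wx"]);
  P.Wh = Rcpp::as<mat>(p["Wh"]);
  P.b  = Rcpp::as<rowvec>(p["b"]);
  P.W1 = Rcpp::as<mat>(p["W1"]);
  P.b1 = Rcpp::as<rowvec>(p["b1"]);
  P.W2 = Rcpp::as<mat>(p["W2"]);
  P.b2 = Rcpp::as<rowvec>(p["b2"]);
  return P;
}

static Rcpp::List paramsToList(const Params& P) {
  return Rcpp::List::create(
    Rcpp::Named("E") = P.E, Rcpp::Named("Wx") = P.Wx,
    Rcpp::Named("Wh") = P.Wh, Rcpp::Named("b") = P.b,
    Rcpp::Named("W1") = P.W1, Rcpp::Named("b1") = P.b1,
    Rcpp::Named("W2") = P.W2, Rcpp::Named("b2") = P.b2);
}

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Cache {
  std::vector<mat> gi, gf, go, gg, tc, cprev, hprev;
  std::vector<vec> m;
  mat hT, z1, a1, a1d, D, scores;
};

// forward pass over a batch of padded token-id rows (0 = pad)
static mat forwardBatch(const Params& P, const umat& ids, double dropout,
                        std::mt19937* rng, Cache* cache) {
  const uword B = ids.n_rows, T = ids.n_cols;
  const uword u = P.Wh.n_rows;
  mat h(B, u, fill::zeros), c(B, u, fill::zeros);
  if (cache) {
    cache->gi.resize(T); cache->gf.resize(T); cache->go.resize(T);
    cache->gg.resize(T); cache->tc.resize(T); cache->cprev.resize(T);
    cache->hprev.resize(T); cache->m.resize(T);
  }
  for (uword t = 0; t < T; ++t) {
    mat x(B, P.E.n_cols, fill::zeros);
    vec m(B);
    for (uword r = 0; r < B; ++r) {
      uword id = ids(r, t);
      m(r) = id == 0 ? 0.0 : 1.0;
      if (id != 0) x.row(r) = P.E.row(id);
    }
    mat a = x * P.Wx + h * P.Wh;
    a.each_row() += P.b;
    mat gi = sigm(a.cols(0, u - 1));
    mat gf = sigm(a.cols(u, 2 * u - 1));
    mat go = sigm(a.cols(2 * u, 3 * u - 1));
    mat gg = tanh(a.cols(3 * u, 4 * u - 1));
    mat cNew = gf % c + gi % gg;
    mat tc = tanh(cNew);
    mat hNew = go % tc;
    mat M = repmat(m, 1, u);
    if (cache) {
      cache->gi[t] = gi; cache->gf[t] = gf; cache->go[t] = go;
      cache->gg[t] = gg; cache->tc[t] = tc;
      cache->cprev[t] = c; cache->hprev[t] = h; cache->m[t] = m;
    }
    c = M % cNew + (1.0 - M) % c;
    h = M % hNew + (1.0 - M) % h;
  }
  mat z1 = h * P.W1;
  z1.each_row() += P.b1;
  mat a1 = clamp(z1, 0.0, datum::inf);  // ReLU
  mat D(a1.n_rows, a1.n_cols, fill::ones);
  if (dropout > 0 && rng) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    for (uword j = 0; j < D.n_cols; ++j)
      for (uword r = 0; r < D.n_rows; ++r)
        D(r, j) = U(*rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
  }
  mat a1d = a1 % D;
  mat z2 = a1d * P.W2;
  z2.each_row() += P.b2;
  mat scores = sigm(z2);
  if (cache) {
    cache->hT = h; cache->z1 = z1; cache->a1 = a1; cache->a1d = a1d;
    cache->D = D; cache->scores = scores;
  }
  return scores;
}

static double bce(const mat& scores, const mat& Y) {
  mat p = clamp(scores, 1e-7, 1.0 - 1e-7);
  return -accu(Y % log(p) + (1.0 - Y) % log(1.0 - p)) / p.n_elem;
}

// gradients of mean binary cross-entropy w.r.t. all parameters
static Params backwardBatch(const Params& P, const umat& ids, const mat& Y,
                            const Cache& C) {
  const uword B = ids.n_rows, T = ids.n_cols, u = P.Wh.n_rows;
  Params G;
  G.E = zeros(size(P.E));   G.Wx = zeros(size(P.Wx));
  G.Wh = zeros(size(P.Wh)); G.b = zeros<rowvec>(P.b.n_elem);
  G.W1 = zeros(size(P.W1)); G.b1 = zeros<rowvec>(P.b1.n_elem);
  G.W2 = zeros(size(P.W2)); G.b2 = zeros<rowvec>(P.b2.n_elem);

  mat dz2 = (C.scores - Y) / double(Y.n_elem);
  G.W2 = C.a1d.t() * dz2;
  G.b2 = sum(dz2, 0);
  mat da1 = (dz2 * P.W2.t()) % C.D;
  mat dz1 = da1 % conv_to<mat>::from(C.z1 > 0);
  G.W1 = C.hT.t() * dz1;
  G.b1 = sum(dz1, 0);
  mat dh = dz1 * P.W1.t();
  mat dc(B, u, fill::zeros);

  for (uword t = T; t-- > 0;) {
    mat M = repmat(C.m[t], 1, u);
    mat dhCand = dh % M;
    mat dhCarry = dh % (1.0 - M);
    mat dcCand = dc % M + dhCand % C.go[t] % (1.0 - square(C.tc[t]));
    mat dcCarry = dc % (1.0 - M);
    mat dgo = dhCand % C.tc[t];
    mat dgi = dcCand % C.gg[t];
    mat dgg = dcCand % C.gi[t];
    mat dgf = dcCand % C.cprev[t];
    mat da(B, 4 * u);
    da.cols(0, u - 1)         = dgi % C.gi[t] % (1.0 - C.gi[t]);
    da.cols(u, 2 * u - 1)     = dgf % C.gf[t] % (1.0 - C.gf[t]);
    da.cols(2 * u, 3 * u - 1) = dgo % C.go[t] % (1.0 - C.go[t]);
    da.cols(3 * u, 4 * u - 1) = dgg % (1.0 - square(C.gg[t]));

    mat x(B, P.E.n_cols, fill::zeros);
    for (uword r = 0; r < B; ++r)
      if (ids(r, t) != 0) x.row(r) = P.E.row(ids(r, t));
    G.Wx += x.t() * da;
    G.Wh += C.hprev[t].t() * da;
    G.b  += sum(da, 0);
    mat dx = da * P.Wx.t();
    for (uword r = 0; r < B; ++r)
      if (ids(r, t) != 0) G.E.row(ids(r, t)) += dx.row(r);
    dh = dhCarry + da * P.Wh.t();
    dc = dcCand % C.gf[t] + dcCarry;
  }
  return G;
}

static double gradNorm(const Params& G) {
  double s = accu(square(G.E)) + accu(square(G.Wx)) + accu(square(G.Wh)) +
             accu(square(G.b)) + accu(square(G.W1)) + accu(square(G.b1)) +
             accu(square(G.W2)) + accu(square(G.b2));
  return std::sqrt(s);
}

static void scaleParams(Params& G, double f) {
  G.E *= f; G.Wx *= f; G.Wh *= f; G.b *= f;
  G.W1 *= f; G.b1 *= f; G.W2 *= f; G.b2 *= f;
}

struct Adam {
  Params m, v;
  long t = 0;
  double lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  explicit Adam(const Params& P, double lr_) : lr(lr_) {
    m.E = zeros(size(P.E));   v.E = m.E;
    m.Wx = zeros(size(P.Wx)); v.Wx = m.Wx;
    m.Wh = zeros(size(P.Wh)); v.Wh = m.Wh;
    m.b = zeros<rowvec>(P.b.n_elem);   v.b = m.b;
    m.W1 = zeros(size(P.W1)); v.W1 = m.W1;
    m.b1 = zeros<rowvec>(P.b1.n_elem); v.b1 = m.b1;
    m.W2 = zeros(size(P.W2)); v.W2 = m.W2;
    m.b2 = zeros<rowvec>(P.b2.n_elem); v.b2 = m.b2;
  }
  template <typename M>
  void upd1(M& p, M& mm, M& vv, const M& g, double corr1, double corr2) {
    mm = beta1 * mm + (1 - beta1) * g;
    vv = beta2 * vv + (1 - beta2) * (g % g);
    p -= lr * (mm / corr1) / (sqrt(vv / corr2) + eps);
  }
  void step(Params& P, const Params& G) {
    ++t;
    double c1 = 1 - std::pow(beta1, t), c2 = 1 - std::pow(beta2, t);
    upd1(P.E, m.E, v.E, G.E, c1, c2);
    upd1(P.Wx, m.Wx, v.Wx, G.Wx, c1, c2);
    upd1(P.Wh, m.Wh, v.Wh, G.Wh, c1, c2);
    upd1(P.b, m.b, v.b, G.b, c1, c2);
    upd1(P.W1, m.W1, v.W1, G.W1, c1, c2);
    upd1(P.b1, m.b1, v.b1, G.b1, c1, c2);
    upd1(P.W2, m.W2, v.W2, G.W2, c1, c2);
    upd1(P.b2, m.b2, v.b2, G.b2, c1, c2);
  }
};

static umat idsFromR(const Rcpp::IntegerMatrix& X) {
  umat ids(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i)
      ids(i, j) = (uword) X(i, j);
  return ids;
}

// micro-averaged precision/recall over all (molecule, class) cells
static void microPR(const mat& scores, const mat& Y, double threshold,
                    double& prec, double& rec) {
  umat pred = scores > threshold;
  umat truth = Y > 0.5;
  double tp = accu(pred % truth);
  double fp = accu(pred % (1 - truth));
  double fn = accu((1 - pred) % truth);
  prec = (tp + fp) > 0 ? tp / (tp + fp) : 0.0;
  rec  = (tp + fn) > 0 ? tp / (tp + fn) : 0.0;
}

// [[Rcpp::export(name = ".lstm_create")]]
Rcpp::List lstm_create(int vocabSize, int embeddingDim, int lstmUnits,
                       int denseUnits, int nClasses, int seed) {
  std::mt19937 rng((unsigned) seed);
  auto uni = [&](mat& M, double a) {
    std::uniform_real_distribution<double> U(-a, a);
    for (uword j = 0; j < M.n_cols; ++j)
      for (uword i = 0; i < M.n_rows; ++i) M(i, j) = U(rng);
  };
  Params P;
  P.E = mat(vocabSize, embeddingDim);
  uni(P.E, 0.05);
  P.E.row(0).zeros();  // padding embedding stays zero
  P.Wx = mat(embeddingDim, 4 * lstmUnits);
  uni(P.Wx, std::sqrt(6.0 / (embeddingDim + 4 * lstmUnits)));
  P.Wh = mat(lstmUnits, 4 * lstmUnits);
  uni(P.Wh, std::sqrt(6.0 / (lstmUnits + 4 * lstmUnits)));
  P.b = rowvec(4 * lstmUnits, fill::zeros);
  P.b.subvec(lstmUnits, 2 * lstmUnits - 1).fill(1.0);  // forget-gate bias
  P.W1 = mat(lstmUnits, denseUnits);
  uni(P.W1, std::sqrt(6.0 / (lstmUnits + denseUnits)));
  P.b1 = rowvec(denseUnits, fill::zeros);
  P.W2 = mat(denseUnits, nClasses);
  uni(P.W2, std::sqrt(6.0 / (denseUnits + nClasses)));
  P.b2 = rowvec(nClasses, fill::zeros);
  return paramsToList(P);
}

// [[Rcpp::export(name = ".lstm_scores")]]
arma::mat lstm_scores(Rcpp::List params, Rcpp::IntegerMatrix X) {
  Params P = paramsFromList(params);
  return forwardBatch(P, idsFromR(X), 0.0, nullptr, nullptr);
}

// [[Rcpp::export(name = ".lstm_loss")]]
double lstm_loss(Rcpp::List params, Rcpp::IntegerMatrix X,
                 Rcpp::NumericMatrix Y) {
  Params P = paramsFromList(params);
  mat scores = forwardBatch(P, idsFromR(X), 0.0, nullptr, nullptr);
  return bce(scores, Rcpp::as<mat>(Y));
}

// [[Rcpp::export(name = ".lstm_grad")]]
Rcpp::List lstm_grad(Rcpp::List params, Rcpp::IntegerMatrix X,
                     Rcpp::NumericMatrix Y) {
  Params P = paramsFromList(params);
  umat ids = idsFromR(X);
  Cache C;
  forwardBatch(P, ids, 0.0, nullptr, &C);
  Params G = backwardBatch(P, ids, Rcpp::as<mat>(Y), C);
  return paramsToList(G);
}

// [[Rcpp::export(name = ".lstm_fit")]]
Rcpp::List lstm_fit(Rcpp::List params, Rcpp::IntegerMatrix X,
                    Rcpp::NumericMatrix Y, Rcpp::IntegerMatrix Xval,
                    Rcpp::NumericMatrix Yval, int epochs, int batchSize,
                    double learningRate, double dropout, double threshold,
                    int seed) {
  Params P = paramsFromList(params);
  umat ids = idsFromR(X);
  mat Ym = Rcpp::as<mat>(Y);
  umat idsVal = idsFromR(Xval);
  mat YvalM = Rcpp::as<mat>(Yval);
  const uword n = ids.n_rows;
  const bool hasVal = idsVal.n_rows > 0;

  std::mt19937 rng((unsigned) seed);
  Adam opt(P, learningRate);
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  Rcpp::NumericVector trLoss(epochs), trPrec(epochs), trRec(epochs),
      vaLoss(epochs), vaPrec(epochs), vaRec(epochs);

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    for (uword start = 0; start < n; start += batchSize) {
      uword end = std::min<uword>(start + batchSize, n) - 1;
      uvec sel(end - start + 1);
      for (uword k = 0; k < sel.n_elem; ++k) sel(k) = order[start + k];
      umat bx = ids.rows(sel);
      mat by = Ym.rows(sel);
      Cache C;
      forwardBatch(P, bx, dropout, &rng, &C);
      Params G = backwardBatch(P, bx, by, C);
      double nrm = gradNorm(G);
      if (nrm > 5.0) scaleParams(G, 5.0 / nrm);
      opt.step(P, G);
    }
    mat sc = forwardBatch(P, ids, 0.0, nullptr, nullptr);
    trLoss[e] = bce(sc, Ym);
    microPR(sc, Ym, threshold, trPrec[e], trRec[e]);
    if (hasVal) {
      mat scv = forwardBatch(P, idsVal, 0.0, nullptr, nullptr);
      vaLoss[e] = bce(scv, YvalM);
      microPR(scv, YvalM, threshold, vaPrec[e], vaRec[e]);
    } else {
      vaLoss[e] = NA_REAL; vaPrec[e] = NA_REAL; vaRec[e] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = paramsToList(P),
    Rcpp::Named("train_loss") = trLoss,
    Rcpp::Named("train_precision") = trPrec,
    Rcpp::Named("train_recall") = trRec,
    Rcpp::Named("val_loss") = vaLoss,
    Rcpp::Named("val_precision") = vaPrec,
    Rcpp::Named("val_recall") = vaRec);
}
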