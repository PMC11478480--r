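// Two-layer bidirectional LSTM stack with a ReLU dense layer and a linear /
// softmax head, plus full backpropagation through time. Layout of a batch:
// cube X with dims (features, batch, time); gate order inside the stacked
// 4H weight blocks is input, forget, cell, output. The sequence-to-one head
// reads the forward direction at the last timestep concatenated with the
// backward direction at the first timestep, as a bidirectional stack with
// return_sequences = FALSE would.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  cube i, f, g, o, c, h, tanhc; // (H, B, T) in processing order
};

// One direction of one LSTM layer. X has dims (D, B, T); if reverse, the
// sequence is consumed back-to-front. Returns hidden states re-indexed to
// INPUT time order as a cube (H, B, T).
static cube lstm_forward(const cube& X, const mat& W, const mat& U,
                         const vec& b, bool reverse, LstmCache& cache) {
  const uword D = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = U.n_cols;
  cache.i.set_size(H, B, T); cache.f.set_size(H, B, T);
  cache.g.set_size(H, B, T); cache.o.set_size(H, B, T);
  cache.c.set_size(H, B, T); cache.h.set_size(H, B, T);
  cache.tanhc.set_size(H, B, T);
  mat h_prev(H, B, fill::zeros), c_prev(H, B, fill::zeros);
  cube out(H, B, T);
  for (uword s = 0; s < T; ++s) {
    uword t = reverse ? (T - 1 - s) : s;
    mat z = W * X.slice(t) + U * h_prev;
    z.each_col() += b;
    mat ig = sigmoid(z.rows(0, H - 1));
    mat fg = sigmoid(z.rows(H, 2 * H - 1));
    mat gg = tanh(z.rows(2 * H, 3 * H - 1));
    mat og = sigmoid(z.rows(3 * H, 4 * H - 1));
    mat c_t = fg % c_prev + ig % gg;
    mat tc = tanh(c_t);
    mat h_t = og % tc;
    cache.i.slice(s) = ig; cache.f.slice(s) = fg;
    cache.g.slice(s) = gg; cache.o.slice(s) = og;
    cache.c.slice(s) = c_t; cache.h.slice(s) = h_t; cache.tanhc.slice(s) = tc;
    out.slice(t) = h_t;
    h_prev = h_t; c_prev = c_t;
  }
  return out;
}

// Backward pass for one direction. dH is the gradient wrt the OUTPUT cube in
// input time order. Returns gradient wrt the input cube; accumulates dW, dU,
// db.
static cube lstm_backward(const cube& X, const mat& W, const mat& U,
                          bool reverse, const LstmCache& cache, const cube& dH,
                          mat& dW, mat& dU, vec& db) {
  const uword D = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword H = U.n_cols;
  dW.zeros(4 * H, D); dU.zeros(4 * H, H); db.zeros(4 * H);
  cube dX(D, B, T, fill::zeros);
  mat dh_next(H, B, fill::zeros), dc_next(H, B, fill::zeros);
  for (uword s = T; s-- > 0;) { // processing order, reversed
    uword t = reverse ? (T - 1 - s) : s;
    mat dh = dH.slice(t) + dh_next;
    const mat& ig = cache.i.slice(s); const mat& fg = cache.f.slice(s);
    const mat& gg = cache.g.slice(s); const mat& og = cache.o.slice(s);
    const mat& tc = cache.tanhc.slice(s);
    mat c_prev = (s == 0) ? mat(H, B, fill::zeros) : cache.c.slice(s - 1);
    mat h_prev = (s == 0) ? mat(H, B, fill::zeros) : cache.h.slice(s - 1);
    mat do_ = dh % tc;
    mat dc = dh % og % (1.0 - tc % tc) + dc_next;
    mat di = dc % gg;
    mat dg = dc % ig;
    mat df = dc % c_prev;
    dc_next = dc % fg;
    mat dz(4 * H, B);
    dz.rows(0, H - 1)         = di % ig % (1.0 - ig);
    dz.rows(H, 2 * H - 1)     = df % fg % (1.0 - fg);
    dz.rows(2 * H, 3 * H - 1) = dg % (1.0 - gg % gg);
    dz.rows(3 * H, 4 * H - 1) = do_ % og % (1.0 - og);
    dW += dz * X.slice(t).t();
    dU += dz * h_prev.t();
    db += sum(dz, 1);
    dX.slice(t) += W.t() * dz;
    dh_next = U.t() * dz;
  }
  return dX;
}

struct Params {
  mat W1f, U1f, W1b, U1b, W2f, U2f, W2b, U2b, Wd, Wo;
  vec b1f, b1b, b2f, b2b, bd, bo;
};

static Params unpack(const Rcpp::List& p) {
  Params q;
  q.W1f = Rcpp::as<mat>(p["W1f"]); q.U1f = Rcpp::as<mat>(p["U1f"]);
  q.b1f = Rcpp::as<vec>(p["b1f"]);
  q.W1b = Rcpp::as<mat>(p["W1b"]); q.U1b = Rcpp::as<mat>(p["U1b"]);
  q.b1b = Rcpp::as<vec>(p["b1b"]);
  q.W2f = Rcpp::as<mat>(p["W2f"]); q.U2f = Rcpp::as<mat>(p["U2f"]);
  q.b2f = Rcpp::as<vec>(p["b2f"]);
  q.W2b = Rcpp::as<mat>(p["W2b"]); q.U2b = Rcpp::as<mat>(p["U2b"]);
  q.b2b = Rcpp::as<vec>(p["b2b"]);
  q.Wd = Rcpp::as<mat>(p["Wd"]); q.bd = Rcpp::as<vec>(p["bd"]);
  q.Wo = Rcpp::as<mat>(p["Wo"]); q.bo = Rcpp::as<vec>(p["bo"]);
  return q;
}

struct Forward {
  cube h1cat, h1drop;
  LstmCache c1f, c1b, c2f, c2b;
  cube h2f_out, h2b_out;
  mat last, last_drop, dense_pre, dense, out;
};

// mask1: (2*H1, B, T) inverted-dropout mask (empty => no dropout);
// mask2: (2*H2, B).
static void forward_pass(const Params& q, const cube& X, const cube& mask1,
                         const mat& mask2, Forward& fw) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword H1 = q.U1f.n_cols, H2 = q.U2f.n_cols;
  cube h1f = lstm_forward(X, q.W1f, q.U1f, q.b1f, false, fw.c1f);
  cube h1b = lstm_forward(X, q.W1b, q.U1b, q.b1b, true, fw.c1b);
  fw.h1cat.set_size(2 * H1, B, T);
  fw.h1cat.tube(0, 0, H1 - 1, B - 1) = h1f;
  fw.h1cat.tube(H1, 0, 2 * H1 - 1, B - 1) = h1b;
  fw.h1drop = mask1.is_empty() ? fw.h1cat : cube(fw.h1cat % mask1);
  fw.h2f_out = lstm_forward(fw.h1drop, q.W2f, q.U2f, q.b2f, false, fw.c2f);
  fw.h2b_out = lstm_forward(fw.h1drop, q.W2b, q.U2b, q.b2b, true, fw.c2b);
  fw.last.set_size(2 * H2, B);
  fw.last.rows(0, H2 - 1) = fw.h2f_out.slice(T - 1); // forward dir, final step
  fw.last.rows(H2, 2 * H2 - 1) = fw.h2b_out.slice(0); // backward dir, final step
  fw.last_drop = mask2.is_empty() ? fw.last : mat(fw.last % mask2);
  fw.dense_pre = q.Wd * fw.last_drop;
  fw.dense_pre.each_col() += q.bd;
  fw.dense = fw.dense_pre;
  fw.dense.elem(find(fw.dense_pre < 0)).zeros(); // ReLU
  fw.out = q.Wo * fw.dense;
  fw.out.each_col() += q.bo;
}

static mat softmax_cols(const mat& x) {
  mat e = exp(x.each_row() - max(x, 0));
  return e.each_row() / sum(e, 0);
}

// task: 0 = classification (softmax + cross-entropy; Y is a K x B one-hot),
//       1 = regression (MSE over all K * B entries; Y is K x B).
static double loss_and_dout(int task, const mat& O, const mat& Y, mat& dO,
                            mat& prob) {
  const uword B = O.n_cols, K = O.n_rows;
  if (task == 0) {
    prob = softmax_cols(O);
    double loss = -accu(Y % log(prob + 1e-12)) / (double)B;
    dO = (prob - Y) / (double)B;
    return loss;
  }
  prob = O;
  mat diff = O - Y;
  dO = 2.0 * diff / (double)(B * K);
  return accu(diff % diff) / (double)(B * K);
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_forward(Rcpp::List params, arma::cube X, int task) {
  Params q = unpack(params);
  Forward fw;
  forward_pass(q, X, cube(), mat(), fw);
  mat out = (task == 0) ? softmax_cols(fw.out) : fw.out;
  return Rcpp::List::create(Rcpp::Named("output") = out);
}

// [[Rcpp::export]]
double cpp_bilstm_loss(Rcpp::List params, arma::cube X, arma::mat Y, int task) {
  Params q = unpack(params);
  Forward fw;
  forward_pass(q, X, cube(), mat(), fw);
  mat dO, prob;
  return loss_and_dout(task, fw.out, Y, dO, prob);
}

// [[Rcpp::export]]
Rcpp::List cpp_bilstm_grad(Rcpp::List params, arma::cube X, arma::mat Y,
                           int task, Rcpp::Nullable<Rcpp::NumericVector> mask1_,
                           Rcpp::Nullable<Rcpp::NumericMatrix> mask2_) {
  Params q = unpack(params);
  const uword B = X.n_cols, T = X.n_slices;
  const uword H1 = q.U1f.n_cols, H2 = q.U2f.n_cols;
  cube mask1;
  mat mask2;
  if (mask1_.isNotNull()) {
    Rcpp::NumericVector mv(mask1_);
    Rcpp::IntegerVector dims = mv.attr("dim");
    mask1 = cube(mv.begin(), dims[0], dims[1], dims[2]);
  }
  if (mask2_.isNotNull()) mask2 = Rcpp::as<mat>(Rcpp::NumericMatrix(mask2_));

  Forward fw;
  forward_pass(q, X, mask1, mask2, fw);
  mat dO, prob;
  double loss = loss_and_dout(task, fw.out, Y, dO, prob);

  // head
  mat dWo = dO * fw.dense.t();
  vec dbo = sum(dO, 1);
  mat dDense = q.Wo.t() * dO;
  dDense.elem(find(fw.dense_pre <= 0)).zeros(); // ReLU gate
  mat dWd = dDense * fw.last_drop.t();
  vec dbd = sum(dDense, 1);
  mat dLast = q.Wd.t() * dDense;
  if (!mask2.is_empty()) dLast %= mask2;

  // split the last-state gradient into the two layer-2 directions
  cube dH2f(H2, B, T, fill::zeros), dH2b(H2, B, T, fill::zeros);
  dH2f.slice(T - 1) = dLast.rows(0, H2 - 1);
  dH2b.slice(0) = dLast.rows(H2, 2 * H2 - 1);

  mat dW2f, dU2f, dW2b, dU2b; vec db2f, db2b;
  cube dH1 = lstm_backward(fw.h1drop, q.W2f, q.U2f, false, fw.c2f, dH2f,
                           dW2f, dU2f, db2f);
  dH1 += lstm_backward(fw.h1drop, q.W2b, q.U2b, true, fw.c2b, dH2b,
                       dW2b, dU2b, db2b);
  if (!mask1.is_empty()) dH1 %= mask1;

  cube dH1f = dH1.tube(0, 0, H1 - 1, B - 1);
  cube dH1b = dH1.tube(H1, 0, 2 * H1 - 1, B - 1);
  mat dW1f, dU1f, dW1b, dU1b; vec db1f, db1b;
  lstm_backward(X, q.W1f, q.U1f, false, fw.c1f, dH1f, dW1f, dU1f, db1f);
  lstm_backward(X, q.W1b, q.U1b, true, fw.c1b, dH1b, dW1b, dU1b, db1b);

  Rcpp::List grads = Rcpp::List::create(
    Rcpp::Named("W1f") = dW1f, Rcpp::Named("U1f") = dU1f, Rcpp::Named("b1f") = db1f,
    Rcpp::Named("W1b") = dW1b, Rcpp::Named("U1b") = dU1b, Rcpp::Named("b1b") = db1b,
    Rcpp::Named("W2f") = dW2f, Rcpp::Named("U2f") = dU2f, Rcpp::Named("b2f") = db2f,
    Rcpp::Named("W2b") = dW2b, Rcpp::Named("U2b") = dU2b, Rcpp::Named("b2b") = db2b,
    Rcpp::Named("Wd") = dWd, Rcpp::Named("bd") = dbd,
    Rcpp::Named("Wo") = dWo, Rcpp::Named("bo") = dbo);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}
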