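// 1D-CNN forward/backward passes and the Adam training loop.
//
// Batch activations are kept in a (sample, position) x filter layout:
// row index (t - 1) * B + b for sample b at position t. In that layout a
// valid convolution is one im2col + one GEMM, the im2col row ranges are
// contiguous, and the flatten step is a no-copy reshape. All randomness
// (mini-batch order, dropout masks) is drawn from R's RNG so fits are
// reproducible from set.seed / the config seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat relu(const mat& z) {
  mat a = z;
  a.for_each([](double& v) { if (v < 0) v = 0; });
  return a;
}

// zero the entries of g where z <= 0, in place
static inline void relu_grad(mat& g, const mat& z) {
  const double* zp = z.memptr();
  double* gp = g.memptr();
  for (uword i = 0; i < g.n_elem; ++i)
    if (zp[i] <= 0) gp[i] = 0;
}

// im2col for the first convolution: batch (B x L) -> (B*L1) x k
static mat im2col_input(const mat& Xb, int k, int L1) {
  mat out(Xb.n_rows * L1, k);
  for (int j = 0; j < k; ++j)
    out.col(j) = vectorise(Xb.cols(j, j + L1 - 1));
  return out;
}

// im2col for the second convolution: (B*L1p) x nf -> (B*L2) x (k*nf);
// shift-j windows are contiguous row ranges in this layout.
static mat im2col_stack(const mat& P, int B, int L2, int k) {
  int nf = P.n_cols;
  mat out(B * L2, k * nf);
  for (int j = 0; j < k; ++j)
    out.cols(j * nf, (j + 1) * nf - 1) = P.rows(j * B, j * B + B * L2 - 1);
  return out;
}

// Non-overlapping max pool with argmax (for backprop).
static void maxpool(const mat& A, int B, int Lp, int p, mat& P, umat& amax) {
  int nf = A.n_cols;
  P.set_size(B * Lp, nf);
  amax.set_size(B * Lp, nf);
  for (int f = 0; f < nf; ++f) {
    const double* a = A.colptr(f);
    double* pp = P.colptr(f);
    uword* am = amax.colptr(f);
    for (int tau = 0; tau < Lp; ++tau) {
      for (int b = 0; b < B; ++b) {
        int base = tau * p * B + b;
        double best = a[base];
        uword bi = 0;
        for (int j = 1; j < p; ++j) {
          double v = a[base + j * B];
          if (v > best) { best = v; bi = j; }
        }
        pp[tau * B + b] = best;
        am[tau * B + b] = bi;
      }
    }
  }
}

static void maxpool_backward(const mat& dP, const umat& amax,
                             int B, int Lp, int p, int Lfull, mat& dA) {
  int nf = dP.n_cols;
  dA.zeros(B * Lfull, nf);
  for (int f = 0; f < nf; ++f) {
    const double* dp = dP.colptr(f);
    const uword* am = amax.colptr(f);
    double* da = dA.colptr(f);
    for (int tau = 0; tau < Lp; ++tau)
      for (int b = 0; b < B; ++b) {
        int i = tau * B + b;
        da[(tau * p + am[i]) * B + b] += dp[i];
      }
  }
}

static void softmax_rows(mat& A) {
  for (uword i = 0; i < A.n_rows; ++i) {
    rowvec r = A.row(i);
    r -= r.max();
    r = exp(r);
    A.row(i) = r / accu(r);
  }
}

struct Weights {
  mat W1, W2, W3, W4;
  rowvec b1, b2, b3, b4;
};

static Weights unpack(const List& w) {
  Weights out;
  out.W1 = as<mat>(w["W1"]); out.W2 = as<mat>(w["W2"]);
  out.W3 = as<mat>(w["W3"]); out.W4 = as<mat>(w["W4"]);
  out.b1 = as<rowvec>(w["b1"]); out.b2 = as<rowvec>(w["b2"]);
  out.b3 = as<rowvec>(w["b3"]); out.b4 = as<rowvec>(w["b4"]);
  return out;
}

struct Sizes {
  int L, L1, L1p, L2, L2p;
};

static Sizes layer_sizes(int L, int k, int p) {
  Sizes s;
  s.L = L;
  s.L1 = L - k + 1;
  s.L1p = s.L1 / p;
  s.L2 = s.L1p - k + 1;
  s.L2p = s.L2 / p;
  if (s.L1 < 1 || s.L1p < 1 || s.L2 < 1 || s.L2p < 1)
    stop("input too short for the network stack");
  return s;
}

// Lean forward pass for a batch; returns softmax scores, optionally the
// dense-layer activations (features).
static mat forward_scores(const mat& Xb, const Weights& w, const Sizes& s,
                          int k, int p, bool relu_out, mat* features) {
  int B = Xb.n_rows;
  mat A1 = im2col_input(Xb, k, s.L1) * w.W1;
  A1.each_row() += w.b1;
  A1 = relu(A1);
  mat P1; umat am1;
  maxpool(A1, B, s.L1p, p, P1, am1);
  mat A2 = im2col_stack(P1, B, s.L2, k) * w.W2;
  A2.each_row() += w.b2;
  A2 = relu(A2);
  mat P2; umat am2;
  maxpool(A2, B, s.L2p, p, P2, am2);
  mat Fl(P2.memptr(), B, s.L2p * w.W1.n_cols, true);
  mat A3 = Fl * w.W3;
  A3.each_row() += w.b3;
  A3 = relu(A3);
  if (features) *features = A3;
  mat Z4 = A3 * w.W4;
  Z4.each_row() += w.b4;
  mat A4 = relu_out ? relu(Z4) : Z4;
  softmax_rows(A4);
  return A4;
}

// [[Rcpp::export]]
arma::mat cnn_scores_cpp(const arma::mat& X, List w_, bool relu_out,
                         int k, int p, int chunk = 128) {
  Weights w = unpack(w_);
  Sizes s = layer_sizes(X.n_cols, k, p);
  int nc = w.W4.n_cols;
  mat out(X.n_rows, nc);
  for (uword start = 0; start < X.n_rows; start += chunk) {
    uword end = std::min<uword>(start + chunk, X.n_rows) - 1;
    out.rows(start, end) =
      forward_scores(X.rows(start, end), w, s, k, p, relu_out, nullptr);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cnn_features_cpp(const arma::mat& X, List w_, bool relu_out,
                           int k, int p, int chunk = 128) {
  Weights w = unpack(w_);
  Sizes s = layer_sizes(X.n_cols, k, p);
  mat out(X.n_rows, w.W3.n_cols);
  for (uword start = 0; start < X.n_rows; start += chunk) {
    uword end = std::min<uword>(start + chunk, X.n_rows) - 1;
    mat feats;
    forward_scores(X.rows(start, end), w, s, k, p, relu_out, &feats);
    out.rows(start, end) = feats;
  }
  return out;
}

struct Adam {
  mat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4;
  rowvec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Weights& w) {
    mW1 = zeros(size(w.W1)); vW1 = mW1;
    mW2 = zeros(size(w.W2)); vW2 = mW2;
    mW3 = zeros(size(w.W3)); vW3 = mW3;
    mW4 = zeros(size(w.W4)); vW4 = mW4;
    mb1 = zeros<rowvec>(w.b1.n_elem); vb1 = mb1;
    mb2 = zeros<rowvec>(w.b2.n_elem); vb2 = mb2;
    mb3 = zeros<rowvec>(w.b3.n_elem); vb3 = mb3;
    mb4 = zeros<rowvec>(w.b4.n_elem); vb4 = mb4;
  }
  template <typename T>
  void step1(T& w, T& m, T& v, const T& g, double lr) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    T mh = m / (1 - std::pow(b1, (double)t));
    T vh = v / (1 - std::pow(b2, (double)t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
};

// [[Rcpp::export]]
List cnn_train_cpp(const arma::mat& X, const arma::ivec& y, List w_,
                   int epochs, int batch_size, double lr,
                   double dropout_rate, bool relu_out, int k, int p,
                   int n_classes,
                   Rcpp::Nullable<Rcpp::NumericMatrix> Xtest_ = R_NilValue,
                   Rcpp::Nullable<Rcpp::IntegerVector> ytest_ = R_NilValue) {
  Weights w = unpack(w_);
  Sizes s = layer_sizes(X.n_cols, k, p);
  int n = X.n_rows, nf = w.W1.n_cols;
  bool has_test = Xtest_.isNotNull();
  mat Xte; ivec yte;
  if (has_test) {
    Xte = as<mat>(Xtest_.get());
    yte = as<ivec>(IntegerVector(ytest_.get()));
  }
  Adam opt;
  opt.init(w);
  double keep = 1.0 - dropout_rate;
  mat history(epochs, 4);
  history.fill(datum::nan);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    IntegerVector ord = Rcpp::sample(n, n, false) - 1;  // R RNG
    double loss_sum = 0, acc_sum = 0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(start + batch_size, n);
      int B = end - start;
      uvec idx(B);
      for (int i = 0; i < B; ++i) idx[i] = ord[start + i];
      mat Xb = X.rows(idx);
      ivec yb = y.elem(idx);

      // ---- forward with caches ----
      mat Xcol1 = im2col_input(Xb, k, s.L1);
      mat Z1 = Xcol1 * w.W1;
      Z1.each_row() += w.b1;
      mat A1 = relu(Z1);
      mat P1; umat am1;
      maxpool(A1, B, s.L1p, p, P1, am1);
      mat Xcol2 = im2col_stack(P1, B, s.L2, k);
      mat Z2 = Xcol2 * w.W2;
      Z2.each_row() += w.b2;
      mat A2 = relu(Z2);
      mat P2; umat am2;
      maxpool(A2, B, s.L2p, p, P2, am2);
      mat Fl(P2.memptr(), B, s.L2p * nf, true);
      mat Z3 = Fl * w.W3;
      Z3.each_row() += w.b3;
      mat A3 = relu(Z3);
      mat mask;
      mat D = A3;
      if (dropout_rate > 0) {
        NumericVector u = Rcpp::runif(B * w.W3.n_cols);  // R RNG
        mask.set_size(B, w.W3.n_cols);
        std::copy(u.begin(), u.end(), mask.memptr());
        mask.transform([&](double v) { return v < keep ? 1.0 / keep : 0.0; });
        D = A3 % mask;
      }
      mat Z4 = D * w.W4;
      Z4.each_row() += w.b4;
      mat S = relu_out ? relu(Z4) : Z4;
      softmax_rows(S);
      if (!S.is_finite()) stop("divergent loss: non-finite activations");

      // batch metrics
      double bl = 0; int bc = 0;
      for (int i = 0; i < B; ++i) {
        bl -= std::log(std::max(S(i, yb[i]), 1e-12));
        uword arg;
        S.row(i).max(arg);
        if ((int)arg == yb[i]) ++bc;
      }
      loss_sum += bl;
      acc_sum += bc;

      // ---- backward ----
      mat Y = zeros(B, n_classes);
      for (int i = 0; i < B; ++i) Y(i, yb[i]) = 1.0;
      mat dZ4 = (S - Y) / B;
      if (relu_out) relu_grad(dZ4, Z4);
      mat gW4 = D.t() * dZ4;
      rowvec gb4 = sum(dZ4, 0);
      mat dA3 = dZ4 * w.W4.t();
      if (dropout_rate > 0) dA3 %= mask;
      mat dZ3 = dA3;
      relu_grad(dZ3, Z3);
      mat gW3 = Fl.t() * dZ3;
      rowvec gb3 = sum(dZ3, 0);
      mat dFl = dZ3 * w.W3.t();
      mat dP2(dFl.memptr(), B * s.L2p, nf, true);
      mat dA2;
      maxpool_backward(dP2, am2, B, s.L2p, p, s.L2, dA2);
      mat dZ2 = dA2;
      relu_grad(dZ2, Z2);
      mat gW2 = Xcol2.t() * dZ2;
      rowvec gb2 = sum(dZ2, 0);
      mat dXcol2 = dZ2 * w.W2.t();
      mat dP1 = zeros(B * s.L1p, nf);
      for (int j = 0; j < k; ++j)
        dP1.rows(j * B, j * B + B * s.L2 - 1) +=
          dXcol2.cols(j * nf, (j + 1) * nf - 1);
      mat dA1;
      maxpool_backward(dP1, am1, B, s.L1p, p, s.L1, dA1);
      mat dZ1 = dA1;
      relu_grad(dZ1, Z1);
      mat gW1 = Xcol1.t() * dZ1;
      rowvec gb1 = sum(dZ1, 0);

      // ---- Adam update ----
      opt.t += 1;
      opt.step1(w.W1, opt.mW1, opt.vW1, gW1, lr);
      opt.step1(w.b1, opt.mb1, opt.vb1, gb1, lr);
      opt.step1(w.W2, opt.mW2, opt.vW2, gW2, lr);
      opt.step1(w.b2, opt.mb2, opt.vb2, gb2, lr);
      opt.step1(w.W3, opt.mW3, opt.vW3, gW3, lr);
      opt.step1(w.b3, opt.mb3, opt.vb3, gb3, lr);
      opt.step1(w.W4, opt.mW4, opt.vW4, gW4, lr);
      opt.step1(w.b4, opt.mb4, opt.vb4, gb4, lr);
    }
    history(epoch, 0) = loss_sum / n;
    history(epoch, 1) = acc_sum / n;
    if (has_test) {
      mat Ste(Xte.n_rows, n_classes);
      for (uword st = 0; st < Xte.n_rows; st += 128) {
        uword en = std::min<uword>(st + 128, Xte.n_rows) - 1;
        Ste.rows(st, en) =
          forward_scores(Xte.rows(st, en), w, s, k, p, relu_out, nullptr);
      }
      double tl = 0; int tc = 0;
      for (uword i = 0; i < Xte.n_rows; ++i) {
        tl -= std::log(std::max(Ste(i, yte[i]), 1e-12));
        uword arg;
        Ste.row(i).max(arg);
        if ((int)arg == yte[i]) ++tc;
      }
      history(epoch, 2) = tl / Xte.n_rows;
      history(epoch, 3) = (double)tc / Xte.n_rows;
    }
  }
  return List::create(
    _["weights"] = List::create(
      _["W1"] = w.W1, _["b1"] = w.b1, _["W2"] = w.W2, _["b2"] = w.b2,
      _["W3"] = w.W3, _["b3"] = w.b3, _["W4"] = w.W4, _["b4"] = w.b4),
    _["history"] = history);
}
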