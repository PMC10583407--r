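// Core numerics for the log-linearized Gaussian mixture network (LLGMN)
// and its sparse variant with an elementwise L1-gated reduction layer.
//
// Layout conventions (mirrored by the R wrappers):
//  * expanded vector of a D-input: (1, y_1..y_D, y_i*y_j for i<=j row-major),
//    H = 1 + D + D(D+1)/2
//  * LLGMN weights: H x (C*M); unit (c,m) lives in column (c-1)*M + m - 1;
//    the last column (class C, component M) is the identifiability anchor,
//    pinned at zero by zeroing its gradient.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double POST_CLIP = 1e-12;

// quadratic log-linearization expansion of an N x D matrix
// [[Rcpp::export]]
arma::mat cpp_expand(const arma::mat& Y) {
  const uword N = Y.n_rows, D = Y.n_cols;
  const uword H = 1 + D + D * (D + 1) / 2;
  mat X(N, H);
  X.col(0).ones();
  X.cols(1, D) = Y;
  uword h = D + 1;
  for (uword i = 0; i < D; ++i)
    for (uword j = i; j < D; ++j)
      X.col(h++) = Y.col(i) % Y.col(j);
  return X;
}

// softmax over units with max-subtraction; returns N x K unit outputs
static mat unit_softmax(const mat& A) {
  mat U = A.each_col() - max(A, 1);
  U = exp(U);
  U.each_col() /= sum(U, 1);
  return U;
}

static mat class_posterior(const mat& U, const uword C, const uword M) {
  mat P(U.n_rows, C);
  for (uword c = 0; c < C; ++c)
    P.col(c) = sum(U.cols(c * M, c * M + M - 1), 1);
  return P;
}

// [[Rcpp::export]]
Rcpp::List cpp_forward(const arma::mat& X, const arma::mat& W, const int M) {
  const uword C = W.n_cols / M;
  mat U = unit_softmax(X * W);
  mat P = class_posterior(U, C, M);
  return Rcpp::List::create(Rcpp::Named("posterior") = P,
                            Rcpp::Named("units") = U);
}

static double ce_loss(const mat& P, const mat& T) {
  mat Pc = clamp(P, POST_CLIP, 1.0);
  return -accu(T % log(Pc));
}

// [[Rcpp::export]]
double cpp_cross_entropy(const arma::mat& X, const arma::mat& W, const int M,
                         const arma::mat& T) {
  const uword C = T.n_cols;
  mat U = unit_softmax(X * W);
  return ce_loss(class_posterior(U, C, M), T);
}

// dE/da for the unit activations; E = cross-entropy of class posteriors
static mat unit_delta(const mat& U, const mat& P, const mat& T, const uword M) {
  const uword C = T.n_cols;
  mat Pc = clamp(P, POST_CLIP, 1.0);
  mat R = T / Pc;                       // N x C
  mat D(U.n_rows, U.n_cols);
  for (uword c = 0; c < C; ++c) {
    mat block = U.cols(c * M, c * M + M - 1);
    block.each_col() %= (1.0 - R.col(c));
    D.cols(c * M, c * M + M - 1) = block;
  }
  return D;
}

// [[Rcpp::export]]
arma::mat cpp_gradient(const arma::mat& X, const arma::mat& W, const int M,
                       const arma::mat& T) {
  mat U = unit_softmax(X * W);
  mat P = class_posterior(U, T.n_cols, M);
  mat G = X.t() * unit_delta(U, P, T, M);
  G.col(G.n_cols - 1).zeros();          // anchor unit stays pinned
  return G;
}

// backprop through the quadratic expansion to the reduced inputs y,
// then to the gate weights w (y = w .* x elementwise)
static vec gate_gradient(const mat& Xraw, const mat& Yred, const mat& dX) {
  const uword D = Yred.n_cols;
  mat dY(Yred.n_rows, D, fill::zeros);
  for (uword i = 0; i < D; ++i) dY.col(i) = dX.col(1 + i);
  uword h = D + 1;
  for (uword i = 0; i < D; ++i)
    for (uword j = i; j < D; ++j) {
      if (i == j) {
        dY.col(i) += 2.0 * dX.col(h) % Yred.col(i);
      } else {
        dY.col(i) += dX.col(h) % Yred.col(j);
        dY.col(j) += dX.col(h) % Yred.col(i);
      }
      ++h;
    }
  return sum(dY % Xraw, 0).t();
}

// [[Rcpp::export]]
arma::vec cpp_gate_gradient(const arma::mat& Xraw, const arma::vec& w,
                            const arma::mat& W, const int M,
                            const arma::mat& T) {
  mat Yred = Xraw.each_row() % w.t();
  mat X = cpp_expand(Yred);
  mat U = unit_softmax(X * W);
  mat P = class_posterior(U, T.n_cols, M);
  mat dX = unit_delta(U, P, T, M) * W.t();
  return gate_gradient(Xraw, Yred, dX);
}

static void soft_threshold(vec& w, const double t) {
  for (uword i = 0; i < w.n_elem; ++i) {
    double a = std::abs(w(i)) - t;
    w(i) = a > 0.0 ? (w(i) > 0.0 ? a : -a) : 0.0;
  }
}

// Cyclic coordinate descent for the Lasso objective
//   (1/2N) ||y - b0 - X b||^2 + lambda ||b||_1
// with centered predictors (so b0 = mean(y) stays optimal).  Stops when the
// largest coefficient change in a sweep falls below tol.
// [[Rcpp::export]]
Rcpp::List cpp_lasso_cd(const arma::mat& X, const arma::vec& y,
                        const double lambda, const arma::vec& beta_init,
                        const double tol, const int max_iter) {
  const uword n = X.n_rows, p = X.n_cols;
  vec v(p);
  for (uword j = 0; j < p; ++j) v(j) = dot(X.col(j), X.col(j)) / n;
  vec beta = beta_init;
  const double b0 = mean(y);
  vec r = y - b0 - X * beta;
  int iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    double delta_max = 0.0;
    for (uword j = 0; j < p; ++j) {
      if (v(j) <= 0.0) continue;
      const double bj = beta(j);
      const double z = v(j) * bj + dot(X.col(j), r) / n;
      double bnew = std::abs(z) - lambda;
      bnew = bnew > 0.0 ? (z > 0.0 ? bnew : -bnew) / v(j) : 0.0;
      if (bnew != bj) {
        r -= X.col(j) * (bnew - bj);
        beta(j) = bnew;
        delta_max = std::max(delta_max, std::abs(bnew - bj));
      }
    }
    ++iters;
    if (delta_max < tol) break;
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("intercept") = b0,
                            Rcpp::Named("iters") = iters);
}

// expansion-space scaling vector of the gate w: the expansion of w .* x
// equals the expansion of x scaled columnwise by (1, w_i, w_i * w_j)
static vec gate_scaling(const vec& w) {
  const uword D = w.n_elem;
  vec sw(1 + D + D * (D + 1) / 2);
  sw(0) = 1.0;
  sw.subvec(1, D) = w;
  uword h = D + 1;
  for (uword i = 0; i < D; ++i)
    for (uword j = i; j < D; ++j)
      sw(h++) = w(i) * w(j);
  return sw;
}

// Mini-batch proximal SGD shared by plain and sparse training.
// When train_gate is false the gate w is frozen at its initial value
// (ones) and no proximal step is taken, which reduces to plain LLGMN
// training on the raw inputs.  The quadratic expansion of the raw data is
// computed once; gating only rescales its columns.
// [[Rcpp::export]]
Rcpp::List cpp_train(const arma::mat& Xraw, const arma::mat& T, const int M,
                     const bool train_gate, const arma::vec& w_init,
                     const double lambda, const double lr, const int batch_size,
                     const int max_epochs, const double min_delta,
                     const int patience, const int seed) {
  const uword N = Xraw.n_rows, D = Xraw.n_cols, C = T.n_cols;
  const uword H = 1 + D + D * (D + 1) / 2, K = C * M;

  vec w = w_init;
  mat W(H, K, fill::zeros);
  const mat E = cpp_expand(Xraw);          // N x H, reused throughout

  auto full_energy = [&](const vec& wv, const mat& Wv) {
    mat X = train_gate ? mat(E.each_row() % gate_scaling(wv).t()) : E;
    mat U = unit_softmax(X * Wv);
    double e = ce_loss(class_posterior(U, C, M), T);
    if (train_gate) e += lambda * accu(abs(wv));
    return e;
  };

  double best = full_energy(w, W);
  vec best_w = w;
  mat best_W = W;
  std::vector<double> trace;
  trace.reserve(max_epochs > 0 ? max_epochs : 1);

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<uword> idx(N);
  for (uword i = 0; i < N; ++i) idx[i] = i;

  const uword B = std::max<uword>(1, std::min<uword>(batch_size, N));
  int bad = 0, epochs_run = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (uword start = 0; start < N; start += B) {
      const uword stop = std::min<uword>(start + B - 1, N - 1);
      uvec rows(stop - start + 1);
      for (uword r = 0; r < rows.n_elem; ++r) rows(r) = idx[start + r];
      mat Eb = E.rows(rows);
      mat Tb = T.rows(rows);
      mat X = train_gate ? mat(Eb.each_row() % gate_scaling(w).t()) : Eb;
      mat U = unit_softmax(X * W);
      mat P = class_posterior(U, C, M);
      mat Dm = unit_delta(U, P, Tb, M);
      mat GW = X.t() * Dm;
      GW.col(K - 1).zeros();
      if (train_gate) {
        mat dX = Dm * W.t();
        mat Xb = Xraw.rows(rows);
        mat Yred = Xb.each_row() % w.t();
        vec gw = gate_gradient(Xb, Yred, dX);
        w -= lr * gw;
        soft_threshold(w, lr * lambda);
      }
      W -= lr * GW;
    }
    ++epochs_run;
    double e = full_energy(w, W);
    trace.push_back(e);
    if (best - e > min_delta) {
      best = e;
      best_w = w;
      best_W = W;
      bad = 0;
    } else {
      if (e < best) { best = e; best_w = w; best_W = W; }
      ++bad;
      if (bad > patience) break;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("W") = best_W, Rcpp::Named("w") = best_w,
      Rcpp::Named("loss") = best, Rcpp::Named("epochs") = epochs_run,
      Rcpp::Named("trace") = trace);
}
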