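// 1D convolutional network for spectra classification.
//
// Topology: three (valid convolution -> ReLU -> non-overlapping max pool)
// blocks, flatten, one affine projection to class scores, softmax
// (multiclass) or sigmoid (binary). Trained full-batch with ADAM and
// cross-entropy loss; training stops when the training loss has not
// decreased for `patience` epochs or at `max_epochs`.
//
// Convolutions are evaluated as im2col matrix products so the heavy work
// runs through BLAS. Activations are cubes (samples x positions x
// channels).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct LayerCache {
  mat im2col;   // (T_out*N) x (K*C)
  cube pre;     // pre-activation (N x T_out x F)
  ucube poolidx; // chosen index (0 or 1) within each pool window
  cube pooled;  // post-pool activation
};

mat build_im2col(const cube& A, int K) {
  const int N = A.n_rows, T = A.n_cols, C = A.n_slices;
  const int Tout = T - K + 1;
  mat M(Tout * N, K * C);
  for (int c = 0; c < C; ++c) {
    const mat& S = A.slice(c);
    for (int k = 0; k < K; ++k) {
      for (int t = 0; t < Tout; ++t) {
        M.col(c * K + k).subvec(t * N, t * N + N - 1) = S.col(t + k);
      }
    }
  }
  return M;
}

cube mat_to_cube(const mat& Z, int N, int Tout) {
  const int F = Z.n_cols;
  cube out(N, Tout, F);
  for (int f = 0; f < F; ++f) {
    for (int t = 0; t < Tout; ++t) {
      out.slice(f).col(t) = Z.col(f).subvec(t * N, t * N + N - 1);
    }
  }
  return out;
}

mat cube_to_mat(const cube& D) {
  const int N = D.n_rows, Tout = D.n_cols, F = D.n_slices;
  mat Z(Tout * N, F);
  for (int f = 0; f < F; ++f) {
    for (int t = 0; t < Tout; ++t) {
      Z.col(f).subvec(t * N, t * N + N - 1) = D.slice(f).col(t);
    }
  }
  return Z;
}

cube col2im(const mat& dM, int N, int T, int C, int K) {
  const int Tout = T - K + 1;
  cube dA(N, T, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < K; ++k) {
      for (int t = 0; t < Tout; ++t) {
        dA.slice(c).col(t + k) += dM.col(c * K + k).subvec(t * N, t * N + N - 1);
      }
    }
  }
  return dA;
}

// forward through one conv->ReLU->pool block; pool size fixed at 2
cube block_forward(const cube& A, const mat& W, const rowvec& b, int K,
                   LayerCache& cache) {
  const int N = A.n_rows;
  const int Tout = A.n_cols - K + 1;
  cache.im2col = build_im2col(A, K);
  mat Z = cache.im2col * W;
  Z.each_row() += b;
  cache.pre = mat_to_cube(Z, N, Tout);
  const int F = W.n_cols;
  const int P = Tout / 2;
  cache.pooled.set_size(N, P, F);
  cache.poolidx.set_size(N, P, F);
  for (int f = 0; f < F; ++f) {
    mat relu = cache.pre.slice(f);
    relu.transform([](double v) { return v > 0.0 ? v : 0.0; });
    for (int p = 0; p < P; ++p) {
      const vec a = relu.col(2 * p);
      const vec bcol = relu.col(2 * p + 1);
      for (int n = 0; n < N; ++n) {
        if (a(n) >= bcol(n)) {  // ties -> earlier position
          cache.pooled(n, p, f) = a(n);
          cache.poolidx(n, p, f) = 0;
        } else {
          cache.pooled(n, p, f) = bcol(n);
          cache.poolidx(n, p, f) = 1;
        }
      }
    }
  }
  return cache.pooled;
}

// backward through one block; returns gradient wrt the block input
cube block_backward(const cube& dPooled, const LayerCache& cache,
                    const mat& W, int K, int Tin, int Cin,
                    mat& dW, rowvec& db) {
  const int N = dPooled.n_rows, P = dPooled.n_cols, F = dPooled.n_slices;
  const int Tout = cache.pre.n_cols;
  cube dZ(N, Tout, F, fill::zeros);
  for (int f = 0; f < F; ++f) {
    for (int p = 0; p < P; ++p) {
      for (int n = 0; n < N; ++n) {
        const int t = 2 * p + cache.poolidx(n, p, f);
        if (cache.pre(n, t, f) > 0.0) dZ(n, t, f) = dPooled(n, p, f);
      }
    }
  }
  mat dZmat = cube_to_mat(dZ);
  dW = cache.im2col.t() * dZmat;
  db = sum(dZmat, 0);
  mat dM = dZmat * W.t();
  return col2im(dM, N, Tin, Cin, K);
}

mat flatten(const cube& A) {
  const int N = A.n_rows, P = A.n_cols, F = A.n_slices;
  mat H(N, P * F);
  for (int f = 0; f < F; ++f) {
    for (int p = 0; p < P; ++p) H.col(f * P + p) = A.slice(f).col(p);
  }
  return H;
}

cube unflatten(const mat& dH, int N, int P, int F) {
  cube dA(N, P, F);
  for (int f = 0; f < F; ++f) {
    for (int p = 0; p < P; ++p) dA.slice(f).col(p) = dH.col(f * P + p);
  }
  return dA;
}

mat softmax_rows(const mat& logits) {
  mat z = logits;
  z.each_col() -= max(z, 1);
  z = exp(z);
  z.each_col() /= sum(z, 1);
  return z;
}

struct Net {
  mat W1, W2, W3, Wd;
  rowvec b1, b2, b3, bd;
  int K;
  bool binary;
};

Net net_from_list(const Rcpp::List& weights, int K, bool binary) {
  Net net;
  net.W1 = Rcpp::as<mat>(weights["W1"]);
  net.b1 = Rcpp::as<rowvec>(weights["b1"]);
  net.W2 = Rcpp::as<mat>(weights["W2"]);
  net.b2 = Rcpp::as<rowvec>(weights["b2"]);
  net.W3 = Rcpp::as<mat>(weights["W3"]);
  net.b3 = Rcpp::as<rowvec>(weights["b3"]);
  net.Wd = Rcpp::as<mat>(weights["Wd"]);
  net.bd = Rcpp::as<rowvec>(weights["bd"]);
  net.K = K;
  net.binary = binary;
  return net;
}

// full forward pass; caches are only filled when `caches` is non-null
mat net_forward(const Net& net, const mat& X, LayerCache* caches) {
  LayerCache local[3];
  LayerCache* c = caches ? caches : local;
  cube A0(X.n_rows, X.n_cols, 1);
  A0.slice(0) = X;
  cube A1 = block_forward(A0, net.W1, net.b1, net.K, c[0]);
  cube A2 = block_forward(A1, net.W2, net.b2, net.K, c[1]);
  cube A3 = block_forward(A2, net.W3, net.b3, net.K, c[2]);
  mat H = flatten(A3);
  mat logits = H * net.Wd;
  logits.each_row() += net.bd;
  if (net.binary) return 1.0 / (1.0 + exp(-logits));
  return softmax_rows(logits);
}

double ce_loss(const mat& probs, const uvec& y, bool binary) {
  const double eps = 1e-12;
  double loss = 0.0;
  if (binary) {
    for (uword n = 0; n < y.n_elem; ++n) {
      const double p = std::min(std::max(probs(n, 0), eps), 1.0 - eps);
      loss += y(n) == 1 ? -std::log(p) : -std::log(1.0 - p);
    }
  } else {
    for (uword n = 0; n < y.n_elem; ++n) {
      loss += -std::log(std::max(probs(n, y(n)), eps));
    }
  }
  return loss / y.n_elem;
}

double accuracy(const mat& probs, const uvec& y, bool binary) {
  uword correct = 0;
  for (uword n = 0; n < y.n_elem; ++n) {
    uword pred;
    if (binary) {
      pred = probs(n, 0) > 0.5 ? 1 : 0;
    } else {
      pred = index_max(probs.row(n));  // first max: lowest class index
    }
    if (pred == y(n)) ++correct;
  }
  return double(correct) / y.n_elem;
}

struct Adam {
  mat m, v;
  Adam(int r, int c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    mat mh = m / (1 - std::pow(b1, t));
    mat vh = v / (1 - std::pow(b2, t));
    w -= lr * mh / (sqrt(vh) + eps);
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(const arma::mat& X, const arma::uvec& y,
                         const arma::mat& Xval, const arma::uvec& yval,
                         Rcpp::List weights, int kernel_size,
                         double learning_rate, int max_epochs,
                         int patience, bool binary) {
  Net net = net_from_list(weights, kernel_size, binary);
  const int N = X.n_rows;
  const int n_out = net.Wd.n_cols;
  const bool has_val = Xval.n_rows > 0;

  mat onehot;
  if (!binary) {
    onehot.zeros(N, n_out);
    for (int n = 0; n < N; ++n) onehot(n, y(n)) = 1.0;
  }

  Adam aW1(net.W1.n_rows, net.W1.n_cols), aW2(net.W2.n_rows, net.W2.n_cols),
      aW3(net.W3.n_rows, net.W3.n_cols), aWd(net.Wd.n_rows, net.Wd.n_cols);
  Adam ab1(1, net.b1.n_elem), ab2(1, net.b2.n_elem), ab3(1, net.b3.n_elem),
      abd(1, net.bd.n_elem);

  std::vector<double> tr_loss, tr_acc, va_loss, va_acc;
  tr_loss.reserve(max_epochs);
  double best_loss = datum::inf;
  int since_improve = 0;
  int epoch = 0;

  for (epoch = 0; epoch < max_epochs; ++epoch) {
    LayerCache caches[3];
    cube A0(N, X.n_cols, 1);
    A0.slice(0) = X;
    cube A1 = block_forward(A0, net.W1, net.b1, net.K, caches[0]);
    cube A2 = block_forward(A1, net.W2, net.b2, net.K, caches[1]);
    cube A3 = block_forward(A2, net.W3, net.b3, net.K, caches[2]);
    mat H = flatten(A3);
    mat logits = H * net.Wd;
    logits.each_row() += net.bd;
    mat probs = binary ? mat(1.0 / (1.0 + exp(-logits))) : softmax_rows(logits);

    const double loss = ce_loss(probs, y, binary);
    tr_loss.push_back(loss);
    tr_acc.push_back(accuracy(probs, y, binary));
    if (has_val) {
      mat pv = net_forward(net, Xval, nullptr);
      va_loss.push_back(ce_loss(pv, yval, binary));
      va_acc.push_back(accuracy(pv, yval, binary));
    }

    // gradient of the mean cross-entropy wrt logits
    mat dlogits;
    if (binary) {
      dlogits = probs;
      for (int n = 0; n < N; ++n) dlogits(n, 0) -= double(y(n));
      dlogits /= N;
    } else {
      dlogits = (probs - onehot) / N;
    }
    mat dWd = H.t() * dlogits;
    rowvec dbd = sum(dlogits, 0);
    mat dH = dlogits * net.Wd.t();
    cube dA3 = unflatten(dH, N, A3.n_cols, A3.n_slices);
    mat dW3, dW2, dW1;
    rowvec db3, db2, db1;
    cube dA2 = block_backward(dA3, caches[2], net.W3, net.K,
                              A2.n_cols, A2.n_slices, dW3, db3);
    cube dA1 = block_backward(dA2, caches[1], net.W2, net.K,
                              A1.n_cols, A1.n_slices, dW2, db2);
    block_backward(dA1, caches[0], net.W1, net.K,
                   A0.n_cols, A0.n_slices, dW1, db1);

    const double t = epoch + 1;
    aW1.step(net.W1, dW1, learning_rate, t);
    aW2.step(net.W2, dW2, learning_rate, t);
    aW3.step(net.W3, dW3, learning_rate, t);
    aWd.step(net.Wd, dWd, learning_rate, t);
    mat b;
    b = net.b1; ab1.step(b, db1, learning_rate, t); net.b1 = b;
    b = net.b2; ab2.step(b, db2, learning_rate, t); net.b2 = b;
    b = net.b3; ab3.step(b, db3, learning_rate, t); net.b3 = b;
    b = net.bd; abd.step(b, dbd, learning_rate, t); net.bd = b;

    if (loss < best_loss) {
      best_loss = loss;
      since_improve = 0;
    } else {
      ++since_improve;
    }
    if (since_improve >= patience) { ++epoch; break; }
  }

  Rcpp::List out_weights = Rcpp::List::create(
      Rcpp::Named("W1") = net.W1, Rcpp::Named("b1") = net.b1,
      Rcpp::Named("W2") = net.W2, Rcpp::Named("b2") = net.b2,
      Rcpp::Named("W3") = net.W3, Rcpp::Named("b3") = net.b3,
      Rcpp::Named("Wd") = net.Wd, Rcpp::Named("bd") = net.bd);
  Rcpp::List history = Rcpp::List::create(
      Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("train_accuracy") = tr_acc,
      Rcpp::Named("val_loss") = va_loss,
      Rcpp::Named("val_accuracy") = va_acc);
  return Rcpp::List::create(Rcpp::Named("weights") = out_weights,
                            Rcpp::Named("history") = history,
                            Rcpp::Named("epochs") = epoch,
                            Rcpp::Named("stopped_early") =
                                since_improve >= patience);
}

// [[Rcpp::export]]
arma::mat cnn_forward_cpp(const arma::mat& X, Rcpp::List weights,
                          int kernel_size, bool binary) {
  Net net = net_from_list(weights, kernel_size, binary);
  return net_forward(net, X, nullptr);
}
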