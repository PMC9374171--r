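// Minibatch Adam trainer for a symmetric fully-connected autoencoder
// with layer widths [d, h, J, h, d] (h = 8*J by convention, enforced in R),
// ReLU on the three hidden layers and a linear output layer.
//
// All randomness (weight init, epoch shuffling) is drawn from R's RNG so a
// set.seed() call in R makes training fully reproducible single-threaded.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static inline mat relu(const mat& x) { return clamp(x, 0.0, datum::inf); }

// Glorot-uniform init via R's RNG, column-major fill for reproducibility
static mat glorot(int nin, int nout) {
  double s = std::sqrt(6.0 / (nin + nout));
  Rcpp::NumericVector v = Rcpp::runif(nin * nout, -s, s);
  return mat(v.begin(), nin, nout);
}

struct Adam {
  mat m, v;
  Adam(int r, int c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
  void step(mat& w, const mat& g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    mat mhat = m / (1 - std::pow(b1, t));
    mat vhat = v / (1 - std::pow(b2, t));
    w -= lr * mhat / (sqrt(vhat) + eps);
  }
};

// hidden layers 1 and 3 are ReLU; the bottleneck is linear so the
// embedding is not clipped to the positive quadrant
static double rmse_of(const mat& X, const std::vector<mat>& W,
                      const std::vector<rowvec>& b) {
  mat a1 = relu(X * W[0] + repmat(b[0], X.n_rows, 1));
  mat z  = a1 * W[1] + repmat(b[1], X.n_rows, 1);
  mat a3 = relu(z * W[2] + repmat(b[2], X.n_rows, 1));
  mat xh = a3 * W[3] + repmat(b[3], X.n_rows, 1);
  return std::sqrt(accu(square(X - xh)) / (X.n_elem));
}

// [[Rcpp::export]]
Rcpp::List ae_train_cpp(const arma::mat& X, const arma::mat& Xval, int J,
                        int epochs, int batch, double lr, bool track_val) {
  const int d = X.n_cols, n = X.n_rows, h = 8 * J;

  std::vector<mat> W;
  W.push_back(glorot(d, h));
  W.push_back(glorot(h, J));
  W.push_back(glorot(J, h));
  W.push_back(glorot(h, d));
  std::vector<rowvec> b(4);
  b[0] = rowvec(h, fill::zeros); b[1] = rowvec(J, fill::zeros);
  b[2] = rowvec(h, fill::zeros); b[3] = rowvec(d, fill::zeros);

  std::vector<Adam> aw, ab;
  for (int l = 0; l < 4; ++l) {
    aw.emplace_back(W[l].n_rows, W[l].n_cols);
    ab.emplace_back(1, b[l].n_elem);
  }

  vec train_curve(epochs, fill::zeros), val_curve(epochs, fill::zeros);
  double t = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    // epoch shuffle through R's RNG
    Rcpp::IntegerVector ord = Rcpp::sample(n, n, false) - 1;
    uvec idx(n);
    for (int i = 0; i < n; ++i) idx[i] = ord[i];

    for (int start = 0; start < n; start += batch) {
      int stop = std::min(start + batch, n);
      uvec bi = idx.subvec(start, stop - 1);
      mat xb = X.rows(bi);
      int m = xb.n_rows;

      // forward
      mat z1 = xb * W[0] + repmat(b[0], m, 1); mat a1 = relu(z1);
      mat z2 = a1 * W[1] + repmat(b[1], m, 1); mat a2 = z2;
      mat z3 = a2 * W[2] + repmat(b[2], m, 1); mat a3 = relu(z3);
      mat xh = a3 * W[3] + repmat(b[3], m, 1);

      // backward: MSE over all entries of the batch
      mat d4 = 2.0 * (xh - xb) / (double)(m * d);
      mat g4 = a3.t() * d4;
      mat d3 = (d4 * W[3].t()) % conv_to<mat>::from(z3 > 0);
      mat g3 = a2.t() * d3;
      mat d2 = d3 * W[2].t();
      mat g2 = a1.t() * d2;
      mat d1 = (d2 * W[1].t()) % conv_to<mat>::from(z1 > 0);
      mat g1 = xb.t() * d1;

      t += 1.0;
      aw[3].step(W[3], g4, lr, t); { mat gb = sum(d4, 0); mat bm(b[3]); ab[3].step(bm, gb, lr, t); b[3] = bm.row(0); }
      aw[2].step(W[2], g3, lr, t); { mat gb = sum(d3, 0); mat bm(b[2]); ab[2].step(bm, gb, lr, t); b[2] = bm.row(0); }
      aw[1].step(W[1], g2, lr, t); { mat gb = sum(d2, 0); mat bm(b[1]); ab[1].step(bm, gb, lr, t); b[1] = bm.row(0); }
      aw[0].step(W[0], g1, lr, t); { mat gb = sum(d1, 0); mat bm(b[0]); ab[0].step(bm, gb, lr, t); b[0] = bm.row(0); }
    }

    train_curve[ep] = rmse_of(X, W, b);
    if (track_val && Xval.n_rows > 0) val_curve[ep] = rmse_of(Xval, W, b);
    if (!std::isfinite(train_curve[ep]))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
  }

  return Rcpp::List::create(
    Rcpp::Named("W1") = W[0], Rcpp::Named("b1") = b[0],
    Rcpp::Named("W2") = W[1], Rcpp::Named("b2") = b[1],
    Rcpp::Named("W3") = W[2], Rcpp::Named("b3") = b[2],
    Rcpp::Named("W4") = W[3], Rcpp::Named("b4") = b[3],
    Rcpp::Named("train_rmse") = train_curve,
    Rcpp::Named("val_rmse") = val_curve);
}

// [[Rcpp::export]]
arma::mat ae_encode_cpp(const arma::mat& X, const arma::mat& W1,
                        const arma::rowvec& b1, const arma::mat& W2,
                        const arma::rowvec& b2) {
  if (X.n_rows == 0) return mat(0, W2.n_cols);
  mat a1 = relu(X * W1 + repmat(b1, X.n_rows, 1));
  return a1 * W2 + repmat(b2, X.n_rows, 1);
}

// [[Rcpp::export]]
arma::mat ae_reconstruct_cpp(const arma::mat& X, const arma::mat& W1,
                             const arma::rowvec& b1, const arma::mat& W2,
                             const arma::rowvec& b2, const arma::mat& W3,
                             const arma::rowvec& b3, const arma::mat& W4,
                             const arma::rowvec& b4) {
  if (X.n_rows == 0) return mat(0, W4.n_cols);
  mat a1 = relu(X * W1 + repmat(b1, X.n_rows, 1));
  mat a2 = a1 * W2 + repmat(b2, X.n_rows, 1);
  mat a3 = relu(a2 * W3 + repmat(b3, X.n_rows, 1));
  return a3 * W4 + repmat(b4, X.n_rows, 1);
}
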