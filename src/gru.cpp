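// Single-/multi-layer GRU sequence regressor with a weighted-MSE loss:
// forward pass, backpropagation through time, and a full-batch Adam
// training loop. Layout and gate order (r, z, n; two bias vectors) follow
// the common deep-learning convention so the parameter count is
// 3(h*in + h^2 + 2h) per layer plus (h + 1) for the affine output head.
//
// Layers are processed sequentially over the whole sequence, so the input
// projections (W_ih * x_t for every t) and the weight-gradient
// accumulations collapse into single large GEMMs; only the recurrent
// matrix-vector products remain inside the time loop. Sequences are held
// as (features x B*T) matrices with columns ordered batch-within-step.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int input, hidden, layers;
  int layer_par(int l) const {
    int in_l = (l == 0) ? input : hidden;
    return 3 * hidden * in_l + 3 * hidden * hidden + 6 * hidden;
  }
  int total() const {
    int n = hidden + 1;  // output head
    for (int l = 0; l < layers; ++l) n += layer_par(l);
    return n;
  }
};

struct LayerView {
  mat W_ih, W_hh;   // 3h x in_l, 3h x h
  vec b_ih, b_hh;   // 3h
};

void unpack(const vec& theta, const Dims& d, std::vector<LayerView>& layers,
            vec& w_out, double& b_out) {
  int off = 0;
  layers.resize(d.layers);
  for (int l = 0; l < d.layers; ++l) {
    int in_l = (l == 0) ? d.input : d.hidden;
    int h3 = 3 * d.hidden;
    layers[l].W_ih = reshape(theta.subvec(off, off + h3 * in_l - 1), h3, in_l);
    off += h3 * in_l;
    layers[l].W_hh = reshape(theta.subvec(off, off + h3 * d.hidden - 1), h3,
                             d.hidden);
    off += h3 * d.hidden;
    layers[l].b_ih = theta.subvec(off, off + h3 - 1); off += h3;
    layers[l].b_hh = theta.subvec(off, off + h3 - 1); off += h3;
  }
  w_out = theta.subvec(off, off + d.hidden - 1); off += d.hidden;
  b_out = theta(off);
}

inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LayerCache {
  mat R, Z, N, G, H;  // h x B*T gate activations and hidden states
};

// forward through all layers; X flattened (input x B*T), columns ordered
// batch-within-step. Optional inverted-dropout mask (h x B*T) applied to
// the top hidden state before the output head. Returns predictions (T x B)
// in Gy.
mat forward(const vec& theta, const mat& Xflat, int B, int T, const Dims& d,
            double dose_norm, const mat& mask, std::vector<LayerCache>* cache) {
  std::vector<LayerView> L;
  vec w_out; double b_out;
  unpack(theta, d, L, w_out, b_out);
  int h = d.hidden;
  if (cache) cache->resize(d.layers);

  mat Xcur = Xflat;
  for (int l = 0; l < d.layers; ++l) {
    mat Ai = L[l].W_ih * Xcur;   // 3h x B*T, one GEMM for all steps
    Ai.each_col() += L[l].b_ih;
    mat H(h, B * T), R, Z, N, G;
    if (cache) { R.set_size(h, B * T); Z.set_size(h, B * T);
                 N.set_size(h, B * T); G.set_size(h, B * T); }
    mat hprev = zeros<mat>(h, B);
    for (int t = 0; t < T; ++t) {
      int c0 = t * B, c1 = (t + 1) * B - 1;
      mat Ah = L[l].W_hh * hprev;
      Ah.each_col() += L[l].b_hh;
      mat r = sigmoid(Ai.submat(0, c0, h - 1, c1) + Ah.rows(0, h - 1));
      mat z = sigmoid(Ai.submat(h, c0, 2 * h - 1, c1) +
                      Ah.rows(h, 2 * h - 1));
      mat g = Ah.rows(2 * h, 3 * h - 1);
      mat n = tanh(Ai.submat(2 * h, c0, 3 * h - 1, c1) + r % g);
      hprev = (1.0 - z) % n + z % hprev;
      H.cols(c0, c1) = hprev;
      if (cache) {
        R.cols(c0, c1) = r; Z.cols(c0, c1) = z;
        N.cols(c0, c1) = n; G.cols(c0, c1) = g;
      }
    }
    if (cache) {
      (*cache)[l].R = std::move(R); (*cache)[l].Z = std::move(Z);
      (*cache)[l].N = std::move(N); (*cache)[l].G = std::move(G);
      (*cache)[l].H = H;
    }
    Xcur = std::move(H);
  }
  if (mask.n_elem > 0) Xcur %= mask;
  rowvec y = w_out.t() * Xcur + b_out;        // 1 x B*T
  mat Y = reshape(mat(y), B, T).t() * dose_norm;  // T x B
  return Y;
}

double wmse(const mat& Yhat, const mat& Y, const mat& S) {
  mat e = Yhat - Y;
  return accu(S % e % e) / Y.n_cols;
}

// gradient of wmse(forward(theta, .), Y, S) wrt theta
vec backward(const vec& theta, const mat& Xflat, int B, int T, const mat& Y,
             const mat& S, const Dims& d, double dose_norm, const mat& mask,
             const std::vector<LayerCache>& cache, const mat& Yhat) {
  std::vector<LayerView> L;
  vec w_out; double b_out;
  unpack(theta, d, L, w_out, b_out);
  int h = d.hidden;

  mat dYm = (2.0 / B) * (S % (Yhat - Y)) * dose_norm;  // T x B
  rowvec dy = vectorise(dYm.t()).t();                  // 1 x B*T, b-in-t

  vec grad(theta.n_elem, fill::zeros);

  // output head
  const mat& Htop = cache[d.layers - 1].H;
  mat Hm = (mask.n_elem > 0) ? mat(Htop % mask) : Htop;
  vec dw_out = Hm * dy.t();
  double db_out = accu(dy);
  mat DH = w_out * dy;                 // h x B*T
  if (mask.n_elem > 0) DH %= mask;

  for (int l = d.layers - 1; l >= 0; --l) {
    const LayerCache& c = cache[l];
    mat DA_i(3 * h, B * T), DA_h(3 * h, B * T);
    mat dh_next = zeros<mat>(h, B);
    for (int t = T - 1; t >= 0; --t) {
      int c0 = t * B, c1 = (t + 1) * B - 1;
      mat dh = dh_next + DH.cols(c0, c1);
      mat r = c.R.cols(c0, c1), z = c.Z.cols(c0, c1);
      mat n = c.N.cols(c0, c1), g = c.G.cols(c0, c1);
      mat hprev = (t > 0) ? mat(c.H.cols(c0 - B, c0 - 1))
                          : zeros<mat>(h, B);
      mat dz = dh % (hprev - n);
      mat dan = dh % (1.0 - z) % (1.0 - n % n);
      mat dar = (dan % g) % r % (1.0 - r);
      mat daz = dz % z % (1.0 - z);
      DA_i.submat(0, c0, h - 1, c1) = dar;
      DA_i.submat(h, c0, 2 * h - 1, c1) = daz;
      DA_i.submat(2 * h, c0, 3 * h - 1, c1) = dan;
      DA_h.submat(0, c0, h - 1, c1) = dar;
      DA_h.submat(h, c0, 2 * h - 1, c1) = daz;
      DA_h.submat(2 * h, c0, 3 * h - 1, c1) = dan % r;  // dg
      dh_next = dh % z + L[l].W_hh.t() * DA_h.cols(c0, c1);
    }
    // lagged hidden states: zeros for t = 0, H shifted one step otherwise
    mat Hprev(h, B * T);
    Hprev.cols(0, B - 1).zeros();
    if (T > 1) Hprev.cols(B, B * T - 1) = c.H.cols(0, B * (T - 1) - 1);

    const mat& Xl = (l == 0) ? Xflat : cache[l - 1].H;
    mat dW_ih = DA_i * Xl.t();
    mat dW_hh = DA_h * Hprev.t();
    vec db_ih = sum(DA_i, 1), db_hh = sum(DA_h, 1);

    int off = 0;
    for (int ll = 0; ll < l; ++ll) off += d.layer_par(ll);
    grad.subvec(off, off + dW_ih.n_elem - 1) = vectorise(dW_ih);
    off += dW_ih.n_elem;
    grad.subvec(off, off + dW_hh.n_elem - 1) = vectorise(dW_hh);
    off += dW_hh.n_elem;
    grad.subvec(off, off + 3 * h - 1) = db_ih; off += 3 * h;
    grad.subvec(off, off + 3 * h - 1) = db_hh;

    if (l > 0) DH = L[l].W_ih.t() * DA_i;
  }
  int off = d.total() - h - 1;
  grad.subvec(off, off + h - 1) = dw_out;
  grad(off + h) = db_out;
  return grad;
}

Dims make_dims(int input, int hidden, int layers) {
  Dims d; d.input = input; d.hidden = hidden; d.layers = layers;
  return d;
}

// cube (in x B x T) -> (in x B*T) matrix; the cube's slice-major memory
// layout already matches the batch-within-step column order
mat flatten_cube(const cube& X) {
  return mat(const_cast<double*>(X.memptr()), X.n_rows,
             X.n_cols * X.n_slices, /*copy*/ true);
}

}  // namespace

// [[Rcpp::export]]
int cpp_gru_n_par(int input, int hidden, int layers) {
  return make_dims(input, hidden, layers).total();
}

// [[Rcpp::export]]
arma::mat cpp_gru_forward(const arma::vec& theta, const arma::cube& X,
                          int hidden, int layers, double dose_norm) {
  Dims d = make_dims(X.n_rows, hidden, layers);
  if ((int)theta.n_elem != d.total())
    Rcpp::stop("parameter vector has %d elements, expected %d",
               (int)theta.n_elem, d.total());
  mat nomask;
  return forward(theta, flatten_cube(X), X.n_cols, X.n_slices, d, dose_norm,
                 nomask, nullptr);
}

// [[Rcpp::export]]
Rcpp::List cpp_gru_loss_grad(const arma::vec& theta, const arma::cube& X,
                             const arma::mat& Y, const arma::mat& S,
                             int hidden, int layers, double dose_norm) {
  Dims d = make_dims(X.n_rows, hidden, layers);
  if ((int)theta.n_elem != d.total())
    Rcpp::stop("parameter vector has %d elements, expected %d",
               (int)theta.n_elem, d.total());
  int B = X.n_cols, T = X.n_slices;
  mat Xflat = flatten_cube(X), nomask;
  std::vector<LayerCache> cache;
  mat Yhat = forward(theta, Xflat, B, T, d, dose_norm, nomask, &cache);
  double loss = wmse(Yhat, Y, S);
  vec grad = backward(theta, Xflat, B, T, Y, S, d, dose_norm, nomask, cache,
                      Yhat);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// Full-batch Adam training. Records the training loss (with the epoch's
// dropout mask applied) after each epoch; if validation inputs are
// supplied, also records the dropout-free validation loss, tracks the
// best parameters and optionally stops after `patience` epochs without
// improvement.
// [[Rcpp::export]]
Rcpp::List cpp_gru_train(const arma::vec& theta0, const arma::cube& X,
                         const arma::mat& Y, const arma::mat& S,
                         int hidden, int layers, double dose_norm,
                         double lr, int epochs, double dropout_p,
                         int seed, double loss_floor,
                         Rcpp::Nullable<Rcpp::NumericVector> Xval_ = R_NilValue,
                         Rcpp::Nullable<Rcpp::NumericVector> Yval_ = R_NilValue,
                         Rcpp::Nullable<Rcpp::NumericVector> Sval_ = R_NilValue,
                         int patience = -1) {
  Dims d = make_dims(X.n_rows, hidden, layers);
  if ((int)theta0.n_elem != d.total())
    Rcpp::stop("parameter vector has %d elements, expected %d",
               (int)theta0.n_elem, d.total());
  int B = X.n_cols, T = X.n_slices, h = d.hidden;
  mat Xflat = flatten_cube(X);

  bool has_val = Xval_.isNotNull();
  mat Xvflat, Yval, Sval;
  int Bv = 0, Tv = 0;
  if (has_val) {
    Rcpp::NumericVector xv(Xval_);
    Rcpp::IntegerVector dim = xv.attr("dim");
    cube Xval(xv.begin(), dim[0], dim[1], dim[2]);
    Bv = dim[1]; Tv = dim[2];
    Xvflat = flatten_cube(Xval);
    Yval = Rcpp::as<mat>(Rcpp::NumericMatrix((SEXP)Yval_.get()));
    Sval = Rcpp::as<mat>(Rcpp::NumericMatrix((SEXP)Sval_.get()));
  }

  vec theta = theta0;
  vec m = zeros<vec>(theta.n_elem), v = zeros<vec>(theta.n_elem);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double keep = 1.0 - dropout_p;

  std::vector<double> train_hist, val_hist;
  vec best_theta = theta;
  double best_val = datum::inf;
  int best_epoch = 0, since_best = 0;
  mat nomask;

  for (int e = 1; e <= epochs; ++e) {
    mat mask;
    if (dropout_p > 0.0) {
      mask.set_size(h, B * T);
      for (uword i = 0; i < mask.n_elem; ++i)
        mask(i) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
    }
    std::vector<LayerCache> cache;
    mat Yhat = forward(theta, Xflat, B, T, d, dose_norm, mask, &cache);
    double train_loss = wmse(Yhat, Y, S);
    if (!std::isfinite(train_loss))
      Rcpp::stop("training loss became non-finite at epoch %d (lr = %g)",
                 e, lr);
    train_hist.push_back(train_loss);
    vec grad = backward(theta, Xflat, B, T, Y, S, d, dose_norm, mask, cache,
                        Yhat);

    // Adam update with bias correction
    m = b1 * m + (1.0 - b1) * grad;
    v = b2 * v + (1.0 - b2) * (grad % grad);
    double c1 = 1.0 - std::pow(b1, e), c2 = 1.0 - std::pow(b2, e);
    theta -= lr * (m / c1) / (sqrt(v / c2) + eps);

    if (has_val) {
      mat Yv = forward(theta, Xvflat, Bv, Tv, d, dose_norm, nomask, nullptr);
      double vl = wmse(Yv, Yval, Sval);
      val_hist.push_back(vl);
      if (vl < best_val) {
        best_val = vl; best_theta = theta; best_epoch = e; since_best = 0;
      } else if (++since_best >= patience && patience > 0) {
        break;
      }
    }
    if (train_loss <= loss_floor) break;
    if (e % 50 == 0) Rcpp::checkUserInterrupt();
  }

  if (!has_val) { best_theta = theta; best_epoch = (int)train_hist.size(); }
  // dropout-free training loss of the returned parameters
  mat Yfin = forward(best_theta, Xflat, B, T, d, dose_norm, nomask, nullptr);
  double final_loss = wmse(Yfin, Y, S);
  return Rcpp::List::create(
      Rcpp::Named("theta") = best_theta,
      Rcpp::Named("final_loss") = final_loss,
      Rcpp::Named("final_theta") = theta,
      Rcpp::Named("train_loss") = train_hist,
      Rcpp::Named("val_loss") = val_hist,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val") = best_val);
}
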