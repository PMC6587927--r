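// Compact convolutional P300 decoder: forward/backward pass for one minibatch.
//
// Layer stack (input C channels x T samples):
//   temporal conv (F1 kernels, 1 x K, same padding, no bias)
//   -> batchnorm -> depthwise spatial conv (C x 1, depth multiplier D, no bias)
//   -> batchnorm -> ELU -> average pool (1 x P1) -> dropout
//   -> separable conv (depthwise 1 x K2 + pointwise F2 x F2, no bias)
//   -> batchnorm -> ELU -> average pool (1 x P2) -> dropout
//   -> dense softmax (2 classes).
//
// All state (weights, batchnorm running moments) lives in R lists so the
// decoder object is a plain, serializable R structure; this file is pure
// number crunching.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct Cfg {
  int C, T, F1, K, D, F2, K2, P1, P2, NC;
  int T2, T3;
  double bn_eps;
};

Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.C  = as<int>(cfg["n_channels"]);
  c.T  = as<int>(cfg["n_samples"]);
  c.F1 = as<int>(cfg["n_temporal_filters"]);
  c.K  = as<int>(cfg["temporal_kernel_len"]);
  c.D  = as<int>(cfg["depth_multiplier"]);
  c.F2 = as<int>(cfg["n_separable_filters"]);
  c.K2 = as<int>(cfg["separable_kernel_len"]);
  c.P1 = as<int>(cfg["pool1"]);
  c.P2 = as<int>(cfg["pool2"]);
  c.NC = as<int>(cfg["n_classes"]);
  c.T2 = c.T / c.P1;
  c.T3 = c.T2 / c.P2;
  c.bn_eps = 1e-3;
  return c;
}

// im2col for the temporal convolution of one trial.
// x: C x T; out: K x (C*T), column j = c*T + t holds the zero-padded
// window around sample t of channel c. Uses a transposed padded copy so
// every column of P is one contiguous memcpy.
void im2col_temporal(const mat& x, int K, int padL, mat& xpadT, mat& P) {
  const int C = x.n_rows, T = x.n_cols;
  xpadT.zeros();  // (T + K - 1) x C
  xpadT.rows(padL, padL + T - 1) = x.t();
  for (int c = 0; c < C; ++c) {
    const double* src = xpadT.colptr(c);
    for (int t = 0; t < T; ++t)
      std::memcpy(P.colptr(c * T + t), src + t, K * sizeof(double));
  }
}

// batchnorm statistics helpers -------------------------------------------

struct BnCache {
  vec mean, invstd;  // per feature
};

// normalize a set of cubes indexed by feature f (layer 1: one cube per f)
void bn_forward_cubevec(std::vector<cube>& xs, const vec& g, const vec& b,
                        vec& rm, vec& rv, bool training, double momentum,
                        double eps, std::vector<cube>& xhat, BnCache& cache) {
  const int F = xs.size();
  cache.mean.set_size(F);
  cache.invstd.set_size(F);
  for (int f = 0; f < F; ++f) {
    double mu, var;
    if (training) {
      mu = arma::accu(xs[f]) / xs[f].n_elem;
      cube d = xs[f] - mu;
      var = arma::accu(d % d) / xs[f].n_elem;
      rm(f) = momentum * rm(f) + (1.0 - momentum) * mu;
      rv(f) = momentum * rv(f) + (1.0 - momentum) * var;
    } else {
      mu = rm(f);
      var = rv(f);
    }
    const double is = 1.0 / std::sqrt(var + eps);
    cache.mean(f) = mu;
    cache.invstd(f) = is;
    xhat[f] = (xs[f] - mu) * is;
    xs[f] = g(f) * xhat[f] + b(f);
  }
}

// normalize per-row features of a cube (rows = feature maps)
void bn_forward_rows(cube& x, const vec& g, const vec& b, vec& rm, vec& rv,
                     bool training, double momentum, double eps, cube& xhat,
                     BnCache& cache) {
  const int F = x.n_rows;
  const double m = double(x.n_cols) * x.n_slices;
  cache.mean.set_size(F);
  cache.invstd.set_size(F);
  xhat.set_size(arma::size(x));
  for (int f = 0; f < F; ++f) {
    double mu, var;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (uword n = 0; n < x.n_slices; ++n)
        for (uword t = 0; t < x.n_cols; ++t) {
          const double v = x(f, t, n);
          s += v; s2 += v * v;
        }
      mu = s / m;
      var = s2 / m - mu * mu;
      if (var < 0) var = 0;
      rm(f) = momentum * rm(f) + (1.0 - momentum) * mu;
      rv(f) = momentum * rv(f) + (1.0 - momentum) * var;
    } else {
      mu = rm(f); var = rv(f);
    }
    const double is = 1.0 / std::sqrt(var + eps);
    cache.mean(f) = mu; cache.invstd(f) = is;
    for (uword n = 0; n < x.n_slices; ++n)
      for (uword t = 0; t < x.n_cols; ++t) {
        const double xh = (x(f, t, n) - mu) * is;
        xhat(f, t, n) = xh;
        x(f, t, n) = g(f) * xh + b(f);
      }
  }
}

// backward through batchnorm given xhat, for per-row layout
void bn_backward_rows(const cube& dout, const cube& xhat, const vec& g,
                      const BnCache& cache, bool training, cube& dx,
                      vec& dg, vec& db) {
  const int F = dout.n_rows;
  const double m = double(dout.n_cols) * dout.n_slices;
  dx.set_size(arma::size(dout));
  dg.zeros(F); db.zeros(F);
  for (int f = 0; f < F; ++f) {
    double sd = 0.0, sdx = 0.0;
    for (uword n = 0; n < dout.n_slices; ++n)
      for (uword t = 0; t < dout.n_cols; ++t) {
        const double d = dout(f, t, n);
        sd += d;
        sdx += d * xhat(f, t, n);
      }
    dg(f) = sdx; db(f) = sd;
    const double is = cache.invstd(f);
    if (training) {
      for (uword n = 0; n < dout.n_slices; ++n)
        for (uword t = 0; t < dout.n_cols; ++t) {
          const double dxh = dout(f, t, n) * g(f);
          dx(f, t, n) = is * (dxh - (g(f) / m) * sd -
                              xhat(f, t, n) * (g(f) / m) * sdx);
        }
    } else {
      for (uword n = 0; n < dout.n_slices; ++n)
        for (uword t = 0; t < dout.n_cols; ++t)
          dx(f, t, n) = dout(f, t, n) * g(f) * is;
    }
  }
}

void bn_backward_cubevec(const std::vector<cube>& dout,
                         const std::vector<cube>& xhat, const vec& g,
                         const BnCache& cache, bool training,
                         std::vector<cube>& dx, vec& dg, vec& db) {
  const int F = dout.size();
  dg.zeros(F); db.zeros(F);
  for (int f = 0; f < F; ++f) {
    const double m = dout[f].n_elem;
    const double sd = arma::accu(dout[f]);
    const double sdx = arma::accu(dout[f] % xhat[f]);
    dg(f) = sdx; db(f) = sd;
    const double is = cache.invstd(f);
    if (training) {
      dx[f] = is * (g(f) * dout[f] - (g(f) / m) * sd -
                    xhat[f] * ((g(f) / m) * sdx));
    } else {
      dx[f] = dout[f] * (g(f) * is);
    }
  }
}

inline double elu(double x) { return x > 0 ? x : std::expm1(x); }

}  // namespace

// One pass over a minibatch.
//
// X: C x T x N cube of epochs; y: length-N integer class labels in {0, 1}
//    (length 0 for pure prediction); w: per-trial sample weights.
// Returns class probabilities, the weighted cross-entropy loss, parameter
// gradients (if want_grad) and updated batchnorm running moments (if
// training).
// [[Rcpp::export]]
List eegnet_pass(const arma::cube& X, const arma::ivec& y, const arma::vec& w,
                 const List& params, const List& state, const List& cfg_list,
                 bool training, bool want_grad, double dropout_p,
                 double bn_momentum, int seed) {
  const Cfg cfg = read_cfg(cfg_list);
  const int N = X.n_slices;
  const int C = cfg.C, T = cfg.T, F1 = cfg.F1, K = cfg.K, D = cfg.D,
            F2 = cfg.F2, K2 = cfg.K2, P1 = cfg.P1, P2 = cfg.P2,
            T2 = cfg.T2, T3 = cfg.T3, NC = cfg.NC;
  if ((int)X.n_rows != C || (int)X.n_cols != T)
    stop("input cube is %d x %d, expected %d x %d", X.n_rows, X.n_cols, C, T);

  const mat W1 = as<mat>(params["W1"]);
  const vec g1 = as<vec>(params["g1"]), b1 = as<vec>(params["b1"]);
  const mat W2 = as<mat>(params["W2"]);
  const vec g2 = as<vec>(params["g2"]), b2 = as<vec>(params["b2"]);
  const mat W3 = as<mat>(params["W3"]);
  const mat W4 = as<mat>(params["W4"]);
  const vec g3 = as<vec>(params["g3"]), b3 = as<vec>(params["b3"]);
  const mat W5 = as<mat>(params["W5"]);
  const vec b5 = as<vec>(params["b5"]);

  vec rm1 = as<vec>(state["rm1"]), rv1 = as<vec>(state["rv1"]);
  vec rm2 = as<vec>(state["rm2"]), rv2 = as<vec>(state["rv2"]);
  vec rm3 = as<vec>(state["rm3"]), rv3 = as<vec>(state["rv3"]);

  const int padL1 = (K - 1) / 2;
  const int padL2 = (K2 - 1) / 2;

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const bool drop = training && dropout_p > 0.0;
  const double keep = 1.0 - dropout_p;

  // ---- forward ----------------------------------------------------------
  // temporal convolution; Y1 slices are stored transposed (T x C) so that
  // filling them from the GEMM output is a single contiguous copy
  std::vector<cube> Y1(F1);
  for (int f = 0; f < F1; ++f) Y1[f].set_size(T, C, N);
  {
    mat P(K, C * T), xpadT(T + K - 1, C);
    for (int n = 0; n < N; ++n) {
      im2col_temporal(X.slice(n), K, padL1, xpadT, P);
      mat M = W1 * P;  // F1 x (C*T), column j = c*T + t
      for (int f = 0; f < F1; ++f) {
        double* dst = Y1[f].slice_memptr(n);
        const double* srcM = M.memptr();  // column-major F1 x (C*T)
        for (int j = 0; j < C * T; ++j) dst[j] = srcM[j * F1 + f];
      }
    }
  }

  std::vector<cube> xhat1(F1);
  BnCache bc1;
  bn_forward_cubevec(Y1, g1, b1, rm1, rv1, training, bn_momentum, cfg.bn_eps,
                     xhat1, bc1);
  // Y1 now holds the normalized+scaled output (input to spatial conv)

  // depthwise spatial convolution (Y1 slices are T x C)
  cube Z(F2, T, N);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F1; ++f) {
      mat zr = Y1[f].slice(n) * W2.rows(f * D, f * D + D - 1).t();  // T x D
      Z.slice(n).rows(f * D, f * D + D - 1) = zr.t();
    }

  cube xhat2;
  BnCache bc2;
  bn_forward_rows(Z, g2, b2, rm2, rv2, training, bn_momentum, cfg.bn_eps,
                  xhat2, bc2);

  // ELU + cache of its derivative
  cube ge2(F2, T, N);
  for (uword i = 0; i < Z.n_elem; ++i) {
    const double x = Z(i);
    Z(i) = elu(x);
    ge2(i) = x > 0 ? 1.0 : Z(i) + 1.0;
  }

  // average pool P1
  cube Q(F2, T2, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F2; ++f)
      for (int t = 0; t < T2; ++t) {
        double s = 0;
        for (int k = 0; k < P1; ++k) s += Z(f, t * P1 + k, n);
        Q(f, t, n) = s / P1;
      }

  cube M1;
  if (drop) {
    M1.set_size(F2, T2, N);
    for (uword i = 0; i < M1.n_elem; ++i)
      M1(i) = unif(rng) < keep ? 1.0 / keep : 0.0;
    Q %= M1;
  }

  // separable conv: depthwise temporal then pointwise
  cube D3(F2, T2, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F2; ++f)
      for (int t = 0; t < T2; ++t) {
        double s = 0;
        for (int k = 0; k < K2; ++k) {
          const int src = t + k - padL2;
          if (src >= 0 && src < T2) s += W3(f, k) * Q(f, src, n);
        }
        D3(f, t, n) = s;
      }

  cube S(F2, T2, N);
  for (int n = 0; n < N; ++n) S.slice(n) = W4 * D3.slice(n);

  cube xhat3;
  BnCache bc3;
  bn_forward_rows(S, g3, b3, rm3, rv3, training, bn_momentum, cfg.bn_eps,
                  xhat3, bc3);

  cube ge3(F2, T2, N);
  for (uword i = 0; i < S.n_elem; ++i) {
    const double x = S(i);
    S(i) = elu(x);
    ge3(i) = x > 0 ? 1.0 : S(i) + 1.0;
  }

  cube R3(F2, T3, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F2; ++f)
      for (int t = 0; t < T3; ++t) {
        double s = 0;
        for (int k = 0; k < P2; ++k) s += S(f, t * P2 + k, n);
        R3(f, t, n) = s / P2;
      }

  cube M2;
  if (drop) {
    M2.set_size(F2, T3, N);
    for (uword i = 0; i < M2.n_elem; ++i)
      M2(i) = unif(rng) < keep ? 1.0 / keep : 0.0;
    R3 %= M2;
  }

  mat Fmat(F2 * T3, N);
  for (int n = 0; n < N; ++n) Fmat.col(n) = arma::vectorise(R3.slice(n));

  mat logits = W5 * Fmat;
  logits.each_col() += b5;
  mat probs(NC, N);
  for (int n = 0; n < N; ++n) {
    vec l = logits.col(n);
    l -= l.max();
    vec e = arma::exp(l);
    probs.col(n) = e / arma::accu(e);
  }

  double loss = NA_REAL;
  const bool have_y = (int)y.n_elem == N;
  if (have_y) {
    double s = 0;
    for (int n = 0; n < N; ++n)
      s += w(n) * -std::log(std::max(probs(y(n), n), 1e-12));
    loss = s / N;
  }

  List out = List::create(_["probs"] = probs, _["loss"] = loss);
  if (training) {
    out["state"] = List::create(_["rm1"] = rm1, _["rv1"] = rv1,
                                _["rm2"] = rm2, _["rv2"] = rv2,
                                _["rm3"] = rm3, _["rv3"] = rv3);
  }
  if (!want_grad) return out;
  if (!have_y) stop("gradients require labels");

  // ---- backward ---------------------------------------------------------
  mat dlogits = probs;
  for (int n = 0; n < N; ++n) {
    dlogits(y(n), n) -= 1.0;
    dlogits.col(n) *= w(n) / N;
  }

  mat dW5 = dlogits * Fmat.t();
  vec db5 = arma::sum(dlogits, 1);
  mat dF = W5.t() * dlogits;

  cube dR3(F2, T3, N);
  for (int n = 0; n < N; ++n)
    dR3.slice(n) = arma::reshape(dF.col(n), F2, T3);
  if (drop) dR3 %= M2;

  cube dS(F2, T2, N);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F2; ++f)
      for (int t = 0; t < T2; ++t)
        dS(f, t, n) = dR3(f, t / P2, n) / P2;
  dS %= ge3;

  cube dSbn;
  vec dg3, db3;
  bn_backward_rows(dS, xhat3, g3, bc3, training, dSbn, dg3, db3);

  mat dW4(F2, F2, arma::fill::zeros);
  cube dD3(F2, T2, N);
  for (int n = 0; n < N; ++n) {
    dW4 += dSbn.slice(n) * D3.slice(n).t();
    dD3.slice(n) = W4.t() * dSbn.slice(n);
  }

  mat dW3(F2, K2, arma::fill::zeros);
  cube dQ(F2, T2, N, arma::fill::zeros);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F2; ++f)
      for (int t = 0; t < T2; ++t) {
        const double d = dD3(f, t, n);
        for (int k = 0; k < K2; ++k) {
          const int src = t + k - padL2;
          if (src >= 0 && src < T2) {
            dW3(f, k) += d * Q(f, src, n);
            dQ(f, src, n) += d * W3(f, k);
          }
        }
      }
  // note: Q here is post-dropout (the actual layer input), as required
  if (drop) dQ %= M1;

  cube dZ(F2, T, N);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F2; ++f)
      for (int t = 0; t < T; ++t)
        dZ(f, t, n) = dQ(f, t / P1, n) / P1;
  dZ %= ge2;

  cube dZbn;
  vec dg2, db2;
  bn_backward_rows(dZ, xhat2, g2, bc2, training, dZbn, dg2, db2);

  mat dW2(F2, C, arma::fill::zeros);
  std::vector<cube> dY1(F1);
  for (int f = 0; f < F1; ++f) dY1[f].set_size(T, C, N);
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F1; ++f) {
      const mat dZr = dZbn.slice(n).rows(f * D, f * D + D - 1);  // D x T
      dW2.rows(f * D, f * D + D - 1) += dZr * Y1[f].slice(n);    // D x C
      dY1[f].slice(n) = dZr.t() * W2.rows(f * D, f * D + D - 1);  // T x C
    }

  std::vector<cube> dY1bn(F1);
  vec dg1, db1;
  bn_backward_cubevec(dY1, xhat1, g1, bc1, training, dY1bn, dg1, db1);

  mat dW1(F1, K, arma::fill::zeros);
  {
    mat P(K, C * T), xpadT(T + K - 1, C);
    mat dM(F1, C * T);
    for (int n = 0; n < N; ++n) {
      im2col_temporal(X.slice(n), K, padL1, xpadT, P);
      for (int f = 0; f < F1; ++f) {
        const double* src = dY1bn[f].slice_memptr(n);  // T x C, j = c*T + t
        double* dstM = dM.memptr();
        for (int j = 0; j < C * T; ++j) dstM[j * F1 + f] = src[j];
      }
      dW1 += dM * P.t();
    }
  }

  out["grads"] = List::create(
      _["W1"] = dW1, _["g1"] = dg1, _["b1"] = db1, _["W2"] = dW2,
      _["g2"] = dg2, _["b2"] = db2, _["W3"] = dW3, _["W4"] = dW4,
      _["g3"] = dg3, _["b3"] = db3, _["W5"] = dW5, _["b5"] = db5);
  return out;
}
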