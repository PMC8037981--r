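// Hot layers of the 1-D CNN: length-preserving convolution and batch
// normalization, forward and backward. Activations are R arrays laid out
// (batch, length, channels); channel slices are therefore contiguous, so
// per-channel work runs on flat memory and convolutions reduce to k shifted
// dgemm calls.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims3(const NumericVector &x, int &a, int &b, int &c) {
  IntegerVector d = x.attr("dim");
  a = d[0]; b = d[1]; c = d[2];
}

// X: (B, L, Cin); W: (k, Cin, Cout); b: length Cout
// [[Rcpp::export]]
NumericVector conv1d_fwd_cpp(NumericVector X, NumericVector W,
                             NumericVector bias) {
  int B, L, Cin, k, wc, Cout;
  get_dims3(X, B, L, Cin);
  get_dims3(W, k, wc, Cout);
  const int pad = (k - 1) / 2, Lp = L + k - 1;
  const size_t N = (size_t)B * L;

  arma::cube Xp(B, Lp, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    std::memcpy(Xp.slice(c).colptr(pad), X.begin() + (size_t)c * N,
                sizeof(double) * N);

  arma::mat Y(N, Cout);
  for (int f = 0; f < Cout; ++f) Y.col(f).fill(bias[f]);

  arma::mat Xs(N, Cin), Wd(Cin, Cout);
  for (int d = 0; d < k; ++d) {
    for (int c = 0; c < Cin; ++c)
      std::memcpy(Xs.colptr(c), Xp.slice(c).colptr(d), sizeof(double) * N);
    for (int f = 0; f < Cout; ++f)
      for (int c = 0; c < Cin; ++c)
        Wd(c, f) = W[d + (size_t)k * (c + (size_t)Cin * f)];
    Y += Xs * Wd;
  }
  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(B, L, Cout);
  return out;
}

// gradients of the same convolution; X is the layer input
// [[Rcpp::export]]
List conv1d_bwd_cpp(NumericVector dY, NumericVector X, NumericVector W) {
  int B, L, Cin, k, wc, Cout;
  get_dims3(X, B, L, Cin);
  get_dims3(W, k, wc, Cout);
  const int pad = (k - 1) / 2, Lp = L + k - 1;
  const size_t N = (size_t)B * L;

  arma::cube Xp(B, Lp, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c)
    std::memcpy(Xp.slice(c).colptr(pad), X.begin() + (size_t)c * N,
                sizeof(double) * N);
  arma::mat dYm(dY.begin(), N, Cout, false);
  arma::cube dXp(B, Lp, Cin, arma::fill::zeros);

  NumericVector dW((size_t)k * Cin * Cout);
  dW.attr("dim") = IntegerVector::create(k, Cin, Cout);
  NumericVector db(Cout);
  for (int f = 0; f < Cout; ++f) db[f] = arma::accu(dYm.col(f));

  arma::mat Xs(N, Cin), Wd(Cin, Cout);
  for (int d = 0; d < k; ++d) {
    for (int c = 0; c < Cin; ++c)
      std::memcpy(Xs.colptr(c), Xp.slice(c).colptr(d), sizeof(double) * N);
    arma::mat dWd = Xs.t() * dYm;  // (Cin x Cout)
    for (int f = 0; f < Cout; ++f)
      for (int c = 0; c < Cin; ++c) {
        dW[d + (size_t)k * (c + (size_t)Cin * f)] = dWd(c, f);
        Wd(c, f) = W[d + (size_t)k * (c + (size_t)Cin * f)];
      }
    arma::mat dXs = dYm * Wd.t();  // (N x Cin)
    for (int c = 0; c < Cin; ++c) {
      double *dst = dXp.slice(c).colptr(d);
      const double *src = dXs.colptr(c);
      for (size_t i = 0; i < N; ++i) dst[i] += src[i];
    }
  }
  NumericVector dX(N * Cin);
  for (int c = 0; c < Cin; ++c)
    std::memcpy(dX.begin() + (size_t)c * N, dXp.slice(c).colptr(pad),
                sizeof(double) * N);
  dX.attr("dim") = IntegerVector::create(B, L, Cin);
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// batch normalization per channel over (batch, length)
// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector X, NumericVector gamma, NumericVector beta,
                NumericVector run_mean, NumericVector run_var, bool training,
                double momentum, double eps) {
  int B, L, C;
  get_dims3(X, B, L, C);
  const size_t N = (size_t)B * L;
  NumericVector out(N * C), xhat(N * C), inv_sd(C);
  NumericVector rm = clone(run_mean), rv = clone(run_var);
  for (int c = 0; c < C; ++c) {
    const double *x = X.begin() + (size_t)c * N;
    double mu, var;
    if (training) {
      double s = 0;
      for (size_t i = 0; i < N; ++i) s += x[i];
      mu = s / N;
      double s2 = 0;
      for (size_t i = 0; i < N; ++i) s2 += (x[i] - mu) * (x[i] - mu);
      var = s2 / N;
      rm[c] = (1 - momentum) * rm[c] + momentum * mu;
      rv[c] = (1 - momentum) * rv[c] + momentum * var;
    } else {
      mu = run_mean[c];
      var = run_var[c];
    }
    const double inv = 1.0 / std::sqrt(var + eps);
    inv_sd[c] = inv;
    const double g = gamma[c], bta = beta[c];
    double *xh = xhat.begin() + (size_t)c * N;
    double *y = out.begin() + (size_t)c * N;
    for (size_t i = 0; i < N; ++i) {
      xh[i] = (x[i] - mu) * inv;
      y[i] = g * xh[i] + bta;
    }
  }
  IntegerVector dm = IntegerVector::create(B, L, C);
  out.attr("dim") = dm;
  xhat.attr("dim") = dm;
  return List::create(_["out"] = out, _["xhat"] = xhat,
                      _["inv_sd"] = inv_sd, _["run_mean"] = rm,
                      _["run_var"] = rv);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector dY, NumericVector xhat, NumericVector inv_sd,
                NumericVector gamma) {
  int B, L, C;
  get_dims3(dY, B, L, C);
  const size_t N = (size_t)B * L;
  NumericVector dX(N * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double *dy = dY.begin() + (size_t)c * N;
    const double *xh = xhat.begin() + (size_t)c * N;
    double sg = 0, sb = 0;
    for (size_t i = 0; i < N; ++i) {
      sg += dy[i] * xh[i];
      sb += dy[i];
    }
    dgamma[c] = sg;
    dbeta[c] = sb;
    // dx = inv_sd/N * (N*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat))
    const double g = gamma[c];
    const double sum_dxhat = g * sb, sum_dxhat_xhat = g * sg;
    const double scale = inv_sd[c] / N;
    double *dx = dX.begin() + (size_t)c * N;
    for (size_t i = 0; i < N; ++i)
      dx[i] = scale * (N * g * dy[i] - sum_dxhat - xh[i] * sum_dxhat_xhat);
  }
  dX.attr("dim") = IntegerVector::create(B, L, C);
  return List::create(_["dX"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// ---------------------------------------------------------------------------
// Whole-network forward/backward. One call per mini-batch: activations stay
// in C++ as (B*L) x C matrices (channel-contiguous, matching the R array
// layout), so the training loop costs one .Call per step.

namespace {

struct LayerParams {
  arma::fmat W;      // (k*Cin) x Cout copy of the conv weight array
  arma::fvec b, gamma, beta;
  int k, Cin, Cout;
  bool pool;
};

struct LayerCache {
  arma::fmat Xcol;    // N x (k*Cin) im2col of the layer input
  arma::fmat xhat;    // N x Cout (batch-normalized, pre-scale)
  arma::fvec inv_sd;
  arma::fmat act;     // post-ReLU, pre-pool
  arma::Mat<unsigned char> takeodd;
  int L;             // input sequence length to this layer's pool
};

void im2col(const arma::fmat &X, int B, int L, int k, arma::fmat &Xcol) {
  // X: (B*L) x Cin, zero-padded shifted copies; Xcol: (B*L) x (k*Cin),
  // column (d + k*c) = channel c shifted by d - pad
  const int Cin = X.n_cols, pad = (k - 1) / 2;
  const size_t N = (size_t)B * L;
  Xcol.zeros(N, (size_t)k * Cin);
  for (int c = 0; c < Cin; ++c) {
    for (int d = 0; d < k; ++d) {
      const int shift = d - pad;  // source position l + shift
      const int l0 = std::max(0, -shift), l1 = std::min(L, L - shift);
      if (l1 <= l0) continue;
      std::memcpy(Xcol.colptr((size_t)d + (size_t)k * c) + (size_t)B * l0,
                  X.colptr(c) + (size_t)B * (l0 + shift),
                  sizeof(float) * (size_t)B * (l1 - l0));
    }
  }
}

void col2im_add(const arma::fmat &dXcol, int B, int L, int k, arma::fmat &dX) {
  const int Cin = dX.n_cols, pad = (k - 1) / 2;
  for (int c = 0; c < Cin; ++c) {
    for (int d = 0; d < k; ++d) {
      const int shift = d - pad;
      const int l0 = std::max(0, -shift), l1 = std::min(L, L - shift);
      if (l1 <= l0) continue;
      const float *src = dXcol.colptr((size_t)d + (size_t)k * c) +
                          (size_t)B * l0;
      float *dst = dX.colptr(c) + (size_t)B * (l0 + shift);
      const size_t len = (size_t)B * (l1 - l0);
      for (size_t i = 0; i < len; ++i) dst[i] += src[i];
    }
  }
}

std::vector<LayerParams> unpack_params(const List &params,
                                       const IntegerVector &kernels,
                                       const LogicalVector &pool_after,
                                       int in_channels) {
  std::vector<LayerParams> out;
  int cin = in_channels;
  for (int i = 0; i < kernels.size(); ++i) {
    std::string p = "conv" + std::to_string(i + 1);
    std::string q = "bn" + std::to_string(i + 1);
    NumericVector Wr = params[p + ".W"];
    NumericVector br = params[p + ".b"];
    NumericVector gr = params[q + ".gamma"];
    NumericVector be = params[q + ".beta"];
    LayerParams lp;
    lp.k = kernels[i];
    lp.Cin = cin;
    lp.Cout = br.size();
    lp.W = arma::conv_to<arma::fmat>::from(
        arma::mat(Wr.begin(), (size_t)lp.k * cin, lp.Cout, false));
    lp.b = arma::conv_to<arma::fvec>::from(arma::vec(br.begin(), lp.Cout, false));
    lp.gamma = arma::conv_to<arma::fvec>::from(arma::vec(gr.begin(), lp.Cout, false));
    lp.beta = arma::conv_to<arma::fvec>::from(arma::vec(be.begin(), lp.Cout, false));
    lp.pool = pool_after[i];
    out.push_back(lp);
    cin = lp.Cout;
  }
  return out;
}

// forward through conv blocks + GAP + dense; fills caches when training.
// The whole-network path runs in single precision: training a regression
// network does not need double precision, and sgemm roughly doubles the
// throughput of the skinny matrix products that dominate the cost.
arma::fvec forward_pass(const std::vector<LayerParams> &layers,
                        NumericVector rmeans, NumericVector rvars,
                        const IntegerVector &bn_offsets,
                        const arma::fmat &X0, int B, int L0,
                        bool training, double momentum, double eps,
                        const arma::fvec &denseW, float denseb,
                        std::vector<LayerCache> *caches, arma::fmat &gap_out) {
  arma::fmat A = X0;
  int L = L0;
  for (size_t i = 0; i < layers.size(); ++i) {
    const LayerParams &lp = layers[i];
    LayerCache cc;
    im2col(A, B, L, lp.k, cc.Xcol);
    arma::fmat Y = cc.Xcol * lp.W;
    Y.each_row() += lp.b.t();
    const size_t N = Y.n_rows;
    // batch norm per channel; statistics accumulate in double
    cc.inv_sd.set_size(lp.Cout);
    double *rm = rmeans.begin() + bn_offsets[i];
    double *rv = rvars.begin() + bn_offsets[i];
    if (training) cc.xhat.set_size(N, lp.Cout);
    for (int c = 0; c < lp.Cout; ++c) {
      double mu, var;
      const float *ycol = Y.colptr(c);
      if (training) {
        double s = 0;
        for (size_t r = 0; r < N; ++r) s += ycol[r];
        mu = s / N;
        double s2 = 0;
        for (size_t r = 0; r < N; ++r) s2 += (ycol[r] - mu) * (ycol[r] - mu);
        var = s2 / N;
        rm[c] = (1 - momentum) * rm[c] + momentum * mu;
        rv[c] = (1 - momentum) * rv[c] + momentum * var;
      } else {
        mu = rm[c];
        var = rv[c];
      }
      const float inv = 1.0 / std::sqrt(var + eps);
      cc.inv_sd[c] = inv;
      float *y = Y.colptr(c);
      const float g = lp.gamma[c], bt = lp.beta[c];
      const float muf = mu;
      if (training) {
        float *xh = cc.xhat.colptr(c);
        for (size_t r = 0; r < N; ++r) {
          xh[r] = (y[r] - muf) * inv;
          y[r] = std::max(0.0f, g * xh[r] + bt);  // BN + ReLU fused
        }
      } else {
        for (size_t r = 0; r < N; ++r)
          y[r] = std::max(0.0f, g * (y[r] - muf) * inv + bt);
      }
    }
    if (training) cc.act = Y;
    cc.L = L;
    if (lp.pool) {
      const int Lh = L / 2;
      arma::fmat P((size_t)B * Lh, lp.Cout);
      if (training) cc.takeodd.set_size((size_t)B * Lh, lp.Cout);
      for (int c = 0; c < lp.Cout; ++c) {
        const float *y = Y.colptr(c);
        float *p = P.colptr(c);
        unsigned char *t = training ? cc.takeodd.colptr(c) : nullptr;
        for (int j = 0; j < Lh; ++j)
          for (int bb = 0; bb < B; ++bb) {
            const float a = y[bb + (size_t)B * (2 * j)];
            const float d = y[bb + (size_t)B * (2 * j + 1)];
            const bool odd = a >= d;
            p[bb + (size_t)B * j] = odd ? a : d;
            if (t) t[bb + (size_t)B * j] = odd;
          }
      }
      A = P;
      L = Lh;
    } else {
      A = Y;
    }
    if (caches) (*caches)[i] = std::move(cc);
  }
  // global average pool: (B*L) x C -> B x C
  const int C = A.n_cols;
  gap_out.zeros(B, C);
  for (int c = 0; c < C; ++c) {
    const float *a = A.colptr(c);
    float *g = gap_out.colptr(c);
    for (int l = 0; l < L; ++l)
      for (int bb = 0; bb < B; ++bb) g[bb] += a[bb + (size_t)B * l];
  }
  gap_out /= (float)L;
  return gap_out * denseW + denseb;
}

void load_bn_state(const List &state, const std::vector<LayerParams> &layers,
                   IntegerVector &bn_offsets, NumericVector &rmeans,
                   NumericVector &rvars) {
  const int n_layers = layers.size();
  int tot = 0;
  for (int i = 0; i < n_layers; ++i) {
    bn_offsets[i] = tot;
    tot += layers[i].Cout;
  }
  rmeans = NumericVector(tot);
  rvars = NumericVector(tot);
  for (int i = 0; i < n_layers; ++i) {
    NumericVector m = state["bn" + std::to_string(i + 1) + ".mean"];
    NumericVector v = state["bn" + std::to_string(i + 1) + ".var"];
    std::copy(m.begin(), m.end(), rmeans.begin() + bn_offsets[i]);
    std::copy(v.begin(), v.end(), rvars.begin() + bn_offsets[i]);
  }
}

}  // namespace

// One training step: forward, MSE loss against yz, full backward.
// Returns loss, predictions, gradients (named like the params), and the
// updated batch-norm running statistics.
// [[Rcpp::export]]
List cnn_train_step_cpp(List params, List state, NumericVector X,
                        NumericVector yz, IntegerVector kernels,
                        LogicalVector pool_after, int in_channels,
                        double momentum = 0.1, double eps = 1e-5) {
  IntegerVector xd = X.attr("dim");
  const int B = xd[0], L0 = xd[1];
  const int n_layers = kernels.size();

  std::vector<LayerParams> layers =
      unpack_params(params, kernels, pool_after, in_channels);
  IntegerVector bn_offsets(n_layers);
  NumericVector rmeans, rvars;
  load_bn_state(state, layers, bn_offsets, rmeans, rvars);
  NumericVector dWv = params["dense.W"];
  arma::fvec denseW = arma::conv_to<arma::fvec>::from(
      arma::vec(dWv.begin(), dWv.size(), false));
  const float denseb = as<double>(params["dense.b"]);

  arma::fmat X0 = arma::conv_to<arma::fmat>::from(
      arma::mat(X.begin(), (size_t)B * L0, in_channels, false));
  std::vector<LayerCache> caches(n_layers);
  arma::fmat gap_out;
  arma::fvec pred = forward_pass(layers, rmeans, rvars, bn_offsets, X0, B, L0,
                                 true, momentum, eps, denseW, denseb,
                                 &caches, gap_out);
  arma::fvec yv = arma::conv_to<arma::fvec>::from(
      arma::vec(yz.begin(), yz.size(), false));
  arma::fvec err = pred - yv;
  const double loss = arma::mean(arma::square(
      arma::conv_to<arma::vec>::from(err)));

  List grads;
  arma::fvec dpred = 2.0f * err / (float)B;
  arma::fvec ddenseW = gap_out.t() * dpred;
  grads["dense.W"] = NumericVector(ddenseW.begin(), ddenseW.end());
  grads["dense.b"] = (double)arma::accu(dpred);
  arma::fmat dgap = dpred * denseW.t();  // B x C

  // un-GAP: broadcast over length
  int L = L0;
  for (int i = 0; i < n_layers; ++i) L = pool_after[i] ? L / 2 : L;
  const int Ctop = layers[n_layers - 1].Cout;
  arma::fmat dA((size_t)B * L, Ctop);
  for (int c = 0; c < Ctop; ++c) {
    const float *g = dgap.colptr(c);
    float *d = dA.colptr(c);
    for (int l = 0; l < L; ++l)
      for (int bb = 0; bb < B; ++bb)
        d[bb + (size_t)B * l] = g[bb] / L;
  }

  for (int i = n_layers - 1; i >= 0; --i) {
    const LayerParams &lp = layers[i];
    LayerCache &cc = caches[i];
    arma::fmat dY;
    if (lp.pool) {  // un-pool
      const int Lh = cc.L / 2;
      dY.zeros((size_t)B * cc.L, lp.Cout);
      for (int c = 0; c < lp.Cout; ++c) {
        const float *da = dA.colptr(c);
        const unsigned char *t = cc.takeodd.colptr(c);
        float *dy = dY.colptr(c);
        for (int j = 0; j < Lh; ++j)
          for (int bb = 0; bb < B; ++bb) {
            const size_t src = bb + (size_t)B * j;
            dy[bb + (size_t)B * (2 * j + (t[src] ? 0 : 1))] = da[src];
          }
      }
    } else {
      dY = dA;
    }
    const size_t N = dY.n_rows;
    // ReLU mask then BN backward, fused per channel
    arma::vec dgamma(lp.Cout), dbeta(lp.Cout);
    for (int c = 0; c < lp.Cout; ++c) {
      float *dy = dY.colptr(c);
      const float *act = cc.act.colptr(c);
      const float *xh = cc.xhat.colptr(c);
      double sg = 0, sb = 0;
      for (size_t r = 0; r < N; ++r) {
        if (act[r] <= 0) dy[r] = 0;
        sg += (double)dy[r] * xh[r];
        sb += dy[r];
      }
      dgamma[c] = sg;
      dbeta[c] = sb;
      const float g = lp.gamma[c];
      const float scale = cc.inv_sd[c] / N;
      const float sdx = g * sb, sdxx = g * sg;
      const float Nf = N, gf = g;
      for (size_t r = 0; r < N; ++r)
        dy[r] = scale * (Nf * gf * dy[r] - sdx - xh[r] * sdxx);
    }
    std::string p = "conv" + std::to_string(i + 1);
    std::string q = "bn" + std::to_string(i + 1);
    grads[q + ".gamma"] = NumericVector(dgamma.begin(), dgamma.end());
    grads[q + ".beta"] = NumericVector(dbeta.begin(), dbeta.end());
    arma::fmat dWmat = cc.Xcol.t() * dY;  // (k*Cin) x Cout
    NumericVector dW(dWmat.begin(), dWmat.end());
    dW.attr("dim") = IntegerVector::create(lp.k, lp.Cin, lp.Cout);
    grads[p + ".W"] = dW;
    arma::frowvec db = arma::sum(dY, 0);
    grads[p + ".b"] = NumericVector(db.begin(), db.end());
    if (i > 0) {
      arma::fmat dXcol = dY * lp.W.t();  // N x (k*Cin)
      dA.zeros(N, lp.Cin);
      col2im_add(dXcol, B, cc.L, lp.k, dA);
    }
  }

  List new_state;
  for (int i = 0; i < n_layers; ++i) {
    std::string q = "bn" + std::to_string(i + 1);
    new_state[q + ".mean"] = NumericVector(
        rmeans.begin() + bn_offsets[i],
        rmeans.begin() + bn_offsets[i] + layers[i].Cout);
    new_state[q + ".var"] = NumericVector(
        rvars.begin() + bn_offsets[i],
        rvars.begin() + bn_offsets[i] + layers[i].Cout);
  }
  return List::create(_["loss"] = loss,
                      _["pred"] = NumericVector(pred.begin(), pred.end()),
                      _["grads"] = grads, _["state"] = new_state);
}

// Inference-mode forward pass (batch norm uses running statistics).
// [[Rcpp::export]]
NumericVector cnn_predict_cpp(List params, List state, NumericVector X,
                              IntegerVector kernels, LogicalVector pool_after,
                              int in_channels, double eps = 1e-5) {
  IntegerVector xd = X.attr("dim");
  const int B = xd[0], L0 = xd[1];
  const int n_layers = kernels.size();
  std::vector<LayerParams> layers =
      unpack_params(params, kernels, pool_after, in_channels);
  IntegerVector bn_offsets(n_layers);
  NumericVector rmeans, rvars;
  load_bn_state(state, layers, bn_offsets, rmeans, rvars);
  NumericVector dWv = params["dense.W"];
  arma::fvec denseW = arma::conv_to<arma::fvec>::from(
      arma::vec(dWv.begin(), dWv.size(), false));
  const float denseb = as<double>(params["dense.b"]);
  arma::fmat X0 = arma::conv_to<arma::fmat>::from(
      arma::mat(X.begin(), (size_t)B * L0, in_channels, false));
  arma::fmat gap_out;
  arma::fvec pred = forward_pass(layers, rmeans, rvars, bn_offsets, X0, B, L0,
                                 false, 0.1, eps, denseW, denseb,
                                 nullptr, gap_out);
  return NumericVector(pred.begin(), pred.end());
}

// Exact batch-normalization statistics for inference: one training-mode
// pass over the whole (sub)set with momentum 1, so the running statistics
// become the exact activation moments under the given weights.
// [[Rcpp::export]]
List cnn_bn_recalibrate_cpp(List params, NumericVector X,
                            IntegerVector kernels, LogicalVector pool_after,
                            int in_channels, double eps = 1e-5) {
  IntegerVector xd = X.attr("dim");
  const int B = xd[0], L0 = xd[1];
  const int n_layers = kernels.size();
  std::vector<LayerParams> layers =
      unpack_params(params, kernels, pool_after, in_channels);
  IntegerVector bn_offsets(n_layers);
  int tot = 0;
  for (int i = 0; i < n_layers; ++i) { bn_offsets[i] = tot; tot += layers[i].Cout; }
  NumericVector rmeans(tot), rvars(tot);
  NumericVector dWv = params["dense.W"];
  arma::fvec denseW = arma::conv_to<arma::fvec>::from(
      arma::vec(dWv.begin(), dWv.size(), false));
  arma::fmat X0 = arma::conv_to<arma::fmat>::from(
      arma::mat(X.begin(), (size_t)B * L0, in_channels, false));
  arma::fmat gap_out;
  forward_pass(layers, rmeans, rvars, bn_offsets, X0, B, L0,
               true, 1.0, eps, denseW, 0.0, nullptr, gap_out);
  List state;
  for (int i = 0; i < n_layers; ++i) {
    std::string q = "bn" + std::to_string(i + 1);
    state[q + ".mean"] = NumericVector(
        rmeans.begin() + bn_offsets[i],
        rmeans.begin() + bn_offsets[i] + layers[i].Cout);
    state[q + ".var"] = NumericVector(
        rvars.begin() + bn_offsets[i],
        rvars.begin() + bn_offsets[i] + layers[i].Cout);
  }
  return state;
}
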