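#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// 1-D convolution kernels for the seizure-detection networks.
//
// Data layout: a batch of feature maps is an arma::cube with
//   rows   = time samples (length)
//   cols   = feature maps (channels of the layer, not EEG channels)
//   slices = batch examples
// which matches an R array of dim c(len, maps, batch) with no copying.
//
// Weights for a standard convolution: mat (k*in_maps, out_maps), where the
// row index is m*k + t for input map m (0-based) and tap t in 0..k-1.
// Zero padding pad_l on the left; pad_r implied by out_len == len (stride 1,
// "same" length output).

// Fill the batched im2col matrix (len*batch x k*in_maps): rows are
// (time, example) pairs with examples stacked, so the whole convolution
// becomes a single GEMM against W.
static void im2col_all(const cube& X, mat& col, int k, int pad_l) {
  const int len = X.n_rows, nin = X.n_cols, batch = X.n_slices;
  for (int s = 0; s < batch; ++s) {
    const mat& Xs = X.slice(s);
    for (int m = 0; m < nin; ++m) {
      for (int t = 0; t < k; ++t) {
        const int shift = t - pad_l;          // input index = o + shift
        const int o0 = std::max(0, -shift);
        const int o1 = std::min(len, len - shift);
        double* base = col.colptr(m * k + t) + size_t(s) * len;
        if (o0 > 0) std::memset(base, 0, sizeof(double) * o0);
        if (o1 < len) std::memset(base + o1, 0, sizeof(double) * (len - o1));
        if (o1 > o0)
          std::memcpy(base + o0, Xs.colptr(m) + o0 + shift,
                      sizeof(double) * (o1 - o0));
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cn_conv_fwd(const arma::cube& X, const arma::mat& W,
                       const arma::vec& b, int k, int pad_l) {
  const int len = X.n_rows, nin = X.n_cols, batch = X.n_slices;
  const int nout = W.n_cols;
  cube Y(len, nout, batch);
  if (k == 1) {                               // pointwise: per-slice GEMM
    for (int s = 0; s < batch; ++s) {
      Y.slice(s) = X.slice(s) * W;
      Y.slice(s).each_row() += b.t();
    }
    return Y;
  }
  mat col(size_t(len) * batch, k * nin);
  im2col_all(X, col, k, pad_l);
  mat Yall = col * W;                         // one large GEMM
  Yall.each_row() += b.t();
  for (int s = 0; s < batch; ++s)
    for (int m = 0; m < nout; ++m)
      std::memcpy(Y.slice(s).colptr(m), Yall.colptr(m) + size_t(s) * len,
                  sizeof(double) * len);
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cn_conv_bwd(const arma::cube& X, const arma::mat& W,
                       const arma::cube& dY, int k, int pad_l,
                       bool want_dx) {
  const int len = X.n_rows, nin = X.n_cols, batch = X.n_slices;
  const int nout = W.n_cols;
  cube dX(len, nin, batch, fill::zeros);
  if (k == 1) {
    mat dW(W.n_rows, W.n_cols, fill::zeros);
    vec db(nout, fill::zeros);
    for (int s = 0; s < batch; ++s) {
      const mat& dYs = dY.slice(s);
      dW += X.slice(s).t() * dYs;
      db += sum(dYs, 0).t();
      if (want_dx) dX.slice(s) = dYs * W.t();
    }
    return Rcpp::List::create(Rcpp::Named("dX") = dX,
                              Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  }
  mat col(size_t(len) * batch, k * nin);
  im2col_all(X, col, k, pad_l);
  mat dYall(size_t(len) * batch, nout);
  for (int s = 0; s < batch; ++s)
    for (int m = 0; m < nout; ++m)
      std::memcpy(dYall.colptr(m) + size_t(s) * len,
                  dY.slice(s).colptr(m), sizeof(double) * len);
  mat dW = col.t() * dYall;
  vec db = sum(dYall, 0).t();
  if (!want_dx)
    return Rcpp::List::create(Rcpp::Named("dX") = dX,
                              Rcpp::Named("dW") = dW,
                              Rcpp::Named("db") = db);
  mat dcol = dYall * W.t();                   // (len*batch x k*nin)
  for (int s = 0; s < batch; ++s) {
    mat& dXs = dX.slice(s);
    for (int m = 0; m < nin; ++m) {
      for (int t = 0; t < k; ++t) {
        const int shift = t - pad_l;
        const int o0 = std::max(0, -shift);
        const int o1 = std::min(len, len - shift);
        if (o1 <= o0) continue;
        double* dst = dXs.colptr(m) + o0 + shift;
        const double* src = dcol.colptr(m * k + t) + size_t(s) * len + o0;
        for (int o = o0; o < o1; ++o) *dst++ += *src++;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Depthwise convolution: one k-tap filter per feature map.
// W: mat (k, maps); b: vec (maps).

// [[Rcpp::export]]
arma::cube cn_dwconv_fwd(const arma::cube& X, const arma::mat& W,
                         const arma::vec& b, int pad_l) {
  const int len = X.n_rows, nm = X.n_cols, batch = X.n_slices;
  const int k = W.n_rows;
  cube Y(len, nm, batch, fill::zeros);
  for (int s = 0; s < batch; ++s) {
    const mat& Xs = X.slice(s);
    mat& Ys = Y.slice(s);
    for (int m = 0; m < nm; ++m) {
      const double* x = Xs.colptr(m);
      double* y = Ys.colptr(m);
      for (int t = 0; t < k; ++t) {
        const int shift = t - pad_l;
        const double w = W(t, m);
        const int o0 = std::max(0, -shift);
        const int o1 = std::min(len, len - shift);
        for (int o = o0; o < o1; ++o) y[o] += w * x[o + shift];
      }
      const double bm = b(m);
      for (int o = 0; o < len; ++o) y[o] += bm;
    }
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cn_dwconv_bwd(const arma::cube& X, const arma::mat& W,
                         const arma::cube& dY, int pad_l) {
  const int len = X.n_rows, nm = X.n_cols, batch = X.n_slices;
  const int k = W.n_rows;
  cube dX(len, nm, batch, fill::zeros);
  mat dW(k, nm, fill::zeros);
  vec db(nm, fill::zeros);
  for (int s = 0; s < batch; ++s) {
    const mat& Xs = X.slice(s);
    const mat& dYs = dY.slice(s);
    mat& dXs = dX.slice(s);
    for (int m = 0; m < nm; ++m) {
      const double* x = Xs.colptr(m);
      const double* dy = dYs.colptr(m);
      double* dx = dXs.colptr(m);
      for (int t = 0; t < k; ++t) {
        const int shift = t - pad_l;
        const double w = W(t, m);
        double g = 0.0;
        const int o0 = std::max(0, -shift);
        const int o1 = std::min(len, len - shift);
        for (int o = o0; o < o1; ++o) {
          g += dy[o] * x[o + shift];
          dx[o + shift] += w * dy[o];
        }
        dW(t, m) += g;
      }
      double s0 = 0.0;
      for (int o = 0; o < len; ++o) s0 += dy[o];
      db(m) += s0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// Per-map mean and (biased) variance over time and batch.
// [[Rcpp::export]]
Rcpp::List cn_map_meanvar(const arma::cube& X) {
  const int len = X.n_rows, nm = X.n_cols, batch = X.n_slices;
  vec mu(nm, fill::zeros), va(nm, fill::zeros);
  for (int s = 0; s < batch; ++s) {
    const mat& Xs = X.slice(s);
    for (int m = 0; m < nm; ++m) {
      const double* x = Xs.colptr(m);
      double a = 0.0, b = 0.0;
      for (int o = 0; o < len; ++o) { a += x[o]; b += x[o] * x[o]; }
      mu(m) += a; va(m) += b;
    }
  }
  const double n = double(len) * batch;
  mu /= n;
  va = va / n - mu % mu;
  return Rcpp::List::create(Rcpp::Named("mean") = mu,
                            Rcpp::Named("var") = va);
}

// Per-map affine transform Y = X * a[m] + b[m] (batch-norm forward).
// [[Rcpp::export]]
arma::cube cn_map_affine(const arma::cube& X, const arma::vec& a,
                         const arma::vec& b) {
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  const int len = X.n_rows, nm = X.n_cols, batch = X.n_slices;
  for (int s = 0; s < batch; ++s)
    for (int m = 0; m < nm; ++m) {
      const double* x = X.slice(s).colptr(m);
      double* y = Y.slice(s).colptr(m);
      const double am = a(m), bm = b(m);
      for (int o = 0; o < len; ++o) y[o] = x[o] * am + bm;
    }
  return Y;
}

// Batch-norm backward. X is the layer input; mu/sig the statistics used
// in the forward pass; training selects the full (batch-statistics)
// gradient versus the frozen-statistics one.
// [[Rcpp::export]]
Rcpp::List cn_bn_bwd(const arma::cube& X, const arma::cube& dY,
                     const arma::vec& mu, const arma::vec& sig,
                     const arma::vec& gamma, bool training) {
  const int len = X.n_rows, nm = X.n_cols, batch = X.n_slices;
  const double n = double(len) * batch;
  vec dgamma(nm, fill::zeros), dbeta(nm, fill::zeros);
  for (int s = 0; s < batch; ++s)
    for (int m = 0; m < nm; ++m) {
      const double* x = X.slice(s).colptr(m);
      const double* dy = dY.slice(s).colptr(m);
      const double im = 1.0 / sig(m), mm = mu(m);
      double a = 0.0, b = 0.0;
      for (int o = 0; o < len; ++o) {
        const double xh = (x[o] - mm) * im;
        a += dy[o] * xh; b += dy[o];
      }
      dgamma(m) += a; dbeta(m) += b;
    }
  cube dX(len, nm, batch);
  for (int s = 0; s < batch; ++s)
    for (int m = 0; m < nm; ++m) {
      const double* x = X.slice(s).colptr(m);
      const double* dy = dY.slice(s).colptr(m);
      double* dx = dX.slice(s).colptr(m);
      const double im = 1.0 / sig(m), mm = mu(m);
      const double gs = gamma(m) * im;
      if (training) {
        const double mdy = dbeta(m) / n, mdyx = dgamma(m) / n;
        for (int o = 0; o < len; ++o) {
          const double xh = (x[o] - mm) * im;
          dx[o] = gs * (dy[o] - mdy - xh * mdyx);
        }
      } else {
        for (int o = 0; o < len; ++o) dx[o] = gs * dy[o];
      }
    }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Fused residual add + ReLU; backward masks on the forward output.
// [[Rcpp::export]]
arma::cube cn_add_relu(const arma::cube& A, const arma::cube& B) {
  cube Y(A.n_rows, A.n_cols, A.n_slices);
  const double* a = A.memptr(); const double* b = B.memptr();
  double* y = Y.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) {
    const double s = a[i] + b[i];
    y[i] = s > 0 ? s : 0.0;
  }
  return Y;
}

// [[Rcpp::export]]
arma::cube cn_relu(const arma::cube& X) {
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  const double* x = X.memptr(); double* y = Y.memptr();
  const size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return Y;
}

// dX = dY where Y > 0 (Y is the ReLU output)
// [[Rcpp::export]]
arma::cube cn_relu_bwd(const arma::cube& Y, const arma::cube& dY) {
  cube dX(Y.n_rows, Y.n_cols, Y.n_slices);
  const double* y = Y.memptr(); const double* dy = dY.memptr();
  double* dx = dX.memptr();
  const size_t n = Y.n_elem;
  for (size_t i = 0; i < n; ++i) dx[i] = y[i] > 0 ? dy[i] : 0.0;
  return dX;
}
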