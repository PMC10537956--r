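#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as (N*H*W) x C matrices, rows ordered
// batch-major, then image row, then image column:
//   row index r = (n*H + i)*W + j   (all 0-based).
// im2col lays each k x k receptive field out as a row of the patch matrix,
// columns ordered (ki, kj, c) with the channel fastest, so a convolution is
// a single GEMM with a (C*k*k) x Cout weight matrix.

// [[Rcpp::export(name = ".im2col_nhwc")]]
NumericMatrix im2col_nhwc(const NumericMatrix& X, int N, int H, int W,
                          int k, int stride, int pad) {
  const int C = X.ncol();
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix P(N * Ho * Wo, C * k * k);
  const double* xp = &X(0, 0);
  double* pp = &P(0, 0);
  const R_xlen_t xn = X.nrow(), pn = P.nrow();
  for (int n = 0; n < N; ++n) {
    for (int io = 0; io < Ho; ++io) {
      for (int jo = 0; jo < Wo; ++jo) {
        const R_xlen_t r = ((R_xlen_t)n * Ho + io) * Wo + jo;
        for (int ki = 0; ki < k; ++ki) {
          const int ii = io * stride - pad + ki;
          if (ii < 0 || ii >= H) continue;
          for (int kj = 0; kj < k; ++kj) {
            const int jj = jo * stride - pad + kj;
            if (jj < 0 || jj >= W) continue;
            const R_xlen_t src = ((R_xlen_t)n * H + ii) * W + jj;
            const int colbase = (ki * k + kj) * C;
            for (int c = 0; c < C; ++c) {
              pp[(colbase + c) * pn + r] = xp[(R_xlen_t)c * xn + src];
            }
          }
        }
      }
    }
  }
  return P;
}

// Transpose of im2col: scatter-adds a patch-matrix gradient back onto the
// input feature-map gradient.
// [[Rcpp::export(name = ".col2im_nhwc")]]
NumericMatrix col2im_nhwc(const NumericMatrix& dP, int N, int H, int W,
                          int C, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix dX(N * H * W, C);
  const double* pp = &dP(0, 0);
  double* xp = &dX(0, 0);
  const R_xlen_t xn = dX.nrow(), pn = dP.nrow();
  for (int n = 0; n < N; ++n) {
    for (int io = 0; io < Ho; ++io) {
      for (int jo = 0; jo < Wo; ++jo) {
        const R_xlen_t r = ((R_xlen_t)n * Ho + io) * Wo + jo;
        for (int ki = 0; ki < k; ++ki) {
          const int ii = io * stride - pad + ki;
          if (ii < 0 || ii >= H) continue;
          for (int kj = 0; kj < k; ++kj) {
            const int jj = jo * stride - pad + kj;
            if (jj < 0 || jj >= W) continue;
            const R_xlen_t dst = ((R_xlen_t)n * H + ii) * W + jj;
            const int colbase = (ki * k + kj) * C;
            for (int c = 0; c < C; ++c) {
              xp[(R_xlen_t)c * xn + dst] += pp[(colbase + c) * pn + r];
            }
          }
        }
      }
    }
  }
  return dX;
}

// Majority-vote block downsampling of an integer label matrix.
// Blocks where fewer than half the pixels are annotated (!= sentinel)
// become the sentinel; otherwise the majority annotated label wins, ties
// broken by the lowest class id.
// [[Rcpp::export(name = ".block_majority")]]
IntegerMatrix block_majority(const IntegerMatrix& lab, int factor,
                             int n_classes, int sentinel) {
  const int H = lab.nrow(), W = lab.ncol();
  const int Ho = H / factor, Wo = W / factor;
  IntegerMatrix out(Ho, Wo);
  std::vector<int> counts(n_classes);
  for (int bi = 0; bi < Ho; ++bi) {
    for (int bj = 0; bj < Wo; ++bj) {
      std::fill(counts.begin(), counts.end(), 0);
      int annotated = 0;
      for (int i = bi * factor; i < (bi + 1) * factor; ++i) {
        for (int j = bj * factor; j < (bj + 1) * factor; ++j) {
          const int v = lab(i, j);
          if (v != sentinel && v >= 0 && v < n_classes) {
            ++counts[v];
            ++annotated;
          }
        }
      }
      if (2 * annotated < factor * factor) {
        out(bi, bj) = sentinel;
      } else {
        int best = 0;
        for (int c = 1; c < n_classes; ++c) {
          if (counts[c] > counts[best]) best = c;  // ties keep lowest id
        }
        out(bi, bj) = best;
      }
    }
  }
  return out;
}

// Fused batch-norm + ReLU forward. A is (n x c); running stats updated in
// place on copies passed from R. Returns y, xhat, invstd.
// [[Rcpp::export(name = ".bn_relu_forward")]]
List bn_relu_forward(const NumericMatrix& A, NumericVector gamma,
                     NumericVector beta, NumericVector rmean,
                     NumericVector rvar, double eps, double momentum,
                     bool training) {
  const int n = A.nrow(), c = A.ncol();
  NumericMatrix Y(n, c), Xhat(n, c);
  NumericVector invstd(c), new_rmean(clone(rmean)), new_rvar(clone(rvar));
  for (int j = 0; j < c; ++j) {
    const double* a = &A(0, j);
    double mu, var;
    if (training) {
      double s = 0, s2 = 0;
      for (int i = 0; i < n; ++i) { s += a[i]; s2 += a[i] * a[i]; }
      mu = s / n;
      var = s2 / n - mu * mu;
      if (var < 0) var = 0;
      new_rmean[j] = (1 - momentum) * new_rmean[j] + momentum * mu;
      new_rvar[j] = (1 - momentum) * new_rvar[j] + momentum * var;
    } else {
      mu = rmean[j];
      var = rvar[j];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    invstd[j] = is;
    const double g = gamma[j], b = beta[j];
    double* xh = &Xhat(0, j);
    double* y = &Y(0, j);
    for (int i = 0; i < n; ++i) {
      const double v = (a[i] - mu) * is;
      xh[i] = v;
      const double o = g * v + b;
      y[i] = o > 0 ? o : 0.0;
    }
  }
  return List::create(_["y"] = Y, _["xhat"] = Xhat, _["invstd"] = invstd,
                      _["rmean"] = new_rmean, _["rvar"] = new_rvar);
}

// Fused ReLU + batch-norm backward: dy is the gradient w.r.t. the ReLU
// output, y the ReLU output (used as the activation mask).
// [[Rcpp::export(name = ".bn_relu_backward")]]
List bn_relu_backward(const NumericMatrix& dY, const NumericMatrix& Y,
                      const NumericMatrix& Xhat, NumericVector invstd,
                      NumericVector gamma) {
  const int n = dY.nrow(), c = dY.ncol();
  NumericMatrix dX(n, c);
  NumericVector dgamma(c), dbeta(c);
  std::vector<double> de(n);
  for (int j = 0; j < c; ++j) {
    const double* dy = &dY(0, j);
    const double* y = &Y(0, j);
    const double* xh = &Xhat(0, j);
    double sg = 0, sb = 0;
    for (int i = 0; i < n; ++i) {
      const double d = y[i] > 0 ? dy[i] : 0.0;
      de[i] = d;
      sg += d * xh[i];
      sb += d;
    }
    dgamma[j] = sg;
    dbeta[j] = sb;
    const double g = gamma[j], is = invstd[j];
    const double m1 = g * sb / n, m2 = g * sg / n;
    double* dx = &dX(0, j);
    for (int i = 0; i < n; ++i) {
      dx[i] = (g * de[i] - m1 - xh[i] * m2) * is;
    }
  }
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
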