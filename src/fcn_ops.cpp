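#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Stride-1 1-D convolution with left padding pl, computed as a sum of
// offset GEMMs on the flat (B*L) x C activation matrix (column-major, lda =
// B*L), avoiding any im2col materialization:
//   Y[b, t, f] = bias[f] + sum_{k,c} X[b, t+k-pl, c] * W[k*C + c, f]
// [[Rcpp::export]]
NumericMatrix conv1d_forward_cpp(const NumericMatrix& X, const NumericMatrix& W,
                                 const NumericVector& bias, int B, int L,
                                 int pl) {
  const int C = X.ncol(), CK = W.nrow(), F = W.ncol();
  const int K = CK / C;
  const int BL = B * L;
  NumericMatrix Y(BL, F);
  for (int f = 0; f < F; ++f) std::fill(&Y(0, f), &Y(0, f) + BL, bias[f]);
  const double one = 1.0;
  for (int k = 0; k < K; ++k) {
    const int s = k - pl;
    const int t0 = s < 0 ? -s : 0;
    const int t1 = s > 0 ? L - 1 - s : L - 1;
    if (t1 < t0) continue;
    const int m = (t1 - t0 + 1) * B;
    F77_CALL(dgemm)("N", "N", &m, &F, &C, &one,
                    &X(0, 0) + (R_xlen_t)(t0 + s) * B, &BL,
                    &W(0, 0) + k * C, &CK, &one,
                    &Y(0, 0) + (R_xlen_t)t0 * B, &BL FCONE FCONE);
  }
  return Y;
}

// Input gradient of the same convolution: dX = sum_k shift(dY, -s) * W_k^T
// [[Rcpp::export]]
NumericMatrix conv1d_backward_data_cpp(const NumericMatrix& dY,
                                       const NumericMatrix& W, int B, int L,
                                       int pl, int C) {
  const int CK = W.nrow(), F = W.ncol();
  const int K = CK / C;
  const int BL = B * L;
  NumericMatrix dX(BL, C);
  const double one = 1.0;
  for (int k = 0; k < K; ++k) {
    const int s = k - pl;
    const int u0 = s > 0 ? s : 0;
    const int u1 = s < 0 ? L - 1 + s : L - 1;
    if (u1 < u0) continue;
    const int m = (u1 - u0 + 1) * B;
    F77_CALL(dgemm)("N", "T", &m, &C, &F, &one,
                    &dY(0, 0) + (R_xlen_t)(u0 - s) * B, &BL,
                    &W(0, 0) + k * C, &CK, &one,
                    &dX(0, 0) + (R_xlen_t)u0 * B, &BL FCONE FCONE);
  }
  return dX;
}

// Weight gradient: dW[k*C + c, f] = sum over valid t of X[t+s, c] dY[t, f]
// [[Rcpp::export]]
NumericMatrix conv1d_grad_weights_cpp(const NumericMatrix& X,
                                      const NumericMatrix& dY, int B, int L,
                                      int pl, int K) {
  const int C = X.ncol(), F = dY.ncol();
  const int CK = C * K;
  const int BL = B * L;
  NumericMatrix dW(CK, F);
  const double one = 1.0;
  for (int k = 0; k < K; ++k) {
    const int s = k - pl;
    const int t0 = s < 0 ? -s : 0;
    const int t1 = s > 0 ? L - 1 - s : L - 1;
    if (t1 < t0) continue;
    const int m = (t1 - t0 + 1) * B;
    F77_CALL(dgemm)("T", "N", &C, &F, &m, &one,
                    &X(0, 0) + (R_xlen_t)(t0 + s) * B, &BL,
                    &dY(0, 0) + (R_xlen_t)t0 * B, &BL, &one,
                    &dW(0, 0) + k * C, &CK FCONE FCONE);
  }
  return dW;
}

// out[i, j] = M[i, j] * a[j] + b[j]
// [[Rcpp::export]]
NumericMatrix col_affine_cpp(const NumericMatrix& M, const NumericVector& a,
                             const NumericVector& b) {
  int n = M.nrow(), p = M.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    const double aj = a[j], bj = b[j];
    const double* src = &M(0, j);
    double* dst = &out(0, j);
    for (int i = 0; i < n; ++i) dst[i] = src[i] * aj + bj;
  }
  return out;
}

// training-mode batch normalization, fused: batch stats + xhat + gamma/beta
// [[Rcpp::export]]
List bn_forward_train_cpp(const NumericMatrix& Y, const NumericVector& g,
                          const NumericVector& be, double eps) {
  int n = Y.nrow(), p = Y.ncol();
  NumericVector mu(p), v(p), invstd(p);
  NumericMatrix xhat(n, p), out(n, p);
  for (int j = 0; j < p; ++j) {
    const double* col = &Y(0, j);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    mu[j] = s / n;
    double var = s2 / n - mu[j] * mu[j];
    v[j] = var > 0 ? var : 0;
    invstd[j] = 1.0 / std::sqrt(v[j] + eps);
    double* xh = &xhat(0, j);
    double* o = &out(0, j);
    const double m = mu[j], is = invstd[j], gj = g[j], bj = be[j];
    for (int i = 0; i < n; ++i) {
      xh[i] = (col[i] - m) * is;
      o[i] = xh[i] * gj + bj;
    }
  }
  return List::create(Named("xhat") = xhat, Named("out") = out,
                      Named("mean") = mu, Named("var") = v,
                      Named("invstd") = invstd);
}

// fused batch-norm input gradient; also returns dbeta and dgamma
// [[Rcpp::export]]
List bn_backward_cpp(const NumericMatrix& dOut, const NumericMatrix& xhat,
                     const NumericVector& ginv) {
  int n = dOut.nrow(), p = dOut.ncol();
  NumericVector s1(p), s2(p);
  NumericMatrix dY(n, p);
  for (int j = 0; j < p; ++j) {
    const double* d = &dOut(0, j);
    const double* xh = &xhat(0, j);
    double a = 0, b = 0;
    for (int i = 0; i < n; ++i) { a += d[i]; b += d[i] * xh[i]; }
    s1[j] = a; s2[j] = b;
    double* o = &dY(0, j);
    const double s1n = a / n, s2n = b / n, gj = ginv[j];
    for (int i = 0; i < n; ++i) o[i] = (d[i] - s1n - xh[i] * s2n) * gj;
  }
  return List::create(Named("dY") = dY, Named("dbe") = s1, Named("dg") = s2);
}

// [[Rcpp::export]]
NumericMatrix relu_cpp(const NumericMatrix& M) {
  int n = M.nrow(), p = M.ncol();
  NumericMatrix out(n, p);
  const double* src = M.begin();
  double* dst = out.begin();
  R_xlen_t len = (R_xlen_t)n * p;
  for (R_xlen_t i = 0; i < len; ++i) dst[i] = src[i] > 0 ? src[i] : 0;
  return out;
}

// dA masked by the forward activation's sign (A is the post-ReLU output)
// [[Rcpp::export]]
NumericMatrix relu_backward_cpp(const NumericMatrix& dA, const NumericMatrix& A) {
  int n = dA.nrow(), p = dA.ncol();
  NumericMatrix out(n, p);
  const double* d = dA.begin();
  const double* a = A.begin();
  double* dst = out.begin();
  R_xlen_t len = (R_xlen_t)n * p;
  for (R_xlen_t i = 0; i < len; ++i) dst[i] = a[i] > 0 ? d[i] : 0;
  return out;
}
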