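// Compiled convolution core: zero-padding, im2col gather, GEMM and the
// transposed scatter. Index vectors are precomputed in R (1-based).
// GEMMs run in single precision — ample for stochastic-gradient training —
// while all interfaces exchange doubles with R. The im2col buffer stays on
// the C++ side (external pointer) so the weight-gradient GEMM reuses it
// without conversion.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// x: (n_in, cin) input feature map (batch-stacked, column-major spatial)
// pidx: rows of the padded buffer holding the unpadded pixels (length n_in)
// idxvec: im2col gather rows into the padded buffer, ordered pixel-fastest
//         then kernel offset (length n_out * k2)
// W: (k2*cin, cout) weights; b: (cout) bias
// returns y = im2col(x) * W + b and a handle to the im2col buffer
// [[Rcpp::export]]
List cpp_conv_fwd(const NumericMatrix x, const IntegerVector pidx,
                  const IntegerVector idxvec, const int npad,
                  const int n_out, const NumericMatrix W,
                  const NumericVector b) {
  const int cin = x.ncol();
  const int n_in = x.nrow();
  const int k2 = idxvec.size() / n_out;
  const int cout = W.ncol();

  arma::fmat xpad(npad, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const double* xc = &x(0, c);
    float* xp = xpad.colptr(c);
    for (int i = 0; i < n_in; ++i) xp[pidx[i] - 1] = (float)xc[i];
  }

  XPtr<arma::fmat> xcol(new arma::fmat(n_out, k2 * cin), true);
  for (int c = 0; c < cin; ++c) {
    const float* xp = xpad.colptr(c);
    for (int j = 0; j < k2; ++j) {
      float* dst = xcol->colptr(c * k2 + j);
      const int* iv = &idxvec[j * n_out];
      for (int p = 0; p < n_out; ++p) dst[p] = xp[iv[p] - 1];
    }
  }

  arma::fmat Wf(W.nrow(), cout);
  for (int c = 0; c < cout; ++c) {
    const double* wc = &W(0, c);
    float* wf = Wf.colptr(c);
    for (int i = 0; i < W.nrow(); ++i) wf[i] = (float)wc[i];
  }
  arma::fmat yf = (*xcol) * Wf;
  NumericMatrix y(n_out, cout);
  for (int c = 0; c < cout; ++c) {
    double* yc = &y(0, c);
    const float* ycf = yf.colptr(c);
    const double bc = b[c];
    for (int p = 0; p < n_out; ++p) yc[p] = (double)ycf[p] + bc;
  }
  return List::create(_["y"] = y, _["xc"] = xcol);
}

// Weight gradient: im2col(x)^T * dy using the retained forward buffer.
// [[Rcpp::export]]
NumericMatrix cpp_conv_dW(SEXP xcol_ptr, const NumericMatrix dy) {
  XPtr<arma::fmat> xcol(xcol_ptr);
  const int n_out = dy.nrow();
  const int cout = dy.ncol();
  arma::fmat dyf(n_out, cout);
  for (int c = 0; c < cout; ++c) {
    const double* d = &dy(0, c);
    float* df = dyf.colptr(c);
    for (int p = 0; p < n_out; ++p) df[p] = (float)d[p];
  }
  arma::fmat dWf = xcol->t() * dyf;
  NumericMatrix dW(dWf.n_rows, dWf.n_cols);
  for (arma::uword c = 0; c < dWf.n_cols; ++c) {
    double* d = &dW(0, c);
    const float* s = dWf.colptr(c);
    for (arma::uword i = 0; i < dWf.n_rows; ++i) d[i] = (double)s[i];
  }
  return dW;
}

// dy: (n_out, cout); W as in the forward. Returns the input gradient
// (n_in, cin) by scattering dy * W^T back through the gather.
// [[Rcpp::export]]
NumericMatrix cpp_conv_bwd_dx(const NumericMatrix dy, const NumericMatrix W,
                              const IntegerVector idxvec, const int npad,
                              const IntegerVector pidx, const int k2) {
  const int n_out = dy.nrow();
  const int cout = dy.ncol();
  const int k2cin = W.nrow();
  const int cin = k2cin / k2;
  const int n_in = pidx.size();

  arma::fmat dyf(n_out, cout);
  for (int c = 0; c < cout; ++c) {
    const double* d = &dy(0, c);
    float* df = dyf.colptr(c);
    for (int p = 0; p < n_out; ++p) df[p] = (float)d[p];
  }
  arma::fmat Wf(k2cin, cout);
  for (int c = 0; c < cout; ++c) {
    const double* wc = &W(0, c);
    float* wf = Wf.colptr(c);
    for (int i = 0; i < k2cin; ++i) wf[i] = (float)wc[i];
  }
  arma::fmat dxc = dyf * Wf.t();

  arma::fmat dxpad(npad, cin, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    float* dp = dxpad.colptr(c);
    for (int j = 0; j < k2; ++j) {
      const float* src = dxc.colptr(c * k2 + j);
      const int* iv = &idxvec[j * n_out];
      for (int p = 0; p < n_out; ++p) dp[iv[p] - 1] += src[p];
    }
  }

  NumericMatrix dx(n_in, cin);
  for (int c = 0; c < cin; ++c) {
    double* d = &dx(0, c);
    const float* dp = dxpad.colptr(c);
    for (int i = 0; i < n_in; ++i) d[i] = (double)dp[pidx[i] - 1];
  }
  return dx;
}
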