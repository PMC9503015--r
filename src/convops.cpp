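// Hot paths of the CNN engine: im2col gather + GEMM convolution and
// max-pooling, forward and backward. Activation layout matches the R
// engine: matrices of shape (H*W*C, N), flat index h fastest, then w,
// then c. Gather index vectors are 1-based; the value H*W*C + 1 marks a
// padding entry (reads 0 for convolution, skipped for pooling).
//
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Xcol(r, l + L*n) = X[idx[r + rows*l], n]; padding entries read 0
static arma::mat gatherCols(const arma::mat& X, const IntegerVector& idx,
                              int rows, int L) {
  const int N = X.n_cols;
  const int HWC = X.n_rows;
  const int M = idx.size();            // rows * L
  arma::mat Xcol(rows, (arma::uword)L * N);
  for (int n = 0; n < N; ++n) {
    const double* xn = X.colptr(n);
    double* dst = Xcol.colptr((arma::uword)n * L);
    for (int m = 0; m < M; ++m) {
      const int j = idx[m] - 1;
      dst[m] = (j < HWC) ? xn[j] : 0.0;
    }
  }
  return Xcol;
}

// [[Rcpp::export]]
NumericMatrix convFwdCpp(const arma::mat& X, List idxList, List WList,
                         const arma::vec& b, int L) {
  const int N = X.n_cols;
  const int G = idxList.size();
  const int Cout = b.n_elem;
  arma::mat Yfull(Cout, (arma::uword)L * N);
  int off = 0;
  for (int g = 0; g < G; ++g) {
    IntegerVector idx = idxList[g];
    arma::mat W = as<arma::mat>(WList[g]);
    const int rows = W.n_cols;
    const int Og = W.n_rows;
    arma::mat Xcol = gatherCols(X, idx, rows, L);
    Yfull.rows(off, off + Og - 1) = W * Xcol;
    off += Og;
  }
  Yfull.each_col() += b;
  // reorder (Cout, L*N) -> (L*Cout, N)
  NumericMatrix out((R_xlen_t)L * Cout, N);
  double* op = REAL(out);
  for (int n = 0; n < N; ++n) {
    for (int l = 0; l < L; ++l) {
      const double* colv = Yfull.colptr((arma::uword)n * L + l);
      double* dst = op + (R_xlen_t)n * L * Cout + l;
      for (int c = 0; c < Cout; ++c) dst[(R_xlen_t)c * L] = colv[c];
    }
  }
  return out;
}

// [[Rcpp::export]]
List convBwdCpp(const arma::mat& X, const arma::mat& dOut, List idxList,
                List WList, int L, bool needDx) {
  const int N = X.n_cols;
  const int HWC = X.n_rows;
  const int G = idxList.size();
  const int Cout = dOut.n_rows / L;
  // (L*Cout, N) -> dYfull (Cout, L*N)
  arma::mat dYfull(Cout, (arma::uword)L * N);
  for (int n = 0; n < N; ++n) {
    const double* src = dOut.colptr(n);
    for (int l = 0; l < L; ++l) {
      double* colv = dYfull.colptr((arma::uword)n * L + l);
      for (int c = 0; c < Cout; ++c) colv[c] = src[(R_xlen_t)c * L + l];
    }
  }
  List dW(G);
  arma::mat dX;
  if (needDx) dX.zeros(HWC, N);
  int off = 0;
  for (int g = 0; g < G; ++g) {
    IntegerVector idx = idxList[g];
    arma::mat W = as<arma::mat>(WList[g]);
    const int rows = W.n_cols;
    const int Og = W.n_rows;
    arma::mat dYg = dYfull.rows(off, off + Og - 1);
    arma::mat Xcol = gatherCols(X, idx, rows, L);
    dW[g] = wrap(arma::mat(dYg * Xcol.t()));
    if (needDx) {
      arma::mat dXcol = W.t() * dYg;  // (rows, L*N)
      const int M = idx.size();
      for (int n = 0; n < N; ++n) {
        double* dxn = dX.colptr(n);
        const double* src = dXcol.colptr((arma::uword)n * L);
        for (int m = 0; m < M; ++m) {
          const int j = idx[m] - 1;
          if (j < HWC) dxn[j] += src[m];
        }
      }
    }
    off += Og;
  }
  arma::vec db = arma::sum(dYfull, 1);
  return List::create(_["dW"] = dW, _["db"] = wrap(db),
                      _["dX"] = needDx ? wrap(dX) : R_NilValue);
}

// [[Rcpp::export]]
List poolFwdCpp(const arma::mat& X, const IntegerVector& idx, int k2) {
  const int N = X.n_cols;
  const int HWC = X.n_rows;
  const int M = idx.size() / k2;       // L * C outputs per sample
  NumericMatrix out(M, N);
  IntegerVector amx((R_xlen_t)M * N);
  double* op = REAL(out);
  const double negInf = -std::numeric_limits<double>::infinity();
  for (int n = 0; n < N; ++n) {
    const double* xn = X.colptr(n);
    for (int m = 0; m < M; ++m) {
      double best = negInf;
      int bj = 1;
      const int base = k2 * m;
      for (int j = 0; j < k2; ++j) {
        const int id = idx[base + j] - 1;
        if (id < HWC) {
          const double v = xn[id];
          if (v > best) { best = v; bj = j + 1; }
        }
      }
      op[(R_xlen_t)n * M + m] = best;
      amx[(R_xlen_t)n * M + m] = bj;
    }
  }
  return List::create(_["max"] = out, _["argmax"] = amx);
}

// [[Rcpp::export]]
NumericMatrix poolBwdCpp(const arma::mat& dOut, const IntegerVector& amx,
                         const IntegerVector& idx, int k2, int HWC) {
  const int N = dOut.n_cols;
  const int M = dOut.n_rows;           // L * C
  NumericMatrix dX(HWC, N);
  double* dp = REAL(dX);
  for (int n = 0; n < N; ++n) {
    const double* dn = dOut.colptr(n);
    double* dxn = dp + (R_xlen_t)n * HWC;
    for (int m = 0; m < M; ++m) {
      const int j = amx[(R_xlen_t)n * M + m] - 1;
      const int id = idx[k2 * m + j] - 1;
      if (id < HWC) dxn[id] += dn[m];
    }
  }
  return dX;
}

// fully connected layers: Y = W X + b and its gradients
// [[Rcpp::export]]
NumericMatrix fcFwdCpp(const arma::mat& X, const arma::mat& W,
                       const arma::vec& b) {
  arma::mat Y = W * X;
  Y.each_col() += b;
  return wrap(Y);
}

// [[Rcpp::export]]
List fcBwdCpp(const arma::mat& X, const arma::mat& W, const arma::mat& dY) {
  return List::create(
    _["dW"] = wrap(arma::mat(dY * X.t())),
    _["db"] = wrap(arma::vec(arma::sum(dY, 1))),
    _["dX"] = wrap(arma::mat(W.t() * dY)));
}

// fused in-place SGD-with-momentum step: v <- mom*v - lr*(g + 2*l2*w);
// w <- w + v. Operates on training-local copies of the parameters.
// [[Rcpp::export]]
void sgdStepCpp(NumericVector w, NumericVector v, const NumericVector& g,
                double lr, double mom, double l2) {
  const R_xlen_t n = w.size();
  double* wp = REAL(w);
  double* vp = REAL(v);
  const double* gp = REAL(g);
  const double c = 2.0 * l2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double vi = mom * vp[i] - lr * (gp[i] + c * wp[i]);
    vp[i] = vi;
    wp[i] += vi;
  }
}

// [[Rcpp::export]]
double sumSquaresCpp(const NumericVector& w) {
  const R_xlen_t n = w.size();
  const double* wp = REAL(w);
  double s = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) s += wp[i] * wp[i];
  return s;
}
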