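// Hot numerical kernels: GELU activation and per-event multi-head attention.
// The surrounding forward/backward orchestration lives in R/nn.R; these
// kernels only remove interpreter overhead from the innermost loops.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double kGeluC = 0.7978845608028654;  // sqrt(2/pi)
static const double kGeluA = 0.044715;

// Forward: returns the activation and the tanh term, which the backward pass
// reuses so the transcendental is evaluated once per element per step.
// [[Rcpp::export]]
Rcpp::List cpp_gelu_fwd(const arma::mat& x) {
  mat y(x.n_rows, x.n_cols), t(x.n_rows, x.n_cols);
  const double* xi = x.memptr();
  double* yi = y.memptr();
  double* ti = t.memptr();
  for (size_t i = 0; i < x.n_elem; ++i) {
    double v = xi[i];
    double tt = std::tanh(kGeluC * (v + kGeluA * v * v * v));
    ti[i] = tt;
    yi[i] = 0.5 * v * (1.0 + tt);
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("t") = t);
}

// [[Rcpp::export]]
arma::mat cpp_gelu_grad(const arma::mat& dy, const arma::mat& x,
                        const arma::mat& t) {
  mat g(x.n_rows, x.n_cols);
  const double* di = dy.memptr();
  const double* xi = x.memptr();
  const double* ti = t.memptr();
  double* gi = g.memptr();
  for (size_t i = 0; i < x.n_elem; ++i) {
    double v = xi[i], tt = ti[i];
    double du = kGeluC * (1.0 + 3.0 * kGeluA * v * v);
    gi[i] = di[i] * (0.5 * (1.0 + tt) + 0.5 * v * (1.0 - tt * tt) * du);
  }
  return g;
}

// Multi-head scaled dot-product self-attention over an event-major batch.
// Q,K: (B*L) x (h*dk); V: (B*L) x (h*dv). Rows (b*L .. b*L+L-1) are event b.
// Returns the concatenated head outputs O ((B*L) x (h*dv)) and the attention
// weights as an (L x L x B*h) cube for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_attn_fwd(const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V, int B, int L, int h,
                        int dk, int dv) {
  mat O(Q.n_rows, (size_t)h * dv);
  cube A(L, L, (size_t)B * h);
  double sc = 1.0 / std::sqrt((double)dk);
  for (int b = 0; b < B; ++b) {
    size_t r0 = (size_t)b * L, r1 = r0 + L - 1;
    for (int j = 0; j < h; ++j) {
      size_t qc0 = (size_t)j * dk, qc1 = qc0 + dk - 1;
      size_t vc0 = (size_t)j * dv, vc1 = vc0 + dv - 1;
      mat S = Q.submat(r0, qc0, r1, qc1) * K.submat(r0, qc0, r1, qc1).t() * sc;
      S.each_col() -= max(S, 1);
      mat E = exp(S);
      E.each_col() /= sum(E, 1);
      A.slice((size_t)b * h + j) = E;
      O.submat(r0, vc0, r1, vc1) = E * V.submat(r0, vc0, r1, vc1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O, Rcpp::Named("A") = A);
}

// Backward pass matching cpp_attn_fwd. dO is the gradient w.r.t. O.
// [[Rcpp::export]]
Rcpp::List cpp_attn_bwd(const arma::mat& dO, const arma::mat& Q,
                        const arma::mat& K, const arma::mat& V,
                        const arma::cube& A, int B, int L, int h,
                        int dk, int dv) {
  mat dQ(Q.n_rows, Q.n_cols, fill::zeros);
  mat dK(K.n_rows, K.n_cols, fill::zeros);
  mat dV(V.n_rows, V.n_cols, fill::zeros);
  double sc = 1.0 / std::sqrt((double)dk);
  for (int b = 0; b < B; ++b) {
    size_t r0 = (size_t)b * L, r1 = r0 + L - 1;
    for (int j = 0; j < h; ++j) {
      size_t qc0 = (size_t)j * dk, qc1 = qc0 + dk - 1;
      size_t vc0 = (size_t)j * dv, vc1 = vc0 + dv - 1;
      const mat& Aij = A.slice((size_t)b * h + j);
      mat dOb = dO.submat(r0, vc0, r1, vc1);
      mat dA = dOb * V.submat(r0, vc0, r1, vc1).t();
      dV.submat(r0, vc0, r1, vc1) = Aij.t() * dOb;
      vec rs = sum(Aij % dA, 1);
      mat dS = (Aij % (dA.each_col() - rs)) * sc;
      dQ.submat(r0, qc0, r1, qc1) = dS * K.submat(r0, qc0, r1, qc1);
      dK.submat(r0, qc0, r1, qc1) = dS.t() * Q.submat(r0, qc0, r1, qc1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// Inverted dropout using R's RNG stream (keeps seeded runs reproducible).
// Returns the dropped activation and the scaled keep-mask for the backward.
// [[Rcpp::export]]
Rcpp::List cpp_dropout(const arma::mat& x, double p) {
  Rcpp::RNGScope scope;
  mat y(x.n_rows, x.n_cols), m(x.n_rows, x.n_cols);
  const double* xi = x.memptr();
  double* yi = y.memptr();
  double* mi = m.memptr();
  double keep = 1.0 / (1.0 - p);
  for (size_t i = 0; i < x.n_elem; ++i) {
    double mk = (unif_rand() >= p) ? keep : 0.0;
    mi[i] = mk;
    yi[i] = xi[i] * mk;
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("mask") = m);
}
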