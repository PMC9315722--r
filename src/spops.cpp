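#include <Rcpp.h>
using namespace Rcpp;

// Fused computational kernels for the GIN forward/backward passes. All node
// embedding matrices are feature-major (d x M: features in rows, nodes of
// the whole minibatch in columns); per-feature parameters index rows.
// Kernels suffixed _inplace mutate their first argument, which callers only
// pass freshly allocated, unshared matrices.

// Dense x sparse product D %*% S for a column-compressed (dgCMatrix) S:
// the aggregation kernel. Each output column is a sum of scaled embedding
// columns; __restrict__ lets the compiler vectorize the axpy loop.
// [[Rcpp::export(rng = false)]]
NumericMatrix dense_sparse_prod(NumericMatrix D, S4 S) {
  IntegerVector dims = S.slot("Dim");
  const int K = dims[0], M = dims[1], h = D.nrow();
  if (D.ncol() != K) stop("dense_sparse_prod: dimension mismatch");
  IntegerVector p = S.slot("p"), ri = S.slot("i");
  NumericVector x = S.slot("x");
  NumericMatrix out(h, M);
  double * __restrict__ po = REAL(out);
  const double * __restrict__ pd = REAL(D);
  const double * __restrict__ px = REAL(x);
  const int *pp = INTEGER(p), *pi = INTEGER(ri);
  for (int m = 0; m < M; ++m) {
    double * __restrict__ oc = po + (size_t)m * h;
    for (int k = pp[m]; k < pp[m + 1]; ++k) {
      const double xv = px[k];
      const double * __restrict__ dc = pd + (size_t)pi[k] * h;
      for (int t = 0; t < h; ++t) oc[t] += xv * dc[t];
    }
  }
  return out;
}

// out += alpha * X  (the (1 + eps) self term of the GIN aggregation)
// [[Rcpp::export(rng = false)]]
void axpy_inplace(NumericMatrix out, NumericMatrix X, double alpha) {
  const R_xlen_t n = out.size();
  if (X.size() != n) stop("axpy_inplace: dimension mismatch");
  double * __restrict__ po = REAL(out);
  const double * __restrict__ px = REAL(X);
  for (R_xlen_t i = 0; i < n; ++i) po[i] += alpha * px[i];
}

// U += b per row (bias broadcast)
// [[Rcpp::export(rng = false)]]
void add_bias_inplace(NumericMatrix U, NumericVector b) {
  const int h = U.nrow(), M = U.ncol();
  if (b.size() != h) stop("add_bias_inplace: dimension mismatch");
  double * __restrict__ pu = REAL(U);
  const double * __restrict__ pb = REAL(b);
  for (int m = 0; m < M; ++m) {
    double * __restrict__ uc = pu + (size_t)m * h;
    for (int t = 0; t < h; ++t) uc[t] += pb[t];
  }
}

// [[Rcpp::export(rng = false)]]
NumericMatrix relu_fwd(NumericMatrix U) {
  NumericMatrix out(U.nrow(), U.ncol());
  const double * __restrict__ pu = REAL(U);
  double * __restrict__ po = REAL(out);
  const R_xlen_t n = U.size();
  for (R_xlen_t i = 0; i < n; ++i) po[i] = pu[i] > 0 ? pu[i] : 0;
  return out;
}

// dU = dH on the active set of the ReLU whose output was Hout
// [[Rcpp::export(rng = false)]]
NumericMatrix relu_bwd(NumericMatrix dH, NumericMatrix Hout) {
  const R_xlen_t n = dH.size();
  if (Hout.size() != n) stop("relu_bwd: dimension mismatch");
  NumericMatrix out(dH.nrow(), dH.ncol());
  const double * __restrict__ pd = REAL(dH);
  const double * __restrict__ ph = REAL(Hout);
  double * __restrict__ po = REAL(out);
  for (R_xlen_t i = 0; i < n; ++i) po[i] = ph[i] > 0 ? pd[i] : 0;
  return out;
}

// Batch-norm affine transform: Uhat = (U - mu) * invstd,
// Bout = Uhat * gamma + beta, in one pass. Per-feature statistics and
// parameters index rows.
// [[Rcpp::export(rng = false)]]
List bn_fwd(NumericMatrix U, NumericVector mu, NumericVector invstd,
            NumericVector gamma, NumericVector beta) {
  const int h = U.nrow(), M = U.ncol();
  NumericMatrix Uhat(h, M), Bout(h, M);
  const double * __restrict__ pu = REAL(U);
  double * __restrict__ puh = REAL(Uhat);
  double * __restrict__ pb = REAL(Bout);
  const double *pm = REAL(mu), *pv = REAL(invstd), *pg = REAL(gamma),
               *pbe = REAL(beta);
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    for (int t = 0; t < h; ++t) {
      const double uh = (pu[off + t] - pm[t]) * pv[t];
      puh[off + t] = uh;
      pb[off + t] = uh * pg[t] + pbe[t];
    }
  }
  return List::create(_["Uhat"] = Uhat, _["Bout"] = Bout);
}

// Batch-norm backward (batch statistics): given the gradient at the affine
// output, returns the gradient at the input plus the per-feature gamma and
// beta gradients, via the standard population-statistics formula
// dU = invstd * gamma * (dBout - mean(dBout) - Uhat * mean(dBout * Uhat)).
// [[Rcpp::export(rng = false)]]
List bn_bwd(NumericMatrix dBout, NumericMatrix Uhat, NumericVector gamma,
            NumericVector invstd) {
  const int h = dBout.nrow(), M = dBout.ncol();
  NumericVector gGamma(h), gBeta(h);
  NumericMatrix dU(h, M);
  const double * __restrict__ pd = REAL(dBout);
  const double * __restrict__ puh = REAL(Uhat);
  double * __restrict__ po = REAL(dU);
  double *pgg = REAL(gGamma), *pgb = REAL(gBeta);
  const double *pg = REAL(gamma), *pv = REAL(invstd);
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    for (int t = 0; t < h; ++t) {
      pgb[t] += pd[off + t];
      pgg[t] += pd[off + t] * puh[off + t];
    }
  }
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    for (int t = 0; t < h; ++t) {
      po[off + t] = pv[t] * pg[t] *
        (pd[off + t] - pgb[t] / M - puh[off + t] * pgg[t] / M);
    }
  }
  return List::create(_["dU"] = dU, _["gGamma"] = gGamma, _["gBeta"] = gBeta);
}

// Attention pooling, vector gate: softmax of Graw across the nodes of each
// graph (independently per feature row) and the gate-weighted sum of node
// embeddings. gid maps batch columns to graphs (1-based, B graphs). A
// per-row global shift keeps exp() in range (any constant shift leaves the
// per-graph softmax exact); denominators are floored as a last resort.
// [[Rcpp::export(rng = false)]]
List softmax_pool_fwd(NumericMatrix Graw, NumericMatrix H,
                      IntegerVector gid, int B) {
  const int h = Graw.nrow(), M = Graw.ncol();
  if (H.nrow() != h || H.ncol() != M || gid.size() != M)
    stop("softmax_pool_fwd: dimension mismatch");
  NumericMatrix gate(h, M), g(h, B);
  NumericVector rmax(h, R_NegInf);
  std::vector<double> den((size_t)h * B, 0.0);
  const double * __restrict__ pgr = REAL(Graw);
  const double * __restrict__ ph = REAL(H);
  double * __restrict__ pgate = REAL(gate);
  double * __restrict__ pg = REAL(g);
  double *prm = REAL(rmax);
  const int *pgid = INTEGER(gid);
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    for (int t = 0; t < h; ++t)
      if (pgr[off + t] > prm[t]) prm[t] = pgr[off + t];
  }
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    double *db = den.data() + (size_t)(pgid[m] - 1) * h;
    for (int t = 0; t < h; ++t) {
      const double e = std::exp(pgr[off + t] - prm[t]);
      pgate[off + t] = e;
      db[t] += e;
    }
  }
  for (size_t i = 0; i < den.size(); ++i)
    if (den[i] < 1e-300) den[i] = 1e-300;
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    const double *db = den.data() + (size_t)(pgid[m] - 1) * h;
    double *gb = pg + (size_t)(pgid[m] - 1) * h;
    for (int t = 0; t < h; ++t) {
      const double w = pgate[off + t] / db[t];
      pgate[off + t] = w;
      gb[t] += w * ph[off + t];
    }
  }
  return List::create(_["gate"] = gate, _["g"] = g);
}

// Backward of softmax_pool_fwd: given dL/dg, returns the pooling
// contribution to dL/dH and the gradient at the pre-softmax gate scores.
// [[Rcpp::export(rng = false)]]
List softmax_pool_bwd(NumericMatrix dg, NumericMatrix H, NumericMatrix gate,
                      IntegerVector gid) {
  const int h = H.nrow(), M = H.ncol(), B = dg.ncol();
  if (dg.nrow() != h || gate.nrow() != h || gate.ncol() != M || gid.size() != M)
    stop("softmax_pool_bwd: dimension mismatch");
  NumericMatrix dH(h, M), dGraw(h, M);
  std::vector<double> s((size_t)h * B, 0.0);
  const double * __restrict__ pdg = REAL(dg);
  const double * __restrict__ ph = REAL(H);
  const double * __restrict__ pgate = REAL(gate);
  double * __restrict__ pdH = REAL(dH);
  double * __restrict__ pdG = REAL(dGraw);
  const int *pgid = INTEGER(gid);
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    const double *dgb = pdg + (size_t)(pgid[m] - 1) * h;
    double *sb = s.data() + (size_t)(pgid[m] - 1) * h;
    for (int t = 0; t < h; ++t) {
      const double dgate = dgb[t] * ph[off + t];
      pdG[off + t] = dgate;                    // temporarily holds dgate
      pdH[off + t] = dgb[t] * pgate[off + t];
      sb[t] += pgate[off + t] * dgate;
    }
  }
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    const double *sb = s.data() + (size_t)(pgid[m] - 1) * h;
    for (int t = 0; t < h; ++t)
      pdG[off + t] = pgate[off + t] * (pdG[off + t] - sb[t]);
  }
  return List::create(_["dH"] = dH, _["dGraw"] = dGraw);
}

// Per-feature mean and biased variance over columns, one pass.
// [[Rcpp::export(rng = false)]]
List row_mean_var(NumericMatrix U) {
  const int h = U.nrow(), M = U.ncol();
  NumericVector mu(h), va(h);
  const double * __restrict__ pu = REAL(U);
  double *pm = REAL(mu), *pv = REAL(va);
  for (int m = 0; m < M; ++m) {
    const size_t off = (size_t)m * h;
    for (int t = 0; t < h; ++t) {
      pm[t] += pu[off + t];
      pv[t] += pu[off + t] * pu[off + t];
    }
  }
  for (int t = 0; t < h; ++t) {
    pm[t] /= M;
    pv[t] = pv[t] / M - pm[t] * pm[t];
    if (pv[t] < 0) pv[t] = 0;
  }
  return List::create(_["mu"] = mu, _["va"] = va);
}
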