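// Gibbs sampler for the liability-threshold animal model.
//
// Location effects (beta, u) are updated by a single-site Gauss-Seidel
// sweep over the mixed-model-equation coefficient matrix
//   C(sigma) = W'W / R  +  sum_b K_b / sigma2_b
// whose sparsity pattern is fixed across iterations: the R side passes
// the combined pattern (cp, ci) once, with the W'W values (mx) and each
// block's K contribution (kx_b, A-inverse for the individual block,
// identity otherwise) aligned to that pattern, so per-iteration cost is
// O(nnz). Latent liabilities are redrawn from one-sided truncated
// normals; variance components from their scaled-inverse-chi-square full
// conditionals, optionally with MCMCglmm-style parameter expansion
// (working scale alpha ~ N(0, alphaV)).

#include <Rcpp.h>
using namespace Rcpp;

// standard normal truncated to (a, Inf); Robert (1995) exponential
// rejection in the far right tail, plain rejection otherwise.
static double rtnorm_above(double a) {
  if (a < 0.45) {
    double x;
    do {
      x = norm_rand();
    } while (x <= a);
    return x;
  }
  const double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a - std::log(unif_rand()) / lambda;
    double d = x - lambda;
    if (std::log(unif_rand()) <= -0.5 * d * d) return x;
  }
}

// one draw from N(mean, sd^2) truncated to (0, Inf) or (-Inf, 0]
static double rtnorm_signed(double mean, double sd, bool above) {
  if (above) return mean + sd * rtnorm_above(-mean / sd);
  return -(-mean + sd * rtnorm_above(mean / sd));
}

// [[Rcpp::export(name = ".rtruncnormCpp")]]
NumericVector rtruncnorm_cpp(int n, double mean, double sd, bool above) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rtnorm_signed(mean, sd, above);
  return out;
}

// [[Rcpp::export(name = ".gibbsChainCpp")]]
List gibbs_chain(
    IntegerVector wp, IntegerVector wi, NumericVector wx, // W by row (CSR)
    IntegerVector cp, IntegerVector ci,                   // C pattern (CSC)
    NumericVector mx,                                     // W'W values on pattern
    List kxList,                                          // per-block K values on pattern
    IntegerVector blockFrom, IntegerVector blockTo,       // column ranges per block
    IntegerVector yBin,            // 1/0/NA_INTEGER (threshold mode)
    NumericVector yGauss,          // response (gaussian mode)
    bool threshold, double rscale,
    NumericVector priorNu, NumericVector priorV,
    LogicalVector px, NumericVector alphaV,
    bool fixVariances, NumericVector sigma2Init,
    int niter, int burnin, int thin, bool recordLiab) {

  const int n = wp.size() - 1;
  const int P = cp.size() - 1;
  const int B = kxList.size();
  const double sdRes = std::sqrt(rscale);

  // column index of every pattern entry
  std::vector<int> colOf(ci.size());
  for (int j = 0; j < P; ++j)
    for (int k = cp[j]; k < cp[j + 1]; ++k) colOf[k] = j;

  // per-block K contributions as (pattern index, value) pairs
  std::vector<std::vector<int> > kidx(B);
  std::vector<std::vector<double> > kval(B);
  for (int b = 0; b < B; ++b) {
    NumericVector kb = as<NumericVector>(kxList[b]);
    for (R_xlen_t k = 0; k < kb.size(); ++k) {
      if (kb[k] != 0.0) {
        kidx[b].push_back(static_cast<int>(k));
        kval[b].push_back(kb[k]);
      }
    }
  }

  // column -> block (-1 fixed), for per-block predictor contributions
  std::vector<int> blockOf(P, -1);
  for (int b = 0; b < B; ++b)
    for (int j = blockFrom[b]; j < blockTo[b]; ++j) blockOf[j] = b;

  NumericVector theta(P, 0.0);
  NumericVector sigma2 = clone(sigma2Init);
  std::vector<double> alpha(B, 1.0);
  NumericVector liab(n);
  if (!threshold) liab = clone(yGauss);

  NumericVector cx(mx.size());
  NumericVector rhs(P);
  std::vector<double> eta(n), contrib;

  const int nret = (niter - burnin) / thin;
  NumericMatrix varOut(nret, B);
  NumericMatrix effOut(nret, P);
  NumericMatrix liabOut(recordLiab ? nret : 0, recordLiab ? n : 0);
  int rec = 0;

  for (int it = 1; it <= niter; ++it) {
    // (1) linear predictor and latent liabilities
    if (threshold) {
      for (int i = 0; i < n; ++i) {
        double e = 0.0;
        for (int k = wp[i]; k < wp[i + 1]; ++k) e += wx[k] * theta[wi[k]];
        eta[i] = e;
        if (yBin[i] == NA_INTEGER) {
          liab[i] = e + sdRes * norm_rand();
        } else {
          liab[i] = rtnorm_signed(e, sdRes, yBin[i] == 1);
        }
      }
    }

    // (2) right-hand side and coefficient values at current variances
    std::fill(rhs.begin(), rhs.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int k = wp[i]; k < wp[i + 1]; ++k)
        rhs[wi[k]] += wx[k] * liab[i] / rscale;
    for (R_xlen_t k = 0; k < cx.size(); ++k) cx[k] = mx[k] / rscale;
    for (int b = 0; b < B; ++b) {
      const double g = 1.0 / sigma2[b];
      const std::vector<int>& idx = kidx[b];
      const std::vector<double>& val = kval[b];
      for (size_t t = 0; t < idx.size(); ++t) cx[idx[t]] += g * val[t];
    }

    // (3) single-site Gauss-Seidel sweep over (beta, u)
    for (int j = 0; j < P; ++j) {
      double s = 0.0, cjj = 0.0;
      for (int k = cp[j]; k < cp[j + 1]; ++k) {
        if (ci[k] == j) cjj = cx[k];
        else s += cx[k] * theta[ci[k]];
      }
      double cmean = (rhs[j] - s) / cjj;
      theta[j] = cmean + norm_rand() / std::sqrt(cjj);
    }

    // (4) variance components
    if (!fixVariances) {
      for (int b = 0; b < B; ++b) {
        const int q = blockTo[b] - blockFrom[b];
        double uKu = 0.0;
        {
          const std::vector<int>& idx = kidx[b];
          const std::vector<double>& val = kval[b];
          for (size_t t = 0; t < idx.size(); ++t)
            uKu += val[t] * theta[ci[idx[t]]] * theta[colOf[idx[t]]];
        }
        if (px[b]) {
          // eta_b = u_b / alpha_b held fixed while alpha is refreshed
          const double a0 = std::abs(alpha[b]) < 1e-12 ?
            (alpha[b] < 0 ? -1e-12 : 1e-12) : alpha[b];
          // predictor contribution of this block per record
          contrib.assign(n, 0.0);
          double ww = 0.0, wr = 0.0;
          for (int i = 0; i < n; ++i) {
            double c = 0.0, e = 0.0;
            for (int k = wp[i]; k < wp[i + 1]; ++k) {
              double v = wx[k] * theta[wi[k]];
              e += v;
              if (blockOf[wi[k]] == b) c += v;
            }
            double w = c / a0;
            double res = liab[i] - (e - c);
            ww += w * w;
            wr += w * res;
          }
          const double prec = ww / rscale + 1.0 / alphaV[b];
          const double amean = (wr / rscale) / prec;
          const double anew = amean + norm_rand() / std::sqrt(prec);
          const double etaKeta = uKu / (a0 * a0);
          const double s2eta =
            (priorNu[b] * priorV[b] + etaKeta) / ::Rf_rchisq(priorNu[b] + q);
          const double scale = anew / a0;
          for (int j = blockFrom[b]; j < blockTo[b]; ++j) theta[j] *= scale;
          alpha[b] = anew;
          sigma2[b] = anew * anew * s2eta;
        } else {
          sigma2[b] =
            (priorNu[b] * priorV[b] + uKu) / ::Rf_rchisq(priorNu[b] + q);
        }
        if (sigma2[b] < 1e-12) sigma2[b] = 1e-12;
        if (sigma2[b] > 1e8)
          stop("divergent variance component (block %d, iteration %d)", b + 1, it);
      }
    }

    // (5) record
    const int post = it - burnin;
    if (post > 0 && post % thin == 0 && rec < nret) {
      for (int b = 0; b < B; ++b) varOut(rec, b) = sigma2[b];
      for (int j = 0; j < P; ++j) effOut(rec, j) = theta[j];
      if (recordLiab)
        for (int i = 0; i < n; ++i) liabOut(rec, i) = liab[i];
      ++rec;
    }
  }

  return List::create(
    _["variances"] = varOut, _["effects"] = effOut, _["liabilities"] = liabOut);
}
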