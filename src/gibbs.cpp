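// Multi-kernel GBLUP Gibbs sampler, run in the eigenbasis of each kernel.
//
// Model: y = X b + sum_k U_k a_k + e,  a_k ~ N(0, D_k sigma_k^2),
//        e ~ N(0, I sigma_e^2), flat prior on b, scaled-inverse-chi-square
//        priors on every variance. U_k D_k U_k' is the (truncated)
//        eigendecomposition of kernel k, so given the rest the coordinates
//        of a_k are conditionally independent. All n-vector quantities are
//        expressed through the precomputed projections U_k'y, U_k'X and
//        cross-products U_k'U_l, which makes a single-kernel update O(r)
//        and a two-kernel update one r x r matrix-vector product.
//
// Uses R's RNG (RNGScope) so set.seed() gives bit-reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// one draw from scaled-inv-chi-square(df, scale): df*scale / chisq(df)
static inline double rscinvchisq(double df, double scale) {
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".gibbs_gblup_cpp")]]
List gibbs_gblup_cpp(int n,
                     const arma::mat& XtX,
                     const arma::vec& Xty,
                     double yty,
                     List kernels,    // each: list(d, Uty, UtX)
                     List cross,      // cross[[k]][[l]], l < k: U_l'U_k
                     const arma::vec& df0,   // genetic dfs then residual
                     const arma::vec& S0,    // matching prior scales
                     int n_iter, int burn_in, int thin) {
  const int K = kernels.size();
  const int f = XtX.n_rows;
  const int S = (n_iter - burn_in) / thin;

  std::vector<arma::vec> d(K), Uty(K), a(K);
  std::vector<arma::mat> UtX(K);
  std::vector<std::vector<arma::mat>> W(K); // W[k][l], l<k: U_l'U_k
  arma::ivec rk(K);
  for (int k = 0; k < K; ++k) {
    List kk = kernels[k];
    d[k]   = as<arma::vec>(kk["d"]);
    Uty[k] = as<arma::vec>(kk["Uty"]);
    UtX[k] = as<arma::mat>(kk["UtX"]);
    rk[k]  = d[k].n_elem;
    a[k]   = arma::zeros(rk[k]);
    W[k].resize(k);
    List crk = cross[k];
    for (int l = 0; l < k; ++l) W[k][l] = as<arma::mat>(crk[l]);
  }

  arma::mat L = arma::chol(XtX, "lower");
  arma::vec b = arma::solve(arma::trimatu(L.t()),
                            arma::solve(arma::trimatl(L), Xty));
  arma::vec sig(K + 1);
  for (int k = 0; k < K; ++k) sig[k] = S0[k];
  double sige = S0[K];

  arma::mat b_draws(S, f), var_draws(S, K + 1);
  arma::vec dev_draws(S);
  List a_draws(K);
  std::vector<arma::mat> a_store(K);
  for (int k = 0; k < K; ++k) a_store[k] = arma::mat(S, rk[k]);

  // scratch
  std::vector<arma::vec> UtXb(K);
  arma::vec z(f), xtr(f), mean_b(f);
  const double ln2pi = std::log(2.0 * M_PI);
  int s = 0;

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    // --- b | rest ---------------------------------------------------
    xtr = Xty;
    for (int k = 0; k < K; ++k) xtr -= UtX[k].t() * a[k];
    mean_b = arma::solve(arma::trimatu(L.t()),
                         arma::solve(arma::trimatl(L), xtr));
    for (int j = 0; j < f; ++j) z[j] = R::norm_rand();
    b = mean_b + std::sqrt(sige) * arma::solve(arma::trimatu(L.t()), z);

    // --- a_k | rest (coordinates independent) -----------------------
    for (int k = 0; k < K; ++k) {
      UtXb[k] = UtX[k] * b;
      arma::vec tt = Uty[k] - UtXb[k];
      for (int l = 0; l < K; ++l) {
        if (l == k) continue;
        if (l < k)      tt -= W[k][l].t() * a[l];
        else            tt -= W[l][k] * a[l];
      }
      const double ise = 1.0 / sige;
      for (int i = 0; i < rk[k]; ++i) {
        double v = 1.0 / (ise + 1.0 / (d[k][i] * sig[k]));
        a[k][i] = v * tt[i] * ise + std::sqrt(v) * R::norm_rand();
      }
    }

    // --- genetic variances ------------------------------------------
    for (int k = 0; k < K; ++k) {
      double quad = arma::accu(arma::square(a[k]) / d[k]);
      double dfp = df0[k] + rk[k];
      sig[k] = rscinvchisq(dfp, (quad + df0[k] * S0[k]) / dfp);
    }

    // --- residual variance via e'e expansion ------------------------
    double sbx = arma::dot(b, Xty);
    double bXXb = arma::dot(b, XtX * b);
    double ete = yty - 2.0 * sbx + bXXb;
    for (int k = 0; k < K; ++k) {
      ete += -2.0 * arma::dot(a[k], Uty[k])
             + 2.0 * arma::dot(a[k], UtXb[k])
             + arma::dot(a[k], a[k]);
      for (int l = 0; l < k; ++l)
        ete += 2.0 * arma::dot(a[l], W[k][l] * a[k]);
    }
    if (ete < 0) ete = 0; // cancellation guard; e'e is a sum of squares
    double dfe = df0[K] + n;
    sige = rscinvchisq(dfe, (ete + df0[K] * S0[K]) / dfe);

    if (!std::isfinite(sige) || !std::isfinite(ete))
      stop("non-finite draw at iteration %d", it);

    // --- record ------------------------------------------------------
    if (it > burn_in && (it - burn_in) % thin == 0) {
      b_draws.row(s) = b.t();
      for (int k = 0; k < K; ++k) {
        a_store[k].row(s) = a[k].t();
        var_draws(s, k) = sig[k];
      }
      var_draws(s, K) = sige;
      dev_draws[s] = n * (ln2pi + std::log(sige)) + ete / sige;
      ++s;
    }
  }

  for (int k = 0; k < K; ++k) a_draws[k] = a_store[k];
  return List::create(_["b_draws"] = b_draws,
                      _["a_draws"] = a_draws,
                      _["var_draws"] = var_draws,
                      _["deviance_draws"] = dev_draws);
}
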