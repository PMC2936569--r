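#include <RcppArmadillo.h>
using namespace Rcpp;

// Weighted identity-by-state similarity over all pairs of individuals.
// Z is the n x m dosage matrix coded -1/0/1; with x = 1 - Z the per-locus
// count of allele "1", the four-way allele comparison score is
// (x_i x_j + (2-x_i)(2-x_j))/4, so with c = X w and s = sum(w):
//   S = (2 X W X' - 2 c 1' - 2 1 c' + 4 s J) / (4 s).
// [[Rcpp::export]]
arma::mat weighted_ibs_cpp(const arma::mat& Z, const arma::vec& w) {
  const arma::uword n = Z.n_rows;
  const double s = arma::accu(w);
  arma::mat X = 1.0 - Z;                 // allele-"1" counts in {0,1,2}
  arma::vec c = X * w;
  arma::mat Xw = X.each_row() % w.t();
  arma::mat S = 2.0 * (Xw * X.t());
  S.each_col() -= 2.0 * c;
  S.each_row() -= 2.0 * c.t();
  S += 4.0 * s;
  S /= 4.0 * s;
  S = 0.5 * (S + S.t());                 // enforce exact symmetry
  (void)n;
  return S;
}

// Gauss-Seidel sweeps on A x = b; convergence on the maximum absolute update.
// [[Rcpp::export]]
List gauss_seidel_cpp(const arma::mat& A, const arma::vec& b, arma::vec x,
                      double tol, int max_iter) {
  const arma::uword n = A.n_rows;
  double delta = R_PosInf;
  int it = 0;
  for (; it < max_iter; ++it) {
    delta = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      const double* col = A.colptr(i);   // A symmetric: column i == row i
      double s = b[i];
      for (arma::uword j = 0; j < n; ++j) s -= col[j] * x[j];
      s += col[i] * x[i];
      const double xi = s / col[i];
      const double d = std::fabs(xi - x[i]);
      if (d > delta) delta = d;
      x[i] = xi;
    }
    if (delta < tol) { ++it; break; }
  }
  return List::create(_["x"] = x, _["iterations"] = it, _["delta"] = delta,
                      _["converged"] = delta < tol);
}

// BayesB marker-effect sampler (Gibbs with embedded Metropolis-Hastings on
// each marker's (indicator, variance) pair). The per-marker variance is 0
// with prior probability pi, otherwise scaled-inverse-chi-square(df, scale).
// MH proposals are drawn from the prior and accepted on the marginal
// likelihood ratio of the data corrected for all other effects. Residual
// variance is held fixed. Post-burn-in samples are averaged.
static inline double loglik_v(double v, double zz, double zr, double se2) {
  // marginal log-likelihood terms of y* that depend on v (y* = r + z g)
  return -0.5 * std::log(se2 + v * zz) +
          0.5 * v * zr * zr / (se2 * (se2 + v * zz));
}

// [[Rcpp::export]]
List bayesb_cpp(const arma::vec& y, const arma::mat& Z, double sigma_e2,
                double pi_zero, double df, double scale,
                int n_cycles, int burn_in, int n_mh, bool use_xtx) {
  const arma::uword n = Z.n_rows, m = Z.n_cols;
  arma::vec zz(m);
  for (arma::uword k = 0; k < m; ++k) zz[k] = arma::dot(Z.col(k), Z.col(k));

  double b = arma::mean(y);
  arma::vec g(m, arma::fill::zeros), v(m, arma::fill::zeros);
  arma::vec r = y - b;
  arma::vec g_sum(m, arma::fill::zeros), v_sum(m, arma::fill::zeros);
  double b_sum = 0.0;
  int n_kept = 0;

  // With the marker cross-product matrix in memory, z_k'r is maintained
  // incrementally: only in-model markers (a fraction 1 - pi of the panel)
  // change the residual within a cycle, so each full sweep costs
  // O(m + n_changes * m) instead of m dot products of length n.
  arma::mat XtX;
  arma::vec zr, zsum;
  if (use_xtx) {
    XtX = Z.t() * Z;
    zr = Z.t() * r;
    zsum = arma::sum(Z, 0).t();
  }

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    // overall mean: full conditional N(b + mean(r), sigma_e2/n)
    const double b_new = b + arma::mean(r) + norm_rand() * std::sqrt(sigma_e2 / n);
    r -= (b_new - b);
    if (use_xtx) zr -= (b_new - b) * zsum;
    b = b_new;

    for (arma::uword k = 0; k < m; ++k) {
      const double zzk = zz[k];
      if (zzk <= 0.0) continue;          // void column (never emitted by sim)
      const double zyk = (use_xtx ? zr[k] : arma::dot(Z.col(k), r)) +
                         g[k] * zzk;     // z'y*
      double vk = v[k];
      double ll_cur = loglik_v(vk, zzk, zyk, sigma_e2);
      for (int t = 0; t < n_mh; ++t) {
        const double vp = (unif_rand() < pi_zero)
                            ? 0.0
                            : df * scale / R::rchisq(df);
        if (vp == vk) continue;
        const double ll_prop = loglik_v(vp, zzk, zyk, sigma_e2);
        if (std::log(unif_rand()) < ll_prop - ll_cur) {
          vk = vp;
          ll_cur = ll_prop;
        }
      }
      double g_new = 0.0;
      if (vk > 0.0) {
        const double c = zzk + sigma_e2 / vk;
        g_new = zyk / c + norm_rand() * std::sqrt(sigma_e2 / c);
      }
      if (g[k] != g_new) {
        const double dg = g_new - g[k];
        r -= Z.col(k) * dg;
        if (use_xtx) zr -= XtX.col(k) * dg;
        g[k] = g_new;
      }
      v[k] = vk;
    }
    if (use_xtx && (cyc + 1) % 500 == 0) zr = Z.t() * r;  // curb drift

    if (cyc >= burn_in) {
      g_sum += g;
      v_sum += v;
      b_sum += b;
      ++n_kept;
    }
  }

  return List::create(_["g_hat"] = g_sum / n_kept,
                      _["var_post"] = v_sum / n_kept,
                      _["b_hat"] = b_sum / n_kept,
                      _["n_kept"] = n_kept);
}
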