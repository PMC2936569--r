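#' Expected variance contributed by a marker
#'
#' `2 p (1 - p) g^2` for an estimated effect `g` at allele frequency `p`;
#' the per-marker weight used by the TAP relationship matrix.
#'
#' @param g_hat Estimated marker effect(s).
#' @param p Allele frequency (either allele; the expression is symmetric).
#' @return Non-negative variance contribution(s).
#' @export
#' @examples
#' expected_marker_variance(1, 0.5)   # 0.5
expected_marker_variance <- function(g_hat, p) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  2 * p * (1 - p) * g_hat^2
}

new_marker_effects <- function(geno, g_hat, weight, method, b_hat, extra = list()) {
  p <- allele_one_freq(geno)
  out <- tibble(marker = if (is.null(colnames(geno))) seq_len(ncol(geno))
                         else colnames(geno),
                g_hat = unname(g_hat), p = unname(p), weight = unname(weight))
  attr(out, "method") <- method
  attr(out, "b_hat") <- b_hat
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("gs_marker_effects", class(out))
  out
}

check_training_data <- function(pheno, geno) {
  if (!all(c("id", "phenotype") %in% names(pheno)))
    stop("`pheno` must have columns `id` and `phenotype`")
  if (nrow(pheno) < 2) stop("at least two phenotyped individuals are required")
  if (anyNA(geno)) stop("missing genotypes are not supported")
  if (ncol(geno) < 1) stop("at least one marker is required")
  ord <- match(as.character(pheno$id), rownames(geno))
  if (anyNA(ord)) stop("every phenotyped individual must be genotyped")
  y <- pheno$phenotype
  if (var(y) == 0) stop("phenotypes are constant; marker effects are not identifiable")
  list(y = y, Z = geno[ord, , drop = FALSE])
}

#' Estimate marker effects by ridge-regression BLUP
#'
#' Fits `y = 1 b + Z g + e` with a common marker-effect variance
#' `sigma_g2 = sigma_a2 / N` (N markers) and the true residual variance,
#' i.e. ridge shrinkage `lambda = sigma_e2 / sigma_g2` on every marker and
#' the overall mean as the only fixed effect. The system is solved in the
#' individual dimension (`n x n`), which is algebraically identical to the
#' marker-dimension ridge solve and far cheaper when markers outnumber
#' individuals.
#'
#' @param pheno Tibble with `id` and `phenotype` (the training records).
#' @param geno Dosage matrix (-1/0/1) with ids as row names; training rows
#'   are matched by id.
#' @param vc [variance_components()] holding the true `sigma_a2` and
#'   `sigma_e2`.
#' @return A `gs_marker_effects` tibble: `marker`, `g_hat`, `p` (training
#'   allele-1 frequency) and `weight` = `2 p (1 - p) g_hat^2`, with the
#'   fitted mean, `sigma_g2` and `lambda` as attributes.
#' @export
estimate_rrblup <- function(pheno, geno, vc) {
  stopifnot(inherits(vc, "gs_vc"))
  dat <- check_training_data(pheno, geno)
  y <- dat$y
  Z <- dat$Z
  n <- length(y)
  N <- ncol(Z)
  sigma_g2 <- vc$sigma_a2 / N
  V <- tcrossprod(Z) * sigma_g2
  diag(V) <- diag(V) + vc$sigma_e2
  Vi <- chol2inv(chol(V))
  one <- rep(1, n)
  b_hat <- sum(Vi %*% y) / sum(Vi)
  g_hat <- drop(sigma_g2 * crossprod(Z, Vi %*% (y - b_hat)))
  p <- allele_one_freq(Z)
  new_marker_effects(Z, g_hat, expected_marker_variance(g_hat, p),
                     method = "RRBLUP", b_hat = b_hat,
                     extra = list(sigma_g2 = sigma_g2,
                                  lambda = vc$sigma_e2 / sigma_g2))
}

#' BayesB chain settings
#'
#' @param pi_in Prior probability `1 - pi` that a marker has a non-zero
#'   effect variance; in the simulation study this is the exact ratio of
#'   simulated QTL to markers.
#' @param n_cycles Total MCMC cycles.
#' @param burn_in Cycles discarded before averaging (`< n_cycles`).
#' @param mh_cycles Metropolis-Hastings proposals per marker within each
#'   Gibbs cycle.
#' @param df Degrees of freedom of the scaled-inverse-chi-square variance
#'   prior.
#' @param scale Scale of that prior; `NULL` (default) derives it from the
#'   data so that it matches the average per-marker variance of an
#'   in-model marker, `sigma_a2 / (pi_in * sum_k 2 p_k (1 - p_k))`.
#' @return A `bayesb_config` list.
#' @export
bayesb_config <- function(pi_in, n_cycles = 10000, burn_in = 2000,
                          mh_cycles = 100, df = 1, scale = NULL) {
  if (pi_in <= 0 || pi_in > 1) stop("`pi_in` (1 - pi) must lie in (0, 1]")
  if (n_cycles <= 0 || burn_in < 0 || mh_cycles <= 0)
    stop("chain lengths must be positive")
  if (burn_in >= n_cycles) stop("`burn_in` must be smaller than `n_cycles`")
  structure(list(pi_in = pi_in, n_cycles = as.integer(n_cycles),
                 burn_in = as.integer(burn_in),
                 mh_cycles = as.integer(mh_cycles), df = df, scale = scale),
            class = "bayesb_config")
}

#' Estimate marker effects by BayesB
#'
#' Markov chain Monte Carlo for the variable-selection model in which a
#' marker's effect variance is 0 with probability `pi` and follows a
#' scaled-inverse-chi-square distribution otherwise. Each Gibbs cycle
#' updates the overall mean, then visits every marker and runs
#' `mh_cycles` Metropolis-Hastings proposals for its (indicator, variance)
#' pair -- proposals drawn from the prior and accepted on the marginal
#' likelihood ratio of the data corrected for all other effects -- before
#' drawing the effect of an in-model marker from its full conditional.
#' The residual variance is held at its true value. Post-burn-in samples
#' are averaged into effect estimates and posterior mean variances (the
#' TAB weights).
#'
#' @inheritParams estimate_rrblup
#' @param config A [bayesb_config()].
#' @param seed Optional seed set just before the chain starts.
#' @return A `gs_marker_effects` tibble with `weight` = posterior mean
#'   per-marker variance.
#' @export
estimate_bayesb <- function(pheno, geno, vc, config, seed = NULL) {
  stopifnot(inherits(vc, "gs_vc"), inherits(config, "bayesb_config"))
  dat <- check_training_data(pheno, geno)
  Z <- dat$Z
  p <- allele_one_freq(Z)
  scale <- config$scale %||%
    (vc$sigma_a2 / (config$pi_in * sum(2 * p * (1 - p))))
  if (!is.null(seed)) set.seed(seed)
  use_xtx <- ncol(Z) <= 8000   # the m x m cross-product fits comfortably
  res <- bayesb_cpp(dat$y, Z * 1.0, vc$sigma_e2,
                    1 - config$pi_in, config$df, scale,
                    config$n_cycles, config$burn_in, config$mh_cycles,
                    use_xtx)
  new_marker_effects(Z, res$g_hat, res$var_post,
                     method = "BayesB", b_hat = res$b_hat,
                     extra = list(prior_scale = scale, config = config))
}
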