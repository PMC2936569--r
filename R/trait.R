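#' Variance components for the evaluation model
#'
#' @param sigma_a2 Total additive genetic variance.
#' @param sigma_e2 Residual (environmental) variance.
#' @return A `gs_vc` list.
#' @export
variance_components <- function(sigma_a2, sigma_e2) {
  if (sigma_a2 < 0 || sigma_e2 < 0) stop("variance components must be non-negative")
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2), class = "gs_vc")
}

#' Sample a trait architecture
#'
#' Draws `n_qtl` QTL uniformly without replacement from the potential QTL
#' slots that are polymorphic in the training generation (a monomorphic
#' slot would contribute zero variance, so it is never admitted). Absolute
#' allele-substitution effects come from a gamma distribution with a random
#' sign, and all effects are then rescaled so that the per-QTL variances
#' `2 p (1 - p) a^2`, taken at training-generation allele frequencies and
#' ignoring linkage-disequilibrium covariances, sum exactly to `sigma_a2`.
#'
#' @param pop A recoded `gs_population` containing generation 1.
#' @param n_qtl Number of QTL.
#' @param sigma_a2 Target total additive variance.
#' @param gamma_shape,gamma_scale Gamma parameters for `|a|`.
#' @param training_generation Generation whose allele frequencies define
#'   the per-QTL variances (default 1).
#' @return A `gs_trait` tibble: `slot` (global locus index), `chrom`,
#'   `pos`, `effect`, `p` (allele-1 frequency) and `qvar` (per-QTL
#'   variance); total variance recorded as an attribute.
#' @export
sample_trait_architecture <- function(pop, n_qtl, sigma_a2 = 1,
                                      gamma_shape = 0.4, gamma_scale = 1.66,
                                      training_generation = 1) {
  stopifnot(inherits(pop, "gs_population"))
  Zq <- genotype_matrix(pop, "qtl", generations = training_generation)
  slots <- qtl_loci(pop$map)
  p1 <- allele_one_freq(Zq)
  poly <- which(p1 > 0 & p1 < 1)
  if (n_qtl > length(poly))
    stop("fewer polymorphic QTL slots than requested QTL")
  pick <- sort(sample(poly, n_qtl))
  a <- rgamma(n_qtl, shape = gamma_shape, scale = gamma_scale) *
    sample(c(-1, 1), n_qtl, replace = TRUE)
  p <- p1[pick]
  raw_var <- sum(2 * p * (1 - p) * a^2)
  a <- a * sqrt(sigma_a2 / raw_var)
  out <- tibble(slot = slots[pick],
                chrom = pop$map$loci$chrom[slots[pick]],
                pos = pop$map$loci$pos[slots[pick]],
                effect = a, p = p,
                qvar = 2 * p * (1 - p) * a^2)
  attr(out, "sigma_a2") <- sigma_a2
  attr(out, "qtl_index") <- pick     # column index into the QTL dosage matrix
  class(out) <- c("gs_trait", class(out))
  out
}

#' True breeding values from QTL genotypes
#'
#' `TBV_j = sum_i a_i Z_ij` with dosage coding 0 (heterozygote 1/2),
#' 1 (homozygote 2/2) and -1 (homozygote 1/1).
#'
#' @param qtl_geno Individuals-by-QTL dosage matrix restricted to the
#'   trait's QTL columns (in `trait` order), or a full QTL-slot matrix from
#'   [genotype_matrix()] from which the trait columns are taken.
#' @param trait A [sample_trait_architecture()] result.
#' @return Tibble with `id` and `tbv`.
#' @export
compute_tbv <- function(qtl_geno, trait) {
  stopifnot(inherits(trait, "gs_trait"))
  if (ncol(qtl_geno) != nrow(trait)) {
    idx <- attr(trait, "qtl_index")
    if (is.null(idx) || ncol(qtl_geno) < max(idx))
      stop("genotype matrix does not match the trait architecture")
    qtl_geno <- qtl_geno[, idx, drop = FALSE]
  }
  tbv <- drop(qtl_geno %*% trait$effect)
  tibble(id = as.integer(rownames(qtl_geno)), tbv = unname(tbv))
}

#' Simulate phenotypes
#'
#' `P_i = TBV_i + e_i` with `e_i ~ N(0, sigma_e2)`; in the study design a
#' record is assigned to the training generation only.
#'
#' @param tbv Tibble with `id` and `tbv` (typically the training subset).
#' @param sigma_e2 Environmental variance (>= 0).
#' @return Tibble with `id` and `phenotype`.
#' @export
simulate_phenotypes <- function(tbv, sigma_e2) {
  if (sigma_e2 < 0) stop("`sigma_e2` must be non-negative")
  tibble(id = tbv$id,
         phenotype = tbv$tbv + rnorm(nrow(tbv), 0, sqrt(sigma_e2)))
}
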