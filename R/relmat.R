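#' Identity-by-state score of two single-locus genotypes
#'
#' All four cross-individual allele comparisons enter:
#' `(I_11 + I_12 + I_21 + I_22) / 4`, where `I_mn` indicates that allele m
#' of the first individual matches allele n of the second. The score is
#' phase-free by construction, taking values in {0, 0.25, 0.5, 0.75, 1}.
#'
#' @param geno_i,geno_j Length-2 vectors of (unordered) allele labels.
#' @return Similarity score in `[0, 1]`.
#' @export
#' @examples
#' locus_similarity(c(1, 2), c(1, 2))   # 0.5
locus_similarity <- function(geno_i, geno_j) {
  if (length(geno_i) != 2 || length(geno_j) != 2)
    stop("genotypes must be unordered allele pairs")
  mean(outer(geno_i, geno_j, `==`))
}

#' Weighted average identity-by-state matrix
#'
#' `S_ij = sum_k w_k S_ijk / sum_k w_k` over all marker loci, where
#' `S_ijk` is the four-comparison similarity score of
#' [locus_similarity()]. Normalising by the weight total (not the marker
#' count) keeps sparse weighting schemes on the `[0, 1]` scale.
#'
#' @param geno Individuals-by-markers dosage matrix coded -1/0/1.
#' @param weights Per-marker non-negative weights with a positive sum;
#'   `NULL` means equal weights.
#' @return Symmetric individuals-by-individuals similarity matrix,
#'   diagonal included (self-similarity reflects homozygosity).
#' @export
weighted_ibs <- function(geno, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, ncol(geno))
  if (length(weights) != ncol(geno))
    stop("`weights` must have one entry per marker")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("at least one weight must be positive")
  S <- weighted_ibs_cpp(geno * 1.0, as.numeric(weights))
  dimnames(S) <- list(rownames(geno), rownames(geno))
  S
}

#' Correct a similarity matrix for the population mean IBS
#'
#' Wright's F-statistic style adjustment
#' `f_ij = (S_ij - S_bar) / (1 - S_bar)` turns raw identity-by-state into
#' relatedness with mean zero; `S_bar` is the average similarity over all
#' off-diagonal pairs (self-similarities are excluded so they cannot
#' deflate the correction).
#'
#' @param S Similarity matrix with entries in `[0, 1]`.
#' @return The corrected matrix with `S_bar` attached as attribute
#'   `s_bar`.
#' @export
correct_mean_ibs <- function(S) {
  n <- nrow(S)
  if (n < 2) stop("at least two individuals are required")
  s_bar <- (sum(S) - sum(diag(S))) / (n * (n - 1))
  if (s_bar >= 1 - 1e-12)
    stop("all individuals are identical at every weighted locus; the mean-IBS correction is degenerate")
  f <- (S - s_bar) / (1 - s_bar)
  attr(f, "s_bar") <- s_bar
  f
}

#' Weighting schemes for marker-derived relationship matrices
#'
#' `weight_scheme()` is the general constructor; the helpers build the
#' schemes compared in the study: `scheme_gblup()` weights all markers
#' equally (the realized relationship matrix G), `scheme_ta()` weights by
#' the per-marker variance column of a fitted [estimate_rrblup()] (scheme
#' TAP) or [estimate_bayesb()] (scheme TAB) object, and `scheme_adhoc()`
#' uses absolute estimated effects with no mean-IBS correction and a unit
#' diagonal.
#'
#' @param name Scheme label carried into results.
#' @param weights Non-negative per-marker weights.
#' @param mean_correction Apply the mean-IBS correction and doubling.
#' @param unit_diagonal Overwrite the diagonal with 1 (no-inbreeding
#'   assumption of the ad-hoc variants).
#' @return A `weight_scheme` list.
#' @export
weight_scheme <- function(name, weights, mean_correction = TRUE,
                          unit_diagonal = FALSE) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with a positive sum")
  structure(list(name = name, weights = as.numeric(weights),
                 mean_correction = mean_correction,
                 unit_diagonal = unit_diagonal),
            class = "weight_scheme")
}

#' @rdname weight_scheme
#' @param n_markers Number of markers (G scheme).
#' @export
scheme_gblup <- function(n_markers) {
  weight_scheme("G", rep(1, n_markers))
}

#' @rdname weight_scheme
#' @param effects A `gs_marker_effects` object.
#' @export
scheme_ta <- function(effects) {
  stopifnot(inherits(effects, "gs_marker_effects"))
  name <- switch(attr(effects, "method"), RRBLUP = "TAP", BayesB = "TAB",
                 paste0("TA-", attr(effects, "method")))
  weight_scheme(name, effects$weight)
}

#' @rdname weight_scheme
#' @export
scheme_adhoc <- function(effects) {
  stopifnot(inherits(effects, "gs_marker_effects"))
  weight_scheme(paste0("adhoc-", attr(effects, "method")),
                abs(effects$g_hat),
                mean_correction = FALSE, unit_diagonal = TRUE)
}

#' Build a marker-derived relationship matrix
#'
#' For the corrected schemes (G, TAP, TAB) the weighted IBS matrix is
#' mean-corrected and doubled -- relatedness is twice the identity by
#' descent -- with the diagonal flowing through the same pipeline so that
#' homozygosity excess is captured. The ad-hoc variants skip the
#' correction, keep the raw weighted IBS off-diagonals and pin the
#' diagonal at 1.
#'
#' @param geno Individuals-by-markers dosage matrix (-1/0/1) with ids as
#'   row names; include every individual the downstream mixed model needs.
#' @param scheme A [weight_scheme()].
#' @param jitter Optional non-negative ridge added to the diagonal; off by
#'   default and only useful when very few markers make the matrix
#'   ill-conditioned.
#' @return A `gs_relmat` object: the matrix plus the scheme name, weights
#'   and (for corrected schemes) the mean IBS used.
#' @export
build_relationship <- function(geno, scheme, jitter = 0) {
  stopifnot(inherits(scheme, "weight_scheme"))
  if (length(scheme$weights) != ncol(geno))
    stop("scheme weights must match the marker count")
  S <- weighted_ibs(geno, scheme$weights)
  s_bar <- NA_real_
  if (scheme$mean_correction) {
    f <- correct_mean_ibs(S)
    s_bar <- attr(f, "s_bar")
    M <- 2 * f
    attr(M, "s_bar") <- NULL
  } else {
    M <- S
  }
  if (scheme$unit_diagonal) diag(M) <- 1
  if (jitter > 0) diag(M) <- diag(M) + jitter
  structure(list(values = M, scheme = scheme$name,
                 weights = scheme$weights, s_bar = s_bar),
            class = "gs_relmat")
}

#' @export
print.gs_relmat <- function(x, ...) {
  cat(sprintf("<gs_relmat> scheme %s, %d individuals (mean IBS %s)\n",
              x$scheme, nrow(x$values),
              ifelse(is.na(x$s_bar), "uncorrected", sprintf("%.4f", x$s_bar))))
  invisible(x)
}
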