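#' Solve Henderson's mixed model equations by Gauss-Seidel iteration
#'
#' Fits `y = 1 b + W u + e` with `u ~ N(0, K sigma_a2)` over all
#' individuals in the relationship matrix `K`; `W` links each record to
#' its individual, and unphenotyped candidates enter with empty record
#' rows so their breeding values are driven purely through `K`. The
#' equations
#' \deqn{\begin{pmatrix} n & 1'W \\ W'1 & W'W + K^{-1}\lambda \end{pmatrix}
#'       \begin{pmatrix} b \\ u \end{pmatrix} =
#'       \begin{pmatrix} 1'y \\ W'y \end{pmatrix}}
#' with `lambda = sigma_e2 / sigma_a2` are built from the explicit
#' numerical inverse of `K` (LU-based) and solved by Gauss-Seidel sweeps
#' until the largest absolute update drops below `tol`.
#'
#' @param pheno Tibble with `id` and `phenotype`; every id must appear in
#'   the relationship matrix.
#' @param relmat A [build_relationship()] result covering training
#'   individuals and candidates.
#' @param vc [variance_components()].
#' @param tol Convergence threshold on the maximum absolute update
#'   (Gauss-Seidel solver).
#' @param max_iter Sweep limit; non-convergence raises a warning carrying
#'   the last update size.
#' @param solver `"direct"` (default) computes the exact solution of the
#'   same equations through Henderson's absorption identities
#'   (generalized-least-squares mean on the record block, then
#'   `u = sigma_a2 K W' V^{-1} (y - 1 b)` with
#'   `V = sigma_a2 W K W' + sigma_e2 I`), which needs no inverse of `K`;
#'   `"gauss_seidel"` iterates on the assembled equations. The two agree
#'   wherever Gauss-Seidel converges, but the mean-IBS correction makes
#'   the relationship matrix indefinite by construction (subtracting the
#'   population mean is a rank-one downdate that leaves exactly one
#'   negative eigenvalue, along the population-mean direction, which the
#'   fixed mean absorbs), and plain Gauss-Seidel is not guaranteed to
#'   converge on such systems -- hence the exact solve as default.
#' @return A `gs_gebv` tibble (`id`, `gebv`) for every individual in the
#'   matrix, with the fixed-effect estimate, iteration count and
#'   convergence flag as attributes.
#' @export
solve_mme <- function(pheno, relmat, vc, tol = 1e-8, max_iter = 10000,
                      solver = c("direct", "gauss_seidel")) {
  stopifnot(inherits(relmat, "gs_relmat"), inherits(vc, "gs_vc"))
  solver <- match.arg(solver)
  if (vc$sigma_a2 <= 0) stop("`sigma_a2` must be positive for the MME")
  K <- relmat$values
  ids <- rownames(K)
  idx <- match(as.character(pheno$id), ids)
  if (anyNA(idx)) stop("every phenotyped individual must appear in the relationship matrix")
  n_all <- nrow(K)
  y <- pheno$phenotype
  if (solver == "gauss_seidel") {
    Kinv <- tryCatch(solve(K), error = function(e) {
      stop(sprintf("relationship matrix (scheme %s) is numerically singular (rcond = %.3g): %s",
                   relmat$scheme, rcond(K), conditionMessage(e)), call. = FALSE)
    })
    lambda <- vc$sigma_e2 / vc$sigma_a2
    n_rec <- nrow(pheno)
    rec_n <- tabulate(idx, nbins = n_all)        # records per individual
    rec_y <- numeric(n_all)
    agg <- rowsum(y, idx)
    rec_y[as.integer(rownames(agg))] <- agg[, 1]
    C <- matrix(0, n_all + 1, n_all + 1)
    C[1, 1] <- n_rec
    C[1, -1] <- rec_n
    C[-1, 1] <- rec_n
    C[-1, -1] <- Kinv * lambda
    diag(C)[-1] <- diag(C)[-1] + rec_n
    rhs <- c(sum(y), rec_y)
    sol <- gauss_seidel_cpp(C, rhs, numeric(n_all + 1), tol, as.integer(max_iter))
    if (!sol$converged)
      warning(sprintf("Gauss-Seidel did not converge in %d sweeps (last update %.3g)",
                      max_iter, sol$delta))
    sol <- list(b = sol$x[1], u = sol$x[-1], iterations = sol$iterations,
                converged = sol$converged, delta = sol$delta)
  } else {
    # Henderson absorption: V = sigma_a2 W K W' + sigma_e2 I on records,
    # GLS mean, then u = sigma_a2 K W' V^-1 (y - 1 b). Identical to the
    # assembled equations whenever K is invertible, and defined for any
    # relationship matrix with invertible V.
    V <- vc$sigma_a2 * K[idx, idx, drop = FALSE]
    diag(V) <- diag(V) + vc$sigma_e2
    Vi_y <- tryCatch(solve(V, cbind(y, 1)), error = function(e) {
      stop(sprintf("record covariance for scheme %s is numerically singular: %s",
                   relmat$scheme, conditionMessage(e)), call. = FALSE)
    })
    b_hat <- sum(Vi_y[, 1]) / sum(Vi_y[, 2])
    alpha <- Vi_y[, 1] - Vi_y[, 2] * b_hat       # V^-1 (y - 1 b)
    u <- vc$sigma_a2 * unname(drop(K[, idx, drop = FALSE] %*% alpha))
    sol <- list(b = b_hat, u = u, iterations = NA_integer_, converged = TRUE)
  }
  out <- tibble(id = as.integer(ids), gebv = sol$u)
  attr(out, "b_hat") <- sol$b
  attr(out, "iterations") <- sol$iterations
  attr(out, "converged") <- sol$converged
  attr(out, "solver") <- solver
  attr(out, "method") <- relmat$scheme
  class(out) <- c("gs_gebv", class(out))
  out
}

#' Breeding values by direct summation of marker effects
#'
#' `GEBV_j = sum_k g_hat_k Z_jk` -- the prediction rule for RRBLUP and
#' BayesB, applied to any genotyped individual.
#'
#' @param geno Dosage matrix (-1/0/1) with ids as row names.
#' @param effects A `gs_marker_effects` object with matching marker order.
#' @return A `gs_gebv` tibble (`id`, `gebv`).
#' @export
gebv_from_effects <- function(geno, effects) {
  stopifnot(inherits(effects, "gs_marker_effects"))
  if (ncol(geno) != nrow(effects))
    stop("genotype matrix and marker effects have different marker counts")
  out <- tibble(id = as.integer(rownames(geno)),
                gebv = unname(drop(geno %*% effects$g_hat)))
  attr(out, "method") <- attr(effects, "method")
  class(out) <- c("gs_gebv", class(out))
  out
}
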