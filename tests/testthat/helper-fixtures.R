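# Shared desk-scale fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small study: 5 x 60 markers, short history, 200 individuals per
# validation generation, 3 validation generations.
tiny_config <- function(...) {
  args <- list(markers_per_chr = 60, n_historical = 150,
               progeny_per_dam_gen1 = 4, n_validation_generations = 3,
               n_cycles = 400, burn_in = 100, mh_cycles = 10)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

tiny_population <- function() {
  if (is.null(.fixture_env$pop))
    .fixture_env$pop <- simulate_population(tiny_config(), seed = 11)
  .fixture_env$pop
}

# Training data derived from the tiny population under fixed stage seeds.
tiny_training <- function() {
  if (is.null(.fixture_env$train)) {
    pop <- tiny_population()
    set.seed(101)
    trait <- sample_trait_architecture(pop, n_qtl = 20)
    Zq <- genotype_matrix(pop, "qtl", generations = 1:3)
    tbv <- compute_tbv(Zq, trait)
    tbv$generation <- pop$pedigree$generation[match(tbv$id, pop$pedigree$id)]
    set.seed(102)
    pheno <- simulate_phenotypes(tbv[tbv$generation == 1, ], sigma_e2 = 1)
    .fixture_env$train <- list(
      pop = pop, trait = trait, tbv = tbv, pheno = pheno,
      Zt = genotype_matrix(pop, "markers", generations = 1),
      vc = variance_components(1, 1))
  }
  .fixture_env$train
}

# Brute-force IBS oracle: per-pair, per-locus four-comparison score from
# the underlying allele pairs, averaged with explicit loops.
bruteforce_ibs <- function(h1, h2, weights) {
  n <- ncol(h1)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0
      for (l in seq_len(nrow(h1))) {
        gi <- c(h1[l, i], h2[l, i])
        gj <- c(h1[l, j], h2[l, j])
        num <- num + weights[l] * mean(outer(gi, gj, `==`))
      }
      S[i, j] <- num / sum(weights)
    }
  }
  S
}

# Direct dense solve of Henderson's equations with the explicit K inverse,
# independent of the package's solvers.
bruteforce_mme <- function(y, idx, K, sigma_a2, sigma_e2) {
  lambda <- sigma_e2 / sigma_a2
  n <- nrow(K)
  W <- matrix(0, length(y), n)
  W[cbind(seq_along(y), idx)] <- 1
  X <- matrix(1, length(y), 1)
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + solve(K) * lambda))
  rhs <- c(crossprod(X, y), crossprod(W, y))
  sol <- solve(C, rhs)
  list(b = sol[1], u = sol[-1])
}
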