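mme_methods <- c("GBLUP", "TAB", "TAP", "adhoc-TAB", "adhoc-TAP")
sum_methods <- c("RRBLUP", "BayesB")

#' Run one replicate of a scenario
#'
#' The full two-step pipeline on a single simulated population: simulate
#' (or reuse) the population, sample the trait and phenotypes, estimate
#' marker effects in the training generation, build the requested
#' relationship matrices, predict breeding values (direct summation for
#' RRBLUP/BayesB, mixed model equations for GBLUP/TAP/TAB and the ad-hoc
#' variants) and evaluate them on the unphenotyped candidate generations.
#'
#' Because breeding is independent of the trait, a prebuilt `population`
#' can be shared between scenarios that differ only in trait parameters
#' (heritability or QTL number), giving common random numbers across a
#' sweep.
#'
#' @param config A [sim_config()].
#' @param seed Master seed for this replicate; all stages derive child
#'   seeds from it.
#' @param methods Any of `"BayesB"`, `"RRBLUP"`, `"GBLUP"`, `"TAB"`,
#'   `"TAP"`, `"adhoc-TAB"`, `"adhoc-TAP"`.
#' @param generations Candidate generations to evaluate.
#' @param mme_generations Candidate generations entering the relationship
#'   matrices (default: all evaluated generations). MME-based methods are
#'   evaluated on `intersect(generations, mme_generations)`.
#' @param mme_mode `"joint"` solves one system over the training
#'   generation plus all of `mme_generations` (the study design);
#'   `"per_generation"` solves training + one candidate generation at a
#'   time, which predicts candidates near-identically (their BLUPs depend
#'   only on their relationship to the training individuals) at a fraction
#'   of the cost for many generations.
#' @param population Optional prebuilt `gs_population` to reuse.
#' @param effects Optional named list of prefitted `gs_marker_effects`
#'   (`RRBLUP`, `BayesB`) to reuse, e.g. from an earlier
#'   `return_details = TRUE` call on the same population and seed.
#' @param solver Passed to [solve_mme()].
#' @param return_details Also return the population, trait, effects and
#'   predictions.
#' @return A tibble of per-method, per-generation metrics (with
#'   `replicate = NA`, filled by [run_scenario()]); or a list when
#'   `return_details = TRUE`.
#' @export
run_replicate <- function(config, seed,
                          methods = c("BayesB", "RRBLUP", "GBLUP", "TAB", "TAP"),
                          generations = 2:6,
                          mme_generations = generations,
                          mme_mode = c("joint", "per_generation"),
                          population = NULL, effects = NULL,
                          solver = c("direct", "gauss_seidel"),
                          return_details = FALSE) {
  solver <- match.arg(solver)
  stopifnot(inherits(config, "sim_config"))
  mme_mode <- match.arg(mme_mode)
  methods <- match.arg(methods, c(sum_methods, mme_methods), several.ok = TRUE)

  pop <- population %||% simulate_population(config, seed)

  set.seed(stage_seed(seed, 3))
  trait <- sample_trait_architecture(pop, config$n_qtl, config$sigma_a2,
                                     config$gamma_shape, config$gamma_scale)
  gens_all <- sort(unique(pop$pedigree$generation[pop$pedigree$generation >= 1]))
  Zq <- genotype_matrix(pop, "qtl", generations = gens_all)
  tbv <- compute_tbv(Zq, trait)
  tbv <- left_join(tbv, pop$pedigree[, c("id", "generation")], by = "id")

  set.seed(stage_seed(seed, 4))
  pheno <- simulate_phenotypes(tbv[tbv$generation == 1, ], config$sigma_e2)

  vc <- variance_components(config$sigma_a2, config$sigma_e2)
  Zt <- genotype_matrix(pop, "markers", generations = 1)
  eff <- effects %||% list()
  if (any(methods %in% c("RRBLUP", "TAP", "adhoc-TAP")) && is.null(eff$RRBLUP))
    eff$RRBLUP <- estimate_rrblup(pheno, Zt, vc)
  if (any(methods %in% c("BayesB", "TAB", "adhoc-TAB")) && is.null(eff$BayesB)) {
    cfg_bb <- bayesb_config(pi_in = config$n_qtl / ncol(Zt),
                            n_cycles = config$n_cycles,
                            burn_in = config$burn_in,
                            mh_cycles = config$mh_cycles, df = config$df)
    eff$BayesB <- estimate_bayesb(pheno, Zt, vc, cfg_bb,
                                  seed = stage_seed(seed, 5))
  }

  preds <- list()
  direct <- intersect(methods, sum_methods)
  if (length(direct)) {
    Zc <- genotype_matrix(pop, "markers", generations = generations)
    for (m in direct) {
      g <- gebv_from_effects(Zc, eff[[m]])
      g$method <- m
      preds[[m]] <- g
    }
  }

  mme_req <- intersect(methods, mme_methods)
  if (length(mme_req)) {
    scheme_of <- function(m) switch(m,
      GBLUP = scheme_gblup(ncol(Zt)),
      TAP = scheme_ta(eff$RRBLUP),
      TAB = scheme_ta(eff$BayesB),
      `adhoc-TAP` = scheme_adhoc(eff$RRBLUP),
      `adhoc-TAB` = scheme_adhoc(eff$BayesB))
    gen_sets <- if (mme_mode == "joint") list(intersect(generations, mme_generations))
                else as.list(intersect(generations, mme_generations))
    for (m in mme_req) {
      sch <- scheme_of(m)
      got <- list()
      for (gs in gen_sets) {
        Zr <- genotype_matrix(pop, "markers", generations = c(1, gs))
        rel <- build_relationship(Zr, sch)
        sol <- solve_mme(pheno, rel, vc, solver = solver)
        cand <- pop$pedigree$id[pop$pedigree$generation %in% gs]
        got[[length(got) + 1]] <- sol[sol$id %in% cand, ]
      }
      g <- bind_rows(got)
      g$method <- m
      preds[[m]] <- g
    }
  }

  metrics <- preds |>
    map(\(p) evaluate_predictions(p, tbv[, c("id", "tbv", "generation")])) |>
    list_rbind() |>
    arrange(.data$method, .data$generation)

  if (return_details)
    list(metrics = metrics, population = pop, trait = trait, effects = eff,
         predictions = bind_rows(preds), phenotypes = pheno, tbv = tbv)
  else metrics
}

#' Run a scenario over replicates
#'
#' Repeats [run_replicate()] with independent child seeds drawn from the
#' master seed and aggregates the metrics into means and standard errors.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates.
#' @param seed Master seed of the scenario; replicate `r` uses child seed
#'   `stage_seed(seed, 100 + r)`.
#' @param ... Passed on to [run_replicate()].
#' @return A `gs_scenario` object: `replicates` (per-replicate metric
#'   tibble), `summary` (from [aggregate_replicates()]) and the
#'   configuration. [tidy()] returns the summary, [glance()] a one-row
#'   description, [autoplot()] the accuracy-by-generation figure.
#' @export
run_scenario <- function(config, n_replicates = 10, seed = 1,
                         methods = c("BayesB", "RRBLUP", "GBLUP", "TAB", "TAP"),
                         generations = 2:6, ...) {
  reps <- map(seq_len(n_replicates), function(r) {
    res <- run_replicate(config, stage_seed(seed, 100 + r),
                         methods = methods, generations = generations, ...)
    res$replicate <- r
    res
  }) |> list_rbind()
  structure(list(replicates = reps,
                 summary = aggregate_replicates(reps),
                 config = config, seed = seed,
                 n_replicates = n_replicates, methods = methods),
            class = "gs_scenario")
}

#' @export
print.gs_scenario <- function(x, ...) {
  cat(sprintf("<gs_scenario> %d replicate(s), methods: %s\n",
              x$n_replicates, paste(x$methods, collapse = ", ")))
  acc <- x$summary |>
    filter(.data$metric == "accuracy",
           .data$generation == min(.data$generation))
  cat(sprintf("  generation-%d accuracy:\n", min(acc$generation)))
  for (i in seq_len(nrow(acc)))
    cat(sprintf("    %-10s %.3f%s\n", acc$method[i], acc$mean[i],
                ifelse(is.na(acc$se[i]), "", sprintf(" ± %.3f", acc$se[i]))))
  invisible(x)
}

#' @rdname run_scenario
#' @param x A `gs_scenario`.
#' @export
tidy.gs_scenario <- function(x, ...) x$summary

#' @rdname run_scenario
#' @export
glance.gs_scenario <- function(x, ...) {
  tibble(n_replicates = x$n_replicates,
         n_methods = length(x$methods),
         n_generations = length(unique(x$replicates$generation)),
         h2 = x$config$h2, n_qtl = x$config$n_qtl,
         markers = x$config$n_chr * x$config$markers_per_chr)
}

#' Contrast methods within a results table
#'
#' Pairwise accuracy differences and the per-method gap between Pearson
#' and rank correlation, the comparisons used to judge how sensitive each
#' estimator is to the trait's genetic architecture.
#'
#' @param x A `gs_scenario`, or a tibble with columns `method`,
#'   `accuracy` and optionally `rank_correlation`.
#' @param generation For a scenario input, the generation to contrast
#'   (default: earliest evaluated).
#' @return A list with `accuracy_differences` (tibble `method_a`,
#'   `method_b`, `difference` = a minus b), `rank_gap` (per-method
#'   Pearson-minus-rank gap) and `mean_rank_gap`.
#' @export
compare_methods <- function(x, generation = NULL) {
  if (inherits(x, "gs_scenario")) {
    generation <- generation %||% min(x$summary$generation)
    x <- x$summary |>
      filter(.data$generation == !!generation) |>
      select("method", "metric", "mean") |>
      pivot_wider(names_from = "metric", values_from = "mean")
  }
  if (nrow(x) < 2) stop("at least two methods are required")
  pairs <- expand.grid(method_a = x$method, method_b = x$method,
                       stringsAsFactors = FALSE) |>
    filter(.data$method_a != .data$method_b)
  acc <- setNames(x$accuracy, x$method)
  diffs <- tibble(method_a = pairs$method_a, method_b = pairs$method_b,
                  difference = unname(acc[pairs$method_a] - acc[pairs$method_b]))
  out <- list(accuracy_differences = diffs)
  if ("rank_correlation" %in% names(x)) {
    out$rank_gap <- tibble(method = x$method,
                           gap = x$accuracy - x$rank_correlation)
    out$mean_rank_gap <- mean(out$rank_gap$gap)
  }
  out
}
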