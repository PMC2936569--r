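#' Simulation settings for a genomic-selection study
#'
#' Collects every tunable of the simulated study design. The defaults are
#' the standard scenario used throughout the package: a genome of five
#' 1-Morgan chromosomes carrying 1,000 markers each, an effective
#' population size of 100 maintained for 1,000 historical generations under
#' mutation-drift equilibrium, a 1,000-individual phenotyped training
#' generation, five further candidate generations of 1,000 produced by
#' 50 randomly chosen sires per generation, 50 QTL, total additive variance
#' 1 and heritability 0.5.
#'
#' @param n_chr Number of chromosomes.
#' @param chr_length Chromosome length in Morgans.
#' @param markers_per_chr Marker loci per chromosome (>= 2); each
#'   inter-marker segment additionally harbours one potential QTL slot.
#' @param n_historical Historical (mutation-drift) generations.
#' @param historical_size Constant historical population size (even; half
#'   males, half females).
#' @param mutation_rate Per gene copy, per locus, per generation mutation
#'   probability under the infinite-alleles model. The historical design
#'   (monogamous pairs, exactly two offspring each) has zero variance of
#'   family size, so its effective size is about twice the census size,
#'   Ne = 2N - 1 = 199; the default 1.25e-3 then gives
#'   theta = 4 * Ne * u = 1 and equilibrium heterozygosity
#'   4Neu/(4Neu + 1) = 0.5.
#' @param n_qtl Number of QTL sampled for the trait.
#' @param h2 Narrow-sense heritability in the training generation, in (0, 1].
#' @param sigma_a2 Total additive genetic variance after rescaling.
#' @param gamma_shape,gamma_scale Gamma parameters for the absolute
#'   allele-substitution effects before rescaling.
#' @param n_validation_generations Candidate generations bred after the
#'   training generation (training = generation 1, candidates 2..n+1).
#' @param progeny_per_dam_gen1 Progeny per dam in the expansion mating that
#'   creates the training generation (half male, half female).
#' @param n_sires Sires sampled at random from the previous generation's
#'   males for each later generation.
#' @param progeny_per_dam Progeny per dam in generations after the first
#'   (one male, one female when equal to 2).
#' @param n_cycles,burn_in,mh_cycles,df BayesB chain settings (see
#'   [bayesb_config()]); stored here so a scenario is fully specified by
#'   one object.
#'
#' @return A `sim_config` list; `sigma_e2` is derived as
#'   `sigma_a2 * (1 - h2) / h2`.
#' @export
#' @examples
#' cfg <- sim_config(markers_per_chr = 50, n_historical = 20)
#' cfg$sigma_e2
sim_config <- function(n_chr = 5, chr_length = 1, markers_per_chr = 1000,
                       n_historical = 1000, historical_size = 100,
                       mutation_rate = 1.25e-3,
                       n_qtl = 50, h2 = 0.5, sigma_a2 = 1,
                       gamma_shape = 0.4, gamma_scale = 1.66,
                       n_validation_generations = 6,
                       progeny_per_dam_gen1 = 20,
                       n_sires = 50, progeny_per_dam = 2,
                       n_cycles = 10000, burn_in = 2000, mh_cycles = 100,
                       df = 1) {
  if (h2 <= 0 || h2 > 1) stop("`h2` must lie in (0, 1]")
  if (historical_size < 2 || historical_size %% 2 != 0)
    stop("`historical_size` must be a positive even number")
  if (n_historical < 0) stop("`n_historical` must be non-negative")
  if (markers_per_chr < 2) stop("`markers_per_chr` must be at least 2")
  if (n_qtl < 1) stop("`n_qtl` must be positive")
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("`mutation_rate` must be a probability")
  structure(list(
    n_chr = n_chr, chr_length = chr_length,
    markers_per_chr = markers_per_chr,
    n_historical = n_historical, historical_size = historical_size,
    mutation_rate = mutation_rate,
    n_qtl = n_qtl, h2 = h2, sigma_a2 = sigma_a2,
    sigma_e2 = sigma_a2 * (1 - h2) / h2,
    gamma_shape = gamma_shape, gamma_scale = gamma_scale,
    n_validation_generations = n_validation_generations,
    progeny_per_dam_gen1 = progeny_per_dam_gen1,
    n_sires = n_sires, progeny_per_dam = progeny_per_dam,
    n_cycles = n_cycles, burn_in = burn_in, mh_cycles = mh_cycles, df = df
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosomes x %g Morgan, %d markers each (%d QTL slots)\n",
              x$n_chr, x$chr_length, x$markers_per_chr,
              x$n_chr * (x$markers_per_chr - 1)))
  cat(sprintf("  history: Ne = %d for %d generations, u = %g per copy\n",
              x$historical_size, x$n_historical, x$mutation_rate))
  cat(sprintf("  trait: %d QTL, sigma_a2 = %g, h2 = %g (sigma_e2 = %g)\n",
              x$n_qtl, x$sigma_a2, x$h2, x$sigma_e2))
  invisible(x)
}

#' Build a random genetic map
#'
#' Marker positions are placed uniformly at random on each chromosome and
#' sorted; every segment between two adjacent markers harbours one
#' potential QTL slot at its midpoint, so a chromosome with m markers
#' carries m - 1 slots.
#'
#' @param n_chr Number of chromosomes.
#' @param chr_length Chromosome length in Morgans (scalar or per
#'   chromosome).
#' @param markers_per_chr Markers per chromosome (>= 2).
#'
#' @return A `gs_map` object: a list with a `loci` tibble (`chrom`, `pos`
#'   in Morgans, `type` = `"marker"` or `"qtl"`, global `locus` index) plus
#'   the map dimensions.
#' @export
#' @examples
#' map <- build_genetic_map(5, 1, 1000)
#' sum(map$loci$type == "qtl")   # 4995 potential QTL slots
build_genetic_map <- function(n_chr, chr_length, markers_per_chr) {
  if (any(chr_length <= 0)) stop("chromosome length must be positive")
  if (markers_per_chr < 2) stop("`markers_per_chr` must be at least 2")
  len <- rep_len(chr_length, n_chr)
  loci <- purrr::map(seq_len(n_chr), function(ch) {
    mpos <- sort(runif(markers_per_chr, 0, len[ch]))
    qpos <- (mpos[-1] + mpos[-markers_per_chr]) / 2
    tibble(chrom = ch,
           pos = c(mpos, qpos),
           type = rep(c("marker", "qtl"), c(markers_per_chr, markers_per_chr - 1))) |>
      arrange(.data$pos)
  }) |> list_rbind()
  loci$locus <- seq_len(nrow(loci))
  structure(list(loci = loci, n_chr = n_chr, chr_length = len,
                 markers_per_chr = markers_per_chr),
            class = "gs_map")
}

#' @export
print.gs_map <- function(x, ...) {
  cat(sprintf("<gs_map> %d chromosomes, %d markers + %d QTL slots\n",
              x$n_chr, sum(x$loci$type == "marker"), sum(x$loci$type == "qtl")))
  invisible(x)
}

marker_loci <- function(map) map$loci$locus[map$loci$type == "marker"]
qtl_loci <- function(map) map$loci$locus[map$loci$type == "qtl"]

#' Haldane's mapping function
#'
#' Probability of an odd number of crossovers (an observable recombination)
#' between two loci `d` Morgans apart, assuming no interference:
#' `0.5 * (1 - exp(-2 d))`.
#'
#' @param d Map distance in Morgans (non-negative).
#' @return Recombination probability in `[0, 0.5)`.
#' @export
#' @examples
#' haldane(0.1)
haldane <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d))
}

#' Simulate one meiosis
#'
#' Produces a gamete as a mosaic of the two parental haplotypes.
#' Chromosomes segregate independently: the first locus of each chromosome
#' is copied from a random parental haplotype and the source switches
#' between adjacent loci with the Haldane probability for their map
#' distance (crossovers are realized as a Poisson process along the
#' chromosome, which yields exactly those switch probabilities,
#' independently across intervals).
#'
#' @param h1,h2 Integer allele vectors, one per parental haplotype, covering
#'   all loci of `map` in map order.
#' @param map A [build_genetic_map()] object.
#' @return Integer gamete haplotype of the same length.
#' @export
meiosis <- function(h1, h2, map) {
  stopifnot(inherits(map, "gs_map"))
  L <- nrow(map$loci)
  if (length(h1) != L || length(h2) != L)
    stop("parental haplotypes must cover all loci on the map")
  meiosis_cpp(as.integer(h1), as.integer(h2),
              as.integer(map$loci$chrom), map$loci$pos,
              as.numeric(map$chr_length))
}

#' Apply infinite-alleles mutation to a gamete
#'
#' Each locus mutates independently with probability `rate`; a mutated
#' locus receives an allele label never used before at that locus, taken
#' from (and advancing) the per-locus counter.
#'
#' @param hap Integer haplotype.
#' @param rate Per-locus mutation probability in `[0, 1]`.
#' @param counter Integer vector of next-free allele labels per locus
#'   (fresh loci start at 2).
#' @return A list with the mutated `haplotype` and the updated `counter`.
#' @export
mutate_haplotype <- function(hap, rate, counter = rep(2L, length(hap))) {
  if (rate < 0 || rate > 1) stop("`rate` must be a probability")
  if (length(counter) != length(hap))
    stop("`counter` must have one entry per locus")
  mutate_cpp(as.integer(hap), rate, as.integer(counter))
}

new_population <- function(map, pedigree, h1, h2, recoded, counter = NULL) {
  colnames(h1) <- colnames(h2) <- as.character(pedigree$id)
  structure(list(map = map, pedigree = pedigree, h1 = h1, h2 = h2,
                 recoded = recoded, counter = counter),
            class = "gs_population")
}

#' @export
print.gs_population <- function(x, ...) {
  gens <- table(x$pedigree$generation)
  cat(sprintf("<gs_population> %d individuals over generations %s (%s); %d loci, %s\n",
              nrow(x$pedigree), paste(range(x$pedigree$generation), collapse = ".."),
              paste(as.integer(gens), collapse = "/"),
              nrow(x$h1),
              if (x$recoded) "biallelic" else "multi-allelic"))
  invisible(x)
}

#' Simulate the historical mutation-drift population
#'
#' Starts from a base population in which every locus is fixed for allele 1
#' and runs `n_generations` of constant-size random mating: the males are
#' randomly paired one-to-one with the females and each mating leaves two
#' offspring (one male, one female), so the population size never changes.
#' Infinite-alleles mutation is applied to every gamete of every historical
#' generation.
#'
#' @param map A [build_genetic_map()] object.
#' @param n_generations Number of historical generations (0 returns the
#'   fully monomorphic base population).
#' @param pop_size Constant population size (even).
#' @param mutation_rate Per gene copy, per locus mutation probability.
#'
#' @return A `gs_population` holding the final historical generation
#'   (labelled generation 0): a pedigree tibble and two loci-by-individuals
#'   haplotype matrices. Columns 1..n/2 are males.
#' @export
simulate_history <- function(map, n_generations, pop_size, mutation_rate) {
  stopifnot(inherits(map, "gs_map"))
  if (pop_size < 2 || pop_size %% 2 != 0)
    stop("`pop_size` must be a positive even number")
  res <- sim_history_cpp(as.integer(map$loci$chrom), map$loci$pos,
                         as.numeric(map$chr_length),
                         as.integer(pop_size), as.integer(n_generations),
                         mutation_rate)
  ped <- tibble(id = seq_len(pop_size), sire = NA_integer_, dam = NA_integer_,
                sex = rep(c("M", "F"), each = pop_size / 2),
                generation = 0L)
  new_population(map, ped, res$h1, res$h2, recoded = FALSE,
                 counter = res$counter)
}

#' Recode a multi-allelic population to biallelic markers
#'
#' At every locus the single allele whose frequency is closest to 0.5 is
#' relabelled 1 and all remaining alleles are collapsed to 2; ties between
#' two equidistant alleles go to the smaller original label, and a
#' monomorphic locus becomes all 1 (it stays in the panel and simply
#' carries no information).
#'
#' @param pop A `gs_population` holding generation 0 (the last historical
#'   generation).
#' @return The population with all allele labels in `{1, 2}`.
#' @export
recode_biallelic <- function(pop) {
  stopifnot(inherits(pop, "gs_population"))
  if (any(pop$pedigree$generation != 0))
    stop("recoding is defined on the final historical generation only")
  res <- recode_cpp(pop$h1, pop$h2)
  out <- new_population(pop$map, pop$pedigree, res$h1, res$h2, recoded = TRUE)
  out
}

#' Breed the training and candidate generations
#'
#' Expands the 100-individual historical population into the validation
#' design: generation 1 arises from random one-to-one mating of all
#' generation-0 males and females with `progeny_per_dam_gen1` progeny per
#' dam (half male, half female); each later generation takes `n_sires`
#' sires at random from the previous generation's males and mates each
#' with an equal share of all its females, every dam leaving
#' `progeny_per_dam` progeny of alternating sex. No mutation occurs after
#' the historical phase. Haplotype 1 of every offspring is the paternal
#' gamete.
#'
#' @param pop A recoded generation-0 `gs_population`.
#' @param n_generations Number of generations to append (training
#'   generation plus candidates).
#' @param progeny_per_dam_gen1,n_sires,progeny_per_dam Design constants;
#'   see [sim_config()].
#' @return The population extended with generations `1..n_generations`,
#'   pedigree included.
#' @export
breed_validation_generations <- function(pop, n_generations = 6,
                                         progeny_per_dam_gen1 = 20,
                                         n_sires = 50, progeny_per_dam = 2) {
  stopifnot(inherits(pop, "gs_population"))
  ped0 <- pop$pedigree[pop$pedigree$generation == 0, ]
  males <- ped0$id[ped0$sex == "M"]
  females <- ped0$id[ped0$sex == "F"]
  if (length(males) != length(females))
    stop("generation 0 must contain equal numbers of males and females")
  if (progeny_per_dam_gen1 %% 2 != 0 || progeny_per_dam %% 2 != 0)
    stop("progeny per dam must be even (half of each sex)")

  map <- pop$map
  chr <- as.integer(map$loci$chrom); posv <- map$loci$pos
  clen <- as.numeric(map$chr_length)
  ped_all <- pop$pedigree
  h1_all <- pop$h1; h2_all <- pop$h2
  prev_ids <- ped0$id
  prev_h1 <- pop$h1; prev_h2 <- pop$h2
  next_id <- max(ped_all$id)

  for (g in seq_len(n_generations)) {
    prev_ped <- ped_all[ped_all$generation == g - 1L, ]
    if (g == 1L) {
      sires <- sample(males)                 # random one-to-one pairing
      dams <- females
      per_dam <- progeny_per_dam_gen1
      dam_sire <- setNames(sires, dams)
    } else {
      pm <- prev_ped$id[prev_ped$sex == "M"]
      pf <- prev_ped$id[prev_ped$sex == "F"]
      sires <- sample(pm, n_sires)
      dams <- sample(pf)                     # shuffle, then chunk per sire
      per_dam <- progeny_per_dam
      dam_sire <- setNames(rep(sires, each = length(pf) / n_sires), dams)
    }
    off_dam <- rep(as.integer(names(dam_sire)), each = per_dam)
    off_sire <- rep(unname(dam_sire), each = per_dam)
    off_sex <- rep_len(c("M", "F"), length(off_dam))
    off_id <- next_id + seq_along(off_dam)
    next_id <- max(off_id)

    sidx <- match(off_sire, prev_ids) - 1L
    didx <- match(off_dam, prev_ids) - 1L
    gam <- breed_cpp(prev_h1, prev_h2, as.integer(sidx), as.integer(didx),
                     chr, posv, clen)
    ped_g <- tibble(id = off_id, sire = off_sire, dam = off_dam,
                    sex = off_sex, generation = as.integer(g))
    ped_all <- bind_rows(ped_all, ped_g)
    colnames(gam$h1) <- colnames(gam$h2) <- as.character(off_id)
    h1_all <- cbind(h1_all, gam$h1)
    h2_all <- cbind(h2_all, gam$h2)
    prev_ids <- off_id
    prev_h1 <- gam$h1; prev_h2 <- gam$h2
  }
  new_population(map, ped_all, h1_all, h2_all, recoded = pop$recoded)
}

#' Run the full population simulation for one replicate
#'
#' Chains [build_genetic_map()], [simulate_history()],
#' [recode_biallelic()] and [breed_validation_generations()] under the
#' deterministic seed-splitting rule: the genetic map and history use one
#' child stream, breeding another, so downstream stages (trait, phenotype,
#' MCMC) can be re-randomized without changing the population.
#'
#' @param config A [sim_config()].
#' @param seed Master seed of the replicate.
#' @return A recoded `gs_population` over generations 0 to
#'   `config$n_validation_generations`.
#' @export
simulate_population <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(seed, 1))
  map <- build_genetic_map(config$n_chr, config$chr_length,
                           config$markers_per_chr)
  pop <- simulate_history(map, config$n_historical, config$historical_size,
                          config$mutation_rate)
  pop <- recode_biallelic(pop)
  set.seed(stage_seed(seed, 2))
  breed_validation_generations(pop,
                               n_generations = config$n_validation_generations,
                               progeny_per_dam_gen1 = config$progeny_per_dam_gen1,
                               n_sires = config$n_sires,
                               progeny_per_dam = config$progeny_per_dam)
}

#' Extract a dosage genotype matrix
#'
#' Genotypes are coded by allele-2 dosage minus one: -1 for the 1/1
#' homozygote, 0 for heterozygotes and 1 for the 2/2 homozygote.
#'
#' @param pop A recoded `gs_population`.
#' @param loci `"markers"`, `"qtl"` (potential QTL slots) or `"all"`.
#' @param generations Optional generation filter (default: all).
#' @return Integer individuals-by-loci matrix with ids as row names.
#' @export
genotype_matrix <- function(pop, loci = c("markers", "qtl", "all"),
                            generations = NULL) {
  stopifnot(inherits(pop, "gs_population"))
  if (!pop$recoded) stop("dosage coding requires a recoded (biallelic) population")
  loci <- match.arg(loci)
  rows <- switch(loci,
                 markers = marker_loci(pop$map),
                 qtl = qtl_loci(pop$map),
                 all = pop$map$loci$locus)
  keep <- if (is.null(generations)) rep(TRUE, nrow(pop$pedigree))
          else pop$pedigree$generation %in% generations
  Z <- t(pop$h1[rows, keep, drop = FALSE] + pop$h2[rows, keep, drop = FALSE]) - 3L
  rownames(Z) <- as.character(pop$pedigree$id[keep])
  Z
}

# allele-"1" frequency per column of a dosage matrix
allele_one_freq <- function(Z) 1 - (colMeans(Z) + 1) / 2
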