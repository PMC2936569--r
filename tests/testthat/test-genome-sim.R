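test_that("genetic map places the expected markers and QTL slots", {
  set.seed(1)
  map <- build_genetic_map(5, 1, 1000)
  expect_equal(sum(map$loci$type == "marker"), 5000)
  expect_equal(sum(map$loci$type == "qtl"), 4995)

  expect_equal(sum(build_genetic_map(1, 1, 2)$loci$type == "qtl"), 1)
  expect_equal(sum(build_genetic_map(2, 1, 3)$loci$type == "qtl"), 4)

  # positions strictly increasing within chromosomes, inside [0, length],
  # and one slot at each inter-marker midpoint
  small <- build_genetic_map(2, 1.5, 10)
  for (ch in 1:2) {
    loci <- small$loci[small$loci$chrom == ch, ]
    expect_true(all(diff(loci$pos) >= 0))
    expect_true(all(loci$pos >= 0 & loci$pos <= 1.5))
    mk <- loci$pos[loci$type == "marker"]
    expect_equal(loci$pos[loci$type == "qtl"],
                 (mk[-1] + mk[-length(mk)]) / 2)
  }

  expect_error(build_genetic_map(1, 0, 10), "length")
  expect_error(build_genetic_map(1, 1, 1), "at least 2")
})

test_that("Haldane mapping function matches its closed form", {
  expect_equal(haldane(0), 0)
  expect_equal(haldane(0.1), 0.5 * (1 - exp(-0.2)))
  expect_equal(haldane(1e6), 0.5)
  expect_error(haldane(-0.01), "non-negative")
})

test_that("meiosis respects degenerate cases", {
  set.seed(5)
  map <- build_genetic_map(2, 1, 25)
  L <- nrow(map$loci)
  h <- sample(1:4, L, replace = TRUE)
  # identical parental haplotypes reproduce themselves
  expect_equal(meiosis(h, h, map), h)

  # (near-)zero chromosome length: unrecombined copy of one haplotype
  # per chromosome
  tiny <- build_genetic_map(2, 1e-12, 5)
  h1 <- rep(1L, nrow(tiny$loci)); h2 <- rep(2L, nrow(tiny$loci))
  gam <- meiosis(h1, h2, tiny)
  for (ch in 1:2) {
    seg <- gam[tiny$loci$chrom == ch]
    expect_true(all(seg == seg[1]))
  }

  expect_error(meiosis(h[-1], h, map), "cover all loci")
})

test_that("empirical recombination fraction follows Haldane's map function", {
  set.seed(42)
  map <- build_genetic_map(1, 1, 2)
  d <- diff(map$loci$pos[map$loci$type == "marker"])
  # use marker loci only (slot midpoint sits in between)
  idx <- which(map$loci$type == "marker")
  n <- 10000
  rec <- 0L
  for (i in seq_len(n)) {
    g <- meiosis(c(1L, 1L, 1L), c(2L, 2L, 2L), map)
    rec <- rec + (g[idx[1]] != g[idx[2]])
  }
  p <- haldane(d)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(rec / n - p), 3 * se)
})

test_that("infinite-alleles mutation creates fresh labels at the stated rate", {
  h <- c(1L, 1L, 1L)
  out <- mutate_haplotype(h, rate = 0)
  expect_equal(out$haplotype, h)
  expect_equal(out$counter, rep(2L, 3))

  set.seed(9)
  out <- mutate_haplotype(h, rate = 1)
  expect_equal(out$haplotype, c(2L, 2L, 2L))   # all loci get their next label
  expect_equal(out$counter, rep(3L, 3))
  # mutating again yields labels never used before at each locus
  out2 <- mutate_haplotype(out$haplotype, rate = 1, counter = out$counter)
  expect_equal(out2$haplotype, c(3L, 3L, 3L))
  expect_error(mutate_haplotype(h, rate = 1.2), "probability")
})

test_that("historical population reaches mutation-drift heterozygosity", {
  set.seed(31)
  map <- build_genetic_map(5, 1, 30)        # 295 loci
  pop <- simulate_history(map, n_generations = 1000, pop_size = 100,
                          mutation_rate = 1.25e-3)
  expect_equal(nrow(pop$pedigree), 100)
  expect_equal(unique(pop$pedigree$generation), 0L)

  alle <- rbind(t(pop$h1), t(pop$h2))        # 200 gene copies x loci
  het <- apply(alle, 2, function(a) 1 - sum((table(a) / length(a))^2))
  # monogamous pairs with exactly two offspring each: zero family-size
  # variance, so the realized effective size is 2N - 1
  theta <- 4 * 199 * 1.25e-3                 # ~ 1, equilibrium H ~ 0.5
  expect_lt(abs(mean(het) - theta / (1 + theta)), 0.05)
  # most loci polymorphic at equilibrium
  expect_gt(mean(apply(alle, 2, function(a) length(unique(a)) > 1)), 0.5)
})

test_that("zero historical generations give the fully monomorphic base", {
  map <- build_genetic_map(1, 1, 5)
  pop <- simulate_history(map, 0, 10, 0.01)
  expect_true(all(pop$h1 == 1L) && all(pop$h2 == 1L))
})

test_that("biallelic recoding keeps the allele nearest frequency 0.5", {
  map <- build_genetic_map(1, 1, 2)
  # 25 individuals, one informative locus: alleles 1 (48%), 3 (30%), 7 (22%)
  labels <- c(rep(1L, 24), rep(3L, 15), rep(7L, 11))
  n <- 25
  h1 <- matrix(1L, nrow(map$loci), n)
  h2 <- matrix(1L, nrow(map$loci), n)
  h1[1, ] <- labels[1:25]; h2[1, ] <- labels[26:50]
  h1[2, ] <- 5L; h2[2, ] <- 5L                       # fixed for allele 5
  h1[3, ] <- rep(c(2L, 9L), c(13, 12))               # tie: 2 and 9 at 50/50
  h2[3, ] <- rep(c(2L, 9L), c(12, 13))
  ped <- tibble::tibble(id = 1:n, sire = NA_integer_, dam = NA_integer_,
                        sex = rep(c("M", "F"), length.out = n),
                        generation = 0L)
  pop <- tablup:::new_population(map, ped, h1, h2, recoded = FALSE)
  rec <- recode_biallelic(pop)

  g1 <- c(rec$h1[1, ], rec$h2[1, ])
  expect_equal(mean(g1 == 1), 0.48)                  # allele 1 kept as "1"
  expect_true(all(c(rec$h1[2, ], rec$h2[2, ]) == 1)) # monomorphic -> all 1
  g3 <- rbind(rec$h1[3, ], rec$h2[3, ])
  o3 <- rbind(h1[3, ], h2[3, ])
  expect_true(all(g3[o3 == 2L] == 1))                # tie-break: lower label
  expect_true(all(g3[o3 == 9L] == 2))
  expect_true(all(rec$h1 %in% c(1L, 2L)))
})

test_that("validation breeding follows the half-sib design", {
  pop <- tiny_population()
  ped <- pop$pedigree
  sizes <- table(ped$generation)
  expect_equal(unname(sizes[c("1", "2", "3")]), rep(200L, 3),
               ignore_attr = TRUE)

  # generation 1: every generation-0 female has progeny_per_dam_gen1
  # progeny, half of each sex
  g1 <- ped[ped$generation == 1, ]
  expect_equal(unname(table(g1$dam)), rep(4L, 50), ignore_attr = TRUE)
  expect_equal(unname(table(g1$sex)), c(100L, 100L), ignore_attr = TRUE)

  # later generations: 50 selected sires, each with
  # (n_females / n_sires) * progeny_per_dam offspring
  g2 <- ped[ped$generation == 2, ]
  prev_males <- ped$id[ped$generation == 1 & ped$sex == "M"]
  expect_true(all(g2$sire %in% prev_males))
  expect_equal(length(unique(g2$sire)), 50)
  expect_equal(unname(table(g2$sire)), rep(4L, 50), ignore_attr = TRUE)
  expect_equal(unname(table(g2$dam)), rep(2L, 100), ignore_attr = TRUE)

  # sex imbalance in the founders is rejected
  bad <- pop
  bad$pedigree <- ped[ped$generation == 0, ]
  bad$pedigree$sex <- "M"
  expect_error(breed_validation_generations(bad), "equal numbers")
})

test_that("every offspring allele is present in the corresponding parent", {
  pop <- tiny_population()
  ped <- pop$pedigree
  for (g in 1:3) {
    off <- which(ped$generation == g)
    si <- match(ped$sire[off], ped$id)
    di <- match(ped$dam[off], ped$id)
    # haplotype 1 is the paternal gamete, haplotype 2 the maternal one
    expect_true(all(pop$h1[, off] == pop$h1[, si] |
                    pop$h1[, off] == pop$h2[, si]))
    expect_true(all(pop$h2[, off] == pop$h1[, di] |
                    pop$h2[, off] == pop$h2[, di]))
  }
})

test_that("trait architecture rescales to the target additive variance", {
  pop <- tiny_population()
  set.seed(21)
  trait <- sample_trait_architecture(pop, n_qtl = 20, sigma_a2 = 1)
  expect_equal(nrow(trait), 20)
  expect_lt(abs(sum(trait$qvar) - 1), 1e-10)
  expect_true(all(trait$p > 0 & trait$p < 1))        # never monomorphic

  # a single QTL must carry the whole variance: |a| = sqrt(1 / (2p(1-p)))
  one <- sample_trait_architecture(pop, n_qtl = 1, sigma_a2 = 1)
  expect_equal(abs(one$effect), sqrt(1 / (2 * one$p * (1 - one$p))))

  # different target variance
  t4 <- sample_trait_architecture(pop, n_qtl = 10, sigma_a2 = 4)
  expect_lt(abs(sum(t4$qvar) - 4), 1e-10)

  expect_error(sample_trait_architecture(pop, n_qtl = 1e6), "polymorphic")
})

test_that("true breeding values sum effect-weighted dosages", {
  pop <- tiny_population()
  set.seed(22)
  trait <- sample_trait_architecture(pop, n_qtl = 5)
  Z <- matrix(0L, 3, 5, dimnames = list(1:3, NULL))
  Z[2, ] <- 1L                                       # homozygote "22" at all QTL
  Z[3, 1] <- -1L
  tbv <- compute_tbv(Z, trait)
  expect_equal(tbv$tbv[1], 0)                        # all-heterozygote
  expect_equal(tbv$tbv[2], sum(trait$effect))
  expect_equal(tbv$tbv[3], -trait$effect[1])

  # one QTL, a = 0.3, genotype 22
  t1 <- trait[1, ]
  attr(t1, "qtl_index") <- NULL
  class(t1) <- class(trait)
  t1$effect <- 0.3
  expect_equal(compute_tbv(matrix(1L, 1, 1, dimnames = list(7, NULL)), t1)$tbv,
               0.3)

  # training-generation TBV variance is near the rescaling target
  fx <- tiny_training()
  v1 <- var(fx$tbv$tbv[fx$tbv$generation == 1])
  expect_lt(abs(v1 - 1), 0.35)
})

test_that("phenotypes add independent environmental noise", {
  fx <- tiny_training()
  tbv1 <- fx$tbv[fx$tbv$generation == 1, ]
  expect_equal(simulate_phenotypes(tbv1, 0)$phenotype, tbv1$tbv)
  expect_error(simulate_phenotypes(tbv1, -1), "non-negative")

  set.seed(77)
  ph <- simulate_phenotypes(tbv1, 1)                 # h2 = 0.5 at sigma_a2 = 1
  expect_lt(abs(var(ph$phenotype) - var(tbv1$tbv) - 1), 0.35)
  expect_equal(sim_config(h2 = 0.5, sigma_a2 = 1)$sigma_e2, 1)
})

test_that("population simulation is reproducible from its seed", {
  cfg <- tiny_config()
  a <- simulate_population(cfg, seed = 5)
  b <- simulate_population(cfg, seed = 5)
  expect_identical(a$h1, b$h1)
  expect_identical(a$pedigree, b$pedigree)
})
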