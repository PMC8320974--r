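test_that("founder-group profiles behave like symmetric Dirichlet draws", {
  # huge concentration -> near-uniform frequencies in every group
  cfg <- small_config(seed = 2, n_loci = 10)
  cfg$founder_divergence <- 1e6
  g <- simulate_founder_groups(cfg)
  for (grp in g$freqs) for (f in grp) {
    expect_lt(max(abs(f - 1 / length(f))), 0.01)
  }
  # low concentration -> groups measurably diverged
  cfg2 <- small_config(seed = 2, n_loci = 30)
  cfg2$founder_divergence <- 0.2
  g2 <- simulate_founder_groups(cfg2)
  d <- nei_distance(g2$freqs[[1]], g2$freqs[[2]])
  expect_gt(d, 0)
  # determinism
  g2b <- simulate_founder_groups(cfg2)
  expect_identical(g2, g2b)
})

test_that("Mendelian segregation drives family simulation", {
  one_locus <- function(a, b) matrix(c(a, b), nrow = 2)
  # selfing a heterozygote: half the offspring heterozygous (binomial 3-sigma)
  off <- simulate_family(list(one_locus(1L, 2L)), "selfing", 4000, seed = 11)
  het <- mean(vapply(off, function(g) g[1, 1] != g[2, 1], TRUE))
  expect_lt(abs(het - 0.5), 0.025)
  # forced segregation
  off2 <- simulate_family(list(one_locus(1L, 1L), one_locus(2L, 2L)),
                          "cross_mating", 50, seed = 1)
  expect_true(all(vapply(off2, function(g) setequal(g[, 1], c(1L, 2L)), TRUE)))
  # selfing a homozygote yields no variation
  off3 <- simulate_family(list(one_locus(3L, 3L)), "selfing", 20, seed = 1)
  expect_true(all(vapply(off3, function(g) all(g == 3L), TRUE)))
  # parent-count contract
  expect_error(simulate_family(list(one_locus(1L, 2L)), "cross_mating", 5),
               "requires 2")
  expect_error(simulate_family(list(one_locus(1L, 2L), one_locus(1L, 2L)),
                               "selfing", 5), "requires 1")
})

test_that("offspring alleles are a subset of the founders' alleles", {
  cfg <- small_config(seed = 21, n_loci = 15)
  sim <- simulate_germplasm(cfg)
  grp <- sim$partition$pop[sim$dataset$individual_ids]
  for (fam in sim$partition$populations) {
    founders <- sim$truth$founders[[fam]]
    rows <- which(grp == fam)
    for (l in seq_len(n_loci(sim$dataset))) {
      parental <- unique(unlist(lapply(founders, function(p) p[, l])))
      seen <- unique(c(sim$dataset$a1[rows, l], sim$dataset$a2[rows, l]))
      seen <- seen[!is.na(seen)]
      expect_true(all(seen %in% parental))
    }
  }
})

test_that("the default germplasm matches the declared family structure", {
  sim <- simulate_germplasm(sim_config(seed = 1))
  expect_equal(n_individuals(sim$dataset), 186)
  expect_equal(length(sim$partition$populations), 12)
  expect_equal(unname(sim$partition$sizes),
               c(20L, 8L, 19L, 12L, 20L, 8L, 13L, 18L, 5L, 12L, 31L, 20L))
  expect_equal(n_loci(sim$dataset), 107)
  # same seed -> identical dataset
  sim2 <- simulate_germplasm(sim_config(seed = 1))
  expect_identical(sim$dataset$a1, sim2$dataset$a1)
})

test_that("missing-rate bounds behave as declared", {
  expect_false(anyNA(simulate_germplasm(small_config(seed = 4,
                                                     missing_rate = 0))$dataset$a1))
  cfg <- small_config(seed = 4, missing_rate = 1)
  sim <- simulate_germplasm(cfg)
  expect_true(all(is.na(sim$dataset$a1)))
  ft <- allele_frequencies(sim$dataset)
  expect_true(all(ft$n_typed == 0L))
  expect_true(all(lengths(ft$freq[["ALL"]]) == 0))
})

test_that("selfed families show half the parent's heterozygous fraction", {
  cfg <- small_config(seed = 31, n_loci = 60,
                      families = data.frame(name = "S1", design = "selfing",
                                            size = 40, founder_group = 1),
                      missing_rate = 0)
  cfg$n_founder_groups <- 1L
  sim <- simulate_germplasm(cfg)
  parent <- sim$truth$founders[["S1"]][[1]]
  het_parent <- mean(parent[1, ] != parent[2, ])
  ho <- mean(sim$dataset$a1 != sim$dataset$a2)
  # expected Ho = het_parent / 2; 3-sigma binomial band on n*L draws
  n_draws <- n_individuals(sim$dataset) * n_loci(sim$dataset)
  band <- 3 * sqrt(0.5 * het_parent * (1 - 0.5 * het_parent) / n_draws) + 0.02
  expect_lt(abs(ho - het_parent / 2), band)
})

test_that("a panmictic cross-mated collection has near-zero pooled F", {
  fam <- data.frame(name = paste0("C", 1:8), design = "cross_mating",
                    size = 12, founder_group = 1)
  cfg <- small_config(seed = 13, n_loci = 50, families = fam, missing_rate = 0)
  cfg$n_founder_groups <- 1L
  cfg$founder_divergence <- 10
  sim <- simulate_germplasm(cfg)
  tab <- locus_diversity_table(sim$dataset)
  f <- mean((tab$He - tab$Ho) / tab$He)
  expect_lt(abs(f), 0.1)
})

test_that("lower founder divergence raises between-family differentiation", {
  fst_at <- function(div, seed) {
    cfg <- small_config(seed = seed, n_loci = 20, divergence = div)
    sim <- simulate_germplasm(cfg)
    # at extreme divergence some family pairs share no alleles (Nei = Inf);
    # only the FST triangle is used here
    pm <- suppressWarnings(population_pair_matrix(sim$dataset, sim$partition))
    mean(pm$fst[upper.tri(pm$fst)])
  }
  seeds <- 1:10
  low <- vapply(seeds, function(s) fst_at(0.1, s), 0)
  high <- vapply(seeds, function(s) fst_at(100, s), 0)
  expect_gt(mean(low), mean(high))
})
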