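freqmap <- function(...) {
  # freqmap(L1 = c(`1` = 0.5, `2` = 0.5), ...)
  lst <- list(...)
  lapply(lst, function(f) stats::setNames(as.numeric(f), names(f)))
}

test_that("Nei's standard distance matches hand computations", {
  fA <- freqmap(L1 = c(`1` = 1, `2` = 0))
  fB <- freqmap(L1 = c(`1` = 0.5, `2` = 0.5))
  expect_equal(nei_distance(fA, fA), 0)
  expect_equal(nei_distance(fA, fB), -log(0.5 / sqrt(0.5)), tolerance = 1e-12)
  fC <- freqmap(L1 = c(`2` = 1))
  expect_warning(d <- nei_distance(fA, fC), "no alleles")
  expect_identical(d, Inf)
})

test_that("pairwise FST matches the gene-diversity formulation", {
  fA <- freqmap(L1 = c(`1` = 1))
  fB <- freqmap(L1 = c(`2` = 1))
  fU <- freqmap(L1 = c(`1` = 0.5, `2` = 0.5))
  expect_warning(f0 <- pairwise_fst(fA, fA), "defined 0")  # monomorphic pair
  expect_equal(f0, 0)
  expect_equal(pairwise_fst(fA, fB), 1)
  expect_equal(pairwise_fst(fA, fU), (0.375 - 0.25) / 0.375, tolerance = 1e-12)
  # symmetry
  expect_equal(pairwise_fst(fA, fU), pairwise_fst(fU, fA))
  expect_equal(nei_distance(fA, fU), nei_distance(fU, fA))
})

test_that("island-model gene flow follows 0.25(1-F)/F", {
  expect_equal(gene_flow(0.25), 0.75)
  expect_equal(gene_flow(1), 0)
  expect_equal(gene_flow(0.2), 1.0)
  expect_error(gene_flow(1.2), "must lie")
  expect_warning(nm <- gene_flow(0), "unbounded")
  expect_identical(nm, Inf)
})

test_that("codominant squared distance reproduces the classic table", {
  expect_equal(genotype_sq_distance(c(1, 1), c(1, 1)), 0)
  expect_equal(genotype_sq_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(genotype_sq_distance(c(1, 1), c(1, 2)), 1)
  expect_equal(genotype_sq_distance(c(1, 2), c(1, 3)), 1)
  expect_equal(genotype_sq_distance(c(1, 2), c(3, 4)), 2)
  expect_equal(genotype_sq_distance(c(1, 1), c(2, 3)), 3)
  expect_equal(genotype_sq_distance(c(1, 1), c(2, 2)), 4)
  # matrix version agrees with the scalar op on complete data
  gd <- random_gd(6, 4, k = 3, seed = 2)
  D2 <- squared_distance_matrix(gd)
  for (i in 1:5) for (j in (i + 1):6) {
    manual <- sum(vapply(seq_len(4), function(l)
      genotype_sq_distance(c(gd$a1[i, l], gd$a2[i, l]),
                           c(gd$a1[j, l], gd$a2[j, l])), 0))
    expect_equal(D2[i, j], manual)
  }
})

test_that("AMOVA on a fixed between-population difference is fully among", {
  gd <- make_gd(list(P1 = list(c(1L, 1L)), P2 = list(c(1L, 1L)),
                     P3 = list(c(2L, 2L)), P4 = list(c(2L, 2L))))
  pop <- c(P1 = "A", P2 = "A", P3 = "B", P4 = "B")
  res <- amova(gd, population_partition(pop), n_perm = 99, seed = 1)
  expect_equal(res$percent_among, 100)
  expect_equal(res$phipt, 1)
  expect_equal(res$SS_within, 0)
  expect_equal(res$df_among + res$df_within, 3)
})

test_that("AMOVA degenerate and determinism contracts hold", {
  gd <- make_gd(list(P1 = list(c(1L, 1L)), P2 = list(c(1L, 1L)),
                     P3 = list(c(1L, 1L)), P4 = list(c(1L, 1L))))
  pop <- c(P1 = "A", P2 = "A", P3 = "B", P4 = "B")
  res <- amova(gd, population_partition(pop), n_perm = 49, seed = 1)
  expect_equal(res$phipt, 0)
  expect_equal(res$p_value, 1)
  # identical seed -> identical p-value on non-degenerate data
  sim <- simulate_germplasm(small_config(seed = 2, n_loci = 10))
  r1 <- amova(sim$dataset, sim$partition, n_perm = 99, seed = 5)
  r2 <- amova(sim$dataset, sim$partition, n_perm = 99, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 100)
})

test_that("AMOVA sums of squares are conserved and match the count-vector oracle", {
  sim <- simulate_germplasm(small_config(seed = 7, n_loci = 8, families =
    data.frame(name = c("A", "B", "C"), design = "cross_mating",
               size = c(3, 2, 3), founder_group = c(1, 2, 3))))
  res <- amova(sim$dataset, sim$partition, n_perm = 0)
  expect_equal(res$SS_among + res$SS_within, res$SS_total, tolerance = 1e-9)
  expect_equal(res$df_among + res$df_within, n_individuals(sim$dataset) - 1)
  oracle <- amova_ss_oracle(sim$dataset, sim$partition)
  expect_equal(res$SS_total, oracle$total, tolerance = 1e-9)
  expect_equal(res$SS_within, oracle$within, tolerance = 1e-9)
  expect_equal(res$SS_among, oracle$among, tolerance = 1e-9)
  # variance components from the expected-mean-squares identities
  k <- 3; N <- 8; sizes <- c(3, 2, 3)
  sw <- oracle$within / (N - k)
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  sa <- max(0, (oracle$among / (k - 1) - sw) / n0)
  expect_equal(res$sigma_within, sw, tolerance = 1e-9)
  expect_equal(res$sigma_among, sa, tolerance = 1e-9)
})

test_that("differentiation rises as founder divergence falls (PhiPT)", {
  phipt_at <- function(div, seed) {
    fam <- data.frame(name = c("A", "B", "C"), design = "cross_mating",
                      size = 8, founder_group = 1:3)
    cfg <- small_config(seed = seed, n_loci = 12, divergence = div,
                        families = fam)
    cfg$n_founder_groups <- 3L
    sim <- simulate_germplasm(cfg)
    amova(sim$dataset, sim$partition, n_perm = 0)$phipt
  }
  seeds <- 1:10
  low <- vapply(seeds, function(s) phipt_at(0.1, s), 0)
  high <- vapply(seeds, function(s) phipt_at(100, s), 0)
  expect_gt(mean(low), mean(high))
})

test_that("the combined pairwise matrix is a valid distance container", {
  sim <- simulate_germplasm(small_config(seed = 12, n_loci = 15))
  pm <- population_pair_matrix(sim$dataset, sim$partition)
  expect_true(all(diag(pm$combined) == 0))
  expect_true(all(pm$nei >= 0))
  expect_true(all(pm$fst >= 0 & pm$fst <= 1))
  expect_equal(pm$nei, t(pm$nei))
  expect_equal(pm$fst, t(pm$fst))
  # CSV round trip preserves the layout
  f <- withr::local_tempfile(fileext = ".csv")
  write_pair_matrix(pm, f)
  back <- read_pair_matrix(f)
  expect_equal(unname(back), unname(round(pm$combined, 6)), tolerance = 1e-9)
})
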