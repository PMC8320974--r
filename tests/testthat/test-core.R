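# Four accessions carrying allele sets {a,b}, {b,c}, {c,d}, {a,d} at four
# mono-band loci: minimum full cover has exactly 2 entries.
ring_fixture <- function() {
  make_gd(list(P1 = list(c(1L, 1L), c(2L, 2L), NA, NA),
               P2 = list(NA, c(2L, 2L), c(3L, 3L), NA),
               P3 = list(NA, NA, c(3L, 3L), c(4L, 4L)),
               P4 = list(c(1L, 1L), NA, NA, c(4L, 4L))))
}

test_that("coverage counts (locus, allele) classes and is monotone", {
  gd <- ring_fixture()
  expect_equal(coverage(gd, gd$individual_ids), 1)
  expect_equal(coverage(gd, "P1"), 0.5)
  expect_error(coverage(gd, character(0)), "non-empty")
  expect_gte(coverage(gd, c("P1", "P2")), coverage(gd, "P1"))
})

test_that("greedy M-strategy finds a minimum cover on the ring fixture", {
  gd <- ring_fixture()
  core <- mstrategy_core(gd)
  expect_equal(core$CV, 1)
  expect_equal(length(core$ids), min_cover_size(gd))
  # a dataset of identical individuals collapses to one entry
  same <- make_gd(list(P1 = list(c(1L, 2L)), P2 = list(c(1L, 2L)),
                       P3 = list(c(1L, 2L))))
  expect_length(mstrategy_core(same)$ids, 1)
  # every allele private to one individual forces the full collection
  priv <- make_gd(list(P1 = list(c(1L, 1L)), P2 = list(c(2L, 2L)),
                       P3 = list(c(3L, 3L))))
  expect_setequal(mstrategy_core(priv)$ids, priv$individual_ids)
})

test_that("greedy core always reaches CV = 1 on synthetic germplasm", {
  sim <- simulate_germplasm(small_config(seed = 14, missing_rate = 0.05))
  core <- mstrategy_core(sim$dataset)
  expect_equal(core$CV, 1)
  expect_lt(length(core$ids), n_individuals(sim$dataset))
  # the redundancy pass leaves no removable entry
  for (id in core$ids) {
    expect_lt(coverage(sim$dataset, setdiff(core$ids, id)), 1)
  }
})

test_that("local search attains the exhaustive optimum on tiny fixtures", {
  gd <- ring_fixture()
  core <- localsearch_core(gd, 0.5, seed = 2, max_stall = 200)
  expect_equal(length(core$ids), 2)
  expect_equal(core$CV, best_cv_at_size(gd, 2))
  # determinism
  core2 <- localsearch_core(gd, 0.5, seed = 2, max_stall = 200)
  expect_identical(core$ids, core2$ids)
  # objective trace is non-decreasing and the final CV is at least the initial
  expect_true(all(diff(core$objective_trace) >= 0))
  expect_error(localsearch_core(gd, 1.2, seed = 1), "intensity")
})

test_that("local search handles heavy redundancy at near-full intensity", {
  same <- make_gd(rep(list(list(c(1L, 2L), c(3L, 4L))), 6))
  core <- localsearch_core(same, 5 / 6 - 1e-9, seed = 1, max_stall = 50)
  expect_equal(core$CV, 1)
  expect_length(core$ids, 5)
})

test_that("core evaluation matches the hand-worked three-accession case", {
  # With homozygous single-band loci, both Dice and Bray-Curtis equal the
  # fraction of mismatching loci. Ten loci planted so that d(1,2) = 0.4,
  # d(1,3) = 0.2, d(2,3) = 0.6: 4 loci shared by all, 2 loci where A3
  # differs, 4 loci where A2 differs.
  hom <- function(alleles) lapply(alleles, function(a) c(a, a))
  gd <- make_gd(list(
    A1 = hom(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)),
    A2 = hom(c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)),
    A3 = hom(c(1L, 1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L, 1L))))
  d <- pairwise_distance(gd, "dice")
  expect_equal(d["A1", "A2"], 0.4)
  expect_equal(d["A1", "A3"], 0.2)
  expect_equal(d["A2", "A3"], 0.6)
  ev <- evaluate_core(gd, c("A1", "A2"), metric = "dice")
  expect_equal(ev$A_NE, 0.2 / 3, tolerance = 1e-12)
  expect_equal(ev$E_E, 0.4)
  expect_equal(ev$E_NE_min, 0.4)
  expect_equal(ev$E_NE_mean, 0.4)
  # whole collection as core: perfect representativeness
  ev_all <- evaluate_core(gd, gd$individual_ids)
  expect_equal(ev_all$A_NE, 0)
  # size-1 core flags E-E/E-NE undefined
  expect_warning(ev1 <- evaluate_core(gd, "A1"), "size 1")
  expect_true(is.na(ev1$E_E))
})

test_that("adding any accession to a core never increases A-NE", {
  sim <- simulate_germplasm(small_config(seed = 15, n_loci = 12))
  ids <- sim$dataset$individual_ids
  core <- ids[1:10]
  base <- evaluate_core(sim$dataset, core)$A_NE
  grown <- evaluate_core(sim$dataset, c(core, ids[30]))$A_NE
  expect_lte(grown, base + 1e-12)
})

test_that("validation of the full collection against itself is the identity", {
  sim <- simulate_germplasm(small_config(seed = 16, n_loci = 10))
  val <- validate_core(sim$dataset, sim$partition, sim$dataset$individual_ids)
  expect_true(all(val$t_tests$t == 0))
  expect_true(all(val$t_tests$p == 1))
  expect_true(all(val$chisq$statistic == 0, na.rm = TRUE))
  expect_equal(val$r_squared, 1)
  expect_equal(val$membership$pct_core, rep(100, 12))
})

test_that("a core missing one allele class raises that locus's chi-square", {
  gd <- make_gd(list(P1 = list(c(1L, 1L)), P2 = list(c(1L, 2L)),
                     P3 = list(c(2L, 2L)), P4 = list(c(1L, 1L))))
  part <- uniform_partition(gd)
  val <- validate_core(gd, part, c("P1", "P4"))  # allele 2 absent from core
  expect_gt(val$chisq$statistic[1], 0)
  expect_lt(val$r_squared, 1)
})

test_that("frequency-correlation R^2 is invariant to locus order", {
  sim <- simulate_germplasm(small_config(seed = 18, n_loci = 8))
  core <- mstrategy_core(sim$dataset)$ids
  v1 <- validate_core(sim$dataset, sim$partition, core)$r_squared
  rev_ds <- genotype_dataset(sim$dataset$a1[, 8:1], sim$dataset$a2[, 8:1])
  v2 <- validate_core(rev_ds, sim$partition, core)$r_squared
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("the intensity scan reports the smallest fully covering intensity", {
  sim <- simulate_germplasm(small_config(seed = 19, n_loci = 10))
  scan <- core_intensity_scan(sim$dataset, grid = c(0.1, 0.2, 0.3),
                              seed = 1, max_stall = 300)
  expect_equal(nrow(scan$table), 3)
  expect_true(all(diff(scan$table$size) > 0))
  if (!is.na(scan$min_full)) {
    expect_gte(scan$table$CV[scan$table$intensity == scan$min_full], 1)
  }
})

test_that("cores preserve the collection's diversity indices across seeds", {
  ls_ok <- 0L
  greedy_ok <- 0L
  for (s in 1:10) {
    sim <- simulate_germplasm(sim_config(seed = s))
    # local search at the ~31% intensity regime: all six indices preserved
    ls_ids <- localsearch_core(sim$dataset, 0.31, seed = s)$ids
    ls_val <- validate_core(sim$dataset, sim$partition, ls_ids)
    if (sum(ls_val$t_tests$p >= 0.05, na.rm = TRUE) >= 5) ls_ok <- ls_ok + 1L
    # the greedy minimal core preserves the frequency-spectrum indices
    # (A, Ae, I, He); its much smaller size deliberately over-samples
    # heterozygous, allele-rich palms, so Ho and F shift upward/downward
    # and are not asserted here
    g_val <- validate_core(sim$dataset, sim$partition,
                           mstrategy_core(sim$dataset)$ids)
    g_p <- g_val$t_tests$p[g_val$t_tests$index %in% c("A", "Ae", "I", "He")]
    if (all(g_p >= 0.05, na.rm = TRUE)) greedy_ok <- greedy_ok + 1L
  }
  expect_gte(ls_ok, 8L)
  expect_gte(greedy_ok, 8L)
})
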