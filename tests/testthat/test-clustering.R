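test_that("band profiles expand genotypes to presence/absence with NA propagation", {
  gd <- make_gd(list(P1 = list(c(100L, 102L)), P2 = list(c(100L, 100L)),
                     P3 = list(NA)))
  b <- band_profile(gd)
  expect_equal(colnames(b), c("L1:100", "L1:102"))
  expect_equal(unname(b["P1", ]), c(1, 1))
  expect_equal(unname(b["P2", ]), c(1, 0))
  expect_true(all(is.na(b["P3", ])))
})

test_that("Dice and Bray-Curtis distances match hand computations", {
  # bands {a,b} vs {b,c}: one shared, two private -> 0.5
  gd <- make_gd(list(P1 = list(c(1L, 2L)), P2 = list(c(2L, 3L))))
  d <- pairwise_distance(gd, "dice")
  expect_equal(d["P1", "P2"], 0.5)
  # identical individuals -> 0 under both metrics
  gd2 <- make_gd(list(P1 = list(c(1L, 2L)), P2 = list(c(1L, 2L))))
  expect_equal(pairwise_distance(gd2, "dice")["P1", "P2"], 0)
  expect_equal(pairwise_distance(gd2, "bray_curtis")["P1", "P2"], 0)
  # counts (2,0) vs (1,1) -> 1 - 2*1/4 = 0.5
  gd3 <- make_gd(list(P1 = list(c(1L, 1L)), P2 = list(c(1L, 2L))))
  expect_equal(pairwise_distance(gd3, "bray_curtis")["P1", "P2"], 0.5)
  # missing loci are excluded pairwise
  gd4 <- make_gd(list(P1 = list(c(1L, 2L), NA), P2 = list(c(2L, 3L), c(5L, 6L))))
  expect_equal(pairwise_distance(gd4, "dice")["P1", "P2"], 0.5)
})

test_that("Bray-Curtis agrees with vegan on complete data", {
  skip_if_not_installed("vegan")
  gd <- random_gd(12, 8, k = 5, seed = 3)
  d <- pairwise_distance(gd, "bray_curtis")
  counts <- allele_count_profile(gd)
  ref <- as.matrix(vegan::vegdist(counts, method = "bray"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12, ignore_attr = TRUE)
})

node_first_pair <- function(tree) {
  # leaves of the lowest internal node
  find <- function(node) {
    if (is.character(node)) return(NULL)
    l <- find(node$left); if (!is.null(l)) return(l)
    r <- find(node$right); if (!is.null(r)) return(r)
    if (is.character(node$left) && is.character(node$right))
      return(c(node$left, node$right))
    NULL
  }
  find(tree$root)
}

test_that("UPGMA reproduces the hand-worked three-leaf case with tie-breaking", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  cm <- cophenetic_upgma(tr)
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["A", "C"], 4)
  expect_equal(tr$heights, c(1, 2))
  # all-equal distances: deterministic lexicographic merge order
  d2 <- matrix(1, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(d2) <- 0
  tr2 <- upgma(d2)
  expect_equal(sort(node_first_pair(tr2)), c("a", "b"))
  expect_true(is_ultrametric(tr2))
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("UPGMA equals the naive oracle and hclust on random matrices", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 25
    x <- matrix(rnorm(n * 4), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgma(d)
    expect_true(is_ultrametric(tr))
    cm <- cophenetic_upgma(tr)
    oracle <- upgma_cophenetic_oracle(d)
    expect_equal(cm, oracle, tolerance = 1e-9)
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(unname(cm[hc$labels, hc$labels]),
                 unname(as.matrix(cophenetic(hc))), tolerance = 1e-9)
  }
})

test_that("Newick export round-trips through ape with consistent heights", {
  skip_if_not_installed("ape")
  set.seed(4)
  x <- matrix(rnorm(10 * 3), 10)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  tr <- upgma(d)
  nwk <- write_newick(tr)
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, rownames(d))
  cm <- cophenetic_upgma(tr)
  expect_equal(unname(ape::cophenetic.phylo(ph)[rownames(cm), colnames(cm)]),
               unname(cm), tolerance = 1e-4)
})

test_that("PCoA matches hand computation and planted configurations", {
  # two points at distance 2: single positive eigenvalue 2, coordinates +-1
  d <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  res <- pcoa(d)
  expect_equal(res$eigenvalues[1], 2, tolerance = 1e-9)
  expect_equal(sort(unname(res$coordinates[, 1])), c(-1, 1), tolerance = 1e-9)
  expect_equal(res$percent[1], 100)
  # planted 2-D Euclidean configuration is recovered exactly
  set.seed(5)
  pts <- matrix(rnorm(16), 8, 2)
  d2 <- as.matrix(dist(pts))
  res2 <- pcoa(d2)
  rec <- as.matrix(dist(res2$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(d2), tolerance = 1e-9)
  # eigenvalue sum equals the trace of the double-centred matrix
  A <- -0.5 * d2^2
  J <- diag(8) - matrix(1 / 8, 8, 8)
  expect_equal(sum(res2$eigenvalues), sum(diag(J %*% A %*% J)), tolerance = 1e-9)
  # duplicated individuals share coordinates
  d3 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  res3 <- pcoa(d3)
  expect_equal(res3$coordinates[1, ], res3$coordinates[2, ], tolerance = 1e-9)
})

test_that("PCoA agrees with cmdscale", {
  set.seed(6)
  pts <- matrix(rnorm(30), 10, 3)
  d <- as.matrix(dist(pts))
  res <- pcoa(d)
  ref <- cmdscale(d, k = 3, eig = TRUE)
  expect_equal(res$eigenvalues[1:3], ref$eig[1:3], tolerance = 1e-9)
  expect_equal(abs(unname(res$coordinates[, 1:3])), abs(unname(ref$points)),
               tolerance = 1e-8)
})
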