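# Small in-code fixtures shared across tests.

# Build a genotype_dataset from a list: one entry per individual, each a list
# of length-2 integer vectors (or NA for a missing call), one per locus.
make_gd <- function(calls, loci = NULL) {
  n <- length(calls)
  p <- length(calls[[1]])
  if (is.null(loci)) loci <- paste0("L", seq_len(p))
  a1 <- matrix(NA_integer_, n, p)
  a2 <- matrix(NA_integer_, n, p)
  for (i in seq_len(n)) for (l in seq_len(p)) {
    g <- calls[[i]][[l]]
    if (length(g) == 2 && !anyNA(g)) {
      a1[i, l] <- g[1]; a2[i, l] <- g[2]
    }
  }
  ids <- names(calls)
  if (is.null(ids)) ids <- paste0("P", seq_len(n))
  genotype_dataset(a1, a2, individual_ids = ids, locus_ids = loci)
}

uniform_partition <- function(dataset, pop = "A") {
  p <- rep(pop, length.out = n_individuals(dataset))
  names(p) <- dataset$individual_ids
  population_partition(p)
}

# Random complete dataset: n individuals, p loci, k alleles per locus.
random_gd <- function(n, p, k = 4, seed = 1) {
  set.seed(seed)
  a1 <- matrix(sample.int(k, n * p, replace = TRUE), n, p)
  a2 <- matrix(sample.int(k, n * p, replace = TRUE), n, p)
  genotype_dataset(a1, a2)
}

# Two-population dataset fixed for different alleles at every locus.
separable_gd <- function(n_per = 10, p = 10) {
  a1 <- rbind(matrix(1L, n_per, p), matrix(2L, n_per, p))
  gd <- genotype_dataset(a1, a1)
  pop <- rep(c("A", "B"), each = n_per)
  names(pop) <- gd$individual_ids
  list(dataset = gd, partition = population_partition(pop))
}

# Compact sim config for fast synthetic-data tests.
small_config <- function(seed = 1, n_loci = 25, divergence = 1,
                         families = NULL, missing_rate = 0) {
  if (is.null(families)) families <- default_families()
  sim_config(n_loci = n_loci, founder_divergence = divergence,
             families = families, missing_rate = missing_rate, seed = seed)
}

# Independent AMOVA oracle: sums of squares from allele-count vectors.
# SS_total = 0.5 * sum_i ||y_i - y_bar||^2 (complete data only), and the
# within term likewise per population around its own centroid.
amova_ss_oracle <- function(dataset, partition) {
  Y <- ssrcore::allele_count_profile(dataset)
  stopifnot(!anyNA(Y))
  grp <- partition$pop[dataset$individual_ids]
  center <- colMeans(Y)
  ss_total <- 0.5 * sum(sweep(Y, 2, center)^2)
  ss_within <- 0
  for (g in unique(grp)) {
    Yg <- Y[grp == g, , drop = FALSE]
    ss_within <- ss_within + 0.5 * sum(sweep(Yg, 2, colMeans(Yg))^2)
  }
  list(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

# Naive O(n^3) UPGMA oracle returning the cophenetic matrix.
upgma_cophenetic_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labs <- rownames(d)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  D <- d
  cm <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(members) > 1) {
    m <- length(members)
    best <- c(NA, NA); bestd <- Inf
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (a in members[[i]]) for (b in members[[j]]) {
      cm[a, b] <- cm[b, a] <- bestd
    }
    newd <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]), c(newd[keep], 0))
    members <- c(members[keep], list(c(members[[i]], members[[j]])))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  cm
}

# Exhaustive minimum-cover oracle for core selection on tiny datasets.
min_cover_size <- function(dataset) {
  n <- n_individuals(dataset)
  ids <- dataset$individual_ids
  for (k in 1:n) {
    combs <- utils::combn(n, k)
    for (c in seq_len(ncol(combs))) {
      if (coverage(dataset, ids[combs[, c]]) >= 1) return(k)
    }
  }
  n
}

best_cv_at_size <- function(dataset, m) {
  n <- n_individuals(dataset)
  ids <- dataset$individual_ids
  combs <- utils::combn(n, m)
  max(apply(combs, 2, function(ix) coverage(dataset, ids[ix])))
}

rdirichlet_test <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }
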