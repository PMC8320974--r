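#' Squared genetic distance between two single-locus diploid calls
#'
#' Codominant squared metric used as the AMOVA substrate. It equals half the
#' squared Euclidean distance between allele-count vectors, which yields the
#' classic table: identical genotypes 0; `ii` vs `ij` 1; `ij` vs `ik` 1;
#' `ij` vs `kl` 2; `ii` vs `jk` 3; `ii` vs `jj` 4.
#'
#' @param callA,callB integer length-2 allele pairs (non-missing)
#' @return squared distance (0, 1, 2, 3 or 4)
#' @export
genotype_sq_distance <- function(callA, callB) {
  if (anyNA(callA) || anyNA(callB)) stop("both calls must be non-missing")
  alleles <- union(callA, callB)
  ca <- vapply(alleles, function(a) sum(callA == a), 0L)
  cb <- vapply(alleles, function(a) sum(callB == a), 0L)
  0.5 * sum((ca - cb)^2)
}

#' Multilocus squared-distance matrix between individuals
#'
#' Sums [genotype_sq_distance] over loci (codominant metric), or for
#' `substrate = "band"` uses the squared Euclidean distance between binary
#' band-presence vectors. Loci missing in either individual of a pair are
#' skipped for that pair.
#'
#' @param dataset a [genotype_dataset]
#' @param substrate `"codominant"` (allele-count metric) or `"band"`
#'   (presence/absence metric)
#' @return symmetric N x N numeric matrix with zero diagonal
#' @export
squared_distance_matrix <- function(dataset, substrate = c("codominant", "band")) {
  substrate <- match.arg(substrate)
  n <- n_individuals(dataset)
  D2 <- matrix(0, n, n, dimnames = list(dataset$individual_ids,
                                        dataset$individual_ids))
  half <- if (substrate == "codominant") 0.5 else 1
  for (l in seq_len(n_loci(dataset))) {
    x1 <- dataset$a1[, l]; x2 <- dataset$a2[, l]
    obs <- as.numeric(!is.na(x1))
    alleles <- sort(unique(c(x1, x2)))
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) next
    C <- matrix(0, n, length(alleles))
    for (a in seq_along(alleles)) {
      C[, a] <- (x1 == alleles[a]) + (x2 == alleles[a])
    }
    C[is.na(C)] <- 0
    if (substrate == "band") C <- (C > 0) + 0
    s <- rowSums(C^2)
    D2 <- D2 + half * (outer(s * obs, obs) + outer(obs, s * obs) - 2 * tcrossprod(C))
  }
  D2
}

phipt_from_ss <- function(ss_among, ss_within, sizes) {
  N <- sum(sizes); k <- length(sizes)
  df_among <- k - 1L; df_within <- N - k
  sigma_within <- ss_within / df_within
  n0 <- (N - sum(sizes^2) / N) / df_among
  sigma_among <- (ss_among / df_among - sigma_within) / n0
  if (!is.finite(sigma_among) || sigma_among < 0) sigma_among <- 0
  total <- sigma_among + sigma_within
  phipt <- if (total > 0) sigma_among / total else 0
  list(sigma_among = sigma_among, sigma_within = sigma_within,
       phipt = min(max(phipt, 0), 1))
}

ss_decomposition <- function(D2, grp) {
  N <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1)
      ss_within <- ss_within + sum(D2[idx, idx]) / 2 / length(idx)
  }
  list(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Decomposes the pairwise squared-distance matrix into among- and
#' within-population sums of squares, estimates variance components with the
#' standard unequal-sample-size coefficient, and tests the fixation analogue
#' PhiPT by permuting individuals among populations (population sizes held
#' fixed). The permutation p-value uses `>=` comparison with +1 smoothing in
#' numerator and denominator.
#'
#' @param dataset a [genotype_dataset]
#' @param partition a [population_partition] with at least two populations
#' @param n_perm number of label permutations
#' @param seed integer seed for the permutation stream
#' @param substrate distance substrate, see [squared_distance_matrix]
#' @return object of class `amova_result`: df, SS, variance components,
#'   percentages, `phipt`, `p_value`, `n_permutations`
#' @export
amova <- function(dataset, partition, n_perm = 999, seed = NULL,
                  substrate = "codominant") {
  check_partition(dataset, partition)
  if (length(partition$populations) < 2) stop("AMOVA needs at least 2 populations")
  if (!is.null(seed)) set.seed(seed)
  grp <- unname(partition$pop[dataset$individual_ids])
  D2 <- squared_distance_matrix(dataset, substrate)
  N <- nrow(D2); k <- length(unique(grp))
  sizes <- as.numeric(table(grp))
  ss <- ss_decomposition(D2, grp)
  comp <- phipt_from_ss(ss$among, ss$within, sizes)
  total_var <- comp$sigma_among + comp$sigma_within
  perm_stats <- numeric(n_perm)
  if (n_perm > 0) {
    for (b in seq_len(n_perm)) {
      pg <- sample(grp)
      pss <- ss_decomposition(D2, pg)
      perm_stats[b] <- phipt_from_ss(pss$among, pss$within, sizes)$phipt
    }
  }
  p_value <- (sum(perm_stats >= comp$phipt) + 1) / (n_perm + 1)
  structure(list(
    df_among = k - 1L, df_within = N - k,
    SS_among = ss$among, SS_within = ss$within, SS_total = ss$total,
    sigma_among = comp$sigma_among, sigma_within = comp$sigma_within,
    percent_among = if (total_var > 0) 100 * comp$sigma_among / total_var else 0,
    percent_within = if (total_var > 0) 100 * comp$sigma_within / total_var else 100,
    phipt = comp$phipt, p_value = p_value, n_permutations = n_perm),
    class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (two-level)\n")
  tab <- data.frame(
    source = c("Among populations", "Within populations", "Total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    SS = round(c(x$SS_among, x$SS_within, x$SS_total), 3),
    sigma2 = round(c(x$sigma_among, x$sigma_within,
                     x$sigma_among + x$sigma_within), 4),
    percent = round(c(x$percent_among, x$percent_within, 100), 1))
  print(tab, row.names = FALSE)
  cat(sprintf("PhiPT = %.4f, p = %.4f (%d permutations)\n",
              x$phipt, x$p_value, x$n_permutations))
  invisible(x)
}
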