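#' Nei's (1972) standard genetic distance between two populations
#'
#' `D = -ln(Jxy / sqrt(Jx * Jy))` where the gene identities
#' `Jx = mean_l sum(p_x^2)`, `Jy = mean_l sum(p_y^2)` and
#' `Jxy = mean_l sum(p_x * p_y)` are averaged across loci before taking the
#' ratio. Loci typed in both populations are used.
#'
#' @param freqA,freqB per-locus frequency maps for the two populations: lists
#'   (indexed by the shared locus ids) of named frequency vectors, as stored
#'   in an [allele_frequencies()] table
#' @return nonnegative distance; `Inf` (with a warning) when the populations
#'   share no alleles anywhere
#' @export
nei_distance <- function(freqA, freqB) {
  loci <- intersect(names(freqA), names(freqB))
  loci <- loci[vapply(loci, function(l) length(freqA[[l]]) > 0 && length(freqB[[l]]) > 0, TRUE)]
  if (!length(loci)) stop("no locus typed in both populations")
  jx <- jy <- jxy <- numeric(length(loci))
  for (i in seq_along(loci)) {
    fa <- freqA[[loci[i]]]; fb <- freqB[[loci[i]]]
    jx[i] <- sum(fa^2); jy[i] <- sum(fb^2)
    shared <- intersect(names(fa), names(fb))
    jxy[i] <- sum(fa[shared] * fb[shared])
  }
  Jxy <- mean(jxy)
  if (Jxy == 0) {
    warning("populations share no alleles at any locus; Nei distance is infinite")
    return(Inf)
  }
  -log(Jxy / sqrt(mean(jx) * mean(jy)))
}

#' Pairwise FST between two populations (gene-diversity formulation)
#'
#' Nei GST-style FST on unweighted population means: per locus,
#' `H_S` is the mean of the two populations' gene diversities and `H_T` the
#' gene diversity of the unweighted mean frequency vector; locus values are
#' combined as `(sum(H_T) - sum(H_S)) / sum(H_T)`.
#'
#' @inheritParams nei_distance
#' @return FST in `[0, 1]`; defined 0 (with a warning) when `H_T` is zero at
#'   every locus
#' @export
pairwise_fst <- function(freqA, freqB) {
  loci <- intersect(names(freqA), names(freqB))
  loci <- loci[vapply(loci, function(l) length(freqA[[l]]) > 0 && length(freqB[[l]]) > 0, TRUE)]
  if (!length(loci)) stop("no locus typed in both populations")
  ht <- hs <- numeric(length(loci))
  for (i in seq_along(loci)) {
    fa <- freqA[[loci[i]]]; fb <- freqB[[loci[i]]]
    alleles <- union(names(fa), names(fb))
    pa <- stats::setNames(numeric(length(alleles)), alleles)
    pb <- pa
    pa[names(fa)] <- fa; pb[names(fb)] <- fb
    pbar <- (pa + pb) / 2
    ht[i] <- 1 - sum(pbar^2)
    hs[i] <- ((1 - sum(pa^2)) + (1 - sum(pb^2))) / 2
  }
  if (sum(ht) == 0) {
    warning("total gene diversity is zero at all loci; FST defined 0")
    return(0)
  }
  (sum(ht) - sum(hs)) / sum(ht)
}

#' Island-model gene-flow estimate from FST
#'
#' `Nm = 0.25 * (1 - FST) / FST`, the classic infinite-island equilibrium
#' migrant-number estimator.
#'
#' @param fst fixation index in `(0, 1]`; `fst = 0` yields `Inf` with a
#'   warning
#' @return estimated number of migrants per generation
#' @export
gene_flow <- function(fst) {
  if (fst < 0 || fst > 1) stop("fst must lie in [0, 1]")
  if (fst == 0) {
    warning("FST = 0 implies unbounded gene flow")
    return(Inf)
  }
  0.25 * (1 - fst) / fst
}

#' Combined pairwise population matrix (Nei distance below, FST above)
#'
#' Builds the population-by-population summary matrix: Nei's standard genetic
#' distance in the lower triangle and pairwise FST in the upper triangle,
#' zero diagonal.
#'
#' @param dataset a [genotype_dataset]
#' @param partition a [population_partition]
#' @return object of class `population_pair_matrix`: list with `combined`
#'   (the mixed matrix), `nei` and `fst` (full symmetric matrices),
#'   `populations`
#' @export
population_pair_matrix <- function(dataset, partition) {
  ft <- allele_frequencies(dataset, partition)
  pops <- ft$populations
  k <- length(pops)
  nei <- fst <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- nei_distance(ft$freq[[pops[i]]], ft$freq[[pops[j]]])
    f <- pairwise_fst(ft$freq[[pops[i]]], ft$freq[[pops[j]]])
    nei[i, j] <- nei[j, i] <- d
    fst[i, j] <- fst[j, i] <- f
  }
  combined <- nei
  combined[upper.tri(combined)] <- fst[upper.tri(fst)]
  structure(list(combined = combined, nei = nei, fst = fst, populations = pops),
            class = "population_pair_matrix")
}

#' Summarise a combined pairwise matrix
#' @param x a `population_pair_matrix` (or a plain combined matrix with Nei
#'   distance below and FST above the diagonal)
#' @return list with means/extremes of the two triangles and the implied
#'   overall gene flow `Nm` from the mean FST
#' @export
pair_matrix_summary <- function(x) {
  m <- if (inherits(x, "population_pair_matrix")) x$combined else as.matrix(x)
  fst <- m[upper.tri(m)]
  nei <- t(m)[upper.tri(m)]  # lower triangle, read symmetrically
  list(n_pairs = length(fst),
       mean_fst = mean(fst), min_fst = min(fst), max_fst = max(fst),
       mean_nei = mean(nei), min_nei = min(nei), max_nei = max(nei),
       Nm = gene_flow(mean(fst)))
}

#' Write / read the combined pairwise matrix as CSV
#' @param x a `population_pair_matrix`
#' @param path file path
#' @return `path` invisibly (writer); combined matrix (reader)
#' @export
write_pair_matrix <- function(x, path) {
  m <- format(round(x$combined, 6), trim = TRUE, scientific = FALSE)
  df <- data.frame(Population = rownames(x$combined), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
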