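#' Binary band profile of each individual
#'
#' Expands codominant genotypes to the dominant (gel-band) view: one column
#' per (locus, allele) class, entry 1 if the individual carries at least one
#' copy of that allele, 0 if typed without it, `NA` across the locus's columns
#' if the genotype is missing.
#'
#' @param dataset a [genotype_dataset]
#' @return numeric matrix individuals x band classes, columns named
#'   `"locus:allele"`
#' @export
band_profile <- function(dataset) {
  counts <- allele_count_profile(dataset)
  b <- (counts > 0) + 0
  b
}

#' Per-allele copy-count profile of each individual
#'
#' Like [band_profile] but with allele copy counts (0, 1 or 2) instead of
#' presence/absence.
#'
#' @param dataset a [genotype_dataset]
#' @return numeric matrix individuals x band classes with `NA` at missing loci
#' @export
allele_count_profile <- function(dataset) {
  n <- n_individuals(dataset)
  cols <- list(); names_out <- character(0); locus_of <- integer(0)
  for (l in seq_len(n_loci(dataset))) {
    x1 <- dataset$a1[, l]; x2 <- dataset$a2[, l]
    alleles <- sort(unique(c(x1, x2)))
    alleles <- alleles[!is.na(alleles)]
    for (a in alleles) {
      cols[[length(cols) + 1L]] <- (x1 == a) + (x2 == a)
      names_out <- c(names_out, paste0(dataset$locus_ids[l], ":", a))
      locus_of <- c(locus_of, l)
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(dataset$individual_ids, names_out)
  attr(m, "locus_of") <- locus_of
  m
}

#' Pairwise genetic distances between individuals
#'
#' `dice`: Nei & Li / Dice dissimilarity `1 - 2a / (2a + b + c)` on binary
#' band vectors (`a` shared bands, `b`, `c` private bands), computed over loci
#' typed in both individuals of a pair. `bray_curtis`:
#' `1 - 2 sum(min(x, y)) / sum(x + y)` on allele copy-count vectors
#' (entries 0/1/2), likewise with pairwise-complete loci.
#'
#' @param dataset a [genotype_dataset] with at least 2 individuals
#' @param metric `"dice"` or `"bray_curtis"`
#' @return symmetric numeric matrix in `[0, 1]` with zero diagonal and
#'   attribute `"metric"`; a pair with no mutually typed locus is `NA` with a
#'   warning
#' @export
pairwise_distance <- function(dataset, metric = c("dice", "bray_curtis")) {
  metric <- match.arg(metric)
  if (n_individuals(dataset) < 2) stop("need at least 2 individuals")
  counts <- allele_count_profile(dataset)
  locus_of <- attr(counts, "locus_of")
  obs_loci <- !is.na(dataset$a1)            # individuals x loci
  M <- obs_loci[, locus_of, drop = FALSE] + 0  # observed mask per band class
  C <- counts; C[is.na(C)] <- 0
  if (metric == "dice") {
    X <- (C > 0) + 0
    a <- tcrossprod(X)
    B <- tcrossprod(X, M)       # bands of i within j's observed classes
    denom <- B + t(B)
    d <- 1 - 2 * a / denom
  } else {
    A1 <- (C >= 1) + 0; A2 <- (C >= 2) + 0
    smin <- tcrossprod(A1) + tcrossprod(A2)
    R <- tcrossprod(C, M)
    denom <- R + t(R)
    d <- 1 - 2 * smin / denom
  }
  und <- !is.finite(d)
  diag(und) <- FALSE
  if (any(und)) {
    warning("some pairs share no typed locus; their distance is NA")
    d[und] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(dataset$individual_ids, dataset$individual_ids)
  attr(d, "metric") <- metric
  d
}
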