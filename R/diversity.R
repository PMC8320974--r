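#' Per-locus diversity summary from an allele-frequency vector
#'
#' Computes, from relative allele frequencies `p`: the observed allele count
#' `A` (non-zero frequencies), the effective allele count `Ae = 1 / sum(p^2)`,
#' Shannon's information index `I = -sum(p * log(p))` in nats, and the
#' expected heterozygosity (gene diversity) `He = 1 - sum(p^2)`. `He` is the
#' plain gene diversity by default; set `unbiased = TRUE` for the
#' small-sample-corrected `2n/(2n-1)` variant (requires `n`).
#'
#' @param freqs numeric vector of allele frequencies summing to 1
#' @param unbiased logical; apply the `2n/(2n-1)` correction to He
#' @param n number of typed individuals (needed when `unbiased = TRUE`)
#' @return list with components `A`, `Ae`, `I`, `He`; all `NA` (with the
#'   `undefined` flag set) for an empty vector
#' @export
locus_diversity <- function(freqs, unbiased = FALSE, n = NULL) {
  if (!length(freqs))
    return(list(A = NA_integer_, Ae = NA_real_, I = NA_real_, He = NA_real_,
                undefined = TRUE))
  p <- freqs[freqs > 0]
  s2 <- sum(p^2)
  he <- 1 - s2
  if (unbiased) {
    if (is.null(n)) stop("unbiased He requires the number of typed individuals n")
    he <- he * 2 * n / (2 * n - 1)
  }
  list(A = length(p), Ae = 1 / s2, I = -sum(p * log(p)), He = he,
       undefined = FALSE)
}

#' Polymorphic information content (Botstein et al. formulation)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`. Always `<= He`.
#'
#' @param freqs numeric vector of allele frequencies summing to 1
#' @return PIC value; `NA` for an empty vector
#' @export
pic <- function(freqs) {
  if (!length(freqs)) return(NA_real_)
  p <- freqs[freqs > 0]
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

ho_by_locus <- function(dataset, rows) {
  a1 <- dataset$a1[rows, , drop = FALSE]
  a2 <- dataset$a2[rows, , drop = FALSE]
  typed <- colSums(!is.na(a1))
  het <- colSums(a1 != a2, na.rm = TRUE)
  ifelse(typed > 0, het / typed, NA_real_)
}

#' Whole-collection per-locus diversity table
#'
#' One row per locus with the marker-level summaries `A`, `Ae`, `I`, `Ho`,
#' `He` and `PIC`, computed over all individuals pooled (complete cases per
#' locus).
#'
#' @param dataset a [genotype_dataset]
#' @param unbiased logical; small-sample-corrected He
#' @return data.frame with one row per locus plus attribute-free columns
#'   `locus`, `n_typed`, `A`, `Ae`, `I`, `Ho`, `He`, `PIC`
#' @export
locus_diversity_table <- function(dataset, unbiased = FALSE) {
  ft <- allele_frequencies(dataset, partition = NULL)
  ho <- ho_by_locus(dataset, seq_len(n_individuals(dataset)))
  rows <- lapply(seq_along(ft$loci), function(l) {
    f <- ft$freq[["ALL"]][[l]]
    n <- ft$n_typed["ALL", l]
    d <- locus_diversity(f, unbiased = unbiased, n = n)
    data.frame(locus = ft$loci[l], n_typed = n, A = d$A, Ae = d$Ae, I = d$I,
               Ho = ho[l], He = d$He, PIC = pic(f))
  })
  do.call(rbind, rows)
}

private_alleles <- function(freq_table) {
  pops <- freq_table$populations
  pa <- stats::setNames(integer(length(pops)), pops)
  for (l in freq_table$loci) {
    present <- lapply(pops, function(p) names(freq_table$freq[[p]][[l]]))
    all_alleles <- unique(unlist(present))
    for (a in all_alleles) {
      holders <- which(vapply(present, function(x) a %in% x, TRUE))
      if (length(holders) == 1L) pa[holders] <- pa[holders] + 1L
    }
  }
  pa
}

#' Per-population diversity table
#'
#' For every population and locus (complete cases within that population):
#' `Ho` = fraction of typed individuals that are heterozygous; `A`, `Ae`, `I`,
#' `He` from the population's allele frequencies; `F = (He - Ho)/He` (0 at
#' monomorphic loci). Population rows are unweighted means across loci with at
#' least one typed individual; `PA` counts alleles private to the population
#' (summed over loci) and `N` is the number of individuals. A final
#' `Mean` row holds column means (total for `PA`).
#'
#' @param dataset a [genotype_dataset]
#' @param partition a [population_partition]
#' @param unbiased logical; small-sample-corrected He
#' @return data.frame with columns `pop`, `N`, `A`, `Ae`, `PA`, `I`, `Ho`,
#'   `He`, `F`; last row is the Mean/Total summary
#' @export
population_diversity <- function(dataset, partition, unbiased = FALSE) {
  check_partition(dataset, partition)
  ft <- allele_frequencies(dataset, partition)
  pa <- private_alleles(ft)
  grp <- partition$pop[dataset$individual_ids]
  out <- list()
  for (p in ft$populations) {
    rows <- which(grp == p)
    if (all(ft$n_typed[p, ] == 0L)) {
      warning("population ", p, " has no typed individuals at any locus; excluded")
      next
    }
    ho <- ho_by_locus(dataset, rows)
    per_locus <- lapply(seq_along(ft$loci), function(l) {
      f <- ft$freq[[p]][[l]]
      if (!length(f)) return(NULL)
      d <- locus_diversity(f, unbiased = unbiased, n = ft$n_typed[p, l])
      hol <- unname(ho[l])
      fx <- if (d$He > 0) (d$He - hol) / d$He else 0
      c(A = d$A, Ae = d$Ae, I = d$I, Ho = hol, He = d$He, F = fx)
    })
    m <- do.call(rbind, per_locus)
    fvals <- m[, "F"]
    fmean <- if (all(m[, "He"] == 0)) NA_real_ else mean(fvals)
    out[[p]] <- data.frame(pop = p, N = length(rows),
                           A = mean(m[, "A"]), Ae = mean(m[, "Ae"]),
                           PA = unname(pa[p]), I = mean(m[, "I"]),
                           Ho = mean(m[, "Ho"]), He = mean(m[, "He"]),
                           F = fmean)
  }
  tab <- do.call(rbind, out)
  mean_row <- data.frame(pop = "Mean", N = sum(tab$N), A = mean(tab$A),
                         Ae = mean(tab$Ae), PA = sum(tab$PA), I = mean(tab$I),
                         Ho = mean(tab$Ho), He = mean(tab$He),
                         F = mean(tab$F))
  rownames(tab) <- NULL
  rbind(tab, mean_row)
}
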