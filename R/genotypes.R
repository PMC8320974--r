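#' Construct a codominant SSR genotype dataset
#'
#' A `genotype_dataset` stores diploid, codominant microsatellite calls as two
#' integer allele matrices (individuals x loci). Allele labels are opaque
#' positive integers (typically fragment sizes); a missing genotype is `NA` in
#' both matrices. Allele pairs are unordered: the constructor canonicalises
#' each call so that `a1 <= a2`, which makes datasets comparable by equality.
#'
#' @param a1,a2 integer matrices of identical dimensions holding the two
#'   allele labels of each call; `NA` in both marks a missing genotype.
#' @param individual_ids character vector of unique individual labels
#'   (defaults to rownames of `a1`).
#' @param locus_ids character vector of unique locus labels (defaults to
#'   colnames of `a1`).
#' @return an object of class `genotype_dataset` with elements `a1`, `a2`,
#'   `individual_ids`, `locus_ids`.
#' @export
genotype_dataset <- function(a1, a2, individual_ids = rownames(a1),
                             locus_ids = colnames(a1)) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == dim(a2))) stop("allele matrices must have equal dimensions")
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(a1)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(a1)))
  individual_ids <- as.character(individual_ids)
  locus_ids <- as.character(locus_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual id: ",
    paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(locus_ids)) stop("duplicate locus id")
  if (length(individual_ids) != nrow(a1)) stop("individual_ids length mismatch")
  if (length(locus_ids) != ncol(a1)) stop("locus_ids length mismatch")
  if (any(xor(is.na(a1), is.na(a2)))) stop("half-missing call: both alleles must be NA or neither")
  if (any(a1 < 1, na.rm = TRUE) || any(a2 < 1, na.rm = TRUE))
    stop("allele labels must be positive integers (0 is reserved for missing in files)")
  # canonical order: smaller allele first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  dimnames(a1) <- dimnames(a2) <- list(individual_ids, locus_ids)
  structure(list(a1 = a1, a2 = a2, individual_ids = individual_ids,
                 locus_ids = locus_ids),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", n_individuals(x), " individuals x ",
      n_loci(x), " loci; ", sum(is.na(x$a1)), " missing calls\n", sep = "")
  invisible(x)
}

#' Number of individuals / loci in a dataset
#' @param x a `genotype_dataset`
#' @return integer count
#' @export
n_individuals <- function(x) nrow(x$a1)

#' @rdname n_individuals
#' @export
n_loci <- function(x) ncol(x$a1)

#' Subset a genotype dataset by individuals
#' @param x a `genotype_dataset`
#' @param ids character or integer index of individuals to keep
#' @return a `genotype_dataset` restricted to `ids`
#' @export
subset_individuals <- function(x, ids) {
  genotype_dataset(x$a1[ids, , drop = FALSE], x$a2[ids, , drop = FALSE])
}

#' Construct a population partition
#'
#' Assigns every individual to exactly one named population (here, a full-sib
#' family from a controlled cross), optionally with the mating design that
#' produced each family.
#'
#' @param pop named character vector: names are individual ids, values are
#'   population labels.
#' @param design optional named character vector (one entry per population)
#'   with values in `c("selfing", "sib_mating", "cross_mating")`.
#' @return an object of class `population_partition` with elements `pop`
#'   (named character), `populations` (unique labels in first-appearance
#'   order), `sizes` (named integer) and `design`.
#' @export
population_partition <- function(pop, design = NULL) {
  if (is.null(names(pop))) stop("pop must be a named vector (individual -> population)")
  pop <- vapply(pop, as.character, "")
  pops <- unique(unname(pop))
  sizes <- vapply(pops, function(p) sum(pop == p), 0L)
  if (!is.null(design)) {
    bad <- setdiff(design, c("selfing", "sib_mating", "cross_mating"))
    if (length(bad)) stop("unknown mating design: ", paste(bad, collapse = ", "))
    design <- design[pops]
    names(design) <- pops
  }
  structure(list(pop = pop, populations = pops, sizes = sizes, design = design),
            class = "population_partition")
}

#' @export
print.population_partition <- function(x, ...) {
  cat("<population_partition> ", length(x$pop), " individuals in ",
      length(x$populations), " populations\n", sep = "")
  print(x$sizes)
  invisible(x)
}

check_partition <- function(dataset, partition) {
  if (!setequal(names(partition$pop), dataset$individual_ids))
    stop("partition does not cover exactly the dataset's individuals")
  if (sum(partition$sizes) != n_individuals(dataset))
    stop("population sizes do not sum to the number of individuals")
  invisible(TRUE)
}

#' Per-population allele frequencies
#'
#' Computes relative allele frequencies per (population, locus) using
#' locus-wise complete cases: each non-missing genotype contributes two allele
#' copies, and the denominator at a cell is `2 * n_typed`. No imputation is
#' performed. Cells with no typed individuals are flagged empty (zero-length
#' frequency vector, `n_typed = 0`).
#'
#' @param dataset a `genotype_dataset`
#' @param partition a `population_partition`, or `NULL` to pool every
#'   individual into one population named `"ALL"`.
#' @return an object of class `allele_freq_table`: list with `freq` (list
#'   indexed by population then locus, each a named numeric vector summing to
#'   1), `n_typed` (populations x loci integer matrix), `populations`, `loci`.
#' @export
allele_frequencies <- function(dataset, partition = NULL) {
  if (is.null(partition)) {
    pop <- rep("ALL", n_individuals(dataset))
    names(pop) <- dataset$individual_ids
    partition <- population_partition(pop)
  }
  check_partition(dataset, partition)
  pops <- partition$populations
  loci <- dataset$locus_ids
  n_typed <- matrix(0L, length(pops), length(loci), dimnames = list(pops, loci))
  freq <- vector("list", length(pops))
  names(freq) <- pops
  grp <- partition$pop[dataset$individual_ids]
  for (p in pops) {
    rows <- which(grp == p)
    fl <- vector("list", length(loci))
    names(fl) <- loci
    for (l in seq_along(loci)) {
      x <- c(dataset$a1[rows, l], dataset$a2[rows, l])
      x <- x[!is.na(x)]
      n_typed[p, l] <- length(x) %/% 2L
      if (length(x)) {
        tab <- table(x)
        f <- as.numeric(tab) / length(x)
        names(f) <- names(tab)
        fl[[l]] <- f
      } else {
        fl[[l]] <- numeric(0)
      }
    }
    freq[[p]] <- fl
  }
  structure(list(freq = freq, n_typed = n_typed, populations = pops, loci = loci),
            class = "allele_freq_table")
}

#' Flatten an allele-frequency table to a data frame
#' @param x an `allele_freq_table`
#' @param ... unused
#' @return data.frame with columns pop, locus, allele, frequency, n_typed
#' @export
as.data.frame.allele_freq_table <- function(x, ...) {
  rows <- list()
  for (p in x$populations) for (l in x$loci) {
    f <- x$freq[[p]][[l]]
    if (!length(f)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pop = p, locus = l, allele = as.integer(names(f)),
      frequency = unname(f), n_typed = x$n_typed[p, l])
  }
  do.call(rbind, rows)
}

#' Distinct (locus, allele) classes present in a dataset
#'
#' @param dataset a `genotype_dataset`
#' @param individuals optional subset of individual ids/indices
#' @return character vector of `"locus:allele"` keys
#' @export
allele_classes <- function(dataset, individuals = NULL) {
  a1 <- dataset$a1; a2 <- dataset$a2
  if (!is.null(individuals)) {
    a1 <- a1[individuals, , drop = FALSE]; a2 <- a2[individuals, , drop = FALSE]
  }
  keys <- character(0)
  for (l in seq_len(ncol(a1))) {
    al <- unique(c(a1[, l], a2[, l]))
    al <- al[!is.na(al)]
    if (length(al))
      keys <- c(keys, paste0(colnames(a1)[l], ":", sort(al)))
  }
  keys
}
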