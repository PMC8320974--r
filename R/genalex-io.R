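#' Read a GenAlEx-dialect codominant genotype CSV
#'
#' Parses the codominant CSV layout used by GenAlEx: row 1 holds
#' `n_loci, n_individuals, n_pops, size_1, ..., size_k`; row 2 holds a title
#' followed by two blank cells and the population names; row 3 holds
#' `Ind, Pop` and each locus name above the first of its two allele columns;
#' every data row is `id, pop, a, b, a, b, ...` with two integer allele
#' columns per locus and `0` coding a missing allele.
#'
#' @param path path to the CSV file
#' @return list with elements `dataset` (a [genotype_dataset]) and
#'   `partition` (a [population_partition])
#' @export
read_genalex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 4) stop("GenAlEx file too short: need 3 header rows plus data")
  cells <- strsplit(lines, ",", fixed = TRUE)
  h1 <- cells[[1]]
  n_loci <- as.integer(h1[1]); n_ind <- as.integer(h1[2]); n_pop <- as.integer(h1[3])
  if (anyNA(c(n_loci, n_ind, n_pop)))
    stop("GenAlEx header row 1 must start with n_loci, n_individuals, n_pops")
  h3 <- cells[[3]]
  locus_cols <- seq(3L, by = 2L, length.out = n_loci)
  need <- 2L + 2L * n_loci
  h3 <- c(h3, rep("", max(0L, need - length(h3))))
  second_cols <- trimws(h3[locus_cols + 1L])
  if (any(second_cols != ""))
    stop("odd number of allele columns: locus name found where a second allele column was expected")
  locus_ids <- trimws(h3[locus_cols])
  if (anyNA(locus_ids) || any(locus_ids == ""))
    stop("locus names missing in header row 3")
  data_rows <- cells[-(1:3)]
  if (length(data_rows) != n_ind)
    stop(sprintf("header declares %d individuals but file has %d data rows (first mismatch at file row %d)",
                 n_ind, length(data_rows), length(data_rows) + 4L))
  ids <- character(n_ind); pop <- character(n_ind)
  a1 <- matrix(NA_integer_, n_ind, n_loci)
  a2 <- matrix(NA_integer_, n_ind, n_loci)
  for (i in seq_len(n_ind)) {
    r <- data_rows[[i]]
    if (length(r) < need)
      stop(sprintf("data row %d has %d columns; expected %d (2 allele columns per locus)",
                   i, length(r), need))
    ids[i] <- trimws(r[1]); pop[i] <- trimws(r[2])
    v <- suppressWarnings(as.integer(r[3:need]))
    if (anyNA(v)) stop(sprintf("non-integer allele value in data row %d", i))
    a1[i, ] <- v[seq(1L, 2L * n_loci, by = 2L)]
    a2[i, ] <- v[seq(2L, 2L * n_loci, by = 2L)]
  }
  half <- xor(a1 == 0L, a2 == 0L)
  if (any(half)) stop("half-missing call (one allele 0, the other not)")
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  names(pop) <- ids
  ds <- genotype_dataset(a1, a2, individual_ids = ids, locus_ids = locus_ids)
  list(dataset = ds, partition = population_partition(pop))
}

#' Write a genotype dataset as GenAlEx-dialect CSV
#'
#' Inverse of [read_genalex]; missing calls are written as `0,0` and allele
#' pairs in canonical (ascending) order, so read-write round trips are exact.
#'
#' @param dataset a [genotype_dataset]
#' @param partition a [population_partition]
#' @param path output path
#' @param title free-text title cell for header row 2
#' @return `path`, invisibly
#' @export
write_genalex <- function(dataset, partition, path, title = "ssrcore export") {
  check_partition(dataset, partition)
  pops <- partition$populations
  h1 <- c(n_loci(dataset), n_individuals(dataset), length(pops),
          unname(partition$sizes[pops]))
  h2 <- c(title, "", "", pops)
  h3 <- c("Ind", "Pop", as.vector(rbind(dataset$locus_ids, "")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(h1, collapse = ","), con)
  writeLines(paste(h2, collapse = ","), con)
  writeLines(paste(h3, collapse = ","), con)
  a1 <- dataset$a1; a2 <- dataset$a2
  a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
  for (i in seq_len(n_individuals(dataset))) {
    id <- dataset$individual_ids[i]
    row <- c(id, partition$pop[[id]], as.vector(rbind(a1[i, ], a2[i, ])))
    writeLines(paste(row, collapse = ","), con)
  }
  invisible(path)
}

#' Write a dataset in STRUCTURE two-row-per-individual format
#'
#' Each individual occupies two whitespace-separated rows (one allele copy per
#' row): individual label, 1-based population index, then one allele label per
#' locus. Missing alleles are coded `-9`.
#'
#' @inheritParams write_genalex
#' @return `path`, invisibly
#' @export
write_structure <- function(dataset, partition, path) {
  check_partition(dataset, partition)
  pop_index <- match(partition$pop[dataset$individual_ids], partition$populations)
  a1 <- dataset$a1; a2 <- dataset$a2
  a1[is.na(a1)] <- -9L; a2[is.na(a2)] <- -9L
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_individuals(dataset))) {
    pre <- c(dataset$individual_ids[i], pop_index[i])
    writeLines(paste(c(pre, a1[i, ]), collapse = " "), con)
    writeLines(paste(c(pre, a2[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read a STRUCTURE two-row-per-individual file
#'
#' Counterpart of [write_structure]; locus names are synthesised as
#' `L1..Lp` since the format carries none.
#'
#' @param path input path
#' @return list with `dataset` and `partition`
#' @export
read_structure <- function(path) {
  rows <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  if (length(rows) %% 2L != 0L) stop("STRUCTURE file must have two rows per individual")
  n <- length(rows) %/% 2L
  p <- length(rows[[1]]) - 2L
  ids <- character(n); pop <- character(n)
  a1 <- matrix(NA_integer_, n, p); a2 <- matrix(NA_integer_, n, p)
  for (i in seq_len(n)) {
    r1 <- rows[[2L * i - 1L]]; r2 <- rows[[2L * i]]
    if (r1[1] != r2[1]) stop("row pair with mismatched individual labels")
    ids[i] <- r1[1]; pop[i] <- r1[2]
    a1[i, ] <- as.integer(r1[-(1:2)]); a2[i, ] <- as.integer(r2[-(1:2)])
  }
  a1[a1 == -9L] <- NA_integer_; a2[a2 == -9L] <- NA_integer_
  names(pop) <- ids
  list(dataset = genotype_dataset(a1, a2, ids, paste0("L", seq_len(p))),
       partition = population_partition(pop))
}
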