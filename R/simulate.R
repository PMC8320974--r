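#' Default family table for the simulated germplasm
#'
#' Twelve full-sib families mirroring a Nigerian-based oil-palm field
#' genebank: family sizes 20, 8, 19, 12, 20, 8, 13, 18, 5, 12, 31 and 20
#' palms (186 in total), produced by selfing, sib-mating or cross-mating.
#' Families are assigned to 8 founder groups (several families share a
#' group), so that the collection carries 8 underlying genetic clusters.
#'
#' @return data.frame with columns `name`, `design`, `size`, `founder_group`
#' @export
default_families <- function() {
  data.frame(
    name = c("596", "597", "598", "599", "600", "601",
             "602", "603", "604", "605", "606", "607"),
    design = c("sib_mating", "sib_mating", "sib_mating", "cross_mating",
               "cross_mating", "selfing", "selfing", "sib_mating",
               "selfing", "selfing", "selfing", "selfing"),
    size = c(20L, 8L, 19L, 12L, 20L, 8L, 13L, 18L, 5L, 12L, 31L, 20L),
    founder_group = c(1L, 2L, 3L, 4L, 5L, 3L, 4L, 3L, 6L, 6L, 7L, 8L),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic germplasm generator
#'
#' @param n_loci number of unlinked SSR loci
#' @param allele_range integer range (min, max) of the per-locus allele count;
#'   each locus draws its count uniformly from this range
#' @param n_founder_groups number of divergent founder groups (base-population
#'   clusters) from which family founders are drawn
#' @param founder_divergence symmetric Dirichlet concentration used to draw
#'   each group's allele-frequency profile; lower values give spikier,
#'   more differentiated groups, very large values approach uniform (and
#'   hence undifferentiated) profiles
#' @param families data.frame as in [default_families()]
#' @param missing_rate i.i.d. probability that a call is missing
#' @param seed integer seed; the same seed reproduces the dataset exactly
#' @return a `sim_config` list
#' @export
sim_config <- function(n_loci = 107L, allele_range = c(3L, 16L),
                       n_founder_groups = 8L, founder_divergence = 1,
                       families = default_families(), missing_rate = 0.01,
                       seed = 1L) {
  families <- as.data.frame(families)
  stopifnot(all(c("name", "design", "size", "founder_group") %in% names(families)))
  if (any(families$size < 1L)) stop("family sizes must be >= 1")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (allele_range[1] < 2L) stop("alleles_per_locus must be >= 2")
  if (any(families$founder_group > n_founder_groups))
    stop("founder_group index exceeds n_founder_groups")
  bad <- setdiff(families$design, c("selfing", "sib_mating", "cross_mating"))
  if (length(bad)) stop("unknown mating design: ", paste(bad, collapse = ", "))
  structure(list(n_loci = as.integer(n_loci),
                 allele_range = as.integer(allele_range),
                 n_founder_groups = as.integer(n_founder_groups),
                 founder_divergence = founder_divergence,
                 families = families,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation config from a YAML or JSON file
#' @param path file path; `.json` is parsed with jsonlite, anything else with
#'   yaml (both encode the [sim_config()] fields as plain key-value pairs,
#'   with `families` a list of records)
#' @return a `sim_config`
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read non-JSON config files")
    yaml::read_yaml(path)
  }
  fam <- if (is.null(raw$families)) default_families() else
    do.call(rbind, lapply(raw$families, as.data.frame))
  sim_config(n_loci = raw$n_loci %||% 107L,
             allele_range = unlist(raw$allele_range %||% c(3L, 16L)),
             n_founder_groups = raw$n_founder_groups %||% 8L,
             founder_divergence = raw$founder_divergence %||% 0.3,
             families = fam,
             missing_rate = raw$missing_rate %||% 0.01,
             seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, k)  # numerical underflow guard at tiny alpha
  g / sum(g)
}

#' Draw founder-group allele-frequency profiles
#'
#' For each locus, an allele set of size drawn uniformly from
#' `allele_range` is created (labels are even integers from 100 upward,
#' imitating fragment sizes); each founder group then receives an independent
#' symmetric-Dirichlet frequency vector over that set, with concentration
#' `founder_divergence`.
#'
#' @param config a [sim_config()]
#' @return list with `loci` (locus ids), `alleles` (list of allele label
#'   vectors per locus), `freqs` (list per group of lists per locus of named
#'   frequency vectors)
#' @export
simulate_founder_groups <- function(config) {
  set.seed(config$seed)
  loci <- sprintf("L%03d", seq_len(config$n_loci))
  n_all <- sample(config$allele_range[1]:config$allele_range[2],
                  config$n_loci, replace = TRUE)
  alleles <- lapply(n_all, function(k) as.integer(100 + 2 * (0:(k - 1))))
  names(alleles) <- loci
  freqs <- lapply(seq_len(config$n_founder_groups), function(g) {
    fl <- lapply(alleles, function(al) {
      f <- rdirichlet1(length(al), config$founder_divergence)
      names(f) <- al
      f
    })
    fl
  })
  list(loci = loci, alleles = alleles, freqs = freqs)
}

draw_founder <- function(group_freqs) {
  vapply(group_freqs, function(f) {
    al <- as.integer(names(f))
    sample(al, 2L, replace = TRUE, prob = f)
  }, integer(2))  # 2 x n_loci
}

mendel_offspring <- function(p1, p2, n) {
  L <- ncol(p1)
  lapply(seq_len(n), function(i) {
    pick1 <- p1[cbind(sample.int(2L, L, replace = TRUE), seq_len(L))]
    pick2 <- p2[cbind(sample.int(2L, L, replace = TRUE), seq_len(L))]
    rbind(pick1, pick2)
  })
}

#' Simulate one full-sib family under a mating design
#'
#' Offspring alleles are drawn by independent Mendelian segregation: at every
#' locus each offspring receives one uniformly chosen allele copy from each
#' parent. `selfing` takes a single parent crossed with itself. For
#' `sib_mating` the supplied pair is treated as the grandparental cross: two
#' full-sib intermediates are generated first and then crossed, so inbreeding
#' arises mechanistically rather than by formula. `cross_mating` crosses the
#' two supplied parents directly.
#'
#' @param parents list of one (`selfing`) or two diploid multilocus genotypes,
#'   each a 2 x n_loci integer matrix of allele labels
#' @param design one of `"selfing"`, `"sib_mating"`, `"cross_mating"`
#' @param n number of offspring
#' @param seed optional integer seed
#' @return list of `n` offspring genotypes (2 x n_loci matrices), with the
#'   immediate parents attached as attribute `"parents"`
#' @export
simulate_family <- function(parents, design, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- match.arg(design, c("selfing", "sib_mating", "cross_mating"))
  need <- if (design == "selfing") 1L else 2L
  if (length(parents) != need)
    stop(sprintf("%s requires %d parent(s), got %d", design, need, length(parents)))
  if (design == "selfing") {
    p1 <- p2 <- parents[[1]]
  } else if (design == "cross_mating") {
    p1 <- parents[[1]]; p2 <- parents[[2]]
  } else {
    sibs <- mendel_offspring(parents[[1]], parents[[2]], 2L)
    p1 <- sibs[[1]]; p2 <- sibs[[2]]
  }
  off <- mendel_offspring(p1, p2, n)
  attr(off, "parents") <- list(p1, p2)
  off
}

#' Simulate a full synthetic germplasm collection
#'
#' Assembles one family per row of `config$families`: founders are drawn in
#' Hardy-Weinberg proportions from their family's founder-group frequency
#' profile, offspring follow the family's mating design, and missing calls are
#' injected i.i.d. at `missing_rate`. A truth record (founder frequencies,
#' founder genotypes, pedigree) is returned for recovery tests.
#'
#' @param config a [sim_config()]
#' @return list with `dataset` (a [genotype_dataset]), `partition`
#'   (a [population_partition]) and `truth` (list: `founder_freqs`,
#'   `alleles`, `founders`, `pedigree`)
#' @export
simulate_germplasm <- function(config) {
  groups <- simulate_founder_groups(config)  # seeds the RNG stream
  fam <- config$families
  ids <- character(0); pop <- character(0)
  a1 <- NULL; a2 <- NULL
  founders <- list(); pedigree <- list()
  for (i in seq_len(nrow(fam))) {
    gf <- groups$freqs[[fam$founder_group[i]]]
    n_parents <- if (fam$design[i] == "selfing") 1L else 2L
    pars <- lapply(seq_len(n_parents), function(j) draw_founder(gf))
    off <- simulate_family(pars, fam$design[i], fam$size[i])
    fam_ids <- sprintf("%s_%02d", fam$name[i], seq_len(fam$size[i]))
    ids <- c(ids, fam_ids)
    pop <- c(pop, rep(fam$name[i], fam$size[i]))
    a1 <- rbind(a1, t(vapply(off, function(g) g[1, ], integer(config$n_loci))))
    a2 <- rbind(a2, t(vapply(off, function(g) g[2, ], integer(config$n_loci))))
    founders[[fam$name[i]]] <- pars
    pedigree[[fam$name[i]]] <- list(design = fam$design[i],
                                    founder_group = fam$founder_group[i],
                                    n_founders = n_parents)
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(a1)) < config$missing_rate,
                   nrow(a1), ncol(a1))
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  names(pop) <- ids
  design <- fam$design; names(design) <- fam$name
  dataset <- genotype_dataset(a1, a2, individual_ids = ids,
                              locus_ids = groups$loci)
  list(dataset = dataset,
       partition = population_partition(pop, design = design),
       truth = list(founder_freqs = groups$freqs, alleles = groups$alleles,
                    founders = founders, pedigree = pedigree))
}
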