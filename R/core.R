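incidence_matrix <- function(dataset) {
  counts <- allele_count_profile(dataset)
  counts[is.na(counts)] <- 0
  (counts > 0) + 0
}

#' Allelic coverage of a subset of accessions
#'
#' `CV` is the fraction of the whole collection's distinct (locus, allele)
#' classes that are carried by at least one member of `subset`.
#'
#' @param dataset a [genotype_dataset]
#' @param subset non-empty vector of individual ids (or indices)
#' @return coverage in `[0, 1]`
#' @export
coverage <- function(dataset, subset) {
  if (!length(subset)) stop("subset must be non-empty")
  X <- incidence_matrix(dataset)
  covered <- colSums(X[subset, , drop = FALSE]) > 0
  sum(covered) / ncol(X)
}

new_core_set <- function(ids, dataset, method, seed, trace) {
  structure(list(ids = ids, method = method, seed = seed,
                 sampling_intensity = length(ids) / n_individuals(dataset),
                 CV = coverage(dataset, ids), objective_trace = trace),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> %s: %d entries (%.1f%% intensity), CV = %.3f\n",
              x$method, length(x$ids), 100 * x$sampling_intensity, x$CV))
  invisible(x)
}

#' Greedy maximization-strategy core selection
#'
#' Greedy set cover over (locus, allele) classes: the accession covering the
#' most still-uncovered alleles is added repeatedly until every allele of the
#' whole collection is covered (ties broken toward higher total band
#' richness, then label order). A backward redundancy pass then removes, in
#' reverse insertion order, any entry whose removal leaves coverage complete.
#' The returned core always has `CV = 1`.
#'
#' @param dataset a [genotype_dataset]
#' @param seed unused by the (deterministic) algorithm, recorded for the run
#'   manifest
#' @return a `core_set`
#' @export
mstrategy_core <- function(dataset, seed = NULL) {
  X <- incidence_matrix(dataset)
  ids <- dataset$individual_ids
  richness <- rowSums(X)
  uncovered <- rep(TRUE, ncol(X))
  chosen <- character(0)
  trace <- numeric(0)
  candidates <- seq_along(ids)
  while (any(uncovered)) {
    gain <- X[, uncovered, drop = FALSE] %*% rep(1, sum(uncovered))
    gain[match(chosen, ids)] <- -1
    best_gain <- max(gain)
    if (best_gain <= 0) break  # unreachable alleles (cannot happen: every allele is carried)
    tied <- which(gain == best_gain)
    tied <- tied[order(-richness[tied], ids[tied])]
    pick <- tied[1]
    chosen <- c(chosen, ids[pick])
    uncovered <- uncovered & (X[pick, ] == 0)
    trace <- c(trace, 1 - sum(uncovered) / ncol(X))
  }
  # backward redundancy pass, reverse insertion order
  for (id in rev(chosen)) {
    if (length(chosen) == 1L) break
    rest <- setdiff(chosen, id)
    if (all(colSums(X[rest, , drop = FALSE]) > 0)) chosen <- rest
  }
  new_core_set(chosen, dataset, "M-strategy (greedy)", seed, trace)
}

#' Local-search core selection at fixed sampling intensity
#'
#' Random-descent over fixed-size subsets: starting from a random subset of
#' size `ceiling(intensity * N)`, single entry/non-entry swaps are proposed
#' uniformly at random and accepted iff allelic coverage strictly increases,
#' with coverage ties broken toward a higher mean entry-to-entry distance.
#' The search stops after `max_stall` consecutive non-improving proposals.
#'
#' @param dataset a [genotype_dataset]
#' @param intensity target core fraction in `(0, 1)`
#' @param seed integer seed (initial subset and proposal stream)
#' @param max_stall stop after this many consecutive rejected proposals
#' @param metric distance used for the tie-break diversity pressure
#' @return a `core_set`
#' @export
localsearch_core <- function(dataset, intensity, seed = 1, max_stall = 2000,
                             metric = "bray_curtis") {
  if (intensity <= 0 || intensity >= 1) stop("intensity must lie in (0, 1)")
  n <- n_individuals(dataset)
  m <- ceiling(intensity * n)
  if (m < 1) stop("intensity yields an empty core")
  set.seed(seed)
  X <- incidence_matrix(dataset)
  d <- suppressWarnings(pairwise_distance(dataset, metric))
  d[is.na(d)] <- mean(d, na.rm = TRUE)
  ids <- dataset$individual_ids
  sel <- sort(sample.int(n, m))
  counts <- colSums(X[sel, , drop = FALSE])
  cv <- function(cnt) sum(cnt > 0) / length(cnt)
  sumd <- if (m > 1) sum(d[sel, sel]) / 2 else 0
  cur_cv <- cv(counts)
  trace <- cur_cv
  stall <- 0L
  while (stall < max_stall && cur_cv < 1) {
    out <- sel[sample.int(length(sel), 1)]
    pool <- setdiff(seq_len(n), sel)
    inn <- pool[sample.int(length(pool), 1)]
    new_counts <- counts - X[out, ] + X[inn, ]
    new_cv <- cv(new_counts)
    keep <- setdiff(sel, out)
    new_sumd <- sumd - sum(d[out, keep]) + sum(d[inn, keep])
    accept <- new_cv > cur_cv || (new_cv == cur_cv && new_sumd > sumd)
    if (accept) {
      improved <- new_cv > cur_cv
      sel <- sort(c(keep, inn))
      counts <- new_counts
      sumd <- new_sumd
      cur_cv <- new_cv
      trace <- c(trace, cur_cv)
      stall <- if (improved) 0L else stall + 1L
    } else {
      stall <- stall + 1L
    }
  }
  new_core_set(ids[sel], dataset, "local search (CV)", seed, trace)
}

#' Smallest sampling intensity reaching full allelic coverage
#'
#' Sweeps [localsearch_core] over a grid of sampling intensities and reports
#' the smallest intensity whose core attains `CV = 1`.
#'
#' @param dataset a [genotype_dataset]
#' @param grid intensities to test (default 20-35% in 1% steps)
#' @param seed integer seed
#' @param ... passed to [localsearch_core]
#' @return list with `table` (intensity, core size, CV) and `min_full`
#'   (smallest intensity with CV = 1, `NA` if none)
#' @export
core_intensity_scan <- function(dataset, grid = seq(0.20, 0.35, by = 0.01),
                                seed = 1, ...) {
  rows <- lapply(seq_along(grid), function(i) {
    cs <- localsearch_core(dataset, grid[i], seed = seed + i, ...)
    data.frame(intensity = grid[i], size = length(cs$ids), CV = cs$CV)
  })
  tab <- do.call(rbind, rows)
  full <- tab$intensity[tab$CV >= 1]
  list(table = tab, min_full = if (length(full)) min(full) else NA_real_)
}

#' Distance-based evaluation of a core collection
#'
#' Computes the classic representativeness/diversity criteria on the chosen
#' metric: `A_NE`, the mean distance from every accession in the collection
#' to its nearest core entry (entries contribute 0); `E_E`, the mean pairwise
#' distance among entries; and `E_NE_min` / `E_NE_mean`, the minimum and mean
#' of each entry's distance to its nearest other entry.
#'
#' @param dataset a [genotype_dataset]
#' @param core a `core_set` or a vector of entry ids
#' @param metric `"bray_curtis"` (default) or `"dice"`
#' @return object of class `core_evaluation`: `A_NE`, `E_E`, `E_NE_min`,
#'   `E_NE_mean`, `metric`, `n_entries`
#' @export
evaluate_core <- function(dataset, core, metric = c("bray_curtis", "dice")) {
  metric <- match.arg(metric)
  ids <- if (inherits(core, "core_set")) core$ids else as.character(core)
  d <- pairwise_distance(dataset, metric)
  all_ids <- dataset$individual_ids
  stopifnot(all(ids %in% all_ids))
  dn <- d[, ids, drop = FALSE]
  nearest <- apply(dn, 1, min)          # 0 for entries themselves
  a_ne <- mean(nearest)
  if (length(ids) < 2) {
    warning("core of size 1: entry-to-entry criteria undefined")
    ee <- ene_min <- ene_mean <- NA_real_
  } else {
    de <- d[ids, ids]
    ee <- mean(de[upper.tri(de)])
    nn <- apply(de + diag(Inf, length(ids)), 1, min)
    ene_min <- min(nn); ene_mean <- mean(nn)
  }
  structure(list(A_NE = a_ne, E_E = ee, E_NE_min = ene_min,
                 E_NE_mean = ene_mean, metric = metric,
                 n_entries = length(ids)),
            class = "core_evaluation")
}

#' @export
print.core_evaluation <- function(x, ...) {
  cat(sprintf("<core_evaluation> (%s) n = %d: A-NE %.3f, E-E %.3f, E-NE min %.3f mean %.3f\n",
              x$metric, x$n_entries, x$A_NE, x$E_E, x$E_NE_min, x$E_NE_mean))
  invisible(x)
}

per_locus_indices <- function(dataset) {
  tab <- locus_diversity_table(dataset)
  tab$F <- ifelse(tab$He > 0, (tab$He - tab$Ho) / tab$He, 0)
  tab
}

#' Statistical validation of a core collection against the whole set
#'
#' Four complementary checks: (i) Welch (or paired) t-tests comparing
#' per-locus diversity indices (A, Ae, I, Ho, He, F) between the core and the
#' whole collection; (ii) per-locus chi-square tests of core allele counts
#' against counts expected from whole-collection frequencies scaled to the
#' core's typed sample size, pooling categories with expected count below 1;
#' (iii) the R-squared of core versus whole allele frequencies over all
#' allele classes; (iv) a UPGMA tree of the core entries for structural
#' comparison.
#'
#' @param dataset a [genotype_dataset]
#' @param partition a [population_partition] (reported per-population core
#'   membership)
#' @param core a `core_set` or vector of entry ids
#' @param metric distance metric for the structural tree
#' @param paired use a paired per-locus t-test instead of Welch two-sample
#' @return object of class `core_validation`: `t_tests` (index, t, p),
#'   `chisq` (locus, statistic, df, p), `n_chisq_significant` (at 0.05),
#'   `r_squared`, `tree`, `membership` (per-population core counts and
#'   percentages)
#' @export
validate_core <- function(dataset, partition, core, metric = "dice",
                          paired = FALSE) {
  ids <- if (inherits(core, "core_set")) core$ids else as.character(core)
  core_ds <- subset_individuals(dataset, ids)
  whole_tab <- per_locus_indices(dataset)
  core_tab <- per_locus_indices(core_ds)
  idx_names <- c("A", "Ae", "I", "Ho", "He", "F")
  t_tests <- do.call(rbind, lapply(idx_names, function(v) {
    x <- core_tab[[v]]; y <- whole_tab[[v]]
    if (isTRUE(all.equal(x, y))) {
      data.frame(index = v, t = 0, p = 1)
    } else {
      tt <- tryCatch(
        if (paired) stats::t.test(x, y, paired = TRUE)
        else stats::t.test(x, y, var.equal = FALSE),
        error = function(e) NULL)  # degenerate: < 2 loci or zero spread
      if (is.null(tt)) data.frame(index = v, t = NA_real_, p = NA_real_)
      else data.frame(index = v, t = unname(tt$statistic), p = tt$p.value)
    }
  }))
  # per-locus chi-square on allele counts
  whole_freq <- allele_frequencies(dataset)$freq[["ALL"]]
  core_ft <- allele_frequencies(core_ds)
  core_freq <- core_ft$freq[["ALL"]]
  chisq <- do.call(rbind, lapply(seq_along(dataset$locus_ids), function(l) {
    locus <- dataset$locus_ids[l]
    wf <- whole_freq[[locus]]
    n2 <- 2 * core_ft$n_typed["ALL", l]
    if (!length(wf) || n2 == 0)
      return(data.frame(locus = locus, statistic = NA_real_, df = NA_real_,
                        p = NA_real_))
    obs <- stats::setNames(numeric(length(wf)), names(wf))
    cf <- core_freq[[locus]]
    obs[names(cf)] <- cf * n2
    expd <- wf * n2
    pool <- expd < 1
    if (any(pool) && sum(!pool) >= 1) {
      obs <- c(obs[!pool], pooled = sum(obs[pool]))
      expd <- c(expd[!pool], pooled = sum(expd[pool]))
    }
    if (length(expd) < 2)
      return(data.frame(locus = locus, statistic = 0, df = 0, p = 1))
    stat <- sum((obs - expd)^2 / expd)
    df <- length(expd) - 1
    data.frame(locus = locus, statistic = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  }))
  # allele-frequency correlation over all classes
  wvec <- cvec <- numeric(0)
  for (locus in dataset$locus_ids) {
    wf <- whole_freq[[locus]]
    if (!length(wf)) next
    cf <- core_freq[[locus]]
    cc <- stats::setNames(numeric(length(wf)), names(wf))
    cc[intersect(names(cf), names(wf))] <- cf[intersect(names(cf), names(wf))]
    wvec <- c(wvec, unname(wf)); cvec <- c(cvec, unname(cc))
  }
  r2 <- stats::cor(wvec, cvec)^2
  tree <- if (length(ids) >= 2) upgma(pairwise_distance(core_ds, metric)) else NULL
  grp <- partition$pop[dataset$individual_ids]
  memb <- do.call(rbind, lapply(partition$populations, function(p) {
    tot <- sum(grp == p)
    inc <- sum(ids %in% dataset$individual_ids[grp == p])
    data.frame(pop = p, n = tot, n_core = inc, pct_core = 100 * inc / tot)
  }))
  structure(list(t_tests = t_tests, chisq = chisq,
                 n_chisq_significant = sum(chisq$p < 0.05, na.rm = TRUE),
                 r_squared = r2, tree = tree, membership = memb),
            class = "core_validation")
}

#' @export
print.core_validation <- function(x, ...) {
  cat("<core_validation>\n")
  print(x$t_tests, row.names = FALSE)
  cat(sprintf("chi-square significant loci (p < 0.05): %d of %d\n",
              x$n_chisq_significant, nrow(x$chisq)))
  cat(sprintf("allele-frequency R^2 = %.3f\n", x$r_squared))
  invisible(x)
}
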