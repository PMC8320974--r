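#' Bayesian admixture inference by Gibbs sampling
#'
#' Model-based clustering of multilocus codominant genotypes into `K`
#' clusters under the admixture model with independent allele frequencies:
#' each allele copy carries a latent cluster assignment, cluster allele
#' frequencies have a `Dirichlet(lambda)` prior, individual membership
#' vectors `Q` a symmetric `Dirichlet(alpha)` prior, and `alpha` itself is
#' updated by a reflected-normal Metropolis step under a uniform
#' `(0, alpha_max)` prior. The data log-likelihood given the current
#' assignments is recorded each post-burn-in sweep. Identical seeds give
#' identical runs.
#'
#' @param dataset a [genotype_dataset] with at least one polymorphic locus
#' @param K number of clusters (>= 1)
#' @param burn_in,n_sweeps burn-in and retained MCMC sweep counts; the
#'   desk-scale defaults (500 / 1500) are deliberately shorter than the
#'   10,000 / 50,000 typically used for publication-scale runs
#' @param seed integer seed (`NULL` leaves the RNG stream untouched)
#' @param lambda Dirichlet prior parameter for cluster allele frequencies
#' @param alpha_init,alpha_max,alpha_step initial value, prior upper bound
#'   and Metropolis step for alpha
#' @return object of class `structure_run`: `K`, `Q` (individuals x K, rows
#'   sum to 1), `P` (K x loci x alleles array of posterior-mean frequencies),
#'   `loglik_trace`, `lnPD` (see [lnpd_estimate]), `alpha`, `seed`,
#'   `burn_in`, `n_sweeps`
#' @export
gibbs_structure <- function(dataset, K, burn_in = 500, n_sweeps = 1500,
                            seed = NULL, lambda = 1, alpha_init = 1,
                            alpha_max = 10, alpha_step = 0.05) {
  if (K < 1) stop("K must be >= 1")
  if (all(is.na(dataset$a1))) stop("dataset has no typed calls")
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(dataset)
  A1 <- matrix(NA_integer_, n_individuals(dataset), L)
  A2 <- A1
  n_alleles <- integer(L)
  allele_labels <- vector("list", L)
  for (l in seq_len(L)) {
    al <- sort(unique(c(dataset$a1[, l], dataset$a2[, l])))
    al <- al[!is.na(al)]
    if (!length(al)) al <- integer(0)
    allele_labels[[l]] <- al
    n_alleles[l] <- max(1L, length(al))
    A1[, l] <- match(dataset$a1[, l], al)
    A2[, l] <- match(dataset$a2[, l], al)
  }
  res <- .gibbs_admixture_cpp(A1, A2, n_alleles, as.integer(K),
                              as.integer(burn_in), as.integer(n_sweeps),
                              lambda, alpha_init, alpha_max, alpha_step)
  Q <- res$Q
  dimnames(Q) <- list(dataset$individual_ids, paste0("cluster", seq_len(K)))
  P <- aperm(res$P_raw, c(3, 2, 1))  # -> K x loci x alleles
  dimnames(P) <- list(paste0("cluster", seq_len(K)), dataset$locus_ids, NULL)
  trace <- as.numeric(res$loglik_trace)
  structure(list(K = K, Q = Q, P = P, allele_labels = allele_labels,
                 loglik_trace = trace, lnPD = lnpd_estimate(trace),
                 alpha = res$alpha, seed = seed,
                 burn_in = burn_in, n_sweeps = n_sweeps),
            class = "structure_run")
}

#' @export
print.structure_run <- function(x, ...) {
  cat("<structure_run> K = ", x$K, ", ", nrow(x$Q), " individuals, lnPD = ",
      round(x$lnPD, 1), "\n", sep = "")
  invisible(x)
}

#' Estimated ln probability of the data from a log-likelihood trace
#'
#' Harmonic-style estimator: `mean(trace) - var(trace)/2`, with the variance
#' taken in its population (1/n) form. A trace of length 1 uses zero variance
#' with a warning.
#'
#' @param loglik_trace numeric vector of per-sweep data log-likelihoods
#' @return scalar lnPD, always `<= mean(loglik_trace)`
#' @export
lnpd_estimate <- function(loglik_trace) {
  if (!length(loglik_trace)) stop("empty log-likelihood trace")
  m <- mean(loglik_trace)
  if (length(loglik_trace) < 2) {
    warning("trace shorter than 2; variance taken as 0")
    return(m)
  }
  v <- mean((loglik_trace - m)^2)
  m - v / 2
}

#' Evanno delta-K table from replicate admixture runs
#'
#' For replicate runs grouped by `K`: `L(K)` is the mean lnPD,
#' `L'(K) = L(K) - L(K-1)`, `|L''(K)| = |L'(K+1) - L'(K)|` and
#' `deltaK = |L''(K)| / sd(L(K))`. `deltaK` is defined only for interior `K`
#' with positive replicate standard deviation; `best_K` is the argmax of the
#' defined values.
#'
#' @param runs list of `structure_run` objects (or any lists with elements
#'   `K` and `lnPD`) covering >= 3 consecutive K values with >= 2 replicates
#'   each
#' @return data.frame with columns `K`, `n_runs`, `mean_lnPD`, `sd_lnPD`,
#'   `lprime`, `lsecond`, `deltaK`, and attribute `best_K`
#' @export
evanno_delta_k <- function(runs) {
  ks <- vapply(runs, function(r) r$K, 0)
  ls <- vapply(runs, function(r) r$lnPD, 0)
  kk <- sort(unique(ks))
  if (length(kk) < 3) stop("need at least 3 consecutive K values")
  if (any(diff(kk) != 1)) stop("K values must be consecutive")
  mean_l <- vapply(kk, function(k) mean(ls[ks == k]), 0)
  sd_l <- vapply(kk, function(k) stats::sd(ls[ks == k]), 0)
  nrep <- vapply(kk, function(k) sum(ks == k), 0)
  m <- length(kk)
  lprime <- c(NA, diff(mean_l))                     # L'(K) = L(K) - L(K-1)
  lsecond <- rep(NA_real_, m)
  deltaK <- rep(NA_real_, m)
  for (i in 2:(m - 1)) {
    lsecond[i] <- abs(lprime[i + 1] - lprime[i])
    if (is.finite(sd_l[i]) && sd_l[i] > 0) {
      deltaK[i] <- lsecond[i] / sd_l[i]
    }
  }
  tab <- data.frame(K = kk, n_runs = nrep, mean_lnPD = mean_l, sd_lnPD = sd_l,
                    lprime = lprime, lsecond = lsecond, deltaK = deltaK)
  if (all(is.na(deltaK))) {
    attr(tab, "best_K") <- NA_integer_
  } else {
    attr(tab, "best_K") <- kk[which.max(deltaK)]
  }
  tab
}

#' Replicated admixture runs across a range of K
#'
#' Convenience driver: runs [gibbs_structure] `replicates` times for every
#' `K` in `K_range`, with per-run seeds derived from `seed` by a simple
#' counter so any single run can be reproduced in isolation.
#'
#' @inheritParams gibbs_structure
#' @param K_range integer vector of K values (e.g. `1:12`)
#' @param replicates replicate runs per K
#' @return list of `structure_run` objects
#' @export
structure_scan <- function(dataset, K_range, replicates = 3, burn_in = 500,
                           n_sweeps = 1500, seed = 1, ...) {
  runs <- list()
  counter <- 0L
  for (K in K_range) for (r in seq_len(replicates)) {
    counter <- counter + 1L
    runs[[counter]] <- gibbs_structure(dataset, K, burn_in = burn_in,
                                       n_sweeps = n_sweeps,
                                       seed = seed + 1000L * counter, ...)
  }
  runs
}

#' Hard cluster assignment from admixture proportions
#'
#' Labels each individual with its majority cluster when the maximum
#' membership reaches `threshold`, otherwise `"admixed"`.
#'
#' @param run a `structure_run`
#' @param threshold membership cutoff in `(0.5, 1]`
#' @return named character vector of cluster labels / `"admixed"`
#' @export
assign_clusters <- function(run, threshold = 0.8) {
  if (threshold <= 0.5 || threshold > 1) stop("threshold must lie in (0.5, 1]")
  apply(run$Q, 1, function(q) {
    k <- which.max(q)
    if (q[k] >= threshold) colnames(run$Q)[k] else "admixed"
  })
}
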