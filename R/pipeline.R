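fmt3 <- function(x) formatC(x, format = "f", digits = 3)
fmt1 <- function(x) formatC(x, format = "f", digits = 1)

write_table_fixed <- function(df, path, digits = 3, pct_cols = character(0)) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- if (nm %in% pct_cols) fmt1(out[[nm]]) else fmt3(out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters. Exactly one of `input` (a GenAlEx CSV
#' path) or `simulate` (a [sim_config()]) must be supplied. The stage
#' defaults are desk-scale: they are chosen so a complete run finishes in
#' minutes on one CPU; publication-scale MCMC lengths can be set explicitly.
#'
#' @param input path to a GenAlEx-dialect CSV, or `NULL` to simulate
#' @param simulate a [sim_config()], or `NULL` to read `input`
#' @param stages character vector of stages to run, a subset of
#'   `c("diversity", "differentiation", "clustering", "admixture", "core",
#'   "validation")`
#' @param n_perm AMOVA permutation count
#' @param K_range,replicates,burn_in,n_sweeps admixture-scan parameters
#' @param core_intensity sampling intensity for the local-search core
#' @param metric individual-level distance metric (`"dice"` or
#'   `"bray_curtis"`) used for clustering/PCoA
#' @param eval_metric metric for core evaluation
#' @param seed global seed; stage s uses `seed + 100 * s` so any stage can be
#'   reproduced in isolation
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(input = NULL, simulate = sim_config(),
                            stages = c("diversity", "differentiation",
                                       "clustering", "admixture", "core",
                                       "validation"),
                            n_perm = 999, K_range = 1:6, replicates = 2,
                            burn_in = 200, n_sweeps = 600,
                            core_intensity = 0.31,
                            metric = "dice", eval_metric = "bray_curtis",
                            seed = 1L) {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of input / simulate must be given")
  structure(list(input = input, simulate = simulate, stages = stages,
                 n_perm = n_perm, K_range = K_range, replicates = replicates,
                 burn_in = burn_in, n_sweeps = n_sweeps,
                 core_intensity = core_intensity, metric = metric,
                 eval_metric = eval_metric, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, stage_index) config$seed + 100L * stage_index

#' Run the full germplasm analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or GenAlEx input),
#' per-locus and per-population diversity tables, population differentiation
#' (combined Nei/FST matrix, AMOVA), individual clustering (distance matrix,
#' UPGMA Newick tree, PCoA), Bayesian admixture with Evanno delta-K, core
#' selection by both optimizers with evaluation, and validation of the cores.
#' All outputs are written as fixed-precision CSV/Newick/JSON files so that a
#' repeated run with the same config is byte-identical. A failing stage
#' halts with the stage name; outputs of earlier stages are retained.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @return (invisibly) list of in-memory stage results, including the run
#'   manifest
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  on <- function(s) s %in% config$stages

  # stage 0: data
  run_stage("data", {
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      cfg$seed <- stage_seed(config, 0L)
      sim <- simulate_germplasm(cfg)
      res$dataset <- sim$dataset; res$partition <- sim$partition
      jsonlite::write_json(
        list(pedigree = sim$truth$pedigree,
             alleles = lapply(sim$truth$alleles, as.integer)),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    } else {
      gx <- read_genalex(config$input)
      res$dataset <- gx$dataset; res$partition <- gx$partition
    }
    write_genalex(res$dataset, res$partition,
                  file.path(out_dir, "genotypes.csv"))
    write_structure(res$dataset, res$partition,
                    file.path(out_dir, "genotypes.str"))
  })

  if (on("diversity")) run_stage("diversity", {
    res$locus_diversity <- locus_diversity_table(res$dataset)
    res$population_diversity <- population_diversity(res$dataset, res$partition)
    write_table_fixed(res$locus_diversity,
                      file.path(out_dir, "locus_diversity.csv"))
    write_table_fixed(res$population_diversity,
                      file.path(out_dir, "population_diversity.csv"))
  })

  if (on("differentiation")) run_stage("differentiation", {
    res$pair_matrix <- population_pair_matrix(res$dataset, res$partition)
    write_pair_matrix(res$pair_matrix, file.path(out_dir, "pair_matrix.csv"))
    res$amova <- amova(res$dataset, res$partition, n_perm = config$n_perm,
                        seed = stage_seed(config, 2L))
    am <- res$amova
    amtab <- data.frame(
      source = c("Among populations", "Within populations", "Total"),
      df = c(am$df_among, am$df_within, am$df_among + am$df_within),
      SS = fmt3(c(am$SS_among, am$SS_within, am$SS_total)),
      variance = fmt3(c(am$sigma_among, am$sigma_within,
                        am$sigma_among + am$sigma_within)),
      percent = fmt1(c(am$percent_among, am$percent_within, 100)))
    utils::write.csv(amtab, file.path(out_dir, "amova.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(sprintf("PhiPT,%s\np_value,%s\nn_permutations,%d\nmean_pairwise_FST,%s\nmean_Nei_distance,%s",
                       fmt3(am$phipt), fmt3(am$p_value), am$n_permutations,
                       fmt3(pair_matrix_summary(res$pair_matrix)$mean_fst),
                       fmt3(pair_matrix_summary(res$pair_matrix)$mean_nei)),
               file.path(out_dir, "differentiation_summary.csv"))
  })

  if (on("clustering")) run_stage("clustering", {
    d <- pairwise_distance(res$dataset, config$metric)
    res$distance <- d
    res$tree <- upgma(d)
    write_newick(res$tree, file.path(out_dir, "upgma.nwk"))
    res$pcoa <- pcoa(d)
    co <- data.frame(id = rownames(res$pcoa$coordinates),
                     res$pcoa$coordinates[, seq_len(min(5, ncol(res$pcoa$coordinates))),
                                          drop = FALSE])
    write_table_fixed(co, file.path(out_dir, "pcoa_coordinates.csv"),
                      digits = 6)
    ev <- data.frame(axis = seq_along(res$pcoa$eigenvalues),
                     eigenvalue = res$pcoa$eigenvalues)
    npos <- length(res$pcoa$percent)
    ev$percent <- c(res$pcoa$percent, rep(NA_real_, nrow(ev) - npos))
    write_table_fixed(ev, file.path(out_dir, "pcoa_eigenvalues.csv"),
                      pct_cols = "percent")
  })

  if (on("admixture")) run_stage("admixture", {
    runs <- structure_scan(res$dataset, config$K_range,
                           replicates = config$replicates,
                           burn_in = config$burn_in,
                           n_sweeps = config$n_sweeps,
                           seed = stage_seed(config, 4L))
    res$structure_runs <- runs
    res$evanno <- evanno_delta_k(runs)
    write_table_fixed(res$evanno, file.path(out_dir, "evanno.csv"))
    best_k <- attr(res$evanno, "best_K")
    best_runs <- Filter(function(r) r$K == best_k, runs)
    best <- best_runs[[which.max(vapply(best_runs, function(r) r$lnPD, 0))]]
    res$best_structure <- best
    qdf <- data.frame(id = rownames(best$Q), best$Q,
                      label = assign_clusters(best, threshold = 0.8))
    write_table_fixed(qdf, file.path(out_dir,
                                     sprintf("q_matrix_K%d.csv", best_k)))
  })

  if (on("core")) run_stage("core", {
    res$core_m <- mstrategy_core(res$dataset, seed = stage_seed(config, 5L))
    res$core_ls <- localsearch_core(res$dataset, config$core_intensity,
                                     seed = stage_seed(config, 5L))
    writeLines(res$core_m$ids, file.path(out_dir, "core_mstrategy_ids.txt"))
    writeLines(res$core_ls$ids, file.path(out_dir, "core_localsearch_ids.txt"))
    evs <- lapply(list(res$core_m, res$core_ls), function(cs) {
      ev <- evaluate_core(res$dataset, cs, config$eval_metric)
      he <- mean(per_locus_indices(subset_individuals(res$dataset, cs$ids))$He)
      data.frame(method = cs$method, N = length(cs$ids),
                 intensity_pct = 100 * cs$sampling_intensity, CV = cs$CV,
                 He = he, A_NE = ev$A_NE, E_E = ev$E_E,
                 E_NE_min = ev$E_NE_min, E_NE_mean = ev$E_NE_mean)
    })
    res$core_evaluation <- do.call(rbind, evs)
    write_table_fixed(res$core_evaluation,
                      file.path(out_dir, "core_evaluation.csv"),
                      pct_cols = "intensity_pct")
  })

  if (on("validation")) run_stage("validation", {
    if (is.null(res$core_m))
      stop("requires the 'core' stage outputs; enable the core stage")
    vals <- list(mstrategy = validate_core(res$dataset, res$partition,
                                           res$core_m, metric = config$metric),
                 localsearch = validate_core(res$dataset, res$partition,
                                             res$core_ls, metric = config$metric))
    res$validation <- vals
    vt <- do.call(rbind, lapply(names(vals), function(nm) {
      cbind(method = nm, vals[[nm]]$t_tests,
            r_squared = vals[[nm]]$r_squared,
            n_chisq_significant = vals[[nm]]$n_chisq_significant)
    }))
    write_table_fixed(vt, file.path(out_dir, "core_validation.csv"))
    memb <- do.call(rbind, lapply(names(vals), function(nm)
      cbind(method = nm, vals[[nm]]$membership)))
    write_table_fixed(memb, file.path(out_dir, "core_membership.csv"),
                      pct_cols = "pct_core")
  })

  manifest <- list(
    package = "ssrcore",
    version = as.character(utils::packageVersion("ssrcore")),
    seed = config$seed,
    stages = config$stages,
    n_individuals = n_individuals(res$dataset),
    n_loci = n_loci(res$dataset),
    n_populations = length(res$partition$populations),
    parameters = list(n_perm = config$n_perm,
                      K_range = range(config$K_range),
                      replicates = config$replicates,
                      burn_in = config$burn_in, n_sweeps = config$n_sweeps,
                      core_intensity = config$core_intensity,
                      metric = config$metric,
                      eval_metric = config$eval_metric))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
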