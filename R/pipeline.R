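#' Validate and normalize a pipeline run configuration
#'
#' Fills every documented default (genome-wide threshold 5e-8, clumping
#' r-squared 0.001, proxy r-squared 0.8, posterior-probability cutoff
#' 0.02, heterogeneity cutoff 10, and the Bonferroni level derived from
#' the number of exposures and outcomes) and rejects out-of-domain values,
#' reporting every offending field at once.
#'
#' @param config a (possibly partial) named list. Recognized fields:
#'   `mode` ("synthetic" or "user-data"), `seed`, `n_snps`,
#'   `n_exposures`, `n_outcomes`, `causal_effects` (named list per
#'   outcome), `gwas` (extra [synthetic_gwas_config()] arguments),
#'   `ld_block_size`, `ld_within_r2`, `confounder_frac`, `p_threshold`,
#'   `clump_r2`, `proxy_r2`, `alpha`, `bma` ([bma_config()] arguments),
#'   `n_knots`, `cohort` (group sizes), plus input `paths` in user-data
#'   mode.
#' @return the normalized config (class `run_config`) or an error listing
#'   every invalid field.
#' @export
validate_run_config <- function(config = list()) {
  defaults <- list(mode = "synthetic", seed = 1L,
                   n_snps = 1000L, n_exposures = 15L, n_outcomes = 2L,
                   outcome_names = c("CD", "UC"),
                   causal_effects = list(CD = c(LYM = -0.2),
                                         UC = c(EOS = 0.3)),
                   gwas = list(),
                   ld_block_size = 5L, ld_within_r2 = 0.85,
                   confounder_frac = 0.05,
                   p_threshold = 5e-8, clump_r2 = 0.001, proxy_r2 = 0.8,
                   alpha = 0.05, bma = list(), n_knots = 4L,
                   cohort = c(healthy = 100L, CD = 230L, UC = 80L),
                   paths = list())
  unknown <- setdiff(names(config), names(defaults))
  cfg <- utils::modifyList(defaults, config)
  errors <- character(0)
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown field(s): ",
                               paste(unknown, collapse = ", ")))
  }
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  chk(cfg$mode %in% c("synthetic", "user-data"),
      "mode: must be 'synthetic' or 'user-data'")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed: must be a single integer (mandatory in synthetic mode)")
  chk(cfg$p_threshold > 0 && cfg$p_threshold < 1,
      "p_threshold: must lie in (0, 1)")
  chk(cfg$clump_r2 >= 0 && cfg$clump_r2 <= 1,
      "clump_r2: must lie in [0, 1]")
  chk(cfg$proxy_r2 >= 0 && cfg$proxy_r2 <= 1,
      "proxy_r2: must lie in [0, 1]")
  chk(cfg$ld_within_r2 >= 0 && cfg$ld_within_r2 <= 1,
      "ld_within_r2: must lie in [0, 1]")
  chk(cfg$confounder_frac >= 0 && cfg$confounder_frac <= 1,
      "confounder_frac: must lie in [0, 1]")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha: must lie in (0, 1)")
  chk(cfg$n_snps >= 1, "n_snps: must be positive")
  chk(cfg$n_exposures >= 1, "n_exposures: must be positive")
  chk(cfg$n_knots >= 3 && cfg$n_knots <= 7,
      "n_knots: must be between 3 and 7")
  chk(all(cfg$cohort >= 1), "cohort: group sizes must be positive")
  bma_ok <- tryCatch({do.call(bma_config, cfg$bma); TRUE},
                     error = function(e) FALSE)
  chk(bma_ok, "bma: invalid Bayesian-model-averaging settings")
  if (length(errors) > 0) {
    stop("invalid run configuration:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  cfg$bonferroni_alpha <- bonferroni_threshold(cfg$alpha, cfg$n_exposures,
                                               cfg$n_outcomes)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# fan one master seed out to reproducible per-stage substreams (< 2^31)
substream_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run the end-to-end MR pipeline
#'
#' Synthetic mode: generates LD, GWAS panels for each outcome, a
#' confounder catalog and a blood-count cohort from the master seed, then
#' runs the full analysis chain — instrument selection (genome-wide
#' filter, proxy substitution, LD clumping, confounder screen),
#' harmonization, all six univariable MR estimators per exposure-outcome
#' pair, multivariable MR with Bayesian model averaging and iterative
#' instrument pruning, and restricted-cubic-spline dose-response fits per
#' trait. Stage failures are isolated: a failing cell or fit is recorded
#' and the remaining stages still run.
#'
#' @param config a [validate_run_config()] result or the raw list for it.
#' @param output_dir optional directory; when given, the summary tables
#'   are written there as TSV/JSON.
#' @return a list of class `run_report`: `selection` (per-outcome
#'   selection logs), `uvmr` (grid data frame), `bma` (per-outcome
#'   pruning results), `rcs` (per-outcome dose-response summaries),
#'   `cohort`, and `provenance` (package version, seed, stage seeds).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  if (config$mode != "synthetic") {
    stop("user-data mode requires input paths; only synthetic mode is ",
         "self-contained")  # user-data ingestion goes through the readers
  }
  seeds <- substream_seeds(config$seed, 5)
  ld <- generate_ld_matrix(config$n_snps, config$ld_block_size,
                           config$ld_within_r2, seed = seeds[1])

  outcome_cc <- list(CD = c(5956, 14927), UC = c(6968, 20464))
  sets <- list()
  selection <- list()
  panels_by_outcome <- list()
  for (i in seq_along(config$outcome_names)) {
    oc <- config$outcome_names[i]
    theta <- numeric(config$n_exposures)
    names(theta) <- exposure_labels(config$n_exposures)
    ce <- config$causal_effects[[oc]]
    ce <- ce[names(ce) %in% names(theta)]
    theta[names(ce)] <- ce
    cc <- outcome_cc[[oc]] %||% c(5000, 15000)
    gw_args <- utils::modifyList(
      list(n_snps = config$n_snps, n_exposures = config$n_exposures,
           causal_effects = theta, n_cases = cc[1], n_controls = cc[2],
           missing_frac = 0.05, seed = seeds[2] %% 100000L + i),
      config$gwas)
    panels <- generate_summary_stats(do.call(synthetic_gwas_config, gw_args),
                                     ld = ld)
    catalog <- generate_confounder_catalog(panels$outcome$SNP,
                                           config$confounder_frac,
                                           seed = seeds[3])
    sel <- select_instruments(panels$exposures, panels$outcome, ld, catalog,
                              config$p_threshold, config$clump_r2,
                              config$proxy_r2)
    sets[[oc]] <- harmonize(panels$exposures, panels$outcome,
                            snp_ids = sel$snp_ids,
                            proxy_map = sel$proxy_map)
    selection[[oc]] <- sel$log
    panels_by_outcome[[oc]] <- panels
  }

  uvmr <- run_uvmr_grid(sets, alpha = config$alpha,
                        p_threshold = config$p_threshold,
                        seed = seeds[4])

  bma_cfg <- do.call(bma_config, config$bma)
  bma <- lapply(sets, function(s) {
    tryCatch(iterative_prune(s, bma_cfg), error = function(e) e)
  })

  cohort <- generate_cbc_cohort(config$cohort[["healthy"]],
                                config$cohort[["CD"]],
                                config$cohort[["UC"]],
                                seed = seeds[5])
  rcs <- list()
  for (oc in intersect(config$outcome_names, c("CD", "UC"))) {
    rcs[[oc]] <- rcs_summary(cohort, oc, n_knots = config$n_knots)
  }

  report <- structure(list(
    selection = selection,
    uvmr = uvmr,
    bma = bma,
    rcs = rcs,
    cohort = cohort,
    truth = lapply(panels_by_outcome, function(p) p$truth$theta),
    provenance = list(
      package = "bloodcellmr",
      version = as.character(utils::packageVersion("bloodcellmr")),
      seed = config$seed, stage_seeds = seeds,
      config = unclass(config))),
    class = "run_report")

  if (!is.null(output_dir)) write_run_report(report, output_dir)
  report
}

#' Write the tabular parts of a run report to disk
#'
#' @param report a `run_report`.
#' @param output_dir directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$uvmr, file.path(output_dir, "uvmr_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(report$selection, unclass),
    file.path(output_dir, "selection_log.json"), auto_unbox = TRUE)
  for (oc in names(report$bma)) {
    b <- report$bma[[oc]]
    if (inherits(b, "error")) next
    write.table(bma_rank_exposures(b$posterior),
                file.path(output_dir, paste0("bma_ranking_", oc, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(head(b$posterior$models, 10),
                file.path(output_dir, paste0("bma_models_", oc, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(b$audit,
                         file.path(output_dir,
                                   paste0("bma_pruning_", oc, ".json")))
  }
  for (oc in names(report$rcs)) {
    cr <- report$rcs[[oc]]$crossings
    if (!is.null(cr)) {
      write.table(cr, file.path(output_dir,
                                paste0("rcs_crossings_", oc, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(output_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("bloodcellmr run (seed ", x$provenance$seed, ")\n", sep = "")
  for (oc in names(x$selection)) {
    cat("  ", oc, ": ", format(x$selection[[oc]]), "\n", sep = "")
  }
  sig <- x$uvmr[!is.na(x$uvmr$bonferroni_significant) &
                  x$uvmr$bonferroni_significant &
                  x$uvmr$method == "ivw_random", ]
  cat("  uvMR Bonferroni-significant (random-effects IVW): ",
      if (nrow(sig)) paste(sig$exposure, "->", sig$outcome, collapse = "; ")
      else "none", "\n", sep = "")
  for (oc in names(x$bma)) {
    b <- x$bma[[oc]]
    if (inherits(b, "error")) next
    top <- bma_rank_exposures(b$posterior)[1, ]
    cat(sprintf("  MR-BMA %s: top exposure %s (MIP %.3f, MACE %.3f), %d SNPs pruned\n",
                oc, top$exposure, top$mip, top$mace, nrow(b$audit)))
  }
  invisible(x)
}
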