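#' Configuration for synthetic GWAS summary statistics
#'
#' Describes a two-sample MR scenario: `n_snps` variants with sparse,
#' correlated per-SD effects on `n_exposures` blood-cell traits, a binary
#' outcome whose per-allele log-odds effect is the linear combination of the
#' exposure effects weighted by the true causal vector `causal_effects`,
#' plus optional direct (pleiotropic) effects that bypass the exposures.
#' Observed coefficients are the true values perturbed by sampling noise
#' whose standard error is implied by the study sizes.
#'
#' @param n_snps number of variants simulated.
#' @param n_exposures number of exposure traits (default 15, the complete
#'   blood count panel; traits are labelled with the CBC names when
#'   `n_exposures == 15`).
#' @param causal_effects true causal log-odds ratio per SD of each exposure;
#'   recycled scalar or length-`n_exposures` vector (zeros allowed).
#' @param exposure_corr K x K correlation matrix of per-SNP exposure effects,
#'   must be symmetric positive semi-definite. Default: exchangeable
#'   correlation 0.3, a moderate level typical of blood-count indices.
#' @param sparsity fraction of SNPs with a nonzero effect on each exposure.
#' @param effect_sd standard deviation of nonzero per-SD exposure effects.
#' @param pleiotropy_frac fraction of SNPs with a direct outcome effect.
#' @param pleiotropy_sd standard deviation of direct effects (log-OR scale).
#' @param n_exposure_study sample size of each exposure GWAS (default
#'   563085, the blood-cell consortium size).
#' @param n_cases,n_controls outcome GWAS case/control counts (defaults are
#'   the UC study: 6968 cases, 20464 controls).
#' @param missing_frac fraction of SNPs absent from the outcome study.
#' @param flip_frac fraction of outcome rows reported on the opposite
#'   effect-allele orientation (exercises harmonization).
#' @param noise if `FALSE`, observed coefficients equal their true values
#'   (standard errors are still reported); used for exact-recovery checks.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return an object of class `synthetic_gwas_config`.
#' @export
synthetic_gwas_config <- function(n_snps = 1000,
                                  n_exposures = 15,
                                  causal_effects = 0,
                                  exposure_corr = NULL,
                                  sparsity = 0.05,
                                  effect_sd = 0.05,
                                  pleiotropy_frac = 0,
                                  pleiotropy_sd = 0.05,
                                  n_exposure_study = 563085,
                                  n_cases = 6968,
                                  n_controls = 20464,
                                  missing_frac = 0,
                                  flip_frac = 0.15,
                                  noise = TRUE,
                                  seed = 1L) {
  stopifnot(n_snps >= 1, n_exposures >= 1,
            n_exposure_study > 1, n_cases > 1, n_controls > 1)
  causal_effects <- rep_len(causal_effects, n_exposures)
  if (is.null(exposure_corr)) {
    exposure_corr <- matrix(0.3, n_exposures, n_exposures)
    diag(exposure_corr) <- 1
  }
  exposure_corr <- as.matrix(exposure_corr)
  if (nrow(exposure_corr) != n_exposures ||
      ncol(exposure_corr) != n_exposures ||
      max(abs(exposure_corr - t(exposure_corr))) > 1e-8) {
    stop("exposure_corr must be a symmetric ", n_exposures, "x",
         n_exposures, " matrix")
  }
  if (min(eigen(exposure_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("exposure_corr must be positive semi-definite")
  }
  for (f in c(sparsity, pleiotropy_frac, missing_frac, flip_frac)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  stopifnot(effect_sd > 0, pleiotropy_sd >= 0)
  structure(list(n_snps = as.integer(n_snps),
                 n_exposures = as.integer(n_exposures),
                 causal_effects = causal_effects,
                 exposure_corr = exposure_corr,
                 sparsity = sparsity,
                 effect_sd = effect_sd,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_sd = pleiotropy_sd,
                 n_exposure_study = n_exposure_study,
                 n_cases = n_cases,
                 n_controls = n_controls,
                 missing_frac = missing_frac,
                 flip_frac = flip_frac,
                 noise = isTRUE(noise),
                 seed = as.integer(seed)),
            class = "synthetic_gwas_config")
}

exposure_labels <- function(K) {
  if (K == length(CBC_TRAITS)) CBC_TRAITS else paste0("X", seq_len(K))
}

# standard log-OR variance approximation at allele frequency f:
# var(beta) ~ 1 / (2 f (1-f) * n * phi * (1-phi)), phi the case fraction
outcome_se <- function(eaf, n_cases, n_controls) {
  n <- n_cases + n_controls
  phi <- n_cases / n
  1 / sqrt(2 * eaf * (1 - eaf) * n * phi * (1 - phi))
}

# per-SD exposure effect of one allele: var(beta) ~ 1 / (2 f (1-f) * n)
exposure_se <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

#' Generate two-sample GWAS summary statistics with known ground truth
#'
#' Draws sparse, correlated per-SNP exposure effects, composes the true
#' outcome effect as the causal combination of exposure effects plus direct
#' pleiotropic effects, adds per-study sampling noise, and returns one
#' summary-statistic panel per exposure plus one outcome panel. Effect
#' alleles and allele frequencies are shared across panels, except that a
#' `flip_frac` fraction of outcome rows is reported on the opposite allele
#' orientation and `missing_frac` of SNPs is withheld from the outcome
#' panel entirely.
#'
#' @param config a [synthetic_gwas_config()].
#' @param ld optional [generate_ld_matrix()] result covering the same SNPs.
#'   When given, SNPs withheld from the outcome panel are chosen among those
#'   with at least one within-block partner, so a valid proxy always exists;
#'   otherwise withheld SNPs are chosen uniformly.
#' @return a list of class `gwas_panels` with elements
#'   `exposures` (named list of data frames, columns SNP, EA, OA, BETA,
#'   SE, P, EAF, N), `outcome` (same columns), and `truth` (true effect
#'   matrix `gamma`, direct effects `alpha`, causal vector `theta`,
#'   pleiotropic/missing SNP ids and the proxy candidates used).
#' @export
generate_summary_stats <- function(config, ld = NULL) {
  stopifnot(inherits(config, "synthetic_gwas_config"))
  J <- config$n_snps
  K <- config$n_exposures
  set.seed(config$seed)
  snp <- paste0("rs", seq_len(J))
  labs <- exposure_labels(K)

  # alleles: unordered pair per SNP; A/T and C/G pairs are palindromic
  bases <- c("A", "C", "G", "T")
  al <- t(vapply(seq_len(J), function(i) sample(bases, 2), character(2)))
  eaf <- runif(J, 0.05, 0.95)

  # sparse correlated true exposure effects (per SD of trait, per allele)
  mask <- matrix(rbinom(J * K, 1, config$sparsity), J, K)
  z <- MASS::mvrnorm(J, mu = rep(0, K), Sigma = config$exposure_corr)
  gamma <- mask * (config$effect_sd * z)

  # true outcome effect: causal path + direct (pleiotropic) path
  n_pleio <- round(config$pleiotropy_frac * J)
  pleio_idx <- if (n_pleio > 0) sample.int(J, n_pleio) else integer(0)
  alpha <- numeric(J)
  alpha[pleio_idx] <- rnorm(n_pleio, 0, config$pleiotropy_sd)
  beta_y_true <- drop(gamma %*% config$causal_effects) + alpha

  se_x <- exposure_se(eaf, config$n_exposure_study)
  se_y <- outcome_se(eaf, config$n_cases, config$n_controls)

  exposures <- vector("list", K)
  names(exposures) <- labs
  for (k in seq_len(K)) {
    b <- gamma[, k]
    if (config$noise) b <- b + rnorm(J, 0, se_x)
    exposures[[k]] <- data.frame(
      SNP = snp, EA = al[, 1], OA = al[, 2],
      BETA = b, SE = se_x,
      P = pmax(2 * pnorm(-abs(b / se_x)), 1e-300),  # guard underflow to 0
      EAF = eaf, N = config$n_exposure_study,
      stringsAsFactors = FALSE)
  }

  by <- beta_y_true
  if (config$noise) by <- by + rnorm(J, 0, se_y)
  outcome <- data.frame(
    SNP = snp, EA = al[, 1], OA = al[, 2],
    BETA = by, SE = se_y,
    P = pmax(2 * pnorm(-abs(by / se_y)), 1e-300),
    EAF = eaf, N = config$n_cases + config$n_controls,
    stringsAsFactors = FALSE)

  # report a fraction of outcome rows on the flipped allele orientation
  n_flip <- round(config$flip_frac * J)
  if (n_flip > 0) {
    fi <- sample.int(J, n_flip)
    outcome[fi, c("EA", "OA")] <- outcome[fi, c("OA", "EA")]
    outcome$BETA[fi] <- -outcome$BETA[fi]
    outcome$EAF[fi] <- 1 - outcome$EAF[fi]
  }

  # withhold SNPs from the outcome study; prefer SNPs with an LD partner
  n_miss <- round(config$missing_frac * J)
  proxy_candidates <- character(0)
  missing_ids <- character(0)
  if (n_miss > 0) {
    eligible <- seq_len(J)
    if (!is.null(ld)) {
      partners <- rowSums(ld$r2 > 0) > 1  # unit diagonal => >1 means a partner
      if (any(partners)) eligible <- which(partners[match(snp, ld$snp_ids)])
    }
    miss_idx <- sample(eligible, min(n_miss, length(eligible)))
    missing_ids <- snp[miss_idx]
    if (!is.null(ld)) {
      proxy_candidates <- vapply(miss_idx, function(i) {
        r <- ld$r2[match(snp[i], ld$snp_ids), ]
        r[match(snp[i], ld$snp_ids)] <- 0
        r[match(missing_ids, ld$snp_ids)] <- 0
        j <- which.max(r)
        if (r[j] > 0) ld$snp_ids[j] else NA_character_
      }, character(1))
      names(proxy_candidates) <- missing_ids
    }
    outcome <- outcome[-miss_idx, , drop = FALSE]
    rownames(outcome) <- NULL
  }

  structure(list(
    exposures = exposures,
    outcome = outcome,
    truth = list(gamma = `dimnames<-`(gamma, list(snp, labs)),
                 alpha = setNames(alpha, snp),
                 theta = setNames(config$causal_effects, labs),
                 pleiotropic = snp[pleio_idx],
                 missing = missing_ids,
                 proxy_candidates = proxy_candidates),
    config = config), class = "gwas_panels")
}

#' Generate a block-diagonal LD matrix
#'
#' Builds a squared-correlation (r-squared) matrix over `n_snps` variants in
#' consecutive blocks of `block_size`, with the stated r-squared inside each
#' block and zero across blocks. The last block may be smaller when
#' `n_snps` is not a multiple of `block_size`.
#'
#' @param n_snps number of variants.
#' @param block_size variants per LD block (must not exceed `n_snps`).
#' @param within_block_r2 r-squared between distinct variants of one block,
#'   in \[0, 1\].
#' @param seed integer seed (kept for interface symmetry; the construction
#'   is deterministic).
#' @return a list of class `ld_matrix` with `snp_ids` and the symmetric
#'   unit-diagonal matrix `r2`.
#' @export
generate_ld_matrix <- function(n_snps, block_size, within_block_r2,
                               seed = 1L) {
  stopifnot(n_snps >= 1, block_size >= 1)
  if (block_size > n_snps) stop("block_size must not exceed n_snps")
  if (within_block_r2 < 0 || within_block_r2 > 1) {
    stop("within_block_r2 must lie in [0, 1]")
  }
  snp <- paste0("rs", seq_len(n_snps))
  block <- ((seq_len(n_snps) - 1) %/% block_size) + 1
  r2 <- outer(block, block, function(a, b) {
    ifelse(a == b, within_block_r2, 0)
  })
  diag(r2) <- 1
  dimnames(r2) <- list(snp, snp)
  structure(list(snp_ids = snp, r2 = r2), class = "ld_matrix")
}

#' Generate a confounder-association catalog
#'
#' Stands in for a phenome-wide lookup service: assigns to an exact
#' `round(confounder_frac * length(snp_ids))` subset of SNPs one
#' genome-wide-significant association (p < 5e-8) with a confounder
#' phenotype drawn from the screening list used for instrument validation
#' (autoimmune disease, metabolic disease, cancer, death).
#'
#' @param snp_ids character vector of variant ids.
#' @param confounder_frac fraction of SNPs to flag, in \[0, 1\].
#' @param seed integer seed.
#' @return data frame with columns `snp_id`, `phenotype`, `pvalue`.
#' @export
generate_confounder_catalog <- function(snp_ids, confounder_frac, seed = 1L) {
  if (confounder_frac < 0 || confounder_frac > 1) {
    stop("confounder_frac must lie in [0, 1]")
  }
  set.seed(seed)
  n <- round(confounder_frac * length(snp_ids))
  if (n == 0) {
    return(data.frame(snp_id = character(0), phenotype = character(0),
                      pvalue = numeric(0), stringsAsFactors = FALSE))
  }
  chosen <- sample(snp_ids, n)
  phenos <- c("autoimmune disease", "metabolic disease", "cancer", "death")
  data.frame(snp_id = chosen,
             phenotype = sample(phenos, n, replace = TRUE),
             pvalue = 10^-runif(n, 7.4, 20),  # all below 5e-8
             stringsAsFactors = FALSE)
}

#' Default trait profile for the synthetic blood-count cohort
#'
#' Healthy geometric-mean levels for the 15 complete-blood-count traits in
#' their clinical units, log-scale standard deviations, and multiplicative
#' group shifts reproducing the reported direction of every significant
#' CD-vs-healthy and UC-vs-healthy difference: CD shows increased RDW, NEU,
#' MON, PLT and decreased HGB, HCT, MCH, MCV, MCHC, LYM, MPV; UC shows
#' increased RDW, WBC, NEU, MON, EOS and decreased HGB, MCH, MCV, MCHC,
#' MPV.
#'
#' @return data frame with columns `trait`, `healthy_mean`, `log_sd`,
#'   `cd_shift`, `uc_shift` (shifts are multiplicative on the trait scale).
#' @export
default_cbc_profile <- function() {
  data.frame(
    trait = CBC_TRAITS,
    healthy_mean = c(4.6, 140, 42, 90, 30, 333, 13.0, 6.0,
                     3.5, 2.0, 0.45, 0.03, 0.15, 250, 10.5),
    log_sd = c(0.08, 0.09, 0.08, 0.05, 0.06, 0.02, 0.06, 0.25,
               0.35, 0.30, 0.40, 0.60, 0.70, 0.25, 0.08),
    cd_shift = c(1.00, 0.88, 0.92, 0.94, 0.92, 0.97, 1.12, 1.00,
                 1.30, 0.65, 1.35, 1.00, 1.00, 1.18, 0.92),
    uc_shift = c(1.00, 0.92, 1.00, 0.95, 0.94, 0.97, 1.08, 1.25,
                 1.30, 1.00, 1.30, 1.00, 1.60, 1.00, 0.93),
    stringsAsFactors = FALSE)
}

#' Generate an individual-level blood-count case-control cohort
#'
#' Draws lognormal trait values per subject with group-specific
#' multiplicative shifts, emulating a hospital case-control study of 100
#' healthy controls, 230 CD and 80 UC patients with ages 28-54.
#'
#' @param n_healthy,n_cd,n_uc group sizes (defaults 100, 230, 80).
#' @param effect_profile per-trait profile as in [default_cbc_profile()];
#'   all `log_sd` must be positive.
#' @param seed integer seed.
#' @return data frame of class `cbc_cohort`: `subject_id`, `group`
#'   (factor healthy/CD/UC), `age`, `sex`, and one column per trait.
#' @export
generate_cbc_cohort <- function(n_healthy = 100, n_cd = 230, n_uc = 80,
                                effect_profile = default_cbc_profile(),
                                seed = 1L) {
  stopifnot(n_healthy >= 1, n_cd >= 1, n_uc >= 1)
  if (any(effect_profile$log_sd <= 0)) stop("log_sd must be positive")
  if (any(effect_profile$healthy_mean <= 0)) {
    stop("healthy_mean must be positive")
  }
  set.seed(seed)
  n <- n_healthy + n_cd + n_uc
  group <- factor(rep(c("healthy", "CD", "UC"), c(n_healthy, n_cd, n_uc)),
                  levels = c("healthy", "CD", "UC"))
  out <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    group = group,
                    age = round(runif(n, 28, 54)),
                    sex = sample(c("F", "M"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  shift <- cbind(healthy = 1, CD = effect_profile$cd_shift,
                 UC = effect_profile$uc_shift)
  rownames(shift) <- effect_profile$trait
  for (i in seq_len(nrow(effect_profile))) {
    tr <- effect_profile$trait[i]
    mu <- log(effect_profile$healthy_mean[i]) +
      log(shift[tr, as.character(group)])
    out[[tr]] <- rlnorm(n, meanlog = mu, sdlog = effect_profile$log_sd[i])
  }
  class(out) <- c("cbc_cohort", "data.frame")
  out
}

#' Write or read a summary-statistic panel as TSV
#'
#' The panel dialect is tab-separated with header columns
#' SNP, EA, OA, BETA, SE, P, EAF, N.
#'
#' @param panel a summary-statistic data frame.
#' @param path file path.
#' @return `read_summary_stats` returns the panel data frame.
#' @export
write_summary_stats <- function(panel, path) {
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write or read an LD matrix as square TSV with id header row and column
#' @param ld an `ld_matrix`.
#' @param path file path.
#' @export
write_ld_matrix <- function(ld, path) {
  write.table(ld$r2, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_ld_matrix
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE))
  structure(list(snp_ids = rownames(m), r2 = m), class = "ld_matrix")
}
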