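# shared fixture builders -------------------------------------------------

# wrap raw coefficient vectors/matrices as a harmonized instrument set
make_set <- function(beta_X, se_X, beta_Y, se_Y, p_X = NULL,
                     snp_ids = NULL) {
  beta_X <- as.matrix(beta_X)
  se_X <- as.matrix(se_X)
  J <- nrow(beta_X)
  if (is.null(snp_ids)) snp_ids <- paste0("rs", seq_len(J))
  if (is.null(p_X)) p_X <- 2 * pnorm(-abs(beta_X / se_X))
  labs <- colnames(beta_X)
  if (is.null(labs)) labs <- paste0("X", seq_len(ncol(beta_X)))
  dimnames(beta_X) <- dimnames(se_X) <- dimnames(p_X) <- list(snp_ids, labs)
  structure(list(snp_ids = snp_ids, beta_X = beta_X, se_X = se_X,
                 p_X = p_X, beta_Y = setNames(beta_Y, snp_ids),
                 se_Y = setNames(se_Y, snp_ids),
                 proxy_map = character(0),
                 dropped = data.frame(snp_id = character(0),
                                      reason = character(0))),
            class = "harmonized_set")
}

# fast panels -> harmonized set, valid when the generator applied no
# orientation flips and withheld no SNPs (flip_frac = 0, missing_frac = 0)
panels_to_set <- function(panels) {
  stopifnot(panels$config$flip_frac == 0, panels$config$missing_frac == 0)
  beta_X <- sapply(panels$exposures, `[[`, "BETA")
  se_X <- sapply(panels$exposures, `[[`, "SE")
  p_X <- sapply(panels$exposures, `[[`, "P")
  make_set(beta_X, se_X, panels$outcome$BETA, panels$outcome$SE,
           p_X = as.matrix(p_X), snp_ids = panels$outcome$SNP)
}

# one draw of a single-exposure instrument panel on the consortium scale:
# J instruments, per-SD exposure effects from the blood-cell GWAS size,
# outcome SEs from the UC case-control sizes
draw_single_exposure <- function(J = 60, theta = 0, seed = 1,
                                 effect_sd = 0.05,
                                 n_cases = 6968, n_controls = 20464) {
  cfg <- synthetic_gwas_config(n_snps = J, n_exposures = 1,
                               causal_effects = theta, sparsity = 1,
                               effect_sd = effect_sd,
                               n_cases = n_cases, n_controls = n_controls,
                               flip_frac = 0, seed = seed)
  panels_to_set(generate_summary_stats(cfg))
}
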