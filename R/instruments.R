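#' Select genome-wide significant variants across exposure panels
#'
#' @param panels a single summary-statistic data frame or a list of them
#'   (one per exposure).
#' @param p_threshold significance threshold (default 5e-8).
#' @return character vector of SNP ids with p below the threshold in at
#'   least one exposure, in panel order. An empty result is allowed.
#' @export
select_genomewide <- function(panels, p_threshold = 5e-8) {
  if (is.data.frame(panels)) panels <- list(panels)
  hits <- unlist(lapply(panels, function(p) p$SNP[p$P < p_threshold]))
  out <- unique(hits)
  if (length(out) == 0) {
    message("select_genomewide: no variant reached p < ", p_threshold)
  }
  out
}

#' Greedy LD clumping
#'
#' Repeatedly retains the remaining candidate with the smallest p-value and
#' drops every other candidate in LD with it above the r-squared threshold,
#' so that no retained pair exceeds the threshold. Ties on p are broken by
#' candidate order.
#'
#' @param candidates character vector of SNP ids.
#' @param ld an `ld_matrix` covering all candidates.
#' @param r2_threshold r-squared above which two variants are dependent
#'   (default 0.001).
#' @param pvalues named numeric vector giving each candidate's smallest
#'   association p-value across exposures.
#' @return character vector of retained (index) SNPs.
#' @export
clump <- function(candidates, ld, r2_threshold = 0.001, pvalues) {
  if (!all(candidates %in% ld$snp_ids)) {
    stop("candidates missing from the LD matrix: ",
         paste(setdiff(candidates, ld$snp_ids), collapse = ", "))
  }
  p <- pvalues[candidates]
  remaining <- candidates
  kept <- character(0)
  while (length(remaining) > 0) {
    idx <- which.min(p[remaining])
    lead <- remaining[idx]
    kept <- c(kept, lead)
    r2 <- ld$r2[lead, remaining]
    remaining <- remaining[!(r2 > r2_threshold)]
    remaining <- setdiff(remaining, lead)
  }
  kept
}

#' Find an LD proxy for a variant absent from the outcome study
#'
#' @param missing_snp id of the variant absent from the outcome panel.
#' @param ld an `ld_matrix`.
#' @param outcome_ids SNP ids present in the outcome panel.
#' @param r2_min minimum r-squared for an acceptable proxy (default 0.8).
#' @return the outcome-present SNP id with maximal r-squared at or above
#'   `r2_min`, or `NULL` when none qualifies.
#' @export
find_proxy <- function(missing_snp, ld, outcome_ids, r2_min = 0.8) {
  if (!missing_snp %in% ld$snp_ids) return(NULL)
  cand <- intersect(outcome_ids, ld$snp_ids)
  cand <- setdiff(cand, missing_snp)
  if (length(cand) == 0) return(NULL)
  r2 <- ld$r2[missing_snp, cand]
  best <- which.max(r2)
  if (r2[best] >= r2_min) cand[best] else NULL
}

#' Drop variants with genome-wide-significant confounder associations
#'
#' @param snps character vector of SNP ids.
#' @param catalog confounder catalog as from
#'   [generate_confounder_catalog()] (columns `snp_id`, `phenotype`,
#'   `pvalue`); `NULL` skips the filter.
#' @param p_threshold significance threshold for a disqualifying
#'   association (default 5e-8).
#' @return list with `kept` and `dropped` id vectors.
#' @export
filter_confounders <- function(snps, catalog, p_threshold = 5e-8) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    return(list(kept = snps, dropped = character(0)))
  }
  bad <- unique(catalog$snp_id[catalog$pvalue < p_threshold])
  list(kept = setdiff(snps, bad), dropped = intersect(snps, bad))
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

flip_allele <- function(a) chartr("ACGT", "TGCA", a)

# align one outcome row to the exposure orientation; returns the row with
# BETA/EAF adjusted, or NULL when the alleles cannot be reconciled
align_outcome_row <- function(row, ea, oa, eaf_exp, maf_ambiguous = 0.42) {
  if (is_palindromic(row$EA, row$OA)) {
    # alleles cannot distinguish a swap from a strand flip; use frequencies
    if (min(row$EAF, 1 - row$EAF) >= maf_ambiguous ||
        min(eaf_exp, 1 - eaf_exp) >= maf_ambiguous) {
      return(NULL)
    }
    same_side <- (row$EAF < 0.5) == (eaf_exp < 0.5)
    if (!same_side) {
      row$BETA <- -row$BETA
      row$EAF <- 1 - row$EAF
      row[c("EA", "OA")] <- row[c("OA", "EA")]
    }
    return(row)
  }
  match_same <- (row$EA == ea && row$OA == oa) ||
    (flip_allele(row$EA) == ea && flip_allele(row$OA) == oa)
  match_swap <- (row$EA == oa && row$OA == ea) ||
    (flip_allele(row$EA) == oa && flip_allele(row$OA) == ea)
  if (match_same) return(row)
  if (match_swap) {
    row$BETA <- -row$BETA
    row$EAF <- 1 - row$EAF
    row[c("EA", "OA")] <- row[c("OA", "EA")]
    return(row)
  }
  NULL
}

#' Harmonize exposure and outcome panels onto one allele orientation
#'
#' Aligns every outcome row to the exposure panels' effect-allele
#' convention: identical orientations pass through, swapped alleles flip
#' the sign of the outcome coefficient, palindromic variants (A/T, C/G)
#' are retained only when allele frequencies identify the orientation
#' unambiguously (both minor-allele frequencies below `maf_ambiguous`),
#' and irreconcilable allele pairs are dropped and logged. Variants absent
#' from the outcome panel are substituted by their proxy when a
#' `proxy_map` is supplied.
#'
#' @param exposure_panels named list of exposure summary-statistic frames
#'   (one per exposure, identical SNP sets and orientations).
#' @param outcome_panel outcome summary-statistic frame.
#' @param snp_ids variants to harmonize (default: all exposure SNPs found
#'   in the outcome panel or the proxy map).
#' @param proxy_map named character vector original id -> proxy id.
#' @param maf_ambiguous palindromic ambiguity bound (default 0.42).
#' @return object of class `harmonized_set`: `snp_ids`, matrices
#'   `beta_X`, `se_X`, `p_X` (J x K), vectors `beta_Y`, `se_Y`,
#'   `proxy_map`, and `dropped` (ids removed with the reason).
#' @export
harmonize <- function(exposure_panels, outcome_panel, snp_ids = NULL,
                      proxy_map = NULL, maf_ambiguous = 0.42) {
  if (is.data.frame(exposure_panels)) exposure_panels <- list(exposure_panels)
  K <- length(exposure_panels)
  labs <- names(exposure_panels) %||% paste0("X", seq_len(K))
  ref <- exposure_panels[[1]]
  if (is.null(snp_ids)) snp_ids <- ref$SNP
  proxy_map <- proxy_map[!is.na(proxy_map)]

  out_idx <- function(id) match(id, outcome_panel$SNP)
  used_proxy <- character(0)
  rows_x <- match(snp_ids, ref$SNP)
  if (anyNA(rows_x)) stop("snp_ids missing from the exposure panels")

  keep <- character(0)
  beta_Y <- numeric(0)
  se_Y <- numeric(0)
  dropped <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (id in snp_ids) {
    oid <- id
    if (is.na(out_idx(oid)) && !is.null(proxy_map) && id %in% names(proxy_map)) {
      oid <- proxy_map[[id]]
      used_proxy[id] <- oid
    }
    i <- out_idx(oid)
    if (is.na(i)) {
      dropped <- rbind(dropped, data.frame(snp_id = id,
                                           reason = "absent_from_outcome"))
      next
    }
    # orientation reference: the (possibly proxied) variant's exposure row
    j <- match(oid, ref$SNP)
    if (is.na(j)) {
      dropped <- rbind(dropped, data.frame(snp_id = id,
                                           reason = "proxy_not_in_exposure"))
      next
    }
    aligned <- align_outcome_row(outcome_panel[i, , drop = FALSE],
                                 ref$EA[j], ref$OA[j], ref$EAF[j],
                                 maf_ambiguous)
    if (is.null(aligned)) {
      dropped <- rbind(dropped, data.frame(snp_id = id,
                                           reason = "allele_mismatch"))
      next
    }
    keep <- c(keep, id)
    beta_Y <- c(beta_Y, aligned$BETA)
    se_Y <- c(se_Y, aligned$SE)
  }

  if (length(keep) == 0) stop("harmonize: no reconcilable variants")
  kx <- match(keep, ref$SNP)
  # exposure rows for proxied variants come from the proxy variant
  kx_eff <- ifelse(keep %in% names(used_proxy),
                   match(used_proxy[keep], ref$SNP), kx)
  beta_X <- sapply(exposure_panels, function(p) p$BETA[kx_eff])
  se_X <- sapply(exposure_panels, function(p) p$SE[kx_eff])
  p_X <- sapply(exposure_panels, function(p) p$P[kx_eff])
  if (length(keep) == 1) {
    beta_X <- matrix(beta_X, 1); se_X <- matrix(se_X, 1)
    p_X <- matrix(p_X, 1)
  }
  dimnames(beta_X) <- dimnames(se_X) <- dimnames(p_X) <- list(keep, labs)
  structure(list(snp_ids = keep,
                 beta_X = beta_X, se_X = se_X, p_X = p_X,
                 beta_Y = setNames(beta_Y, keep),
                 se_Y = setNames(se_Y, keep),
                 proxy_map = used_proxy,
                 dropped = dropped),
            class = "harmonized_set")
}

# internal: rewrite an outcome panel onto the exposure orientation; applying
# harmonization to the result is the identity (involutivity)
align_outcome_panel <- function(outcome_panel, reference_panel,
                                maf_ambiguous = 0.42) {
  keep <- logical(nrow(outcome_panel))
  for (i in seq_len(nrow(outcome_panel))) {
    j <- match(outcome_panel$SNP[i], reference_panel$SNP)
    if (is.na(j)) next
    aligned <- align_outcome_row(outcome_panel[i, , drop = FALSE],
                                 reference_panel$EA[j],
                                 reference_panel$OA[j],
                                 reference_panel$EAF[j], maf_ambiguous)
    if (is.null(aligned)) next
    outcome_panel[i, ] <- aligned
    keep[i] <- TRUE
  }
  outcome_panel[keep, , drop = FALSE]
}

#' Subset a harmonized set by SNP id or index
#' @param set a `harmonized_set`.
#' @param ids SNP ids (character) or row indices (integer/logical).
#' @return the subset `harmonized_set`.
#' @export
subset_instruments <- function(set, ids) {
  i <- if (is.character(ids)) match(ids, set$snp_ids) else ids
  structure(list(snp_ids = set$snp_ids[i],
                 beta_X = set$beta_X[i, , drop = FALSE],
                 se_X = set$se_X[i, , drop = FALSE],
                 p_X = set$p_X[i, , drop = FALSE],
                 beta_Y = set$beta_Y[i],
                 se_Y = set$se_Y[i],
                 proxy_map = set$proxy_map,
                 dropped = set$dropped),
            class = "harmonized_set")
}

#' Run the full instrument-selection funnel
#'
#' Chains genome-wide selection, proxy lookup for variants absent from the
#' outcome study, greedy LD clumping, and the confounder screen, recording
#' the count at every stage.
#'
#' @param exposure_panels named list of exposure panels.
#' @param outcome_panel outcome panel.
#' @param ld optional `ld_matrix`; without it clumping and proxy lookup
#'   are skipped (every variant treated as independent).
#' @param catalog optional confounder catalog; `NULL` skips that screen.
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param clump_r2 clumping r-squared threshold (default 0.001).
#' @param proxy_r2 minimum proxy r-squared (default 0.8).
#' @return list with `snp_ids` (final instruments), `proxy_map`, and
#'   `log`, a `selection_log` with the per-stage counts
#'   (genome-wide significant, missing in outcome, proxied, post-LD,
#'   confounder-removed, final).
#' @export
select_instruments <- function(exposure_panels, outcome_panel, ld = NULL,
                               catalog = NULL, p_threshold = 5e-8,
                               clump_r2 = 0.001, proxy_r2 = 0.8) {
  gw <- select_genomewide(exposure_panels, p_threshold)
  missing <- setdiff(gw, outcome_panel$SNP)
  proxy_map <- character(0)
  if (length(missing) > 0 && !is.null(ld)) {
    for (id in missing) {
      pr <- find_proxy(id, ld, outcome_panel$SNP, proxy_r2)
      if (!is.null(pr)) proxy_map[id] <- pr
    }
  }
  usable <- c(setdiff(gw, missing), names(proxy_map))
  usable <- gw[gw %in% usable]  # preserve order

  if (!is.null(ld)) {
    # clump on the exposure-side minimum p-value per variant
    pmin_tab <- Reduce(pmin, lapply(exposure_panels, function(p) {
      p$P[match(usable, p$SNP)]
    }))
    names(pmin_tab) <- usable
    post_ld <- clump(usable, ld, clump_r2, pmin_tab)
  } else {
    post_ld <- usable
  }

  conf <- filter_confounders(post_ld, catalog, p_threshold)
  log <- structure(list(genomewide = length(gw),
                        missing_in_outcome = length(missing),
                        proxied = length(proxy_map),
                        post_ld = length(post_ld),
                        confounder_removed = length(conf$dropped),
                        final = length(conf$kept)),
                   class = "selection_log")
  list(snp_ids = conf$kept, proxy_map = proxy_map, log = log)
}

#' @export
format.selection_log <- function(x, ...) {
  paste0("instrument selection funnel: ", x$genomewide,
         " genome-wide significant; ", x$missing_in_outcome,
         " missing in outcome (", x$proxied, " proxied); ",
         x$post_ld, " after LD clumping; ", x$confounder_removed,
         " removed as confounder-associated; ", x$final, " final")
}

#' @export
print.selection_log <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Overall instrument-strength F-statistic
#'
#' F = (R2/k) / ((1 - R2) / (n - k - 1)), where R2 is the fraction of
#' exposure variance explained by the k instruments in a study of size n.
#' F at or above 10 conventionally indicates negligible weak-instrument
#' bias.
#'
#' @param r2 variance explained, in (0, 1).
#' @param n exposure-study sample size.
#' @param k number of instruments; requires n > k + 1 >= 2.
#' @return the F value.
#' @export
f_statistic <- function(r2, n, k) {
  stopifnot(r2 > 0, r2 < 1, k >= 1, n > k + 1)
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Single-variant instrument-strength approximation
#'
#' The first-order per-SNP F, the squared z-score (beta/se)^2.
#'
#' @param beta,se the variant's exposure effect and standard error
#'   (`se > 0`).
#' @return the per-SNP F value (always non-negative).
#' @export
per_snp_f <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Power of a two-sample MR test with a binary outcome
#'
#' Normal-approximation power for detecting a causal odds ratio with k
#' instruments jointly explaining `r2_sum` of the exposure variance:
#' power = Phi(|ln OR| * sqrt(n * r2_sum * ratio * (1 - ratio)) -
#' z_(1-alpha/2)), with `ratio` the case fraction of the outcome study.
#'
#' @param n_outcome outcome-study size.
#' @param case_ratio case fraction, in (0, 1).
#' @param r2_sum exposure variance explained by the instruments, in (0, 1).
#' @param odds_ratio causal odds ratio per SD of exposure (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return power in \[0, 1\].
#' @export
mr_power <- function(n_outcome, case_ratio, r2_sum, odds_ratio,
                     alpha = 0.05) {
  stopifnot(case_ratio > 0, case_ratio < 1, r2_sum > 0, r2_sum < 1,
            odds_ratio > 0, n_outcome > 0, alpha > 0, alpha < 1)
  ncp <- abs(log(odds_ratio)) *
    sqrt(n_outcome * r2_sum * case_ratio * (1 - case_ratio))
  pnorm(ncp - qnorm(1 - alpha / 2))
}
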