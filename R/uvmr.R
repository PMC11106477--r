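#' Wald ratio causal estimate for a single variant
#'
#' @param beta_x,se_x variant-exposure association and its SE.
#' @param beta_y,se_y variant-outcome association and its SE.
#' @return list with `estimate` (beta_y / beta_x) and first-order
#'   delta-method `se` (se_y / |beta_x|).
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (any(beta_x == 0)) stop("wald_ratio: zero exposure effect")
  list(estimate = beta_y / beta_x, se = se_y / abs(beta_x))
}

uvmr_result <- function(method, estimate, se, pvalue = NULL, n_snps,
                        q_stat = NA_real_, q_pvalue = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_p = NA_real_) {
  estimate <- unname(estimate)
  se <- unname(se)
  z <- qnorm(0.975)
  ci_low <- estimate - z * se
  ci_high <- estimate + z * se
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(estimate / se))
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
                 or = exp(estimate), or_ci_low = exp(ci_low),
                 or_ci_high = exp(ci_high), n_snps = n_snps,
                 q_stat = q_stat, q_pvalue = q_pvalue,
                 egger_intercept = egger_intercept,
                 egger_intercept_p = egger_intercept_p),
            class = "uvmr_result")
}

#' @export
print.uvmr_result <- function(x, ...) {
  cat(sprintf("%s: logOR %.4f (SE %.4f), OR %.3f [%.3f, %.3f], p = %.3g, %d SNPs\n",
              x$method, x$estimate, x$se, x$or, x$or_ci_low, x$or_ci_high,
              x$pvalue, x$n_snps))
  invisible(x)
}

get_exposure_vectors <- function(set, exposure) {
  k <- if (is.character(exposure)) match(exposure, colnames(set$beta_X)) else exposure
  list(bx = set$beta_X[, k], sx = set$se_X[, k],
       by = set$beta_Y, sy = set$se_Y)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of outcome on exposure coefficients through the
#' origin: estimate = sum(bx * by / sy^2) / sum(bx^2 / sy^2). The fixed-
#' effects SE is 1/sqrt(sum(bx^2 / sy^2)); the multiplicative random-
#' effects SE scales it by max(1, sqrt(Q / (J - 1))) so heterogeneity never
#' shrinks the uncertainty. Confidence intervals and p-values use the
#' normal reference.
#'
#' @param set a `harmonized_set` (or pass vectors via `bx`, `by`, `sy`).
#' @param exposure exposure name or column index.
#' @param mode `"random"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @param bx,by,sy optional explicit vectors overriding `set`/`exposure`.
#' @return a `uvmr_result` including Cochran's Q and its p-value.
#' @export
mr_ivw <- function(set = NULL, exposure = NULL,
                   mode = c("random", "fixed"),
                   bx = NULL, by = NULL, sy = NULL) {
  mode <- match.arg(mode)
  if (is.null(bx)) {
    v <- get_exposure_vectors(set, exposure)
    bx <- v$bx; by <- v$by; sy <- v$sy
  }
  J <- length(bx)
  if (J < 2) stop("mr_ivw needs at least 2 SNPs; use wald_ratio for one")
  w <- bx^2 / sy^2
  est <- sum(bx * by / sy^2) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (by / bx - est)^2)
  se <- if (mode == "random") se_fixed * max(1, sqrt(q / (J - 1))) else se_fixed
  uvmr_result(paste0("ivw_", mode), est, se, n_snps = J, q_stat = q,
              q_pvalue = pchisq(q, J - 1, lower.tail = FALSE))
}

# weighted 50th percentile of per-SNP ratios (Bowden's interpolation)
weighted_median_estimate <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(r[1])
  n <- length(r)
  if (cum[n] <= 0.5) return(r[n])
  i <- max(which(cum < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - cum[i]) / (cum[i + 1] - cum[i])
}

median_weights <- function(bx, by, sy, variant, penalty = 20) {
  ratios <- by / bx
  se_ratio <- sy / abs(bx)
  w <- switch(variant,
              simple = rep(1, length(bx)),
              weighted = ,
              penalized = 1 / se_ratio^2)
  if (variant == "penalized") {
    est0 <- weighted_median_estimate(ratios, w)
    qj <- w * (ratios - est0)^2
    pj <- pchisq(qj, df = 1, lower.tail = FALSE)
    w <- w * pmin(1, penalty * pj)
  }
  w
}

#' Median-based causal estimators
#'
#' Simple (unweighted), weighted (inverse-variance of the per-SNP Wald
#' ratios), or penalized weighted median, where the penalized variant
#' multiplies each weight by min(1, penalty * p_j) with p_j the upper
#' chi-square(1) tail of the SNP's heterogeneity contribution about the
#' weighted median. The SE comes from a seeded parametric bootstrap
#' (resampling beta_x and beta_y from their standard errors) with a
#' normal-theory CI from the bootstrap SD.
#'
#' @inheritParams mr_ivw
#' @param variant `"simple"`, `"weighted"` or `"penalized"`.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param penalty penalization constant (default 20).
#' @param sx optional exposure SEs when passing explicit vectors.
#' @return a `uvmr_result`.
#' @export
mr_median <- function(set = NULL, exposure = NULL,
                      variant = c("weighted", "simple", "penalized"),
                      n_boot = 1000, seed = 1L, penalty = 20,
                      bx = NULL, sx = NULL, by = NULL, sy = NULL) {
  variant <- match.arg(variant)
  if (is.null(bx)) {
    v <- get_exposure_vectors(set, exposure)
    bx <- v$bx; sx <- v$sx; by <- v$by; sy <- v$sy
  }
  J <- length(bx)
  if (J < 3) stop("mr_median needs at least 3 SNPs")
  est <- weighted_median_estimate(by / bx, median_weights(bx, by, sy,
                                                          variant, penalty))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bxi <- rnorm(J, bx, sx)
    byi <- rnorm(J, by, sy)
    ok <- bxi != 0
    weighted_median_estimate((byi / bxi)[ok],
                             median_weights(bxi[ok], byi[ok], sy[ok],
                                            variant, penalty))
  }, numeric(1))
  uvmr_result(paste0("median_", variant), est, sd(boots), n_snps = J)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome coefficients on the exposure
#' coefficients with an intercept (weights 1/se_y^2), after orienting all
#' exposure effects to be non-negative. The slope is the pleiotropy-
#' corrected causal estimate; the intercept and its p-value test for
#' directional pleiotropy. Standard errors carry the multiplicative
#' residual scaling max(1, sigma) so heterogeneity never shrinks them.
#'
#' @inheritParams mr_ivw
#' @return a `uvmr_result` with `egger_intercept` and
#'   `egger_intercept_p` filled in.
#' @export
mr_egger <- function(set = NULL, exposure = NULL,
                     bx = NULL, by = NULL, sy = NULL) {
  if (is.null(bx)) {
    v <- get_exposure_vectors(set, exposure)
    bx <- v$bx; by <- v$by; sy <- v$sy
  }
  J <- length(bx)
  if (J < 3) stop("mr_egger needs at least 3 SNPs")
  s <- ifelse(bx < 0, -1, 1)
  bx <- bx * s
  by <- by * s
  if (max(bx) - min(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    stop("mr_egger: exposure effects are all equal, slope not identifiable")
  }
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  X <- cbind(1, bx)
  w <- 1 / sy^2
  V <- solve(crossprod(X, w * X))
  sigma <- sqrt(sum(w * fit$residuals^2) / (J - 2))
  se0 <- sqrt(diag(V)) * max(1, sigma)  # multiplicative scaling, floored at 1
  slope <- unname(coef(fit)["bx"])
  slope_se <- se0[2]
  int <- unname(coef(fit)["(Intercept)"])
  int_se <- se0[1]
  uvmr_result("egger", slope, slope_se, n_snps = J,
              egger_intercept = int,
              egger_intercept_p = 2 * pnorm(-abs(int / int_se)))
}

#' Cochran's Q heterogeneity statistic for a set of instruments
#'
#' Q = sum_j w_j (ratio_j - estimate)^2 with inverse-variance ratio
#' weights w_j = bx_j^2 / sy_j^2; p < 0.05 indicates significant
#' heterogeneity among the per-SNP causal estimates.
#'
#' @inheritParams mr_ivw
#' @param estimate the pooled causal estimate to measure dispersion about
#'   (default: the fixed-effects IVW estimate of the same data).
#' @return list with `Q`, `df` (J - 1), `pvalue`, and the per-SNP
#'   `contributions` q_j (summing to Q).
#' @export
cochran_q <- function(set = NULL, exposure = NULL, estimate = NULL,
                      bx = NULL, by = NULL, sy = NULL) {
  if (is.null(bx)) {
    v <- get_exposure_vectors(set, exposure)
    bx <- v$bx; by <- v$by; sy <- v$sy
  }
  J <- length(bx)
  if (J < 2) stop("cochran_q needs at least 2 SNPs")
  w <- bx^2 / sy^2
  if (is.null(estimate)) estimate <- sum(bx * by / sy^2) / sum(w)
  qj <- w * (by / bx - estimate)^2
  Q <- sum(qj)
  list(Q = Q, df = J - 1, pvalue = pchisq(Q, J - 1, lower.tail = FALSE),
       contributions = qj)
}

uvmr_methods <- c("ivw_random", "ivw_fixed", "median_simple",
                  "median_weighted", "median_penalized", "egger")

run_one_uvmr <- function(bx, sx, by, sy, method, seed) {
  switch(method,
         ivw_random = mr_ivw(bx = bx, by = by, sy = sy, mode = "random"),
         ivw_fixed = mr_ivw(bx = bx, by = by, sy = sy, mode = "fixed"),
         median_simple = mr_median(bx = bx, sx = sx, by = by, sy = sy,
                                   variant = "simple", seed = seed),
         median_weighted = mr_median(bx = bx, sx = sx, by = by, sy = sy,
                                     variant = "weighted", seed = seed),
         median_penalized = mr_median(bx = bx, sx = sx, by = by, sy = sy,
                                      variant = "penalized", seed = seed),
         egger = mr_egger(bx = bx, by = by, sy = sy))
}

#' Run all six univariable MR estimators over every exposure and outcome
#'
#' For each exposure the instruments are the harmonized variants reaching
#' genome-wide significance for that exposure; all six estimators are
#' applied per exposure-outcome pair. Significance is flagged at the
#' Bonferroni-corrected level alpha / (K exposures x number of outcomes).
#' Per-cell failures (e.g. too few instruments) are recorded as NA rows
#' with a note; the grid never aborts.
#'
#' @param sets named list of `harmonized_set` objects, one per outcome.
#' @param alpha family-wise significance level (default 0.05).
#' @param p_threshold instrument-relevance threshold per exposure
#'   (default 5e-8).
#' @param n_boot,seed bootstrap controls passed to the median estimators.
#' @return data frame of class `uvmr_grid`, one row per exposure-method-
#'   outcome, with the Bonferroni threshold in attribute
#'   `bonferroni_alpha`.
#' @export
run_uvmr_grid <- function(sets, alpha = 0.05, p_threshold = 5e-8,
                          n_boot = 1000, seed = 1L) {
  stopifnot(length(sets) >= 1)
  K <- ncol(sets[[1]]$beta_X)
  bon <- alpha / (K * length(sets))
  rows <- list()
  for (outcome in names(sets)) {
    set <- sets[[outcome]]
    for (k in seq_len(K)) {
      label <- colnames(set$beta_X)[k]
      inst <- which(set$p_X[, k] < p_threshold)
      for (m in uvmr_methods) {
        res <- tryCatch(
          run_one_uvmr(set$beta_X[inst, k], set$se_X[inst, k],
                       set$beta_Y[inst], set$se_Y[inst], m, seed),
          error = function(e) e)
        if (inherits(res, "error")) {
          rows[[length(rows) + 1]] <- data.frame(
            exposure = label, outcome = outcome, method = m,
            estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
            ci_high = NA_real_, pvalue = NA_real_, or = NA_real_,
            or_ci_low = NA_real_, or_ci_high = NA_real_,
            n_snps = length(inst), q_stat = NA_real_,
            q_pvalue = NA_real_, egger_intercept = NA_real_,
            egger_intercept_p = NA_real_, bonferroni_significant = NA,
            note = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1]] <- data.frame(
            exposure = label, outcome = outcome, method = m,
            estimate = res$estimate, se = res$se, ci_low = res$ci_low,
            ci_high = res$ci_high, pvalue = res$pvalue, or = res$or,
            or_ci_low = res$or_ci_low, or_ci_high = res$or_ci_high,
            n_snps = res$n_snps, q_stat = res$q_stat,
            q_pvalue = res$q_pvalue,
            egger_intercept = res$egger_intercept,
            egger_intercept_p = res$egger_intercept_p,
            bonferroni_significant = res$pvalue < bon,
            note = "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_alpha") <- bon
  class(out) <- c("uvmr_grid", "data.frame")
  out
}

#' Bonferroni-corrected significance threshold for the trait grid
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_exposures number of exposures tested (default 15).
#' @param n_outcomes number of outcomes tested (default 2).
#' @return alpha / (n_exposures * n_outcomes); 0.05 / 30 for the full
#'   blood-count panel against CD and UC.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_exposures = 15,
                                 n_outcomes = 2) {
  stopifnot(alpha > 0, n_exposures >= 1, n_outcomes >= 1)
  alpha / (n_exposures * n_outcomes)
}
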