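#' Restricted (natural) cubic spline basis
#'
#' Truncated-power natural-spline basis constrained to linearity beyond
#' the boundary knots: m knots yield m - 1 columns, the first the linear
#' term, the remaining m - 2 cubic terms scaled by the squared boundary
#' span for numerical stability. Below the first knot every cubic term is
#' exactly zero; the second derivative vanishes at and beyond both
#' boundary knots.
#'
#' @param x numeric values (finite).
#' @param knots at least 3 strictly increasing knot locations.
#' @return matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  if (any(!is.finite(x))) stop("x must be finite")
  m <- length(knots)
  if (m < 3) stop("at least 3 knots required")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  cub <- function(u) pmax(u, 0)^3
  k_last <- knots[m]
  k_pen <- knots[m - 1]
  span2 <- (k_last - knots[1])^2
  out <- matrix(0, length(x), m - 1)
  out[, 1] <- x
  for (j in seq_len(m - 2)) {
    kj <- knots[j]
    out[, j + 1] <- (cub(x - kj) -
                       cub(x - k_pen) * (k_last - kj) / (k_last - k_pen) +
                       cub(x - k_last) * (k_pen - kj) / (k_last - k_pen)) /
      span2
  }
  colnames(out) <- c("linear", if (m > 2) paste0("cubic", seq_len(m - 2)))
  out
}

# Harrell's default knot percentiles by knot count
harrell_knot_quantiles <- function(n_knots) {
  switch(as.character(n_knots),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
         "7" = c(0.025, 0.1833, 0.3417, 0.5, 0.6583, 0.8167, 0.975),
         stop("n_knots must be between 3 and 7"))
}

#' Restricted-cubic-spline logistic dose-response fit
#'
#' Logistic regression of case status (one case group versus healthy) on
#' the restricted-cubic-spline basis of a blood-count trait, with knots at
#' Harrell's default percentiles of the pooled trait values. The reported
#' curve is the log odds ratio relative to a reference trait value
#' (default: the healthy-group median), with a pointwise delta-method 95%
#' confidence band; trait values where a band boundary crosses zero are
#' candidate clinical risk-assessment thresholds.
#'
#' @param cohort a cohort data frame with a `group` column (levels
#'   healthy/CD/UC) and one column per trait.
#' @param trait trait column name.
#' @param case_group `"CD"` or `"UC"`.
#' @param n_knots number of spline knots (default 4).
#' @param reference_value trait value where logOR is anchored to 0
#'   (default: healthy-group median).
#' @param n_grid evaluation grid size (default 300, minimum 200).
#' @param adjust also adjust for age and sex (default FALSE).
#' @return object of class `rcs_fit` with fields `trait`, `outcome`,
#'   `knots`, `coefficients`, `reference_value`, `grid`, `log_or`,
#'   `ci_low`, `ci_high`, `crossings`, `separation` (TRUE when the fit
#'   showed signs of separation and SEs are inflated).
#' @export
fit_rcs_logistic <- function(cohort, trait, case_group = c("CD", "UC"),
                             n_knots = 4, reference_value = NULL,
                             n_grid = 300, adjust = FALSE) {
  case_group <- match.arg(case_group)
  stopifnot(trait %in% names(cohort), n_grid >= 200)
  sub <- cohort[cohort$group %in% c("healthy", case_group), , drop = FALSE]
  x <- sub[[trait]]
  y <- as.integer(sub$group == case_group)
  if (sum(y) == 0 || sum(1 - y) == 0) stop("both groups must be non-empty")
  if (sd(x) == 0) stop("trait has zero variance")
  knots <- unique(quantile(x, harrell_knot_quantiles(n_knots), names = FALSE))
  if (length(knots) < 3) stop("degenerate knots: trait too discrete")
  B <- rcs_basis(x, knots)
  df <- data.frame(y = y, B)
  form <- y ~ .
  if (adjust) {
    df$age <- sub$age
    df$sex <- factor(sub$sex)
  }
  fit <- suppressWarnings(glm(form, data = df, family = binomial()))
  separation <- !fit$converged ||
    any(abs(coef(fit)[colnames(B)]) > 1e3) ||
    any(sqrt(diag(vcov(fit)))[colnames(B)] > 1e3)
  if (separation) {
    warning("possible separation in ", trait, " vs ", case_group,
            ": standard errors are inflated")
  }
  if (is.null(reference_value)) {
    reference_value <- median(cohort[[trait]][cohort$group == "healthy"])
  }
  grid <- seq(min(x), max(x), length.out = n_grid)
  Bg <- rcs_basis(grid, knots)
  Br <- rcs_basis(reference_value, knots)
  Cmat <- sweep(Bg, 2, as.numeric(Br))  # basis contrast; intercept cancels
  beta <- coef(fit)[colnames(B)]
  V <- vcov(fit)[colnames(B), colnames(B)]
  log_or <- drop(Cmat %*% beta)
  se <- sqrt(pmax(rowSums((Cmat %*% V) * Cmat), 0))
  z <- qnorm(0.975)
  out <- structure(list(trait = trait, outcome = case_group,
                        knots = knots,
                        coefficients = coef(fit),
                        reference_value = reference_value,
                        grid = grid, log_or = log_or,
                        ci_low = log_or - z * se,
                        ci_high = log_or + z * se,
                        separation = separation),
                   class = "rcs_fit")
  out$crossings <- find_crossings(out)
  out
}

#' Zero crossings of the confidence band of a dose-response fit
#'
#' Linear-interpolated trait values where the lower or upper 95% band
#' boundary changes sign, reported to 2 decimals. These are the
#' intersection points between the band and the zero-logOR line used as
#' clinical risk-assessment thresholds; an empty result means the band
#' never crosses zero.
#'
#' @param fit an `rcs_fit` (grid of at least 200 points).
#' @return numeric vector of crossing trait values (possibly empty), with
#'   names `"low"`/`"high"` marking which boundary crossed.
#' @export
find_crossings <- function(fit) {
  stopifnot(length(fit$grid) >= 200)
  one_band <- function(yv) {
    s <- sign(yv)
    idx <- which(s[-1] * s[-length(s)] < 0)
    interp <- vapply(idx, function(i) {
      x0 <- fit$grid[i]; x1 <- fit$grid[i + 1]
      y0 <- yv[i]; y1 <- yv[i + 1]
      x0 - y0 * (x1 - x0) / (y1 - y0)
    }, numeric(1))
    exact <- fit$grid[s == 0]  # boundary touches zero at a grid point
    sort(c(interp, exact))
  }
  lo <- one_band(fit$ci_low)
  hi <- one_band(fit$ci_high)
  out <- round(c(lo, hi), 2)
  names(out) <- c(rep("low", length(lo)), rep("high", length(hi)))
  out[order(out)]
}

#' Two-sample location comparison of a trait between cohort groups
#'
#' Rank-based (Wilcoxon) comparison with a direction flag giving the sign
#' of the second group's median relative to the first.
#'
#' @param cohort a cohort data frame.
#' @param trait trait column name.
#' @param groups length-2 character vector, reference group first.
#' @return object of class `group_comparison`: `trait`, `groups`,
#'   `medians`, `statistic`, `pvalue`, `direction` (+1 when group 2 is
#'   higher, -1 lower, 0 tied).
#' @export
group_compare <- function(cohort, trait, groups = c("healthy", "CD")) {
  stopifnot(length(groups) == 2, trait %in% names(cohort))
  x1 <- cohort[[trait]][cohort$group == groups[1]]
  x2 <- cohort[[trait]][cohort$group == groups[2]]
  if (length(x1) < 2 || length(x2) < 2) stop("both groups need >= 2 members")
  if (sd(c(x1, x2)) == 0) stop("degenerate trait variance")
  wt <- wilcox.test(x2, x1, exact = FALSE)
  med <- c(median(x1), median(x2))
  structure(list(trait = trait, groups = groups,
                 medians = setNames(med, groups),
                 statistic = unname(wt$statistic),
                 pvalue = wt$p.value,
                 direction = sign(med[2] - med[1])),
            class = "group_comparison")
}

#' Dose-response and group-comparison summary for every trait
#'
#' @param cohort a cohort data frame.
#' @param case_group `"CD"` or `"UC"`.
#' @param traits trait columns (default: the 15 blood-count traits).
#' @param ... passed to [fit_rcs_logistic()].
#' @return list with `fits` (named list of `rcs_fit`), `crossings`
#'   (data frame trait/boundary/value), and `comparisons` (data frame of
#'   group tests).
#' @export
rcs_summary <- function(cohort, case_group = c("CD", "UC"),
                        traits = intersect(CBC_TRAITS, names(cohort)),
                        ...) {
  case_group <- match.arg(case_group)
  fits <- lapply(traits, function(tr) {
    tryCatch(fit_rcs_logistic(cohort, tr, case_group, ...),
             error = function(e) NULL)
  })
  names(fits) <- traits
  crossings <- do.call(rbind, lapply(traits, function(tr) {
    f <- fits[[tr]]
    if (is.null(f) || length(f$crossings) == 0) return(NULL)
    data.frame(trait = tr, boundary = names(f$crossings),
               value = unname(f$crossings), stringsAsFactors = FALSE)
  }))
  comparisons <- do.call(rbind, lapply(traits, function(tr) {
    gc <- tryCatch(group_compare(cohort, tr, c("healthy", case_group)),
                   error = function(e) NULL)
    if (is.null(gc)) return(NULL)
    data.frame(trait = tr, pvalue = gc$pvalue, direction = gc$direction,
               stringsAsFactors = FALSE)
  }))
  list(fits = fits, crossings = crossings, comparisons = comparisons)
}
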