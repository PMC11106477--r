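#' Configuration for multivariable MR with Bayesian model averaging
#'
#' @param prior_inclusion_prob prior probability that any one exposure is
#'   causal (default 0.1).
#' @param prior_effect_sd prior standard deviation of each included causal
#'   coefficient on the inverse-variance-standardized scale (default 0.25).
#' @param max_model_size largest exposure subset enumerated (default 12;
#'   set to K for the full model space).
#' @param pp_threshold posterior-probability cutoff defining the "best
#'   models" whose diagnostics drive pruning (default 0.02).
#' @param q_threshold per-SNP heterogeneity contribution above which an
#'   instrument is deemed an outlier (default 10).
#' @param cd_quantile F-distribution quantile defining the Cook's-distance
#'   influence cutoff (default 0.5, the F median).
#' @param max_prune_rounds maximum pruning iterations (default 10).
#' @return an object of class `bma_config`.
#' @export
bma_config <- function(prior_inclusion_prob = 0.1,
                       prior_effect_sd = 0.25,
                       max_model_size = 12,
                       pp_threshold = 0.02,
                       q_threshold = 10,
                       cd_quantile = 0.5,
                       max_prune_rounds = 10) {
  stopifnot(prior_inclusion_prob > 0, prior_inclusion_prob < 1,
            prior_effect_sd > 0, max_model_size >= 1,
            pp_threshold > 0, q_threshold > 0,
            cd_quantile > 0, cd_quantile < 1, max_prune_rounds >= 1)
  structure(as.list(environment()), class = "bma_config")
}

#' Inverse-variance standardization for multivariable MR
#'
#' Divides every SNP's outcome coefficient and exposure-coefficient row by
#' the outcome SE, yielding a regression problem with (approximately) unit
#' residual variance and no intercept: response_j = beta_Yj / se_Yj,
#' design_jk = beta_Xjk / se_Yj.
#'
#' @param set a `harmonized_set`.
#' @return list with `response` (length J) and `design` (J x K matrix).
#' @export
bma_transform <- function(set) {
  design <- set$beta_X / set$se_Y
  if (any(colSums(abs(design)) == 0)) {
    stop("bma_transform: design has an all-zero exposure column")
  }
  list(response = unname(set$beta_Y / set$se_Y),
       design = unname(as.matrix(design)))
}

#' Log marginal likelihood of one exposure subset
#'
#' Conjugate Gaussian model on the standardized scale: response ~
#' N(X_S theta, I) with independent N(0, sigma^2) priors on each included
#' coefficient, so the marginal is N(0, I + sigma^2 X_S X_S') with the
#' closed form evaluated through the k x k Gram matrix.
#'
#' @param subset integer indices of the included exposures (non-empty).
#' @param response,design standardized data from [bma_transform()].
#' @param sigma prior effect SD.
#' @return the log marginal likelihood.
#' @export
log_marginal_likelihood <- function(subset, response, design, sigma) {
  stopifnot(length(subset) >= 1)
  X <- design[, subset, drop = FALSE]
  J <- length(response)
  A <- crossprod(X) + diag(1 / sigma^2, length(subset))
  ch <- tryCatch(chol(A), error = function(e) {
    stop("log_marginal_likelihood: singular subset design")
  })
  Xty <- crossprod(X, response)
  quad <- sum(response^2) - sum(backsolve(ch, Xty, transpose = TRUE)^2)
  # log det(I + sigma^2 X'X) = log det(A) + k log(sigma^2)
  logdet <- 2 * sum(log(diag(ch))) + length(subset) * 2 * log(sigma)
  -J / 2 * log(2 * pi) - logdet / 2 - quad / 2
}

subset_key <- function(idx) paste(idx, collapse = ",")

#' Enumerate the exposure model space and average over it
#'
#' Computes, for every non-empty exposure subset up to
#' `config$max_model_size`, the posterior model probability
#' PP_m proportional to p^|m| (1-p)^(K-|m|) exp(logML_m), normalized over
#' the enumerated space; the subset-specific causal estimates
#' (least squares on the standardized data restricted to the subset); the
#' per-exposure marginal inclusion probability MIP_k (sum of PP over
#' models containing k); and the model-averaged causal estimate MACE_k
#' (PP-weighted average of the subset estimates over models containing k).
#'
#' @param response,design standardized data from [bma_transform()].
#' @param config a [bma_config()].
#' @return object of class `bma_posterior`: `models` (data frame ranked by
#'   PP with subset key, size, pp, log marginal), `theta` (list of named
#'   subset-estimate vectors parallel to `models`), `mip` and `mace`
#'   (named per-exposure vectors), `exposures`, `config`.
#' @export
enumerate_posterior <- function(response, design, config = bma_config()) {
  K <- ncol(design)
  labs <- colnames(design) %||% paste0("X", seq_len(K))
  J <- length(response)
  if (J <= ncol(design)) {
    warning("fewer SNPs than exposures; subset estimates may be unstable")
  }
  dmax <- min(config$max_model_size, K)
  n_models <- sum(choose(K, seq_len(dmax)))
  if (n_models > 2^20) stop("model space too large to enumerate")

  XtX <- crossprod(design)
  Xty <- drop(crossprod(design, response))
  yty <- sum(response^2)
  s2 <- config$prior_effect_sd^2
  lp_in <- log(config$prior_inclusion_prob)
  lp_out <- log1p(-config$prior_inclusion_prob)

  subsets <- vector("list", n_models)
  logml <- numeric(n_models)
  logprior <- numeric(n_models)
  theta <- vector("list", n_models)
  i <- 0
  for (d in seq_len(dmax)) {
    cmb <- combn(K, d)
    for (c in seq_len(ncol(cmb))) {
      S <- cmb[, c]
      i <- i + 1
      A <- XtX[S, S, drop = FALSE] + diag(1 / s2, d)
      ch <- chol(A)
      quad <- yty - sum(backsolve(ch, Xty[S], transpose = TRUE)^2)
      logdet <- 2 * sum(log(diag(ch))) + d * log(s2)
      subsets[[i]] <- S
      logml[i] <- -J / 2 * log(2 * pi) - logdet / 2 - quad / 2
      logprior[i] <- d * lp_in + (K - d) * lp_out
      th <- tryCatch(drop(solve(XtX[S, S, drop = FALSE], Xty[S])),
                     error = function(e) {
                       # rank-deficient subset (e.g. duplicated exposures):
                       # minimal-norm least squares
                       drop(MASS::ginv(XtX[S, S, drop = FALSE]) %*% Xty[S])
                     })
      theta[[i]] <- setNames(th, labs[S])
    }
  }
  lp <- logml + logprior
  pp <- exp(lp - max(lp))
  pp <- pp / sum(pp)

  mip <- setNames(numeric(K), labs)
  mace <- setNames(numeric(K), labs)
  for (i in seq_len(n_models)) {
    S <- subsets[[i]]
    mip[S] <- mip[S] + pp[i]
    mace[S] <- mace[S] + pp[i] * theta[[i]]
  }

  o <- order(pp, decreasing = TRUE)
  models <- data.frame(
    model = vapply(subsets, function(s) subset_key(labs[s]), character(1)),
    size = lengths(subsets),
    pp = pp,
    log_marginal = logml,
    stringsAsFactors = FALSE)[o, ]
  rownames(models) <- NULL
  structure(list(models = models,
                 subsets = subsets[o],
                 theta = theta[o],
                 mip = mip, mace = mace,
                 exposures = labs,
                 config = config),
            class = "bma_posterior")
}

#' @export
print.bma_posterior <- function(x, n = 10, ...) {
  cat("Multivariable MR Bayesian model averaging over",
      nrow(x$models), "models\n")
  cat("Top models by posterior probability:\n")
  print(head(x$models[, c("model", "pp")], n), digits = 3)
  cat("\nMarginal inclusion probabilities and averaged estimates:\n")
  tab <- data.frame(mip = x$mip, mace = x$mace)
  print(tab[order(-tab$mip), ], digits = 3)
  invisible(x)
}

#' Rank exposures by marginal inclusion probability
#' @param posterior a `bma_posterior`.
#' @return data frame with `exposure`, `mip`, `mace`, sorted by MIP.
#' @export
bma_rank_exposures <- function(posterior) {
  out <- data.frame(exposure = posterior$exposures,
                    mip = unname(posterior$mip),
                    mace = unname(posterior$mace),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mip), ]
  rownames(out) <- NULL
  out
}

subset_fit <- function(subset, response, design) {
  X <- design[, subset, drop = FALSE]
  th <- drop(solve(crossprod(X), crossprod(X, response)))
  fitted <- drop(X %*% th)
  list(theta = th, fitted = fitted, residuals = response - fitted, X = X)
}

#' Per-SNP heterogeneity contributions under a subset model
#'
#' Squared standardized residuals of the least-squares fit of the chosen
#' exposure subset; on the inverse-variance-standardized scale these sum
#' to the model's Cochran Q.
#'
#' @param subset integer exposure indices of the fitted model.
#' @param response,design standardized data from [bma_transform()].
#' @return numeric vector q_j, one per SNP.
#' @export
snp_q_contributions <- function(subset, response, design) {
  subset_fit(subset, response, design)$residuals^2
}

#' Cook's distance of each SNP under a subset model
#'
#' Classical leverage-based influence: Cd_j = r_j^2 h_j /
#' (d s^2 (1 - h_j)^2) with h_j the hat-matrix diagonal, d the number of
#' predictors and s^2 the residual mean square. The conventional exclusion
#' cutoff is the median of the F(d, J - d) distribution
#' ([cooks_threshold()]).
#'
#' @inheritParams snp_q_contributions
#' @return numeric vector Cd_j, one per SNP.
#' @export
cooks_distance_mr <- function(subset, response, design) {
  f <- subset_fit(subset, response, design)
  d <- length(subset)
  J <- length(response)
  if (J <= d) stop("cooks_distance_mr requires more SNPs than predictors")
  h <- rowSums((f$X %*% solve(crossprod(f$X))) * f$X)
  s2 <- sum(f$residuals^2) / (J - d)
  f$residuals^2 * h / (d * s2 * (1 - h)^2)
}

#' @rdname cooks_distance_mr
#' @param d model size, `J` number of SNPs, `quantile` the F quantile.
#' @param J number of SNPs.
#' @param quantile F-distribution quantile (default 0.5).
#' @export
cooks_threshold <- function(d, J, quantile = 0.5) qf(quantile, d, J - d)

#' Iteratively prune outlying and influential instruments
#'
#' Repeats: fit the Bayesian model average, take every model with
#' posterior probability above `config$pp_threshold` (or the single top
#' model when none exceeds it), compute per-SNP heterogeneity
#' contributions and Cook's distances under each, and drop every SNP whose
#' q exceeds `config$q_threshold` or whose Cook's distance exceeds the
#' F(d, J - d) quantile in any of those models. Stops when a round removes
#' nothing or `config$max_prune_rounds` is reached.
#'
#' @param set a `harmonized_set`.
#' @param config a [bma_config()].
#' @return list with `set` (pruned instruments), `posterior` (final
#'   `bma_posterior`), `initial_posterior` (before any pruning, for the
#'   consistency comparison), `audit` (data frame: round, snp_id, reason,
#'   value), and `rounds_run`.
#' @export
iterative_prune <- function(set, config = bma_config()) {
  audit <- data.frame(round = integer(0), snp_id = character(0),
                      reason = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  current <- set
  initial_posterior <- NULL
  posterior <- NULL
  round <- 0
  repeat {
    td <- bma_transform(current)
    colnames(td$design) <- colnames(current$beta_X)
    posterior <- enumerate_posterior(td$response, td$design, config)
    if (is.null(initial_posterior)) initial_posterior <- posterior
    if (round >= config$max_prune_rounds) break
    best <- which(posterior$models$pp > config$pp_threshold)
    if (length(best) == 0) best <- 1L
    J <- length(td$response)
    offender <- rep(FALSE, J)
    reason <- rep(NA_character_, J)
    value <- rep(NA_real_, J)
    for (b in best) {
      S <- posterior$subsets[[b]]
      qj <- snp_q_contributions(S, td$response, td$design)
      cd <- cooks_distance_mr(S, td$response, td$design)
      thr <- cooks_threshold(length(S), J, config$cd_quantile)
      bad_q <- qj > config$q_threshold
      bad_cd <- cd > thr
      newq <- bad_q & !offender
      offender <- offender | bad_q
      reason[newq] <- "Q"
      value[newq] <- qj[newq]
      newc <- bad_cd & !offender
      offender <- offender | bad_cd
      reason[newc] <- "Cd"
      value[newc] <- cd[newc]
    }
    if (!any(offender)) break
    round <- round + 1
    audit <- rbind(audit, data.frame(round = round,
                                     snp_id = current$snp_ids[offender],
                                     reason = reason[offender],
                                     value = value[offender],
                                     stringsAsFactors = FALSE))
    if (sum(!offender) <= ncol(current$beta_X)) {
      stop("iterative_prune: pruning would leave too few instruments")
    }
    current <- subset_instruments(current, which(!offender))
  }
  list(set = current, posterior = posterior,
       initial_posterior = initial_posterior,
       audit = audit, rounds_run = round)
}

#' Multivariable MR by Bayesian model averaging on a harmonized set
#'
#' Convenience wrapper: standardize, enumerate the posterior, and
#' optionally run the iterative instrument-pruning loop.
#'
#' @param set a `harmonized_set`.
#' @param config a [bma_config()].
#' @param prune run [iterative_prune()] first (default TRUE).
#' @return the [iterative_prune()] result (with `prune = FALSE`, the same
#'   shape with zero rounds).
#' @export
run_mr_bma <- function(set, config = bma_config(), prune = TRUE) {
  if (prune) return(iterative_prune(set, config))
  td <- bma_transform(set)
  colnames(td$design) <- colnames(set$beta_X)
  posterior <- enumerate_posterior(td$response, td$design, config)
  list(set = set, posterior = posterior, initial_posterior = posterior,
       audit = data.frame(round = integer(0), snp_id = character(0),
                          reason = character(0), value = numeric(0)),
       rounds_run = 0L)
}
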