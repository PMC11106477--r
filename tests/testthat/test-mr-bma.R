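make_td <- function(J = 30, K = 3, theta = c(0.4, 0, 0), seed = 1,
                    sparsity = 0.5) {
  cfg <- synthetic_gwas_config(n_snps = J, n_exposures = K,
                               causal_effects = theta, sparsity = sparsity,
                               flip_frac = 0, seed = seed)
  set <- panels_to_set(generate_summary_stats(cfg))
  td <- bma_transform(set)
  colnames(td$design) <- colnames(set$beta_X)
  list(set = set, td = td)
}

test_that("the inverse-variance standardization scales rows correctly", {
  set <- make_set(beta_X = cbind(c(0.1, 0.2), c(0.3, 0.1)),
                  se_X = matrix(0.01, 2, 2),
                  beta_Y = c(0.05, 0.02), se_Y = c(1, 1))
  td <- bma_transform(set)
  expect_equal(td$response, c(0.05, 0.02))        # unit SEs: identity
  expect_equal(td$design, unname(set$beta_X))

  set2 <- set; set2$se_Y <- c(2, 1)               # doubling halves row 1
  td2 <- bma_transform(set2)
  expect_equal(td2$response[1], td$response[1] / 2)
  expect_equal(td2$design[1, ], td$design[1, ] / 2)

  set3 <- set; set3$beta_X[, 2] <- 0
  expect_error(bma_transform(set3), "all-zero")

  # weighted regression on transformed data = explicit IVW fit on raw data
  d <- make_td(J = 40, K = 2, theta = c(0.3, 0), seed = 8)
  ols <- lm(d$td$response ~ 0 + d$td$design)
  wls <- lm(d$set$beta_Y ~ 0 + d$set$beta_X, weights = 1 / d$set$se_Y^2)
  expect_equal(unname(coef(ols)), unname(coef(wls)), tolerance = 1e-10)
})

test_that("the marginal likelihood is ordered, symmetric, and matches quadrature", {
  # orthonormal-ish design: strong predictor beats a null predictor
  set.seed(4)
  X <- cbind(rnorm(20), rnorm(20))
  y <- 0.8 * X[, 1] + rnorm(20, 0, 0.5)
  expect_gt(log_marginal_likelihood(1, y, X, 0.25),
            log_marginal_likelihood(2, y, X, 0.25))

  # duplicated columns give identical marginals
  Xd <- cbind(X[, 1], X[, 1])
  expect_equal(log_marginal_likelihood(1, y, Xd, 0.3),
               log_marginal_likelihood(2, y, Xd, 0.3))

  # two-predictor toy (J = 6) vs 2-D trapezoid quadrature over the prior
  X6 <- cbind(c(1, 2, -1, 0.5, -2, 1.5), c(0.5, -1, 1, 2, 0.3, -0.7))
  y6 <- c(0.3, 0.9, -0.2, 0.5, -1.1, 0.4)
  sigma <- 0.4
  gr <- seq(-6 * sigma, 6 * sigma, length.out = 601)
  h <- gr[2] - gr[1]
  lik <- outer(seq_along(gr), seq_along(gr), Vectorize(function(i, j) {
    mu <- X6 %*% c(gr[i], gr[j])
    prod(dnorm(y6 - mu)) * dnorm(gr[i], 0, sigma) * dnorm(gr[j], 0, sigma)
  }))
  oracle <- log(sum(lik) * h^2)
  expect_equal(log_marginal_likelihood(c(1, 2), y6, X6, sigma), oracle,
               tolerance = 1e-6)
})

test_that("posterior enumeration satisfies its identities", {
  d <- make_td(J = 60, K = 4, theta = c(0.4, 0, 0, 0), seed = 2)
  post <- enumerate_posterior(d$td$response, d$td$design, bma_config())
  expect_equal(sum(post$models$pp), 1, tolerance = 1e-10)
  # MIP_k = sum of PP over models containing k
  for (k in seq_len(4)) {
    lab <- post$exposures[k]
    in_m <- vapply(post$subsets, function(s) k %in% s, logical(1))
    expect_equal(unname(post$mip[lab]), sum(post$models$pp[in_m]),
                 tolerance = 1e-12)
    # MACE_k = sum PP_m * theta_m,k over models containing k
    mace_k <- sum(post$models$pp[in_m] *
                    vapply(post$theta[in_m], `[[`, numeric(1), lab))
    expect_equal(unname(post$mace[lab]), mace_k, tolerance = 1e-12)
  }
  # ranked by PP
  expect_true(all(diff(post$models$pp) <= 1e-15))
})

test_that("identical exposure columns get exchangeable inclusion", {
  set.seed(9)
  X <- cbind(rnorm(40), rnorm(40))
  X <- cbind(X[, 1], X[, 1], X[, 2])
  y <- 0.5 * X[, 1] + rnorm(40)
  post <- enumerate_posterior(y, X, bma_config())
  expect_equal(unname(post$mip[1]), unname(post$mip[2]), tolerance = 1e-10)
})

test_that("K = 1 model averaging collapses to the least-squares estimate", {
  d <- make_td(J = 30, K = 1, theta = 0.3, seed = 6, sparsity = 1)
  post <- enumerate_posterior(d$td$response,
                              d$td$design, bma_config())
  wls <- sum(d$td$design * d$td$response) / sum(d$td$design^2)
  expect_equal(unname(post$mace[1]), wls, tolerance = 1e-12)
  expect_equal(unname(post$mip[1]), 1)
})

test_that("the posterior is invariant to SNP row order", {
  d <- make_td(J = 50, K = 3, theta = c(0, 0.3, 0), seed = 12)
  post1 <- enumerate_posterior(d$td$response, d$td$design, bma_config())
  set.seed(1); perm <- sample(50)
  post2 <- enumerate_posterior(d$td$response[perm],
                               d$td$design[perm, ], bma_config())
  expect_equal(post1$mip, post2$mip, tolerance = 1e-10)
  expect_equal(post1$models$pp, post2$models$pp, tolerance = 1e-10)
})

test_that("noiseless single-cause data put the true singleton model on top", {
  cfg <- synthetic_gwas_config(n_snps = 80, n_exposures = 4,
                               causal_effects = c(0, 0, 0.4, 0),
                               sparsity = 0.4, noise = FALSE,
                               flip_frac = 0, seed = 3)
  set <- panels_to_set(generate_summary_stats(cfg))
  td <- bma_transform(set)
  colnames(td$design) <- colnames(set$beta_X)
  for (sig in c(0.05, 0.1, 0.25, 0.5, 1)) {
    post <- enumerate_posterior(td$response, td$design,
                                bma_config(prior_effect_sd = sig))
    expect_equal(post$models$model[1], "X3")
  }
})

test_that("per-SNP diagnostics obey their closed forms", {
  set.seed(21)
  X <- cbind(rnorm(12), rnorm(12))
  theta <- c(0.5, -0.2)
  y_perfect <- drop(X %*% theta)
  expect_equal(snp_q_contributions(c(1, 2), y_perfect, X), rep(0, 12),
               tolerance = 1e-20)
  y <- y_perfect + rnorm(12, 0, 0.3)
  qj <- snp_q_contributions(c(1, 2), y, X)
  fit <- lm(y ~ 0 + X)
  expect_equal(sum(qj), sum(fit$residuals^2), tolerance = 1e-10)

  # a planted 10-sigma outlier dominates and exceeds 10
  y_out <- y_perfect; y_out[5] <- y_perfect[5] + 10
  qo <- snp_q_contributions(c(1, 2), y_out, X)
  expect_equal(which.max(qo), 5)
  expect_gt(qo[5], 10)

  # Cook's distance: hat-matrix formula vs leave-one-out refits
  cd <- cooks_distance_mr(c(1, 2), y, X)
  d <- 2; J <- 12
  s2 <- sum(fit$residuals^2) / (J - d)
  loo <- vapply(seq_len(J), function(j) {
    fit_j <- lm(y[-j] ~ 0 + X[-j, ])
    pred_all <- drop(X %*% coef(fit_j))
    sum((fitted(fit) - pred_all)^2) / (d * s2)
  }, numeric(1))
  expect_equal(cd, loo, tolerance = 1e-10)
  # duplicated rows share identical influence
  Xd <- X[c(1, 1, 2:12), ]; yd <- y[c(1, 1, 2:12)]
  cdd <- cooks_distance_mr(c(1, 2), yd, Xd)
  expect_equal(cdd[1], cdd[2], tolerance = 1e-12)
  # threshold is the F median
  expect_equal(cooks_threshold(1, 100), qf(0.5, 1, 99))
  expect_equal(cooks_threshold(1, 100), 0.458, tolerance = 1e-3)
})

test_that("clean data are not pruned and pruning is idempotent", {
  d <- make_td(J = 70, K = 3, theta = c(0.3, 0, 0), seed = 33)
  res <- iterative_prune(d$set, bma_config())
  expect_equal(res$rounds_run, 0)
  expect_equal(nrow(res$audit), 0)
  expect_length(res$set$snp_ids, 70)

  # plant three strong direct effects; re-running removes nothing more
  set2 <- d$set
  out_ids <- c(5, 23, 41)
  set2$beta_Y[out_ids] <- set2$beta_Y[out_ids] +
    8 * set2$se_Y[out_ids] * c(1, -1, 1)
  res2 <- iterative_prune(set2, bma_config())
  expect_true(all(set2$snp_ids[out_ids] %in% res2$audit$snp_id))
  res3 <- iterative_prune(res2$set, bma_config())
  expect_equal(nrow(res3$audit), 0)
  expect_identical(res3$set$snp_ids, res2$set$snp_ids)
  # before/after results are both reported for the consistency check
  expect_s3_class(res2$initial_posterior, "bma_posterior")
  expect_false(identical(res2$initial_posterior$mip, res2$posterior$mip))
})
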