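test_that("Wald ratios follow the delta method", {
  expect_equal(wald_ratio(0.5, 0.01, 0.2, 0.05)$estimate, 0.4)
  expect_equal(wald_ratio(0.5, 0.01, 0, 0.05)$estimate, 0)
  expect_equal(wald_ratio(0.5, 0.01, 0.2, 0.05)$se, 0.1)
  expect_error(wald_ratio(0, 0.01, 0.2, 0.05), "zero exposure")
  # delta-method SE vs parametric bootstrap at strong instrument
  set.seed(1)
  bx <- 0.5; sx <- 0.02; by <- 0.1; sy <- 0.05
  boot <- rnorm(2e5, by, sy) / rnorm(2e5, bx, sx)
  expect_equal(wald_ratio(bx, sx, by, sy)$se, sd(boot), tolerance = 0.05)
})

test_that("IVW matches the frozen example and its oracle properties", {
  bx <- c(0.1, 0.2, 0.3); by <- c(0.05, 0.08, 0.14); sy <- rep(0.01, 3)
  fit <- mr_ivw(bx = bx, by = by, sy = sy, mode = "fixed")
  expect_equal(fit$estimate, 0.45)  # weighted LS through the origin

  # homogeneous ratios: estimate c, Q = 0, random se = fixed se
  bx2 <- c(0.1, 0.2, 0.4); by2 <- 0.3 * bx2
  f_fix <- mr_ivw(bx = bx2, by = by2, sy = rep(0.02, 3), mode = "fixed")
  f_ran <- mr_ivw(bx = bx2, by = by2, sy = rep(0.02, 3), mode = "random")
  expect_equal(f_fix$estimate, 0.3)
  expect_equal(f_fix$q_stat, 0, tolerance = 1e-20)
  expect_equal(f_ran$se, f_fix$se)

  # random-mode se never undercuts fixed-mode se
  set.seed(2)
  for (i in 1:20) {
    bxi <- rnorm(8, 0, 0.1); syi <- runif(8, 0.01, 0.05)
    byi <- 0.2 * bxi + rnorm(8, 0, syi)
    expect_gte(mr_ivw(bx = bxi, by = byi, sy = syi, mode = "random")$se,
               mr_ivw(bx = bxi, by = byi, sy = syi, mode = "fixed")$se)
  }
  expect_error(mr_ivw(bx = 0.1, by = 0.1, sy = 0.1), "wald_ratio")
})

test_that("a duplicated single instrument reproduces its Wald ratio", {
  w <- wald_ratio(0.21, 0.01, 0.08, 0.03)
  fit <- mr_ivw(bx = rep(0.21, 2), by = rep(0.08, 2), sy = rep(0.03, 2),
                mode = "fixed")
  expect_equal(fit$estimate, w$estimate, tolerance = 1e-12)
})

test_that("median estimators: simple, dominance, and weight conventions", {
  bx <- rep(1, 3); sx <- rep(0.01, 3); sy <- rep(0.1, 3)
  by <- c(0.1, 0.2, 0.3)
  m <- mr_median(bx = bx, sx = sx, by = by, sy = sy, variant = "simple",
                 n_boot = 50)
  expect_equal(m$estimate, 0.2)

  # one SNP holding >50% of the weight dominates the weighted median
  bx2 <- c(1, 1, 1, 1); sy2 <- c(0.001, 1, 1, 1)  # SNP 1 weight ~ all
  by2 <- c(0.7, 0.1, 0.2, 0.3)
  mw <- mr_median(bx = bx2, sx = rep(0.01, 4), by = by2, sy = sy2,
                  variant = "weighted", n_boot = 50)
  expect_equal(mw$estimate, 0.7, tolerance = 1e-3)

  # weighted median with equal weights equals the simple median
  set.seed(3)
  bx3 <- runif(9, 0.5, 1.5); by3 <- runif(9, 0, 0.5)
  ms <- mr_median(bx = bx3, sx = rep(0.01, 9), by = by3,
                  sy = abs(bx3) * 0.3, variant = "weighted", n_boot = 50)
  # se_ratio = sy/|bx| constant -> equal weights
  m0 <- mr_median(bx = bx3, sx = rep(0.01, 9), by = by3,
                  sy = abs(bx3) * 0.3, variant = "simple", n_boot = 50)
  expect_equal(ms$estimate, m0$estimate, tolerance = 1e-12)
  expect_error(mr_median(bx = 1:2, sx = 1:2, by = 1:2, sy = 1:2),
               "3 SNPs")
})

test_that("weighted median is less biased than IVW under 40% pleiotropy", {
  set.seed(7)
  reps <- 200; theta <- 0.3
  bias <- t(sapply(seq_len(reps), function(i) {
    J <- 20
    bx <- runif(J, 0.05, 0.15); sy <- rep(0.02, J)
    pleio <- c(rep(0.15, 8), rep(0, 12))   # 40% invalid, directional
    by <- theta * bx + pleio + rnorm(J, 0, sy)
    ivw <- mr_ivw(bx = bx, by = by, sy = sy, mode = "fixed")$estimate
    wm <- bloodcellmr:::weighted_median_estimate(
      by / bx, bx^2 / sy^2)
    c(ivw = ivw, wm = wm)
  }))
  expect_lt(abs(mean(bias[, "wm"]) - theta),
            abs(mean(bias[, "ivw"]) - theta))
})

test_that("Egger recovers exact linear fits and directional pleiotropy", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.05 + 0.3 * bx
  fit <- mr_egger(bx = bx, by = by, sy = rep(0.02, 4))
  expect_equal(fit$estimate, 0.3, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(bx = rep(0.2, 3), by = 1:3, sy = rep(1, 3)),
               "identifiable")

  # directional pleiotropy +0.05 recovered on average
  set.seed(11)
  ints <- replicate(300, {
    J <- 25
    bxi <- runif(J, 0.05, 0.2); syi <- rep(0.02, J)
    byi <- 0.2 * bxi + 0.05 + rnorm(J, 0, syi)
    mr_egger(bx = bxi, by = byi, sy = syi)$egger_intercept
  })
  expect_equal(mean(ints), 0.05, tolerance = 0.01)

  # balanced pleiotropy: intercept test rejects at ~ nominal rate
  set.seed(12)
  ps <- replicate(400, {
    J <- 25
    bxi <- runif(J, 0.05, 0.2); syi <- rep(0.02, J)
    byi <- 0.2 * bxi + rnorm(J, 0, syi)
    mr_egger(bx = bxi, by = byi, sy = syi)$egger_intercept_p
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("Cochran's Q behaves like a chi-square under the null", {
  bx <- c(0.1, 0.2); by <- 0.25 * bx; sy <- rep(0.01, 2)
  q0 <- cochran_q(bx = bx, by = by, sy = sy)
  expect_equal(q0$Q, 0, tolerance = 1e-20)
  expect_equal(q0$pvalue, 1)
  expect_equal(sum(q0$contributions), q0$Q)

  set.seed(5)
  qs <- replicate(500, {
    J <- 20
    bxi <- runif(J, 0.05, 0.2); syi <- rep(0.02, J)
    byi <- 0.1 * bxi + rnorm(J, 0, syi)
    cochran_q(bx = bxi, by = byi, sy = syi)$Q
  })
  expect_equal(mean(qs), 19, tolerance = 0.05)  # E[chi2_19] = 19

  # penalized-median penalty uses the same contribution definition
  bx2 <- runif(6, 0.1, 0.3); sy2 <- rep(0.03, 6)
  by2 <- 0.2 * bx2 + rnorm(6, 0, sy2)
  w <- bx2^2 / sy2^2
  est <- bloodcellmr:::weighted_median_estimate(by2 / bx2, w)
  expect_equal(sum(cochran_q(bx = bx2, by = by2, sy = sy2,
                             estimate = est)$contributions),
               cochran_q(bx = bx2, by = by2, sy = sy2, estimate = est)$Q)
})

test_that("all six estimators are sign-flip invariant and exact in the noiseless limit", {
  cfg <- synthetic_gwas_config(n_snps = 40, n_exposures = 1,
                               causal_effects = 0.25, sparsity = 1,
                               pleiotropy_frac = 0, noise = FALSE,
                               flip_frac = 0, seed = 17)
  set <- panels_to_set(generate_summary_stats(cfg))
  bx <- set$beta_X[, 1]; sx <- set$se_X[, 1]
  by <- set$beta_Y; sy <- set$se_Y
  methods <- list(
    function(a, b, c, d) mr_ivw(bx = a, by = c, sy = d, mode = "fixed"),
    function(a, b, c, d) mr_ivw(bx = a, by = c, sy = d, mode = "random"),
    function(a, b, c, d) mr_median(bx = a, sx = b, by = c, sy = d,
                                   variant = "simple", n_boot = 20),
    function(a, b, c, d) mr_median(bx = a, sx = b, by = c, sy = d,
                                   variant = "weighted", n_boot = 20),
    function(a, b, c, d) mr_median(bx = a, sx = b, by = c, sy = d,
                                   variant = "penalized", n_boot = 20),
    function(a, b, c, d) mr_egger(bx = a, by = c, sy = d))
  s <- rep(1, length(bx)); s[seq(1, length(bx), by = 3)] <- -1
  for (m in methods) {
    expect_equal(m(bx, sx, by, sy)$estimate, 0.25, tolerance = 1e-10)
    expect_equal(m(bx * s, sx, by * s, sy)$estimate,
                 m(bx, sx, by, sy)$estimate, tolerance = 1e-10)
  }
  # Egger with the intercept constrained to zero is fixed-effects IVW
  constrained <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_equal(mr_ivw(bx = bx, by = by, sy = sy, mode = "fixed")$estimate,
               unname(coef(constrained)), tolerance = 1e-12)
})

test_that("the estimator grid covers every pair and flags by Bonferroni", {
  expect_equal(bonferroni_threshold(0.05, 15, 2), 0.05 / 30)
  expect_equal(bonferroni_threshold(0.05, 1, 1), 0.05)

  cfg <- function(oc_seed, theta) {
    synthetic_gwas_config(n_snps = 150, n_exposures = 3,
                          causal_effects = theta, sparsity = 0.3,
                          flip_frac = 0, seed = oc_seed)
  }
  sets <- list(
    CD = panels_to_set(generate_summary_stats(cfg(31, c(0, 0, 0)))),
    UC = panels_to_set(generate_summary_stats(cfg(32, c(0.3, 0, 0)))))
  grid <- run_uvmr_grid(sets, n_boot = 50)
  expect_equal(nrow(grid), 3 * 2 * 6)
  expect_equal(attr(grid, "bonferroni_alpha"), 0.05 / 6)
  ivw_uc_x1 <- grid[grid$outcome == "UC" & grid$exposure == "X1" &
                      grid$method == "ivw_random", ]
  expect_true(ivw_uc_x1$bonferroni_significant)
  expect_lt(abs(ivw_uc_x1$estimate - 0.3), 0.15)

  # a failing cell is isolated, not fatal
  tiny <- subset_instruments(sets$CD, 1:2)
  tiny$p_X[] <- 1e-300
  g2 <- run_uvmr_grid(list(CD = tiny), n_boot = 20)
  expect_true(any(g2$note != ""))   # medians/Egger need 3 SNPs
  expect_true(any(is.finite(g2$estimate)))  # IVW still reported
})
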