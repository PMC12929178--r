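test_that("EM at K = 1 reproduces the closed-form single-class fit", {
  set.seed(31)
  y <- cbind(matrix(rnorm(120 * 3, 1.2, 0.4), 120),
             matrix(rnorm(120 * 3, 1.5, 0.4), 120))
  closed <- fit_lcga(y, 1)
  em <- copanel:::lcga_em(growth_scores(y), 1L,
                          matrix(c(1, 0, 1, 0), 4, 1),
                          tol = 1e-12, max_iter = 2000)
  expect_equal(em$ll, closed$logLik, tolerance = 1e-8)
  expect_equal(unname(em$theta), unname(closed$theta), tolerance = 1e-6)
})

test_that("information criteria follow their formulas exactly", {
  set.seed(32)
  y <- cbind(matrix(rnorm(60 * 3, 1, 0.3), 60),
             matrix(rnorm(60 * 3, 1, 0.3), 60))
  f <- fit_lcga(y, 2, n_restarts = 2, seed = 1)
  q <- (2 - 1) + 4 * 2 + 2
  expect_equal(f$n_params, q)
  expect_equal(f$AIC, -2 * f$logLik + 2 * q)
  expect_equal(f$BIC, -2 * f$logLik + q * log(60))
  expect_equal(f$aBIC, -2 * f$logLik + q * log((60 + 2) / 24))
  expect_lt(f$aBIC, f$BIC)  # holds whenever n > 22
})

test_that("relative entropy hits its extremes and ignores relabelling", {
  hard <- cbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  expect_equal(relative_entropy(hard), 1)
  expect_equal(relative_entropy(matrix(1 / 3, 9, 3)), 0)
  soft <- cbind(runif(10, 0.2, 0.8))
  soft <- cbind(soft, 1 - soft)
  expect_equal(relative_entropy(soft), relative_entropy(soft[, 2:1]))
  expect_true(is.na(relative_entropy(matrix(1, 10, 1))))
})

test_that("the EM log-likelihood never decreases across iterations", {
  set.seed(33)
  sim <- simulate_growth_mixture(recovery_config(n_subjects = 600, seed = 33))
  f <- fit_lcga(score_panel(sim$panel), 3, n_restarts = 2, seed = 1)
  expect_true(all(diff(f$loglik_trace) > -1e-8))
})

test_that("a separated three-class mixture is recovered accurately", {
  sim <- simulate_growth_mixture(recovery_config(n_subjects = 5000, seed = 34))
  f <- fit_lcga(score_panel(sim$panel), 3, n_restarts = 3, seed = 2)
  # modal assignment accuracy against the generating labels
  expect_gt(mean(f$assignment == sim$class), 0.95)
  expect_gt(f$entropy, 0.80)
  expect_lt(max(abs(f$theta - recovery_theta())), 0.05)
  expect_lt(max(abs(f$pi - c(0.698, 0.272, 0.030))), 0.03)
})

test_that("the canonicalized solution is stable across restart seeds", {
  sim <- simulate_growth_mixture(recovery_config(n_subjects = 1000, seed = 35))
  s <- score_panel(sim$panel)
  f1 <- fit_lcga(s, 3, n_restarts = 4, seed = 10)
  f2 <- fit_lcga(s, 3, n_restarts = 4, seed = 77)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-4)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("class enumeration tabulates every K and the BLRT p-value", {
  sim <- simulate_growth_mixture(recovery_config(n_subjects = 400, seed = 36))
  enum <- enumerate_classes(score_panel(sim$panel), k_max = 3,
                            n_restarts = 2, blrt_reps = 19, seed = 3)
  expect_equal(enum$table$k, 1:3)
  expect_true(is.na(enum$table$blrt_p[1]))
  expect_true(all(enum$table$blrt_p[2:3] > 0 & enum$table$blrt_p[2:3] <= 1))
  # a 2-vs-1 split of strongly separated classes is overwhelmingly supported
  expect_lt(enum$table$blrt_p[2], 0.1)
  expect_true(all(diff(enum$table$logLik) > 0))
})

test_that("near-noiseless growth data saturate the parallel-process model", {
  # every subject on its own line (real growth-factor spread, vanishing
  # residual): the model is exactly true, so the misfit statistic stays at
  # chance level and the residual variances collapse toward zero
  set.seed(38)
  n <- 500
  fgt <- cbind(rnorm(n, 1, 0.3), rnorm(n, 0.3, 0.1),
               rnorm(n, 1.2, 0.3), rnorm(n, 0.2, 0.1))
  y <- fgt %*% t(copanel:::pp_lgcm_lambda()) + matrix(rnorm(n * 6, 0, 1e-3), n)
  f <- suppressWarnings(fit_pp_lgcm(y, seed = 1))
  expect_equal(unname(f$mu), c(1, 0.3, 1.2, 0.2), tolerance = 0.05)
  expect_lt(f$RMSEA, 0.05)
  expect_true(all(f$theta < 1e-4))
})

test_that("the growth-factor covariance structure is recovered", {
  cfg <- growth_mixture_config(
    n_subjects = 3000, class_proportions = 1,
    intercept_anx = 1.2, slope_anx = 0.2, intercept_dep = 1.4, slope_dep = 0.2,
    growth_factor_sd = c(0.33, 0.12, 0.34, 0.11),
    growth_factor_cor = c(intercept = 0.4, slope = 0.0),
    residual_sd = 0.25, item_sd = 0.6,
    offsets_anx = rep(0, 7), offsets_dep = rep(0, 9),
    covariates = FALSE, seed = 37)
  f <- fit_pp_lgcm(score_panel(simulate_growth_mixture(cfg)$panel), seed = 2)
  expect_lt(abs(f$r_intercept - 0.4), 0.05)
  # slope factors were generated uncorrelated across processes
  expect_lt(abs(f$r_slope), 0.1)
  expect_true(f$CFI <= 1 && f$RMSEA >= 0)
  expect_equal(f$psi, t(f$psi))
  expect_true(min(eigen(f$psi, symmetric = TRUE, only.values = TRUE)$values)
              > -1e-8)
})
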