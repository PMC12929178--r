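test_that("a fixed seed makes generation bit-identical", {
  cfg <- growth_mixture_config(n_subjects = 50, seed = 99)
  s1 <- simulate_growth_mixture(cfg)
  s2 <- simulate_growth_mixture(cfg)
  expect_identical(s1, s2)
  tr <- planted_truth(edges = list(list(5, 8, 1.5)))
  c1 <- simulate_clpn_panel(tr, 100, seed = 7)
  c2 <- simulate_clpn_panel(tr, 100, seed = 7)
  expect_identical(c1, c2)
})

test_that("degenerate zero config yields an all-zero panel", {
  cfg <- growth_mixture_config(
    n_subjects = 20, class_proportions = 1,
    intercept_anx = 0, slope_anx = 0, intercept_dep = 0, slope_dep = 0,
    residual_sd = 0, item_sd = 0,
    offsets_anx = rep(0, 7), offsets_dep = rep(0, 9),
    covariates = FALSE, seed = 1)
  sim <- simulate_growth_mixture(cfg)
  expect_true(all(as.matrix(sim$panel[copanel:::all_item_cols()]) == 0))
})

test_that("noiseless linear growth reproduces the configured line exactly", {
  # integer-valued line 1, 2, 3: no rounding ambiguity away from boundaries
  cfg <- growth_mixture_config(
    n_subjects = 10, class_proportions = 1,
    intercept_anx = 1, slope_anx = 1, intercept_dep = 1, slope_dep = 1,
    residual_sd = 0, item_sd = 0,
    offsets_anx = rep(0, 7), offsets_dep = rep(0, 9),
    covariates = FALSE, seed = 2)
  s <- score_panel(simulate_growth_mixture(cfg)$panel)
  for (w in 1:3) {
    expect_true(all(s$gad_mean[s$wave == w] == w))
    expect_true(all(s$phq_mean[s$wave == w] == w))
  }
})

test_that("class frequencies converge to the configured proportions", {
  cfg <- recovery_config(n_subjects = 10000, seed = 3)
  sim <- simulate_growth_mixture(cfg)
  p_hat <- tabulate(sim$class, 3) / 10000
  p <- cfg$class_proportions
  # binomial 99.9% bands
  for (k in 1:3) {
    se <- sqrt(p[k] * (1 - p[k]) / 10000)
    expect_lt(abs(p_hat[k] - p[k]), 3.3 * se + 1e-12)
  }
})

test_that("class-wise empirical mean trajectories track the configured lines", {
  # Monte-Carlo estimate of the generator's class-wave means: averaged over
  # replicates so the 3% class (n ~ 150 per cohort) is estimated precisely
  th <- recovery_theta()
  reps <- 5
  acc <- array(0, dim = c(3, 6))
  cnt <- numeric(3)
  for (r in seq_len(reps)) {
    sim <- simulate_growth_mixture(recovery_config(n_subjects = 5000,
                                                   seed = 400 + r))
    y <- growth_scores(score_panel(sim$panel))
    for (k in 1:3) {
      acc[k, ] <- acc[k, ] + colSums(y[sim$class == k, , drop = FALSE])
      cnt[k] <- cnt[k] + sum(sim$class == k)
    }
  }
  for (k in 1:3) {
    means <- acc[k, ] / cnt[k]
    line <- c(th[1, k] + th[2, k] * 0:2, th[3, k] + th[4, k] * 0:2)
    expect_lt(max(abs(means - line)), 0.05)
  }
})

test_that("lagged binary generator follows its closed-form transition model", {
  # null model: all transitions logistic(0) = 0.5
  tr0 <- clpn_truth(matrix(0, 16, 16), intercepts = rep(0, 16))
  sim0 <- simulate_clpn_panel(tr0, 4000, seed = 5)
  w2 <- copanel:::item_matrix(sim0$panel, 2)
  expect_true(all(abs(colMeans(w2) - 0.5) < 0.03))

  # single planted edge: P(child | parent) = logistic(b + w), else logistic(b)
  W <- matrix(0, 16, 16); W[1, 2] <- 2
  tr <- clpn_truth(W, intercepts = c(0, -1, rep(0, 14)))
  sim <- simulate_clpn_panel(tr, 8000, seed = 6)
  x1 <- copanel:::item_matrix(sim$panel, 1)
  x2 <- copanel:::item_matrix(sim$panel, 2)
  p_on <- mean(x2[x1[, 1] == 1, 2])
  p_off <- mean(x2[x1[, 1] == 0, 2])
  expect_lt(abs(p_on - plogis(1)), 0.03)
  expect_lt(abs(p_off - plogis(-1)), 0.03)
})

test_that("empirical conditional log-odds recover a sparse truth matrix", {
  tr <- planted_truth(auto = 1.2,
                      edges = list(list(5, 8, 0.8), list(3, 12, -1.2)))
  sim <- simulate_clpn_panel(tr, 20000, seed = 8)
  x1 <- copanel:::item_matrix(sim$panel, 1)
  x2 <- copanel:::item_matrix(sim$panel, 2)
  # brute-force frequency estimate of each planted parent->child effect,
  # holding the child's other parent (its own lag) fixed at zero
  for (e in list(c(5, 8, 0.8), c(3, 12, -1.2), c(4, 4, 1.2))) {
    i <- e[1]; j <- e[2]
    keep <- if (i == j) rep(TRUE, nrow(x1)) else x1[, j] == 0
    lo_on <- qlogis(mean(x2[keep & x1[, i] == 1, j]))
    lo_off <- qlogis(mean(x2[keep & x1[, i] == 0, j]))
    expect_lt(abs((lo_on - lo_off) - e[3]), 0.1)
  }
})

test_that("invalid simplex and malformed truth objects are rejected", {
  expect_error(growth_mixture_config(class_proportions = c(0.5, 0.4)),
               "simplex")
  expect_error(clpn_truth(matrix(0, 4, 4)))
  expect_error(clpn_truth(matrix(0, 16, 16), p0 = rep(1.5, 16)))
})
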