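test_that("zero-penalty fit matches unpenalized maximum likelihood", {
  tr <- planted_truth(auto = 1.0, edges = list(list(2, 5, 0.8),
                                               list(7, 3, -0.6)))
  sim <- simulate_clpn_panel(tr, 500, seed = 41)
  net <- fit_clpn(sim$panel, 1, lambda = 0)
  x1 <- copanel:::item_matrix(sim$panel, 1)
  x2 <- copanel:::item_matrix(sim$panel, 2)
  for (j in c(3, 5, 9)) {
    ml <- glm(x2[, j] ~ x1, family = binomial())
    expect_equal(unname(net$beta[, j]), unname(coef(ml)[-1]),
                 tolerance = 1e-4)
    expect_equal(unname(net$intercepts[j]), unname(coef(ml)[1]),
                 tolerance = 1e-4)
  }
})

test_that("relabelling nodes permutes the coefficient matrix on both axes", {
  tr <- planted_truth(edges = list(list(1, 2, 1.0), list(5, 8, 1.5)))
  sim <- simulate_clpn_panel(tr, 800, seed = 42)
  perm <- c(16:9, 1:8)
  df <- as.data.frame(sim$panel)
  items <- panel_items()
  for (w in 1:3) {
    for (i in seq_along(items)) {
      df[[copanel:::item_col(items[i], w)]] <-
        as.data.frame(sim$panel)[[copanel:::item_col(items[perm[i]], w)]]
    }
  }
  permuted <- structure(df, covariates = character(),
                        class = c("binary_panel", "data.frame"))
  net_o <- fit_clpn(sim$panel, 1, lambda = 0.02)
  net_p <- fit_clpn(permuted, 1, lambda = 0.02)
  expect_equal(unname(net_p$beta), unname(net_o$beta[perm, perm]),
               tolerance = 1e-6)
})

test_that("increasing the penalty never adds edges", {
  tr <- planted_truth(edges = list(list(1, 2, 1.0), list(5, 8, 1.5),
                                   list(3, 12, -0.8)))
  sim <- simulate_clpn_panel(tr, 600, seed = 43)
  lams <- c(0.001, 0.01, 0.05, 0.1, 0.2)
  counts <- vapply(lams, function(l) {
    network_density(fit_clpn(sim$panel, 1, lambda = l))$n_edges
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("odds-ratio conversion is exp elementwise with OR = 1 at zero", {
  b <- matrix(0, 16, 16)
  b[1, 2] <- log(2)
  b[3, 4] <- -log(4)
  net <- make_net(b)
  or <- edge_or(net)
  expect_equal(or[1, 2], 2)
  expect_equal(or[3, 4], 0.25)
  expect_true(all(or[b == 0] == 1))
  expect_equal(log(edge_or(net)), net$beta)
})

test_that("density counts edges, cross-lagged edges and the 256 denominator", {
  b <- matrix(0, 16, 16)
  diag(b)[1:4] <- 1
  b[1, 2] <- 0.5
  b[2, 1] <- -0.5
  d <- network_density(make_net(b))
  expect_equal(d$n_edges, 6)
  expect_equal(d$n_cross_lagged, 2)
  expect_equal(d$density, 6 / 256)
  d0 <- network_density(make_net(matrix(0, 16, 16)))
  expect_equal(d0$n_edges, 0)
  expect_equal(d0$density, 0)
})

test_that("expected influence matches a hand-summed toy and standardizes", {
  b <- matrix(0, 16, 16)
  b[1, 2] <- 0.5
  b[1, 3] <- 0.25
  b[3, 2] <- -0.25
  diag(b)[1:3] <- 2.0       # autoregressive loops are excluded from EI
  ct <- expected_influence(make_net(b))
  expect_equal(ct$out_ei[1:3], c(0.75, 0, -0.25))
  expect_equal(ct$in_ei[1:3], c(0, 0.25, 0.25))
  expect_equal(sum(ct$out_ei_z), 0, tolerance = 1e-12)
  expect_equal(sd(ct$out_ei_z), 1, tolerance = 1e-12)
  expect_equal(sum(ct$in_ei_z), 0, tolerance = 1e-12)
  expect_warning(
    expect_warning(ei0 <- expected_influence(make_net(matrix(0, 16, 16))),
                   "zero variance"),
    "zero variance")
  expect_true(all(ei0$out_ei == 0) && all(ei0$out_ei_z == 0))
})

test_that("constant outcomes give a zero column with a warning, tiny n errors", {
  tr <- planted_truth()
  sim <- simulate_clpn_panel(tr, 200, seed = 44)
  df <- as.data.frame(sim$panel)
  for (it in c("gad1")) df[[copanel:::item_col(it, 2)]] <- 1L
  const <- structure(df, covariates = character(),
                     class = c("binary_panel", "data.frame"))
  expect_warning(net <- fit_clpn(const, 1, lambda = 0.05), "constant")
  expect_true(all(net$beta[, 1] == 0))
  expect_error(fit_clpn(sim$panel[1:30, ], 1), "50")
})

test_that("independent covariates barely move the symptom coefficients", {
  tr <- planted_truth(edges = list(list(5, 8, 1.2)))
  sim <- simulate_clpn_panel(tr, 8000, seed = 45)
  df <- as.data.frame(sim$panel)
  set.seed(46)
  df$sex <- rbinom(8000, 1, 0.5)
  df$age <- sample(17:24, 8000, replace = TRUE)
  withcov <- structure(df, covariates = c("sex", "age"),
                       class = c("binary_panel", "data.frame"))
  net_plain <- fit_clpn(sim$panel, 1, lambda = 0.02)
  net_adj <- fit_clpn(withcov, 1, covariates = c("sex", "age"),
                      lambda = 0.02)
  expect_lt(max(abs(net_adj$beta - net_plain$beta)), 0.05)
  expect_equal(dim(net_adj$covariate_coefs), c(2L, 16L))
})
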