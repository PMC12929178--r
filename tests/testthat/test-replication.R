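# helper: coefficient matrix with a prescribed support and sign pattern
support_beta <- function(n_pos, n_neg, n_auto, seed) {
  set.seed(seed)
  b <- matrix(0, 16, 16)
  off <- which(row(b) != col(b))
  picked <- sample(off, n_pos + n_neg)
  b[picked[seq_len(n_pos)]] <- runif(n_pos, 0.1, 0.6)
  if (n_neg > 0) b[picked[n_pos + seq_len(n_neg)]] <- -runif(n_neg, 0.1, 0.4)
  diag(b)[sample(16, n_auto)] <- runif(n_auto, 0.5, 1.2)
  b
}

test_that("a network compared with itself replicates perfectly", {
  net <- make_net(support_beta(30, 10, 12, seed = 61))
  cmp <- compare_networks(net, net)
  tab <- cmp$table
  all_rows <- tab[tab$split == "all", ]
  expect_true(all(abs(all_rows$r[!is.na(all_rows$r)] - 1) < 1e-12))
  rep_row <- tab[tab$subset == "replicated" & tab$split == "all", ]
  expect_equal(rep_row$pct_a, 100)
  expect_equal(rep_row$pct_b, 100)
  expect_equal(cmp$centrality["out_ei", "r"], 1, tolerance = 1e-12)
})

test_that("comparison counts and correlations are symmetric in the arguments", {
  na <- make_net(support_beta(40, 15, 10, seed = 62))
  nb <- make_net(support_beta(35, 20, 11, seed = 63))
  ab <- compare_networks(na, nb)
  ba <- compare_networks(nb, na)
  rep_ab <- ab$table[ab$table$subset == "replicated" & ab$table$split == "all", ]
  rep_ba <- ba$table[ba$table$subset == "replicated" & ba$table$split == "all", ]
  expect_equal(rep_ab$count_a, rep_ba$count_b)
  expect_equal(rep_ab$r, rep_ba$r)
  all_ab <- ab$table[ab$table$subset == "all" & ab$table$split == "all", ]
  all_ba <- ba$table[ba$table$subset == "all" & ba$table$split == "all", ]
  expect_equal(all_ab$r, all_ba$r)
})

test_that("table arithmetic reproduces counts, percentages and nesting", {
  na <- make_net(support_beta(45, 20, 12, seed = 64))
  nb <- make_net(support_beta(38, 25, 9, seed = 65))
  cmp <- compare_networks(na, nb)
  tab <- cmp$table
  n_a <- sum(na$beta != 0)
  n_b <- sum(nb$beta != 0)
  expect_equal(unname(cmp$n_edges), c(n_a, n_b))
  all_row <- tab[tab$subset == "all" & tab$split == "all", ]
  expect_equal(all_row$count_a, n_a)
  expect_equal(all_row$pct_a, 100)
  auto_row <- tab[tab$subset == "autoregressive" & tab$split == "all", ]
  cross_row <- tab[tab$subset == "cross_lagged" & tab$split == "all", ]
  expect_equal(auto_row$count_a + cross_row$count_a, n_a)
  expect_equal(auto_row$pct_a, 100 * sum(diag(na$beta) != 0) / n_a)
  rep_row <- tab[tab$subset == "replicated" & tab$split == "all", ]
  shared <- sum(na$beta != 0 & nb$beta != 0)
  expect_equal(rep_row$count_a, shared)
  expect_equal(rep_row$pct_a, 100 * shared / n_a)
  expect_equal(rep_row$pct_b, 100 * shared / n_b)
  expect_lte(rep_row$count_a, min(n_a, n_b))
  # OR>1 / OR<1 splits partition each subset's support
  gt <- tab[tab$subset == "all" & tab$split == "or_gt1", ]
  lt <- tab[tab$subset == "all" & tab$split == "or_lt1", ]
  expect_equal(gt$count_a + lt$count_a, n_a)
  # mean/sd summarize OR values over the support
  or_a <- exp(na$beta)
  expect_equal(all_row$mean_or_a, mean(or_a[na$beta != 0]))
  expect_equal(all_row$sd_or_a, sd(or_a[na$beta != 0]))
})

test_that("disjoint-support networks share nothing and decorrelate", {
  set.seed(66)
  b1 <- matrix(0, 16, 16)
  b2 <- matrix(0, 16, 16)
  off <- sample(which(row(b1) != col(b1)), 120)
  b1[off[1:60]] <- rnorm(60, 0, 0.4)
  b2[off[61:120]] <- rnorm(60, 0, 0.4)
  cmp <- compare_networks(make_net(b1), make_net(b2))
  rep_row <- cmp$table[cmp$table$subset == "replicated" &
                         cmp$table$split == "all", ]
  expect_equal(rep_row$count_a, 0)
  expect_true(is.na(rep_row$r))
  all_r <- cmp$table[cmp$table$subset == "all" & cmp$table$split == "all", "r"]
  expect_lt(abs(all_r), 0.35)
})

test_that("tiny subsets yield an undefined correlation", {
  b1 <- matrix(0, 16, 16)
  b2 <- matrix(0, 16, 16)
  diag(b1)[1:2] <- 0.5
  diag(b2)[1:2] <- 0.4
  cmp <- compare_networks(make_net(b1), make_net(b2))
  auto_row <- cmp$table[cmp$table$subset == "autoregressive" &
                          cmp$table$split == "all", ]
  expect_true(is.na(auto_row$r))
})
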