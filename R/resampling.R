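# Nonparametric bootstrap accuracy, edge/centrality difference tests, and
# case-dropping stability of the cross-lagged panel network.

# refit the network on a row subset; "fixed" reuses the full-sample penalty
# per outcome, "cv" reruns the full selection procedure
refit_clpn_beta <- function(panel, rows, net, refit, covariates, nfolds) {
  sub <- panel[rows, , drop = FALSE]
  attr(sub, "covariates") <- attr(panel, "covariates")
  class(sub) <- class(panel)
  from_wave <- net$wave_pair[1]
  if (refit == "cv") {
    rule <- if (net$lambda_rule == "fixed") "min" else net$lambda_rule
    f <- suppressWarnings(
      fit_clpn(sub, from_wave, covariates = covariates, nfolds = nfolds,
               lambda_rule = rule))
    return(f$beta)
  }
  x_from <- item_matrix(sub, from_wave)
  x_to <- item_matrix(sub, from_wave + 1L)
  cm <- covariate_matrix(sub, covariates)
  x <- if (is.null(cm)) x_from else cbind(x_from, cm)
  n_cov <- if (is.null(cm)) 0L else ncol(cm)
  pf <- c(rep(1, 16), rep(0, n_cov))
  beta <- matrix(0, 16, 16, dimnames = list(panel_items(), panel_items()))
  for (j in seq_len(16)) {
    yj <- x_to[, j]
    if (min(tabulate(yj + 1L, 2L)) < 2L) next  # (nearly) constant: zeros
    lam <- net$lambda[j]
    if (is.na(lam)) next
    path <- sort(unique(c(lam, max(lam, 0.01) * 2^(4:0))), decreasing = TRUE)
    fit <- glmnet::glmnet(x, yj, family = "binomial", lambda = path,
                          standardize = FALSE, penalty.factor = pf)
    beta[, j] <- as.numeric(coef(fit, s = lam, exact = FALSE))[2:17]
  }
  beta
}

#' Bootstrap edge-weight accuracy and edge difference tests
#'
#' Draws `B` subject resamples with replacement, refits the network on each,
#' and summarizes every edge with a 95 percent percentile confidence
#' interval. A pair of edges differs significantly when the bootstrap 95
#' percent interval of their difference excludes zero.
#'
#' @param panel A `binary_panel` (or [panel_data], binarized automatically).
#' @param from_wave Predictor wave of the network.
#' @param B Number of bootstrap resamples.
#' @param seed Optional seed for the resample stream.
#' @param refit `"fixed"` refits at the full-sample penalties (the desk-scale
#'   default); `"cv"` reruns penalty selection inside every replicate.
#' @param covariates,nfolds,lambda_rule Passed to the network estimator.
#' @param conf_level Confidence level of the percentile intervals.
#' @return An `edge_bootstrap` list: the full-sample `network`, `estimate` /
#'   `ci_lower` / `ci_upper` matrices, logical `edge_diff_significant`
#'   (256 x 256, edges in column-major order of the coefficient matrix),
#'   per-replicate centrality draws, and meta data.
#' @export
bootstrap_edges <- function(panel, from_wave = 1, B = 1000, seed = NULL,
                            refit = c("fixed", "cv"), covariates = NULL,
                            nfolds = 10, lambda_rule = "min",
                            conf_level = 0.95) {
  refit <- match.arg(refit)
  if (inherits(panel, "panel_data")) panel <- binarize(panel)
  if (B < 2) warning("B < 2: intervals collapse to the single replicate",
                     call. = FALSE)
  net <- fit_clpn(panel, from_wave, covariates = covariates, nfolds = nfolds,
                  lambda_rule = lambda_rule, seed = seed)
  n <- nrow(panel)
  if (!is.null(seed)) set.seed(seed)
  edges <- matrix(NA_real_, 256, B)               # column-major edge vector
  out_ei <- matrix(NA_real_, 16, B, dimnames = list(net$nodes, NULL))
  in_ei <- matrix(NA_real_, 16, B, dimnames = list(net$nodes, NULL))
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    bb <- refit_clpn_beta(panel, rows, net, refit, covariates, nfolds)
    edges[, b] <- as.vector(bb)
    ei <- raw_ei(bb)
    out_ei[, b] <- ei$out_ei
    in_ei[, b] <- ei$in_ei
  }
  alpha <- 1 - conf_level
  qs <- apply(edges, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2))
  ci_lower <- matrix(qs[1, ], 16, 16, dimnames = dimnames(net$beta))
  ci_upper <- matrix(qs[2, ], 16, 16, dimnames = dimnames(net$beta))
  structure(list(
    network = net, estimate = net$beta,
    ci_lower = ci_lower, ci_upper = ci_upper,
    edge_diff_significant = pairwise_difference_significant(edges, alpha),
    edge_replicates = edges, out_ei = out_ei, in_ei = in_ei,
    B = B, seed = seed, refit = refit, conf_level = conf_level),
    class = "edge_bootstrap")
}

# symmetric logical matrix: does the bootstrap CI of v_a - v_b exclude 0?
pairwise_difference_significant <- function(draws, alpha = 0.05) {
  m <- nrow(draws)
  sig <- matrix(FALSE, m, m)
  for (a in seq_len(m - 1)) {
    d <- draws[(a + 1):m, , drop = FALSE] -
      matrix(draws[a, ], m - a, ncol(draws), byrow = TRUE)
    lo <- apply(d, 1, quantile, probs = alpha / 2)
    hi <- apply(d, 1, quantile, probs = 1 - alpha / 2)
    s <- lo > 0 | hi < 0
    sig[a, (a + 1):m] <- s
    sig[(a + 1):m, a] <- s
  }
  sig
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat(sprintf("<edge_bootstrap> B = %d (%s refit), %.0f%% percentile CIs\n",
              x$B, x$refit, 100 * x$conf_level))
  invisible(x)
}

#' Centrality difference test from bootstrap replicates
#'
#' Two nodes differ significantly on a centrality index when the bootstrap
#' 95 percent interval of their difference excludes zero.
#'
#' @param boot An [bootstrap_edges()] result.
#' @param index `"out_ei"` or `"in_ei"` (raw expected influence).
#' @return 16 x 16 symmetric logical matrix (diagonal FALSE).
#' @export
centrality_difference_test <- function(boot, index = c("out_ei", "in_ei")) {
  stopifnot(inherits(boot, "edge_bootstrap"))
  index <- match.arg(index)
  draws <- boot[[index]]
  sig <- pairwise_difference_significant(draws, 1 - boot$conf_level)
  dimnames(sig) <- list(rownames(draws), rownames(draws))
  sig
}

#' Case-dropping stability of expected-influence centrality
#'
#' For each drop proportion p, draws `B_per_prop` subsamples of size
#' ceiling((1 - p) n) without replacement, refits the network, and
#' correlates the subsample raw centrality with the full-sample centrality.
#' The CS coefficient is the largest p such that, for every proportion up to
#' p, the 5th percentile of those correlations stays at or above 0.7 (a
#' first-failure scan; a subsample whose centrality is constant counts as a
#' failed correlation).
#'
#' @param panel A `binary_panel` (or [panel_data]).
#' @param from_wave Predictor wave of the network.
#' @param proportions Grid of case-drop proportions.
#' @param B_per_prop Subsamples per proportion.
#' @param seed Optional seed.
#' @param refit,covariates,nfolds,lambda_rule As in [bootstrap_edges()].
#' @param cor_threshold Correlation level that must be maintained.
#' @param certainty Quantile level (0.05 = "with 95 percent certainty").
#' @return A `cs_result` list: `cs` (named vector, out_ei and in_ei),
#'   `correlations` (long data frame of all subsample correlations), meta.
#' @export
case_drop_stability <- function(panel, from_wave = 1,
                                proportions = seq(0.05, 0.75, by = 0.05),
                                B_per_prop = 250, seed = NULL,
                                refit = c("fixed", "cv"), covariates = NULL,
                                nfolds = 10, lambda_rule = "min",
                                cor_threshold = 0.7, certainty = 0.05) {
  refit <- match.arg(refit)
  if (inherits(panel, "panel_data")) panel <- binarize(panel)
  net <- fit_clpn(panel, from_wave, covariates = covariates, nfolds = nfolds,
                  lambda_rule = lambda_rule, seed = seed)
  full_ei <- raw_ei(net$beta)
  n <- nrow(panel)
  if (!is.null(seed)) set.seed(seed)
  rows_list <- list()
  cors <- list()
  for (p in proportions) {
    m <- ceiling((1 - p) * n)
    if (m < 50 || m >= n) next                    # estimator floor
    r_out <- numeric(B_per_prop)
    r_in <- numeric(B_per_prop)
    for (b in seq_len(B_per_prop)) {
      rows <- sample.int(n, m)
      bb <- refit_clpn_beta(panel, rows, net, refit, covariates, nfolds)
      ei <- raw_ei(bb)
      r_out[b] <- safe_cor(ei$out_ei, full_ei$out_ei)
      r_in[b] <- safe_cor(ei$in_ei, full_ei$in_ei)
    }
    cors[[length(cors) + 1L]] <- data.frame(
      proportion = p,
      index = rep(c("out_ei", "in_ei"), each = B_per_prop),
      correlation = c(r_out, r_in))
  }
  cors <- do.call(rbind, cors)
  cs <- c(out_ei = cs_scan(cors, "out_ei", cor_threshold, certainty),
          in_ei = cs_scan(cors, "in_ei", cor_threshold, certainty))
  structure(list(cs = cs, correlations = cors, proportions = proportions,
                 B_per_prop = B_per_prop, cor_threshold = cor_threshold,
                 certainty = certainty, network = net),
            class = "cs_result")
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# monotone first-failure scan over the proportion grid
cs_scan <- function(cors, index, threshold, certainty) {
  sub <- cors[cors$index == index, ]
  props <- sort(unique(sub$proportion))
  cs <- 0
  for (p in props) {
    r <- sub$correlation[sub$proportion == p]
    r[is.na(r)] <- -1                              # undefined: failure
    if (quantile(r, certainty) >= threshold) cs <- p else break
  }
  cs
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("<cs_result> CS(out-EI) = %.2f, CS(in-EI) = %.2f (r >= %.1f at %.0f%% certainty)\n",
              x$cs["out_ei"], x$cs["in_ei"], x$cor_threshold,
              100 * (1 - x$certainty)))
  invisible(x)
}
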