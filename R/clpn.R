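# Cross-lagged panel network: 16 nodewise L1-penalized logistic regressions
# of each symptom's presence at wave t+1 on all 16 presences at wave t (plus
# optional unpenalized covariates). B[i, j] is the log-odds coefficient of
# predictor i on outcome j; the diagonal holds the autoregressive effects.

#' Estimate a cross-lagged panel network between two waves
#'
#' For each of the 16 symptoms at wave `from_wave + 1`, fits an L1-penalized
#' (lasso) logistic regression on all 16 symptom presences at `from_wave`,
#' with any covariates entered unpenalized and standardized. The penalty
#' level of each regression is chosen by stratified cross-validated deviance
#' (rule `"min"`), or one standard error above it (`"1se"`, the parsimony
#' rule used for sparse-support recovery). Binary symptom predictors enter
#' on their common 0/1 scale without standardization.
#'
#' An outcome that is constant, or whose minority category has fewer cases
#' than there are folds, cannot support a cross-validated regression; its
#' coefficient column is returned as all zero with a warning.
#'
#' @param panel A `binary_panel` (a [panel_data] is binarized automatically).
#' @param from_wave Predictor wave t; the outcome wave is t + 1.
#' @param covariates Character vector of covariate columns, or NULL.
#' @param lambda_rule `"min"` or `"1se"` cross-validation rule.
#' @param nfolds Number of CV folds.
#' @param seed Optional seed fixing the fold assignment.
#' @param lambda Optional fixed penalty (scalar, may be 0) applied to every
#'   regression, bypassing cross-validation.
#' @return A `clpn_network` list: `beta` (16 x 16 log-odds matrix, predictor
#'   rows x outcome columns), `intercepts`, `covariate_coefs`, `lambda` (per
#'   outcome), `wave_pair`, `n`, `nodes`.
#' @export
fit_clpn <- function(panel, from_wave = 1, covariates = NULL,
                     lambda_rule = c("min", "1se"), nfolds = 10, seed = NULL,
                     lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  if (inherits(panel, "panel_data")) panel <- binarize(panel)
  stopifnot(inherits(panel, "binary_panel"))
  to_wave <- from_wave + 1L
  n <- nrow(panel)
  if (n < 50) stop("fewer than 50 subjects: network would be unstable",
                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x_from <- item_matrix(panel, from_wave)
  x_to <- item_matrix(panel, to_wave)
  cm <- covariate_matrix(panel, covariates)
  x <- if (is.null(cm)) x_from else cbind(x_from, cm)
  n_cov <- if (is.null(cm)) 0L else ncol(cm)
  pf <- c(rep(1, 16), rep(0, n_cov))
  nodes <- panel_items()
  beta <- matrix(0, 16, 16, dimnames = list(nodes, nodes))
  gamma <- if (n_cov > 0) {
    matrix(0, n_cov, 16, dimnames = list(colnames(cm), nodes))
  } else NULL
  intercepts <- setNames(numeric(16), nodes)
  lambdas <- setNames(rep(NA_real_, 16), nodes)
  for (j in seq_len(16)) {
    yj <- x_to[, j]
    if (min(tabulate(yj + 1L, 2L)) < max(2L, if (is.null(lambda)) nfolds else 0L)) {
      warning("outcome ", nodes[j], " is (nearly) constant at wave ", to_wave,
              "; its coefficient column is set to zero", call. = FALSE)
      next
    }
    if (is.null(lambda)) {
      foldid <- stratified_folds(yj, nfolds)
      cv <- glmnet::cv.glmnet(x, yj, family = "binomial", foldid = foldid,
                              standardize = FALSE, penalty.factor = pf)
      s <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
      cf <- as.numeric(coef(cv, s = s))
      lambdas[j] <- s
    } else {
      # glmnet rescales penalty.factor to sum to the variable count, which
      # would inflate the symptom penalty when unpenalized covariates are
      # present; compensate so `lambda` always means the same per-symptom
      # penalty regardless of the covariate set
      lam_use <- lambda * 16 / (16 + n_cov)
      # a decreasing path ending at the target penalty stabilizes glmnet
      path <- sort(unique(c(lam_use, max(lam_use, 0.01) * 2^(5:0))),
                   decreasing = TRUE)
      fit <- glmnet::glmnet(x, yj, family = "binomial", lambda = path,
                            standardize = FALSE, penalty.factor = pf,
                            thresh = 1e-12)
      cf <- as.numeric(coef(fit, s = lam_use, exact = FALSE))
      lambdas[j] <- lam_use
    }
    intercepts[j] <- cf[1]
    beta[, j] <- cf[2:17]
    if (n_cov > 0) gamma[, j] <- cf[18:(17 + n_cov)]
  }
  structure(list(beta = beta, intercepts = intercepts,
                 covariate_coefs = gamma, lambda = lambdas,
                 lambda_rule = if (is.null(lambda)) lambda_rule else "fixed",
                 wave_pair = c(from_wave, to_wave), n = n, nodes = nodes),
            class = "clpn_network")
}

# fold ids balanced within each outcome level
stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' @export
print.clpn_network <- function(x, ...) {
  d <- network_density(x)
  cat(sprintf(
    "<clpn_network> T%d -> T%d, n = %d: %d edges (%d cross-lagged), density %.3f\n",
    x$wave_pair[1], x$wave_pair[2], x$n, d$n_edges, d$n_cross_lagged,
    d$density))
  invisible(x)
}

#' Odds-ratio view of a network
#'
#' Exponentiates the log-odds coefficient matrix elementwise; a zero
#' (absent) coefficient maps to OR = 1, OR > 1 is a positive lagged
#' association and OR < 1 a negative one.
#'
#' @param net A `clpn_network`.
#' @return 16 x 16 matrix of odds ratios.
#' @export
edge_or <- function(net) {
  stopifnot(inherits(net, "clpn_network"))
  exp(net$beta)
}

#' Edge counts and density of a network
#'
#' An edge is any coefficient that survived the penalty (nonzero at machine
#' precision); no post-hoc threshold is applied. Density is the edge count
#' over the 256 possible directed edges.
#'
#' @param net A `clpn_network` (or a bare 16 x 16 coefficient matrix).
#' @return List with `n_edges`, `n_cross_lagged`, `density`.
#' @export
network_density <- function(net) {
  b <- if (inherits(net, "clpn_network")) net$beta else as.matrix(net)
  n_edges <- sum(b != 0)
  n_auto <- sum(diag(b) != 0)
  list(n_edges = n_edges, n_cross_lagged = n_edges - n_auto,
       density = n_edges / length(b))
}

#' Expected-influence centrality of a network
#'
#' Out expected influence (out-EI) of node i is the sum of its outgoing
#' cross-lagged coefficients (row i of the log-odds matrix, diagonal
#' excluded); in-EI of node j is the sum of incoming ones (column j,
#' diagonal excluded). Standardized versions are z-scores across the 16
#' nodes; a node is flagged influential when its standardized out-EI
#' exceeds 1.
#'
#' @param net A `clpn_network`.
#' @param influential_threshold Threshold on standardized out-EI.
#' @return A `centrality_table` data frame: `node`, `in_ei`, `out_ei`,
#'   `in_ei_z`, `out_ei_z`, `influential`.
#' @export
expected_influence <- function(net, influential_threshold = 1) {
  stopifnot(inherits(net, "clpn_network"))
  b <- net$beta
  diag(b) <- 0
  out_ei <- rowSums(b)
  in_ei <- colSums(b)
  zscore <- function(v) {
    s <- sd(v)
    if (s == 0) {
      warning("centrality has zero variance; z-scores set to 0",
              call. = FALSE)
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  out <- data.frame(node = net$nodes, in_ei = unname(in_ei),
                    out_ei = unname(out_ei),
                    in_ei_z = unname(zscore(in_ei)),
                    out_ei_z = unname(zscore(out_ei)))
  out$influential <- out$out_ei_z > influential_threshold
  structure(out, class = c("centrality_table", "data.frame"))
}

# raw in/out expected influence from a bare coefficient matrix (fast path
# used by the resampling module)
raw_ei <- function(b) {
  diag(b) <- 0
  list(out_ei = rowSums(b), in_ei = colSums(b))
}
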