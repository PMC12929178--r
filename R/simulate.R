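#' Configuration for the growth-mixture panel generator
#'
#' Defines a population of subjects whose anxiety (A) and depression (D)
#' mean-score trajectories follow class-specific linear growth. Subject i in
#' class k has latent mean score at wave t (time scores 0, 1, 2)
#' \deqn{m_{it} = \alpha_k + \beta_k t + u_i + v_i t + e_{it}}
#' clipped to the 0-3 scale, with optional within-class growth-factor
#' variation (u, v) and wave-level residual e. Item scores are drawn as
#' round(clip(Normal(m + offset_item, item_sd), 0, 3)), a discretized clipped
#' normal matching the first two moments of ordinal responses.
#'
#' The defaults describe three trajectory classes of the kind reported for
#' pandemic-era student cohorts: a large low-stable ("resistance") class, a
#' moderate rising ("persistent growth") class, and a small chronically high
#' class, in proportions 69.8/27.2/3.0%.
#'
#' @param n_subjects Number of subjects.
#' @param class_proportions Simplex vector of class weights (length K).
#' @param intercept_anx,slope_anx,intercept_dep,slope_dep Per-class growth
#'   means on the 0-3 mean-score scale (each length K).
#' @param growth_factor_sd Standard deviations of the within-class growth
#'   factors (u_A, v_A, u_D, v_D). Default 0: pure latent-class growth.
#' @param growth_factor_cor Cross-process correlations of the growth factors,
#'   named `intercept` (u_A with u_D) and `slope` (v_A with v_D).
#' @param residual_sd Wave-level residual standard deviation of the latent
#'   mean score.
#' @param item_sd Item dispersion around the latent mean score.
#' @param offsets_anx,offsets_dep Item location offsets (lengths 7 and 9);
#'   zero-mean by convention so the wave mean tracks the latent line.
#' @param discretize If `FALSE`, item scores are left as continuous clipped
#'   normals (diagnostic mode; the resulting panel skips ordinal validation).
#' @param covariates Generate baseline covariates (sex, age and four binary
#'   pandemic-exposure indicators), none of which affect the outcomes.
#' @param seed Optional integer seed.
#' @return A `growth_mixture_config` list.
#' @export
growth_mixture_config <- function(n_subjects = 5000,
                                  class_proportions = c(0.698, 0.272, 0.030),
                                  intercept_anx = c(0.25, 0.75, 1.80),
                                  slope_anx = c(0.02, 0.30, 0.05),
                                  intercept_dep = c(0.35, 0.90, 1.90),
                                  slope_dep = c(0.05, 0.30, 0.05),
                                  growth_factor_sd = c(0, 0, 0, 0),
                                  growth_factor_cor = c(intercept = 0, slope = 0),
                                  residual_sd = 0.30,
                                  item_sd = 0.60,
                                  offsets_anx = c(0.20, 0.10, 0.15, 0, -0.10,
                                                  -0.15, -0.20),
                                  offsets_dep = c(0.30, 0.10, 0.15, 0.20, -0.10,
                                                  -0.25, -0.05, -0.15, -0.20),
                                  discretize = TRUE,
                                  covariates = TRUE,
                                  seed = NULL) {
  k <- length(class_proportions)
  if (abs(sum(class_proportions) - 1) > 1e-8 || any(class_proportions < 0)) {
    stop("class_proportions must be a simplex vector", call. = FALSE)
  }
  stopifnot(k >= 1L,
            length(intercept_anx) == k, length(slope_anx) == k,
            length(intercept_dep) == k, length(slope_dep) == k,
            length(growth_factor_sd) == 4L, all(growth_factor_sd >= 0),
            residual_sd >= 0, item_sd >= 0,
            length(offsets_anx) == 7L, length(offsets_dep) == 9L)
  structure(list(
    n_subjects = n_subjects, class_proportions = class_proportions,
    intercept_anx = intercept_anx, slope_anx = slope_anx,
    intercept_dep = intercept_dep, slope_dep = slope_dep,
    growth_factor_sd = growth_factor_sd,
    growth_factor_cor = growth_factor_cor,
    residual_sd = residual_sd, item_sd = item_sd,
    offsets_anx = offsets_anx, offsets_dep = offsets_dep,
    discretize = discretize, covariates = covariates, seed = seed),
    class = "growth_mixture_config")
}

clip01 <- function(x, lo = 0, hi = 3) pmin(pmax(x, lo), hi)

# draw (u_A, v_A, u_D, v_D) for n subjects under the configured sds/cors
draw_growth_factors <- function(n, sds, cors) {
  if (all(sds == 0)) return(matrix(0, n, 4))
  r_i <- unname(cors["intercept"]); r_s <- unname(cors["slope"])
  sigma <- diag(sds^2)
  sigma[1, 3] <- sigma[3, 1] <- r_i * sds[1] * sds[3]
  sigma[2, 4] <- sigma[4, 2] <- r_s * sds[2] * sds[4]
  ch <- chol(sigma + diag(1e-12, 4))
  matrix(rnorm(n * 4), n, 4) %*% ch
}

#' Generate a growth-mixture symptom panel with known class labels
#'
#' @param config A [growth_mixture_config()].
#' @return A list: `panel` (a [panel_data]), `class` (true class per subject),
#'   `latent` (data frame of the latent wave mean scores per process).
#' @export
simulate_growth_mixture <- function(config) {
  stopifnot(inherits(config, "growth_mixture_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  k <- length(config$class_proportions)
  cls <- sample.int(k, n, replace = TRUE, prob = config$class_proportions)
  gf <- draw_growth_factors(n, config$growth_factor_sd,
                            config$growth_factor_cor)
  out <- data.frame(subject_id = sprintf("s%05d", seq_len(n)))
  latent <- data.frame(subject_id = out$subject_id)
  for (w in panel_waves()) {
    lam <- w - 1L
    m_a <- clip01(config$intercept_anx[cls] + config$slope_anx[cls] * lam +
                    gf[, 1] + gf[, 2] * lam + rnorm(n, 0, config$residual_sd))
    m_d <- clip01(config$intercept_dep[cls] + config$slope_dep[cls] * lam +
                    gf[, 3] + gf[, 4] * lam + rnorm(n, 0, config$residual_sd))
    latent[[paste0("anx_t", w)]] <- m_a
    latent[[paste0("dep_t", w)]] <- m_d
    for (j in seq_len(7)) {
      x <- clip01(rnorm(n, m_a + config$offsets_anx[j], config$item_sd))
      out[[item_col(gad_items()[j], w)]] <-
        if (config$discretize) as.integer(round(x)) else x
    }
    for (j in seq_len(9)) {
      x <- clip01(rnorm(n, m_d + config$offsets_dep[j], config$item_sd))
      out[[item_col(phq_items()[j], w)]] <-
        if (config$discretize) as.integer(round(x)) else x
    }
  }
  covs <- character()
  if (isTRUE(config$covariates)) {
    out$sex <- rbinom(n, 1, 0.5)
    out$age <- sample(17:24, n, replace = TRUE)
    out$severe_province <- rbinom(n, 1, 0.2)
    out$community_case <- rbinom(n, 1, 0.3)
    out$relative_infected <- rbinom(n, 1, 0.1)
    out$media_exposure <- rbinom(n, 1, 0.5)
    covs <- c("sex", "age", "severe_province", "community_case",
              "relative_infected", "media_exposure")
  }
  panel <- panel_data(out, covariates = covs,
                      validate = isTRUE(config$discretize))
  list(panel = panel, class = cls, latent = latent)
}

#' Ground truth for the lagged binary-symptom generator
#'
#' Defines a first-order transition model for 16 binary symptoms:
#' wave-1 presences are independent Bernoulli(p0), and
#' \deqn{P(X^{t+1}_j = 1 \mid X^t) = logistic(b_j + \sum_i W_{ij} X^t_i)}
#' so `W[i, j]` is the log-odds effect of symptom i at one wave on symptom j
#' at the next (diagonal = autoregressive effects).
#'
#' @param W 16 x 16 matrix of lagged log-odds coefficients
#'   (predictor rows x outcome columns).
#' @param intercepts Length-16 vector of outcome intercepts b.
#' @param p0 Length-16 vector of wave-1 prevalences, in (0, 1).
#' @param covariate_effects Optional matrix (covariates x 16) of log-odds
#'   effects of baseline covariates on each outcome.
#' @return A `clpn_truth` list.
#' @export
clpn_truth <- function(W, intercepts = rep(0, 16), p0 = rep(0.3, 16),
                       covariate_effects = NULL) {
  W <- as.matrix(W)
  stopifnot(all(dim(W) == c(16L, 16L)), all(is.finite(W)),
            length(intercepts) == 16L, length(p0) == 16L,
            all(p0 > 0), all(p0 < 1))
  dimnames(W) <- list(panel_items(), panel_items())
  structure(list(W = W, intercepts = intercepts, p0 = p0,
                 covariate_effects = covariate_effects),
            class = "clpn_truth")
}

#' Generate a binary symptom panel from a known lagged transition model
#'
#' Waves are generated sequentially from the logistic transition model in
#' [clpn_truth()]; the result is the generative twin of the cross-lagged
#' panel network estimator, so recovery of `W` can be tested directly.
#'
#' @param truth A [clpn_truth()] object.
#' @param n_subjects Number of subjects.
#' @param n_waves Number of waves to generate (default 3).
#' @param covariate_values Optional numeric matrix (subjects x covariates)
#'   entering the transitions through `truth$covariate_effects`.
#' @param seed Optional integer seed.
#' @return A list: `panel` (a `binary_panel`) and `truth` (as given).
#' @export
simulate_clpn_panel <- function(truth, n_subjects, n_waves = 3,
                                covariate_values = NULL, seed = NULL) {
  stopifnot(inherits(truth, "clpn_truth"), n_waves >= 2)
  if (!is.null(seed)) set.seed(seed)
  n <- n_subjects
  x <- matrix(rbinom(n * 16L, 1L, rep(truth$p0, each = n)), n, 16L)
  waves <- vector("list", n_waves)
  waves[[1L]] <- x
  cov_term <- 0
  if (!is.null(covariate_values) && !is.null(truth$covariate_effects)) {
    cov_term <- as.matrix(covariate_values) %*% truth$covariate_effects
  }
  for (t in 2:n_waves) {
    eta <- sweep(waves[[t - 1L]] %*% truth$W, 2L, truth$intercepts, "+") +
      cov_term
    waves[[t]] <- matrix(rbinom(n * 16L, 1L, plogis(as.vector(eta))), n, 16L)
  }
  out <- data.frame(subject_id = sprintf("s%05d", seq_len(n)))
  for (w in seq_len(n_waves)) {
    for (j in seq_len(16L)) {
      out[[item_col(panel_items()[j], w)]] <- as.integer(waves[[w]][, j])
    }
  }
  covs <- character()
  if (!is.null(covariate_values)) {
    covariate_values <- as.matrix(covariate_values)
    covs <- colnames(covariate_values)
    if (is.null(covs)) covs <- paste0("cov", seq_len(ncol(covariate_values)))
    for (i in seq_along(covs)) out[[covs[i]]] <- covariate_values[, i]
  }
  panel <- structure(out, covariates = covs,
                     class = c("binary_panel", "data.frame"))
  list(panel = panel, truth = truth)
}
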