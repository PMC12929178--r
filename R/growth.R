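# Growth models operate on the n x 6 matrix of wave-level mean scores:
# columns anx_t1..anx_t3, dep_t1..dep_t3, time scores fixed at 0, 1, 2.

growth_loadings <- function() cbind(intercept = 1, slope = 0:2)

#' Wave-level mean-score matrix for the growth models
#'
#' @param scores A `score_table` from [score_panel()], or an n x 6 numeric
#'   matrix already in mean-score layout (passed through).
#' @return n x 6 matrix with columns `anx_t1..anx_t3`, `dep_t1..dep_t3`.
#' @export
growth_scores <- function(scores) {
  if (is.matrix(scores)) {
    stopifnot(ncol(scores) == 6L)
    colnames(scores) <- c(paste0("anx_t", 1:3), paste0("dep_t", 1:3))
    return(scores)
  }
  stopifnot(inherits(scores, "score_table"))
  ids <- unique(scores$subject_id)
  y <- matrix(NA_real_, length(ids), 6L,
              dimnames = list(NULL, c(paste0("anx_t", 1:3),
                                      paste0("dep_t", 1:3))))
  for (w in 1:3) {
    sw <- scores[scores$wave == w, ]
    idx <- match(ids, sw$subject_id)
    y[, w] <- sw$gad_mean[idx]
    y[, w + 3L] <- sw$phq_mean[idx]
  }
  if (anyNA(y)) stop("every subject needs mean scores at all 3 waves",
                     call. = FALSE)
  y
}

# ---------------------------------------------------------------------------
# Latent-class growth analysis (zero within-class growth variance).
# Class k has mean trajectory Lambda %*% theta_k per process; residual
# variances are shared across classes and waves but free per process, so the
# within-class density is diagonal normal. The M-step for the class growth
# means is then ordinary least squares on the posterior-weighted wave means.

lcga_param_count <- function(k) (k - 1L) + 4L * k + 2L

# one EM run from a given 4 x K start matrix; returns NULL on degeneracy.
# Squared distances use the expansion ||y - mu||^2 = ||y||^2 - 2 y.mu +
# ||mu||^2 so each iteration is a handful of matrix products.
lcga_em <- function(y, k, theta0, tol, max_iter, pi0 = NULL, s20 = NULL) {
  n <- nrow(y)
  lam <- growth_loadings()
  proj <- solve(crossprod(lam)) %*% t(lam)        # OLS projector, 2 x 3
  y_a <- y[, 1:3, drop = FALSE]
  y_d <- y[, 4:6, drop = FALSE]
  rs_a <- rowSums(y_a^2)
  rs_d <- rowSums(y_d^2)
  theta <- theta0
  pi_k <- if (is.null(pi0)) rep(1 / k, k) else pi0
  s2 <- if (is.null(s20)) {
    c(max(var(as.vector(y_a)), 1e-6), max(var(as.vector(y_d)), 1e-6))
  } else s20
  ll_trace <- numeric(0)
  ll_old <- -Inf
  quad <- function(mu_a, mu_d) {
    list(a = rs_a - 2 * (y_a %*% mu_a) + rep(colSums(mu_a^2), each = n),
         d = rs_d - 2 * (y_d %*% mu_d) + rep(colSums(mu_d^2), each = n))
  }
  for (it in seq_len(max_iter)) {
    mu_a <- lam %*% theta[1:2, , drop = FALSE]    # 3 x K
    mu_d <- lam %*% theta[3:4, , drop = FALSE]
    q <- quad(mu_a, mu_d)
    logd <- -0.5 * (q$a / s2[1] + q$d / s2[2]) -
      1.5 * log(2 * pi * s2[1]) - 1.5 * log(2 * pi * s2[2]) +
      rep(log(pi_k), each = n)
    mx <- logd[cbind(seq_len(n), max.col(logd, ties.method = "first"))]
    w <- exp(logd - mx)
    sw <- rowSums(w)
    ll <- sum(log(sw) + mx)
    w <- w / sw
    nk <- colSums(w)
    if (any(nk < 1)) return(NULL)                  # empty class: degenerate
    pi_k <- nk / n
    theta[1:2, ] <- proj %*% t(crossprod(w, y_a) / nk)
    theta[3:4, ] <- proj %*% t(crossprod(w, y_d) / nk)
    q <- quad(lam %*% theta[1:2, , drop = FALSE],
              lam %*% theta[3:4, , drop = FALSE])
    s2 <- pmax(c(sum(w * q$a), sum(w * q$d)) / (3 * n), 1e-10)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(ll = ll, theta = theta, pi = pi_k, s2 = s2, posterior = w,
       iterations = it, loglik_trace = ll_trace)
}

# per-subject OLS (intercept, slope) for both processes: n x 4
subject_ols <- function(y) {
  lam <- growth_loadings()
  proj <- solve(crossprod(lam)) %*% t(lam)
  cbind(y[, 1:3, drop = FALSE] %*% t(proj), y[, 4:6, drop = FALSE] %*% t(proj))
}

# Candidate starting values for the EM search. Plain k-means is known to
# absorb small distant trajectory classes into splits of the large ones (its
# within-SS objective is not the mixture likelihood), and rare extreme
# classes -- chronic/severe groups of a few percent -- are exactly what this
# kind of cohort produces. The pool therefore mixes: k-means on standardized
# wave profiles, "tail-seeded" starts that dedicate one class to the extreme
# 2 percent of trajectories, k-means on per-subject growth-factor estimates,
# and kmeans++-style distance-weighted random seeds.
lcga_starts <- function(y, k, n_candidates, prev_assignment = NULL) {
  lam <- growth_loadings()
  proj <- solve(crossprod(lam)) %*% t(lam)
  f <- subject_ols(y)                              # (iA, sA, iD, sD)
  n <- nrow(y)
  # classify-then-EM start from a hard partition: class growth means from
  # the member profiles, class weights from the partition shares, residual
  # variances pooled within classes. Without the informed weights a rare
  # class seeded at 1/K absorbs a third of the cohort in the first E-step
  # and its center is dragged off the tail it was meant to capture.
  partition_start <- function(grp) {
    sizes <- tabulate(grp, k)
    if (any(sizes < 2L)) return(NULL)
    theta <- matrix(0, 4, k)
    rss <- c(0, 0)
    for (j in seq_len(k)) {
      prof <- colMeans(y[grp == j, , drop = FALSE])
      theta[1:2, j] <- proj %*% prof[1:3]
      theta[3:4, j] <- proj %*% prof[4:6]
      mu <- c(lam %*% theta[1:2, j], lam %*% theta[3:4, j])
      r <- sweep(y[grp == j, , drop = FALSE], 2L, mu)
      rss <- rss + c(sum(r[, 1:3]^2), sum(r[, 4:6]^2))
    }
    list(theta = theta, pi = sizes / n, s2 = pmax(rss / (3 * n), 1e-8))
  }
  km_grp <- function(x, centers) {
    tryCatch(suppressWarnings(kmeans(x, centers = centers, nstart = 3,
                                     iter.max = 50)$cluster),
             error = function(e) NULL)
  }
  starts <- list()
  add <- function(s) if (!is.null(s)) starts[[length(starts) + 1L]] <<- s
  sdf <- pmax(apply(f, 2, sd), 1e-8)
  fz <- sweep(f, 2L, sdf, "/")
  # incremental splits: the (k-1)-class solution with one class divided in
  # two by 2-means on its members' standardized growth factors -- the
  # within-class structured variation is exactly what a merged pair hides
  if (!is.null(prev_assignment) && k >= 2L) {
    for (j in sort(unique(prev_assignment))) {
      idx <- prev_assignment == j
      if (sum(idx) < 10L) next
      sub <- km_grp(fz[idx, , drop = FALSE], 2L)
      if (is.null(sub)) next
      grp <- prev_assignment
      grp[idx][sub == 2L] <- k
      add(partition_start(grp))
    }
  }
  sdy <- pmax(apply(y, 2, sd), 1e-8)
  grp <- km_grp(sweep(y, 2L, sdy, "/"), k)
  if (!is.null(grp)) add(partition_start(grp))
  # standardized growth-factor k-means: upweights the slope dimensions,
  # whose spread is small but which separate rising from stable classes
  grp <- km_grp(fz, k)
  if (!is.null(grp)) add(partition_start(grp))
  # tail-seeded partitions: one class pinned on the extreme trajectories
  total <- f[, 1] + f[, 3]
  for (tail in c("high", "low")) {
    if (k < 2L) break
    idx <- if (tail == "high") total >= quantile(total, 0.98) else
      total <= quantile(total, 0.02)
    if (sum(idx) < 3L || sum(!idx) < 3L * (k - 1L)) next
    sub <- if (k == 2L) rep(1L, sum(!idx)) else
      km_grp(f[!idx, , drop = FALSE], k - 1L)
    if (is.null(sub)) next
    grp <- integer(n)
    grp[idx] <- k
    grp[!idx] <- sub
    add(partition_start(grp))
  }
  grp <- km_grp(f, k)
  if (!is.null(grp)) add(partition_start(grp))
  # kmeans++-style seeds: modal assignment to subject profiles drawn with
  # probability proportional to squared distance from those already chosen
  while (length(starts) < n_candidates) {
    picked <- sample.int(n, 1)
    d2 <- rowSums(sweep(f, 2L, f[picked, ])^2)
    for (j in seq_len(k - 1L)) {
      nxt <- sample.int(n, 1, prob = pmax(d2, 1e-12))
      picked <- c(picked, nxt)
      d2 <- pmin(d2, rowSums(sweep(f, 2L, f[nxt, ])^2))
    }
    dist <- vapply(picked, function(i) {
      rowSums(sweep(f, 2L, f[i, ])^2)
    }, numeric(n))
    add(partition_start(max.col(-dist, ties.method = "first")))
  }
  starts[seq_len(min(n_candidates, length(starts)))]
}

# reorder classes by ascending total intercept (alpha_A + alpha_D)
lcga_canonicalize <- function(fit) {
  ord <- order(fit$theta[1, ] + fit$theta[3, ])
  fit$theta <- fit$theta[, ord, drop = FALSE]
  dimnames(fit$theta) <- NULL
  fit$pi <- unname(fit$pi[ord])
  fit$posterior <- fit$posterior[, ord, drop = FALSE]
  dimnames(fit$posterior) <- NULL
  fit
}

#' Relative entropy of a posterior classification
#'
#' E = 1 + sum(p log p) / (n log K); 1 for crisp 0/1 posteriors, 0 for
#' uninformative (uniform) ones. Undefined (NA) at K = 1.
#'
#' @param posterior n x K matrix of class posterior probabilities.
#' @return A single number in \[0, 1\], or NA for K = 1.
#' @export
relative_entropy <- function(posterior) {
  k <- ncol(posterior)
  if (k < 2L) return(NA_real_)
  p <- posterior
  plogp <- ifelse(p > 0, p * log(p), 0)
  1 + sum(plogp) / (nrow(p) * log(k))
}

#' Fit a latent-class growth model to two parallel processes
#'
#' Maximizes, by EM, the K-component mixture likelihood of the six wave-level
#' mean scores (three waves of anxiety and of depression), where each class
#' has its own linear growth means per process (intercept and slope on time
#' scores 0, 1, 2), within-class growth-factor variance is fixed at zero, and
#' residual variances are shared across classes and waves but free per
#' process. Initialization is per-subject least squares followed by k-means;
#' additional restarts perturb those starts and the best likelihood wins.
#' Classes are reported in ascending order of total intercept.
#'
#' @param y A `score_table` or an n x 6 mean-score matrix ([growth_scores()]).
#' @param k Number of classes (K >= 1; K = 1 is the plain linear growth
#'   model, fitted in closed form).
#' @param n_restarts Number of EM starts.
#' @param seed Optional seed controlling initialization.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param prev_fit Optional fitted (k-1)-class model; its solution seeds the
#'   incremental-split starts. Computed internally when absent.
#' @return An `lcga_fit` list: `k`, `pi`, `theta` (4 x K growth means, rows
#'   `alpha_anx`, `beta_anx`, `alpha_dep`, `beta_dep`), `residual_var`
#'   (per process), `logLik`, `n`, `n_params`, `AIC`, `BIC`, `aBIC`,
#'   `entropy`, `posterior`, `assignment`, `loglik_trace`.
#' @export
fit_lcga <- function(y, k, n_restarts = 5, seed = NULL, tol = 1e-7,
                     max_iter = 500, prev_fit = NULL) {
  y <- growth_scores(y)
  n <- nrow(y)
  stopifnot(k >= 1L, n > k)
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) {
    lam <- growth_loadings()
    proj <- solve(crossprod(lam)) %*% t(lam)
    theta <- cbind(c(proj %*% colMeans(y[, 1:3, drop = FALSE]),
                     proj %*% colMeans(y[, 4:6, drop = FALSE])))
    mu <- c(lam %*% theta[1:2, , drop = FALSE],
            lam %*% theta[3:4, , drop = FALSE])
    r <- sweep(y, 2L, mu)
    s2 <- c(sum(r[, 1:3]^2), sum(r[, 4:6]^2)) / (3 * n)
    ll <- -1.5 * n * (log(2 * pi * s2[1]) + log(2 * pi * s2[2])) - 3 * n
    best <- list(ll = ll, theta = theta, pi = 1, s2 = s2,
                 posterior = matrix(1, n, 1), iterations = 1L,
                 loglik_trace = ll)
  } else {
    # short-EM candidate search: every start gets a burn-in, then up to four
    # candidates are continued to convergence (warm continuation: class
    # weights and residual variances carry over, so burn-in plus
    # continuation is the same EM trajectory as one long run). Short
    # likelihoods barely separate basins, so the cut is deliberately wide.
    if (is.null(prev_fit) && k > 1L) {
      prev_fit <- fit_lcga(y, k - 1L, n_restarts = max(2L, n_restarts - 1L),
                           tol = tol, max_iter = max_iter)
    }
    starts <- lcga_starts(y, k, max(2L, 2L * n_restarts - 2L),
                          prev_assignment = prev_fit$assignment)
    shorts <- lapply(starts, function(s) {
      lcga_em(y, k, s$theta, 1e-4, 30L, pi0 = s$pi, s20 = s$s2)
    })
    ok <- which(!vapply(shorts, is.null, logical(1)))
    if (length(ok) == 0L) {
      stop("all EM restarts degenerated to an empty class", call. = FALSE)
    }
    ok <- ok[order(vapply(shorts[ok], `[[`, numeric(1), "ll"),
                   decreasing = TRUE)]
    best <- NULL
    for (i in ok[seq_len(min(4L, length(ok)))]) {
      fit <- lcga_em(y, k, shorts[[i]]$theta, tol, max_iter,
                     pi0 = shorts[[i]]$pi, s20 = shorts[[i]]$s2)
      if (is.null(fit)) next
      if (is.null(best) || fit$ll > best$ll) best <- fit
    }
    if (is.null(best)) {
      stop("all EM restarts degenerated to an empty class", call. = FALSE)
    }
    best <- lcga_canonicalize(best)
  }
  q <- lcga_param_count(k)
  rownames(best$theta) <- c("alpha_anx", "beta_anx", "alpha_dep", "beta_dep")
  structure(list(
    k = k, pi = best$pi, theta = best$theta,
    residual_var = setNames(best$s2, c("anx", "dep")),
    logLik = best$ll, n = n, n_params = q,
    AIC = -2 * best$ll + 2 * q,
    BIC = -2 * best$ll + q * log(n),
    aBIC = -2 * best$ll + q * log((n + 2) / 24),
    entropy = relative_entropy(best$posterior),
    posterior = best$posterior,
    assignment = max.col(best$posterior, ties.method = "first"),
    iterations = best$iterations,
    loglik_trace = best$loglik_trace),
    class = "lcga_fit")
}

#' @export
print.lcga_fit <- function(x, ...) {
  cat(sprintf("<lcga_fit> K = %d, n = %d, logLik = %.2f, BIC = %.2f\n",
              x$k, x$n, x$logLik, x$BIC))
  cat("class proportions:", paste(sprintf("%.3f", x$pi), collapse = " / "),
      "\n")
  if (!is.na(x$entropy)) cat(sprintf("relative entropy: %.3f\n", x$entropy))
  invisible(x)
}

# simulate mean-score data from a fitted LCGA model (parametric bootstrap)
simulate_lcga <- function(fit, n) {
  lam <- growth_loadings()
  cls <- sample.int(fit$k, n, replace = TRUE, prob = fit$pi)
  mu_a <- lam %*% fit$theta[1:2, , drop = FALSE]
  mu_d <- lam %*% fit$theta[3:4, , drop = FALSE]
  y <- cbind(t(mu_a)[cls, , drop = FALSE] +
               matrix(rnorm(n * 3, 0, sqrt(fit$residual_var[1])), n, 3),
             t(mu_d)[cls, , drop = FALSE] +
               matrix(rnorm(n * 3, 0, sqrt(fit$residual_var[2])), n, 3))
  colnames(y) <- c(paste0("anx_t", 1:3), paste0("dep_t", 1:3))
  y
}

#' Bootstrap likelihood ratio test for K versus K - 1 classes
#'
#' Parametric bootstrap: datasets are simulated from the fitted (K-1)-class
#' model, both models are refitted to each, and the p-value is
#' (1 + #\{LR_b >= LR_obs\}) / (reps + 1).
#'
#' @param y Mean-score data (matrix or `score_table`).
#' @param fit_small,fit_big Fitted models with K - 1 and K classes.
#' @param reps Number of bootstrap replicates.
#' @param seed Optional seed.
#' @param n_restarts EM restarts used for the refits.
#' @param ... Passed to [fit_lcga()] for the refits (`tol`, `max_iter`).
#' @return List with `statistic` (observed LR), `p_value`, `reps`.
#' @export
blrt <- function(y, fit_small, fit_big, reps = 99, seed = NULL,
                 n_restarts = 2, ...) {
  stopifnot(fit_big$k == fit_small$k + 1L)
  if (!is.null(seed)) set.seed(seed)
  y <- growth_scores(y)
  lr_obs <- 2 * (fit_big$logLik - fit_small$logLik)
  n <- nrow(y)
  exceed <- 0L
  for (b in seq_len(reps)) {
    yb <- simulate_lcga(fit_small, n)
    f0 <- fit_lcga(yb, fit_small$k, n_restarts = n_restarts, ...)
    f1 <- fit_lcga(yb, fit_big$k, n_restarts = n_restarts, ...)
    if (2 * (f1$logLik - f0$logLik) >= lr_obs) exceed <- exceed + 1L
  }
  list(statistic = lr_obs, p_value = (1 + exceed) / (reps + 1), reps = reps)
}

#' Class enumeration table for K = 1..K_max
#'
#' Fits the latent-class growth model for an increasing number of classes
#' and tabulates log-likelihood, information criteria (AIC, BIC, aBIC),
#' relative entropy, class proportions and, optionally, the bootstrap
#' likelihood ratio test of K against K - 1.
#'
#' @param y Mean-score data (matrix or `score_table`).
#' @param k_max Largest number of classes to fit.
#' @param n_restarts EM restarts per fit.
#' @param blrt_reps Bootstrap replicates for the BLRT; 0 skips the test.
#' @param seed Optional seed.
#' @param ... Passed to [fit_lcga()] (`tol`, `max_iter`).
#' @return A `class_enumeration` object: `table` (data frame with one row per
#'   K) and `fits` (list of `lcga_fit`).
#' @export
enumerate_classes <- function(y, k_max = 5, n_restarts = 5, blrt_reps = 0,
                              seed = NULL, ...) {
  stopifnot(k_max >= 1L)
  y <- growth_scores(y)
  if (!is.null(seed)) set.seed(seed)
  fits <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- fit_lcga(y, k, n_restarts = n_restarts,
                          prev_fit = if (k > 1L) fits[[k - 1L]], ...)
  }
  tab <- data.frame(
    k = seq_len(k_max),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    n_params = vapply(fits, `[[`, numeric(1), "n_params"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    BIC = vapply(fits, `[[`, numeric(1), "BIC"),
    aBIC = vapply(fits, `[[`, numeric(1), "aBIC"),
    entropy = vapply(fits, `[[`, numeric(1), "entropy"),
    blrt_p = NA_real_,
    proportions = vapply(fits, function(f) {
      paste(sprintf("%.3f", f$pi), collapse = "/")
    }, character(1)))
  if (blrt_reps > 0 && k_max >= 2L) {
    for (k in 2:k_max) {
      tab$blrt_p[k] <- blrt(y, fits[[k - 1L]], fits[[k]], reps = blrt_reps,
                            n_restarts = max(2, n_restarts - 3))$p_value
    }
  }
  structure(list(table = tab, fits = fits), class = "class_enumeration")
}

#' @export
print.class_enumeration <- function(x, ...) {
  cat("<class_enumeration>\n")
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parallel-process latent growth curve model (K = 1, random growth factors).
# y_i ~ MVN(Lambda mu, Lambda Psi Lambda' + Theta), Lambda block-diagonal
# linear loadings per process, Theta diagonal. Psi is parameterized by its
# Cholesky factor so it stays positive (semi)definite; growth-factor means
# are profiled out by generalized least squares.

pp_lgcm_lambda <- function() {
  lam <- growth_loadings()
  rbind(cbind(lam, matrix(0, 3, 2)), cbind(matrix(0, 3, 2), lam))
}

# discrepancy F_ML(Sigma; mu profiled) given sample mean/cov (ML covariance)
pp_lgcm_objective <- function(par, scov, ybar_v, loadmat, logdet_s) {
  l <- diag(exp(par[1:4]))
  l[lower.tri(l)] <- par[5:10]
  psi <- l %*% t(l)
  theta <- exp(2 * par[11:16])
  sigma <- loadmat %*% psi %*% t(loadmat) + diag(theta)
  ev <- eigen(sigma, symmetric = TRUE)
  if (min(ev$values) < 1e-10) return(1e10)
  sigma_inv <- ev$vectors %*% (t(ev$vectors) / ev$values)
  # GLS-profiled growth-factor means
  a <- t(loadmat) %*% sigma_inv
  mu_f <- solve(a %*% loadmat, a %*% ybar_v)
  d <- ybar_v - loadmat %*% mu_f
  sum(log(ev$values)) + sum(sigma_inv * scov) - logdet_s - 6 +
    as.numeric(t(d) %*% sigma_inv %*% d)
}

#' Fit the parallel-process latent growth curve model
#'
#' Maximum-likelihood fit of a joint linear growth model for anxiety and
#' depression mean scores: per-subject growth factors
#' (intercept, slope) x (anxiety, depression) with free mean vector and a
#' free 4 x 4 covariance, plus diagonal wave-level residual variances.
#' Fit statistics come from the likelihood-ratio statistic against the
#' saturated model with the independence model as baseline.
#'
#' @param y Mean-score data (matrix or `score_table`).
#' @param n_restarts Optimizer restarts from jittered starting values.
#' @param seed Optional seed (used only for restart jitter).
#' @return A `pp_lgcm_fit` list: growth-factor means `mu`, covariance `psi`,
#'   residual variances `theta`, `logLik`, `T_stat`, `df`, `CFI`, `TLI`,
#'   `RMSEA`, and the derived cross-process correlations `r_intercept`,
#'   `r_slope`.
#' @export
fit_pp_lgcm <- function(y, n_restarts = 3, seed = NULL) {
  y <- growth_scores(y)
  n <- nrow(y)
  if (!is.null(seed)) set.seed(seed)
  lam <- pp_lgcm_lambda()
  ybar <- colMeans(y)
  s <- crossprod(sweep(y, 2L, ybar)) / n           # ML covariance
  ev_s <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  logdet_s <- sum(log(pmax(ev_s, 1e-12)))
  # starting values from per-subject OLS growth-factor estimates
  f <- subject_ols(y)
  psi0 <- var(f) * 0.7 + diag(1e-3, 4)
  l0 <- t(chol(psi0))
  r0 <- y - f[, c(1, 1, 1, 3, 3, 3)] -
    f[, c(2, 2, 2, 4, 4, 4)] * rep(c(0, 1, 2), 2)[col(y)]
  th0 <- pmax(apply(r0, 2, var), 1e-3)
  par0 <- c(log(diag(l0)), l0[lower.tri(l0)], 0.5 * log(th0))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    p0 <- if (r == 1) par0 else par0 + rnorm(length(par0), 0, 0.2)
    opt <- tryCatch(
      stats::nlminb(p0, pp_lgcm_objective, scov = s, ybar_v = ybar,
                    loadmat = lam, logdet_s = logdet_s,
                    control = list(iter.max = 1000, eval.max = 2000)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("PP-LGCM optimization failed to converge",
                          call. = FALSE)
  par <- best$par
  l <- diag(exp(par[1:4]))
  l[lower.tri(l)] <- par[5:10]
  psi <- l %*% t(l)
  if (any(diag(psi) < 1e-6)) {
    warning("growth-factor covariance at the boundary (near-zero variance)",
            call. = FALSE)
  }
  theta <- exp(2 * par[11:16])
  sigma <- lam %*% psi %*% t(lam) + diag(theta)
  sigma_inv <- solve(sigma)
  a <- t(lam) %*% sigma_inv
  mu <- as.numeric(solve(a %*% lam, a %*% ybar))
  names(mu) <- c("alpha_anx", "beta_anx", "alpha_dep", "beta_dep")
  dimnames(psi) <- list(names(mu), names(mu))
  f_ml <- best$objective
  ll <- -0.5 * n * (6 * log(2 * pi) + f_ml + logdet_s + 6)
  t_stat <- (n - 1) * f_ml
  df <- 27 - 20                                    # 27 moments, 20 parameters
  f0 <- sum(log(diag(s))) - logdet_s               # independence baseline
  t0 <- (n - 1) * f0
  df0 <- 27 - 12
  excess <- max(t_stat - df, 0)
  cfi <- 1 - excess / max(t0 - df0, t_stat - df, 0)
  tli <- ((t0 / df0) - (t_stat / df)) / ((t0 / df0) - 1)
  rmsea <- sqrt(excess / (df * (n - 1)))
  structure(list(
    mu = mu, psi = psi,
    theta = setNames(theta, colnames(growth_scores(y))),
    logLik = ll, n = n, T_stat = t_stat, df = df,
    CFI = cfi, TLI = min(tli, 1), RMSEA = rmsea,
    r_intercept = psi[1, 3] / sqrt(psi[1, 1] * psi[3, 3]),
    r_slope = psi[2, 4] / sqrt(psi[2, 2] * psi[4, 4]),
    convergence = best$convergence),
    class = "pp_lgcm_fit")
}

#' @export
print.pp_lgcm_fit <- function(x, ...) {
  cat(sprintf("<pp_lgcm_fit> n = %d, T(%d) = %.2f, CFI = %.3f, RMSEA = %.3f\n",
              x$n, x$df, x$T_stat, x$CFI, x$RMSEA))
  cat(sprintf("growth means: %s\n",
              paste(sprintf("%s=%.3f", names(x$mu), x$mu), collapse = ", ")))
  cat(sprintf("intercept-intercept r = %.3f, slope-slope r = %.3f\n",
              x$r_intercept, x$r_slope))
  invisible(x)
}
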