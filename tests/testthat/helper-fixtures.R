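# Fixture builders shared across the test files. Everything is generated in
# code; no data files are read.

# minimal wide panel data frame for n subjects with constant item score
toy_panel_df <- function(n = 2, score = 0) {
  out <- data.frame(subject_id = paste0("s", seq_len(n)))
  for (col in copanel:::all_item_cols()) out[[col]] <- rep(score, n)
  out
}

# wide panel with uniformly random item scores (seeded by the caller)
random_panel <- function(n = 10) {
  out <- data.frame(subject_id = paste0("s", seq_len(n)))
  for (col in copanel:::all_item_cols()) {
    out[[col]] <- sample(0:3, n, replace = TRUE)
  }
  panel_data(out)
}

# wrap a bare 16 x 16 coefficient matrix as a fitted network object
make_net <- function(beta, wave_pair = c(1, 2), n = 1000) {
  nodes <- panel_items()
  beta <- as.matrix(beta)
  dimnames(beta) <- list(nodes, nodes)
  structure(list(beta = beta, intercepts = setNames(numeric(16), nodes),
                 covariate_coefs = NULL,
                 lambda = setNames(rep(0.01, 16), nodes),
                 lambda_rule = "min", wave_pair = wave_pair, n = n,
                 nodes = nodes),
            class = "clpn_network")
}

# sparse ground-truth transition matrix with autoregressive diagonal
planted_truth <- function(auto = 1.2, edges = list(), intercept = -1) {
  W <- matrix(0, 16, 16)
  diag(W) <- auto
  for (e in edges) W[e[[1]], e[[2]]] <- e[[3]]
  clpn_truth(W, intercepts = rep(intercept, 16))
}

# the three-class mean-recovery cohort: trajectories kept inside the part of
# the 0-3 scale where item discretization is unbiased, pairwise separation
# of the class mean curves >= 1 on the mean-score scale
recovery_config <- function(n_subjects = 5000, seed = NULL) {
  growth_mixture_config(
    n_subjects = n_subjects,
    class_proportions = c(0.698, 0.272, 0.030),
    intercept_anx = c(1.0, 1.2, 2.0), slope_anx = c(0.0, 0.4, 0.0),
    intercept_dep = c(1.0, 1.2, 2.0), slope_dep = c(0.0, 0.4, 0.0),
    residual_sd = 0.3, item_sd = 0.6,
    offsets_anx = rep(0, 7), offsets_dep = rep(0, 9),
    covariates = FALSE, seed = seed)
}

# configured class mean curves of recovery_config as a 4 x 3 theta matrix
recovery_theta <- function() {
  unname(rbind(c(1.0, 1.2, 2.0), c(0.0, 0.4, 0.0),
               c(1.0, 1.2, 2.0), c(0.0, 0.4, 0.0)))
}

# single-class cohort used for the bootstrap likelihood-ratio null
null_growth_config <- function(n_subjects = 200, seed = NULL) {
  growth_mixture_config(
    n_subjects = n_subjects, class_proportions = 1,
    intercept_anx = 1.2, slope_anx = 0.2,
    intercept_dep = 1.4, slope_dep = 0.2,
    residual_sd = 0.3, item_sd = 0.6,
    offsets_anx = rep(0, 7), offsets_dep = rep(0, 9),
    covariates = FALSE, seed = seed)
}
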