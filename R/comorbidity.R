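#' Per-wave prevalence of clinical-level symptoms
#'
#' Counts subjects flagged above the clinical cutoff at each wave and the
#' corresponding proportion of the cohort.
#'
#' @param scores A `score_table` from [score_panel()].
#' @param condition `"anxiety"` (GAD flag) or `"depression"` (PHQ flag).
#' @return Data frame with columns `wave`, `n`, `count`, `proportion`.
#' @export
prevalence <- function(scores, condition = c("anxiety", "depression")) {
  stopifnot(inherits(scores, "score_table"))
  if (nrow(scores) == 0L) stop("empty score table", call. = FALSE)
  condition <- match.arg(condition)
  flag <- if (condition == "anxiety") scores$anxious else scores$depressed
  out <- do.call(rbind, lapply(sort(unique(scores$wave)), function(w) {
    idx <- scores$wave == w
    data.frame(wave = w, n = sum(idx), count = sum(flag[idx]),
               proportion = mean(flag[idx]))
  }))
  rownames(out) <- NULL
  out
}

#' Chi-square trend test across waves
#'
#' Pearson chi-square on the waves x {flagged, not flagged} contingency
#' table under homogeneity of the flagged proportion, treating waves as
#' independent samples. The accompanying contingency effect size is
#' eta = sqrt(chi-square / N_total) with N_total the grand total of the
#' table (waves x n per wave).
#'
#' @param counts Integer vector of flagged counts, one per wave.
#' @param n_per_wave Number of subjects observed at each wave.
#' @return A `trend_test` list: `chi_square`, `df`, `p_value`, `eta`.
#' @export
trend_chi_square <- function(counts, n_per_wave) {
  stopifnot(length(n_per_wave) == 1L, all(counts >= 0),
            all(counts <= n_per_wave))
  w <- length(counts)
  obs <- rbind(counts, n_per_wave - counts)
  total <- w * n_per_wave
  p_flag <- sum(counts) / total
  expd <- rbind(rep(n_per_wave * p_flag, w), rep(n_per_wave * (1 - p_flag), w))
  if (any(expd == 0)) stop("zero expected cell count", call. = FALSE)
  chi2 <- sum((obs - expd)^2 / expd)
  df <- w - 1L
  structure(
    list(chi_square = chi2, df = df,
         p_value = pchisq(chi2, df, lower.tail = FALSE),
         eta = sqrt(chi2 / total)),
    class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.1f, p = %.3g, eta = %.3f\n",
              x$df, x$chi_square, x$p_value, x$eta))
  invisible(x)
}

#' Cross-wave comorbidity rates
#'
#' For every ordered wave pair (t, s) with s >= t: among subjects above the
#' depression cutoff at wave t, the count and proportion above the anxiety
#' cutoff at wave s.
#'
#' @param scores A `score_table` from [score_panel()].
#' @return Data frame with columns `depression_wave`, `anxiety_wave`,
#'   `n_depressed`, `n_comorbid`, `proportion` (NA when nobody is depressed
#'   at wave t).
#' @export
comorbidity_rates <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  waves <- sort(unique(scores$wave))
  dep <- lapply(waves, function(w) scores$subject_id[scores$wave == w &
                                                       scores$depressed])
  anx <- lapply(waves, function(w) scores$subject_id[scores$wave == w &
                                                       scores$anxious])
  rows <- list()
  for (ti in seq_along(waves)) {
    for (si in ti:length(waves)) {
      n_dep <- length(dep[[ti]])
      n_com <- sum(dep[[ti]] %in% anx[[si]])
      rows[[length(rows) + 1L]] <- data.frame(
        depression_wave = waves[ti], anxiety_wave = waves[si],
        n_depressed = n_dep, n_comorbid = n_com,
        proportion = if (n_dep > 0L) n_com / n_dep else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
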