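#' Construct a three-wave symptom panel
#'
#' A `panel_data` object is a wide data frame with one row per subject: a
#' `subject_id` column, the 48 item columns `<item>_t<wave>` (16 items at each
#' of 3 waves, scored 0-3), and any number of baseline covariate columns.
#' Covariates are measured once (at baseline) and so are constant across waves
#' by construction.
#'
#' @param x A data frame holding `subject_id`, all 48 item columns and the
#'   named covariates.
#' @param covariates Character vector of covariate column names (may be empty).
#' @param validate Check item ranges. Only disable for the continuous-score
#'   diagnostic mode of the simulator.
#' @return `x` with class `panel_data` and a `covariates` attribute.
#' @seealso [read_panel()], [score_panel()], [binarize()]
#' @export
panel_data <- function(x, covariates = character(), validate = TRUE) {
  x <- as.data.frame(x)
  needed <- c("subject_id", all_item_cols(), covariates)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("panel schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$subject_id)) {
    stop("duplicate subject_id values", call. = FALSE)
  }
  if (validate) validate_item_scores(x)
  x <- x[, needed, drop = FALSE]
  structure(x, covariates = covariates,
            class = c("panel_data", "data.frame"))
}

validate_item_scores <- function(x, values = 0:3) {
  for (col in all_item_cols()) {
    v <- x[[col]]
    bad <- which(!(v %in% values))
    if (length(bad) > 0L) {
      stop(sprintf(
        "item score out of range in column '%s' for subject '%s' (value %s)",
        col, x$subject_id[bad[1L]], v[bad[1L]]), call. = FALSE)
    }
  }
  invisible(x)
}

#' @export
print.panel_data <- function(x, ...) {
  covs <- attr(x, "covariates")
  cat(sprintf("<panel_data> %d subjects x 3 waves x 16 items", nrow(x)))
  if (length(covs)) cat("; covariates:", paste(covs, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Read a wide-format panel CSV
#'
#' Expects one row per subject with a header; item columns are named
#' `<item>_t<wave>` (e.g. `gad3_t2`, `phq9_t3`) unless a `schema` map renames
#' them. Subjects missing any item response are dropped (the design is
#' complete-case; the number dropped is reported with a message). Unknown
#' columns are ignored with a warning.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param covariates Covariate column names to retain (after schema mapping).
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the names used in the file (values).
#' @return A [panel_data] object.
#' @export
read_panel <- function(path, covariates = character(), schema = NULL) {
  raw <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      idx <- match(schema[[canon]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- canon
    }
  }
  needed <- c("subject_id", all_item_cols(), covariates)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop("panel schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), needed)
  if (length(extra) > 0L) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[, needed, drop = FALSE]
  }
  complete <- complete.cases(raw[, all_item_cols(), drop = FALSE])
  if (any(!complete)) {
    message(sum(!complete), " subject(s) missing item responses dropped ",
            "(complete-case design)")
    raw <- raw[complete, , drop = FALSE]
  }
  panel_data(raw, covariates = covariates)
}

#' Write a panel back to wide CSV
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(x, f))` reproduces `x`
#' exactly up to column order.
#'
#' @param x A [panel_data] or binary panel object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Scale scores, mean scores and clinical flags per subject-wave
#'
#' Sums the 7 anxiety and 9 depression items at each wave, derives mean
#' scores (sum divided by the number of items; the scale used by the growth
#' models), and flags clinical-level symptoms as a total score at or above
#' `cutoff` (the screeners' conventional threshold of 7).
#'
#' @param x A [panel_data] object.
#' @param cutoff Positive integer; flag threshold on the total score.
#' @return A `score_table` data frame with one row per subject-wave and
#'   columns `subject_id`, `wave`, `gad_sum`, `phq_sum`, `gad_mean`,
#'   `phq_mean`, `anxious`, `depressed`.
#' @export
score_panel <- function(x, cutoff = 7) {
  stopifnot(inherits(x, "panel_data") || inherits(x, "binary_panel"))
  stopifnot(length(cutoff) == 1L, cutoff > 0)
  out <- do.call(rbind, lapply(panel_waves(), function(w) {
    g <- as.matrix(x[, item_col(gad_items(), w), drop = FALSE])
    p <- as.matrix(x[, item_col(phq_items(), w), drop = FALSE])
    data.frame(
      subject_id = x$subject_id,
      wave = w,
      gad_sum = rowSums(g),
      phq_sum = rowSums(p),
      gad_mean = rowSums(g) / 7,
      phq_mean = rowSums(p) / 9,
      stringsAsFactors = FALSE
    )
  }))
  out$anxious <- out$gad_sum >= cutoff
  out$depressed <- out$phq_sum >= cutoff
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, n_subjects = nrow(x),
            class = c("score_table", "data.frame"))
}

#' Binarize item scores to symptom presence
#'
#' Recodes every item to presence/absence: 0 stays 0, scores 1-3 become 1.
#' This is the representation the cross-lagged panel network is estimated on.
#'
#' @param x A [panel_data] object (or an already binary panel, in which case
#'   the values are unchanged).
#' @return A `binary_panel` object with the same shape and covariates.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "panel_data") || inherits(x, "binary_panel"))
  y <- as.data.frame(x)
  for (col in all_item_cols()) y[[col]] <- as.integer(y[[col]] >= 1)
  structure(y, covariates = attr(x, "covariates"),
            class = c("binary_panel", "data.frame"))
}

#' @export
print.binary_panel <- function(x, ...) {
  cat(sprintf("<binary_panel> %d subjects x 3 waves x 16 symptom indicators\n",
              nrow(x)))
  invisible(x)
}

# n x 16 matrix of the item values at one wave, columns in panel_items() order
item_matrix <- function(x, wave) {
  m <- as.matrix(x[, item_col(panel_items(), wave), drop = FALSE])
  colnames(m) <- panel_items()
  storage.mode(m) <- "double"
  m
}

# covariate design matrix (standardized), or NULL when none requested
covariate_matrix <- function(x, covariates, standardize = TRUE) {
  if (is.null(covariates) || length(covariates) == 0L) return(NULL)
  miss <- setdiff(covariates, names(x))
  if (length(miss) > 0L) {
    stop("unknown covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(as.data.frame(lapply(x[covariates], as.numeric)))
  colnames(m) <- covariates
  if (standardize) {
    s <- apply(m, 2, sd)
    s[s == 0] <- 1
    m <- scale(m, center = TRUE, scale = s)
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  m
}
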