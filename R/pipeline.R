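# End-to-end orchestration: (simulate | read) -> score -> descriptives ->
# trajectory classes -> per-class lagged networks at both wave pairs ->
# optional stability -> replicability, all under one master seed.

#' Configuration for a full pipeline run
#'
#' @param input Either a path to a wide panel CSV or a
#'   [growth_mixture_config()] to simulate from.
#' @param out_dir Output directory (created if needed).
#' @param cutoff Clinical cutoff on the scale totals.
#' @param covariates Covariate columns used when reading a CSV and when
#'   adjusting the networks (NULL: none).
#' @param k_max Largest class count for enumeration.
#' @param n_restarts EM restarts per mixture fit.
#' @param blrt_reps BLRT bootstrap replicates (0 skips the test).
#' @param select Class-count selection rule applied to the enumeration
#'   table: currently `"bic"` (minimum BIC).
#' @param lambda_rule,nfolds Network penalty selection settings.
#' @param bootstrap_B Edge-bootstrap replicates per network (0 skips).
#' @param stability_B Case-dropping subsamples per proportion (0 skips).
#' @param class_floor Minimum class size for fitting its networks; classes
#'   below it are skipped and recorded in the manifest.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, cutoff = 7, covariates = NULL,
                       k_max = 4, n_restarts = 5, blrt_reps = 0,
                       select = "bic", lambda_rule = "min", nfolds = 10,
                       bootstrap_B = 0, stability_B = 0, class_floor = 200,
                       seed = 1) {
  stopifnot(is.character(input) || inherits(input, "growth_mixture_config"),
            seed >= 0)
  structure(list(input = input, out_dir = out_dir, cutoff = cutoff,
                 covariates = covariates, k_max = k_max,
                 n_restarts = n_restarts, blrt_reps = blrt_reps,
                 select = select, lambda_rule = lambda_rule, nfolds = nfolds,
                 bootstrap_B = bootstrap_B, stability_B = stability_B,
                 class_floor = class_floor, seed = seed),
            class = "run_config")
}

stage_seeds <- function(master, n = 12) {
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: panel acquisition (simulation or CSV), scoring and
#' descriptives (prevalence, trend tests, comorbidity), class enumeration on
#' the wave-level mean scores with a BIC-selected solution, and, for every
#' class at or above the size floor, T1->T2 and T2->T3 networks, their
#' replicability comparison, and (optionally) bootstrap accuracy and
#' case-dropping stability. All artifacts are written under
#' `config$out_dir`; the returned manifest lists each file with an MD5
#' content hash.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list: `files` (named paths), `hashes`,
#'   `selected_k`, `class_sizes`, `skipped_classes`, `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- stage_seeds(config$seed)
  files <- character()
  path_for <- function(name) file.path(config$out_dir, name)

  # --- stage 1: acquire panel -------------------------------------------
  if (inherits(config$input, "growth_mixture_config")) {
    cfg <- config$input
    cfg$seed <- seeds[1]
    sim <- simulate_growth_mixture(cfg)
    panel <- sim$panel
    covariates <- if (is.null(config$covariates)) character() else
      config$covariates
    write_panel(panel, path_for("panel.csv"))
    files["panel"] <- path_for("panel.csv")
  } else {
    covariates <- if (is.null(config$covariates)) character() else
      config$covariates
    panel <- read_panel(config$input, covariates = covariates)
  }

  # --- stage 2: scoring + descriptives ----------------------------------
  scores <- score_panel(panel, cutoff = config$cutoff)
  n <- attr(scores, "n_subjects")
  prev_anx <- prevalence(scores, "anxiety")
  prev_dep <- prevalence(scores, "depression")
  descriptives <- list(
    n_subjects = n, cutoff = config$cutoff,
    prevalence_anxiety = prev_anx,
    prevalence_depression = prev_dep,
    trend_anxiety = unclass(trend_chi_square(prev_anx$count, n)),
    trend_depression = unclass(trend_chi_square(prev_dep$count, n)),
    comorbidity = comorbidity_rates(scores))
  files["descriptives"] <- write_json_file(descriptives,
                                           path_for("descriptives.json"))

  # --- stage 3: trajectory classes --------------------------------------
  enum <- enumerate_classes(scores, k_max = config$k_max,
                            n_restarts = config$n_restarts,
                            blrt_reps = config$blrt_reps, seed = seeds[2])
  write.csv(enum$table, path_for("class_enumeration.csv"), row.names = FALSE)
  files["class_enumeration"] <- path_for("class_enumeration.csv")
  selected_k <- enum$table$k[which.min(enum$table$BIC)]
  best <- enum$fits[[selected_k]]
  assignments <- data.frame(subject_id = panel$subject_id,
                            class = best$assignment)
  write.csv(assignments, path_for("class_assignments.csv"),
            row.names = FALSE)
  files["class_assignments"] <- path_for("class_assignments.csv")

  # --- stage 4: per-class networks --------------------------------------
  class_sizes <- tabulate(best$assignment, nbins = selected_k)
  skipped <- which(class_sizes < config$class_floor)
  nets <- list()
  seed_i <- 3L
  for (k in seq_len(selected_k)) {
    if (k %in% skipped) next
    sub <- panel[best$assignment == k, , drop = FALSE]
    attr(sub, "covariates") <- attr(panel, "covariates")
    class(sub) <- class(panel)
    bsub <- binarize(sub)
    for (fw in 1:2) {
      tag <- sprintf("class%d_t%d%d", k, fw, fw + 1L)
      net <- suppressWarnings(
        fit_clpn(bsub, fw, covariates = config$covariates,
                 lambda_rule = config$lambda_rule, nfolds = config$nfolds,
                 seed = seeds[seed_i]))
      seed_i <- seed_i + 1L
      nets[[tag]] <- net
      write.csv(as.data.frame(net$beta), path_for(paste0(tag, "_beta.csv")))
      write.csv(as.data.frame(edge_or(net)), path_for(paste0(tag, "_or.csv")))
      write.csv(as.data.frame(expected_influence(net)),
                path_for(paste0(tag, "_centrality.csv")), row.names = FALSE)
      files[paste0(tag, "_beta")] <- path_for(paste0(tag, "_beta.csv"))
      files[paste0(tag, "_or")] <- path_for(paste0(tag, "_or.csv"))
      files[paste0(tag, "_centrality")] <-
        path_for(paste0(tag, "_centrality.csv"))
      if (config$bootstrap_B > 0) {
        boot <- bootstrap_edges(bsub, fw, B = config$bootstrap_B,
                                seed = seeds[seed_i],
                                covariates = config$covariates,
                                lambda_rule = config$lambda_rule)
        seed_i <- seed_i + 1L
        acc <- list(mean_ci_lower = mean(boot$ci_lower),
                    mean_ci_upper = mean(boot$ci_upper), B = boot$B)
        files[paste0(tag, "_bootstrap")] <-
          write_json_file(acc, path_for(paste0(tag, "_bootstrap.json")))
      }
      if (config$stability_B > 0) {
        cs <- case_drop_stability(bsub, fw, B_per_prop = config$stability_B,
                                  seed = seeds[seed_i],
                                  covariates = config$covariates,
                                  lambda_rule = config$lambda_rule)
        seed_i <- seed_i + 1L
        files[paste0(tag, "_stability")] <-
          write_json_file(as.list(cs$cs),
                          path_for(paste0(tag, "_stability.json")))
      }
    }
    cmp <- compare_networks(nets[[sprintf("class%d_t12", k)]],
                            nets[[sprintf("class%d_t23", k)]])
    write.csv(cmp$table, path_for(sprintf("class%d_replicability.csv", k)),
              row.names = FALSE)
    files[sprintf("class%d_replicability", k)] <-
      path_for(sprintf("class%d_replicability.csv", k))
  }

  # --- manifest ----------------------------------------------------------
  summary <- list(
    seed = config$seed, n_subjects = n, selected_k = selected_k,
    class_sizes = class_sizes,
    skipped_classes = if (length(skipped)) skipped else integer(0),
    class_proportions = round(class_sizes / sum(class_sizes), 6),
    entropy = best$entropy)
  files["summary"] <- write_json_file(summary, path_for("summary.json"))
  hashes <- vapply(files, function(f) unname(tools::md5sum(f)), character(1))
  manifest <- list(files = as.list(files), hashes = as.list(hashes),
                   seed = config$seed, selected_k = selected_k,
                   class_sizes = class_sizes, skipped_classes = skipped)
  write_json_file(manifest, path_for("manifest.json"))
  structure(c(manifest, list(networks = nets, enumeration = enum,
                             descriptives = descriptives)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d: selected K = %d, class sizes %s\n",
              x$seed, x$selected_k, paste(x$class_sizes, collapse = "/")))
  cat(length(x$files), "artifact(s) written\n")
  invisible(x)
}
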