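# Replicability of two lagged networks (e.g. T1->T2 vs T2->T3): edge-subset
# summaries on the odds-ratio scale, percentage of edges replicated in both,
# and correlations of edge weights and centrality indices.

#' Compare two cross-lagged panel networks
#'
#' Edges are "present" when their OR differs from 1 (nonzero log-odds).
#' Summaries are produced for the subsets all / autoregressive (diagonal) /
#' cross-lagged (off-diagonal) / replicated-in-both, each split by OR > 1
#' and OR < 1. Edge-weight correlations use the union of the two support
#' sets within a subset ("replicated" uses the intersection by definition);
#' `support = "all"` correlates all entries of the subset instead.
#' Percentages are relative to each network's own total edge count, and the
#' centrality correlations are over the 16 raw in-EI and out-EI values.
#'
#' @param net_a,net_b `clpn_network` objects over the same node set.
#' @param scale Correlate `"or"` values (the scale the summaries use) or
#'   `"log"` odds.
#' @param support `"union"` (default) or `"all"` entries for the all /
#'   cross-lagged correlations.
#' @param min_entries Minimum subset size for a defined correlation.
#' @return A `network_comparison` list: `table` (one row per subset x OR
#'   split, with per-network counts, percentages, mean and sd of OR, and the
#'   correlation), `centrality` (in/out-EI correlations with p-values),
#'   `n_edges` per network.
#' @export
compare_networks <- function(net_a, net_b, scale = c("or", "log"),
                             support = c("union", "all"), min_entries = 3) {
  stopifnot(inherits(net_a, "clpn_network"), inherits(net_b, "clpn_network"),
            identical(net_a$nodes, net_b$nodes))
  scale <- match.arg(scale)
  support <- match.arg(support)
  or_a <- edge_or(net_a)
  or_b <- edge_or(net_b)
  pres_a <- net_a$beta != 0
  pres_b <- net_b$beta != 0
  n_a <- sum(pres_a)
  n_b <- sum(pres_b)
  diag_mask <- diag(TRUE, 16)

  val <- function(m) if (scale == "or") m else log(m)
  cor_over <- function(mask) {
    if (sum(mask) < min_entries) return(NA_real_)
    cor(val(or_a)[mask], val(or_b)[mask])
  }
  subset_rows <- function(label, region, replicated = FALSE) {
    in_a <- pres_a & region
    in_b <- pres_b & region
    cor_mask <- if (replicated) {
      in_a & in_b
    } else if (support == "union") in_a | in_b else region
    splits <- list(all = TRUE, or_gt1 = "gt", or_lt1 = "lt")
    rows <- lapply(names(splits), function(sp) {
      mask_a <- if (replicated) in_a & in_b else in_a
      mask_b <- if (replicated) in_a & in_b else in_b
      if (sp == "or_gt1") {
        mask_a <- mask_a & or_a > 1; mask_b <- mask_b & or_b > 1
      } else if (sp == "or_lt1") {
        mask_a <- mask_a & or_a < 1; mask_b <- mask_b & or_b < 1
      }
      data.frame(
        subset = label, split = sp,
        count_a = sum(mask_a), pct_a = 100 * sum(mask_a) / n_a,
        mean_or_a = if (any(mask_a)) mean(or_a[mask_a]) else NA_real_,
        sd_or_a = if (sum(mask_a) > 1) sd(or_a[mask_a]) else NA_real_,
        count_b = sum(mask_b), pct_b = 100 * sum(mask_b) / n_b,
        mean_or_b = if (any(mask_b)) mean(or_b[mask_b]) else NA_real_,
        sd_or_b = if (sum(mask_b) > 1) sd(or_b[mask_b]) else NA_real_,
        r = if (sp == "all") cor_over(cor_mask) else NA_real_)
    })
    do.call(rbind, rows)
  }
  tab <- rbind(
    subset_rows("all", matrix(TRUE, 16, 16)),
    subset_rows("autoregressive", diag_mask),
    subset_rows("cross_lagged", !diag_mask),
    subset_rows("replicated", matrix(TRUE, 16, 16), replicated = TRUE))
  rownames(tab) <- NULL

  ei_a <- raw_ei(net_a$beta)
  ei_b <- raw_ei(net_b$beta)
  ctest <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- cor.test(a, b)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  centrality <- rbind(in_ei = ctest(ei_a$in_ei, ei_b$in_ei),
                      out_ei = ctest(ei_a$out_ei, ei_b$out_ei))

  structure(list(table = tab, centrality = as.data.frame(centrality),
                 n_edges = c(a = n_a, b = n_b), scale = scale,
                 support = support),
            class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  rep_row <- x$table[x$table$subset == "replicated" & x$table$split == "all", ]
  cat(sprintf("<network_comparison> edges: %d vs %d; replicated %d (%.1f%% / %.1f%%)\n",
              x$n_edges["a"], x$n_edges["b"], rep_row$count_a, rep_row$pct_a,
              rep_row$pct_b))
  cat(sprintf("replicated-edge r = %.3f; out-EI r = %.3f, in-EI r = %.3f\n",
              rep_row$r, x$centrality["out_ei", "r"],
              x$centrality["in_ei", "r"]))
  invisible(x)
}
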