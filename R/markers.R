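#' Marker-finder settings
#'
#' @param n_top Markers reported per group. The default of 13 mirrors a
#'   typical per-cluster budget for a PBMC-scale dataset (roughly 118 genes
#'   over 9 clusters).
#' @param lfc_min Minimum natural-log fold-change (group vs rest) a marker
#'   must exceed; up-regulated markers only.
#' @param pct_min Minimum fraction of in-group cells expressing the gene.
#' @param adjust_method Multiple-testing correction: `"bonferroni"` or
#'   `"bh"`.
#' @return A list of class `marker_config`.
#' @export
marker_config <- function(n_top = 13, lfc_min = 0.25, pct_min = 0.1,
                          adjust_method = c("bonferroni", "bh")) {
  adjust_method <- match.arg(adjust_method)
  stopifnot(n_top >= 1, pct_min >= 0, pct_min <= 1)
  structure(list(n_top = as.integer(n_top), lfc_min = lfc_min,
                 pct_min = pct_min, adjust_method = adjust_method),
            class = "marker_config")
}

#' One-vs-rest marker genes for a grouping of cell clusters
#'
#' For every group in `grouping`, tests each gene's `lognorm` expression in
#' the group's cells against all other cells in the grouping's scope with a
#' two-sided Wilcoxon rank-sum test (tie-corrected normal approximation),
#' filters to up-regulated genes (`log_fc > lfc_min`, `pct_in >= pct_min`),
#' ranks by ascending adjusted p-value with ties broken by descending
#' log-fold-change then gene ID, and keeps the top `n_top`. The
#' log-fold-change is the difference of the natural logs of mean de-logged
#' expression (plus a 1e-9 pseudocount) in and out of the group.
#'
#' @param ds Preprocessed, labeled dataset.
#' @param grouping A [cluster_grouping()], or `NULL` for the flat grouping of
#'   every base cluster as its own group.
#' @param cfg A [marker_config()].
#' @return A data.frame of class `marker_table` with columns `group`,
#'   `rank`, `gene`, `stat`, `p`, `p_adj`, `log_fc`, `pct_in`, `pct_out`.
#'   Attribute `groups` holds the ordered group labels (kept even for groups
#'   whose table is empty after filtering); attribute `group_members` the
#'   base clusters of each group.
#' @export
one_vs_all_markers <- function(ds, grouping = NULL, cfg = marker_config()) {
  stopifnot(inherits(cfg, "marker_config"))
  cl <- as.character(cluster_labels(ds))
  if (is.null(grouping)) {
    grouping <- cluster_grouping(as.list(sort(unique(cl))))
  }
  stopifnot(inherits(grouping, "cluster_grouping"))
  if (length(grouping$groups) < 2L) {
    stop("grouping must have at least 2 groups")
  }
  scope_cells <- which(cl %in% grouping$scope)
  lognorm <- SummarizedExperiment::assay(ds, "lognorm")[, scope_cells,
                                                        drop = FALSE]
  cl <- cl[scope_cells]
  rk <- .rank_matrix(lognorm)
  .markers_impl(lognorm, cl, grouping, cfg, rk)
}

# Core marker finder on a precomputed scope: lognorm and rk are restricted
# to the scope's cells. Split out so agglomeration can reuse the rank matrix
# across the many candidate groupings of one scope.
.markers_impl <- function(lognorm, cl, grouping, cfg, rk) {
  expd <- expm1(lognorm)
  eps <- 1e-9
  out <- vector("list", length(grouping$groups))
  labels <- group_labels(grouping)
  for (i in seq_along(grouping$groups)) {
    members <- grouping$groups[[i]]
    idx <- which(cl %in% members)
    if (length(idx) < 2L) {
      stop("group '", labels[i], "' has fewer than 2 cells")
    }
    if (length(idx) == ncol(lognorm)) {
      stop("group '", labels[i], "' covers the whole scope")
    }
    wt <- .wilcox_group_vs_rest(rk, idx)
    mean_in <- rowMeans(expd[, idx, drop = FALSE])
    mean_out <- rowMeans(expd[, -idx, drop = FALSE])
    log_fc <- log(mean_in + eps) - log(mean_out + eps)
    pct_in <- rowMeans(lognorm[, idx, drop = FALSE] > 0)
    pct_out <- rowMeans(lognorm[, -idx, drop = FALSE] > 0)
    p_adj <- stats::p.adjust(
      wt$p_value,
      method = if (cfg$adjust_method == "bh") "BH" else "bonferroni")
    keep <- which(log_fc > cfg$lfc_min & pct_in >= cfg$pct_min)
    if (length(keep)) {
      genes <- rownames(lognorm)[keep]
      ord <- order(p_adj[keep], -log_fc[keep], genes)
      keep <- keep[ord][seq_len(min(cfg$n_top, length(keep)))]
      out[[i]] <- data.frame(
        group = labels[i], rank = seq_along(keep),
        gene = rownames(lognorm)[keep],
        stat = wt$statistic[keep], p = wt$p_value[keep],
        p_adj = p_adj[keep], log_fc = log_fc[keep],
        pct_in = pct_in[keep], pct_out = pct_out[keep],
        row.names = NULL)
    } else {
      out[[i]] <- NULL
    }
  }
  tab <- do.call(rbind, out)
  if (is.null(tab)) {
    tab <- data.frame(group = character(), rank = integer(),
                      gene = character(), stat = numeric(), p = numeric(),
                      p_adj = numeric(), log_fc = numeric(),
                      pct_in = numeric(), pct_out = numeric())
  }
  attr(tab, "groups") <- labels
  attr(tab, "group_members") <- grouping$groups
  class(tab) <- c("marker_table", class(tab))
  tab
}

#' Genes per group of a marker table, in rank order
#' @param mt A `marker_table`.
#' @return Named list (one entry per group, possibly empty character
#'   vectors), in the table's group order.
#' @export
marker_genes <- function(mt) {
  labels <- attr(mt, "groups")
  out <- lapply(labels, function(g) mt$gene[mt$group == g])
  names(out) <- labels
  out
}

#' Write / read a marker table as TSV
#'
#' @param mt A `marker_table`.
#' @param path Output TSV path.
#' @param split_id Identifier recorded in the `split_id` column.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(mt, path, split_id = "S1") {
  df <- cbind(split_id = split_id, as.data.frame(mt))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
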