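#' Assemble the zero-masked hierarchical feature matrix
#'
#' Concatenates the per-split marker submatrices of a hierarchy into one
#' feature matrix (features in rows, cells in columns). Splits are taken in
#' tree pre-order; within a split, groups in grouping order and genes in
#' marker rank order. For a feature belonging to split *S*, cells whose base
#' cluster is outside *S*'s scope are set to exactly 0 (they were not part
#' of that split's analysis). The same gene may appear under several splits
#' as distinct features, since their masks differ. This matrix backs both
#' the assembled heatmap and the downstream UMAP/classification.
#'
#' @param ds Preprocessed, labeled dataset the hierarchy was built on.
#' @param root A `hierarchy_node` from [build_hierarchy()].
#' @param layer Expression layer to read: `"scaled"` (default) or
#'   `"lognorm"`.
#' @return A list of class `assembled_features`: `values` (features x cells
#'   matrix), `feature_meta` (data.frame with `split_id`, `group`, `gene`),
#'   `cell_ids`, `split_order`, `layer`.
#' @export
assemble_features <- function(ds, root, layer = c("scaled", "lognorm")) {
  layer <- match.arg(layer)
  L <- SummarizedExperiment::assay(ds, layer)
  cl <- as.character(cluster_labels(ds))
  splits <- hierarchy_splits(root)
  blocks <- list()
  meta <- list()
  for (nd in splits) {
    genes_by_group <- marker_genes(nd$split_markers)
    in_scope <- cl %in% nd$members
    for (grp in names(genes_by_group)) {
      genes <- genes_by_group[[grp]]
      if (!length(genes)) next
      block <- L[genes, , drop = FALSE]
      block[, !in_scope] <- 0
      blocks[[length(blocks) + 1L]] <- block
      meta[[length(meta) + 1L]] <- data.frame(
        split_id = nd$split_id, group = grp, gene = genes, row.names = NULL)
    }
  }
  if (!length(blocks)) stop("no marker genes at any split; nothing to assemble")
  values <- do.call(rbind, blocks)
  feature_meta <- do.call(rbind, meta)
  rownames(values) <- paste(feature_meta$split_id, feature_meta$gene,
                            sep = ":")
  structure(list(values = values, feature_meta = feature_meta,
                 cell_ids = colnames(ds),
                 split_order = vapply(splits, function(nd) nd$split_id, ""),
                 layer = layer),
            class = "assembled_features")
}

#' Render the assembled marker heatmap
#'
#' Features (rows) are grouped into horizontal sections per split; cells
#' (columns) are grouped by base cluster. Masked (out-of-scope) entries are
#' drawn white; everything else on a blue-white-red scale clipped at
#' `±clip`.
#'
#' @param am An `assembled_features` object.
#' @param ds The dataset it was assembled from.
#' @param path Output image path (`.png` or `.pdf`).
#' @param clip Color-scale bound.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(am, ds, path, clip = 2.5) {
  disp <- .assembled_display(am, ds, clip)
  M <- disp$matrix
  gaps_col <- disp$gaps_col
  gaps_row <- disp$gaps_row
  breaks <- seq(-clip, clip, length.out = 101)
  cols <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(100)
  grDevices::png(path, width = 1200, height = 900)
  on.exit(grDevices::dev.off(), add = TRUE)
  pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                     show_colnames = FALSE, show_rownames = nrow(M) <= 80,
                     gaps_col = utils::head(as.numeric(gaps_col), -1),
                     gaps_row = utils::head(as.numeric(gaps_row), -1),
                     color = cols, breaks = breaks, na_col = "#FFFFFF",
                     border_color = NA, legend = TRUE)
  invisible(path)
}

# Display form of the assembled matrix: cells ordered by base cluster,
# values clipped, masked (out-of-scope) entries as NA so they render white.
.assembled_display <- function(am, ds, clip = 2.5) {
  cl <- as.character(cluster_labels(ds))
  cell_ord <- order(cl, colnames(ds))
  M <- am$values[, cell_ord, drop = FALSE]
  M <- pmin(pmax(M, -clip), clip)
  splits <- split(seq_len(nrow(M)), am$feature_meta$split_id)
  scope_by_split <- .split_scopes(am, ds)
  cl_ord <- cl[cell_ord]
  for (sid in names(splits)) {
    out_cols <- !(cl_ord %in% scope_by_split[[sid]])
    if (any(out_cols)) M[splits[[sid]], out_cols] <- NA
  }
  sect <- factor(am$feature_meta$split_id,
                 levels = unique(am$feature_meta$split_id))
  list(matrix = M,
       gaps_col = cumsum(table(factor(cl_ord, levels = unique(cl_ord)))),
       gaps_row = cumsum(table(sect)))
}

# scope (member base clusters) of each split id in an assembled matrix
.split_scopes <- function(am, ds) {
  scopes <- list()
  # reconstruct scopes from feature_meta group labels: a split's scope is the
  # union of its group labels' members ("A+B" -> A, B)
  for (sid in unique(am$feature_meta$split_id)) {
    grps <- unique(am$feature_meta$group[am$feature_meta$split_id == sid])
    scopes[[sid]] <- unique(unlist(strsplit(grps, "+", fixed = TRUE)))
  }
  scopes
}

#' Count structurally masked entries of an assembled matrix
#' @param am An `assembled_features` object.
#' @param ds The dataset it was assembled from.
#' @return Integer count of entries zeroed because the cell lies outside the
#'   feature's split scope.
#' @export
masked_entry_count <- function(am, ds) {
  cl <- as.character(cluster_labels(ds))
  scopes <- .split_scopes(am, ds)
  sum(vapply(seq_len(nrow(am$values)), function(i) {
    sum(!(cl %in% scopes[[am$feature_meta$split_id[i]]]))
  }, 0L))
}

#' 2-D UMAP embedding of a feature matrix
#'
#' @param features Features x cells numeric matrix (e.g.
#'   `assemble_features()$values`).
#' @param labels Per-cell labels for the output table.
#' @param seed Integer seed; embeddings are reproducible for a fixed seed.
#' @param n_neighbors UMAP neighborhood size.
#' @param path Optional TSV output (`cell_id`, `x`, `y`, `label`).
#' @return Data.frame with columns `cell_id`, `x`, `y`, `label`.
#' @export
export_umap <- function(features, labels, seed = 1, n_neighbors = 15,
                        path = NULL) {
  if (inherits(features, "assembled_features")) features <- features$values
  if (ncol(features) < 10L) stop("need at least 10 cells for an embedding")
  if (all(apply(features, 1, stats::sd) == 0)) {
    stop("embedding failed: feature matrix is constant")
  }
  emb <- tryCatch({
    set.seed(seed)
    uwot::umap(t(features), n_neighbors = min(n_neighbors, ncol(features) - 1),
               n_threads = 1, n_sgd_threads = 1, batch = FALSE)
  }, error = function(e) {
    stop("embedding failed: ", conditionMessage(e))
  })
  out <- data.frame(cell_id = colnames(features), x = emb[, 1], y = emb[, 2],
                    label = as.character(labels), row.names = NULL)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}

#' Write an assembled matrix as sparse MTX plus feature metadata TSV
#' @param am An `assembled_features` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_assembled <- function(am, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(am$values, sparse = TRUE),
                  file.path(dir, "assembled.mtx"))
  utils::write.table(am$feature_meta, file.path(dir, "features_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(am$cell_ids, file.path(dir, "cells.tsv"))
  invisible(dir)
}
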