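#' A partition of base cell clusters into groups
#'
#' @param groups List of character vectors of base cluster labels; must be
#'   disjoint and non-empty. Members are sorted and groups ordered by their
#'   smallest member, so equal partitions compare identical.
#' @param scope Optional set of base clusters in play; defaults to the union
#'   of `groups`, and must equal it.
#' @return A list of class `cluster_grouping` with elements `groups` and
#'   `scope`.
#' @export
cluster_grouping <- function(groups, scope = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  groups <- lapply(groups, function(g) sort(as.character(g)))
  if (any(lengths(groups) == 0L)) stop("empty group in grouping")
  all_members <- unlist(groups)
  if (anyDuplicated(all_members)) {
    stop("groups are not disjoint: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  if (is.null(scope)) scope <- all_members
  scope <- sort(as.character(scope))
  if (!identical(sort(all_members), scope)) {
    stop("groups do not partition the scope")
  }
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  structure(list(groups = groups, scope = scope),
            class = "cluster_grouping")
}

#' Group labels of a grouping (members joined by "+")
#' @param grouping A `cluster_grouping`.
#' @return Character vector of labels, in group order.
#' @export
group_labels <- function(grouping) {
  vapply(grouping$groups, paste, "", collapse = "+")
}

.partition_key <- function(grouping) {
  paste(group_labels(grouping), collapse = "|")
}

.merge_pair <- function(grouping, i, j) {
  stopifnot(i != j, i >= 1, j >= 1,
            i <= length(grouping$groups), j <= length(grouping$groups))
  g <- grouping$groups
  merged <- c(g[[i]], g[[j]])
  cluster_grouping(c(g[-c(i, j)], list(merged)), scope = grouping$scope)
}

#' Scoring settings for the marker heatmap
#'
#' @param k Weight of the off-diagonal penalty; the score is
#'   `s = (V_diagonal - k * V_offdiagonal) / n_groups`. Default 5.
#' @param layer Expression layer the heatmap reads: `"scaled"` (default) or
#'   `"lognorm"`.
#' @param clip Upper bound applied to the layer before averaging (the usual
#'   display convention for z-scored heatmaps), or `NULL`.
#' @param floor Lower bound applied to the layer before averaging. The
#'   default 0 treats below-average expression as absent signal rather than
#'   negative signal, so an empty off-diagonal block contributes ~0 instead
#'   of a negative value that would reward arbitrary merges. Set to `-clip`
#'   for a symmetric clamp, or `NULL` for none.
#' @param off_blocks Resolution of the off-diagonal maximum: `"cluster"`
#'   (default) takes the maximum block mean over the base cell clusters
#'   outside the marker set's group, `"group"` over the other groups of the
#'   current grouping. Base-cluster resolution keeps a concentrated
#'   off-diagonal signal visible even when the surrounding grouping is
#'   coarse.
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(k = 5, layer = c("scaled", "lognorm"),
                           clip = 2.5, floor = 0,
                           off_blocks = c("cluster", "group")) {
  layer <- match.arg(layer)
  off_blocks <- match.arg(off_blocks)
  stopifnot(k > 0, is.null(clip) || clip > 0)
  structure(list(k = k, layer = layer, clip = clip, floor = floor,
                 off_blocks = off_blocks),
            class = "scoring_config")
}

#' Block score of a marker-gene heatmap
#'
#' Reads the implicit heatmap whose row blocks are each group's marker genes
#' and whose column blocks are each group's cells (restricted to the
#' grouping's scope). For group *i*, the diagonal term is the mean layer
#' value over its markers in its own cells; the off-diagonal term is the
#' maximum over other groups *j* of the mean over its markers in group *j*'s
#' cells. The score is
#' `s = (sum(diag) - k * sum(max offdiag)) / n_groups`; higher is better
#' (less off-diagonal marker expression). A group with no markers
#' contributes 0 to both sums.
#'
#' @param ds Preprocessed, labeled dataset.
#' @param grouping A [cluster_grouping()] with at least 2 groups.
#' @param markers A `marker_table` for this grouping, or a named list of
#'   gene vectors (one per group, in group order).
#' @param cfg A [scoring_config()].
#' @return A list of class `score_report`: `v_diagonal`, `v_off_diagonal`,
#'   `s`, `celltype_number`, `per_group_diag`, `per_group_max_offdiag`, `k`.
#' @export
heatmap_score <- function(ds, grouping, markers, cfg = scoring_config()) {
  stopifnot(inherits(grouping, "cluster_grouping"),
            inherits(cfg, "scoring_config"))
  if (length(grouping$groups) < 2L) {
    stop("score undefined for a single-group grouping")
  }
  cl <- as.character(cluster_labels(ds))
  scope_cells <- which(cl %in% grouping$scope)
  if (!length(scope_cells)) stop("empty scope: no cells in grouping$scope")
  L <- SummarizedExperiment::assay(ds, cfg$layer)[, scope_cells, drop = FALSE]
  .heatmap_score_impl(L, cl[scope_cells], grouping, markers, cfg)
}

.heatmap_score_impl <- function(L, cl, grouping, markers, cfg) {
  if (!is.null(cfg$clip)) L <- pmin(L, cfg$clip)
  if (!is.null(cfg$floor)) L <- pmax(L, cfg$floor)
  genes <- if (inherits(markers, "marker_table")) marker_genes(markers)
           else markers
  g <- length(grouping$groups)
  stopifnot(length(genes) == g)
  cell_idx <- lapply(grouping$groups, function(m) which(cl %in% m))
  diag_v <- numeric(g)
  off_v <- numeric(g)
  for (i in seq_len(g)) {
    gi <- genes[[i]]
    if (!length(gi)) next  # empty marker list contributes 0 to both terms
    diag_v[i] <- mean(L[gi, cell_idx[[i]], drop = FALSE])
    off_units <- if (cfg$off_blocks == "cluster") {
      setdiff(grouping$scope, grouping$groups[[i]])
    } else {
      group_labels(grouping)[-i]
    }
    off_members <- if (cfg$off_blocks == "cluster") {
      as.list(off_units)
    } else {
      grouping$groups[-i]
    }
    off_v[i] <- max(vapply(off_members, function(m) {
      mean(L[gi, which(cl %in% m), drop = FALSE])
    }, 0))
  }
  structure(list(v_diagonal = sum(diag_v), v_off_diagonal = sum(off_v),
                 s = (sum(diag_v) - cfg$k * sum(off_v)) / g,
                 celltype_number = g,
                 per_group_diag = diag_v, per_group_max_offdiag = off_v,
                 k = cfg$k),
            class = "score_report")
}

# Evaluation context for one cell scope: restricted layers, labels, and the
# rank matrix, plus a memo cache of (markers, report) keyed on the exact
# partition. Marker recomputation dominates agglomeration cost, and the same
# grouping recurs across the pair loop, so the cache pays for itself.
.scope_ctx <- function(ds, scope, cfg, mcfg) {
  cl <- as.character(cluster_labels(ds))
  scope <- sort(as.character(scope))
  idx <- which(cl %in% scope)
  if (!length(idx)) stop("empty scope: no cells for ", paste(scope, collapse = ","))
  lognorm <- SummarizedExperiment::assay(ds, "lognorm")[, idx, drop = FALSE]
  layer <- SummarizedExperiment::assay(ds, cfg$layer)[, idx, drop = FALSE]
  counts_per_cluster <- table(cl[idx])
  short <- names(counts_per_cluster)[counts_per_cluster < 2L]
  if (length(short)) {
    stop("base cluster(s) with fewer than 2 cells in scope: ",
         paste(short, collapse = ", "))
  }
  list(cl = cl[idx], lognorm = lognorm, layer = layer,
       rk = .rank_matrix(lognorm), cfg = cfg, mcfg = mcfg,
       cache = new.env(parent = emptyenv()))
}

.eval_grouping <- function(ctx, grouping) {
  key <- .partition_key(grouping)
  if (!is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  mt <- .markers_impl(ctx$lognorm, ctx$cl, grouping, ctx$mcfg, ctx$rk)
  rep <- .heatmap_score_impl(ctx$layer, ctx$cl, grouping, mt, ctx$cfg)
  res <- list(markers = mt, report = rep)
  ctx$cache[[key]] <- res
  res
}

#' Merge a pair of groups and re-score
#'
#' Merges the two indexed groups, re-identifies one-vs-rest markers for the
#' merged grouping, and scores it.
#'
#' @param ds Preprocessed, labeled dataset.
#' @param grouping Current [cluster_grouping()].
#' @param pair Integer vector of two distinct group indices.
#' @param cfg A [scoring_config()].
#' @param mcfg A [marker_config()].
#' @return List with `grouping` (merged), `report` (its `score_report`) and
#'   `markers` (its `marker_table`).
#' @export
score_after_merge <- function(ds, grouping, pair, cfg = scoring_config(),
                              mcfg = marker_config()) {
  if (length(grouping$groups) <= 2L) {
    stop("merging would leave a single group")
  }
  merged <- .merge_pair(grouping, pair[1L], pair[2L])
  ctx <- .scope_ctx(ds, grouping$scope, cfg, mcfg)
  ev <- .eval_grouping(ctx, merged)
  list(grouping = merged, report = ev$report, markers = ev$markers)
}

#' One greedy merge step of the agglomeration
#'
#' Evaluates every pair of groups, each with freshly identified markers, and
#' returns the merge with the highest score if it strictly improves on the
#' current grouping's score (beyond a 1e-9 tie tolerance); otherwise signals
#' no improvement. Ties among candidates are broken by the smallest (i, j)
#' index pair.
#'
#' @inheritParams score_after_merge
#' @return List with `improved` (logical); when `TRUE` also `grouping`,
#'   `report`, `markers`, `pair`; when `FALSE` also `report` for the current
#'   grouping.
#' @export
best_merge_step <- function(ds, grouping, cfg = scoring_config(),
                            mcfg = marker_config()) {
  if (length(grouping$groups) < 3L) {
    stop("need at least 3 groups to attempt a merge")
  }
  ctx <- .scope_ctx(ds, grouping$scope, cfg, mcfg)
  .best_merge_impl(ctx, grouping)
}

.best_merge_impl <- function(ctx, grouping, tol = 1e-9) {
  cur <- .eval_grouping(ctx, grouping)
  g <- length(grouping$groups)
  best <- NULL
  for (i in seq_len(g - 1L)) {
    for (j in seq.int(i + 1L, g)) {
      merged <- .merge_pair(grouping, i, j)
      ev <- .eval_grouping(ctx, merged)
      if (is.null(best) || ev$report$s > best$report$s + tol) {
        best <- list(grouping = merged, report = ev$report,
                     markers = ev$markers, pair = c(i, j))
      }
    }
  }
  if (best$report$s > cur$report$s + tol) {
    c(list(improved = TRUE), best)
  } else {
    list(improved = FALSE, report = cur$report, markers = cur$markers)
  }
}

#' Score-guided agglomeration of base clusters
#'
#' Starting from every base cluster as its own group, repeatedly applies the
#' best accepted merge ([best_merge_step()]) until no merge improves the
#' score or only two groups remain. The score acts as both distance metric
#' and stopping criterion.
#'
#' @param ds Preprocessed, labeled dataset.
#' @param scope Base clusters to agglomerate (default: all).
#' @param cfg A [scoring_config()].
#' @param mcfg A [marker_config()].
#' @return List with `grouping` (final, always >= 2 groups), `markers` (its
#'   marker table), `report` (its score), and `trace` — a list of
#'   `(grouping, report)` pairs from the singleton grouping to the final one.
#' @export
agglomerate <- function(ds, scope = NULL, cfg = scoring_config(),
                        mcfg = marker_config()) {
  cl <- as.character(cluster_labels(ds))
  if (is.null(scope)) scope <- sort(unique(cl))
  scope <- sort(as.character(scope))
  if (length(scope) < 2L) stop("scope must contain at least 2 base clusters")
  ctx <- .scope_ctx(ds, scope, cfg, mcfg)
  grouping <- cluster_grouping(as.list(scope))
  cur <- .eval_grouping(ctx, grouping)
  trace <- list(list(grouping = grouping, report = cur$report))
  markers <- cur$markers
  while (length(grouping$groups) >= 3L) {
    step <- .best_merge_impl(ctx, grouping)
    if (!step$improved) break
    grouping <- step$grouping
    markers <- step$markers
    trace[[length(trace) + 1L]] <- list(grouping = grouping,
                                        report = step$report)
  }
  list(grouping = grouping, markers = markers,
       report = trace[[length(trace)]]$report, trace = trace)
}

#' Build the divisive cluster hierarchy
#'
#' At the root, [agglomerate()] over all base clusters defines the first
#' split: each final group becomes a child. The same analysis is applied
#' recursively inside every child with two or more member clusters, with the
#' data restricted to that child's cells, until all leaves are single base
#' clusters. Each internal node keeps the split's marker table (the merged
#' grouping's one-vs-rest markers) and the agglomeration trace.
#'
#' @inheritParams agglomerate
#' @return The root `hierarchy_node`: a nested list with `members`,
#'   `children`, `split_markers`, `trace`, `split_id` (pre-order `"S1"`,
#'   `"S2"`, ...; `NULL` at leaves).
#' @export
build_hierarchy <- function(ds, cfg = scoring_config(),
                            mcfg = marker_config()) {
  cl <- as.character(cluster_labels(ds))
  base <- sort(unique(cl))
  if (length(base) < 2L) stop("need at least 2 base clusters")
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  build <- function(members) {
    if (length(members) == 1L) {
      return(structure(list(members = members, children = list(),
                            split_markers = NULL, trace = NULL,
                            split_id = NULL),
                       class = "hierarchy_node"))
    }
    counter$n <- counter$n + 1L
    sid <- paste0("S", counter$n)
    agg <- agglomerate(ds, scope = members, cfg = cfg, mcfg = mcfg)
    children <- lapply(agg$grouping$groups, build)
    structure(list(members = members, children = children,
                   split_markers = agg$markers, trace = agg$trace,
                   split_id = sid),
              class = "hierarchy_node")
  }
  build(base)
}

#' Internal (split) nodes of a hierarchy in pre-order
#' @param root A `hierarchy_node`.
#' @return List of internal `hierarchy_node`s, pre-order.
#' @export
hierarchy_splits <- function(root) {
  if (!length(root$children)) return(list())
  c(list(root), do.call(c, lapply(root$children, hierarchy_splits)))
}

#' Leaf labels of a hierarchy
#' @param root A `hierarchy_node`.
#' @return Character vector of base cluster labels at the leaves.
#' @export
hierarchy_leaves <- function(root) {
  if (!length(root$children)) return(root$members)
  unlist(lapply(root$children, hierarchy_leaves))
}

#' Distinct genes used across all splits of a hierarchy
#' @param root A `hierarchy_node`.
#' @return Character vector of unique gene IDs.
#' @export
hierarchy_marker_genes <- function(root) {
  unique(unlist(lapply(hierarchy_splits(root),
                       function(nd) nd$split_markers$gene)))
}

#' Serialize a hierarchy as nested JSON
#'
#' @param root A `hierarchy_node`.
#' @param path Output path, or `NULL` to return the JSON string.
#' @return `path` (invisibly) or the JSON string.
#' @export
hierarchy_to_json <- function(root, path = NULL) {
  to_list <- function(nd) {
    out <- list(members = as.list(nd$members))
    if (!is.null(nd$split_id)) {
      out$split_id <- nd$split_id
      out$score_trace <- lapply(nd$trace, function(tr) {
        list(groups = lapply(tr$grouping$groups, as.list),
             s = tr$report$s, v_diagonal = tr$report$v_diagonal,
             v_off_diagonal = tr$report$v_off_diagonal,
             celltype_number = tr$report$celltype_number,
             k = tr$report$k)
      })
      out$split_markers <- as.data.frame(nd$split_markers)
      out$children <- lapply(nd$children, to_list)
    }
    out
  }
  js <- jsonlite::toJSON(to_list(root), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Newick string of the hierarchy topology
#'
#' Leaf names are base cluster labels; internal nodes are labeled by their
#' split ID.
#'
#' @param root A `hierarchy_node`.
#' @return Single-element character vector (with trailing `;`).
#' @export
as_newick <- function(root) {
  esc <- function(x) gsub("[,();: ]", "_", x)
  rec <- function(nd) {
    if (!length(nd$children)) return(esc(nd$members))
    paste0("(", paste(vapply(nd$children, rec, ""), collapse = ","), ")",
           esc(nd$split_id))
  }
  paste0(rec(root), ";")
}
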