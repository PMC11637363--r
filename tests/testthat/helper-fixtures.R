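# Shared fixtures and independent oracles, built in code at test time.

suppressPackageStartupMessages({
  library(SingleCellExperiment)
  library(SummarizedExperiment)
})

# permissive QC: synthetic cells detect ~180/500 genes, so the tutorial
# default of 200 would empty the dataset
pp <- function(ds, target_sum = 1e4) {
  preprocess(ds, qc_config(min_genes_per_cell = 0, max_mito_fraction = 1,
                           target_sum = target_sum))
}

gen2x2 <- function(seed = 1, ...) {
  generate_hier_counts(hier_spec(seed = seed, ...))
}

# strongly distinct clusters with no shared structure (marker effect well
# above the sparse-count noise floor), the degenerate regime where the
# hierarchy should collapse to the flat one-vs-rest structure
gen_orthogonal <- function(seed = 1, n_per = 60) {
  generate_hier_counts(hier_spec(
    tree = list(A = n_per, B = n_per, C = n_per, D = n_per),
    n_genes = 400, lineage_effect = 2.5, seed = seed))
}

# SCE with an arbitrary expression layer and labels, for direct score tests
layer_sce <- function(L, clusters, layer = "scaled") {
  colnames(L) <- sprintf("c%03d", seq_len(ncol(L)))
  rownames(L) <- sprintf("g%03d", seq_len(nrow(L)))
  assays <- stats::setNames(list(L), layer)
  ds <- SingleCellExperiment::SingleCellExperiment(assays = assays)
  attach_labels(ds, data.frame(cell_id = colnames(L),
                               cluster = clusters))
}

# Independent score oracle: materializes the full heatmap matrix and
# computes every block mean with explicit loops. Mirrors the default
# scoring convention (clamp to [floor, clip], off-diagonal maximum over
# base clusters outside the group).
naive_block_score <- function(L, clusters, groups, genes_list, k = 5,
                              clip = 2.5, floor = 0) {
  for (r in seq_len(nrow(L))) for (cc in seq_len(ncol(L))) {
    v <- L[r, cc]
    if (!is.null(clip) && v > clip) v <- clip
    if (!is.null(floor) && v < floor) v <- floor
    L[r, cc] <- v
  }
  block_mean <- function(genes, cells) {
    tot <- 0; n <- 0
    for (gene in genes) for (cc in cells) {
      tot <- tot + L[gene, cc]; n <- n + 1
    }
    tot / n
  }
  g <- length(groups)
  scope <- sort(unique(unlist(groups)))
  diag_v <- numeric(g)
  off_v <- numeric(g)
  for (i in seq_len(g)) {
    genes <- genes_list[[i]]
    if (length(genes) == 0) next
    diag_v[i] <- block_mean(genes, which(clusters %in% groups[[i]]))
    others <- setdiff(scope, groups[[i]])
    vals <- numeric(0)
    for (cl_out in others) {
      vals <- c(vals, block_mean(genes, which(clusters == cl_out)))
    }
    off_v[i] <- max(vals)
  }
  list(v_diagonal = sum(diag_v), v_off_diagonal = sum(off_v),
       s = (sum(diag_v) - k * sum(off_v)) / g,
       per_group_diag = diag_v, per_group_max_offdiag = off_v)
}

# Exhaustive Wilcoxon oracle: U distribution over all combn() group
# assignments of the pooled observations.
enum_wilcox_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  u_all <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
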