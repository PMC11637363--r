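#' Specification of a hierarchically structured synthetic population
#'
#' Describes a two-level cell population (lineages containing subtypes, or
#' flat leaf clusters) with planted marker genes at every node. Cells of a
#' subtype up-regulate both their lineage's markers (shared with sister
#' subtypes — the source of off-diagonal marker expression) and their own
#' subtype markers. Counts follow a negative binomial with log-normal cell
#' library-size factors.
#'
#' @param tree Named list. Each element is either a named numeric vector of
#'   subtype cell counts (a lineage, e.g. `L1 = c(A = 100, B = 100)`) or a
#'   single unnamed count (a flat leaf cluster, e.g. `A = 100`). Leaf names
#'   must be unique; every leaf needs at least 2 cells.
#' @param n_genes Total genes.
#' @param markers_per_node Planted markers per node (disjoint across nodes).
#' @param lineage_effect,subtype_effect Log-scale mean shifts of the planted
#'   markers (defaults 1.5 and 1.0).
#' @param base_mean Baseline negative-binomial mean per gene (default 0.5).
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`; default 0.5).
#' @param library_size_cv Coefficient of variation of the log-normal cell
#'   library-size factors (default 0.2).
#' @param seed Integer seed.
#' @return A list of class `hier_spec`.
#' @export
hier_spec <- function(tree = list(L1 = c(A = 100, B = 100),
                                  L2 = c(C = 100, D = 100)),
                      n_genes = 500, markers_per_node = 20,
                      lineage_effect = 1.5, subtype_effect = 1.0,
                      base_mean = 0.5, dispersion = 0.5,
                      library_size_cv = 0.2, seed = 1) {
  stopifnot(length(tree) >= 1L, n_genes >= 1L, markers_per_node >= 1L,
            lineage_effect >= 0, subtype_effect >= 0, base_mean > 0,
            dispersion > 0, library_size_cv >= 0)
  leaves <- character()
  n_nodes <- 0L
  for (nm in names(tree)) {
    el <- tree[[nm]]
    if (length(el) == 1L && is.null(names(el))) {
      leaves <- c(leaves, nm)
      n_nodes <- n_nodes + 1L
    } else {
      if (is.null(names(el))) stop("lineage '", nm, "' needs named subtypes")
      leaves <- c(leaves, names(el))
      n_nodes <- n_nodes + 1L + length(el)
    }
    if (any(unlist(el) < 2)) stop("every leaf needs at least 2 cells")
  }
  if (anyDuplicated(leaves)) stop("duplicate leaf names in tree")
  if (n_nodes * markers_per_node > n_genes) {
    stop("infeasible marker budget: ", n_nodes, " nodes x ",
         markers_per_node, " markers > ", n_genes, " genes")
  }
  structure(list(tree = tree, n_genes = as.integer(n_genes),
                 markers_per_node = as.integer(markers_per_node),
                 lineage_effect = lineage_effect,
                 subtype_effect = subtype_effect, base_mean = base_mean,
                 dispersion = dispersion, library_size_cv = library_size_cv,
                 seed = as.integer(seed)),
            class = "hier_spec")
}

#' Generate hierarchically structured synthetic counts
#'
#' Counts for gene *g* in cell *c* are drawn from a negative binomial with
#' mean `base_mean * lib_c * exp(sum of node effects along the cell's path
#' for which g is a planted marker)` and size `1/dispersion`. Marker gene
#' blocks are assigned disjointly to nodes in a fixed order, so the planted
#' map is deterministic. Fully reproducible for a fixed spec seed.
#'
#' @param spec A [hier_spec()].
#' @return List with `dataset` (a labeled `SingleCellExperiment` of raw
#'   counts; labels are the leaf/subtype names), `tree` (named list mapping
#'   each lineage to its member leaves), and `markers` (named list mapping
#'   each node to its planted marker gene IDs).
#' @export
generate_hier_counts <- function(spec) {
  stopifnot(inherits(spec, "hier_spec"))
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  # enumerate nodes: lineages first (tree order), then leaves (tree order)
  lineages <- list()
  leaf_counts <- c()
  leaf_lineage <- c()
  for (nm in names(spec$tree)) {
    el <- spec$tree[[nm]]
    if (length(el) == 1L && is.null(names(el))) {
      leaf_counts[nm] <- el
      leaf_lineage[nm] <- NA_character_
    } else {
      lineages[[nm]] <- names(el)
      leaf_counts[names(el)] <- as.numeric(el)
      leaf_lineage[names(el)] <- nm
    }
  }
  nodes <- c(names(lineages), names(leaf_counts))
  markers <- list()
  next_gene <- 1L
  for (nd in nodes) {
    markers[[nd]] <- gene_ids[seq.int(next_gene,
                                      next_gene + spec$markers_per_node - 1L)]
    next_gene <- next_gene + spec$markers_per_node
  }
  n_cells <- sum(leaf_counts)
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$library_size_cv^2))
  lib <- stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  counts <- matrix(0L, nrow = spec$n_genes, ncol = n_cells)
  cell_leaf <- rep(names(leaf_counts), times = leaf_counts)
  size <- 1 / spec$dispersion
  for (leaf in names(leaf_counts)) {
    cols <- which(cell_leaf == leaf)
    logfc <- numeric(spec$n_genes)
    names(logfc) <- gene_ids
    lin <- leaf_lineage[leaf]
    if (!is.na(lin)) {
      logfc[markers[[lin]]] <- logfc[markers[[lin]]] + spec$lineage_effect
      logfc[markers[[leaf]]] <- logfc[markers[[leaf]]] + spec$subtype_effect
    } else {
      # flat top-level cluster: its single node carries the lineage effect
      logfc[markers[[leaf]]] <- logfc[markers[[leaf]]] + spec$lineage_effect
    }
    mu_gene <- spec$base_mean * exp(logfc)
    for (cc in cols) {
      counts[, cc] <- stats::rnbinom(spec$n_genes, size = size,
                                     mu = mu_gene * lib[cc])
    }
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  ds <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  ds <- attach_labels(ds, data.frame(cell_id = colnames(counts),
                                     cluster = cell_leaf))
  tree_out <- lapply(names(spec$tree), function(nm) {
    el <- spec$tree[[nm]]
    if (length(el) == 1L && is.null(names(el))) nm else names(el)
  })
  names(tree_out) <- names(spec$tree)
  list(dataset = ds, tree = tree_out, markers = markers)
}

#' Apply a simulated batch effect
#'
#' Multiplies every gene's counts by a seeded gene-wise log-normal factor
#' shared across cells, then restores integrality by seeded stochastic
#' rounding (floor plus a Bernoulli on the fractional part, which keeps
#' per-gene means unbiased). Labels are preserved. With `amplitude = 0` the
#' counts are returned unchanged.
#'
#' @param ds Labeled dataset with a `counts` assay.
#' @param amplitude Standard deviation of the log-scale gene factors.
#' @param seed Integer seed.
#' @return A dataset with shifted counts and identical labels.
#' @export
batch_shift <- function(ds, amplitude, seed = 1) {
  stopifnot(amplitude >= 0)
  counts <- as.matrix(SummarizedExperiment::assay(ds, "counts"))
  set.seed(seed)
  f <- exp(stats::rnorm(nrow(counts), mean = 0, sd = amplitude))
  shifted <- counts * f
  frac <- shifted - floor(shifted)
  add <- matrix(stats::rbinom(length(shifted), 1L, as.numeric(frac)),
                nrow = nrow(shifted))
  out <- floor(shifted) + add
  dimnames(out) <- dimnames(counts)
  res <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = out))
  cl <- SummarizedExperiment::colData(ds)$cluster
  if (!is.null(cl)) SummarizedExperiment::colData(res)$cluster <- cl
  res
}

#' Write a generated dataset with its ground truth
#'
#' Writes the 10x-style MTX triplet, the labels TSV, and a
#' `ground_truth.json` holding the tree and planted marker map, so generated
#' data exercise the same I/O path as real data.
#'
#' @param gen Output of [generate_hier_counts()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(gen, dir) {
  write_dataset_mtx(gen$dataset, dir)
  jsonlite::write_json(list(tree = gen$tree, markers = gen$markers),
                       file.path(dir, "ground_truth.json"))
  invisible(dir)
}
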