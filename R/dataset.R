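#' Read a count matrix into an expression dataset
#'
#' Builds a [SingleCellExperiment::SingleCellExperiment] holding a raw count
#' matrix (genes in rows, cells in columns) from either a 10x Genomics MTX
#' triplet directory or a dense delimited table. Cluster labels are attached
#' separately with [attach_labels()].
#'
#' Duplicate gene symbols are disambiguated deterministically with
#' [make.unique()] (second occurrence gets suffix `.1`, and so on).
#'
#' @param path Path to an MTX directory (containing `matrix.mtx[.gz]`,
#'   `barcodes.tsv[.gz]` and `features.tsv[.gz]` or `genes.tsv[.gz]`) or to a
#'   dense TSV file with row and column names.
#' @param format `"mtx_dir"` or `"dense_tsv"`.
#' @param genes_in For `dense_tsv`: whether genes are in `"rows"` or `"cols"`
#'   of the table.
#' @return A `SingleCellExperiment` with a `counts` assay, gene IDs as
#'   rownames and cell IDs as colnames.
#' @export
read_counts <- function(path, format = c("mtx_dir", "dense_tsv"),
                        genes_in = c("rows", "cols")) {
  format <- match.arg(format)
  genes_in <- match.arg(genes_in)
  if (!file.exists(path)) {
    stop("path does not exist: ", path)
  }
  if (format == "mtx_dir") {
    mat_file <- .find_10x_file(path, c("matrix.mtx", "matrix.mtx.gz"))
    bc_file  <- .find_10x_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    ft_file  <- .find_10x_file(path, c("features.tsv", "features.tsv.gz",
                                       "genes.tsv", "genes.tsv.gz"))
    counts <- tryCatch(
      as(Matrix::readMM(mat_file), "CsparseMatrix"),
      error = function(e) stop("malformed MTX file '", mat_file, "': ",
                               conditionMessage(e))
    )
    barcodes <- readLines(bc_file)
    features <- utils::read.delim(ft_file, header = FALSE,
                                  stringsAsFactors = FALSE)
    gene_ids <- as.character(features[[min(2L, ncol(features))]])
    if (nrow(counts) != length(gene_ids)) {
      stop("MTX has ", nrow(counts), " rows but features file lists ",
           length(gene_ids), " genes")
    }
    if (ncol(counts) != length(barcodes)) {
      stop("MTX has ", ncol(counts), " columns but barcodes file lists ",
           length(barcodes), " cells")
    }
    cell_ids <- barcodes
  } else {
    tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    row_ids <- as.character(tab[[1]])  # duplicates allowed for gene rows
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- row_ids
    if (!is.numeric(counts)) stop("non-numeric entries in dense TSV")
    if (genes_in == "cols") counts <- t(counts)
    gene_ids <- rownames(counts)
    cell_ids <- colnames(counts)
  }
  if (any(counts < 0)) stop("count matrix contains negative entries")
  if (any(counts != floor(counts))) {
    stop("count matrix contains non-integer entries")
  }
  rownames(counts) <- make.unique(gene_ids, sep = ".")
  colnames(counts) <- cell_ids
  if (anyDuplicated(cell_ids)) stop("duplicate cell IDs in input")
  SingleCellExperiment::SingleCellExperiment(assays = list(counts = counts))
}

.find_10x_file <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("none of ", paste(candidates, collapse = ", "), " found in ", dir)
}

#' Attach per-cell cluster labels
#'
#' @param ds A `SingleCellExperiment` from [read_counts()].
#' @param labels Either a path to a TSV with header `cell_id<TAB>cluster`, or
#'   a data.frame with those two columns. Every cell in `ds` must appear
#'   exactly once and no unknown cells may appear; every cluster must have at
#'   least 2 cells.
#' @return `ds` with `colData(ds)$cluster` set (factor, levels in
#'   lexicographic order).
#' @export
attach_labels <- function(ds, labels) {
  if (is.character(labels) && length(labels) == 1L) {
    labels <- utils::read.delim(labels, header = TRUE,
                                stringsAsFactors = FALSE)
  }
  if (!all(c("cell_id", "cluster") %in% colnames(labels))) {
    stop("labels must have columns 'cell_id' and 'cluster'")
  }
  cells <- colnames(ds)
  if (anyDuplicated(labels$cell_id)) {
    stop("duplicate cell_id in labels: ",
         paste(unique(labels$cell_id[duplicated(labels$cell_id)]),
               collapse = ", "))
  }
  missing <- setdiff(cells, labels$cell_id)
  if (length(missing)) {
    stop("labels missing for ", length(missing), " cell(s), e.g. ",
         missing[1L])
  }
  unknown <- setdiff(labels$cell_id, cells)
  if (length(unknown)) {
    stop("labels contain unknown cell_id(s), e.g. ", unknown[1L])
  }
  cl <- labels$cluster[match(cells, labels$cell_id)]
  tab <- table(cl)
  if (any(tab < 2L)) {
    stop("cluster(s) with fewer than 2 cells: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  SummarizedExperiment::colData(ds)$cluster <-
    factor(cl, levels = sort(unique(as.character(cl))))
  ds
}

#' Per-cell cluster labels of a dataset
#' @param ds A labeled dataset.
#' @return Factor of cluster labels, one per cell.
#' @export
cluster_labels <- function(ds) {
  cl <- SummarizedExperiment::colData(ds)$cluster
  if (is.null(cl)) stop("dataset has no cluster labels; see attach_labels()")
  cl
}

#' Write a dataset as a 10x-style MTX triplet plus labels TSV
#'
#' @param ds Dataset with a `counts` assay (labels optional).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset_mtx <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts <- SummarizedExperiment::assay(ds, "counts")
  Matrix::writeMM(as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(ds), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = rownames(ds), name = rownames(ds),
               type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  cl <- SummarizedExperiment::colData(ds)$cluster
  if (!is.null(cl)) {
    utils::write.table(
      data.frame(cell_id = colnames(ds), cluster = as.character(cl)),
      file.path(dir, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
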