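#' Quality-control and normalization settings
#'
#' @param min_genes_per_cell Cells detecting fewer genes are removed.
#' @param max_mito_fraction Cells with a higher fraction of counts on
#'   mitochondrial genes are removed.
#' @param mito_prefix Gene-ID prefix identifying mitochondrial genes.
#' @param target_sum Per-cell library size after normalization.
#' @param clip_value Absolute bound applied to the z-scored layer, or `NULL`
#'   for no clipping.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_genes_per_cell = 200, max_mito_fraction = 0.05,
                      mito_prefix = "MT-", target_sum = 1e4,
                      clip_value = 10) {
  stopifnot(min_genes_per_cell >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1,
            target_sum > 0,
            is.null(clip_value) || clip_value > 0)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix,
                 target_sum = target_sum,
                 clip_value = clip_value),
            class = "qc_config")
}

#' Filter cells and derive normalized expression layers
#'
#' Applies the standard scRNA-seq preprocessing chain: cell-level QC
#' (minimum genes detected, maximum mitochondrial fraction), library-size
#' normalization to `target_sum` followed by `log1p` (the `lognorm` layer),
#' and per-gene z-scoring of `lognorm` (the `scaled` layer), optionally
#' clipped at `±clip_value`. Genes are never removed; zero-variance genes
#' scale to 0.
#'
#' @param ds Dataset with a `counts` assay.
#' @param cfg A [qc_config()].
#' @return The dataset with cells failing QC removed and dense `lognorm` and
#'   `scaled` assays added. A per-cell QC table (`cell_id`, `n_genes`,
#'   `mito_fraction`, `kept`) is stored in `metadata(ds)$qc_report`.
#' @export
preprocess <- function(ds, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  counts <- SummarizedExperiment::assay(ds, "counts")
  n_genes <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), cfg$mito_prefix)
  tot <- Matrix::colSums(counts)
  mito_frac <- if (any(mito)) {
    as.numeric(Matrix::colSums(counts[mito, , drop = FALSE])) / pmax(tot, 1)
  } else {
    numeric(ncol(counts))
  }
  keep <- n_genes >= cfg$min_genes_per_cell & mito_frac <= cfg$max_mito_fraction
  report <- data.frame(cell_id = colnames(ds), n_genes = as.numeric(n_genes),
                       mito_fraction = mito_frac, kept = keep)
  if (!any(keep)) stop("all cells removed by QC")
  ds <- ds[, keep]
  cl <- SummarizedExperiment::colData(ds)$cluster
  if (!is.null(cl)) {
    SummarizedExperiment::colData(ds)$cluster <- droplevels(cl)
  }
  counts <- as.matrix(SummarizedExperiment::assay(ds, "counts"))
  libsize <- colSums(counts)
  lognorm <- log1p(sweep(counts, 2, libsize / cfg$target_sum, "/"))
  mu <- rowMeans(lognorm)
  sdv <- apply(lognorm, 1, stats::sd)
  scaled <- (lognorm - mu) / ifelse(sdv > 0, sdv, 1)
  scaled[sdv == 0, ] <- 0
  if (!is.null(cfg$clip_value)) {
    scaled <- pmin(pmax(scaled, -cfg$clip_value), cfg$clip_value)
  }
  SummarizedExperiment::assay(ds, "lognorm") <- lognorm
  SummarizedExperiment::assay(ds, "scaled") <- scaled
  S4Vectors::metadata(ds)$qc_report <- report
  S4Vectors::metadata(ds)$qc_config <- cfg
  ds
}

#' Select highly variable genes by binned dispersion
#'
#' Implements the classic dispersion-based recipe: per-gene mean and
#' dispersion (variance/mean) are computed on the de-logged `lognorm` layer,
#' dispersions are log-transformed and means log1p-transformed, genes are cut
#' into `n_bins` equal-width bins of transformed mean, dispersions are
#' z-normalized within each bin, and a gene is selected when its transformed
#' mean lies strictly inside `(min_mean, max_mean)` and its dispersion
#' z-score strictly exceeds `min_disp`. Bins holding a single gene get a
#' z-score of 1 (the bin's standard deviation is taken as the gene's own
#' dispersion and its mean as 0, so the ratio is 1).
#'
#' @param ds Preprocessed dataset (needs the `lognorm` assay).
#' @param min_mean,max_mean Bounds on log1p-transformed mean expression.
#' @param min_disp Threshold on the within-bin dispersion z-score.
#' @param n_bins Number of mean bins; reduced with a warning when there are
#'   fewer genes than bins.
#' @return A data.frame of class `hvg_result` with one row per gene:
#'   `gene`, `mean` (raw mean of de-logged expression), `dispersion` (raw
#'   variance/mean), `dispersion_z`, `selected`; attribute `n_bins`.
#' @export
select_hvgs <- function(ds, min_mean = 0.0125, max_mean = 3, min_disp = 0.5,
                        n_bins = 20) {
  X <- expm1(SummarizedExperiment::assay(ds, "lognorm"))
  n <- ncol(X)
  mu <- rowMeans(X)
  v <- rowSums((X - mu)^2) / (n - 1)
  disp_raw <- ifelse(mu > 0, v / mu, 0)
  mu_safe <- ifelse(mu == 0, 1e-12, mu)
  disp <- v / mu_safe
  disp[disp == 0] <- NA_real_
  disp_log <- log(disp)
  mean_t <- log1p(mu)
  if (nrow(X) < n_bins) {
    warning("fewer genes (", nrow(X), ") than bins; using ", nrow(X), " bins")
    n_bins <- nrow(X)
  }
  bin <- cut(mean_t, breaks = n_bins)
  bin_mean <- tapply(disp_log, bin, mean, na.rm = TRUE)
  bin_sd <- tapply(disp_log, bin, stats::sd, na.rm = TRUE)
  # single-gene bins: sd is NA -> use the gene's own dispersion as the
  # denominator and 0 as the center, giving z = 1
  single <- is.na(bin_sd) | bin_sd == 0
  bin_sd[single] <- bin_mean[single]
  bin_mean[single] <- 0
  z <- (disp_log - bin_mean[bin]) / bin_sd[bin]
  selected <- !is.na(z) & mean_t > min_mean & mean_t < max_mean & z > min_disp
  res <- data.frame(gene = rownames(ds), mean = mu, dispersion = disp_raw,
                    dispersion_z = as.numeric(z), selected = selected,
                    row.names = NULL)
  attr(res, "n_bins") <- n_bins
  class(res) <- c("hvg_result", class(res))
  res
}
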