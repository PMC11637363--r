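#' Within-dataset KNN classification of cell types
#'
#' Stratified train/test split of the cells, a Euclidean K-nearest-neighbor
#' classifier fit on the training cells, and per-class recall on the test
#' cells. The reported average is the unweighted (macro) mean of the
#' per-class accuracies, so rare cell types count as much as abundant ones.
#'
#' @param features Features x cells numeric matrix, or an
#'   `assembled_features` object.
#' @param labels Per-cell class labels (factor or character).
#' @param train_frac Fraction of each class assigned to training (default
#'   0.7).
#' @param n_neighbors K for the classifier (default 15).
#' @param seed Integer seed for the split.
#' @param feature_set_name Recorded in the result.
#' @return A list of class `eval_result`: `per_class_accuracy` (named),
#'   `average_accuracy`, `n_train`, `n_test`, `feature_set_name`, `seed`,
#'   `n_neighbors`.
#' @export
knn_within <- function(features, labels, train_frac = 0.7, n_neighbors = 15,
                       seed = 1, feature_set_name = "features") {
  if (inherits(features, "assembled_features")) features <- features$values
  stopifnot(train_frac > 0, train_frac < 1)
  labels <- factor(labels)
  n <- ncol(features)
  stopifnot(length(labels) == n)
  if (any(table(labels) < 2L)) stop("every class needs at least 2 cells")
  idx_train <- .stratified_train(labels, train_frac, seed)
  pred <- .knn_predict(features[, idx_train, drop = FALSE],
                       features[, -idx_train, drop = FALSE],
                       labels[idx_train], n_neighbors)
  truth <- labels[-idx_train]
  per_class <- vapply(levels(labels), function(cls) {
    mean(pred[truth == cls] == cls)
  }, 0)
  structure(list(per_class_accuracy = per_class,
                 average_accuracy = mean(per_class),
                 n_train = length(idx_train), n_test = n - length(idx_train),
                 feature_set_name = feature_set_name, seed = seed,
                 n_neighbors = n_neighbors),
            class = "eval_result")
}

.stratified_train <- function(labels, train_frac, seed) {
  set.seed(seed)
  idx <- unlist(lapply(levels(labels), function(cls) {
    members <- which(labels == cls)
    n_tr <- round(train_frac * length(members))
    if (n_tr < 1L || n_tr >= length(members)) {
      stop("stratification failed: class '", cls,
           "' would be absent from train or test")
    }
    sort(sample(members, n_tr))
  }))
  sort(idx)
}

# Euclidean KNN with deterministic tie handling: neighbors ordered by
# (distance, training index); vote ties broken by class level order.
.knn_predict <- function(train, test, train_labels, k) {
  train_labels <- factor(train_labels)
  k <- min(k, ncol(train))
  tt <- t(train)
  qq <- t(test)
  d2 <- outer(rowSums(qq^2), rowSums(tt^2), "+") - 2 * qq %*% t(tt)
  pred <- character(nrow(qq))
  for (i in seq_len(nrow(qq))) {
    ord <- order(d2[i, ], seq_len(ncol(train)))[seq_len(k)]
    votes <- table(train_labels[ord])
    pred[i] <- names(votes)[which.max(votes)]
  }
  factor(pred, levels = levels(train_labels))
}

#' Cross-dataset cell-type mapping with a reference-trained classifier
#'
#' Selects feature genes on the reference dataset only (intersected with the
#' genes present in the query), trains a Euclidean KNN classifier on all
#' reference cells, predicts query cell types, and reports per-class recall
#' on the query with its macro average.
#'
#' Selectors: `"all"` (every shared gene), `"hvg_overlap"` (genes selected
#' as highly variable independently in reference and query, intersected),
#' `"flat_markers"` (one-vs-rest markers on the reference's base clusters),
#' and `"hier_markers"` (the hierarchy is built on the reference and its
#' assembled zero-masked features are used; query cells receive full,
#' unmasked expression on every split feature, because masking requires the
#' cluster identity that is exactly what is being predicted).
#'
#' @param ref,query Preprocessed, labeled datasets sharing gene namespace
#'   and label vocabulary.
#' @param selector Feature selection strategy (see above).
#' @param n_neighbors K for the classifier.
#' @param seed Recorded in the result (the mapping itself is
#'   deterministic).
#' @param layer Expression layer used as feature values.
#' @param cfg,mcfg Scoring and marker settings for the marker-based
#'   selectors.
#' @return An `eval_result` (per-class accuracy on the query, macro
#'   average). Attribute `features` holds the feature gene/feature IDs used.
#' @export
cross_dataset_map <- function(ref, query,
                              selector = c("all", "hvg_overlap",
                                           "flat_markers", "hier_markers"),
                              n_neighbors = 15, seed = 1,
                              layer = c("scaled", "lognorm"),
                              cfg = scoring_config(),
                              mcfg = marker_config()) {
  selector <- match.arg(selector)
  layer <- match.arg(layer)
  ref_lab <- factor(cluster_labels(ref))
  qry_lab <- factor(cluster_labels(query))
  vocab_diff <- c(setdiff(levels(ref_lab), levels(qry_lab)),
                  setdiff(levels(qry_lab), levels(ref_lab)))
  if (length(vocab_diff)) {
    stop("label vocabulary mismatch between reference and query: ",
         paste(vocab_diff, collapse = ", "))
  }
  shared <- intersect(rownames(ref), rownames(query))
  if (!length(shared)) stop("empty gene intersection between datasets")
  if (selector == "hier_markers") {
    root <- build_hierarchy(ref, cfg = cfg, mcfg = mcfg)
    am <- assemble_features(ref, root, layer = layer)
    keep <- am$feature_meta$gene %in% shared
    if (!any(keep)) stop("no hierarchy marker genes present in query")
    train <- am$values[keep, , drop = FALSE]
    # query cluster membership is unknown at prediction time, so query
    # cells carry unmasked expression on every split feature
    test <- SummarizedExperiment::assay(query, layer)[
      am$feature_meta$gene[keep], , drop = FALSE]
    rownames(test) <- rownames(train)
    feature_ids <- rownames(train)
  } else {
    genes <- switch(selector,
      all = shared,
      hvg_overlap = {
        hv_r <- select_hvgs(ref)
        hv_q <- select_hvgs(query)
        intersect(intersect(hv_r$gene[hv_r$selected],
                            hv_q$gene[hv_q$selected]), shared)
      },
      flat_markers = intersect(unique(one_vs_all_markers(ref, NULL,
                                                         mcfg)$gene),
                               shared))
    if (!length(genes)) stop("empty feature gene set for selector ", selector)
    train <- SummarizedExperiment::assay(ref, layer)[genes, , drop = FALSE]
    test <- SummarizedExperiment::assay(query, layer)[genes, , drop = FALSE]
    feature_ids <- genes
  }
  pred <- .knn_predict(train, test, ref_lab, n_neighbors)
  per_class <- vapply(levels(qry_lab), function(cls) {
    mean(pred[qry_lab == cls] == cls)
  }, 0)
  res <- structure(list(per_class_accuracy = per_class,
                        average_accuracy = mean(per_class),
                        n_train = ncol(train), n_test = ncol(test),
                        feature_set_name = selector, seed = seed,
                        n_neighbors = n_neighbors),
                   class = "eval_result")
  attr(res, "features") <- feature_ids
  res
}

#' Write an evaluation result as TSV plus JSON summary
#'
#' @param res An `eval_result`.
#' @param path_prefix Output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_eval_result <- function(res, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  js <- paste0(path_prefix, ".json")
  utils::write.table(
    data.frame(selector = res$feature_set_name,
               class = c(names(res$per_class_accuracy), "Average"),
               accuracy = c(as.numeric(res$per_class_accuracy),
                            res$average_accuracy)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(res), js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
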