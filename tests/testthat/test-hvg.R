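# Straight-line reimplementation of the binned-dispersion recipe, kept
# deliberately naive (explicit loops over bins) as an independent oracle.
hvg_oracle <- function(lognorm, n_bins = 20, min_mean = 0.0125, max_mean = 3,
                       min_disp = 0.5) {
  X <- expm1(lognorm)
  n <- ncol(X)
  sel <- logical(nrow(X))
  mu <- numeric(nrow(X)); dl <- numeric(nrow(X))
  for (g in seq_len(nrow(X))) {
    m <- mean(X[g, ])
    v <- sum((X[g, ] - m)^2) / (n - 1)
    d <- v / ifelse(m == 0, 1e-12, m)
    mu[g] <- log1p(m)
    dl[g] <- ifelse(d == 0, NA, log(d))
  }
  bin <- cut(mu, breaks = n_bins)
  z <- rep(NA_real_, nrow(X))
  for (b in levels(bin)) {
    idx <- which(bin == b)
    if (!length(idx)) next
    vals <- dl[idx]
    m_b <- mean(vals, na.rm = TRUE)
    s_b <- sd(vals, na.rm = TRUE)
    if (is.na(s_b) || s_b == 0) { s_b <- m_b; m_b <- 0 }
    z[idx] <- (vals - m_b) / s_b
  }
  which(!is.na(z) & mu > min_mean & mu < max_mean & z > min_disp)
}

test_that("HVG selection matches a straight-line oracle on random counts", {
  set.seed(42)
  counts <- matrix(rnbinom(200 * 60, size = 2,
                           mu = rep(runif(200, 0.2, 6), 60)),
                   nrow = 200)
  counts[seq(1, 200, by = 17), ] <- counts[seq(1, 200, by = 17), ] * 3L
  rownames(counts) <- sprintf("g%03d", 1:200)
  colnames(counts) <- sprintf("c%02d", 1:60)
  ds <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  ds <- attach_labels(ds, data.frame(cell_id = colnames(counts),
                                     cluster = rep(c("a", "b"), 30)))
  ds <- pp(ds, target_sum = 300)
  hv <- select_hvgs(ds)
  lognorm <- SummarizedExperiment::assay(ds, "lognorm")
  expect_identical(which(hv$selected), hvg_oracle(lognorm))
  expect_true(all(hv$dispersion[hv$mean > 0] >= 0))
})

test_that("planted high-dispersion genes are exactly the genes selected", {
  # 5 mean clumps; within each, 9 background genes share one permuted count
  # multiset (identical mean and dispersion) and 1 planted gene has the same
  # mean but higher variance. With a top-up gene equalizing library sizes,
  # every clump lands in a single mean bin where the background z-score is
  # exactly -sqrt(0.1) and the planted z-score exactly 9*sqrt(0.1) = 2.85.
  set.seed(7)
  n_cells <- 60
  rows <- list()
  planted <- integer(0)
  for (lam in c(1, 2, 4, 8, 16)) {
    base <- rep(c(0L, lam, 2L * lam), each = n_cells / 3)
    for (j in 1:9) rows[[length(rows) + 1L]] <- sample(base)
    rows[[length(rows) + 1L]] <- sample(rep(c(0L, 2L * lam),
                                            each = n_cells / 2))
    planted <- c(planted, length(rows))
  }
  counts <- do.call(rbind, rows)
  csum <- colSums(counts)
  topup <- max(csum) - csum + 25L  # equal library sizes; mean above max_mean
  counts <- rbind(counts, topup)
  rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("c%02d", seq_len(n_cells))
  ds <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  ds <- attach_labels(ds, data.frame(cell_id = colnames(counts),
                                     cluster = rep(c("a", "b"), 30)))
  ds <- pp(ds, target_sum = sum(counts[, 1]))
  hv <- select_hvgs(ds)
  expect_identical(which(hv$selected), planted)
  expect_equal(hv$dispersion_z[planted], rep(9 * sqrt(0.1), 5),
               tolerance = 1e-9)
})

test_that("zero-variance genes have dispersion 0 and are never selected", {
  counts <- matrix(rpois(50 * 30, 4), nrow = 50)
  counts[10, ] <- 0L
  rownames(counts) <- sprintf("g%02d", 1:50)
  colnames(counts) <- sprintf("c%02d", 1:30)
  ds <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  ds <- attach_labels(ds, data.frame(cell_id = colnames(counts),
                                     cluster = rep(c("a", "b"), 15)))
  ds <- pp(ds, target_sum = 100)
  hv <- select_hvgs(ds)
  expect_equal(hv$dispersion[10], 0)
  expect_false(hv$selected[10])
})

test_that("selection is invariant to gene order and symmetric for ties", {
  set.seed(11)
  counts <- matrix(rpois(80 * 40, 4), nrow = 80)
  counts[5, ] <- counts[6, ]  # identical pair
  rownames(counts) <- sprintf("g%02d", 1:80)
  colnames(counts) <- sprintf("c%02d", 1:40)
  ds <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  ds <- attach_labels(ds, data.frame(cell_id = colnames(counts),
                                     cluster = rep(c("a", "b"), 20)))
  ds <- pp(ds, target_sum = 150)
  hv <- select_hvgs(ds)
  expect_equal(hv$dispersion_z[5], hv$dispersion_z[6])

  perm <- sample(nrow(ds))
  hv_p <- select_hvgs(ds[perm, ])
  expect_setequal(hv_p$gene[hv_p$selected], hv$gene[hv$selected])
})

test_that("fewer genes than bins reduces the bin count with a warning", {
  counts <- matrix(rpois(10 * 30, 4), nrow = 10)
  rownames(counts) <- sprintf("g%02d", 1:10)
  colnames(counts) <- sprintf("c%02d", 1:30)
  ds <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts))
  ds <- attach_labels(ds, data.frame(cell_id = colnames(counts),
                                     cluster = rep(c("a", "b"), 15)))
  ds <- pp(ds, target_sum = 50)
  expect_warning(hv <- select_hvgs(ds), "bins")
  expect_identical(attr(hv, "n_bins"), 10L)
})
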