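#' Two-sample Wilcoxon rank-sum test
#'
#' Computes the Mann-Whitney U statistic for `x` (rank sum of `x` minus its
#' minimum) with midrank handling of ties. In exact mode the p-value is
#' computed from the exact null distribution of U over all assignments of
#' the pooled ranks to the two groups (a counting DP over the midrank
#' multiset, so ties are handled exactly); otherwise a tie-corrected normal
#' approximation with continuity correction is used. Exact mode is only
#' available for `length(x) + length(y) <= 12`.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode `"auto"` (exact when the pooled size is at most 12),
#'   `"exact"`, or `"normal"`.
#' @return List with `statistic` (U for `x`), `p_value` (two-sided), and
#'   `mode` actually used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (mode == "auto") mode <- if (n <= 12L) "exact" else "normal"
  if (mode == "exact") {
    if (n > 12L) stop("exact mode limited to pooled sample size <= 12")
    p <- .wilcox_exact_p(r, n1, U)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- U - n1 * n2 / 2
      z <- sign(d) * max(abs(d) - 0.5, 0) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = U, p_value = p, mode = mode)
}

# Exact two-sided p for U via a subset-counting DP over the pooled midranks.
# Ranks are doubled so midranks (.5) become integers; counts[j, s] = number
# of j-subsets of the doubled ranks with sum s.
.wilcox_exact_p <- function(r, n1, U) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  total <- sum(r2)
  counts <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (rv in r2) {
    jmax <- n1
    for (j in seq.int(jmax, 1L)) {
      shifted <- c(rep(0, rv), counts[j, seq_len(total + 1L - rv)])
      counts[j + 1L, ] <- counts[j + 1L, ] + shifted
    }
  }
  dist <- counts[n1 + 1L, ]
  sums2 <- which(dist > 0) - 1L           # doubled rank sums with support
  probs <- dist[dist > 0] / sum(dist[dist > 0])
  u_vals <- sums2 / 2 - n1 * (n1 + 1) / 2 # convert rank sums to U
  p_le <- sum(probs[u_vals <= U + 1e-9])
  p_ge <- sum(probs[u_vals >= U - 1e-9])
  min(1, 2 * min(p_le, p_ge))
}

# Midranks of every gene across cells plus the tie correction term
# sum(t^3 - t); X is genes x cells. Computed once per cell scope and reused
# across candidate groupings during agglomeration.
.rank_matrix <- function(X) {
  nr <- nrow(X); nc <- ncol(X)
  R <- matrix(0, nr, nc, dimnames = dimnames(X))
  tie <- numeric(nr)
  for (g in seq_len(nr)) {
    v <- X[g, ]
    R[g, ] <- rank(v)
    t <- tabulate(match(v, v[!duplicated(v)]))
    tie[g] <- sum(t^3 - t)
  }
  list(ranks = R, tie = tie)
}

# Vectorized one-vs-rest Wilcoxon over all genes for one group of cells.
# rk is the output of .rank_matrix over the scope; idx_in indexes columns.
.wilcox_group_vs_rest <- function(rk, idx_in) {
  N <- ncol(rk$ranks)
  n1 <- length(idx_in)
  n2 <- N - n1
  R1 <- rowSums(rk$ranks[, idx_in, drop = FALSE])
  U <- R1 - n1 * (n1 + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - rk$tie / (N * (N - 1)))
  d <- U - n1 * n2 / 2
  z <- sign(d) * pmax(abs(d) - 0.5, 0) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- ifelse(sigma2 <= 0, 1, pmin(1, 2 * stats::pnorm(-abs(z))))
  list(statistic = U, p_value = p)
}
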