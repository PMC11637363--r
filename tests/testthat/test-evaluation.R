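test_that("perfectly separated classes classify perfectly", {
  set.seed(90)
  feats <- cbind(matrix(rnorm(2 * 30, mean = 0), nrow = 2),
                 matrix(rnorm(2 * 30, mean = 20), nrow = 2))
  colnames(feats) <- sprintf("c%02d", 1:60)
  labels <- rep(c("near", "far"), each = 30)
  res <- knn_within(feats, labels, seed = 2)
  expect_equal(unname(res$per_class_accuracy), c(1, 1))
  expect_equal(res$average_accuracy, 1)
  expect_equal(res$n_train + res$n_test, 60L)
  expect_equal(res$n_train, 2 * round(0.7 * 30))
})

test_that("shuffled labels give chance-level macro accuracy", {
  accs <- sapply(1:20, function(s) {
    set.seed(s + 1000)
    feats <- matrix(rnorm(5 * 120), nrow = 5)
    colnames(feats) <- sprintf("c%03d", 1:120)
    labels <- sample(rep(letters[1:4], each = 30))
    knn_within(feats, labels, seed = s)$average_accuracy
  })
  expect_lt(abs(mean(accs) - 0.25), 0.1)
})

test_that("tiny fixture predictions equal a hand-executed neighbor vote", {
  # 1-D features; train cells at 0,1,2,10,11,12 labeled lo/lo/lo/hi/hi/hi
  feats <- matrix(c(0, 1, 2, 10, 11, 12, 1.4, 9.6), nrow = 1)
  colnames(feats) <- paste0("c", 1:8)
  train <- feats[, 1:6, drop = FALSE]
  test <- feats[, 7:8, drop = FALSE]
  labs <- factor(c("lo", "lo", "lo", "hi", "hi", "hi"))
  pred <- hiermarkers:::.knn_predict(train, test, labs, k = 3)
  # c7 at 1.4: nearest three are 1,2,0 -> lo; c8 at 9.6: 10,11,12 -> hi
  expect_identical(as.character(pred), c("lo", "hi"))
})

test_that("internal KNN agrees with class::knn on tie-free data", {
  set.seed(91)
  train <- matrix(rnorm(3 * 40), nrow = 3)
  test <- matrix(rnorm(3 * 15), nrow = 3)
  labs <- factor(sample(c("a", "b"), 40, replace = TRUE))
  ours <- hiermarkers:::.knn_predict(train, test, labs, k = 1)
  ref <- class::knn(t(train), t(test), labs, k = 1)
  expect_identical(as.character(ours), as.character(ref))
})

test_that("splits are stratified, seeded, and fail loudly when impossible", {
  feats <- matrix(rnorm(2 * 20), nrow = 2)
  colnames(feats) <- paste0("c", 1:20)
  labels <- rep(c("a", "b"), each = 10)
  r1 <- knn_within(feats, labels, seed = 7)
  r2 <- knn_within(feats, labels, seed = 7)
  expect_identical(r1$per_class_accuracy, r2$per_class_accuracy)
  expect_error(knn_within(feats, labels, train_frac = 0.04, seed = 1),
               "stratification")
  expect_error(knn_within(feats, c(rep("a", 19), "b"), seed = 1),
               "at least 2 cells")
})

# strongly separated subtypes (large effects, many planted markers) so that
# self-mapping is unambiguous; target_sum scaled to the gene count so mean
# expression falls inside the HVG mean window
xmap_fixture <- function(seed = 1, amplitude = 0) {
  gen <- gen2x2(seed = seed, tree = list(L1 = c(A = 40, B = 40),
                                         L2 = c(C = 40, D = 40)),
                n_genes = 300, markers_per_node = 20,
                lineage_effect = 2.5, subtype_effect = 2)
  ref <- pp(gen$dataset, target_sum = 500)
  qd <- if (amplitude > 0) {
    batch_shift(gen$dataset, amplitude, seed = seed + 500)
  } else {
    gen$dataset
  }
  list(ref = ref, query = pp(qd, target_sum = 500))
}

test_that("mapping a dataset onto itself is perfect for every selector", {
  fx <- xmap_fixture(95)
  for (sel in c("all", "flat_markers", "hier_markers")) {
    res <- cross_dataset_map(fx$ref, fx$query, sel)
    expect_equal(res$average_accuracy, 1, info = sel)
  }
})

test_that("feature genes are reference-selected and present in the query", {
  fx <- xmap_fixture(97, amplitude = 0.5)
  query_small <- fx$query[seq_len(250), ]  # drop genes from the query
  for (sel in c("all", "hvg_overlap", "flat_markers")) {
    res <- cross_dataset_map(fx$ref, query_small, sel)
    expect_true(all(attr(res, "features") %in% rownames(query_small)),
                info = sel)
    expect_true(all(attr(res, "features") %in% rownames(fx$ref)), info = sel)
  }
  res <- cross_dataset_map(fx$ref, query_small, "hier_markers")
  genes_used <- sub("^S[0-9]+:", "", attr(res, "features"))
  expect_true(all(genes_used %in% rownames(query_small)))
})

test_that("accuracy degrades as query noise grows", {
  # moderate effect sizes so the mapping is not saturated at 100%
  noise_fixture <- function(a) {
    gen <- gen2x2(seed = 101, tree = list(L1 = c(A = 30, B = 30),
                                          L2 = c(C = 30, D = 30)),
                  n_genes = 300, markers_per_node = 12)
    qd <- if (a > 0) batch_shift(gen$dataset, a, seed = 601) else gen$dataset
    list(ref = pp(gen$dataset, target_sum = 500),
         query = pp(qd, target_sum = 500))
  }
  accs <- sapply(c(0, 1.5, 3), function(a) {
    fx <- noise_fixture(a)
    cross_dataset_map(fx$ref, fx$query, "all")$average_accuracy
  })
  expect_true(all(diff(accs) <= 0))
  expect_gt(accs[1], accs[3])
})

test_that("label vocabulary mismatches are reported", {
  fx <- xmap_fixture(103)
  q <- fx$query
  cl <- as.character(cluster_labels(q))
  cl[cl == "D"] <- "Z"
  SummarizedExperiment::colData(q)$cluster <- factor(cl)
  expect_error(cross_dataset_map(fx$ref, q, "all"), "Z")
})

test_that("eval results serialize with a macro average row", {
  fx <- xmap_fixture(107)
  res <- cross_dataset_map(fx$ref, fx$query, "flat_markers")
  expect_equal(res$average_accuracy,
               mean(res$per_class_accuracy))
  prefix <- file.path(withr::local_tempdir(), "eval")
  write_eval_result(res, prefix)
  tab <- read.delim(paste0(prefix, ".tsv"))
  expect_identical(tail(tab$class, 1), "Average")
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$average_accuracy, res$average_accuracy)
})
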