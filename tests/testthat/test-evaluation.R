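classes <- default_class_order()

test_that("leave-one-out on the disjoint-pool toy collection is perfect", {
  col <- disjoint_toy_collection()
  loo <- leave_one_out(col$matrix, col$metadata)
  expect_length(loo$results, nrow(col$metadata))
  expect_identical(loo$metrics$accuracy, 1)
  expect_identical(loo$metrics$recall, 1)
  expect_identical(loo$metrics$f1, 1)
  expect_true(all(vapply(loo$curves$auc, identical, logical(1), 1)))
})

test_that("each leave-one-out run excludes its sink from the sources", {
  col <- disjoint_toy_collection()
  n <- nrow(col$metadata)
  # re-run the split by hand and check the contract on the column sets
  for (j in seq_len(n)) {
    src_ids <- col$matrix$sample_ids[-j]
    expect_false(col$metadata$sample_id[j] %in% src_ids)
  }
  loo <- leave_one_out(col$matrix, col$metadata)
  expect_identical(vapply(loo$results, `[[`, character(1), "sink_id"),
                   col$metadata$sample_id)
  expect_error(leave_one_out(col$matrix, col$metadata[0, ]),
               class = "kmst_error")
})

test_that("label shuffling collapses leave-one-out accuracy to chance", {
  col <- grouped_collection()
  expect_identical(leave_one_out(col$matrix, col$metadata)$metrics$accuracy,
                   1)
  set.seed(31)
  accs <- replicate(50, {
    shuf <- col$metadata
    shuf$label <- sample(shuf$label)
    suppressWarnings(leave_one_out(col$matrix, shuf)$metrics$accuracy)
  })
  # permuted labels leave ~1/|C| = 0.25 expected accuracy (slightly less
  # under permutation without replacement); wide band, far below 1
  expect_gt(mean(accs), 0.15)
  expect_lt(mean(accs), 0.35)
})

test_that("group-stratified folds satisfy the non-overlap constraint exactly", {
  md <- decomposable_metadata()
  fa <- make_group_stratified_folds(md, n_folds = 5, seed = 1)
  expect_identical(sort(unique(unname(fa$fold_of))), 1:5)
  # every sample in exactly one fold
  expect_identical(sort(names(fa$fold_of)), sort(md$sample_id))
  # a group never spans two folds
  for (g in unique(md$group)) {
    expect_length(unique(fa$fold_of[md$sample_id[md$group == g]]), 1L)
  }
  # perfectly decomposable instance: 8 samples per fold, exact 25% splits
  for (f in 1:5) {
    ids <- names(fa$fold_of)[fa$fold_of == f]
    expect_length(ids, 8L)
    expect_identical(as.vector(table(md$label[md$sample_id %in% ids])),
                     rep(2L, 4))
  }
  # determinism and degenerate single fold
  fa2 <- make_group_stratified_folds(md, n_folds = 5, seed = 1)
  expect_identical(fa$fold_of, fa2$fold_of)
  fa1 <- make_group_stratified_folds(md, n_folds = 1, seed = 9)
  expect_true(all(fa1$fold_of == 1L))
  expect_error(make_group_stratified_folds(md, n_folds = 11, seed = 1),
               class = "kmst_parameter_error")
})

test_that("fold non-overlap holds on uneven random group structures", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(30:80, 1)
    md <- data.frame(
      sample_id = sprintf("s%03d", seq_len(n)),
      label = sample(classes, n, replace = TRUE),
      group = sample(sprintf("bp%02d", 1:12), n, replace = TRUE),
      stringsAsFactors = FALSE)
    md$group[1:12] <- sprintf("bp%02d", 1:12) # ensure 12 distinct groups
    fa <- make_group_stratified_folds(md, n_folds = 4, seed = rep)
    split_count <- tapply(fa$fold_of[md$sample_id], md$group,
                          function(x) length(unique(x)))
    expect_true(all(split_count == 1))
    expect_length(unique(unname(fa$fold_of)), 4L)
  }
})

test_that("cross-validation keeps fold sinks out of their own sources", {
  col <- grouped_collection()
  cv <- cross_validate(col$matrix, col$metadata, n_folds = 5, seed = 3)
  expect_length(cv$per_fold, 5L)
  fold_of <- cv$folds$fold_of
  # contract: a sink's fold never contributes sources in its own fold run
  for (f in 1:5) {
    sinks <- names(fold_of)[fold_of == f]
    sources <- names(fold_of)[fold_of != f]
    expect_length(intersect(sinks, sources), 0L)
  }
  expect_identical(cv$pooled$accuracy, 1) # disjoint pools: still perfect
  expect_identical(cv$pooled$n, nrow(col$metadata))
})

test_that("metrics match hand-computed confusion tables", {
  r <- suppressWarnings(
    compute_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                    class_order = c("A", "B")))
  expect_identical(r$accuracy, 3 / 4)
  expect_identical(r$precision, (1 + 2 / 3) / 2)
  expect_identical(r$recall, (1 / 2 + 1) / 2)
  expect_identical(r$per_class$support, c(2, 2))

  perfect <- compute_metrics(classes, classes)
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$precision, 1)
  expect_identical(perfect$f1, 1)

  wrong <- suppressWarnings(
    compute_metrics(c("A", "A"), c("B", "B"), class_order = c("A", "B")))
  expect_identical(wrong$accuracy, 0)
  expect_identical(wrong$recall, 0)

  expect_error(compute_metrics("A", c("A", "B"), c("A", "B")),
               class = "kmst_shape_error")
})

test_that("metrics agree with the independent confusion oracle", {
  set.seed(2024)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    y_true <- sample(classes, n, replace = TRUE)
    y_pred <- sample(c(classes, "unassigned"), n, replace = TRUE)
    got <- suppressWarnings(compute_metrics(y_true, y_pred, classes))
    want <- oracle_metrics(y_true, y_pred, classes)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
    # confusion row sums equal per-class support
    expect_identical(unname(rowSums(got$confusion)),
                     unname(vapply(classes, function(cl)
                       sum(y_true == cl), numeric(1))))
  }
})

test_that("unassigned predictions count against every class", {
  r <- suppressWarnings(
    compute_metrics(c("A", "B"), c("unassigned", "B"),
                    class_order = c("A", "B")))
  expect_identical(r$accuracy, 1 / 2)
  expect_identical(r$per_class$recall, c(0, 1))
})

test_that("ROC and PR curves behave at the extremes and under the null", {
  truth <- c("A", "A", "B", "B")
  scores <- cbind(A = c(0.9, 0.8, 0.1, 0.2), B = c(0.1, 0.2, 0.9, 0.8))
  cs <- mst_curves(truth, scores, class_order = c("A", "B"))
  expect_identical(unname(cs$auc), c(1, 1))
  for (cl in c("A", "B")) {
    roc <- cs$roc[[cl]]
    expect_identical(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_identical(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
    expect_true(all(diff(roc$tpr) >= 0))
  }

  set.seed(17)
  n <- 1000
  truth <- sample(c("A", "B"), n, replace = TRUE)
  scores <- cbind(A = runif(n), B = runif(n))
  null_cs <- mst_curves(truth, scores, class_order = c("A", "B"))
  expect_true(all(abs(null_cs$auc - 0.5) < 0.05))
  expect_lt(abs(null_cs$macro_auc - 0.5), 0.05)
  expect_identical(nrow(null_cs$macro_roc), 101L)

  # class B absent from the truth: its curve is skipped with a warning
  expect_warning(
    skipped <- mst_curves(c("A", "C"),
                          cbind(A = c(1, 0), B = c(0, 0), C = c(0, 1)),
                          class_order = c("A", "B", "C")),
    class = "kmst_missing_class_warning")
  expect_null(skipped$roc[["B"]])
  expect_identical(names(skipped$auc), c("A", "C"))
})

test_that("curve AUCs agree with pROC on random score vectors", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:10) {
    n <- 60
    truth <- sample(c("A", "B"), n, replace = TRUE)
    truth[1:2] <- c("A", "B")
    sc <- runif(n)
    cs <- mst_curves(truth, cbind(A = sc, B = 1 - sc),
                     class_order = c("A", "B"))
    ref <- pROC::auc(pROC::roc(truth == "A", sc, quiet = TRUE,
                               direction = "<"))
    expect_equal(unname(cs$auc["A"]), as.numeric(ref))
  }
})

test_that("mono/multi-source categorization uses a strict 75% threshold", {
  p <- function(x) setNames(c(x, (1 - x) / 3, (1 - x) / 3, (1 - x) / 3),
                            classes)
  expect_identical(diversity_class(p(0.80)), "mono-source")
  expect_identical(diversity_class(p(0.75)), "multi-source") # boundary
  expect_identical(diversity_class(p(0.20)), "multi-source")
  expect_warning(out <- diversity_class(NULL),
                 class = "kmst_no_match_warning")
  expect_identical(out, "multi-source")
})

test_that("grouped CV is not more optimistic than leave-one-out here", {
  col <- grouped_collection()
  loo <- leave_one_out(col$matrix, col$metadata)
  cv <- cross_validate(col$matrix, col$metadata, n_folds = 5, seed = 1)
  expect_lte(cv$pooled$accuracy, loo$metrics$accuracy)
})
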