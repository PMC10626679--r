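# Internal: keep a subset of matrix columns, leaving the row index intact
# so sink vectors built from the full matrix stay aligned.
subset_matrix_columns <- function(matrix, keep) {
  new_kmer_matrix(
    kmers = matrix$kmers,
    sample_ids = matrix$sample_ids[keep],
    cells = matrix$cells[, keep, drop = FALSE],
    k = matrix$k, partition_id = matrix$partition_id,
    provenance = matrix$provenance
  )
}

# Internal: score one in-matrix sink (column j) against the remaining
# source columns.
score_column_sink <- function(matrix, metadata, j, source_idx, class_order,
                              include_unknown = TRUE) {
  bits <- as.integer(matrix$cells[, j] > 0)
  sources <- subset_matrix_columns(matrix, source_idx)
  H <- encode_one_hot(metadata[source_idx, , drop = FALSE], class_order)
  w <- count_environment_balls(bits, sources, H)
  p <- suppressWarnings(normalize_proportions(w))
  hard <- predict_label(p, class_order)
  sink_kmers <- matrix$kmers[bits == 1L]
  unk <- if (include_unknown && length(sink_kmers) > 0)
    unknown_fraction(sink_kmers, sources) else NA_real_
  structure(
    list(sink_id = matrix$sample_ids[j], w = w, proportions = p,
         percentages = if (is.null(p)) NULL else 100 * p,
         unknown_fraction = unk,
         predicted_label = hard$label, tie = hard$tie,
         n_matched_kmers = sum(bits * (Matrix::rowSums(sources$cells) > 0)),
         n_sink_kmers_total = sum(bits)),
    class = "mst_result"
  )
}

scores_from_results <- function(results, class_order) {
  t(vapply(results, function(r) {
    if (is.null(r$proportions)) setNames(rep(0, length(class_order)),
                                         class_order)
    else r$proportions[class_order]
  }, numeric(length(class_order))))
}

#' Leave-one-out source tracking over a collection
#'
#' Each sample of the matrix in turn is treated as the sink, with its
#' column removed from the sources and its row removed from the one-hot
#' encoding; the remaining samples are the sources. Hard labels are then
#' compared with the true metadata labels.
#'
#' @param matrix A `kmer_matrix` over the whole collection.
#' @param metadata Metadata aligned with the matrix columns.
#' @param class_order Ordered class set.
#' @param include_unknown Compute unknown fractions (slower)?
#' @return List with `results` (one `mst_result` per sample), `metrics`
#'   (a `metrics_report`), and `curves` (a `curve_set`).
#' @export
leave_one_out <- function(matrix, metadata,
                          class_order = default_class_order(),
                          include_unknown = FALSE) {
  stopifnot(is(matrix, "kmer_matrix"))
  validate_metadata(metadata)
  if (!identical(metadata$sample_id, matrix$sample_ids)) {
    abort_kmst("kmst_metadata_error",
               "metadata rows must match matrix columns in order")
  }
  n <- length(matrix$sample_ids)
  if (n < 2L) {
    abort_kmst("kmst_parameter_error", "leave-one-out needs >= 2 samples")
  }
  results <- lapply(seq_len(n), function(j) {
    score_column_sink(matrix, metadata, j, setdiff(seq_len(n), j),
                      class_order, include_unknown)
  })
  y_pred <- vapply(results, `[[`, character(1), "predicted_label")
  metrics <- compute_metrics(metadata$label, y_pred, class_order)
  curves <- mst_curves(metadata$label,
                       scores_from_results(results, class_order),
                       class_order)
  list(results = results, metrics = metrics, curves = curves)
}

#' Group-stratified cross-validation folds
#'
#' Splits samples into `n_folds` folds such that no group (BioProject)
#' ever spans two folds — the non-overlap constraint is exact — while a
#' greedy heuristic keeps the per-fold class proportions close to the
#' global ones: groups are taken largest-first (ties shuffled by `seed`)
#' and each is placed in the fold where the resulting class composition
#' deviates least from the global proportions, preferring smaller folds
#' on ties.
#'
#' @param metadata Metadata `data.frame` with `sample_id`, `label`,
#'   `group`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed making the split deterministic.
#' @return A `fold_assignment`: list with `n_folds`, `fold_of` (named
#'   integer vector, sample_id -> fold in `1..n_folds`), and `groups`
#'   (named character vector, sample_id -> group).
#' @export
make_group_stratified_folds <- function(metadata, n_folds = 5L, seed = 1L) {
  validate_metadata(metadata)
  n_folds <- assert_scalar_int(n_folds, "n_folds")
  groups <- unique(metadata$group)
  if (length(groups) < n_folds) {
    abort_kmst("kmst_parameter_error",
               "%d groups cannot fill %d folds", length(groups), n_folds)
  }
  classes <- sort(unique(metadata$label))
  global_prop <- prop.table(table(factor(metadata$label, levels = classes)))
  grp_counts <- table(factor(metadata$group, levels = groups),
                      factor(metadata$label, levels = classes))
  grp_sizes <- rowSums(grp_counts)

  ord <- withr::with_seed(seed, {
    order(-grp_sizes, runif(length(groups)))
  })
  fold_counts <- matrix(0, nrow = n_folds, ncol = length(classes))
  fold_sizes <- numeric(n_folds)
  fold_of_group <- setNames(integer(length(groups)), groups)
  for (g in ord) {
    # squared deviation of per-class counts across folds after placing the
    # group in fold f: balances fold sizes and class composition at once
    cost <- vapply(seq_len(n_folds), function(f) {
      trial <- fold_counts
      trial[f, ] <- trial[f, ] + grp_counts[g, ]
      sum(sweep(trial, 2, colMeans(trial))^2)
    }, numeric(1))
    best <- which(cost == min(cost))
    if (length(best) > 1L) {
      best <- best[fold_sizes[best] == min(fold_sizes[best])]
    }
    f <- best[1]
    fold_counts[f, ] <- fold_counts[f, ] + grp_counts[g, ]
    fold_sizes[f] <- fold_sizes[f] + grp_sizes[g]
    fold_of_group[groups[g]] <- f
  }
  fold_of <- setNames(fold_of_group[metadata$group], metadata$sample_id)
  structure(
    list(n_folds = n_folds, fold_of = fold_of,
         groups = setNames(metadata$group, metadata$sample_id)),
    class = "fold_assignment"
  )
}

#' Group-stratified k-fold cross-validation of the MST classifier
#'
#' For each fold, every sample in the fold is scored as a sink against
#' sources drawn exclusively from the other folds, so a sink is never
#' compared against samples from its own BioProject — removing the
#' optimistic bias of leave-one-out when groups carry class-correlated
#' k-mer structure.
#'
#' @inheritParams leave_one_out
#' @param n_folds Number of folds (default 5).
#' @param seed Seed for the fold split.
#' @return List with `folds` (the `fold_assignment`), `results`,
#'   `per_fold` (list of `metrics_report`), and `pooled` (metrics over
#'   all predictions).
#' @export
cross_validate <- function(matrix, metadata, n_folds = 5L, seed = 1L,
                           class_order = default_class_order(),
                           include_unknown = FALSE) {
  stopifnot(is(matrix, "kmer_matrix"))
  validate_metadata(metadata)
  if (!identical(metadata$sample_id, matrix$sample_ids)) {
    abort_kmst("kmst_metadata_error",
               "metadata rows must match matrix columns in order")
  }
  folds <- make_group_stratified_folds(metadata, n_folds, seed)
  fold_of <- folds$fold_of[metadata$sample_id]
  results <- vector("list", nrow(metadata))
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sink_idx <- which(fold_of == f)
    source_idx <- which(fold_of != f)
    missing <- setdiff(unique(metadata$label),
                       metadata$label[source_idx])
    if (length(missing) > 0) {
      warn_kmst("kmst_missing_class_warning",
                "fold %d has no sources for class(es): %s",
                f, paste(missing, collapse = ", "))
    }
    for (j in sink_idx) {
      results[[j]] <- score_column_sink(matrix, metadata, j, source_idx,
                                        class_order, include_unknown)
    }
    per_fold[[f]] <- compute_metrics(
      metadata$label[sink_idx],
      vapply(results[sink_idx], `[[`, character(1), "predicted_label"),
      class_order)
  }
  y_pred <- vapply(results, `[[`, character(1), "predicted_label")
  list(folds = folds, results = results, per_fold = per_fold,
       pooled = compute_metrics(metadata$label, y_pred, class_order))
}

#' Multi-class classification metrics
#'
#' Accuracy is the global fraction of exact matches; precision, recall
#' and F1 are computed per class one-vs-rest and macro-averaged
#' (unweighted mean over classes present in the truth). `"unassigned"`
#' predictions count as wrong for every class. A class predicted for no
#' sample gets precision 0 with a warning.
#'
#' @param y_true,y_pred Character label vectors of equal length;
#'   predictions may contain `"unassigned"`.
#' @param class_order Ordered class set.
#' @return A `metrics_report`: list with `accuracy`,
#'   `balanced_accuracy`, macro `precision`, `recall`, `f1`, `per_class`
#'   data frame, and the `confusion` table (truth rows, prediction
#'   columns including `"unassigned"`).
#' @export
compute_metrics <- function(y_true, y_pred,
                            class_order = default_class_order()) {
  if (length(y_true) != length(y_pred)) {
    abort_kmst("kmst_shape_error",
               "y_true (%d) and y_pred (%d) differ in length",
               length(y_true), length(y_pred))
  }
  pred_levels <- c(class_order, "unassigned")
  bad <- !(y_true %in% class_order)
  if (any(bad)) {
    abort_kmst("kmst_unknown_class_error",
               "true label %s not in class_order", deparse(y_true[bad][1]))
  }
  bad <- !(y_pred %in% pred_levels)
  if (any(bad)) {
    abort_kmst("kmst_unknown_class_error",
               "predicted label %s not in class_order",
               deparse(y_pred[bad][1]))
  }
  confusion <- table(truth = factor(y_true, levels = class_order),
                     prediction = factor(y_pred, levels = pred_levels))
  support <- rowSums(confusion)
  tp <- vapply(class_order, function(cl) confusion[cl, cl], numeric(1))
  predicted <- colSums(confusion)[class_order]
  if (any(predicted == 0 & support > 0)) {
    warn_kmst("kmst_zero_division_warning",
              "class(es) never predicted; precision set to 0: %s",
              paste(class_order[predicted == 0 & support > 0],
                    collapse = ", "))
  }
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), 0)
  f1[is.na(recall)] <- NA_real_
  present <- support > 0
  per_class <- data.frame(
    class = class_order, precision = unname(precision),
    recall = unname(recall), f1 = unname(f1),
    support = unname(support), stringsAsFactors = FALSE)
  structure(
    list(accuracy = mean(y_true == y_pred),
         balanced_accuracy = mean(recall[present]),
         precision = mean(precision[present]),
         recall = mean(recall[present]),
         f1 = mean(f1[present]),
         per_class = per_class,
         confusion = confusion,
         n = length(y_true)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d accuracy=%.4f precision=%.4f recall=%.4f f1=%.4f (macro)\n",
    x$n, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

# Internal: one-vs-rest ROC/PR sweep for a single class. Thresholds are
# the unique scores in decreasing order; a point is emitted after each
# threshold, so the ROC runs from (0,0) to (1,1).
binary_sweep <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]
  score <- score[ord]
  # cumulative counts at each distinct-score cut
  cuts <- which(c(diff(score) != 0, TRUE))
  tps <- cumsum(truth)[cuts]
  fps <- cumsum(!truth)[cuts]
  P <- sum(truth)
  N <- sum(!truth)
  data.frame(
    threshold = c(Inf, score[cuts]),
    tpr = c(0, tps / P),
    fpr = c(0, fps / N),
    precision = c(1, ifelse(tps + fps > 0, tps / (tps + fps), 1)),
    recall = c(0, tps / P)
  )
}

trapezoid_auc <- function(x, y) {
  ord <- order(x)
  sum(diff(x[ord]) * (head(y[ord], -1) + y[ord][-1]) / 2)
}

#' One-vs-rest ROC and precision-recall curves
#'
#' For each class, the binary truth `y_true == class` is scored by the
#' estimated proportion of that class; ROC and PR points come from a
#' threshold sweep over the distinct scores. The macro-averaged ROC is
#' the mean true-positive rate interpolated on a fixed grid of 101
#' false-positive rates. Samples with undefined proportions must be
#' given score 0 for every class before calling (the evaluation drivers
#' do this).
#'
#' @param y_true Character vector of true labels.
#' @param scores Numeric matrix, samples by classes (columns named or in
#'   `class_order` order).
#' @param class_order Ordered class set.
#' @return A `curve_set`: per-class `roc` and `pr` point data frames,
#'   per-class `auc`, `macro_roc` (101-point grid) and `macro_auc`.
#' @export
mst_curves <- function(y_true, scores, class_order = default_class_order()) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- class_order
  if (nrow(scores) != length(y_true)) {
    abort_kmst("kmst_shape_error", "scores rows != length(y_true)")
  }
  grid <- seq(0, 1, length.out = 101L)
  roc <- list(); pr <- list(); auc <- c(); tpr_on_grid <- list()
  for (cl in class_order) {
    if (!any(y_true == cl)) {
      warn_kmst("kmst_missing_class_warning",
                "class %s absent from y_true; curve skipped", cl)
      next
    }
    if (all(y_true == cl)) {
      warn_kmst("kmst_missing_class_warning",
                "class %s has no negatives; curve skipped", cl)
      next
    }
    sw <- binary_sweep(y_true == cl, scores[, cl])
    roc[[cl]] <- sw[, c("threshold", "fpr", "tpr")]
    pr[[cl]] <- sw[, c("threshold", "recall", "precision")]
    auc[cl] <- trapezoid_auc(sw$fpr, sw$tpr)
    tpr_on_grid[[cl]] <- stats::approx(sw$fpr, sw$tpr, xout = grid,
                                       ties = max, rule = 2)$y
  }
  macro_roc <- if (length(tpr_on_grid) > 0) {
    data.frame(fpr = grid,
               tpr = Reduce(`+`, tpr_on_grid) / length(tpr_on_grid))
  } else NULL
  structure(
    list(roc = roc, pr = pr, auc = auc, macro_roc = macro_roc,
         macro_auc = if (is.null(macro_roc)) NA_real_ else
           trapezoid_auc(macro_roc$fpr, macro_roc$tpr)),
    class = "curve_set"
  )
}

#' Mono- versus multi-source categorization
#'
#' A sink is called "mono-source" when its top estimated environment
#' proportion strictly exceeds the threshold (default 75%): it is
#' dominated by one environment and only lightly contaminated by others.
#' Everything else — including sinks with undefined proportions — is
#' "multi-source".
#'
#' @param result An `mst_result`, or a proportion vector (or `NULL`).
#' @param threshold Strict lower bound on the top proportion (default
#'   0.75).
#' @return `"mono-source"` or `"multi-source"`.
#' @export
#' @examples
#' diversity_class(c(aOral = 0.8, mOral = 0.1, skin = 0.05, soil = 0.05))
diversity_class <- function(result, threshold = 0.75) {
  p <- if (is(result, "mst_result")) result$proportions else result
  if (is.null(p)) {
    warn_kmst("kmst_no_match_warning",
              "undefined proportions; classified multi-source")
    return("multi-source")
  }
  if (max(p) > threshold) "mono-source" else "multi-source"
}
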