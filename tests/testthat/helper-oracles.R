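# Independent oracles, deliberately written as naive loops so they share
# no code path with the package implementation.

# Ball counting: triple loop over k-mers x sources x classes.
oracle_ball_counts <- function(sink_bits, source_cells, labels, class_order) {
  w <- setNames(rep(0, length(class_order)), class_order)
  for (i in seq_along(sink_bits)) {
    if (sink_bits[i] == 0) next
    for (j in seq_len(ncol(source_cells))) {
      if (source_cells[i, j] == 0) next
      for (cl in class_order) {
        if (labels[j] == cl) w[cl] <- w[cl] + 1
      }
    }
  }
  w
}

# Confusion-matrix metrics computed from first principles.
oracle_metrics <- function(y_true, y_pred, class_order) {
  acc <- sum(y_true == y_pred) / length(y_true)
  prec <- rec <- f1 <- c()
  for (cl in class_order) {
    if (!any(y_true == cl)) next
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / (tp + fn)
    prec <- c(prec, p)
    rec <- c(rec, r)
    f1 <- c(f1, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  list(accuracy = acc, precision = mean(prec), recall = mean(rec),
       f1 = mean(f1))
}

# Small random binary instance for the Eq.-style counting checks.
random_ball_instance <- function(K, L, class_order) {
  cells <- Matrix::Matrix(
    matrix(rbinom(K * L, 1, 0.3), nrow = K), sparse = TRUE)
  labels <- sample(class_order, L, replace = TRUE)
  sink <- rbinom(K, 1, 0.4)
  list(sink = sink, cells = cells, labels = labels)
}

kmer_matrix_from_cells <- function(cells, sample_ids = NULL, kmers = NULL,
                                   k = 31L) {
  cells <- methods::as(Matrix::Matrix(cells, sparse = TRUE),
                       "CsparseMatrix")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(cells)))
  if (is.null(kmers)) kmers <- sprintf("kmer%05d", seq_len(nrow(cells)))
  colnames(cells) <- sample_ids
  structure(
    list(kmers = kmers, sample_ids = sample_ids, cells = cells,
         k = as.integer(k), partition_id = "all",
         provenance = list(min_abundance = 2L, min_recurrence = 1L,
                           num_partitions = 1L, salt = 0L)),
    class = "kmer_matrix")
}
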