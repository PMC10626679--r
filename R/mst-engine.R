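#' Vectorize a sink sample against a source matrix
#'
#' Projects the sink's canonical k-mer set onto the row index of a source
#' matrix, producing the binary presence vector used by the counting step.
#' Sink k-mers absent from the matrix rows are not represented in the
#' vector; their number is recoverable from `n_sink_kmers_total`.
#'
#' @param sink_kmers A `sample_kmer_set` or character vector of canonical
#'   k-mers (already abundance-filtered).
#' @param matrix A `kmer_matrix` of sources.
#' @return An object of class `sink_vector`: list with `sink_id`, `bits`
#'   (0/1 vector of length `K`), and `n_sink_kmers_total`.
#' @export
vectorize_sink <- function(sink_kmers, matrix) {
  stopifnot(is(matrix, "kmer_matrix"))
  sink_id <- NA_character_
  if (is(sink_kmers, "sample_kmer_set")) {
    if (!is.na(matrix$k) && sink_kmers$k != matrix$k) {
      abort_kmst("kmst_parameter_error",
                 "sink k (%d) does not match matrix k (%d)",
                 sink_kmers$k, matrix$k)
    }
    sink_id <- sink_kmers$sample_id
    sink_kmers <- sink_kmers$kmers
  }
  sink_kmers <- unique(as.character(sink_kmers))
  structure(
    list(sink_id = sink_id,
         bits = as.integer(matrix$kmers %in% sink_kmers),
         n_sink_kmers_total = length(sink_kmers)),
    class = "sink_vector"
  )
}

#' Count environment balls for a sink
#'
#' The ball-and-bin counting at the heart of the method: every (k-mer,
#' source) pair where the k-mer is present in both the sink and that
#' source drops one ball into the bin of the source's environment label.
#' In matrix form, `w = m' %*% M %*% H` where `m` is the sink presence
#' vector, `M` the source matrix and `H` the one-hot label encoding.
#'
#' @param sink A `sink_vector` (or plain 0/1 vector of length `K`).
#' @param sources A `kmer_matrix` (or a `K x (L-1)` binary matrix).
#' @param H One-hot label matrix from [encode_one_hot()].
#' @return Named numeric vector `w` of ball counts, one per class.
#' @export
count_environment_balls <- function(sink, sources, H) {
  bits <- if (is(sink, "sink_vector")) sink$bits else as.numeric(sink)
  cells <- if (is(sources, "kmer_matrix")) sources$cells else sources
  if (length(bits) != nrow(cells)) {
    abort_kmst("kmst_shape_error",
               "sink vector length %d does not match %d matrix rows",
               length(bits), nrow(cells))
  }
  if (ncol(cells) != nrow(H)) {
    abort_kmst("kmst_shape_error",
               "%d source columns but %d one-hot rows",
               ncol(cells), nrow(H))
  }
  w <- as.numeric(Matrix::crossprod(bits, cells %*% H))
  names(w) <- colnames(H)
  w
}

#' Normalize ball counts to proportions
#'
#' Converts the raw ball counts into proportions of the total over all
#' known source environments, so that the reported contributions always
#' sum to 100%. When the sink shares no k-mer with any source the
#' denominator is zero: the proportions are undefined (`NULL`) and a
#' `kmst_no_match_warning` is signalled instead of crashing.
#'
#' @param w Named non-negative count vector from
#'   [count_environment_balls()].
#' @return Named proportions summing to 1, or `NULL` if `sum(w) == 0`.
#' @export
#' @examples
#' normalize_proportions(c(aOral = 3, mOral = 0, skin = 2, soil = 1))
normalize_proportions <- function(w) {
  if (any(w < 0)) {
    abort_kmst("kmst_parameter_error", "ball counts must be non-negative")
  }
  total <- sum(w)
  if (total == 0) {
    warn_kmst("kmst_no_match_warning",
              "sink shares no k-mer with any source; proportions undefined")
    return(NULL)
  }
  w / total
}

#' Assign the hard environment label
#'
#' The hard label is the environment with the highest estimated
#' contribution. If the maximum is attained by two or more classes the
#' earliest one in `class_order` is reported and the tie is flagged; a
#' `NULL` proportion vector (no shared k-mers) yields `"unassigned"`.
#'
#' @param p Proportion vector from [normalize_proportions()], or `NULL`.
#' @param class_order Ordered class set used for tie-breaking.
#' @return List with `label` and logical `tie`.
#' @export
predict_label <- function(p, class_order = default_class_order()) {
  if (is.null(p)) return(list(label = "unassigned", tie = FALSE))
  p <- p[class_order]
  mx <- max(p)
  at_max <- which(p == mx)
  list(label = class_order[at_max[1]], tie = length(at_max) > 1L)
}

#' Unknown-source fraction of a sink
#'
#' The share of the sink's k-mers that are present in the sink but absent
#' from every source: k-mers missing from the matrix row index entirely,
#' or sitting on an all-zero row. This quantifies how much of the sink is
#' unexplained by the known environments; it is reported alongside — not
#' folded into — the known-class proportions, which are normalized over
#' ball counts on a different scale.
#'
#' @param sink_kmers A `sample_kmer_set` or character vector of canonical
#'   k-mers.
#' @param sources A `kmer_matrix`.
#' @return Fraction in `[0, 1]`.
#' @export
unknown_fraction <- function(sink_kmers, sources) {
  stopifnot(is(sources, "kmer_matrix"))
  if (is(sink_kmers, "sample_kmer_set")) sink_kmers <- sink_kmers$kmers
  sink_kmers <- unique(as.character(sink_kmers))
  if (length(sink_kmers) == 0L) {
    abort_kmst("kmst_empty_input_error", "sink has no k-mers")
  }
  covered <- sources$kmers[Matrix::rowSums(sources$cells) > 0]
  sum(!(sink_kmers %in% covered)) / length(sink_kmers)
}

#' Run microbial source tracking for one sink
#'
#' Orchestrates the full estimator: extract the sink's abundance-filtered
#' canonical k-mers (if reads are given), restrict them to the matrix's
#' hash partition, vectorize against the source rows, count environment
#' balls, normalize to proportions, assign the hard label, and compute the
#' unknown fraction. When the matrix was built on a single partition, the
#' sink's k-mers are filtered to that same partition so that the unknown
#' fraction is estimated on the same random subsample of k-mer space as
#' the sources.
#'
#' @param sink Reads (character vector), a path to a FASTA/FASTQ file, or
#'   a precomputed `sample_kmer_set`.
#' @param sources A `kmer_matrix` of sources.
#' @param metadata Metadata `data.frame` aligned with the matrix columns.
#' @param class_order Ordered class set.
#' @param sink_id Identifier for the result (defaults to the kmer set's).
#' @param min_abundance Within-sample abundance filter used when `sink`
#'   is reads (defaults to the matrix provenance, else 2).
#' @param include_unknown Compute the unknown-source fraction?
#' @return An `mst_result`: list with `sink_id`, `w` (ball counts),
#'   `proportions`, `percentages`, `unknown_fraction`, `predicted_label`,
#'   `tie`, `n_matched_kmers`, `n_sink_kmers_total`.
#' @export
run_mst <- function(sink, sources, metadata,
                    class_order = default_class_order(),
                    sink_id = NULL, min_abundance = NULL,
                    include_unknown = TRUE) {
  stopifnot(is(sources, "kmer_matrix"))
  validate_metadata(metadata)
  if (!identical(metadata$sample_id, sources$sample_ids)) {
    abort_kmst("kmst_metadata_error",
               "metadata rows must match matrix columns in order")
  }
  if (is.null(min_abundance)) {
    min_abundance <- sources$provenance$min_abundance
    if (is.null(min_abundance) || is.na(min_abundance)) min_abundance <- 2L
  }
  if (is.character(sink) && length(sink) == 1L && file.exists(sink)) {
    sink <- read_sequences(sink)
  }
  kset <- if (is(sink, "sample_kmer_set")) sink else
    extract_present_kmers(sink, k = sources$k, min_abundance = min_abundance,
                          sample_id = if (is.null(sink_id)) "sink" else sink_id)
  if (is.null(sink_id)) sink_id <- kset$sample_id

  sink_kmers <- kset$kmers
  if (!identical(sources$partition_id, "all")) {
    part <- assign_partition(sink_kmers,
                             sources$provenance$num_partitions,
                             sources$provenance$salt)
    sink_kmers <- sink_kmers[part == sources$partition_id]
  }

  sv <- vectorize_sink(
    structure(list(sample_id = sink_id, kmers = sink_kmers,
                   counts = kset$counts, k = kset$k,
                   min_abundance = kset$min_abundance),
              class = "sample_kmer_set"),
    sources)
  H <- encode_one_hot(metadata, class_order)
  w <- count_environment_balls(sv, sources, H)
  p <- withCallingHandlers(
    normalize_proportions(w),
    kmst_no_match_warning = function(wrn) invokeRestart("muffleWarning"))
  if (is.null(p)) {
    warn_kmst("kmst_no_match_warning",
              "sink %s shares no k-mer with any source; label unassigned",
              sink_id)
  }
  hard <- predict_label(p, class_order)
  unk <- if (include_unknown && length(sink_kmers) > 0)
    unknown_fraction(sink_kmers, sources) else NA_real_

  structure(
    list(sink_id = sink_id,
         w = w,
         proportions = p,
         percentages = if (is.null(p)) NULL else 100 * p,
         unknown_fraction = unk,
         predicted_label = hard$label,
         tie = hard$tie,
         n_matched_kmers = sum(sv$bits),
         n_sink_kmers_total = sv$n_sink_kmers_total),
    class = "mst_result"
  )
}

#' @export
print.mst_result <- function(x, ...) {
  cat(sprintf("<mst_result> %s -> %s%s\n", x$sink_id, x$predicted_label,
              if (x$tie) " (tie)" else ""))
  if (!is.null(x$percentages)) {
    cat(paste(sprintf("  %-14s %6.2f%%", names(x$percentages),
                      x$percentages), collapse = "\n"), "\n")
  }
  if (!is.na(x$unknown_fraction)) {
    cat(sprintf("  unknown fraction: %.3f\n", x$unknown_fraction))
  }
  invisible(x)
}

#' Convert MST results to a data frame
#'
#' One row per sink: proportion columns per class, then
#' `unknown_fraction`, `predicted_label`, `tie`, `n_matched_kmers`,
#' `n_sink_kmers_total`. Sinks with undefined proportions get `NA`
#' proportions and the label `"unassigned"`.
#'
#' @param x An `mst_result` or list of them.
#' @param ... Unused.
#' @return A `data.frame`.
#' @export
as.data.frame.mst_result <- function(x, ...) {
  classes <- names(x$w)
  p <- if (is.null(x$proportions)) setNames(rep(NA_real_, length(classes)),
                                            classes) else x$proportions
  df <- data.frame(sink_id = x$sink_id, stringsAsFactors = FALSE)
  for (cl in classes) df[[cl]] <- unname(p[cl])
  df$unknown_fraction <- x$unknown_fraction
  df$predicted_label <- x$predicted_label
  df$tie <- x$tie
  df$n_matched_kmers <- x$n_matched_kmers
  df$n_sink_kmers_total <- x$n_sink_kmers_total
  df
}

#' @rdname as.data.frame.mst_result
#' @export
mst_results_table <- function(x) {
  if (is(x, "mst_result")) x <- list(x)
  do.call(rbind, lapply(x, as.data.frame))
}
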