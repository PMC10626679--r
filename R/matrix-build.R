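#' Sample metadata tables
#'
#' Metadata is a plain `data.frame` with columns `sample_id`, `label`
#' (environment class) and `group` (a BioProject-like accession grouping
#' used as the non-overlap unit in cross-validation).
#'
#' @param sample_id,label,group Character vectors of equal length.
#' @return A validated metadata `data.frame`.
#' @export
sample_metadata <- function(sample_id, label, group) {
  md <- data.frame(sample_id = as.character(sample_id),
                   label = as.character(label),
                   group = as.character(group),
                   stringsAsFactors = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(metadata) {
  need <- c("sample_id", "label", "group")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata))) {
    abort_kmst("kmst_metadata_error",
               "metadata must be a data.frame with columns %s",
               paste(need, collapse = ", "))
  }
  if (anyDuplicated(metadata$sample_id)) {
    abort_kmst("kmst_duplicate_sample_error",
               "duplicated sample_id: %s",
               metadata$sample_id[duplicated(metadata$sample_id)][1])
  }
  bad <- is.na(metadata$label) | metadata$label == ""
  if (any(bad)) {
    abort_kmst("kmst_metadata_error", "sample %s has no label",
               metadata$sample_id[bad][1])
  }
  bad <- is.na(metadata$group) | metadata$group == ""
  if (any(bad)) {
    abort_kmst("kmst_metadata_error", "sample %s has no group",
               metadata$sample_id[bad][1])
  }
  invisible(metadata)
}

kmer_set_strings <- function(x) {
  if (is(x, "sample_kmer_set")) x$kmers else sort(unique(as.character(x)))
}

#' Build the labelled binary source matrix
#'
#' Assembles the presence/absence matrix over canonical k-mers (rows,
#' lexicographically sorted) by samples (columns). Three filters shape the
#' rows: the per-sample abundance filter (already applied inside each
#' `sample_kmer_set`), the partition subsampling (only k-mers hashing into
#' `selected_partition` are kept, unless `"all"`), and the cross-sample
#' recurrence filter — a k-mer must be present in at least
#' `min_recurrence` samples of the collection to carry any signal for
#' distinguishing environments. The default `min_recurrence = 3` matches
#' the regime used on real collections; toy examples use smaller values.
#'
#' @param kmer_sets Named list (names = sample ids) of `sample_kmer_set`
#'   objects or plain character vectors of canonical k-mers.
#' @param metadata Metadata `data.frame` (see [sample_metadata()]) with one
#'   row per sample, in any order; returned reordered to column order.
#' @param min_recurrence Minimum number of samples a k-mer must appear in
#'   (default 3).
#' @param num_partitions Number of hash partitions (default 700).
#' @param selected_partition Partition id to keep, or `"all"` to disable
#'   partition subsampling.
#' @param salt Hash salt for partition assignment.
#' @return A list with `matrix` (a `kmer_matrix`) and `metadata` (the
#'   metadata reordered to match the matrix columns).
#' @export
build_source_matrix <- function(kmer_sets, metadata, min_recurrence = 3L,
                                num_partitions = 700L,
                                selected_partition = "all", salt = 0L) {
  if (length(kmer_sets) < 2L) {
    abort_kmst("kmst_parameter_error", "need at least 2 samples")
  }
  ids <- names(kmer_sets)
  if (is.null(ids) || any(ids == "")) {
    abort_kmst("kmst_metadata_error", "kmer_sets must be a named list")
  }
  if (anyDuplicated(ids)) {
    abort_kmst("kmst_duplicate_sample_error", "duplicated sample_id: %s",
               ids[duplicated(ids)][1])
  }
  validate_metadata(metadata)
  if (!all(ids %in% metadata$sample_id)) {
    abort_kmst("kmst_metadata_error", "sample %s missing from metadata",
               setdiff(ids, metadata$sample_id)[1])
  }
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  min_recurrence <- assert_scalar_int(min_recurrence, "min_recurrence")
  num_partitions <- assert_scalar_int(num_partitions, "num_partitions")

  sets <- lapply(kmer_sets, kmer_set_strings)
  if (!identical(selected_partition, "all")) {
    selected_partition <- assert_scalar_int(selected_partition,
                                            "selected_partition", min = 0L)
    if (selected_partition >= num_partitions) {
      abort_kmst("kmst_parameter_error",
                 "selected_partition must be < num_partitions")
    }
    sets <- lapply(sets, function(km) {
      km[assign_partition(km, num_partitions, salt) == selected_partition]
    })
  }

  all_kmers <- sort(unique(unlist(sets, use.names = FALSE)))
  n <- length(sets)
  i_idx <- lapply(sets, match, table = all_kmers)
  cells <- Matrix::sparseMatrix(
    i = unlist(i_idx, use.names = FALSE),
    j = rep.int(seq_len(n), lengths(i_idx)),
    x = 1,
    dims = c(length(all_kmers), n),
    dimnames = list(NULL, ids)
  )
  keep <- Matrix::rowSums(cells) >= min_recurrence
  cells <- cells[keep, , drop = FALSE]
  all_kmers <- all_kmers[keep]

  empty <- Matrix::colSums(cells) == 0
  if (any(empty)) {
    warn_kmst("kmst_empty_column_warning",
              "sample(s) with zero surviving k-mers retained as all-zero columns: %s",
              paste(ids[empty], collapse = ", "))
  }

  ks <- unique(unlist(lapply(kmer_sets, function(x)
    if (is(x, "sample_kmer_set")) x$k else NULL)))
  if (length(ks) > 1L) {
    abort_kmst("kmst_parameter_error", "samples disagree on k: %s",
               paste(ks, collapse = ", "))
  }
  if (length(ks) == 0L) {
    ks <- if (length(all_kmers)) nchar(all_kmers[1]) else NA_integer_
  }
  mab <- unique(unlist(lapply(kmer_sets, function(x)
    if (is(x, "sample_kmer_set")) x$min_abundance else NULL)))

  mat <- new_kmer_matrix(
    kmers = all_kmers, sample_ids = ids, cells = cells, k = ks,
    partition_id = if (identical(selected_partition, "all")) "all"
                   else selected_partition,
    provenance = list(
      min_abundance = if (length(mab) == 1L) mab else NA_integer_,
      min_recurrence = min_recurrence,
      num_partitions = num_partitions,
      salt = as.integer(salt))
  )
  list(matrix = mat, metadata = metadata)
}

new_kmer_matrix <- function(kmers, sample_ids, cells, k, partition_id,
                            provenance) {
  structure(
    list(kmers = kmers, sample_ids = sample_ids, cells = cells,
         k = as.integer(k), partition_id = partition_id,
         provenance = provenance),
    class = "kmer_matrix"
  )
}

#' @export
print.kmer_matrix <- function(x, ...) {
  cat(sprintf(
    "<kmer_matrix> %d canonical %d-mers x %d samples (partition %s/%s, min_recurrence=%s)\n",
    length(x$kmers), x$k, length(x$sample_ids),
    as.character(x$partition_id), x$provenance$num_partitions,
    x$provenance$min_recurrence))
  invisible(x)
}

#' @export
dim.kmer_matrix <- function(x) dim(x$cells)

#' One-hot encode environment labels
#'
#' Encodes the categorical label vector of the sources as a sparse binary
#' matrix `H` of size `(L-1) x |C|`, with `H[i, j] = 1` iff sample `i`
#' carries label `class_order[j]`. Every row sums to exactly 1.
#'
#' @param metadata Metadata `data.frame`, or a plain character vector of
#'   labels.
#' @param class_order Ordered class set; defaults to
#'   [default_class_order()].
#' @return A sparse `dgCMatrix` with sample ids as rownames and classes as
#'   colnames.
#' @export
#' @examples
#' encode_one_hot(c("aOral", "skin"))
encode_one_hot <- function(metadata, class_order = default_class_order()) {
  labels <- if (is.data.frame(metadata)) metadata$label else
    as.character(metadata)
  ids <- if (is.data.frame(metadata)) metadata$sample_id else
    as.character(seq_along(labels))
  bad <- !(labels %in% class_order)
  if (any(bad)) {
    abort_kmst("kmst_unknown_class_error",
               "label %s not in class_order", deparse(labels[bad][1]))
  }
  Matrix::sparseMatrix(
    i = seq_along(labels),
    j = match(labels, class_order),
    x = 1,
    dims = c(length(labels), length(class_order)),
    dimnames = list(ids, class_order)
  )
}

# Serialization ----------------------------------------------------------

sidecar_paths <- function(path) {
  base <- sub("\\.tsv$", "", path)
  list(matrix = path,
       meta = paste0(base, ".meta.tsv"),
       json = paste0(base, ".json"))
}

#' Write a k-mer matrix and its metadata to disk
#'
#' The on-disk dialect is deliberately human-inspectable: a TSV whose
#' header line is `#kmer` followed by the sample ids, one row per k-mer
#' with literal `0`/`1` cells, LF line endings, k-mers uppercase and
#' lexicographically sorted. Two sidecar files accompany the matrix: a
#' metadata TSV (`sample_id`, `label`, `group`) and a JSON file recording
#' `k`, the partition settings and the filter provenance, so a read-back
#' reproduces every field bit-exactly.
#'
#' @param matrix A `kmer_matrix`.
#' @param metadata Metadata `data.frame` in matrix column order.
#' @param path Output path for the matrix TSV; sidecars are derived by
#'   replacing the extension (`<base>.meta.tsv`, `<base>.json`).
#' @return `path`, invisibly.
#' @export
write_kmer_matrix <- function(matrix, metadata, path) {
  stopifnot(is(matrix, "kmer_matrix"))
  validate_metadata(metadata)
  if (!identical(metadata$sample_id, matrix$sample_ids)) {
    abort_kmst("kmst_metadata_error",
               "metadata rows must match matrix columns in order")
  }
  p <- sidecar_paths(path)
  dense <- as.matrix(matrix$cells)
  storage.mode(dense) <- "integer"
  header <- paste(c("#kmer", matrix$sample_ids), collapse = "\t")
  rows <- if (nrow(dense) > 0) {
    paste(matrix$kmers,
          apply(dense, 1L, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  writeLines(c(header, rows), p$matrix, sep = "\n")
  writeLines(c("sample_id\tlabel\tgroup",
               paste(metadata$sample_id, metadata$label, metadata$group,
                     sep = "\t")),
             p$meta, sep = "\n")
  jsonlite::write_json(
    list(k = matrix$k, partition_id = matrix$partition_id,
         provenance = matrix$provenance),
    p$json, auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  invisible(path)
}

#' Read a k-mer matrix written by [write_kmer_matrix()]
#'
#' Strictly validates the dialect: a `#kmer` header, constant column
#' counts, and literal `0`/`1` cells; violations raise a
#' `kmst_format_error` naming the offending line.
#'
#' @param path Path to the matrix TSV (sidecars found alongside).
#' @return A list with `matrix` (a `kmer_matrix`) and `metadata`.
#' @export
read_kmer_matrix <- function(path) {
  p <- sidecar_paths(path)
  if (!file.exists(p$matrix)) {
    abort_kmst("kmst_format_error", "file not found: %s", p$matrix)
  }
  lines <- readLines(p$matrix)
  if (length(lines) == 0L || !startsWith(lines[1], "#kmer")) {
    abort_kmst("kmst_format_error", "%s line 1: expected '#kmer' header",
               p$matrix)
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  n <- length(ids)
  body <- lines[-1]
  kmers <- character(length(body))
  cells01 <- matrix(0L, nrow = length(body), ncol = n)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != n + 1L) {
      abort_kmst("kmst_format_error",
                 "%s line %d: expected %d columns, found %d",
                 p$matrix, i + 1L, n + 1L, length(f))
    }
    vals <- f[-1]
    if (!all(vals %in% c("0", "1"))) {
      abort_kmst("kmst_format_error",
                 "%s line %d: cell value %s is not 0/1",
                 p$matrix, i + 1L, deparse(vals[!vals %in% c("0", "1")][1]))
    }
    kmers[i] <- f[1]
    cells01[i, ] <- as.integer(vals)
  }
  meta <- utils::read.table(p$meta, header = TRUE, sep = "\t",
                            colClasses = "character")
  validate_metadata(meta)
  side <- jsonlite::read_json(p$json, simplifyVector = TRUE)
  part <- side$partition_id
  if (!identical(part, "all")) part <- as.integer(part)
  int_or_na <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  mat <- new_kmer_matrix(
    kmers = kmers, sample_ids = ids,
    cells = as(Matrix::Matrix(cells01, sparse = TRUE,
                              dimnames = list(NULL, ids)), "CsparseMatrix"),
    k = int_or_na(side$k), partition_id = part,
    provenance = lapply(side$provenance, int_or_na)
  )
  list(matrix = mat, metadata = meta)
}
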