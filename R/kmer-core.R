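#' Canonicalize k-mer strings
#'
#' Maps each k-mer to its canonical form, the lexicographic minimum of the
#' k-mer and its reverse complement. Canonical k-mers make presence/absence
#' counting strand-insensitive: a fragment and its complement collapse to
#' one row of the matrix.
#'
#' @param kmers Character vector of DNA strings over `{A,C,G,T}`, all of
#'   length `k`. Lower-case input is uppercased first.
#' @param k Integer k-mer length. Defaults to the length of the first
#'   element.
#' @return Character vector of canonical k-mers, same length as `kmers`.
#' @export
#' @examples
#' canonicalize(c("ACG", "TTT", "ACGT"), k = NULL)
canonicalize <- function(kmers, k = NULL) {
  if (length(kmers) == 0L) return(character(0))
  if (is.null(k)) k <- nchar(kmers[[1]])
  k <- assert_scalar_int(k, "k")
  kmers <- toupper(kmers)
  bad <- grepl("[^ACGT]", kmers)
  if (any(bad)) {
    abort_kmst("kmst_invalid_base_error",
               "k-mer %d contains a character outside {A,C,G,T}",
               which(bad)[1])
  }
  if (any(nchar(kmers) != k)) {
    i <- which(nchar(kmers) != k)[1]
    abort_kmst("kmst_length_error",
               "k-mer %d has length %d, expected %d", i, nchar(kmers[i]), k)
  }
  cpp_canonicalize(kmers, k)
}

#' Extract the canonical k-mers present in a sample
#'
#' Slides a window of length `k` over every read, canonicalizes each
#' window, sums abundances over both strands, and keeps k-mers whose total
#' within-sample count reaches `min_abundance`. The default
#' `min_abundance = 2` discards k-mers seen only once in a sample, which
#' are overwhelmingly sequencing errors. Windows containing any non-ACGT
#' character (e.g. `N`) are skipped, and reads shorter than `k` contribute
#' nothing.
#'
#' @param reads Character vector of read sequences (case-insensitive), or
#'   a `Biostrings::DNAStringSet`.
#' @param k Odd k-mer length, default 31.
#' @param min_abundance Minimum within-sample abundance for a k-mer to
#'   count as present, default 2.
#' @param sample_id Optional sample identifier carried in the result.
#' @return An object of class `sample_kmer_set`: a list with elements
#'   `sample_id`, `kmers` (sorted canonical k-mers passing the filter),
#'   `counts` (named integer vector of raw abundances of *all* observed
#'   canonical k-mers), `k`, and `min_abundance`.
#' @export
#' @examples
#' extract_present_kmers(c("AAAAA", "AAAAA"), k = 5, min_abundance = 2)
extract_present_kmers <- function(reads, k = 31L, min_abundance = 2L,
                                  sample_id = NA_character_) {
  if (is(reads, "DNAStringSet")) reads <- as.character(reads)
  if (length(reads) == 0L) {
    abort_kmst("kmst_empty_input_error", "no reads supplied")
  }
  k <- assert_scalar_int(k, "k")
  min_abundance <- assert_scalar_int(min_abundance, "min_abundance")
  counts <- cpp_count_kmers(toupper(reads), k)
  kept <- sort(names(counts)[counts >= min_abundance])
  structure(
    list(sample_id = sample_id, kmers = kept, counts = counts,
         k = k, min_abundance = min_abundance),
    class = "sample_kmer_set"
  )
}

#' @export
print.sample_kmer_set <- function(x, ...) {
  cat(sprintf(
    "<sample_kmer_set> %s: %d present %d-mers (%d distinct observed, min_abundance=%d)\n",
    x$sample_id, length(x$kmers), x$k, length(x$counts), x$min_abundance))
  invisible(x)
}

#' Assign k-mers to disjoint partitions
#'
#' Full k-mer matrices are too large to hold in memory, so rows are split
#' into disjoint partitions and a single partition — effectively a random
#' subset of the rows — is retained for analysis. Here the partition of a
#' canonical k-mer is a salted 64-bit FNV-1a hash of its string, reduced
#' modulo `num_partitions`: deterministic, uniform, and independent of the
#' sample the k-mer came from.
#'
#' @param kmers Character vector of canonical k-mers.
#' @param num_partitions Number of disjoint partitions (default 700).
#' @param salt Integer salt mixed into the hash (default 0).
#' @return Integer vector of partition ids in `[0, num_partitions)`.
#' @export
#' @examples
#' assign_partition(c("AAA", "ACG"), num_partitions = 10)
assign_partition <- function(kmers, num_partitions = 700L, salt = 0L) {
  num_partitions <- assert_scalar_int(num_partitions, "num_partitions")
  if (length(kmers) == 0L) return(integer(0))
  cpp_partition_of(as.character(kmers), num_partitions, as.numeric(salt))
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that sniffs the
#' format from the first byte (`>` for FASTA, `@` for FASTQ), transparently
#' handling gzip compression. FASTQ quality strings are ignored: the
#' method only uses presence/absence of k-mers.
#'
#' @param path Path to a FASTA/FASTQ file, optionally gzipped.
#' @return Character vector of uppercased read sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) {
    abort_kmst("kmst_empty_input_error", "file not found: %s", path)
  }
  con <- gzfile(path, "rb")
  first <- readChar(con, 1L, useBytes = TRUE)
  close(con)
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                abort_kmst("kmst_format_error",
                           "%s: not FASTA or FASTQ (starts with %s)",
                           path, deparse(first)))
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(seqs) == 0L) {
    abort_kmst("kmst_empty_input_error", "no sequences in %s", path)
  }
  toupper(as.character(seqs))
}
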