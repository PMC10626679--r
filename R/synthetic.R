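#' Configuration for the synthetic metagenome generator
#'
#' The generator emulates the statistical structure the source-tracking
#' method relies on: each environment has a pan-genome "pool" of sequence,
#' pools of related environments share a fraction of their content (as
#' oral and skin microbiomes share taxa in real data), each sample draws a
#' random subset of its environment's pool, and reads are sampled with
#' substitution errors. It does not attempt realistic taxonomic
#' composition, fragment-length or ancient-damage modelling.
#'
#' @param environments Environment names; defaults to
#'   [default_class_order()].
#' @param pool_length Bases per environment pan-genome (default 100000).
#' @param overlap Symmetric numeric matrix of pairwise shared fractions in
#'   `[0, 1]` (rows/cols = environments), or `NULL` for the default: 0.10
#'   between adjacent environments in `environments`, 0 elsewhere.
#' @param samples_per_env Pure-label samples per environment (default 5).
#' @param groups_per_env Pseudo-BioProjects per environment (default 2).
#' @param read_length Read length in bases (default 100).
#' @param coverage Expected fold-coverage of the sampled pool subset
#'   (default 5).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param sample_subset_fraction Fraction of the pool each sample draws
#'   (default 0.8), so two samples of one environment overlap but do not
#'   coincide.
#' @param seed Integer seed; mandatory, every downstream draw derives
#'   from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(environments = default_class_order(),
                       pool_length = 100000L,
                       overlap = NULL,
                       samples_per_env = 5L,
                       groups_per_env = 2L,
                       read_length = 100L,
                       coverage = 5,
                       error_rate = 0.005,
                       sample_subset_fraction = 0.8,
                       seed) {
  if (missing(seed)) {
    abort_kmst("kmst_config_error", "sim_config requires an explicit seed")
  }
  n_env <- length(environments)
  if (n_env < 1L || anyDuplicated(environments)) {
    abort_kmst("kmst_config_error", "environments must be distinct names")
  }
  pool_length <- assert_scalar_int(pool_length, "pool_length")
  read_length <- assert_scalar_int(read_length, "read_length")
  if (pool_length < read_length) {
    abort_kmst("kmst_config_error", "pool_length must be >= read_length")
  }
  if (is.null(overlap)) {
    overlap <- matrix(0, n_env, n_env,
                      dimnames = list(environments, environments))
    if (n_env > 1L) {
      for (i in seq_len(n_env - 1L)) {
        overlap[i, i + 1L] <- overlap[i + 1L, i] <- 0.10
      }
    }
  }
  overlap <- as.matrix(overlap)
  if (!all(dim(overlap) == n_env) || !isTRUE(all.equal(overlap, t(overlap)))) {
    abort_kmst("kmst_config_error",
               "overlap must be a symmetric %d x %d matrix", n_env, n_env)
  }
  dimnames(overlap) <- list(environments, environments)
  diag(overlap) <- 0
  if (any(overlap < 0 | overlap > 1)) {
    abort_kmst("kmst_config_error", "overlap fractions must lie in [0, 1]")
  }
  if (any(rowSums(overlap) > 1)) {
    abort_kmst("kmst_config_error",
               "overlap fractions for %s sum to more than 1",
               environments[which(rowSums(overlap) > 1)[1]])
  }
  if (error_rate < 0 || error_rate > 1 ||
      sample_subset_fraction <= 0 || sample_subset_fraction > 1) {
    abort_kmst("kmst_config_error", "rates/fractions must lie in [0, 1]")
  }
  if (coverage <= 0) {
    abort_kmst("kmst_config_error", "coverage must be positive")
  }
  structure(
    list(environments = environments, pool_length = pool_length,
         overlap = overlap,
         samples_per_env = assert_scalar_int(samples_per_env,
                                             "samples_per_env"),
         groups_per_env = assert_scalar_int(groups_per_env,
                                            "groups_per_env"),
         read_length = read_length, coverage = coverage,
         error_rate = error_rate,
         sample_subset_fraction = sample_subset_fraction,
         seed = assert_scalar_int(seed, "seed", min = 0L)),
    class = "sim_config"
  )
}

sanitize_id <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Generate environment pan-genome pools
#'
#' Each environment gets an i.i.d. uniform random DNA sequence of
#' `pool_length` bases; for every configured overlapping pair, a
#' contiguous block of the given fraction is copied from one pool into
#' the other, so the two environments share (approximately) that
#' fraction of their distinct k-mers. Copied blocks occupy disjoint
#' stretches within each pool. Deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return Named character vector, one pool sequence per environment.
#' @export
make_environment_pools <- function(config) {
  stopifnot(is(config, "sim_config"))
  envs <- config$environments
  L <- config$pool_length
  withr::with_seed(config$seed, {
    pools <- vapply(envs, function(e) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = "")
    }, character(1))
    cursor <- setNames(rep(1L, length(envs)), envs)
    for (i in seq_along(envs)) {
      for (j in seq_along(envs)) {
        if (j <= i) next
        f <- config$overlap[i, j]
        if (f <= 0) next
        len <- as.integer(round(f * L))
        a <- envs[i]; b <- envs[j]
        block <- substr(pools[[a]], cursor[a], cursor[a] + len - 1L)
        substr(pools[[b]], cursor[b], cursor[b] + len - 1L) <- block
        cursor[a] <- cursor[a] + len
        cursor[b] <- cursor[b] + len
      }
    }
    pools
  })
}

#' Simulate one metagenomic sample from weighted environment pools
#'
#' Draws a random contiguous subset (`sample_subset_fraction`) of each
#' contributing environment's pool, samples reads uniformly from the
#' weighted union to the target coverage (the read count is the
#' deterministic `round(coverage * effective_length / read_length)`),
#' and applies per-base substitution errors at `error_rate`. Read ids
#' encode the originating environment for debugging.
#'
#' @param pools Named pool sequences from [make_environment_pools()].
#' @param weights Named non-negative mixture weights over environments,
#'   summing to 1.
#' @param config A `sim_config`.
#' @param sample_id,group Identifiers recorded in the truth record.
#' @param seed Seed for this sample's draws (default: the config seed).
#' @return List with `sample_id`, `reads`, `read_ids`, and `truth`
#'   (list of `sample_id`, `weights` over all environments, `group`).
#' @export
simulate_sample <- function(pools, weights, config, sample_id,
                            group = "g1", seed = config$seed) {
  stopifnot(is(config, "sim_config"))
  envs <- config$environments
  w <- setNames(rep(0, length(envs)), envs)
  w[names(weights)] <- weights
  if (any(w < 0) || sum(w) == 0) {
    abort_kmst("kmst_config_error",
               "mixture weights must be non-negative and not all zero")
  }
  w <- w / sum(w)
  contrib <- envs[w > 0]
  rl <- config$read_length
  withr::with_seed(seed, {
    subsets <- vapply(contrib, function(e) {
      L <- nchar(pools[[e]])
      subL <- max(rl, as.integer(round(config$sample_subset_fraction * L)))
      start <- sample.int(L - subL + 1L, 1L)
      substr(pools[[e]], start, start + subL - 1L)
    }, character(1))
    effective_length <- sum(nchar(subsets))
    n_reads <- as.integer(round(config$coverage * effective_length / rl))
    origin <- sample(contrib, n_reads, replace = TRUE, prob = w[contrib])
    starts <- vapply(nchar(subsets)[origin] - rl + 1L, sample.int,
                     integer(1), size = 1L)
    reads <- substring(subsets[origin], starts, starts + rl - 1L)
    if (config$error_rate > 0) {
      total <- n_reads * rl
      n_err <- stats::rbinom(1L, total, config$error_rate)
      if (n_err > 0) {
        pos <- sample.int(total, n_err)
        ridx <- (pos - 1L) %/% rl + 1L
        off <- (pos - 1L) %% rl + 1L
        for (m in seq_len(n_err)) {
          old <- substr(reads[ridx[m]], off[m], off[m])
          substr(reads[ridx[m]], off[m], off[m]) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
    }
    list(sample_id = sample_id,
         reads = unname(reads),
         read_ids = sprintf("%s_read%06d_%s", sample_id,
                            seq_len(n_reads), sanitize_id(origin)),
         truth = list(sample_id = sample_id, weights = w, group = group))
  })
}

#' Write reads as FASTQ
#'
#' Constant quality `"I"`; gzip output when `path` ends in `.gz`.
#'
#' @param sample A list with `reads` and `read_ids` (as returned by
#'   [simulate_sample()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sample, path) {
  qual <- strrep("I", nchar(sample$reads))
  lines <- as.vector(rbind(paste0("@", sample$read_ids), sample$reads,
                           "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Generate a labelled synthetic metagenome collection
#'
#' Simulates `samples_per_env` pure-label samples per environment,
#' assigned round-robin to `groups_per_env` pseudo-BioProjects per
#' environment, plus optional mixture sinks with known weights. By
#' default everything stays in memory; with `out_dir` the FASTQ files,
#' the `samples.tsv` metadata consumed by the matrix builder, and a
#' `truth.tsv` with the mixing weights are written to disk.
#'
#' @param config A `sim_config`.
#' @param mixtures Optional named list of mixture weight vectors (names =
#'   sink ids; each vector named by environment) appended as sinks.
#' @param out_dir Optional output directory.
#' @param force Overwrite a non-empty `out_dir`?
#' @return List with `config`, `pools`, `samples` (list of simulated
#'   pure samples), `metadata` (data.frame for the matrix builder),
#'   `sinks` (list of simulated mixture sinks), and `truth` (data.frame
#'   of mixing weights for every sample and sink).
#' @export
generate_collection <- function(config, mixtures = NULL, out_dir = NULL,
                                force = FALSE) {
  stopifnot(is(config, "sim_config"))
  pools <- make_environment_pools(config)
  envs <- config$environments
  n_pure <- length(envs) * config$samples_per_env
  n_total <- n_pure + length(mixtures)
  seeds <- withr::with_seed(config$seed + 1L,
                            sample.int(.Machine$integer.max - 1L, n_total))
  samples <- list()
  meta <- list()
  idx <- 0L
  for (e in envs) {
    for (s in seq_len(config$samples_per_env)) {
      idx <- idx + 1L
      sid <- sprintf("%s_s%02d", sanitize_id(e), s)
      grp <- sprintf("%s_g%d", sanitize_id(e),
                     (s - 1L) %% config$groups_per_env + 1L)
      samples[[sid]] <- simulate_sample(pools, setNames(1, e), config,
                                        sid, grp, seed = seeds[idx])
      meta[[sid]] <- data.frame(sample_id = sid, label = e, group = grp,
                                stringsAsFactors = FALSE)
    }
  }
  sinks <- list()
  for (nm in names(mixtures)) {
    idx <- idx + 1L
    sinks[[nm]] <- simulate_sample(pools, mixtures[[nm]], config, nm,
                                   group = "sink", seed = seeds[idx])
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  truth <- do.call(rbind, lapply(c(samples, sinks), function(sm) {
    df <- data.frame(sample_id = sm$truth$sample_id,
                     group = sm$truth$group, stringsAsFactors = FALSE)
    for (e in envs) df[[sanitize_id(e)]] <- unname(sm$truth$weights[e])
    df
  }))
  rownames(truth) <- NULL

  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
      abort_kmst("kmst_file_exists_error",
                 "output directory %s is not empty (use force = TRUE)",
                 out_dir)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- vapply(c(samples, sinks), function(sm) {
      p <- file.path(out_dir, paste0(sm$sample_id, ".fastq"))
      write_fastq(sm, p)
      p
    }, character(1))
    metadata$reads_path <- unname(paths[metadata$sample_id])
    write.table(metadata, file.path(out_dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(config = config, pools = pools, samples = samples,
       metadata = metadata, sinks = sinks, truth = truth,
       out_dir = out_dir)
}

#' Extract per-sample k-mer sets from a simulated collection
#'
#' Convenience bridge from the generator to the matrix builder: applies
#' [extract_present_kmers()] to every pure sample of a collection.
#'
#' @param collection Result of [generate_collection()].
#' @param k K-mer length (default 31).
#' @param min_abundance Within-sample abundance filter (default 2).
#' @return Named list of `sample_kmer_set` objects.
#' @export
collection_kmer_sets <- function(collection, k = 31L, min_abundance = 2L) {
  lapply(collection$samples, function(sm) {
    extract_present_kmers(sm$reads, k = k, min_abundance = min_abundance,
                          sample_id = sm$sample_id)
  })
}
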