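# Shared synthetic collections, memoized so several test files can reuse
# one simulation instead of regenerating it.

.kmst_test_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .kmst_test_cache)) {
    assign(key, force(expr), envir = .kmst_test_cache)
  }
  get(key, envir = .kmst_test_cache)
}

no_overlap <- function(n = 4) matrix(0, n, n)

# Disjoint-pool toy collection: 4 environments x 2 samples, no read
# errors, so within-class k-mer sharing is high and between-class sharing
# is nil -- label recovery must be exact.
disjoint_toy_collection <- function() {
  memoize("disjoint_toy", {
    cfg <- sim_config(samples_per_env = 2, groups_per_env = 1,
                      overlap = no_overlap(), error_rate = 0,
                      pool_length = 20000L, coverage = 4, seed = 101)
    col <- generate_collection(cfg)
    ks <- collection_kmer_sets(col)
    bm <- build_source_matrix(ks, col$metadata, min_recurrence = 2)
    c(col, bm)
  })
}

# Group-structured collection for cross-validation: 4 environments x 10
# samples spread over 5 groups per environment (20 groups total).
grouped_collection <- function() {
  memoize("grouped", {
    cfg <- sim_config(samples_per_env = 10, groups_per_env = 5,
                      overlap = no_overlap(), error_rate = 0,
                      pool_length = 8000L, coverage = 4, seed = 202)
    col <- generate_collection(cfg)
    ks <- collection_kmer_sets(col)
    bm <- build_source_matrix(ks, col$metadata, min_recurrence = 2)
    c(col, bm)
  })
}

# Perfectly decomposable metadata instance: 10 groups of 4 samples, one
# sample per class per group.
decomposable_metadata <- function() {
  classes <- default_class_order()
  do.call(rbind, lapply(1:10, function(g) {
    data.frame(sample_id = sprintf("g%02d_%s", g, sub("/", "_", classes)),
               label = classes, group = sprintf("g%02d", g),
               stringsAsFactors = FALSE)
  }))
}
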