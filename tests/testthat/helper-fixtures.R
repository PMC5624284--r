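# Shared fixtures: cohorts are cached per test run so the generator executes
# once per configuration.

.fixture_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed = 42, ...) {
  key <- paste("cohort", seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_cohort(cohort_config(seed = seed, ...))
  }
  .fixture_cache[[key]]
}

null_cohort <- function(seed) {
  simulate_cohort(cohort_config(seed = seed, signature_fold = 1,
                                ko_log_effect = 0, covariate_strength = 0,
                                ptr_effect = 0, include_coverage = FALSE))
}

truth_labels <- function(cohort) {
  comp <- cohort$truth$component
  lab <- match(comp, sort(unique(comp)))
  names(lab) <- names(comp)
  lab
}

truth_scheme <- function(cohort) {
  default_scheme(cohort$metadata, truth_labels(cohort))
}

# Small deterministic count table.
toy_counts <- function(n = 6, t = 4, seed = 1, depth = 100) {
  set.seed(seed)
  m <- matrix(rpois(n * t, depth / t), n, t)
  m[m == 0] <- 1
  rownames(m) <- paste0("S", seq_len(n))
  colnames(m) <- paste0("F", seq_len(t))
  abundance_table(m, mode = "counts")
}

# Relative table from a plain matrix.
rel_table <- function(m) {
  rownames(m) <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% paste0("F", seq_len(ncol(m)))
  abundance_table(m / rowSums(m), mode = "relative")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
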