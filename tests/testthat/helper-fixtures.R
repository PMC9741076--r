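# Shared fixtures, all generated in code.

# Small random spectra set on an arbitrary uniform grid.
random_spectra <- function(n = 5, p = 50, seed = 1, start = 600, step = 2) {
  withr::with_seed(seed, {
    spectra_set(seq(start, by = step, length.out = p),
                matrix(rnorm(n * p), n, p),
                sprintf("S%02d", seq_len(n)))
  })
}

# A composition vector with all nine acids named (defaults zero).
composition_vec <- function(...) {
  v <- stats::setNames(numeric(length(fa_names())), fa_names())
  args <- list(...)
  v[names(args)] <- unlist(args)
  v
}

# One default-condition pipeline run, cached so several test files can
# inspect the same registry without refitting.
.fixture_env <- new.env(parent = emptyenv())
pipeline_fixture <- function(seed = 7) {
  key <- paste0("run", seed)
  if (is.null(.fixture_env[[key]])) {
    ds <- generate_dataset(synthetic_config(n_samples = 50, seed = seed))
    reg <- suppressWarnings(
      train_all_targets(ds$spectra, ds$profile, ds$clinical,
                        pipeline_config(seed = seed)))
    .fixture_env[[key]] <- list(ds = ds, reg = reg)
  }
  .fixture_env[[key]]
}
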