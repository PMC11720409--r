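# Small in-code fixtures shared across test files.

make_matrix <- function(values, scale = "LINEAR_RFU", platform = "SOMA_A",
                        reagents = NULL, samples = NULL) {
  if (is.null(reagents)) reagents <- sprintf("r%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(reagents, samples)
  expression_matrix(values, scale, platform)
}

random_zscored <- function(n_reagents, n_samples, seed = 1,
                           platform = "SOMA_A") {
  with_seed(seed, {
    v <- matrix(rnorm(n_reagents * n_samples), nrow = n_reagents)
    m <- make_matrix(2^v * 1000, "LINEAR_RFU", platform)
    log2_zscale(m)
  })
}

# A small full study used by several files; cached per session.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 120, n_proteins = 150,
                        n_soma_reagents = 170, n_olink_reagents = 60,
                        plate_count = 6, seed = 202L)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# Restrict an assay matrix to the study (non-calibrator) samples.
study_only <- function(m, cohort) {
  expression_matrix(m$values[, cohort$sample_id, drop = FALSE],
                    m$scale, m$platform)
}
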