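# Shared fixtures: small acquisition layouts that keep the unit tests fast
# while preserving the statistical structure of the full campaign.

tiny_cfg <- function(metal = "Cr6", seed = 1L, ...) {
  generator_config(metal = metal, map_shape = c(3L, 3L), n_maps_per_class = 1L,
                   n_control_surfaces = 2L,
                   wavenumbers = seq(300, 1800, by = 5), seed = seed, ...)
}

# Random score-space features for classifier/SMOTE tests: well-separated
# Gaussian blobs, one per class, in `p` dimensions.
blob_features <- function(n_per_class, n_classes, p = 5, sep = 6, sd = 1,
                          seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_classes) - 1L, function(k) {
      S <- matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p)
      S[, 1] <- S[, 1] + k * sep
      colnames(S) <- paste0("PC", seq_len(p))
      dplyr::bind_cols(
        tibble::tibble(spectrum_id = sprintf("c%d_%04d", k, seq_len(n_per_class)),
                       class_index = k,
                       concentration_molar = if (k == 0) 0 else 10^(k - 13),
                       synthetic = FALSE),
        tibble::as_tibble(S)
      )
    })
    dplyr::bind_rows(rows)
  })
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
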