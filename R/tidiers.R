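#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted pipeline objects
#'
#' `tidy()` returns the per-class (or per-epoch) detail of a result object
#' as a tibble; `glance()` returns a one-row summary.
#'
#' @param x A `sers_eval`, `sers_lod`, `sers_limits`, `sers_cnn` or
#'   `sers_pca` object.
#' @param ... Unused.
#' @return A tibble.
#' @name sersdecoder-tidiers
NULL

#' @rdname sersdecoder-tidiers
#' @export
tidy.sers_eval <- function(x, ...) x$metrics

#' @rdname sersdecoder-tidiers
#' @export
glance.sers_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n = sum(x$confusion),
                 n_classes = nrow(x$confusion))
}

#' @rdname sersdecoder-tidiers
#' @export
tidy.sers_lod <- function(x, ...) x$per_class

#' @rdname sersdecoder-tidiers
#' @export
glance.sers_lod <- function(x, ...) {
  tibble::tibble(detected = x$detected, lod = x$lod, lod_class = x$lod_class,
                 threshold = x$threshold, rule = x$rule)
}

#' @rdname sersdecoder-tidiers
#' @export
tidy.sers_limits <- function(x, ...) x$intervals

#' @rdname sersdecoder-tidiers
#' @export
glance.sers_limits <- function(x, ...) {
  tibble::tibble(lob_lower = x$lob[1], lob_upper = x$lob[2], lod = x$lod,
                 loq = x$loq, dynamic_range_low = x$dynamic_range[1],
                 dynamic_range_high = x$dynamic_range[2])
}

#' @rdname sersdecoder-tidiers
#' @export
tidy.sers_cnn <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = numeric(), train_loss = numeric(),
                                val_loss = numeric())
}

#' @rdname sersdecoder-tidiers
#' @export
glance.sers_cnn <- function(x, ...) {
  h <- tidy(x)
  tibble::tibble(epochs_run = nrow(h),
                 final_train_loss = if (nrow(h)) h$train_loss[nrow(h)] else NA_real_,
                 final_val_loss = if (nrow(h)) h$val_loss[nrow(h)] else NA_real_,
                 head = x$head)
}

#' @rdname sersdecoder-tidiers
#' @export
tidy.sers_pca <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 explained_variance_ratio = x$explained_variance_ratio,
                 cumulative = cumsum(x$explained_variance_ratio))
}

#' @export
print.sers_lod <- function(x, ...) {
  cat("Classification-based limit of detection\n")
  if (x$detected) {
    cat(sprintf("  LOD: %.3g mol/L (class %d), rule '%s' at %.0f%%\n",
                x$lod, x$lod_class, x$rule, 100 * x$threshold))
  } else {
    cat("  Not detected at any class under the rule.\n")
  }
  invisible(x)
}

#' @export
print.sers_limits <- function(x, ...) {
  cat("Empirical detection limits (prediction scale LOB, molar LOD/LOQ)\n")
  cat(sprintf("  LOB: [%.3f, %.3f]\n", x$lob[1], x$lob[2]))
  cat(sprintf("  LOD: %s\n", format(x$lod)))
  cat(sprintf("  LOQ: %s\n", format(x$loq)))
  cat(sprintf("  Dynamic range: %s - %s mol/L\n",
              format(x$dynamic_range[1]), format(x$dynamic_range[2])))
  invisible(x)
}

#' @export
print.sers_verdict <- function(x, ...) {
  cat(sprintf("Water-sample verdict: %s the %.3g mol/L limit (%.0f%% of %d spectra vote below)\n",
              toupper(x$verdict), x$who_limit, 100 * x$fraction_below, x$n_spectra))
  invisible(x)
}

#' Benchmark performance of the full-scale acquisition campaign
#'
#' Reference values achieved on the complete laboratory dataset (about
#' 20,000 measured spectra per metal; archived at
#' doi:10.5281/zenodo.7109184). They are replication targets for users who
#' download that archive and run this pipeline on it; the synthetic
#' generator shipped here emulates the acquisition layout but not the
#' biological sample, so these numbers are not expected from synthetic
#' runs.
#'
#' @return Tibble with columns `quantity`, `metal`, `value`, `unit`.
#' @export
reference_performance <- function() {
  tibble::tribble(
    ~quantity,                    ~metal, ~value,   ~unit,
    "svm_min_class_metric",       "both", 0.97,     "fraction",
    "metal_type_accuracy",        "both", 0.988,    "fraction",
    "cnn_mse_balanced",           "As3",  0.09,     "squared class index",
    "cnn_mse_balanced",           "Cr6",  0.11,     "squared class index",
    "cnn_r2_balanced",            "As3",  0.99,     "fraction",
    "cnn_r2_balanced",            "Cr6",  0.99,     "fraction",
    "lod",                        "Cr6",  6.8e-12,  "mol/L",
    "lod",                        "As3",  0.5e-12,  "mol/L",
    "loq",                        "Cr6",  68e-12,   "mol/L",
    "loq",                        "As3",  5e-12,    "mol/L",
    "transfer_tap_accuracy",      "As3",  0.99,     "fraction",
    "transfer_wastewater_accuracy", "As3", 0.92,    "fraction"
  )
}
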