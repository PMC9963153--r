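#' Preprocessing parameters
#'
#' Defaults follow common chemometric practice for Raman baselines:
#' asymmetric-least-squares smoothness `lambda = 1e5`, asymmetry `p = 0.01`,
#' 10 reweighting iterations; Savitzky-Golay window 11 points, polynomial
#' order 3; silicon internal standard located as the maximum inside
#' 520 +/- 15 cm^-1 (a window, not a fixed index, to tolerate small
#' calibration shifts).
#'
#' @param asls_lambda Baseline smoothness weight (> 0).
#' @param asls_p Asymmetry in (0, 1); small values hug the lower envelope.
#' @param asls_iters Reweighting iterations (>= 1).
#' @param savgol_window Odd window length >= 3.
#' @param savgol_order Polynomial order < window.
#' @param si_center Internal-standard position, cm^-1.
#' @param si_halfwidth Search half-window, cm^-1.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(asls_lambda = 1e5, asls_p = 0.01, asls_iters = 10L,
                              savgol_window = 11L, savgol_order = 3L,
                              si_center = 520, si_halfwidth = 15) {
  assert_scalar_number(asls_lambda, "asls_lambda", min = 0, strict = TRUE)
  if (asls_p <= 0 || asls_p >= 1) abort("`asls_p` must lie in (0, 1).")
  if (asls_iters < 1L) abort("`asls_iters` must be >= 1.")
  if (savgol_window < 3L || savgol_window %% 2L == 0L) {
    abort("`savgol_window` must be an odd integer >= 3.")
  }
  if (savgol_order >= savgol_window) abort("`savgol_order` must be < `savgol_window`.")
  structure(list(asls_lambda = asls_lambda, asls_p = asls_p,
                 asls_iters = as.integer(asls_iters),
                 savgol_window = as.integer(savgol_window),
                 savgol_order = as.integer(savgol_order),
                 si_center = si_center, si_halfwidth = si_halfwidth),
            class = "preprocess_params")
}

#' Asymmetric-least-squares baseline of one trace
#'
#' Finds the baseline `z` minimizing
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)` with
#' asymmetric weights `w = p` where `y > z` and `1 - p` otherwise,
#' re-estimated for `asls_iters` iterations from the previous `z`
#' (all-ones weights on the first pass). The banded normal equations are
#' solved with a sparse Cholesky factorization.
#'
#' @param y Numeric intensity trace (length >= 3, finite).
#' @param params A [preprocess_params()].
#' @return List with `corrected` (`y - baseline`) and `baseline`.
#' @export
baseline_asls <- function(y, params = preprocess_params()) {
  if (any(!is.finite(y))) abort("Intensities must be finite for baseline correction.")
  n <- length(y)
  if (n < 3L) abort("Need at least 3 points for a second-difference penalty.")
  DtD <- asls_penalty(n) * params$asls_lambda
  w <- rep(1, n)
  z <- y
  for (it in seq_len(params$asls_iters)) {
    A <- DtD + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    w <- ifelse(y > z, params$asls_p, 1 - params$asls_p)
  }
  list(corrected = y - z, baseline = z)
}

# Cached D'D for the second-difference penalty (n x n, pentadiagonal).
asls_penalty_cache <- new.env(parent = emptyenv())
asls_penalty <- function(n) {
  key <- as.character(n)
  if (is.null(asls_penalty_cache[[key]])) {
    D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                            diagonals = list(rep(1, n - 2L), rep(-2, n - 2L), rep(1, n - 2L)))
    asls_penalty_cache[[key]] <- Matrix::crossprod(D)
  }
  asls_penalty_cache[[key]]
}

#' Savitzky-Golay smoothing of one trace
#'
#' Local least-squares polynomial smoothing; interior points take the centre
#' value of the windowed fit and the `(window-1)/2` points at each end are
#' evaluated from the first/last full-window fits (polynomial extrapolation
#' of the edge fits).
#'
#' @param y Numeric trace with `length(y) >= savgol_window`.
#' @param params A [preprocess_params()].
#' @return Smoothed numeric trace of the same length.
#' @export
smooth_savgol <- function(y, params = preprocess_params()) {
  if (params$savgol_window > length(y)) {
    abort("`savgol_window` exceeds the spectrum length.")
  }
  as.numeric(signal::sgolayfilt(y, p = params$savgol_order, n = params$savgol_window))
}

#' Silicon internal-standard normalization of one trace
#'
#' Divides the whole trace by its maximum inside the silicon window
#' `si_center +/- si_halfwidth`, so the substrate phonon line is set to 1
#' and multiplicative surface/replicate gains cancel.
#'
#' @param y Numeric trace.
#' @param wn Wavenumber grid of `y`.
#' @param params A [preprocess_params()].
#' @return Normalized trace with window maximum exactly 1.
#' @export
normalize_silicon <- function(y, wn, params = preprocess_params()) {
  idx <- which(abs(wn - params$si_center) <= params$si_halfwidth)
  if (!length(idx)) abort("Silicon window does not intersect the wavenumber grid.")
  ref <- max(y[idx])
  if (!is.finite(ref) || ref <= 0) {
    abort("Silicon window maximum is not positive; cannot normalize this spectrum.")
  }
  y / ref
}

#' Preprocess every spectrum of a dataset
#'
#' Applies, in order, asymmetric-least-squares baseline correction,
#' Savitzky-Golay smoothing, and silicon internal-standard normalization.
#' The order is deliberate: normalizing last leaves the silicon window
#' maximum at exactly 1. The chain is not idempotent (a second baseline
#' pass removes real signal), so re-applying it to an already-processed
#' dataset raises a warning via the recorded provenance.
#'
#' @param ds A `sers_dataset`.
#' @param params A [preprocess_params()].
#' @return A `sers_dataset` with the same grid, row order and metadata.
#' @export
preprocess_dataset <- function(ds, params = preprocess_params()) {
  if (isTRUE(attr(ds, "preprocessed"))) {
    warn("Dataset appears to be preprocessed already; re-applying the chain changes the data.")
  }
  wn <- wavenumbers(ds)
  if (nrow(ds) > 0L) {
    mat <- intensity_matrix(ds)
    for (i in seq_len(nrow(mat))) {
      y <- tryCatch({
        y <- baseline_asls(mat[i, ], params)$corrected
        y <- smooth_savgol(y, params)
        normalize_silicon(y, wn, params)
      }, error = function(e) {
        abort(sprintf("Preprocessing failed for spectrum '%s': %s",
                      ds$spectrum_id[i], conditionMessage(e)))
      })
      mat[i, ] <- y
    }
    ds <- set_intensities(ds, mat)
  }
  attr(ds, "preprocessed") <- TRUE
  attr(ds, "preprocess_params") <- params
  ds
}
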