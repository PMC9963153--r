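#' SERS spectral datasets
#'
#' A `sers_dataset` is a tibble with one row per spectrum. Metadata columns
#' describe provenance (`metal`, `salt`, `concentration_molar`, `class_index`,
#' `surface_id`, `replicate_id`, `map_id`, `water_matrix`) and the `intensity`
#' list-column holds one numeric trace per row. All spectra share a single
#' wavenumber grid stored as the `wavenumbers` attribute; the grid must be
#' strictly increasing with uniform spacing (relative tolerance 1e-6).
#'
#' `class_index` follows the decade-ladder convention: 0 for unexposed
#' controls, and `1 + log10(c / c_min)` (rounded) for exposed classes, where
#' `c_min` is the lowest nonzero concentration in the experiment.
#'
#' @param meta Data frame of per-spectrum metadata; missing columns are filled
#'   with defaults (control sample in DI water).
#' @param intensity List of numeric vectors (or an n x p matrix), one trace
#'   per row of `meta`, each of length `length(wavenumbers)`.
#' @param wavenumbers Numeric grid in cm^-1.
#' @return A tibble of class `sers_dataset`.
#' @export
#' @examples
#' ds <- sers_dataset(
#'   meta = data.frame(class_index = 0L),
#'   intensity = list(c(1, 2, 3)),
#'   wavenumbers = c(400, 401, 402)
#' )
#' wavenumbers(ds)
sers_dataset <- function(meta, intensity, wavenumbers) {
  if (is.matrix(intensity)) {
    intensity <- lapply(seq_len(nrow(intensity)), function(i) intensity[i, ])
  }
  meta <- tibble::as_tibble(meta)
  n <- max(nrow(meta), length(intensity))
  if (nrow(meta) == 0L && length(intensity) > 0L) {
    meta <- tibble::tibble(.rows = length(intensity))
  }
  defaults <- list(
    spectrum_id = sprintf("s%06d", seq_len(n)),
    metal = "none", salt = "none", concentration_molar = 0,
    class_index = 0L, surface_id = "S1", replicate_id = "R1",
    map_id = "M1", water_matrix = "DI"
  )
  for (nm in names(defaults)) {
    if (is.null(meta[[nm]])) meta[[nm]] <- if (n) rep_len(defaults[[nm]], n) else defaults[[nm]][0]
  }
  meta <- meta[, names(defaults)]
  meta$intensity <- intensity
  validate_grid(wavenumbers)
  bad <- which(vapply(intensity, length, 1L) != length(wavenumbers))
  if (length(bad)) {
    abort(sprintf("Spectrum %d has %d points but the grid has %d.",
                  bad[1], length(intensity[[bad[1]]]), length(wavenumbers)))
  }
  if (any(meta$concentration_molar < 0)) abort("Concentrations must be nonnegative.")
  if (any((meta$class_index == 0L) != (meta$concentration_molar == 0))) {
    abort("`class_index` must be 0 exactly for zero-concentration controls.")
  }
  new_sers_dataset(meta, wavenumbers)
}

new_sers_dataset <- function(df, wavenumbers) {
  structure(df,
    wavenumbers = as.numeric(wavenumbers),
    class = c("sers_dataset", class(tibble::tibble())))
}

validate_grid <- function(wn) {
  if (length(wn) < 1L || any(!is.finite(wn))) abort("Wavenumber grid must be finite and nonempty.")
  if (length(wn) > 1L) {
    d <- diff(wn)
    if (any(d <= 0)) abort("Wavenumber grid must be strictly increasing.")
    if ((max(d) - min(d)) > 1e-6 * max(abs(d))) {
      abort("Wavenumber grid spacing must be uniform (relative tolerance 1e-6).")
    }
  }
  invisible(wn)
}

#' @rdname sers_dataset
#' @param ds A `sers_dataset`.
#' @export
wavenumbers <- function(ds) {
  wn <- attr(ds, "wavenumbers")
  if (is.null(wn)) abort("Object carries no `wavenumbers` attribute; is it a `sers_dataset`?")
  wn
}

#' @rdname sers_dataset
#' @export
intensity_matrix <- function(ds) {
  p <- length(wavenumbers(ds))
  if (nrow(ds) == 0L) return(matrix(numeric(), 0L, p))
  matrix(unlist(ds$intensity, use.names = FALSE), nrow = nrow(ds), ncol = p, byrow = TRUE)
}

# Replace all intensity traces from a matrix, keeping metadata and grid.
set_intensities <- function(ds, mat) {
  stopifnot(nrow(mat) == nrow(ds), ncol(mat) == length(wavenumbers(ds)))
  ds$intensity <- lapply(seq_len(nrow(mat)), function(i) mat[i, ])
  ds
}

#' Class and surface tallies of a dataset
#'
#' @param ds A `sers_dataset`.
#' @param by `"class"` (default), `"surface"`, or both.
#' @return A tibble of counts; with both groupings, a list of two tibbles.
#'   Counts always sum to `nrow(ds)`.
#' @export
dataset_summary <- function(ds, by = "class") {
  count_by <- function(var) {
    dplyr::count(tibble::as_tibble(ds)[var], .data[[var]], name = "n")
  }
  tabs <- list(class = "class_index", surface = "surface_id")
  if (length(by) == 1L) count_by(tabs[[by]]) else lapply(tabs[by], count_by)
}

#' Read a spectral table
#'
#' Supports the two plain-text dialects common for instrument exports: a
#' two-column ASCII table (wavenumber, intensity; whitespace- or
#' comma-separated) holding one spectrum, and a CSV matrix whose header row
#' is the wavenumber grid and whose data rows are spectra. Monotone
#' *decreasing* grids (a common export convention) are re-sorted ascending
#' with intensities reversed in lockstep; any other non-monotone grid is an
#' error.
#'
#' @param path File path.
#' @param dialect `"two_column_ascii"` or `"csv_matrix"`.
#' @param meta Optional metadata data frame recycled across spectra.
#' @return A `sers_dataset` (one row for the two-column dialect).
#' @export
read_spectrum_table <- function(path, dialect = c("two_column_ascii", "csv_matrix"),
                                meta = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "two_column_ascii") {
    rows <- parse_numeric_rows(lines, path, min_cols = 2L)
    wn <- vapply(rows, `[`, 1, 1L)
    y <- vapply(rows, `[`, 1, 2L)
    ord <- orient_grid(wn)
    out <- sers_dataset(meta %||% tibble::tibble(.rows = 1L),
                        list(y[ord]), wn[ord])
  } else {
    rows <- parse_numeric_rows(lines, path, min_cols = 2L)
    wn <- rows[[1]]
    mat <- do.call(rbind, rows[-1])
    if (ncol(mat) != length(wn)) {
      abort(sprintf("Row length %d does not match header length %d in %s.",
                    ncol(mat), length(wn), path))
    }
    ord <- orient_grid(wn)
    out <- sers_dataset(meta %||% tibble::tibble(.rows = nrow(mat)),
                        mat[, ord, drop = FALSE], wn[ord])
  }
  out
}

# Parse delimited numeric lines; ragged or non-numeric input errors with the
# offending (1-based, non-blank) line.
parse_numeric_rows <- function(lines, path, min_cols = 2L) {
  fields <- strsplit(trimws(lines), "[,[:space:]]+")
  rows <- vector("list", length(fields))
  width <- NULL
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v)) {
      abort(sprintf("Non-numeric value on line %d of %s: '%s'",
                    i, path, fields[[i]][which(is.na(v))[1]]))
    }
    if (length(v) < min_cols) abort(sprintf("Line %d of %s has fewer than %d columns.", i, path, min_cols))
    if (is.null(width)) width <- length(v)
    else if (length(v) != width && i > 2L) {
      abort(sprintf("Ragged row on line %d of %s: %d columns, expected %d.",
                    i, path, length(v), width))
    }
    rows[[i]] <- v
  }
  rows
}

orient_grid <- function(wn) {
  if (length(wn) > 1L && all(diff(wn) < 0)) rev(seq_along(wn)) else seq_along(wn)
}

#' Write and re-read a dataset directory
#'
#' `write_dataset()` writes one two-column ASCII table per spectrum plus a
#' TSV manifest listing every metadata field and relative file path, ordered
#' deterministically by (class_index, surface_id, map_id, spectrum_id) so two
#' writes of the same dataset are byte-identical. Concentrations are
#' serialized in mol/L scientific notation. `read_dataset()` inverts it.
#'
#' @param ds A nonempty `sers_dataset`.
#' @param dir Output directory (created if needed).
#' @return `write_dataset()` returns the manifest path invisibly;
#'   `read_dataset()` returns a `sers_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  if (nrow(ds) == 0L) abort("Refusing to write an empty dataset.")
  dir.create(file.path(dir, "spectra"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory %s", dir))
  ord <- order(ds$class_index, ds$surface_id, ds$map_id, ds$spectrum_id)
  ds <- ds[ord, ]
  wn <- wavenumbers(ds)
  files <- file.path("spectra", paste0(ds$spectrum_id, ".txt"))
  for (i in seq_len(nrow(ds))) {
    writeLines(sprintf("%.10e %.10e", wn, ds$intensity[[i]]), file.path(dir, files[i]))
  }
  man <- tibble::as_tibble(ds)[, c("spectrum_id", "metal", "salt", "concentration_molar",
                                   "class_index", "surface_id", "replicate_id",
                                   "map_id", "water_matrix")]
  man$concentration_molar <- sprintf("%.10e", man$concentration_molar)
  man$file <- files
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest)) abort(sprintf("No manifest.tsv under %s", dir))
  man <- utils::read.table(manifest, sep = "\t", header = TRUE,
                           colClasses = "character")
  man$concentration_molar <- as.numeric(man$concentration_molar)
  man$class_index <- as.integer(man$class_index)
  wn <- NULL
  ints <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    one <- read_spectrum_table(file.path(dir, man$file[i]))
    if (is.null(wn)) wn <- wavenumbers(one)
    ints[[i]] <- one$intensity[[1]]
  }
  sers_dataset(man[, setdiff(names(man), "file")], ints, wn)
}

# Row/column subsetting keeps the grid and provenance attributes.
#' @export
`[.sers_dataset` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("wavenumbers", "preprocessed", "preprocess_params")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- class(x)
  }
  out
}

#' @export
tbl_sum.sers_dataset <- function(x, ...) {
  wn <- attr(x, "wavenumbers")
  c("SERS dataset" = sprintf("%d spectra x %d points (%g-%g cm^-1)",
                             nrow(x), length(wn), min(wn), max(wn)))
}
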