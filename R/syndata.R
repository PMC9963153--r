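#' Spectral peak specification with a Hill dose-response
#'
#' Each metabolite band is a Lorentzian line whose amplitude follows a Hill
#' dose-response in the exposure concentration:
#' `amp(c) = base_amplitude * (1 + direction * max_fold_change * c^h / (K^h + c^h))`,
#' clipped at zero. `hill_K` is the half-effect concentration (mol/L) and
#' `hill_h` the Hill slope; small slopes stretch the response over several
#' decades, which is what makes a decade ladder resolvable.
#'
#' @param center Band position, cm^-1.
#' @param width Full width at half maximum, cm^-1 (> 0).
#' @param base_amplitude Unexposed amplitude, arbitrary intensity units.
#' @param response_direction `+1` (up-regulated) or `-1` (down-regulated).
#' @param hill_K Half-effect concentration, mol/L (> 0).
#' @param hill_h Hill slope (> 0).
#' @param max_fold_change Saturating fractional change (>= 0).
#' @return A list of class `peak_spec`.
#' @export
peak_spec <- function(center, width, base_amplitude, response_direction = 1,
                      hill_K = 1e-9, hill_h = 1, max_fold_change = 0) {
  assert_scalar_number(width, "width", min = 0, strict = TRUE)
  assert_scalar_number(hill_K, "hill_K", min = 0, strict = TRUE)
  assert_scalar_number(hill_h, "hill_h", min = 0, strict = TRUE)
  assert_scalar_number(max_fold_change, "max_fold_change", min = 0)
  if (!response_direction %in% c(-1, 1)) abort("`response_direction` must be +1 or -1.")
  structure(list(center = center, width = width, base_amplitude = base_amplitude,
                 response_direction = response_direction, hill_K = hill_K,
                 hill_h = hill_h, max_fold_change = max_fold_change),
            class = "peak_spec")
}

#' Band amplitude at a given exposure concentration
#'
#' @param c Concentration, mol/L (vectorised, >= 0).
#' @param pk A [peak_spec()].
#' @return Amplitude in the peak's intensity units; monotone in `c`,
#'   clipped at zero.
#' @export
#' @examples
#' pk <- peak_spec(730, 16, 60, +1, hill_K = 1e-9, hill_h = 1, max_fold_change = 1.5)
#' dose_response(0, pk)     # base amplitude
#' dose_response(1e-9, pk)  # half of the saturating change
dose_response <- function(c, pk) {
  if (!inherits(pk, "peak_spec")) abort("`pk` must be a `peak_spec`.")
  if (any(!is.finite(c)) || any(c < 0)) abort("Concentration must be nonnegative and finite.")
  hill <- ifelse(c == 0, 0, c^pk$hill_h / (pk$hill_K^pk$hill_h + c^pk$hill_h))
  pmax(0, pk$base_amplitude * (1 + pk$response_direction * pk$max_fold_change * hill))
}

lorentzian <- function(nu, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((nu - center)^2 + hw2)
}

#' Default decade ladders of the two exposure experiments
#'
#' Cr6+: 0.68 pM to 68 uM (9 decades); As3+: 5 fM to 5 mM (13 decades).
#'
#' @param metal `"Cr6"` or `"As3"`.
#' @return Numeric vector of concentrations in mol/L.
#' @export
decade_ladder <- function(metal = c("Cr6", "As3")) {
  metal <- match.arg(metal)
  switch(metal,
    Cr6 = 0.68e-12 * 10^(0:8),
    As3 = 5e-15 * 10^(0:12)
  )
}

#' Default metabolite band library for a concentration ladder
#'
#' Nine Raman bands between 600 and 1600 cm^-1 with half-effect
#' concentrations staggered along the ladder (in log space) so every decade
#' transition moves at least one band appreciably. The dominant band sits at
#' 730 cm^-1, inside the 700-750 cm^-1 region where nucleotide-related
#' features carry most spectral variance. The `As3` library differs from the
#' `Cr6` one in a few directions and an extra band, reflecting distinct
#' toxicity mechanisms, so the two metals are separable.
#'
#' @param metal `"Cr6"` or `"As3"`.
#' @param concentrations Ladder used to place `hill_K` values (mol/L).
#' @return List of [peak_spec()] objects.
#' @export
default_peak_library <- function(metal = c("Cr6", "As3"),
                                 concentrations = decade_ladder(metal)) {
  metal <- match.arg(metal)
  lc <- log10(range(concentrations[concentrations > 0]))
  K_at <- function(f) 10^(lc[1] + f * (lc[2] - lc[1]))
  base <- list(
    #          center width amp dir  Kfrac   h   mfc
    c(640,  14, 30, +1, 0.10, 0.6, 1.2),
    c(730,  16, 60, +1, 0.35, 0.6, 1.5),
    c(785,  14, 40, -1, 0.25, 0.6, 0.8),
    c(960,  12, 25, +1, 0.55, 0.6, 1.0),
    c(1003, 10, 35, -1, 0.45, 0.7, 0.7),
    c(1245, 18, 30, +1, 0.70, 0.6, 1.2),
    c(1330, 16, 45, +1, 0.85, 0.6, 1.0),
    c(1450, 18, 35, -1, 0.60, 0.7, 0.6),
    c(1575, 16, 40, +1, 0.95, 0.7, 0.9)
  )
  if (metal == "As3") {
    base[[3]][4] <- +1       # 785 cm^-1 band goes up instead of down
    base[[5]][7] <- 1.1      # stronger 1003 cm^-1 response
    base[[8]][4] <- +1
    base <- c(base, list(c(1080, 14, 30, +1, 0.50, 0.6, 1.3)))
  }
  lapply(base, function(b) {
    peak_spec(center = b[1], width = b[2], base_amplitude = b[3],
              response_direction = b[4], hill_K = K_at(b[5]),
              hill_h = b[6], max_fold_change = b[7])
  })
}

#' Synthetic acquisition configuration
#'
#' Describes one acquisition campaign: a decade ladder of exposure
#' concentrations, Raman maps of `map_shape` points with
#' `n_maps_per_class` maps per concentration class, and a control class
#' pooled from `n_control_surfaces` surfaces each measured in biological
#' duplicate. Surface-to-surface and replicate-to-replicate variation enter
#' as multiplicative log-normal gains applied before noise; the silicon
#' 520 cm^-1 substrate line rides along and is what internal-standard
#' normalization later cancels the gains with.
#'
#' @param metal `"Cr6"`, `"As3"` or `"none"`.
#' @param concentrations Nonzero class concentrations, mol/L.
#' @param n_maps_per_class Maps per class (>= 1).
#' @param map_shape Integer `(rows, cols)` of each map.
#' @param n_control_surfaces Surfaces pooled into the control class.
#' @param peak_library List of [peak_spec()]; defaults per metal.
#' @param si_line [peak_spec()] of the silicon internal standard (520 cm^-1,
#'   no dose response).
#' @param baseline List `offset`, `slope` (counts per cm^-1), `g_amp`,
#'   `g_center`, `g_width` of a broad Gaussian hump.
#' @param noise_sd Additive Gaussian noise SD, counts.
#' @param surface_gain_sd,replicate_gain_sd Log-scale SDs of the
#'   multiplicative gains.
#' @param water_matrix `"DI"`, `"tap"` or `"wastewater"`.
#' @param extra_peaks Matrix-background bands (constant amplitude), normally
#'   installed by [make_matrix_shifted()].
#' @param wavenumbers Spectral grid; default 300-1800 cm^-1 at 1 cm^-1.
#' @param seed Integer seed driving all randomness of [simulate_dataset()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(metal = "Cr6",
                             concentrations = decade_ladder(metal),
                             n_maps_per_class = 3L,
                             map_shape = c(20L, 20L),
                             n_control_surfaces = 8L,
                             peak_library = default_peak_library(metal, concentrations),
                             si_line = peak_spec(520, 12, 200),
                             baseline = list(offset = 60, slope = 0.02,
                                             g_amp = 40, g_center = 1400, g_width = 300),
                             noise_sd = 2,
                             surface_gain_sd = 0.15,
                             replicate_gain_sd = 0.05,
                             water_matrix = "DI",
                             extra_peaks = list(),
                             wavenumbers = seq(300, 1800, by = 1),
                             seed = 1L) {
  if (n_maps_per_class < 1L || any(map_shape < 1L)) {
    abort("`n_maps_per_class` and `map_shape` entries must be >= 1.")
  }
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  if (any(concentrations <= 0)) abort("`concentrations` must be positive (control is implicit).")
  validate_grid(wavenumbers)
  structure(list(metal = metal, concentrations = sort(concentrations),
                 n_maps_per_class = as.integer(n_maps_per_class),
                 map_shape = as.integer(map_shape),
                 n_control_surfaces = as.integer(n_control_surfaces),
                 peak_library = peak_library, si_line = si_line,
                 baseline = baseline, noise_sd = noise_sd,
                 surface_gain_sd = surface_gain_sd,
                 replicate_gain_sd = replicate_gain_sd,
                 water_matrix = water_matrix, extra_peaks = extra_peaks,
                 wavenumbers = as.numeric(wavenumbers), seed = as.integer(seed)),
            class = "generator_config")
}

#' Expected class counts of a configuration
#'
#' Closed form: every nonzero class holds
#' `n_maps_per_class * rows * cols` spectra, the control
#' `n_control_surfaces` times that.
#'
#' @param cfg A [generator_config()].
#' @return Tibble with `class_index` and expected `n`.
#' @export
expected_class_counts <- function(cfg) {
  per <- cfg$n_maps_per_class * prod(cfg$map_shape)
  tibble::tibble(
    class_index = c(0L, class_index_of(cfg$concentrations, cfg$concentrations)),
    n = c(cfg$n_control_surfaces * per, rep(per, length(cfg$concentrations)))
  )
}

# Decade class index: control 0, then 1 + log10(c / c_min), rounded.
class_index_of <- function(c, ladder) {
  cmin <- min(ladder)
  ifelse(c == 0, 0L, as.integer(1L + round(log10(c / cmin))))
}

# Noise-free spectrum (before gain) at concentration c.
clean_spectrum <- function(cfg, c) {
  nu <- cfg$wavenumbers
  b <- cfg$baseline
  y <- b$offset + b$slope * (nu - nu[1]) +
    b$g_amp * exp(-(nu - b$g_center)^2 / (2 * b$g_width^2))
  for (pk in cfg$peak_library) {
    y <- y + dose_response(c, pk) * lorentzian(nu, pk$center, pk$width)
  }
  for (pk in cfg$extra_peaks) {
    y <- y + pk$base_amplitude * lorentzian(nu, pk$center, pk$width)
  }
  y + cfg$si_line$base_amplitude * lorentzian(nu, cfg$si_line$center, cfg$si_line$width)
}

#' Simulate a single spectrum
#'
#' `intensity = gain * [baseline + dose-responsive bands + matrix background
#' + Si line] + N(0, noise_sd)`, clipped at zero. Uses the current RNG
#' stream unless `seed` is given.
#'
#' @param cfg A [generator_config()].
#' @param concentration mol/L (0 for control).
#' @param surface_gain,replicate_gain Multiplicative gains.
#' @param seed Optional seed for reproducibility of the noise draw.
#' @return One-row `sers_dataset`.
#' @export
simulate_spectrum <- function(cfg, concentration, surface_gain = 1,
                              replicate_gain = 1, seed = NULL) {
  y <- with_seed(seed, {
    g <- surface_gain * replicate_gain
    pmax(0, g * clean_spectrum(cfg, concentration) +
              rnorm(length(cfg$wavenumbers), 0, cfg$noise_sd))
  })
  meta <- tibble::tibble(
    metal = if (concentration > 0) cfg$metal else "none",
    salt = if (concentration > 0) salt_name(cfg$metal) else "none",
    concentration_molar = concentration,
    class_index = class_index_of(concentration, cfg$concentrations),
    water_matrix = cfg$water_matrix
  )
  sers_dataset(meta, list(y), cfg$wavenumbers)
}

salt_name <- function(metal) {
  switch(metal, Cr6 = "K2Cr2O7", As3 = "NaAsO2", "none")
}

#' Simulate a full acquisition campaign
#'
#' Generates every class of the ladder plus the pooled control:
#' each nonzero class is `n_maps_per_class` maps of `prod(map_shape)` points
#' on one surface; the control class is acquired on all
#' `n_control_surfaces` surfaces (maps alternating between two biological
#' replicates per surface). Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A `sers_dataset`.
#' @export
#' @examples
#' cfg <- generator_config(map_shape = c(2, 2), n_maps_per_class = 1,
#'                         n_control_surfaces = 2, wavenumbers = seq(300, 1800, 50))
#' dataset_summary(simulate_dataset(cfg))
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "generator_config")) abort("`cfg` must be a `generator_config`.")
  with_seed(cfg$seed, {
    n_pts <- prod(cfg$map_shape)
    p <- length(cfg$wavenumbers)
    surfaces <- sprintf("S%02d", seq_len(cfg$n_control_surfaces))
    sg <- exp(rnorm(length(surfaces), 0, cfg$surface_gain_sd))
    names(sg) <- surfaces
    rg <- matrix(exp(rnorm(2L * length(surfaces), 0, cfg$replicate_gain_sd)),
                 nrow = length(surfaces), dimnames = list(surfaces, c("R1", "R2")))

    blocks <- list()
    emit <- function(conc, surface, replicate, map) {
      clean <- clean_spectrum(cfg, conc)
      g <- sg[[surface]] * rg[surface, replicate]
      mat <- matrix(rnorm(n_pts * p, 0, cfg$noise_sd), n_pts, p, byrow = TRUE)
      mat <- pmax(sweep(mat, 2, g * clean, `+`), 0)
      pos <- expand.grid(col = seq_len(cfg$map_shape[2]), row = seq_len(cfg$map_shape[1]))
      meta <- tibble::tibble(
        spectrum_id = sprintf("c%02d_%s_%s_%s_r%02dc%02d",
                              class_index_of(conc, cfg$concentrations), surface,
                              replicate, map, pos$row, pos$col),
        metal = if (conc > 0) cfg$metal else "none",
        salt = if (conc > 0) salt_name(cfg$metal) else "none",
        concentration_molar = conc,
        class_index = class_index_of(conc, cfg$concentrations),
        surface_id = surface, replicate_id = replicate, map_id = map,
        water_matrix = cfg$water_matrix
      )
      meta$intensity <- lapply(seq_len(n_pts), function(i) mat[i, ])
      blocks[[length(blocks) + 1L]] <<- meta
    }

    # Control: every surface, maps alternating between biological duplicates.
    for (s in surfaces) {
      for (m in seq_len(cfg$n_maps_per_class)) {
        emit(0, s, c("R1", "R2")[(m - 1L) %% 2L + 1L], sprintf("M%d", m))
      }
    }
    # Exposed classes: one surface each (cycled), first replicate.
    for (k in seq_along(cfg$concentrations)) {
      s <- surfaces[(k - 1L) %% length(surfaces) + 1L]
      for (m in seq_len(cfg$n_maps_per_class)) {
        emit(cfg$concentrations[k], s, "R1", sprintf("M%d", m))
      }
    }
    df <- dplyr::bind_rows(blocks)
    new_sers_dataset(df, cfg$wavenumbers)
  })
}

#' Simulate repeat spectra of one water sample
#'
#' Draws `n` spectra at a single concentration (0 for an unspiked sample)
#' on one surface with unit gains; used for sample-level verdicts.
#'
#' @param cfg A [generator_config()].
#' @param concentration mol/L.
#' @param n Number of spectra.
#' @param seed Optional seed.
#' @return A `sers_dataset` of `n` rows.
#' @export
simulate_sample <- function(cfg, concentration, n = 100L, seed = NULL) {
  with_seed(seed, {
    clean <- clean_spectrum(cfg, concentration)
    p <- length(cfg$wavenumbers)
    mat <- matrix(rnorm(n * p, 0, cfg$noise_sd), n, p, byrow = TRUE)
    mat <- pmax(sweep(mat, 2, clean, `+`), 0)
    meta <- tibble::tibble(
      spectrum_id = sprintf("sample_%04d", seq_len(n)),
      metal = if (concentration > 0) cfg$metal else "none",
      salt = if (concentration > 0) salt_name(cfg$metal) else "none",
      concentration_molar = concentration,
      class_index = class_index_of(concentration, cfg$concentrations),
      water_matrix = cfg$water_matrix
    )
    sers_dataset(meta, mat, cfg$wavenumbers)
  })
}

#' Derive a matrix-shifted configuration
#'
#' Water matrices other than deionized water add constant-amplitude
#' background bands (e.g. nitrate/sulfate in tap water, a richer organic
#' background in secondary-treated wastewater) and shift the baseline.
#' Dose-responsive metabolite bands and the silicon internal standard are
#' untouched: only the background changes with the matrix.
#'
#' @param cfg A DI-water [generator_config()].
#' @param water_matrix `"DI"`, `"tap"` or `"wastewater"`.
#' @return A modified `generator_config` (unchanged for `"DI"`).
#' @export
make_matrix_shifted <- function(cfg, water_matrix = c("DI", "tap", "wastewater")) {
  water_matrix <- match.arg(water_matrix)
  if (water_matrix == "DI") return(cfg)
  shift <- switch(water_matrix,
    tap = list(
      peaks = list(peak_spec(980, 12, 18), peak_spec(1049, 14, 25)),
      offset = 20, slope = 0
    ),
    wastewater = list(
      peaks = list(peak_spec(1002, 12, 25), peak_spec(1340, 18, 30),
                   peak_spec(1600, 20, 35)),
      offset = 40, slope = 0.01
    )
  )
  cfg$extra_peaks <- c(cfg$extra_peaks, shift$peaks)
  cfg$baseline$offset <- cfg$baseline$offset + shift$offset
  cfg$baseline$slope <- cfg$baseline$slope + shift$slope
  cfg$water_matrix <- water_matrix
  cfg
}
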