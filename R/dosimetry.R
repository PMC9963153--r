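#' Salt specifications for the two heavy-metal exposure compounds
#'
#' Sodium arsenite (NaAsO2) carries one As(III) ion per formula unit;
#' potassium dichromate (K2Cr2O7) carries two Cr(VI) ions, which doubles the
#' ion molarity relative to the salt molarity. Molar masses are standard
#' 2-decimal atomic-weight sums.
#'
#' @param name `"NaAsO2"` or `"K2Cr2O7"`.
#' @return A list of class `salt_spec` with fields `name`, `molar_mass`
#'   (g/mol), `ions_per_formula` and `element_mass` (g/mol of the metal).
#' @export
#' @examples
#' salt_spec("K2Cr2O7")$ions_per_formula # 2 Cr per formula unit
salt_spec <- function(name = c("NaAsO2", "K2Cr2O7")) {
  name <- match.arg(name)
  spec <- switch(name,
    NaAsO2 = list(name = "NaAsO2", molar_mass = 129.91, ions_per_formula = 1L,
                  element = "As", element_mass = 74.92, metal = "As3"),
    K2Cr2O7 = list(name = "K2Cr2O7", molar_mass = 294.18, ions_per_formula = 2L,
                   element = "Cr", element_mass = 52.00, metal = "Cr6")
  )
  structure(spec, class = "salt_spec")
}

#' Convert a mass concentration to molarity
#'
#' Three bases are supported: `"salt"` divides by the salt molar mass,
#' `"ion"` additionally multiplies by the number of metal ions per formula
#' unit (so 0.1 ng/L K2Cr2O7 becomes 0.68 pM Cr6+), and `"element"` divides
#' by the elemental mass of the metal, which is how WHO drinking-water limits
#' quoted in micrograms of the element per litre are converted (10 ug/L As is
#' 0.13 uM).
#'
#' @param mass_conc Mass concentration in g/L (vectorised).
#' @param salt A [salt_spec()].
#' @param basis `"salt"`, `"ion"` or `"element"`.
#' @return Molarity in mol/L.
#' @export
#' @examples
#' mass_to_molar(10e-6, salt_spec("NaAsO2"), basis = "element") # 1.33e-7 M
mass_to_molar <- function(mass_conc, salt, basis = c("salt", "ion", "element")) {
  basis <- match.arg(basis)
  if (!inherits(salt, "salt_spec")) abort("`salt` must be a `salt_spec` object.")
  if (any(!is.finite(mass_conc)) || any(mass_conc < 0)) {
    abort("`mass_conc` must be nonnegative and finite.")
  }
  switch(basis,
    salt = mass_conc / salt$molar_mass,
    ion = mass_conc / salt$molar_mass * salt$ions_per_formula,
    element = mass_conc / salt$element_mass
  )
}

#' Convert a molarity back to a mass concentration
#'
#' Inverse of [mass_to_molar()] on every basis.
#'
#' @inheritParams mass_to_molar
#' @param molarity mol/L (vectorised).
#' @return Mass concentration in g/L.
#' @export
molar_to_mass <- function(molarity, salt, basis = c("salt", "ion", "element")) {
  basis <- match.arg(basis)
  if (!inherits(salt, "salt_spec")) abort("`salt` must be a `salt_spec` object.")
  switch(basis,
    salt = molarity * salt$molar_mass,
    ion = molarity * salt$molar_mass / salt$ions_per_formula,
    element = molarity * salt$element_mass
  )
}

#' Culture specification for dosimetry
#'
#' The conversion from optical density (OD) to cell density uses the common
#' E. coli calibration of 1e9 cells/mL per OD unit, i.e. 5e8 cells/mL at the
#' exposure OD of 0.5. The factor is exposed because colorimeters differ.
#'
#' @param od Optical density of the exposed culture (dimensionless, >= 0).
#' @param cells_per_ml_per_od Cell density per OD unit (mL^-1).
#' @return A list of class `culture_spec`.
#' @export
culture_spec <- function(od = 0.5, cells_per_ml_per_od = 1e9) {
  assert_scalar_number(od, "od", min = 0)
  assert_scalar_number(cells_per_ml_per_od, "cells_per_ml_per_od", min = 0, strict = TRUE)
  structure(list(od = od, cells_per_ml_per_od = cells_per_ml_per_od),
            class = "culture_spec")
}

AVOGADRO <- 6.02214e23

#' Metal ions per bacterium in the exposure culture
#'
#' Number of free metal ions per cell at a given ion molarity:
#' `molarity * N_A / 1000` ions per mL divided by the cell density
#' `od * cells_per_ml_per_od`. At the classification-based detection limits
#' (0.5 pM As3+, 6.8 pM Cr6+) and OD 0.5 this gives 0.6 and 8.2 ions per
#' bacterium.
#'
#' @param molarity Ion molarity in mol/L (vectorised).
#' @param culture A [culture_spec()]; `od` must be positive.
#' @return Dimensionless ions-per-cell ratio.
#' @export
ions_per_cell <- function(molarity, culture = culture_spec()) {
  if (!inherits(culture, "culture_spec")) abort("`culture` must be a `culture_spec`.")
  if (culture$od <= 0) abort("`od` must be > 0 to define a cell density.")
  if (any(molarity < 0)) abort("`molarity` must be nonnegative.")
  ions_per_ml <- molarity * AVOGADRO / 1000
  ions_per_ml / (culture$od * culture$cells_per_ml_per_od)
}

#' WHO drinking-water limits for the two metals
#'
#' @return Tibble with metal, mass limit (g/L of the element) and the molar
#'   equivalent computed on the element basis.
#' @export
who_limits <- function() {
  tibble::tibble(
    metal = c("As3", "Cr6"),
    mass_limit_g_per_L = c(10e-6, 50e-6),
    molar_limit = c(
      mass_to_molar(10e-6, salt_spec("NaAsO2"), "element"),
      mass_to_molar(50e-6, salt_spec("K2Cr2O7"), "element")
    )
  )
}
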