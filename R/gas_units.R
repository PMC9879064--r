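#' Diffusivity constants for a gas species
#'
#' Literature diffusion coefficients used throughout the package, for oxygen
#' and carbon dioxide in PDMS (the gas-permeable membrane material) and in
#' water. Hydrogels made of natural extracellular matrix behave like water
#' slowed by the polymer network; measured values for common hydrogels
#' (alginate, agarose, collagen, fibrin, rBM) cluster around 75% of the
#' water value.
#'
#' @param species `"O2"` or `"CO2"`.
#' @return A list of class `gas_constants` with fields `species`, `D_pdms`,
#'   `D_water` (cm^2/s) and `hydrogel_fraction_of_water`.
#' @export
#' @examples
#' gas_constants("O2")$D_pdms   # 3.5e-5 cm^2/s
gas_constants <- function(species = c("O2", "CO2")) {
  species <- match.arg(species)
  out <- switch(species,
    O2  = list(species = "O2",  D_pdms = 3.5e-5, D_water = 2.5e-5,
               hydrogel_fraction_of_water = 0.75),
    CO2 = list(species = "CO2", D_pdms = 2.2e-5, D_water = 2.1e-5,
               hydrogel_fraction_of_water = 0.75)
  )
  structure(out, class = "gas_constants")
}

#' Solubility of oxygen in water
#'
#' Henry-law solubility linking partial pressure (atm) to dissolved
#' concentration (mol/cm^3). The water value is used for aqueous media and,
#' by default, for PDMS, whose solubility the model does not require
#' independently because partial pressure is continuous across interfaces.
#'
#' @format A single number, mol/(cm^3 atm).
#' @export
ALPHA_O2_WATER <- 1.1e-6

#' Default oxygen diffusivity of an ECM hydrogel
#'
#' The value used for lung-ECM-type hydrogels, 1.87e-5 cm^2/s. This is the
#' conventional printed figure for "75% of water"; it takes precedence over
#' recomputing `0.75 * D_water` (which would give 1.875e-5) so that worked
#' estimates reproduce to their printed precision.
#'
#' @format A single number, cm^2/s.
#' @export
D_O2_HYDROGEL <- 1.87e-5

#' Table of the package's physical constants
#'
#' @return A data.frame with one row per constant: name, value, unit.
#' @export
constants_table <- function() {
  o2 <- gas_constants("O2"); co2 <- gas_constants("CO2")
  data.frame(
    name = c("D_O2_pdms", "D_O2_water", "D_O2_hydrogel",
             "D_CO2_pdms", "D_CO2_water",
             "alpha_O2_water", "atmospheric_pressure"),
    value = c(o2$D_pdms, o2$D_water, D_O2_HYDROGEL,
              co2$D_pdms, co2$D_water, ALPHA_O2_WATER, .MMHG_PER_ATM),
    unit = c(rep("cm2/s", 5), "mol/(cm3*atm)", "mmHg"),
    stringsAsFactors = FALSE
  )
}

#' Convert an O2 volume fraction to partial pressure
#'
#' @param fraction O2 volume fraction in `[0, 1]` (20% O2 is 0.20).
#' @param pressure_mmHg atmospheric reference pressure, mmHg (default 760).
#' @return Partial pressure in mmHg.
#' @export
#' @examples
#' fraction_to_partial_pressure(0.20)  # 152 mmHg
fraction_to_partial_pressure <- function(fraction, pressure_mmHg = 760) {
  check_number(pressure_mmHg, "pressure_mmHg", lower = 0, strict_lower = TRUE)
  if (!is.numeric(fraction) || any(!is.finite(fraction)) ||
      any(fraction < 0) || any(fraction > 1))
    stop_domain("'fraction' must lie in [0, 1]")
  fraction * pressure_mmHg
}

#' @rdname fraction_to_partial_pressure
#' @param p partial pressure, mmHg.
#' @export
partial_pressure_to_fraction <- function(p, pressure_mmHg = 760) {
  check_number(pressure_mmHg, "pressure_mmHg", lower = 0, strict_lower = TRUE)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop_domain("'p' must be non-negative")
  p / pressure_mmHg
}

#' Henry-law conversion between partial pressure and concentration
#'
#' Dissolved concentration is `alpha * p / 760` with `alpha` in
#' mol/(cm^3 atm) and `p` in mmHg.
#'
#' @param p partial pressure, mmHg (non-negative).
#' @param alpha solubility, mol/(cm^3 atm).
#' @return Concentration in mol/cm^3.
#' @export
#' @examples
#' partial_pressure_to_concentration(152)  # 2.2e-7 mol/cm3
partial_pressure_to_concentration <- function(p, alpha = ALPHA_O2_WATER) {
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop_domain("'p' must be non-negative")
  alpha * p / .MMHG_PER_ATM
}

#' @rdname partial_pressure_to_concentration
#' @param C concentration, mol/cm^3.
#' @export
concentration_to_partial_pressure <- function(C, alpha = ALPHA_O2_WATER) {
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  if (!is.numeric(C) || any(!is.finite(C)) || any(C < 0))
    stop_domain("'C' must be non-negative")
  C / alpha * .MMHG_PER_ATM
}

#' Characteristic diffusion time of a slab
#'
#' The conventional "3D diffusion time" `L^2 / (6 D)`. The factor 6 is the
#' three-dimensional (spherical) convention; it is applied verbatim to
#' membranes and scaffolds alike, as is customary in this field's worked
#' estimates, even though the geometry here is planar. See the methods
#' vignette for the consequences of that convention.
#'
#' @param L thickness, cm (non-negative).
#' @param D diffusivity, cm^2/s (positive).
#' @return Time in seconds.
#' @export
#' @examples
#' diffusion_time(um(500), D_O2_HYDROGEL)  # ~22 s
diffusion_time <- function(L, D) {
  if (!is.numeric(L) || any(!is.finite(L)) || any(L < 0))
    stop_domain("'L' must be non-negative")
  if (!is.numeric(D) || any(!is.finite(D)) || any(D <= 0))
    stop_domain("'D' must be > 0")
  L^2 / (6 * D)
}
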