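#' Thermal energy k_B T
#'
#' Boltzmann constant times absolute temperature, the energy scale of the
#' thermal fluctuations that drive intrachain Brownian motion. At room
#' temperature (298 K) this is about 4.1 pN nm.
#'
#' @param temperature Absolute temperature in kelvin. Must be >= 0 (0 only
#'   as the trivial zero-energy limit).
#' @param unit `"J"` (default) or `"pN.nm"` (1 pN nm = 1e-21 J).
#' @return Thermal energy as a double, in the requested unit.
#' @examples
#' thermal_energy(298)            # ~4.11e-21 J
#' thermal_energy(298, "pN.nm")   # ~4.11
#' @export
thermal_energy <- function(temperature, unit = c("J", "pN.nm")) {
  unit <- match.arg(unit)
  if (!is.numeric(temperature) || length(temperature) != 1L || is.na(temperature)) {
    abort("`temperature` must be a single finite number (kelvin).")
  }
  if (temperature < 0) {
    abort("`temperature` must be non-negative (kelvin).")
  }
  e <- .kB * temperature
  if (unit == "pN.nm") e / 1e-21 else e
}

#' Contour length of double-stranded DNA
#'
#' Fully extended length, base pairs times the axial rise per base pair
#' (0.34 nm for B-form DNA). For the 166 kbp T4 GT7 genome this gives
#' about 56.4 um, consistent with the commonly quoted ~57 um.
#'
#' @param base_pairs Number of base pairs (> 0).
#' @param rise_per_bp_nm Axial rise per base pair in nm (default 0.34,
#'   B-form).
#' @return Contour length in micrometres.
#' @examples
#' contour_length_um(166e3)   # T4 GT7 DNA, ~56.4 um
#' contour_length_um(48502)   # lambda DNA, ~16.5 um
#' @export
contour_length_um <- function(base_pairs, rise_per_bp_nm = 0.34) {
  if (!is.numeric(base_pairs) || length(base_pairs) != 1L || is.na(base_pairs) ||
      base_pairs <= 0) {
    abort("`base_pairs` must be a single positive number.")
  }
  if (!is.numeric(rise_per_bp_nm) || length(rise_per_bp_nm) != 1L ||
      is.na(rise_per_bp_nm) || rise_per_bp_nm <= 0) {
    abort("`rise_per_bp_nm` must be a single positive number.")
  }
  base_pairs * rise_per_bp_nm * 1e-3
}

#' Semiflexible-chain spring constant
#'
#' Effective harmonic stiffness of a semiflexible polymer coil near its
#' free-energy minimum, k ~ kBT / (l_p * L_c), with persistence length l_p
#' and contour length L_c. For T4 GT7 DNA (l_p ~ 50 nm, L_c ~ 57 um) this
#' evaluates to about 1.4 nN/m; measured long-axis fluctuations give values
#' several times larger, since bending stiffness alone enters the estimate
#' while twist and segment-segment interactions also stiffen the real coil.
#'
#' @param persistence_length_nm Persistence length in nm (> 0; ~50 for dsDNA).
#' @param contour_length_um Contour length in um (> 0).
#' @param temperature Absolute temperature in kelvin (default 298).
#' @return Spring constant in N/m.
#' @examples
#' spring_constant_wlc(50, 57)   # ~1.44e-9 N/m
#' @export
spring_constant_wlc <- function(persistence_length_nm, contour_length_um,
                                temperature = 298) {
  for (v in c(persistence_length_nm, contour_length_um)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort("persistence and contour lengths must be single positive numbers.")
    }
  }
  if (temperature <= 0) abort("`temperature` must be positive.")
  thermal_energy(temperature) / (persistence_length_nm * 1e-9 * contour_length_um * 1e-6)
}

#' Manning counterion condensation fractions
#'
#' For a line charge with Manning parameter xi = l_B / b (Bjerrum length
#' over axial charge spacing), counterions condense until the effective
#' charge density corresponds to xi = 1, neutralizing a fraction 1 - 1/xi
#' of the intrinsic charge when xi > 1 (none below threshold). For dsDNA
#' in water at 25 C (l_B = 0.714 nm, b = 0.17 nm) xi = 4.2: ~76% of the
#' phosphate charge is neutralized and ~24% remains dissociated.
#'
#' @param bjerrum_length_nm Bjerrum length in nm (default 0.714, water 25 C).
#' @param charge_spacing_nm Axial spacing of unit charges in nm (default
#'   0.17, dsDNA: two phosphates per 0.34 nm rise).
#' @return A one-row tibble with `manning_parameter`,
#'   `neutralized_fraction` and `dissociated_fraction`.
#' @examples
#' manning_fractions()   # xi = 4.2, 76.2% neutralized, 23.8% dissociated
#' @export
manning_fractions <- function(bjerrum_length_nm = 0.714, charge_spacing_nm = 0.17) {
  for (v in c(bjerrum_length_nm, charge_spacing_nm)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort("Bjerrum length and charge spacing must be single positive numbers.")
    }
  }
  xi <- bjerrum_length_nm / charge_spacing_nm
  neut <- if (xi > 1) 1 - 1 / xi else 0
  tibble(
    manning_parameter = xi,
    neutralized_fraction = neut,
    dissociated_fraction = 1 - neut
  )
}

#' Ionic strength of an electrolyte solution
#'
#' I = (1/2) sum c_i Z_i^2 over all ionic species.
#'
#' @param species A data frame with columns `concentration_M` (mol/L, >= 0)
#'   and `valence` (signed integer charge).
#' @return Ionic strength in mol/L.
#' @examples
#' # 0.15 M NaCl
#' ionic_strength(data.frame(concentration_M = c(0.15, 0.15), valence = c(1, -1)))
#' @export
ionic_strength <- function(species) {
  if (!is.data.frame(species) || nrow(species) == 0) {
    abort("`species` must be a data frame with at least one ionic species.")
  }
  if (!all(c("concentration_M", "valence") %in% names(species))) {
    abort("`species` needs columns `concentration_M` and `valence`.")
  }
  if (any(!is.finite(species$concentration_M)) || any(species$concentration_M < 0)) {
    abort("concentrations must be finite and non-negative.")
  }
  0.5 * sum(species$concentration_M * species$valence^2)
}

#' Debye screening length
#'
#' Electrostatic screening length in aqueous electrolyte,
#' lambda_D = 0.304 nm / sqrt(I) with I in mol/L (prefactor for water at
#' 25 C and monovalent-dominated screening). Scales as I^(-1/2): quadrupling
#' the ionic strength halves the screening length.
#'
#' @param ionic_strength_M Ionic strength in mol/L (> 0).
#' @return Debye length in nm.
#' @examples
#' debye_length_nm(0.15)   # ~0.78 nm, physiological salt
#' @export
debye_length_nm <- function(ionic_strength_M) {
  if (!is.numeric(ionic_strength_M) || length(ionic_strength_M) != 1L ||
      !is.finite(ionic_strength_M) || ionic_strength_M <= 0) {
    abort("`ionic_strength_M` must be a single positive number.")
  }
  0.304 / sqrt(ionic_strength_M)
}

#' Spring constant from the zero-lag autocovariance
#'
#' The fluctuation-dissipation route to the stiffness: the variance of the
#' long-axis fluctuation equals kBT/k, so k = kBT / C(0).
#'
#' @param C0_um2 Zero-lag autocovariance (variance) of the long-axis
#'   length, in um^2 (> 0).
#' @param temperature Absolute temperature in kelvin (default 298).
#' @return Spring constant in N/m.
#' @examples
#' spring_from_C0(0.343)   # ~12e-9 N/m
#' @export
spring_from_C0 <- function(C0_um2, temperature = 298) {
  if (!is.numeric(C0_um2) || length(C0_um2) != 1L || !is.finite(C0_um2) ||
      C0_um2 <= 0) {
    abort("`C0_um2` must be a single positive variance in um^2.")
  }
  thermal_energy(temperature) / (C0_um2 * 1e-12)
}
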