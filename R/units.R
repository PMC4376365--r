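#' Unit conversions between the spatial and metabolic layers
#'
#' The lattice stores concentrations in mol L^-1, lengths in m and time in s,
#' while flux balance analysis works in the field's customary
#' mmol gDwt^-1 hr^-1. All conversions between the two systems are
#' centralized here.
#'
#' @param v specific flux, mmol gDwt^-1 hr^-1 (positive = uptake)
#' @param rho local cell volume fraction (dimensionless)
#' @param m_cell dry mass of one cell, g
#' @param V_cell volume of one cell, m^3
#' @param dtau sub-step length, s
#' @return `flux_to_dconc`: the concentration change (mol L^-1) removed from a
#'   lattice site's pool when cells at volume fraction `rho` sustain specific
#'   uptake `v` for `dtau` seconds.
#' @export
flux_to_dconc <- function(v, rho, m_cell, V_cell, dtau) {
  v * 1e-3 / 3600 * m_cell * dtau / (V_cell * 1e3) * rho
}

#' @rdname flux_to_dconc
#' @param phi available concentration, mol L^-1
#' @return `conc_to_vmax`: the maximum specific uptake rate
#'   (mmol gDwt^-1 hr^-1) a cell can sustain over one sub-step given access
#'   only to the substrate within its own volume.
#' @export
conc_to_vmax <- function(phi, m_cell, V_cell, dtau) {
  phi * (V_cell * 1e3) / (m_cell * dtau) * 1e3 * 3600
}

#' @rdname flux_to_dconc
#' @param g_per_l mass concentration, g L^-1
#' @param molar_mass g mol^-1
#' @return `mass_conc_to_molar`: concentration in mol L^-1.
#' @export
mass_conc_to_molar <- function(g_per_l, molar_mass) g_per_l / molar_mass

#' Molar mass of glucose, g mol^-1
#' @export
MOLAR_MASS_GLUCOSE <- 180.156
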