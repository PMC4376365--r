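#' Michaelis-Menten uptake kinetics for an actively imported substrate
#'
#' Bundles the specific transporter capacity (`E k_cat / m_cell`, reported
#' as mmol gDwt^-1 hr^-1), the Michaelis constant, and the per-cell mass
#' and volume used to convert the specific rate to a volumetric one.
#'
#' @param vmax_specific maximum specific import rate, mmol gDwt^-1 hr^-1
#' @param km Michaelis constant, mol L^-1
#' @param m_cell dry mass per cell, g
#' @param V_cell volume per cell, m^3
#' @return an object of class `uptake_kinetics`
#' @export
uptake_kinetics <- function(vmax_specific, km, m_cell = 2.58e-13,
                            V_cell = 1e-18) {
  stopifnot(vmax_specific > 0, km > 0, m_cell > 0, V_cell > 0)
  structure(list(vmax_specific = vmax_specific, km = km,
                 m_cell = m_cell, V_cell = V_cell,
                 # volumetric prefactor E k_cat / V_cell, mol L^-1 s^-1 at rho = 1
                 vmax_volumetric = vmax_specific * 1e-3 / 3600 *
                   m_cell / (V_cell * 1e3)),
            class = "uptake_kinetics")
}

#' Instantaneous local active-import rate
#'
#' `rho * (E k_cat / V_cell) * phi / (km + phi)`: the rate (mol L^-1 s^-1)
#' at which transporter-bearing cells at volume fraction `rho` move
#' substrate from the shared extracellular pool into their intracellular
#' pool. Linear in `rho`, saturating in the extracellular concentration.
#'
#' @param rho local cell volume fraction
#' @param kinetics an [uptake_kinetics()]
#' @param phi_ext extracellular concentration, mol L^-1
#' @return import rate, mol L^-1 s^-1
#' @export
uptake_rate <- function(rho, kinetics, phi_ext) {
  stopifnot(inherits(kinetics, "uptake_kinetics"))
  if (any(rho < 0) || any(phi_ext < 0)) stop("inputs must be non-negative")
  rho * kinetics$vmax_volumetric * phi_ext / (kinetics$km + phi_ext)
}

#' One active-import sub-step
#'
#' Moves `k dtau` of each ACTIVE substrate from the extracellular field to
#' the intracellular pool at every cell site, with the rate silently capped
#' at `phi_ext / dtau` so the extracellular pool can never go negative
#' (capping events are counted in the `"uptake_capped"` attribute). The
#' per-site sum `phi_ext + phi_int` is exactly conserved.
#'
#' @param lattice a `colony_lattice`
#' @param dtau sub-step, s
#' @return the updated lattice
#' @export
active_uptake_step <- function(lattice, dtau = lattice$config$dtau) {
  cfg <- lattice$config
  rho <- rho_total(lattice)
  capped <- 0L
  for (nm in names(lattice$intra)) {
    s <- lattice$substrates[[nm]]
    kin <- uptake_kinetics(s$uptake_vmax, s$uptake_km, cfg$m_cell, cfg$V_cell)
    phi <- lattice$ext[[nm]]
    k <- uptake_rate(rho, kin, phi)
    over <- k * dtau > phi
    capped <- capped + sum(over & k > 0)
    k[over] <- phi[over] / dtau
    lattice$ext[[nm]] <- phi - k * dtau
    lattice$intra[[nm]] <- lattice$intra[[nm]] + k * dtau
  }
  attr(lattice, "uptake_capped") <- capped
  lattice
}
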