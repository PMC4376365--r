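#' @useDynLib colonyFBA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Site type codes shared with the compiled kernels.
SITE_AIR  <- 0L
SITE_AGAR <- 1L
SITE_CELL <- 2L

#' Simulation geometry and physical parameter set
#'
#' Collects the lattice geometry, time-stepping constants and per-cell
#' physical constants of the simulator. Defaults reproduce the headline
#' configuration: a 3.2 x 3.2 x 1.92 mm volume at 10 um spacing with a
#' 0.96 mm agar slab, 1 ms sub-steps, a 1 s relaxation window and 60 s
#' between colony updates.
#'
#' @param dims integer triple: number of sites along x, y, z
#' @param lambda lattice spacing, m
#' @param agar_height height of the agar slab, m (must be a multiple of
#'   `lambda` smaller than the z extent)
#' @param dtau diffusion/uptake/FBA sub-step, s
#' @param t_ss steady-state relaxation window per colony cycle, s
#' @param t_grow interval between colony (growth/expansion/regulation)
#'   updates, s
#' @param rho_max maximum cell volume fraction before expansion
#' @param delta_rho expansion convergence cutoff on over-filling
#' @param m_cell dry mass per cell, g
#' @param V_cell volume per cell, m^3
#' @return an object of class `lattice_config`
#' @export
lattice_config <- function(dims = c(320L, 320L, 192L),
                           lambda = 1e-5,
                           agar_height = 0.96e-3,
                           dtau = 1e-3,
                           t_ss = 1,
                           t_grow = 60,
                           rho_max = 0.65,
                           delta_rho = 0.01,
                           m_cell = 2.58e-13,
                           V_cell = 1e-18) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  vals <- c(lambda = lambda, agar_height = agar_height, dtau = dtau,
            t_ss = t_ss, t_grow = t_grow, rho_max = rho_max,
            delta_rho = delta_rho, m_cell = m_cell, V_cell = V_cell)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all lattice_config parameters must be strictly positive")
  if (t_ss > t_grow) stop("t_ss must not exceed t_grow")
  if (rho_max >= 1) stop("rho_max must lie in (0, 1)")
  if (delta_rho >= rho_max) stop("delta_rho must lie in (0, rho_max)")
  nz_agar <- as.integer(round(agar_height / lambda))
  if (nz_agar < 1L || nz_agar >= dims[3L])
    stop("agar_height must cover at least one layer and be below the z extent")
  structure(list(dims = dims, lambda = lambda, agar_height = agar_height,
                 nz_agar = nz_agar, dtau = dtau, t_ss = t_ss, t_grow = t_grow,
                 rho_max = rho_max, delta_rho = delta_rho,
                 m_cell = m_cell, V_cell = V_cell),
            class = "lattice_config")
}

#' Physical and kinetic description of one tracked substrate
#'
#' @param name substrate name (used to key concentration fields and
#'   exchange reactions)
#' @param D_aq diffusivity in water, m^2 s^-1
#' @param D_agar diffusivity in agar, m^2 s^-1
#' @param transport `"PASSIVE"` (membrane-permeant, e.g. oxygen) or
#'   `"ACTIVE"` (transporter-mediated Michaelis-Menten import, e.g. glucose)
#' @param hindered should diffusion in cell-occupied sites be slowed by
#'   crowding (substrates that must diffuse around cells)?
#' @param air_value fixed concentration in air sites, mol L^-1
#'   (0 for non-volatile species)
#' @param dirichlet_agar_boundary concentration held fixed on the walls and
#'   floor of the agar, mol L^-1, or `NULL` for no constraint
#' @param uptake_vmax Michaelis-Menten maximum specific import rate,
#'   mmol gDwt^-1 hr^-1 (ACTIVE transport only)
#' @param uptake_km Michaelis constant, mol L^-1 (ACTIVE transport only)
#' @param fba_cap kinetic cap on the FBA exchange constraint,
#'   mmol gDwt^-1 hr^-1 (used for all substrates)
#' @return an object of class `substrate_spec`
#' @export
substrate_spec <- function(name, D_aq, D_agar,
                           transport = c("PASSIVE", "ACTIVE"),
                           hindered = FALSE,
                           air_value = 0,
                           dirichlet_agar_boundary = NULL,
                           uptake_vmax = NULL,
                           uptake_km = NULL,
                           fba_cap = Inf) {
  transport <- match.arg(transport)
  stopifnot(is.character(name), length(name) == 1L,
            D_aq > 0, D_agar > 0, air_value >= 0)
  if (transport == "ACTIVE") {
    if (is.null(uptake_vmax) || is.null(uptake_km))
      stop("ACTIVE substrates must define uptake_vmax and uptake_km")
    stopifnot(uptake_vmax > 0, uptake_km > 0)
  } else if (!is.null(uptake_vmax) || !is.null(uptake_km)) {
    stop("PASSIVE substrates must not define Michaelis-Menten uptake kinetics")
  }
  structure(list(name = name, D_aq = D_aq, D_agar = D_agar,
                 transport = transport, hindered = hindered,
                 air_value = air_value,
                 dirichlet_agar_boundary = dirichlet_agar_boundary,
                 uptake_vmax = uptake_vmax, uptake_km = uptake_km,
                 fba_cap = fba_cap),
            class = "substrate_spec")
}

#' Default substrate set: glucose, oxygen and acetate
#'
#' Glucose is actively imported (v_max 10.4 mmol gDwt^-1 hr^-1,
#' k_m 0.37 mM) and hindered by cell crowding; oxygen is membrane-permeant
#' with its air/agar boundary concentration set by Henry's law (260 uM);
#' acetate is passively available to the metabolic layer with a 16.0
#' mmol gDwt^-1 hr^-1 kinetic cap and held at zero on the agar boundary so
#' that all acetate present is colony-made.
#'
#' @param glc_boundary glucose concentration held on the agar walls and
#'   floor, mol L^-1 (default 1.39e-2 M, i.e. 2.5 g/L)
#' @return named list of [substrate_spec()] objects
#' @export
default_substrates <- function(glc_boundary = 1.39e-2) {
  list(
    glc = substrate_spec("glc", D_aq = 7.8e-10, D_agar = 7.4e-10,
                         transport = "ACTIVE", hindered = TRUE,
                         air_value = 0,
                         dirichlet_agar_boundary = glc_boundary,
                         uptake_vmax = 10.4, uptake_km = 0.37e-3,
                         fba_cap = 10.4),
    o2 = substrate_spec("o2", D_aq = 2.6e-9, D_agar = 2.5e-9,
                        transport = "PASSIVE", hindered = FALSE,
                        air_value = 2.6e-4,
                        dirichlet_agar_boundary = 2.6e-4,
                        fba_cap = 31.8),
    ace = substrate_spec("ace", D_aq = 1.2e-9, D_agar = 1.1e-9,
                         transport = "PASSIVE", hindered = TRUE,
                         air_value = 0,
                         dirichlet_agar_boundary = 0,
                         fba_cap = 16.0)
  )
}

#' Explicit-stencil stability bound
#'
#' Returns `lambda^2 / (2 D_max)`, the upper limit on the diffusive
#' sub-step quoted for the seven-point stencil. For the 10 um lattice and
#' oxygen in water this evaluates to about 2e-2 s; production runs use a
#' considerably smaller sub-step.
#'
#' @param lambda lattice spacing, m
#' @param D_max largest aqueous diffusivity present, m^2 s^-1
#' @return maximum sub-step, s
#' @export
stability_bound <- function(lambda, D_max) {
  stopifnot(lambda > 0, D_max > 0)
  lambda^2 / (2 * D_max)
}

#' Dissolved gas concentration from Henry's law
#'
#' @param partial_pressure atm
#' @param henry_constant mol L^-1 atm^-1
#' @return equilibrium dissolved concentration, mol L^-1
#' @export
henry_concentration <- function(partial_pressure, henry_constant) {
  stopifnot(partial_pressure >= 0, henry_constant >= 0)
  partial_pressure * henry_constant
}

#' Number of cells in a fully packed lattice site
#'
#' @param rho_max maximum cell volume fraction
#' @param lambda lattice spacing, m
#' @param V_cell volume per cell, m^3
#' @return cell count `rho_max * lambda^3 / V_cell`
#' @export
cells_per_site <- function(rho_max, lambda, V_cell) {
  stopifnot(rho_max >= 0, lambda > 0, V_cell > 0)
  rho_max * lambda^3 / V_cell
}

zero_field <- function(dims) array(0, dim = dims)

#' Build the simulation lattice
#'
#' Types the bottom slab of height `agar_height` as agar and the remainder
#' as air, then initializes every substrate field: agar sites take the
#' substrate's Dirichlet boundary value (where defined), air sites its air
#' value, and all cell fields start empty. Rejects configurations whose
#' sub-step violates the stencil stability bound for the fastest-diffusing
#' substrate present.
#'
#' @param config a [lattice_config()]
#' @param substrates named list of [substrate_spec()] objects
#' @return an object of class `colony_lattice`: a list holding `config`,
#'   `substrates`, the integer `site_type` array (0 = air, 1 = agar,
#'   2 = cell), per-substrate extracellular fields `ext`, intracellular
#'   pools `intra` (ACTIVE substrates), per-state volume fractions `rho`,
#'   per-state growth-rate fields `growth`, and per-state/per-substrate
#'   last-recorded exchange fluxes `exch`
#' @export
build_lattice <- function(config, substrates = default_substrates()) {
  stopifnot(inherits(config, "lattice_config"))
  if (length(substrates)) {
    stopifnot(all(vapply(substrates, inherits, TRUE, "substrate_spec")))
    names(substrates) <- vapply(substrates, `[[`, "", "name")
    D_max <- max(vapply(substrates, `[[`, 0, "D_aq"))
    if (config$dtau > stability_bound(config$lambda, D_max))
      stop("unstable stencil: dtau exceeds lambda^2/(2 D_max) = ",
           signif(stability_bound(config$lambda, D_max), 4), " s")
  }
  dims <- config$dims
  site_type <- array(SITE_AIR, dim = dims)
  site_type[, , seq_len(config$nz_agar)] <- SITE_AGAR
  ext <- lapply(substrates, function(s) {
    f <- zero_field(dims)
    agar_val <- if (!is.null(s$dirichlet_agar_boundary)) s$dirichlet_agar_boundary else 0
    f[, , seq_len(config$nz_agar)] <- agar_val
    if (config$nz_agar < dims[3L])
      f[, , (config$nz_agar + 1L):dims[3L]] <- s$air_value
    f
  })
  intra <- lapply(Filter(function(s) s$transport == "ACTIVE", substrates),
                  function(s) zero_field(dims))
  structure(list(config = config, substrates = substrates,
                 site_type = site_type, ext = ext, intra = intra,
                 rho = list(), growth = list(), exch = list(),
                 seed = NULL),
            class = "colony_lattice")
}

# Convert a 0-based site triple to a linear (1-based) array index.
site_index <- function(lattice, site) {
  site <- as.integer(site)
  dims <- lattice$config$dims
  stopifnot(length(site) == 3L, all(site >= 0L), all(site < dims))
  1L + site[1L] + dims[1L] * (site[2L] + dims[2L] * site[3L])
}

#' Seed a colony at an air site on the agar surface
#'
#' Converts the given air site (which must sit directly on the agar
#' surface) to a cell site carrying `volume_fraction` of cells of state
#' `state_id`. On conversion, non-volatile substrate concentrations at the
#' site are set to 0 and volatile ones to their air value; diffusion
#' re-equilibrates them during the next relaxation window.
#'
#' @param lattice a [build_lattice()] result
#' @param state_id character id of the cell state being seeded
#' @param volume_fraction initial cell volume fraction, in (0, rho_max]
#' @param site 0-based integer triple (x, y, z)
#' @return the updated lattice
#' @export
seed_colony <- function(lattice, state_id, volume_fraction, site) {
  cfg <- lattice$config
  stopifnot(volume_fraction > 0, volume_fraction <= cfg$rho_max)
  idx <- site_index(lattice, site)
  type <- lattice$site_type[idx]
  if (type == SITE_AGAR) stop("cannot seed inside the agar")
  if (site[3L] != cfg$nz_agar && type != SITE_CELL)
    stop("seed site must lie on the agar surface")
  if (type == SITE_AIR) {
    lattice$site_type[idx] <- SITE_CELL
    for (nm in names(lattice$ext))
      lattice$ext[[nm]][idx] <- lattice$substrates[[nm]]$air_value
  }
  if (is.null(lattice$rho[[state_id]])) {
    lattice$rho[[state_id]] <- zero_field(cfg$dims)
    lattice$growth[[state_id]] <- zero_field(cfg$dims)
  }
  lattice$rho[[state_id]][idx] <- lattice$rho[[state_id]][idx] + volume_fraction
  total <- sum(vapply(lattice$rho, `[`, 0, idx))
  if (total > cfg$rho_max + 1e-12)
    stop("total seeded volume fraction exceeds rho_max")
  if (is.null(lattice$seed)) lattice$seed <- as.integer(site)
  lattice
}

# Total cell volume fraction across states; zero array when no states exist.
rho_total <- function(lattice) {
  if (!length(lattice$rho)) return(zero_field(lattice$config$dims))
  Reduce(`+`, lattice$rho)
}

#' @export
print.colony_lattice <- function(x, ...) {
  d <- x$config$dims
  cat("colony_lattice ", paste(d, collapse = " x "),
      " (", x$config$nz_agar, " agar layers)\n", sep = "")
  cat(" substrates:", paste(names(x$ext), collapse = ", "), "\n")
  cat(" states:", if (length(x$rho)) paste(names(x$rho), collapse = ", ") else "(none)", "\n")
  if (length(x$rho))
    cat(" total cell volume fraction:", signif(sum(rho_total(x)), 6), "\n")
  invisible(x)
}
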