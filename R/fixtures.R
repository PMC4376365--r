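#' Desk-scale toy metabolic model
#'
#' A minimal stoichiometric network with the qualitative metabolism the
#' colony simulations exercise: aerobic respiration of glucose (high
#' yield, 3 O2 per glucose), anaerobic overflow of glucose to acetate
#' (low yield), and aerobic acetate oxidation (intermediate yield).
#' Yields are tuned so fully fed aerobic growth doubles in about 46
#' minutes. By construction: aerobic glucose growth is strictly faster
#' than anaerobic; anaerobic growth is possible only through overflow
#' (with obligatory acetate secretion); and acetate growth requires
#' oxygen.
#'
#' With `crowding = TRUE` the model carries per-reaction crowding
#' coefficients; under the default set the respiration pathway's crowding
#' cost exceeds overflow's, so the unconstrained-oxygen optimum mixes
#' respiration with overflow and secretes acetate -- the overflow
#' (Warburg-like) regime. Supplying cheaper coefficients (e.g.
#' `c(RESP = 0.05, OVFL = 0.02, ACEOX = 0.1)`) keeps pure respiration
#' optimal and no acetate is secreted.
#'
#' @param crowding attach crowding coefficients?
#' @param crowding_coefficients named numeric overriding the default set
#' @return a [metabolic_model()] with tracked exchanges `glc`, `o2`, `ace`
#'   (kinetic caps 10.4, 31.8, 16.0 mmol gDwt^-1 hr^-1)
#' @export
build_toy_model <- function(crowding = FALSE, crowding_coefficients = NULL) {
  mets <- c("GLC", "O2", "ACE", "CO2", "BIO")
  rxns <- c("EX_glc", "EX_o2", "EX_ace", "EX_co2",
            "RESP", "OVFL", "ACEOX", "BIOMASS")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["GLC", "EX_glc"] <- -1
  S["O2", "EX_o2"] <- -1
  S["ACE", "EX_ace"] <- -1
  S["CO2", "EX_co2"] <- -1
  S[c("GLC", "O2", "CO2", "BIO"), "RESP"] <- c(-1, -3, 3, 0.0865)
  S[c("GLC", "ACE", "BIO"), "OVFL"] <- c(-1, 2, 0.02)
  S[c("ACE", "O2", "CO2", "BIO"), "ACEOX"] <- c(-1, -2, 2, 0.025)
  S["BIO", "BIOMASS"] <- -1
  lb <- c(EX_glc = -10.4, EX_o2 = -31.8, EX_ace = -16, EX_co2 = 0,
          RESP = 0, OVFL = 0, ACEOX = 0, BIOMASS = 0)
  ub <- c(EX_glc = 0, EX_o2 = 0, EX_ace = 1000, EX_co2 = 1000,
          RESP = 1000, OVFL = 1000, ACEOX = 1000, BIOMASS = 1000)
  cr <- NULL
  if (crowding) {
    cr <- c(RESP = 0.13, OVFL = 0.006, ACEOX = 0.16)
    if (!is.null(crowding_coefficients)) cr <- crowding_coefficients
  }
  metabolic_model(S, lb, ub, objective = "BIOMASS",
                  exchanges = c(glc = "EX_glc", o2 = "EX_o2", ace = "EX_ace"),
                  crowding = cr)
}

#' The two regulatory states of the acetate switch
#'
#' `glc`: glucose consumers, acetate uptake forbidden; `ace`: acetate
#' consumers, glucose uptake forbidden. For the non-crossfeeding control
#' use [noncrossfeeding_state()], a single state that can never take up
#' acetate.
#'
#' @return list of two [cell_state()] objects
#' @export
acetate_switch_states <- function() {
  list(cell_state("glc", overrides = list(EX_ace = c(0, Inf))),
       cell_state("ace", overrides = list(EX_glc = c(0, Inf))))
}

#' @rdname acetate_switch_states
#' @export
noncrossfeeding_state <- function() {
  list(cell_state("glc", overrides = list(EX_ace = c(0, Inf))))
}

#' Synthetic batch-culture calibration data
#'
#' Simulates the batch acetate-switch model under the three calibration
#' conditions (glucose-only, acetate-only, mixed), samples the stated time
#' grids and applies unbiased multiplicative log-normal noise. Emulates
#' the kind of optical-density plus substrate-assay time series the
#' staged calibration was designed for.
#'
#' @param params a [batch_model_params()] (ground truth)
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 gives exact trajectories)
#' @param seed integer fixing the noise stream
#' @param glc0 initial glucose, mol L^-1; `ace0` initial acetate in the
#'   acetate-only culture; `ace_mixed` initial acetate in the mixed
#'   culture; `M0` inoculum biomass, g L^-1
#' @param ace0,ace_mixed,M0 see above
#' @return a [batch_calibration_data()]
#' @export
synthetic_batch_data <- function(params = default_batch_params(),
                                 noise_cv = 0, seed = 1L,
                                 glc0 = 1.39e-2, ace0 = 1e-2,
                                 ace_mixed = 2e-3, M0 = 0.01) {
  stopifnot(noise_cv >= 0)
  run <- function(init, duration, by) {
    times <- seq(0, duration, by = by)
    simulate_batch(params, init, duration = duration, times = times)
  }
  glc_only <- run(c(M_glc = M0, M_ace = 0, glc = glc0, ace = 0), 8, 0.25)
  ace_only <- run(c(M_glc = 0, M_ace = M0, glc = 0, ace = ace0), 10, 0.25)
  mixed <- run(c(M_glc = M0, M_ace = 0, glc = glc0, ace = ace_mixed), 14, 0.1)
  if (noise_cv > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    noisy <- function(d) {
      for (col in c("M_glc", "M_ace", "glc", "ace"))
        d[[col]] <- d[[col]] *
          stats::rlnorm(nrow(d), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      d
    }
    glc_only <- noisy(glc_only); ace_only <- noisy(ace_only); mixed <- noisy(mixed)
  }
  batch_calibration_data(glc_only = glc_only, ace_only = ace_only,
                         mixed = mixed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Constant-consumption pseudo flux table
#'
#' A `flux_table` whose every node reports the same specific exchange
#' fluxes and growth rate, regardless of availability (queries are still
#' clamped to the availability constraint, so consumption shuts off as a
#' pool empties). Used to impose a known zero-order consumption in
#' analytic test scenarios.
#'
#' @param v named specific fluxes, mmol gDwt^-1 hr^-1 (uptake positive)
#' @param caps named axis caps per tracked substrate
#' @param g constant growth rate, hr^-1
#' @param state state id the table answers for
#' @return a `flux_table`
#' @export
constant_flux_table <- function(v, caps, g = 0, state = "cells") {
  tracked <- names(caps)
  axes <- lapply(caps, function(cap) c(0, cap))
  nd <- rep(2L, length(tracked))
  garr <- array(g, dim = c(nd, 1L))
  ex <- lapply(tracked, function(s)
    array(if (s %in% names(v)) v[[s]] else 0, dim = c(nd, 1L)))
  names(ex) <- tracked
  structure(list(axes = axes, states = state, tracked = tracked,
                 g = garr, ex = ex,
                 feasible = array(TRUE, dim = c(nd, 1L)),
                 crowding = FALSE, checksum = "constant"),
            class = "flux_table")
}

#' Analytic 1D oxygen-consumption column
#'
#' A 1 x 1 x (n+1) column: one agar site at the bottom holding the surface
#' concentration `C0` by a Dirichlet condition, and `n` cell sites above
#' it at fixed volume fraction `rho` consuming the substrate at the
#' constant volumetric rate `Q` (imposed through a constant-consumption
#' pseudo-table). At steady state, zero-order consumption below
#' saturation gives the parabolic profile
#' `C(z) = C0 (1 - z / z_p)^2` for `z <= z_p`, with penetration depth
#' `z_p = sqrt(2 D_eff C0 / Q)`.
#'
#' @param Q volumetric consumption rate, mol L^-1 s^-1
#' @param C0 surface concentration, mol L^-1
#' @param rho cell volume fraction in the column
#' @param n number of cell sites
#' @param lambda lattice spacing, m
#' @param D aqueous diffusivity, m^2 s^-1 (substrate is not hindered, so
#'   `D_eff = D`)
#' @param dtau sub-step, s
#' @return list with the `lattice`, the pseudo `table`, the state id, the
#'   closed-form `profile` function of height z (m), and `z_p` (m)
#' @export
analytic_column_scenario <- function(Q = 1.352e-4, C0 = 2.6e-4, rho = 0.65,
                                     n = 24L, lambda = 1e-5, D = 2.6e-9,
                                     dtau = 2e-3) {
  cfg <- lattice_config(dims = c(1L, 1L, n + 1L), lambda = lambda,
                        agar_height = lambda, dtau = dtau,
                        t_ss = 1, t_grow = 60,
                        rho_max = max(0.65, rho), delta_rho = 0.01)
  subs <- list(o2 = substrate_spec("o2", D_aq = D, D_agar = D,
                                   transport = "PASSIVE", hindered = FALSE,
                                   air_value = 0,
                                   dirichlet_agar_boundary = C0,
                                   fba_cap = Inf))
  lat <- build_lattice(cfg, subs)
  # colonize the whole column above the agar at fixed rho
  for (z in seq_len(n)) {
    lat$site_type[1, 1, z + 1L] <- SITE_CELL
    lat$ext$o2[1, 1, z + 1L] <- 0
  }
  lat$rho$cells <- zero_field(cfg$dims)
  lat$rho$cells[1, 1, 1 + seq_len(n)] <- rho
  lat$growth$cells <- zero_field(cfg$dims)
  lat$seed <- c(0L, 0L, 1L)
  # specific flux sustaining volumetric rate Q at volume fraction rho
  v_spec <- Q / (rho * cfg$m_cell / (cfg$V_cell * 1e3)) * 3600 * 1e3
  table <- constant_flux_table(c(o2 = v_spec), caps = c(o2 = 1e6),
                               g = 0, state = "cells")
  z_p <- sqrt(2 * D * C0 / Q)
  profile <- function(z) C0 * pmax(0, 1 - z / z_p)^2
  list(lattice = lat, table = table, state = "cells",
       profile = profile, z_p = z_p, Q = Q, C0 = C0)
}

#' Scaled-down colony study conditions
#'
#' Assembles the lattice, flux table and switching model for the
#' desk-scale colony scenarios: a 64 x 64 x 48 lattice (10 um spacing,
#' 160 um agar slab) seeded at the center of the agar surface with one
#' fully packed site of glucose-state cells (~650 cells; streaked inocula
#' deposit clumps, and a packed-site seed brings the interesting emergent
#' regimes inside a short simulated horizon), the toy metabolic model
#' served from a 9-node-per-axis flux table, and a 5 ms sub-step (below
#' the three-dimensional explicit-stencil stability limit).
#'
#' @param variant `"regulated"` (glucose/acetate switching),
#'   `"noncrossfeeding"` (acetate uptake forbidden everywhere, no
#'   switching) or `"unregulated"` (a single unconstrained state)
#' @param dims lattice dimensions
#' @param agar_layers agar slab depth, sites
#' @param dtau sub-step, s
#' @param axis_nodes flux-table nodes per constraint axis
#' @param glc_boundary agar-boundary glucose, mol L^-1
#' @param seed_fraction seeded volume fraction
#' @param table optional prebuilt [build_flux_table()] to reuse
#' @return list with `lattice`, `table`, `switching` (NULL for the
#'   unswitched variants), `states` and `config`
#' @export
scaled_scenario <- function(variant = c("regulated", "noncrossfeeding",
                                        "unregulated"),
                            dims = c(64L, 64L, 48L), agar_layers = 16L,
                            dtau = 5e-3, axis_nodes = 9L,
                            glc_boundary = 1.39e-2, seed_fraction = 0.65,
                            table = NULL) {
  variant <- match.arg(variant)
  cfg <- lattice_config(dims = dims, lambda = 1e-5,
                        agar_height = agar_layers * 1e-5,
                        dtau = dtau, t_ss = 1, t_grow = 60)
  lat <- build_lattice(cfg, default_substrates(glc_boundary = glc_boundary))
  states <- switch(variant,
                   regulated = acetate_switch_states(),
                   noncrossfeeding = noncrossfeeding_state(),
                   unregulated = list(cell_state("wt")))
  seed_id <- states[[1L]]$id
  center <- as.integer(dims[1:2] %/% 2) - 1L
  lat <- seed_colony(lat, seed_id, seed_fraction,
                     c(center[1L], center[2L], agar_layers))
  if (is.null(table)) {
    model <- build_toy_model()
    table <- build_flux_table(model, states,
                              axes = default_axes(model, axis_nodes))
  }
  switching <- if (variant == "regulated") default_switching_model("s")
  list(lattice = lat, table = table, switching = switching,
       states = states, config = cfg)
}
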