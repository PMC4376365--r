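#' Per-site substrate availability constraints
#'
#' Converts a cell site's local concentrations into the maximum specific
#' uptake rate each substrate can sustain during one sub-step: for
#' passively transported substrates the cells have access to the substrate
#' within their own volume, `phi V_cell / (m_cell dtau)`; for actively
#' imported substrates the intracellular pool (confined entirely to the
#' cells) gives `(phi_int / rho) V_cell / (m_cell dtau)`. Each raw
#' availability is then capped by the substrate's kinetic cap.
#'
#' @param lattice a `colony_lattice`
#' @param site 0-based integer triple of a cell site
#' @param substrates substrates to constrain (default: all tracked)
#' @param dtau sub-step, s
#' @return named non-negative numeric, mmol gDwt^-1 hr^-1
#' @export
exchange_constraints <- function(lattice, site,
                                 substrates = names(lattice$ext),
                                 dtau = lattice$config$dtau) {
  cfg <- lattice$config
  idx <- site_index(lattice, site)
  if (lattice$site_type[idx] != SITE_CELL)
    stop("exchange constraints are defined only for cell sites")
  rho <- sum(vapply(lattice$rho, `[`, 0, idx))
  if (rho <= 0) stop("site carries no cell volume")
  out <- stats::setNames(numeric(length(substrates)), substrates)
  for (nm in substrates) {
    s <- lattice$substrates[[nm]]
    phi <- if (s$transport == "ACTIVE") lattice$intra[[nm]][idx] / rho
           else lattice$ext[[nm]][idx]
    out[nm] <- min(conc_to_vmax(phi, cfg$m_cell, cfg$V_cell, dtau), s$fba_cap)
  }
  out
}

#' Apply a flux solution to a site's substrate pools
#'
#' Deducts each predicted uptake from the pool it was constrained against
#' (the extracellular field for passive substrates, the intracellular pool
#' for active ones) and credits secretions (negative uptake-positive flux)
#' to the extracellular field. The site's growth rate is recorded. A pool
#' driven below -1e-15 M indicates a constraint/solution mismatch and
#' aborts.
#'
#' @param lattice a `colony_lattice`
#' @param site 0-based integer triple
#' @param solution a `flux_solution` with uptake-positive `v_exchange`
#' @param dtau sub-step, s
#' @param state_id state whose cells realize the fluxes (defaults to the
#'   single state present)
#' @return the updated lattice
#' @export
apply_exchange_fluxes <- function(lattice, site, solution,
                                  dtau = lattice$config$dtau,
                                  state_id = names(lattice$rho)[1L]) {
  cfg <- lattice$config
  idx <- site_index(lattice, site)
  rho_s <- lattice$rho[[state_id]][idx]
  for (nm in names(solution$v_exchange)) {
    v <- solution$v_exchange[[nm]]
    if (v == 0) next
    dphi <- flux_to_dconc(v, rho_s, cfg$m_cell, cfg$V_cell, dtau)
    active <- lattice$substrates[[nm]]$transport == "ACTIVE"
    if (v > 0 && active) {
      lattice$intra[[nm]][idx] <- lattice$intra[[nm]][idx] - dphi
      if (lattice$intra[[nm]][idx] < -1e-15)
        stop("intracellular ", nm, " pool overdrawn at site; ",
             "constraint/solution mismatch")
      lattice$intra[[nm]][idx] <- max(0, lattice$intra[[nm]][idx])
    } else {
      lattice$ext[[nm]][idx] <- lattice$ext[[nm]][idx] - dphi
      if (lattice$ext[[nm]][idx] < -1e-15)
        stop("extracellular ", nm, " pool overdrawn at site; ",
             "constraint/solution mismatch")
      lattice$ext[[nm]][idx] <- max(0, lattice$ext[[nm]][idx])
    }
  }
  if (is.null(lattice$growth[[state_id]]))
    lattice$growth[[state_id]] <- zero_field(cfg$dims)
  lattice$growth[[state_id]][idx] <- solution$g
  lattice
}

#' Precompute a lookup table of flux solutions
#'
#' Solves the state-constrained FBA problem at every node of a rectangular
#' grid over the availability-constraint space, one grid per cell state.
#' During the simulation the table is queried by multilinear interpolation
#' in place of per-site LP solves.
#'
#' @param model a [metabolic_model()]
#' @param states list of [cell_state()] objects
#' @param axes named list (one entry per tracked substrate, in the order of
#'   `model$exchanges`) of strictly increasing constraint grids; each must
#'   start at 0 and end at the substrate's kinetic cap
#' @param crowding apply the molecular-crowding constraint at every node?
#' @return an object of class `flux_table` holding the axes, state ids,
#'   node arrays of growth rates and uptake-positive exchange fluxes, a
#'   feasibility array, and an md5 checksum of the model
#' @export
build_flux_table <- function(model, states, axes = default_axes(model),
                             crowding = FALSE) {
  tracked <- names(model$exchanges)
  stopifnot(setequal(names(axes), tracked))
  axes <- axes[tracked]
  for (a in axes) stopifnot(length(a) >= 2L, a[1L] == 0, all(diff(a) > 0))
  if (inherits(states, "cell_state")) states <- list(states)
  ids <- vapply(states, `[[`, "", "id")
  nd <- unname(vapply(axes, length, 0L))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  nn <- nrow(grid)
  g <- array(0, dim = c(nd, length(ids)))
  feas <- array(TRUE, dim = c(nd, length(ids)))
  ex <- lapply(tracked, function(s) array(0, dim = c(nd, length(ids))))
  names(ex) <- tracked
  for (k in seq_along(states)) {
    off <- (k - 1L) * nn
    for (i in seq_len(nn)) {
      cons <- stats::setNames(grid[i, ], tracked)
      sol <- solve_fba(model, states[[k]], cons, crowding = crowding)
      g[off + i] <- sol$g
      feas[off + i] <- sol$feasible
      for (s in tracked) ex[[s]][off + i] <- sol$v_exchange[[s]]
    }
  }
  structure(list(axes = axes, states = ids, tracked = tracked,
                 g = g, ex = ex, feasible = feas,
                 crowding = crowding, checksum = model_checksum(model)),
            class = "flux_table")
}

#' @rdname build_flux_table
#' @param n nodes per axis (linear grids including 0 and the cap)
#' @export
default_axes <- function(model, n = 17L) {
  caps <- -model$lb[model$exchanges]
  stats::setNames(lapply(caps, function(cap) seq(0, cap, length.out = n)),
                  names(model$exchanges))
}

model_checksum <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(model, f, version = 2)
  unname(tools::md5sum(f))
}

#' Interpolated table lookup
#'
#' Multilinear interpolation of the growth rate and each exchange flux over
#' the grid cell enclosing the query; out-of-range components are clamped
#' to the axis range, and every interpolated uptake is additionally clamped
#' to its queried availability so cells can never consume more than their
#' site holds.
#'
#' @param table a [build_flux_table()] result
#' @param state state id
#' @param constraints named availability vector, mmol gDwt^-1 hr^-1
#' @return a `flux_solution`
#' @export
query_flux_table <- function(table, state, constraints) {
  k <- match(state, table$states)
  if (is.na(k)) stop("state ", state, " not in table")
  tracked <- table$tracked
  x <- pmin(pmax(as.numeric(constraints[tracked]), 0),
            vapply(table$axes, max, 0))
  nd <- vapply(table$axes, length, 0L)
  lo <- integer(length(nd)); w <- numeric(length(nd))
  for (d in seq_along(nd)) {
    ax <- table$axes[[d]]
    i <- findInterval(x[d], ax, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nd[d] - 1L)
    lo[d] <- i
    w[d] <- (x[d] - ax[i]) / (ax[i + 1L] - ax[i])
  }
  nstate_stride <- prod(nd)
  g <- 0
  vex <- stats::setNames(numeric(length(tracked)), tracked)
  for (corner in seq_len(2L^length(nd)) - 1L) {
    bits <- bitwAnd(bitwShiftR(corner, seq_along(nd) - 1L), 1L)
    wt <- prod(ifelse(bits == 1L, w, 1 - w))
    if (wt == 0) next
    idx <- lo + bits
    lin <- idx[1L]
    stride <- nd[1L]
    if (length(nd) > 1L)
      for (d in 2:length(nd)) { lin <- lin + (idx[d] - 1L) * stride; stride <- stride * nd[d] }
    lin <- lin + (k - 1L) * nstate_stride
    g <- g + wt * table$g[lin]
    for (s in tracked) vex[s] <- vex[s] + wt * table$ex[[s]][lin]
  }
  up <- vex > 0
  vex[up] <- pmin(vex[up], as.numeric(constraints[tracked])[up])
  flux_solution(g, vex, TRUE)
}

#' Persist or restore a flux table
#'
#' Tables are written as a single JSON container with the layout:
#' `axes` (named arrays), `states`, `tracked`, `dims`, flattened
#' column-major node arrays `g`, `feasible` and `ex_<substrate>`, the
#' `crowding` flag and the source-model `checksum`.
#'
#' @param table a `flux_table`
#' @param path file path
#' @export
write_flux_table <- function(table, path) {
  payload <- list(axes = table$axes, states = as.list(table$states),
                  tracked = as.list(table$tracked),
                  dims = dim(table$g),
                  g = as.numeric(table$g),
                  feasible = as.logical(table$feasible),
                  crowding = table$crowding, checksum = table$checksum)
  for (s in table$tracked) payload[[paste0("ex_", s)]] <- as.numeric(table$ex[[s]])
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_flux_table
#' @return `read_flux_table`: the restored `flux_table`
#' @export
read_flux_table <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(p$dims)
  tracked <- as.character(unlist(p$tracked))
  ex <- lapply(tracked, function(s) array(as.numeric(p[[paste0("ex_", s)]]), dims))
  names(ex) <- tracked
  structure(list(axes = lapply(p$axes, as.numeric)[tracked],
                 states = as.character(unlist(p$states)), tracked = tracked,
                 g = array(as.numeric(p$g), dims),
                 ex = ex,
                 feasible = array(as.logical(p$feasible), dims),
                 crowding = isTRUE(p$crowding), checksum = p$checksum),
            class = "flux_table")
}

#' Read molecular-crowding coefficients from a two-column CSV
#'
#' @param path CSV with columns `reaction` and `a` (gDwt hr mmol^-1)
#' @return named numeric vector of coefficients
#' @export
read_crowding_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction", "a") %in% names(d)))
  stats::setNames(as.numeric(d$a), d$reaction)
}
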