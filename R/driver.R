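# Reformat a flux_table into the per-state flat layout the compiled
# steady-state kernel consumes; tracked order must match the lattice's
# substrate order.
tables_for_cpp <- function(table, lattice, states) {
  stopifnot(inherits(table, "flux_table"))
  if (!identical(table$tracked, names(lattice$ext)))
    stop("flux table tracks (", paste(table$tracked, collapse = ", "),
         ") but the lattice carries (", paste(names(lattice$ext), collapse = ", "), ")")
  nd <- vapply(table$axes, length, 0L)
  nn <- prod(nd)
  lapply(states, function(id) {
    k <- match(id, table$states)
    if (is.na(k)) stop("no table entry for state ", id)
    sel <- (k - 1L) * nn + seq_len(nn)
    list(axes = table$axes,
         g = as.numeric(table$g)[sel],
         ex = lapply(table$ex, function(a) as.numeric(a)[sel]))
  })
}

sub_info_for_cpp <- function(lattice) {
  cfg <- lattice$config
  lapply(lattice$substrates, function(s) {
    act <- s$transport == "ACTIVE"
    kin <- if (act) uptake_kinetics(s$uptake_vmax, s$uptake_km,
                                    cfg$m_cell, cfg$V_cell)
    list(D_aq = s$D_aq, D_agar = s$D_agar, hindered = as.integer(s$hindered),
         air_value = s$air_value,
         has_dirichlet = as.integer(!is.null(s$dirichlet_agar_boundary)),
         dirichlet = if (is.null(s$dirichlet_agar_boundary)) 0 else s$dirichlet_agar_boundary,
         active = as.integer(act),
         vmax_volumetric = if (act) kin$vmax_volumetric else 0,
         km = if (act) kin$km else 1,
         fba_cap = min(s$fba_cap, 1e300))
  })
}

#' Relax substrate fields to quasi-steady state
#'
#' Runs `t_ss / dtau` sub-steps, each consisting of a diffusion sweep, the
#' active-import step, and a table-served FBA update at every occupied
#' cell site. The per-site growth rates and exchange fluxes from the final
#' sub-step are recorded on the lattice; the net per-site field rates over
#' that sub-step (used by [project_consumption()]) and the maximum
#' relative field change over the last 10% of sub-steps (a convergence
#' diagnostic) are attached as attributes `"rates"` and `"maxrel"`.
#'
#' @param lattice a `colony_lattice` with at least one seeded state
#' @param table a [build_flux_table()] covering every state present
#' @param dtau sub-step, s
#' @param t_ss relaxation window, s
#' @return the updated lattice
#' @export
steady_state_cycle <- function(lattice, table,
                               dtau = lattice$config$dtau,
                               t_ss = lattice$config$t_ss) {
  cfg <- lattice$config
  nsub <- max(1L, as.integer(round(t_ss / dtau)))
  states <- names(lattice$rho)
  tabs <- tables_for_cpp(table, lattice, states)
  res <- cpp_steady_state(cfg$dims, lattice$site_type,
                          lattice$ext, lattice$intra, lattice$rho,
                          sub_info_for_cpp(lattice), tabs,
                          cfg$lambda, dtau, nsub, cfg$m_cell, cfg$V_cell)
  redim <- function(a) { dim(a) <- cfg$dims; a }
  lattice$ext <- lapply(res$ext, redim)
  lattice$intra <- lapply(res$intra, redim)
  lattice$growth <- lapply(res$growth, redim)
  lattice$exch <- lapply(res$exch, function(e) lapply(e, redim))
  attr(lattice, "rates") <- lapply(res$rate, redim)
  attr(lattice, "maxrel") <- res$maxrel
  attr(lattice, "uptake_capped") <- res$uptake_capped
  lattice
}

#' Project converged consumption forward to the next colony update
#'
#' The quasi-steady fields drift only slowly (the agar reservoir drains at
#' the colony's aggregate consumption rate); the net per-site drawdown
#' rates recorded by the last steady-state sub-step are extrapolated over
#' the remaining `t_grow - t_ss` seconds, floored at zero, with air values
#' and Dirichlet boundaries re-imposed. Only the negative (consumption)
#' component is extrapolated: extrapolating a still-rising field would
#' overshoot its quasi-steady value and can feed an inter-cycle
#' oscillation, whereas leaving sources to the relaxation windows is
#' conservative and cannot create mass. The summed flooring deficit is
#' attached as attribute `"projection_deficit"`.
#'
#' @param lattice lattice returned by [steady_state_cycle()]
#' @param t_grow colony update interval, s
#' @return the updated lattice
#' @export
project_consumption <- function(lattice, t_grow = lattice$config$t_grow) {
  rates <- attr(lattice, "rates")
  if (is.null(rates)) stop("run steady_state_cycle before project_consumption")
  dt <- t_grow - lattice$config$t_ss
  if (dt <= 0) return(lattice)
  air <- lattice$site_type == SITE_AIR
  dir_idx <- dirichlet_indices(lattice)
  deficit <- 0
  for (nm in names(lattice$ext)) {
    s <- lattice$substrates[[nm]]
    phi <- lattice$ext[[nm]] + pmin(0, rates[[nm]]) * dt
    deficit <- deficit - sum(phi[phi < 0])
    phi[phi < 0] <- 0
    phi[air] <- s$air_value
    if (!is.null(s$dirichlet_agar_boundary))
      phi[dir_idx] <- s$dirichlet_agar_boundary
    lattice$ext[[nm]] <- phi
  }
  attr(lattice, "projection_deficit") <- deficit
  lattice
}

#' Summary observables of the current colony
#'
#' Radius and height use the half-maximum boundary (sites with total
#' volume fraction at least `rho_max / 2`); the oxygen penetration depth
#' is measured in the first cell layer above the agar, inward from the
#' colony edge along the seed row, at the point where oxygen first falls
#' below 1% of its air value; the glucose penetration height is measured
#' upward from the agar along the colony axis against 1% of the agar
#' boundary value. Colony-wide average uptake and production rates are
#' biomass-weighted means of the positive (respectively negative) parts of
#' the recorded exchange fluxes.
#'
#' @param lattice a `colony_lattice`
#' @param time simulation time to stamp, hr
#' @return one-row data.frame (`colony_summary`)
#' @export
summarize_colony <- function(lattice, time = NA_real_) {
  cfg <- lattice$config
  lam <- cfg$lambda
  rho <- rho_total(lattice)
  mask <- rho >= cfg$rho_max / 2
  out <- data.frame(time = time, radius = 0, height = 0, biomass = 0,
                    n_cell_sites = sum(lattice$site_type == SITE_CELL))
  subs <- names(lattice$ext)
  for (nm in subs) {
    out[[paste0("uptake_", nm)]] <- 0
    out[[paste0("production_", nm)]] <- 0
  }
  for (id in names(lattice$rho))
    out[[paste0("volume_", id)]] <- sum(lattice$rho[[id]]) * lam^3
  out$o2_penetration <- NA_real_
  out$glc_penetration <- NA_real_
  out$biomass <- sum(rho) * lam^3 / cfg$V_cell * cfg$m_cell
  if (!any(mask) || is.null(lattice$seed)) return(out)
  d <- cfg$dims
  ix <- slice.index(rho, 1L) - 1L; iy <- slice.index(rho, 2L) - 1L
  iz <- slice.index(rho, 3L) - 1L
  sx <- lattice$seed[1L]; sy <- lattice$seed[2L]
  out$radius <- max(sqrt((ix[mask] - sx)^2 + (iy[mask] - sy)^2)) * lam
  out$height <- (max(iz[mask]) - cfg$nz_agar + 1L) * lam
  tot <- sum(rho)
  for (nm in subs) {
    up <- 0; pr <- 0
    for (id in names(lattice$rho)) {
      v <- lattice$exch[[id]][[nm]]
      if (is.null(v)) next
      r <- lattice$rho[[id]]
      up <- up + sum(pmax(0, v) * r)
      pr <- pr + sum(pmax(0, -v) * r)
    }
    out[[paste0("uptake_", nm)]] <- up / tot
    out[[paste0("production_", nm)]] <- pr / tot
  }
  # oxygen penetration: first cell layer above the agar, along the seed row
  if ("o2" %in% subs) {
    zb <- cfg$nz_agar + 1L
    row_mask <- mask[, sy + 1L, zb]
    if (any(row_mask)) {
      edge <- max(which(row_mask))
      o2row <- lattice$ext$o2[, sy + 1L, zb]
      thresh <- 0.01 * lattice$substrates$o2$air_value
      inside <- which(o2row[seq_len(edge)] < thresh)
      if (length(inside)) out$o2_penetration <- (edge - max(inside)) * lam
    }
  }
  # glucose penetration: upward from the agar surface along the colony axis
  if ("glc" %in% subs) {
    col_mask <- mask[sx + 1L, sy + 1L, ]
    if (any(col_mask)) {
      top <- max(which(col_mask))
      glccol <- lattice$ext$glc[sx + 1L, sy + 1L, ]
      bval <- lattice$substrates$glc$dirichlet_agar_boundary
      if (!is.null(bval) && bval > 0) {
        zs <- (cfg$nz_agar + 1L):top
        starved <- zs[glccol[zs] < 0.01 * bval]
        if (length(starved))
          out$glc_penetration <- (min(starved) - cfg$nz_agar) * lam
        else out$glc_penetration <- out$height
      }
    }
  }
  out
}

#' One full colony update cycle
#'
#' Applies the outer kernels in order -- exponential growth, expansion
#' relaxation, regulatory switching (when a switching model is supplied) --
#' then summarizes the colony and finally projects the converged
#' consumption forward. The summary is taken before the projection: the
#' projection intentionally pre-draws local pools as bookkeeping for the
#' coming interval, so observables like penetration depths are meaningful
#' only on the converged quasi-steady fields.
#'
#' @param lattice lattice returned by [steady_state_cycle()]
#' @param switching optional [switching_model()] with rates in s^-1
#' @param t_grow colony update interval, s
#' @param time summary timestamp, hr
#' @return list with `lattice`, `summary` and the expansion `report`
#' @export
colony_cycle <- function(lattice, switching = NULL,
                         t_grow = lattice$config$t_grow, time = NA_real_) {
  lattice <- growth_step(lattice, t_grow)
  rx <- relax_expansion(lattice)
  lattice <- rx$lattice
  if (!is.null(switching)) lattice <- regulation_step(lattice, switching, t_grow)
  summary <- summarize_colony(lattice, time)
  lattice <- project_consumption(lattice, t_grow)
  list(lattice = lattice, summary = summary, report = rx$report)
}

#' Run a colony simulation
#'
#' Alternates steady-state relaxation of the substrate fields with colony
#' update cycles for the requested simulated time, collecting one summary
#' row per cycle.
#'
#' @param lattice a seeded `colony_lattice`
#' @param table flux table covering every state that can arise
#' @param switching optional [switching_model()] (s^-1); `NULL` disables
#'   regulation
#' @param hours simulated time
#' @param checkpoint_every write VTK checkpoints every this many cycles
#'   (`NULL` disables)
#' @param checkpoint_dir directory for checkpoints
#' @param verbose print a progress line every simulated hour?
#' @return list with the final `lattice` and the `summaries` data.frame
#' @export
simulate_colony <- function(lattice, table, switching = NULL, hours,
                            checkpoint_every = NULL, checkpoint_dir = NULL,
                            verbose = FALSE) {
  cfg <- lattice$config
  ncycle <- as.integer(round(hours * 3600 / cfg$t_grow))
  summaries <- vector("list", ncycle)
  manifest <- NULL
  for (cy in seq_len(ncycle)) {
    lattice <- steady_state_cycle(lattice, table)
    step <- colony_cycle(lattice, switching, time = cy * cfg$t_grow / 3600)
    lattice <- step$lattice
    summaries[[cy]] <- step$summary
    if (!is.null(checkpoint_every) && cy %% checkpoint_every == 0L) {
      f <- file.path(checkpoint_dir,
                     sprintf("checkpoint_%05d.vtk", cy))
      write_vtk(lattice, f)
      manifest <- rbind(manifest,
                        data.frame(cycle = cy, time_hr = cy * cfg$t_grow / 3600,
                                   file = basename(f)))
    }
    if (verbose && (cy * cfg$t_grow) %% 3600 == 0)
      message(sprintf("t = %5.1f hr  radius = %6.1f um  biomass = %.3g gDwt",
                      step$summary$time, step$summary$radius * 1e6,
                      step$summary$biomass))
  }
  if (!is.null(manifest))
    utils::write.csv(manifest, file.path(checkpoint_dir, "checkpoints.csv"),
                     row.names = FALSE)
  list(lattice = lattice, summaries = do.call(rbind, summaries))
}

#' Late-phase radial expansion rate and growth-regime transition
#'
#' Fits the colony radius against time by least squares over the late
#' window to estimate the constant radial expansion rate, and locates the
#' exponential-to-linear transition by a two-phase changepoint fit: for
#' each candidate breakpoint an exponential (log-linear) model is fitted
#' before it and a linear model after it, and the transition is the
#' breakpoint minimizing the total squared error -- i.e. the earliest time
#' after which the linear description beats the exponential one. The
#' two-phase model must beat a single global linear fit by the configured
#' information-criterion margin, otherwise no transition is reported.
#'
#' @param summaries data.frame with columns `time` (hr) and `radius` (m)
#' @param window numeric pair (hr): window for the rate fit; default the
#'   last third of the series
#' @param ic_margin required AIC advantage of the linear model
#' @return list with `rate_um_s`, `r_squared`, and `transition_hr` (NA if
#'   no transition is detected)
#' @export
fit_radial_rate <- function(summaries, window = NULL, ic_margin = 2) {
  d <- summaries[is.finite(summaries$radius), c("time", "radius")]
  if (is.null(window)) {
    t1 <- max(d$time)
    window <- c(t1 - (t1 - min(d$time)) / 3, t1)
  }
  dd <- d[d$time >= window[1] & d$time <= window[2], ]
  if (nrow(dd) < 5L) stop("fewer than 5 summary points in the fit window")
  fit <- stats::lm(radius ~ time, data = dd)
  rate <- unname(stats::coef(fit)[2L]) / 3600 * 1e6   # m/hr -> um/s
  r2 <- suppressWarnings(summary(fit)$r.squared)      # exact fits are fine
  # two-phase (exponential, then linear) changepoint scan
  dp <- d[d$radius > 0, ]
  cand <- dp$time[dp$time >= stats::quantile(dp$time, 0.1) &
                  dp$time <= stats::quantile(dp$time, 0.9)]
  transition <- NA_real_
  if (length(cand) && nrow(dp) >= 10L) {
    rss2 <- vapply(cand, function(tb) {
      pre <- dp[dp$time <= tb, ]; post <- dp[dp$time >= tb, ]
      if (nrow(pre) < 4L || nrow(post) < 4L) return(Inf)
      expf <- stats::lm(log(radius) ~ time, data = pre)
      lin <- stats::lm(radius ~ time, data = post)
      sum((pre$radius - exp(stats::fitted(expf)))^2) +
        sum(stats::resid(lin)^2)
    }, 0)
    if (any(is.finite(rss2))) {
      best <- which.min(rss2)
      n <- nrow(dp)
      glob <- stats::lm(radius ~ time, data = dp)
      ic_two <- n * log(max(rss2[best], 1e-300) / n) + 2 * 5
      ic_one <- n * log(sum(stats::resid(glob)^2) / n) + 2 * 2
      if (ic_two < ic_one - ic_margin) transition <- cand[best]
    }
  }
  list(rate_um_s = rate, r_squared = r2, transition_hr = transition)
}
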