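#' Batch acetate-switch model parameters
#'
#' Parameters of the well-mixed two-state growth model used to calibrate
#' the switching rates: glucose- and acetate-state growth rates (hr^-1),
#' specific glucose/acetate consumption rates and the acetate production
#' rate of glucose consumers (mol per g biomass per hr, with biomass in
#' g L^-1 so concentrations evolve in mol L^-1 hr^-1), plus the switching
#' model for the two transitions.
#'
#' @param g_glc,g_ace state growth rates, hr^-1
#' @param v_glc,v_ace substrate consumption rates, mol gDwt^-1 hr^-1
#' @param eps_ace acetate production rate of glucose consumers,
#'   mol gDwt^-1 hr^-1
#' @param switching a [switching_model()] with rates in hr^-1
#' @return an object of class `batch_model_params`
#' @export
batch_model_params <- function(g_glc, g_ace, v_glc, v_ace, eps_ace,
                               switching = default_switching_model("hr")) {
  vals <- c(g_glc, g_ace, v_glc, v_ace, eps_ace)
  stopifnot(all(is.finite(vals)), all(vals >= 0),
            switching$time_unit == "hr")
  structure(list(g_glc = g_glc, g_ace = g_ace, v_glc = v_glc,
                 v_ace = v_ace, eps_ace = eps_ace, switching = switching),
            class = "batch_model_params")
}

#' Reference batch parameters used by the synthetic-data generator
#'
#' Growth and exchange rates consistent with the toy metabolic model's
#' aerobic glucose growth (doubling ~46 min), aerobic acetate growth, and
#' a modest overflow acetate yield.
#'
#' @return a [batch_model_params()]
#' @export
default_batch_params <- function() {
  batch_model_params(g_glc = 0.9, g_ace = 0.4,
                     v_glc = 0.0104, v_ace = 0.016, eps_ace = 0.004)
}

batch_rates <- function(t, y, params) {
  glc <- max(0, y[["glc"]]); ace <- max(0, y[["ace"]])
  Mg <- max(0, y[["M_glc"]]); Ma <- max(0, y[["M_ace"]])
  k_ga <- switching_rate(params$switching, "glc->ace", glc, ace)
  k_ag <- switching_rate(params$switching, "ace->glc", glc, ace)
  grow_g <- if (glc > 0) params$g_glc else 0
  grow_a <- if (ace > 0) params$g_ace else 0
  dMg <- grow_g * Mg + k_ag * Ma - k_ga * Mg
  dMa <- grow_a * Ma + k_ga * Mg - k_ag * Ma
  dglc <- if (glc > 0) -Mg * params$v_glc else 0
  dace <- (if (glc > 0) Mg * params$eps_ace else 0) -
          (if (ace > 0) Ma * params$v_ace else 0)
  list(c(dMg, dMa, dglc, dace))
}

#' Integrate the batch acetate-switch model
#'
#' Fourth-order Runge-Kutta integration of the four coupled rate equations
#' (glucose-state biomass, acetate-state biomass, glucose, acetate) with
#' concentrations floored at zero: consumption and growth on a substrate
#' stop once it is exhausted.
#'
#' @param params a [batch_model_params()]
#' @param init named numeric: `M_glc`, `M_ace` (g L^-1), `glc`, `ace`
#'   (mol L^-1)
#' @param duration hours
#' @param step integration step, hours
#' @param times optional explicit output times (hours)
#' @return data.frame with columns `time`, `M_glc`, `M_ace`, `glc`, `ace`
#' @export
simulate_batch <- function(params, init, duration = 12, step = 0.01,
                           times = NULL) {
  stopifnot(inherits(params, "batch_model_params"), step > 0,
            all(init >= 0))
  y0 <- c(M_glc = unname(init[["M_glc"]]), M_ace = unname(init[["M_ace"]]),
          glc = unname(init[["glc"]]), ace = unname(init[["ace"]]))
  tgrid <- sort(unique(c(seq(0, duration, by = step),
                         duration, times)))
  sol <- deSolve::ode(y = y0, times = tgrid, func = batch_rates,
                      parms = params, method = "rk4")
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  out[c("M_glc", "M_ace", "glc", "ace")] <-
    lapply(out[c("M_glc", "M_ace", "glc", "ace")], pmax, 0)
  if (!is.null(times)) out <- out[out$time %in% times, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Batch calibration data container
#'
#' Time series of biomass and substrate concentrations for the three
#' culture conditions the staged calibration needs: glucose-only,
#' acetate-only, and mixed. Each element is a data.frame with columns
#' `time` (hr, strictly increasing), `M_glc`, `M_ace` (or a single `M`
#' total-biomass column), `glc`, `ace`.
#'
#' @param glc_only,ace_only,mixed data.frames as described (any may be
#'   `NULL` if that condition was not measured)
#' @return an object of class `batch_calibration_data`
#' @export
batch_calibration_data <- function(glc_only = NULL, ace_only = NULL,
                                   mixed = NULL) {
  chk <- function(d) {
    if (is.null(d)) return(invisible())
    stopifnot(all(c("time", "glc", "ace") %in% names(d)),
              all(diff(d$time) > 0),
              all(d$glc >= 0), all(d$ace >= 0))
  }
  chk(glc_only); chk(ace_only); chk(mixed)
  structure(list(glc_only = glc_only, ace_only = ace_only, mixed = mixed),
            class = "batch_calibration_data")
}

# Log-linear growth-rate fit over the window where the limiting substrate
# is still present.
fit_exponential_growth <- function(d, biomass_col, substrate_col,
                                   frac = 0.05) {
  keep <- d[[substrate_col]] > frac * d[[substrate_col]][1] &
          d[[biomass_col]] > 0
  dd <- d[keep, , drop = FALSE]
  if (nrow(dd) < 3L) stop("too few points in the exponential window")
  fit <- stats::lm(log(dd[[biomass_col]]) ~ dd$time)
  list(g = unname(stats::coef(fit)[2L]),
       M0 = exp(unname(stats::coef(fit)[1L])),
       window = dd$time)
}

#' Staged calibration of the batch acetate-switch model
#'
#' Stage 1 fits the two growth rates by log-linear regression of the
#' single-substrate biomass curves. Stage 2, with those fixed, fits the
#' consumption and production rates from the same experiments' substrate
#' curves (each is linear in the unknown rate given the exponential
#' biomass, so closed-form least squares applies). Stage 3, with stages
#' 1-2 fixed, fits the declared switching-polynomial coefficients to the
#' mixed-culture trajectories by Levenberg-Marquardt least squares.
#' Without mixed-culture data stage 3 is reported under-determined and the
#' template's coefficients are returned unchanged.
#'
#' @param data a [batch_calibration_data()]
#' @param template a [switching_model()] (hr^-1) declaring which
#'   polynomial terms to fit per transition: `NA` coefficients are free,
#'   numeric coefficients are held fixed (see [calibration_template()])
#' @param init named initial conditions for the mixed culture; defaults to
#'   the first row of the mixed data
#' @param stages which calibration stages to run (stage 3 is the only
#'   expensive one; growth-rate studies can stop after stages 1-2)
#' @return a [batch_model_params()] with attributes `stage3` (status) and
#'   `fit` (residual diagnostics)
#' @export
calibrate_switching <- function(data, template = calibration_template(),
                                init = NULL, stages = 1:3) {
  stopifnot(inherits(data, "batch_calibration_data"))
  if (is.null(data$glc_only) || is.null(data$ace_only))
    stop("both single-substrate cultures are required for stages 1-2")
  gcol <- function(d) if ("M_glc" %in% names(d)) "M_glc" else "M"
  acol <- function(d) if ("M_ace" %in% names(d)) "M_ace" else "M"

  # stage 1: growth rates
  fg <- fit_exponential_growth(data$glc_only, gcol(data$glc_only), "glc")
  fa <- fit_exponential_growth(data$ace_only, acol(data$ace_only), "ace")

  # stage 2: consumption/production rates, growth fixed. With exponential
  # biomass, substrate(t) - substrate(0) = slope * M0 (e^{g t} - 1) / g is
  # linear in the unknown rate (slope = -v for consumption, +eps for
  # production), so closed-form least squares applies.
  stage2_slope <- function(d, col, g, M0, window) {
    dd <- d[d$time %in% unique(c(d$time[1L], window)), , drop = FALSE]
    x <- M0 * (exp(g * dd$time) - 1) / g
    y <- dd[[col]] - dd[[col]][1L]
    unname(stats::coef(stats::lm(y ~ x - 1))[1L])
  }
  v_glc <- max(0, -stage2_slope(data$glc_only, "glc", fg$g, fg$M0, fg$window))
  eps_ace <- max(0, stage2_slope(data$glc_only, "ace", fg$g, fg$M0, fg$window))
  v_ace <- max(0, -stage2_slope(data$ace_only, "ace", fa$g, fa$M0, fa$window))

  fixed_template <- template
  for (nm in names(fixed_template$transitions)) {
    a <- fixed_template$transitions[[nm]]$alpha
    a[is.na(a)] <- 0
    fixed_template$transitions[[nm]]$alpha <- a
  }
  params <- batch_model_params(g_glc = fg$g, g_ace = fa$g,
                               v_glc = v_glc, v_ace = v_ace,
                               eps_ace = eps_ace, switching = fixed_template)
  if (!(3L %in% stages)) {
    attr(params, "stage3") <- "skipped"
    return(params)
  }
  if (is.null(data$mixed)) {
    attr(params, "stage3") <- "under-determined: no mixed-culture data"
    return(params)
  }

  # stage 3: switching coefficients from the mixed culture
  free <- lapply(template$transitions, function(tr) which(is.na(tr$alpha)))
  npar <- sum(lengths(free))
  if (npar == 0L) {
    attr(params, "stage3") <- "under-determined: template declares no free terms"
    return(params)
  }
  d <- data$mixed
  if (is.null(init)) {
    Mg0 <- if ("M_glc" %in% names(d)) d$M_glc[1L] else d$M[1L]
    Ma0 <- if ("M_ace" %in% names(d)) d$M_ace[1L] else 0
    init <- c(M_glc = Mg0, M_ace = Ma0, glc = d$glc[1L], ace = d$ace[1L])
  }
  per_state <- "M_glc" %in% names(d)
  obs <- if (per_state) cbind(d$M_glc + d$M_ace, d$M_ace, d$glc, d$ace)
         else cbind(d$M, d$glc, d$ace)
  scales <- pmax(apply(abs(obs), 2L, max), 1e-12)

  build_model <- function(theta) {
    trs <- template$transitions
    off <- 0L
    for (nm in names(trs)) {
      a <- trs[[nm]]$alpha
      idx <- free[[nm]]
      if (length(idx)) a[idx] <- theta[off + seq_along(idx)]
      off <- off + length(idx)
      trs[[nm]]$alpha <- a
    }
    switching_model(unname(trs), time_unit = "hr")
  }
  residfun <- function(theta) {
    p <- params
    p$switching <- build_model(theta)
    sim <- simulate_batch(p, init, duration = max(d$time), times = d$time)
    pred <- if (per_state) cbind(sim$M_glc + sim$M_ace, sim$M_ace, sim$glc, sim$ace)
            else cbind(sim$M_glc + sim$M_ace, sim$glc, sim$ace)
    as.numeric(sweep(pred - obs, 2L, scales, "/"))
  }
  # gradient-matching start: in the low-glucose window the switching flux
  # balance  dM_ace/dt - g_ace M_ace 1[ace>0] =
  #          k_ga(phi) M_glc - k_ag(phi) M_ace
  # is linear in the free polynomial coefficients (clamps ignored), so a
  # closed-form regression seeds the trajectory fit near the optimum.
  smart <- NULL
  if (per_state && npar > 0L) smart <- try({
    tt <- d$time
    dMa <- c(NA, diff(d$M_ace) / diff(tt))
    keep <- which(d$glc < 0.05 * max(d$glc) & !is.na(dMa))
    poly_terms <- function(m, n) cbind(1, m, n, m^2, n^2, m * n)
    X <- NULL; off <- numeric(length(keep))
    for (nm in names(template$transitions)) {
      tr <- template$transitions[[nm]]
      P <- poly_terms(d[[tr$subs[1]]][keep], d[[tr$subs[2]]][keep])
      wgt <- if (tr$to == "ace") d$M_glc[keep] else -d$M_ace[keep]
      fixed_idx <- setdiff(seq_len(6L), free[[nm]])
      fixed_a <- tr$alpha[fixed_idx]
      off <- off + (P[, fixed_idx, drop = FALSE] %*% fixed_a) * wgt
      if (length(free[[nm]]))
        X <- cbind(X, P[, free[[nm]], drop = FALSE] * wgt)
    }
    yy <- dMa[keep] - params$g_ace * d$M_ace[keep] * (d$ace[keep] > 0) - off
    as.numeric(stats::coef(stats::lm.fit(X, yy)))
  }, silent = TRUE)
  starts <- list(rep(0, npar), rep(0.1, npar))
  if (!inherits(smart, "try-error") && !is.null(smart) &&
      all(is.finite(smart)))
    starts <- c(list(smart), starts)
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(par = st, fn = residfun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < 1e-10) break   # essentially exact; no need to restart
  }
  if (is.null(best)) stop("stage-3 optimization failed")
  params$switching <- build_model(best$par)
  attr(params, "stage3") <- "fitted"
  attr(params, "fit") <- list(deviance = best$deviance, niter = best$niter)
  params
}
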