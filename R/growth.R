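#' Exponential biomass growth over one colony cycle
#'
#' Multiplies each state's volume fraction at every cell site by
#' `exp(g t_grow)` using that state's own last-recorded growth rate field.
#' Co-resident states therefore grow at the rates their own metabolism
#' supports under the site's shared substrate availability.
#'
#' @param lattice a `colony_lattice` with growth fields populated by the
#'   last steady-state cycle
#' @param t_grow colony update interval, s (growth rates are hr^-1)
#' @return the updated lattice
#' @export
growth_step <- function(lattice, t_grow = lattice$config$t_grow) {
  t_hr <- t_grow / 3600
  for (id in names(lattice$rho)) {
    g <- lattice$growth[[id]]
    if (is.null(g)) next
    lattice$rho[[id]] <- lattice$rho[[id]] * exp(g * t_hr)
  }
  lattice
}

#' Volume fraction moved through one face per relaxation sweep
#'
#' `(1/12) [max(0, rho_i - rho_max) - max(0, rho_j - rho_max)]`: cell
#' volume flows from the more over-filled site toward the less over-filled
#' one; negative values mean transfer from j to i. The 1/12 = (1/2)(1/6)
#' spreads the excess over the six faces with a factor-of-two convergence
#' damping.
#'
#' @param rho_i,rho_j total volume fractions of the two sites
#' @param rho_max packing limit
#' @return volume fraction transferred i -> j this sweep
#' @export
expansion_transfer <- function(rho_i, rho_j, rho_max) {
  (pmax(0, rho_i - rho_max) - pmax(0, rho_j - rho_max)) / 12
}

#' Relax over-filled sites by iterative expansion
#'
#' Jacobi sweeps of [expansion_transfer()] across all faces between cell
#' sites and their non-agar neighbors until the largest total volume
#' fraction falls within `delta_rho` of `rho_max`. Transfers into air sites
#' convert them to cell sites; transfers into agar are forbidden, so the
#' colony grows upward and outward only. Where several states coexist the
#' face transfer is determined by the total over-filling and split among
#' the states (and the intracellular pools, which travel with the cell
#' volume) in proportion to the donor site's composition.
#'
#' @param lattice a `colony_lattice`
#' @param max_sweeps abort (with the residual) after this many sweeps
#' @return list with elements `lattice` and `report` (class
#'   `expansion_report`: sweeps used, total volume moved, air sites
#'   converted, final residual over-filling)
#' @export
relax_expansion <- function(lattice, max_sweeps = 10000L) {
  cfg <- lattice$config
  nstate <- length(lattice$rho)
  if (nstate == 0L)
    return(list(lattice = lattice,
                report = expansion_report(0L, 0, 0L, 0)))
  res <- cpp_relax_expansion(cfg$dims, lattice$site_type,
                             lattice$rho, lattice$intra,
                             cfg$rho_max, cfg$delta_rho,
                             as.integer(max_sweeps))
  if (res$residual > cfg$delta_rho + 1e-12)
    stop("expansion failed to converge after ", max_sweeps,
         " sweeps (residual over-filling ", signif(res$residual, 4), ")")
  dim(res$site_type) <- cfg$dims
  lattice$site_type <- res$site_type
  lattice$rho <- lapply(res$rho, function(a) { dim(a) <- cfg$dims; a })
  lattice$intra <- lapply(res$intra, function(a) { dim(a) <- cfg$dims; a })
  # growth fields for newly converted sites stay 0 until the next FBA pass
  list(lattice = lattice,
       report = expansion_report(res$sweeps, res$volume_moved,
                                 res$converted, res$residual))
}

expansion_report <- function(sweeps, volume_moved, converted, residual) {
  structure(list(sweeps = sweeps, volume_moved = volume_moved,
                 converted = converted, residual = residual),
            class = "expansion_report")
}

#' @export
print.expansion_report <- function(x, ...) {
  cat("expansion: ", x$sweeps, " sweeps, ", signif(x$volume_moved, 4),
      " volume fraction moved, ", x$converted, " sites colonized, residual ",
      signif(x$residual, 4), "\n", sep = "")
  invisible(x)
}
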