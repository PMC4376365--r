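#' Crowding-hindered effective diffusivity
#'
#' Substrates that cannot cross cell membranes must diffuse around the
#' cells occupying a site; their effective diffusivity falls with the local
#' cell volume fraction as `D (1 - rho) / (1 + rho / 2)`.
#'
#' @param rho local total cell volume fraction, in \[0, 1\]
#' @param D free-water diffusivity, m^2 s^-1
#' @return effective diffusivity, m^2 s^-1
#' @export
effective_diffusion <- function(rho, D) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  D * (1 - rho) / (1 + rho / 2)
}

#' Diffusive flux across the face shared by two sites
#'
#' Mixed-coefficient faces use the arithmetic mean of the two sites'
#' diffusivities, which keeps the flux continuous across agar/cell
#' interfaces. Antisymmetric in (i, j).
#'
#' @param phi_j,phi_i concentrations in the donor and receiver site, mol L^-1
#' @param D_j,D_i their diffusivities, m^2 s^-1
#' @param lambda lattice spacing, m
#' @return flux from j into i (concentration times m s^-1)
#' @export
pair_flux <- function(phi_j, phi_i, D_j, D_i, lambda) {
  (D_j + D_i) / 2 * (phi_j - phi_i) / lambda
}

# Per-site diffusivity for one substrate: D_agar in agar, D_aq in air and in
# non-hindered cell sites, crowding-hindered in hindered cell sites.
diffusivity_field <- function(lattice, name) {
  s <- lattice$substrates[[name]]
  D <- array(s$D_aq, dim = lattice$config$dims)
  D[lattice$site_type == SITE_AGAR] <- s$D_agar
  if (s$hindered) {
    cellmask <- lattice$site_type == SITE_CELL
    if (any(cellmask)) {
      rho <- rho_total(lattice)
      D[cellmask] <- effective_diffusion(rho[cellmask], s$D_aq)
    }
  }
  D
}

# Shift a 3D array by one site along axis (+1 or -1); out-of-domain entries
# are NA so callers can zero the corresponding face flux.
shift3 <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(NA_real_, dim = d)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (dir > 0) { src[[axis]] <- src[[axis]][-1]; dst[[axis]] <- dst[[axis]][-d[axis]] }
  else { src[[axis]] <- src[[axis]][-d[axis]]; dst[[axis]] <- dst[[axis]][-1] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Linear indices of agar sites lying on the domain walls or floor, where
# Dirichlet values are re-imposed after every sweep.
dirichlet_indices <- function(lattice) {
  d <- lattice$config$dims
  ix <- slice.index(lattice$site_type, 1L)
  iy <- slice.index(lattice$site_type, 2L)
  iz <- slice.index(lattice$site_type, 3L)
  on_boundary <- ix == 1L | ix == d[1] | iy == 1L | iy == d[2] | iz == 1L
  which(on_boundary & lattice$site_type == SITE_AGAR)
}

#' One explicit diffusion sweep over all substrates
#'
#' Seven-point-stencil Jacobi update: every non-air site receives the sum
#' of face fluxes from its six neighbors, computed simultaneously from the
#' pre-sweep field so the result is independent of traversal order. Air
#' sites act as sources: they are clamped to each substrate's air value,
#' flux from air into agar/cell sites is allowed for volatile substrates,
#' and flux from agar/cell sites into air is zeroed for all substrates so
#' that aqueous species cannot escape. Dirichlet boundary values on the
#' agar walls and floor are re-imposed after the sweep.
#'
#' @param lattice a `colony_lattice`
#' @param dtau sub-step, s (defaults to the configured value)
#' @return the lattice with updated extracellular fields
#' @export
diffusion_step <- function(lattice, dtau = lattice$config$dtau) {
  cfg <- lattice$config
  lam <- cfg$lambda
  type <- lattice$site_type
  air <- type == SITE_AIR
  dir_idx <- dirichlet_indices(lattice)
  for (nm in names(lattice$ext)) {
    s <- lattice$substrates[[nm]]
    phi <- lattice$ext[[nm]]
    D <- diffusivity_field(lattice, nm)
    acc <- array(0, dim = cfg$dims)
    for (axis in 1:3) for (dr in c(1L, -1L)) {
      phi_n <- shift3(phi, axis, dr)
      D_n <- shift3(D, axis, dr)
      type_n <- shift3(type, axis, dr)
      J <- (D + D_n) / 2 * (phi_n - phi) / lam
      # faces with an air neighbor: one-way (air -> site) and only if volatile
      air_face <- !is.na(type_n) & type_n == SITE_AIR
      if (s$air_value > 0) {
        J[air_face] <- pmax(0, ((D + D_n) / 2 * (s$air_value - phi) / lam)[air_face])
      } else {
        J[air_face] <- 0
      }
      J[is.na(J)] <- 0            # domain boundary: no flux
      acc <- acc + J
    }
    phi_new <- phi + dtau / lam * acc
    phi_new[air] <- s$air_value
    if (!is.null(s$dirichlet_agar_boundary))
      phi_new[dir_idx] <- s$dirichlet_agar_boundary
    if (min(phi_new) < -1e-15)
      stop("diffusion instability: negative concentration in ", nm,
           " (min = ", signif(min(phi_new), 4), ")")
    lattice$ext[[nm]] <- phi_new
  }
  lattice
}
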