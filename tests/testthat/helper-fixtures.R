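# Shared fixtures: small lattices, the toy model and tables, and two
# independent oracles (toy-LP vertex enumeration; an R composition of the
# per-sub-step kernels used to cross-check the compiled fused loop).

toy_model <- build_toy_model()
toy_states <- acetate_switch_states()
toy_table5 <- build_flux_table(toy_model, toy_states,
                               axes = default_axes(toy_model, 5))

# A fully closed all-cell lattice (no air, no Dirichlet faces): every site
# is typed CELL and carries volume fraction `rho`; substrate "s" has no
# air value and no boundary condition, so diffusion conserves mass
# exactly.
closed_cell_lattice <- function(dims = c(4L, 3L, 3L), rho = 0.3,
                                D = 2.6e-9, hindered = FALSE,
                                dtau = 1e-3, phi = NULL) {
  cfg <- lattice_config(dims = dims, lambda = 1e-5,
                        agar_height = 1e-5, dtau = dtau,
                        t_ss = 1, t_grow = 60)
  subs <- list(s = substrate_spec("s", D_aq = D, D_agar = D,
                                  transport = "PASSIVE", hindered = hindered,
                                  air_value = 0, fba_cap = Inf))
  lat <- build_lattice(cfg, subs)
  lat$site_type[] <- colonyFBA:::SITE_CELL
  lat$rho$cells <- array(rho, dim = dims)
  lat$growth$cells <- array(0, dim = dims)
  if (!is.null(phi)) lat$ext$s <- phi
  lat$seed <- c(0L, 0L, 1L)
  lat
}

# Small seeded glucose/oxygen/acetate lattice for integration tests.
small_colony <- function(dims = c(10L, 10L, 10L), agar_layers = 3L,
                         seed_rho = 0.65, state = "glc", dtau = 2e-3) {
  cfg <- lattice_config(dims = dims, lambda = 1e-5,
                        agar_height = agar_layers * 1e-5, dtau = dtau,
                        t_ss = 0.2, t_grow = 60)
  lat <- build_lattice(cfg, default_substrates())
  ctr <- as.integer(dims[1:2] %/% 2)
  seed_colony(lat, state, seed_rho, c(ctr[1L], ctr[2L], agar_layers))
}

# Independent oracle for the toy model: its optimal growth reduces to a
# three-variable LP over (respiration, overflow, acetate oxidation)
# fluxes. All vertices of the feasible polytope are enumerated from
# triples of active constraints; the optimum (and, among optimal
# vertices, the minimum-total-|flux| one) is selected by brute force.
toy_vertex_oracle <- function(glc, o2, ace,
                              y = c(r = 0.0865, o = 0.02, a = 0.025)) {
  # constraints rows: a.x <= b over x = (vr, vo, va)
  A <- rbind(c(1, 1, 0),      # glucose supply
             c(3, 0, 2),      # oxygen supply
             c(0, -2, 1),     # acetate supply (uptake cap + own overflow)
             c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
  b <- c(glc, o2, ace, 0, 0, 0)
  verts <- list()
  combs <- utils::combn(nrow(A), 3)
  for (k in seq_len(ncol(combs))) {
    M <- A[combs[, k], , drop = FALSE]
    if (abs(det(M)) < 1e-12) next
    x <- solve(M, b[combs[, k]])
    if (all(A %*% x <= b + 1e-9)) verts[[length(verts) + 1L]] <- x
  }
  if (!length(verts)) return(NULL)
  V <- do.call(rbind, verts)
  gs <- as.numeric(V %*% y)
  gmax <- max(gs)
  best <- V[gs >= gmax - 1e-9, , drop = FALSE]
  # parsimonious tie-break: minimum total absolute flux over all reactions
  totflux <- function(x) {
    vr <- x[1]; vo <- x[2]; va <- x[3]
    vglc <- vr + vo; vo2 <- 3 * vr + 2 * va; vace <- va - 2 * vo
    vco2 <- 3 * vr + 2 * va
    g <- sum(y * x)
    vglc + vo2 + abs(vace) + vco2 + vr + vo + va + g
  }
  tf <- apply(best, 1L, totflux)
  x <- best[which.min(tf), ]
  list(g = gmax, n_opt = nrow(unique(round(best, 9))),
       v_exchange = c(glc = x[1] + x[2], o2 = 3 * x[1] + 2 * x[3],
                      ace = x[3] - 2 * x[2]))
}

# Pure-R composition of one steady-state sub-step, mirroring the order of
# the compiled fused loop: diffusion sweep, active import, then
# availability-constrained table FBA at every occupied cell site.
r_reference_substep <- function(lat, table, dtau = lat$config$dtau) {
  lat <- diffusion_step(lat, dtau)
  lat <- active_uptake_step(lat, dtau)
  rho <- colonyFBA:::rho_total(lat)
  cells <- which(lat$site_type == colonyFBA:::SITE_CELL & rho > 1e-14)
  dims <- lat$config$dims
  for (idx in cells) {
    i0 <- arrayInd(idx, dims) - 1L
    cons <- exchange_constraints(lat, i0, dtau = dtau)
    for (st in names(lat$rho)) {
      if (lat$rho[[st]][idx] < 1e-14) next
      sol <- query_flux_table(table, st, cons)
      lat <- apply_exchange_fluxes(lat, i0, sol, dtau, state_id = st)
    }
  }
  lat
}

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y)) / max(abs(y), 1e-300), tol)
}
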