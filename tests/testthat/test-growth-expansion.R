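test_that("exponential growth multiplies each state by exp(g t)", {
  lat <- small_colony()
  idx <- colonyFBA:::site_index(lat, c(5, 5, 3))
  # g t = ln 2 doubles the occupancy
  lat$growth$glc[idx] <- log(2)
  out <- growth_step(lat, t_grow = 3600)
  expect_equal(out$rho$glc[idx], 2 * lat$rho$glc[idx])
  # g = 0 leaves everything unchanged
  lat$growth$glc[idx] <- 0
  expect_equal(growth_step(lat, 3600)$rho$glc, lat$rho$glc)
  # 0.1 * exp(0.693 * 60/3600) = 0.101161
  lat$rho$glc[idx] <- 0.1
  lat$growth$glc[idx] <- 0.693
  out <- growth_step(lat, t_grow = 60)
  expect_equal(out$rho$glc[idx], 0.1 * exp(0.693 / 60))
  expect_equal(out$rho$glc[idx], 0.10116, tolerance = 1e-4)
})

test_that("face transfers move 1/12 of the over-filling difference", {
  expect_equal(expansion_transfer(0.77, 0.0, 0.65), 0.01)
  expect_equal(expansion_transfer(0.5, 0.3, 0.65), 0)
  expect_equal(expansion_transfer(0.9, 0.9, 0.65), 0)
  expect_equal(expansion_transfer(0.7, 0.9, 0.65),
               -expansion_transfer(0.9, 0.7, 0.65))
})

make_expansion_lattice <- function(center_rho, dims = c(5, 5, 5),
                                   agar_layers = 1L) {
  cfg <- lattice_config(dims = dims, lambda = 1e-5,
                        agar_height = agar_layers * 1e-5, dtau = 1e-3,
                        t_ss = 1, t_grow = 60)
  lat <- build_lattice(cfg, default_substrates())
  ctr <- as.integer(dims[1:2] %/% 2)
  lat <- seed_colony(lat, "glc", 0.65, c(ctr[1], ctr[2], agar_layers))
  idx <- colonyFBA:::site_index(lat, c(ctr[1], ctr[2], agar_layers))
  lat$rho$glc[idx] <- center_rho
  attr(lat, "center") <- c(ctr, agar_layers)
  lat
}

test_that("relaxation spreads an over-filled site, conserving volume exactly", {
  lat <- make_expansion_lattice(0.95)
  tot0 <- sum(lat$rho$glc)
  res <- relax_expansion(lat)
  out <- res$lattice
  expect_lt(abs(sum(out$rho$glc) - tot0) / tot0, 1e-12)
  expect_lte(max(colonyFBA:::rho_total(out)),
             lat$config$rho_max + lat$config$delta_rho)
  expect_gt(res$report$sweeps, 0)
  expect_gt(res$report$converted, 0)          # air sites were colonized
  # nothing enters the agar
  expect_true(all(out$rho$glc[out$site_type == 1L] == 0))
  # lateral symmetry of the spread around the seed column
  expect_equal(out$rho$glc[2, 3, 2], out$rho$glc[4, 3, 2])
  expect_equal(out$rho$glc[3, 2, 2], out$rho$glc[3, 4, 2])
})

test_that("a colony exactly at rho_max needs zero sweeps", {
  lat <- make_expansion_lattice(0.65)
  res <- relax_expansion(lat)
  expect_identical(res$report$sweeps, 0L)
  expect_equal(res$lattice$rho$glc, lat$rho$glc)
})

test_that("expansion keeps the colony face-connected", {
  lat <- make_expansion_lattice(1.4)
  out <- relax_expansion(lat)$lattice
  cells <- which(out$site_type == 2L, arr.ind = TRUE)
  # every cell site has a face neighbor that is also a cell site
  # (single-site colonies excepted)
  if (nrow(cells) > 1L) for (r in seq_len(nrow(cells))) {
    nb <- 0L
    for (dshift in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                        c(0,0,1), c(0,0,-1))) {
      p <- cells[r, ] + dshift
      if (any(p < 1) || any(p > dim(out$site_type))) next
      if (out$site_type[p[1], p[2], p[3]] == 2L) nb <- nb + 1L
    }
    expect_gt(nb, 0L)
  }
})

test_that("mixed states and intracellular pools move with donor proportions", {
  lat <- make_expansion_lattice(0.3)
  ctr <- attr(lat, "center")
  idx <- colonyFBA:::site_index(lat, ctr)
  lat <- seed_colony(lat, "ace", 0.001, ctr)  # create the second state field
  lat$rho$glc[idx] <- 0.6                     # 3:1 mixture, over-filled total
  lat$rho$ace[idx] <- 0.2
  lat$intra$glc[idx] <- 8e-4
  tot_int <- sum(lat$intra$glc)
  res <- relax_expansion(lat)
  out <- res$lattice
  # receiving sites carry the donor's 3:1 state ratio exactly
  recv <- which(out$rho$glc > 0 & seq_along(out$rho$glc) != idx)
  for (i in recv) expect_equal(out$rho$ace[i] / out$rho$glc[i], 1 / 3)
  # intracellular pool conserved globally and transported with volume
  expect_lt(abs(sum(out$intra$glc) - tot_int) / tot_int, 1e-12)
  moved_vol <- 1 - out$rho$glc[idx] / 0.6
  expect_equal(1 - out$intra$glc[idx] / 8e-4, moved_vol, tolerance = 1e-10)
})

test_that("global conservation holds across random over-filled colonies", {
  set.seed(31)
  for (rep in 1:4) {
    lat <- make_expansion_lattice(0.65, dims = c(7, 7, 6))
    mask <- lat$site_type == 2L | lat$site_type == 0L
    bump <- array(0, dim = lat$config$dims)
    # random over-filling on a few surface sites
    picks <- sample(which(lat$site_type == 2L), 1)
    lat$rho$glc[picks] <- runif(length(picks), 0.7, 1.6)
    tot0 <- sum(lat$rho$glc)
    out <- relax_expansion(lat)$lattice
    expect_lt(abs(sum(out$rho$glc) - tot0) / tot0, 1e-12)
    expect_true(all(out$rho$glc >= 0))
  }
})
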