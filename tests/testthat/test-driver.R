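test_that("the compiled steady-state loop matches the R kernel composition", {
  lat <- small_colony(dims = c(6, 6, 6), agar_layers = 2, seed_rho = 0.5,
                      dtau = 2e-3)
  lat <- seed_colony(lat, "ace", 0.1, c(3, 3, 2))
  # a short fixed window through both paths
  nsub <- 4L
  fused <- steady_state_cycle(lat, toy_table5, dtau = lat$config$dtau,
                              t_ss = nsub * lat$config$dtau)
  ref <- lat
  for (i in seq_len(nsub)) ref <- r_reference_substep(ref, toy_table5)
  for (nm in names(lat$ext))
    expect_equal(fused$ext[[nm]], ref$ext[[nm]], tolerance = 1e-12)
  expect_equal(fused$intra$glc, ref$intra$glc, tolerance = 1e-12)
  for (st in names(lat$rho))
    expect_equal(fused$growth[[st]], ref$growth[[st]], tolerance = 1e-12)
})

test_that("with no cells the cycle is pure diffusion toward the boundary values", {
  cfg <- lattice_config(dims = c(6, 6, 8), agar_height = 3e-5, dtau = 2e-3,
                        t_ss = 0.5, t_grow = 60)
  lat <- build_lattice(cfg)
  lat <- seed_colony(lat, "glc", 1e-9, c(3, 3, 3))   # negligible occupancy
  lat$ext$glc[3, 3, 2] <- 0                          # dent the agar field
  out <- steady_state_cycle(lat, toy_table5)
  expect_gt(out$ext$glc[3, 3, 2], 0)                 # relaxing back up
  expect_true(all(out$ext$o2[out$site_type == 0L] == 2.6e-4))
})

test_that("a seeded site depletes local oxygen and glucose and records growth", {
  lat <- small_colony(dims = c(8, 8, 8), agar_layers = 3, seed_rho = 0.65,
                      dtau = 2e-3)
  out <- lat
  for (i in 1:5) out <- steady_state_cycle(out, toy_table5, t_ss = 1)
  idx <- colonyFBA:::site_index(out, c(4, 4, 3))
  expect_lt(out$ext$o2[idx], 2.6e-4)
  expect_lt(out$ext$glc[idx], 1.39e-2)
  expect_gt(out$growth$glc[idx], 0)
  expect_gt(out$exch$glc$glc[idx], 0)      # glucose uptake recorded
  expect_gt(out$exch$glc$o2[idx], 0)       # oxygen uptake recorded
})

test_that("projection extrapolates drawdown linearly and floors at zero", {
  lat <- small_colony(dims = c(6, 6, 6), agar_layers = 2, dtau = 2e-3)
  lat <- steady_state_cycle(lat, toy_table5, t_ss = 0.2)
  rates <- attr(lat, "rates")
  # zero rates: no change
  attr(lat, "rates") <- lapply(rates, function(r) r * 0)
  out0 <- project_consumption(lat, t_grow = 60)
  expect_equal(out0$ext, lat$ext)
  # constant drawdown r over t_grow - t_ss seconds removes (t_grow-t_ss) r
  r0 <- lapply(rates, function(r) r * 0)
  idx <- colonyFBA:::site_index(lat, c(3, 3, 2))
  r0$ace[idx] <- -1e-6
  lat$ext$ace[idx] <- 1e-3
  attr(lat, "rates") <- r0
  out <- project_consumption(lat, t_grow = 60 + lat$config$t_ss)
  expect_equal(out$ext$ace[idx], 1e-3 - 60 * 1e-6)
  # overshoot is floored and the deficit logged
  lat$ext$ace[idx] <- 1e-6
  out2 <- project_consumption(lat, t_grow = 60 + lat$config$t_ss)
  expect_equal(out2$ext$ace[idx], 0)
  expect_gt(attr(out2, "projection_deficit"), 0)
  # rising fields are left to the relaxation window (no projection)
  r0$ace[idx] <- +1e-6
  lat$ext$ace[idx] <- 1e-3
  attr(lat, "rates") <- r0
  out3 <- project_consumption(lat, t_grow = 60 + lat$config$t_ss)
  expect_equal(out3$ext$ace[idx], 1e-3)
})

test_that("colony summaries use the stated conventions", {
  lat <- small_colony(dims = c(12, 12, 8), agar_layers = 2, seed_rho = 0.65)
  s <- summarize_colony(lat, time = 0)
  expect_equal(s$radius, 0)                       # single-site colony
  expect_equal(s$height, lat$config$lambda)
  expect_equal(s$biomass, 0.65 * 1e-15 / 1e-18 * 2.58e-13)
  # hand-built two-region exchange map: half the biomass secretes at 2.0,
  # half takes up at 1.0 -> average production 1.0, average uptake 0.5
  idx2 <- colonyFBA:::site_index(lat, c(7, 6, 2))
  lat$site_type[idx2] <- 2L
  lat$rho$glc[idx2] <- 0.65
  ex <- array(0, dim = lat$config$dims)
  ex[colonyFBA:::site_index(lat, c(6, 6, 2))] <- -2.0
  ex[idx2] <- 1.0
  lat$exch <- list(glc = list(glc = ex * 0, o2 = ex * 0, ace = ex))
  s2 <- summarize_colony(lat, time = 1)
  expect_equal(s2$production_ace, 1.0)
  expect_equal(s2$uptake_ace, 0.5)
  # oxygen penetration against a synthetic exponential profile with a
  # 20 um decay length: the 1% point sits at 92.1 um from the edge
  lat3 <- small_colony(dims = c(40, 9, 6), agar_layers = 2, seed_rho = 0.65)
  zb <- 3L; sy <- 5L
  lat3$rho$glc[, , ] <- 0
  lat3$site_type[lat3$site_type == 0L] <- 0L
  for (x in 3:36) {
    i <- colonyFBA:::site_index(lat3, c(x, 4, 2))
    lat3$site_type[i] <- 2L
    lat3$rho$glc[i] <- 0.65
  }
  edge_x <- 36
  for (x in 3:36) {
    depth <- (edge_x - x) * 10   # um from the colony edge
    lat3$ext$o2[x + 1, sy, zb] <- 2.6e-4 * exp(-depth / 20)
  }
  lat3$seed <- c(4L, 4L, 2L)
  s3 <- summarize_colony(lat3, time = 0)
  expect_lt(abs(s3$o2_penetration * 1e6 - (-20 * log(0.01))),
            10 + 1e-9)   # within one lattice spacing of 92.1 um
  # an empty colony summarizes to zeros
  empty <- build_lattice(lattice_config(dims = c(6, 6, 6), agar_height = 2e-5))
  s4 <- summarize_colony(empty, time = 0)
  expect_equal(s4$radius, 0); expect_equal(s4$biomass, 0)
})

test_that("radial-rate fits recover synthetic expansion laws", {
  # exact linear series at 0.011 um/s
  t_hr <- seq(10, 20, by = 0.25)
  r_lin <- 1e-4 + 0.011e-6 * 3600 * (t_hr - 10)
  fit <- fit_radial_rate(data.frame(time = t_hr, radius = r_lin))
  expect_equal(fit$rate_um_s, 0.011, tolerance = 1e-9)
  expect_gt(fit$r_squared, 0.999999)
  # constant radius: zero slope
  fit0 <- fit_radial_rate(data.frame(time = t_hr, radius = rep(2e-4, length(t_hr))))
  expect_equal(fit0$rate_um_s, 0)
  # exponential-to-linear series with a 15 h breakpoint
  tt <- seq(0.5, 30, by = 0.1)
  g <- 0.35
  r0 <- 5e-6
  rb <- r0 * exp(g * 15)
  slope <- g * rb                      # continuous first derivative
  rr <- ifelse(tt <= 15, r0 * exp(g * tt), rb + slope * (tt - 15))
  fit2 <- fit_radial_rate(data.frame(time = tt, radius = rr),
                          window = c(20, 30))
  expect_false(is.na(fit2$transition_hr))
  expect_lt(abs(fit2$transition_hr - 15), 1)
  expect_error(fit_radial_rate(data.frame(time = 1:3, radius = 1:3 * 1e-5)),
               "5 summary")
})

test_that("identical configurations give bit-identical trajectories", {
  run_once <- function() {
    lat <- small_colony(dims = c(8, 8, 8), agar_layers = 2, seed_rho = 0.65,
                        dtau = 2e-3)
    simulate_colony(lat, toy_table5, default_switching_model("s"), hours = 0.2)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$summaries, b$summaries)
  expect_identical(a$lattice$ext, b$lattice$ext)
  expect_identical(a$lattice$rho, b$lattice$rho)
})

test_that("halving the relaxation window barely moves the converged fields", {
  lat <- small_colony(dims = c(8, 8, 8), agar_layers = 2, seed_rho = 0.65,
                      dtau = 2e-3)
  # settle into quasi-steady state first
  for (i in 1:3) lat <- steady_state_cycle(lat, toy_table5, t_ss = 1)
  full <- steady_state_cycle(lat, toy_table5, t_ss = 1)
  half <- steady_state_cycle(lat, toy_table5, t_ss = 0.5)
  for (nm in names(lat$ext)) {
    scale <- max(full$ext[[nm]], 1e-12)
    expect_lt(max(abs(full$ext[[nm]] - half$ext[[nm]])) / scale, 1e-3)
  }
})
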