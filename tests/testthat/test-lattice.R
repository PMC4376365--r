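test_that("physical constants and bounds evaluate to their closed forms", {
  # Henry's law: lab-air oxygen
  expect_equal(henry_concentration(0.2, 0.0013), 2.6e-4)
  expect_equal(henry_concentration(0, 0.0013), 0)
  expect_equal(henry_concentration(1.0, 0.0013), 1.3e-3)
  # stencil bound for the fastest-diffusing species
  expect_equal(stability_bound(1e-5, 2.6e-9), 1e-10 / 5.2e-9)
  expect_equal(stability_bound(2e-5, 2.6e-9), 4 * stability_bound(1e-5, 2.6e-9))
  expect_equal(stability_bound(1e-5, 7.8e-10), 1e-10 / 1.56e-9, tolerance = 1e-12)
  # packed-site cell count
  expect_equal(cells_per_site(0.65, 1e-5, 1e-18), 650)
  expect_equal(cells_per_site(0.74, 1e-5, 1e-18), 740)
  expect_equal(cells_per_site(0, 1e-5, 1e-18), 0)
})

test_that("the headline geometry types a 96-layer agar slab under air", {
  cfg <- lattice_config()   # 3.2 x 3.2 x 1.92 mm at 10 um
  expect_identical(cfg$dims, c(320L, 320L, 192L))
  expect_identical(cfg$nz_agar, 96L)
  lat <- build_lattice(cfg, substrates = list())   # typing only
  n_agar <- sum(lat$site_type == 1L)
  expect_identical(n_agar, 320L * 320L * 96L)
  expect_identical(sum(lat$site_type == 0L) + n_agar, as.integer(prod(cfg$dims)))
  rm(lat)
})

test_that("field initialization follows the boundary prescription", {
  cfg <- lattice_config(dims = c(6, 6, 6), agar_height = 2e-5)
  lat <- build_lattice(cfg)
  agar <- lat$site_type == 1L
  air <- lat$site_type == 0L
  expect_true(all(lat$ext$glc[agar] == 1.39e-2))
  expect_true(all(lat$ext$glc[air] == 0))
  expect_true(all(lat$ext$o2[air] == 2.6e-4))
  expect_true(all(lat$ext$ace == 0))
  expect_true(all(lat$intra$glc == 0))
  expect_length(lat$rho, 0L)
  # determinism: identical configs give identical lattices
  expect_identical(lat, build_lattice(cfg))
})

test_that("unstable sub-steps are rejected at construction", {
  cfg <- lattice_config(dims = c(6, 6, 6), agar_height = 2e-5, dtau = 0.05)
  expect_error(build_lattice(cfg), "unstable")
  # 0.05 s > lambda^2/(2 D_O2) = 1.92e-2 s
  expect_gt(0.05, stability_bound(1e-5, 2.6e-9))
})

test_that("seeding converts one surface air site and books the exact volume", {
  cfg <- lattice_config(dims = c(7, 7, 7), agar_height = 3e-5)
  lat <- build_lattice(cfg)
  # single-cell equivalent: V_cell / lambda^3 = 1e-18 / 1e-15
  lat <- seed_colony(lat, "glc", 1e-3, c(3, 3, 3))
  idx <- colonyFBA:::site_index(lat, c(3, 3, 3))
  expect_identical(lat$site_type[idx], 2L)
  expect_equal(lat$rho$glc[idx], 1e-3)
  expect_equal(sum(lat$rho$glc) * cfg$lambda^3, 1e-3 * cfg$lambda^3)
  # aqueous substrates reset, volatile to air value
  expect_equal(lat$ext$glc[idx], 0)
  expect_equal(lat$ext$o2[idx], 2.6e-4)
  # a second state at the same site accumulates
  lat <- seed_colony(lat, "ace", 2e-3, c(3, 3, 3))
  expect_equal(lat$rho$ace[idx], 2e-3)
  expect_equal(sum(vapply(lat$rho, `[`, 0, idx)), 3e-3)
})

test_that("invalid seeds are rejected", {
  cfg <- lattice_config(dims = c(7, 7, 7), agar_height = 3e-5)
  lat <- build_lattice(cfg)
  expect_error(seed_colony(lat, "glc", 0.1, c(3, 3, 1)), "agar")
  expect_error(seed_colony(lat, "glc", 0.1, c(3, 3, 5)), "surface")
  expect_error(seed_colony(lat, "glc", 0.9, c(3, 3, 3)))
  # at the packing cap is allowed
  expect_silent(seed_colony(lat, "glc", 0.65, c(3, 3, 3)))
})

test_that("config invariants are enforced", {
  expect_error(lattice_config(rho_max = 1.2), "rho_max")
  expect_error(lattice_config(delta_rho = 0.7), "delta_rho")
  expect_error(lattice_config(t_ss = 120, t_grow = 60), "t_ss")
  expect_error(lattice_config(dims = c(4, 4, 4), agar_height = 4e-5), "agar")
  expect_error(substrate_spec("x", 1e-9, 1e-9, transport = "ACTIVE"),
               "uptake_vmax")
  expect_error(substrate_spec("x", 1e-9, 1e-9, transport = "PASSIVE",
                              uptake_vmax = 1, uptake_km = 1e-3),
               "PASSIVE")
})
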