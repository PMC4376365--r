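test_that("toy-model optima agree with exhaustive vertex enumeration", {
  set.seed(42)
  cases <- list(c(10.4, 31.8, 16), c(10.4, 0, 16), c(0, 31.8, 16),
                c(0, 0, 0), c(10.4, 0, 0), c(5, 10, 2))
  for (i in 1:10) cases[[length(cases) + 1L]] <-
    c(runif(1, 0, 10.4), runif(1, 0, 31.8), runif(1, 0, 16))
  for (cs in cases) {
    cons <- c(glc = cs[1], o2 = cs[2], ace = cs[3])
    sol <- solve_fba(toy_model, constraints = cons)
    ora <- toy_vertex_oracle(cs[1], cs[2], cs[3])
    expect_equal(sol$g, ora$g, tolerance = 1e-8)
    if (ora$n_opt == 1L)
      expect_equal(sol$v_exchange, ora$v_exchange, tolerance = 1e-7)
  }
})

test_that("aerobic growth outpaces anaerobic overflow, which secretes acetate", {
  aer <- solve_fba(toy_model, constraints = c(glc = 10.4, o2 = 31.8, ace = 16))
  ana <- solve_fba(toy_model, constraints = c(glc = 10.4, o2 = 0, ace = 16))
  expect_gt(aer$g, ana$g)
  expect_gt(ana$g, 0)
  expect_gte(aer$v_exchange[["ace"]], 0)       # no secretion when oxygen is ample
  expect_lt(ana$v_exchange[["ace"]], 0)        # overflow secretes
  # acetate growth requires oxygen
  expect_gt(solve_fba(toy_model, constraints = c(glc = 0, o2 = 31.8, ace = 16))$g, 0)
  expect_equal(solve_fba(toy_model, constraints = c(glc = 0, o2 = 0, ace = 16))$g, 0)
  # doubling time at full availability lies in the fast-growth regime
  dbl_min <- log(2) / aer$g * 60
  expect_gt(dbl_min, 40); expect_lt(dbl_min, 50)
})

test_that("state overrides only tighten and forbid the right exchanges", {
  sts <- acetate_switch_states()
  s_glc <- solve_fba(toy_model, sts[[1]], c(glc = 10.4, o2 = 31.8, ace = 16))
  expect_equal(s_glc$v_exchange[["ace"]], 0)   # glc state cannot eat acetate
  s_ace <- solve_fba(toy_model, sts[[2]], c(glc = 10.4, o2 = 31.8, ace = 16))
  expect_equal(s_ace$v_exchange[["glc"]], 0)   # ace state cannot eat glucose
  expect_gt(s_ace$g, 0)
})

test_that("infeasible problems report zero growth and a flag", {
  S <- matrix(c(1), 1, 1, dimnames = list("M", "R1"))
  bad <- metabolic_model(S, lb = c(R1 = 1), ub = c(R1 = 2),
                         objective = "R1", exchanges = c(m = "R1"))
  sol <- solve_fba(bad)
  expect_false(sol$feasible)
  expect_equal(sol$g, 0)
  expect_true(all(sol$v_exchange == 0))
})

test_that("repeated solves are bit-identical (parsimonious tie-breaking)", {
  cons <- c(glc = 7.3, o2 = 12.1, ace = 4.4)
  a <- solve_fba(toy_model, constraints = cons)
  b <- solve_fba(toy_model, constraints = cons)
  expect_identical(a, b)
})

test_that("growth is non-decreasing in every availability component", {
  set.seed(5)
  for (i in 1:12) {
    base <- c(glc = runif(1, 0, 9), o2 = runif(1, 0, 28), ace = runif(1, 0, 14))
    g0 <- solve_fba(toy_model, constraints = base)$g
    for (s in names(base)) {
      up <- base; up[s] <- up[s] + 1
      expect_gte(solve_fba(toy_model, constraints = up)$g + 1e-9, g0)
    }
  }
})

test_that("crowding redirects the fast aerobic optimum per the coefficient regime", {
  # costly respiration: mixed respiration/overflow optimum secretes acetate
  mc <- build_toy_model(crowding = TRUE)
  s <- solve_fba(mc, constraints = c(glc = 10.4, o2 = 31.8, ace = 16),
                 crowding = TRUE)
  expect_lt(s$v_exchange[["ace"]], 0)
  expect_lt(s$g, 0.9071)
  expect_lte(sum(mc$crowding * abs(s$fluxes)), 1 + 1e-8)
  # cheap respiration: pure respiration stays optimal, nothing secreted
  mc2 <- build_toy_model(crowding = TRUE,
                         crowding_coefficients = c(RESP = 0.05, OVFL = 0.02,
                                                   ACEOX = 0.1))
  s2 <- solve_fba(mc2, constraints = c(glc = 10.4, o2 = 31.8, ace = 16),
                  crowding = TRUE)
  expect_gte(s2$v_exchange[["ace"]], 0)
  expect_equal(s2$g, 0.9071, tolerance = 1e-6)
})

test_that("availability constraints convert concentrations with the stated units", {
  lat <- small_colony(dims = c(6, 6, 6), agar_layers = 2, seed_rho = 0.65)
  idx <- colonyFBA:::site_index(lat, c(3, 3, 2))
  lat$ext$o2[idx] <- 2.6e-4
  lat$ext$glc[idx] <- 0
  lat$intra$glc[idx] <- 1e-6
  lat$ext$ace[idx] <- 0
  cons <- exchange_constraints(lat, c(3, 3, 2), dtau = 1e-3)
  # passive O2: 2.6e-4 M * V_cell/(m_cell * 1 ms) = 3628.8 -> capped at 31.8
  raw_o2 <- 2.6e-4 * 1e-15 / (2.58e-13 * 1e-3) * 3.6e6
  expect_equal(raw_o2, 3628.8, tolerance = 1e-3)
  expect_equal(cons[["o2"]], 31.8)
  # active glucose: (1e-6/0.65) M equivalent -> 21.5, capped at 10.4
  raw_glc <- 1e-6 / 0.65 * 1e-15 / (2.58e-13 * 1e-3) * 3.6e6
  expect_equal(raw_glc, 21.47, tolerance = 1e-3)
  expect_equal(cons[["glc"]], 10.4)
  expect_equal(cons[["ace"]], 0)
})

test_that("applying exchange fluxes moves the exact concentration increments", {
  lat <- small_colony(dims = c(6, 6, 6), agar_layers = 2, seed_rho = 0.65)
  idx <- colonyFBA:::site_index(lat, c(3, 3, 2))
  # zero fluxes: fields unchanged, growth recorded
  sol0 <- colonyFBA:::flux_solution(0.5, c(glc = 0, o2 = 0, ace = 0), TRUE)
  out0 <- apply_exchange_fluxes(lat, c(3, 3, 2), sol0, dtau = 1e-3)
  expect_equal(out0$ext, lat$ext)
  expect_equal(out0$growth$glc[idx], 0.5)
  # acetate secretion -3.5 mmol/gDwt/hr at rho = 0.65 for 1 ms:
  # 3.5e-3/3600 mol/g/s * 2.58e-13 g * 1e-3 s / 1e-15 L * 0.65 = 1.6299e-7 M
  sol <- colonyFBA:::flux_solution(0.2, c(glc = 0, o2 = 0, ace = -3.5), TRUE)
  out <- apply_exchange_fluxes(lat, c(3, 3, 2), sol, dtau = 1e-3)
  d_ace <- 3.5e-3 / 3600 * 2.58e-13 * 1e-3 / 1e-15 * 0.65
  expect_equal(d_ace, 1.629875e-7, tolerance = 1e-6)
  expect_equal(out$ext$ace[idx] - lat$ext$ace[idx], d_ace)
  # uptake exactly at the availability constraint lands the pool on zero
  # (small enough that the kinetic cap does not bind)
  lat$intra$glc[idx] <- 1e-7
  cons <- exchange_constraints(lat, c(3, 3, 2), dtau = 1e-3)
  solg <- colonyFBA:::flux_solution(0.2, c(glc = cons[["glc"]], o2 = 0, ace = 0), TRUE)
  outg <- apply_exchange_fluxes(lat, c(3, 3, 2), solg, dtau = 1e-3)
  expect_equal(outg$intra$glc[idx], 0, tolerance = 1e-20)
})

test_that("lookup tables are node-exact and multilinear between nodes", {
  # every node reproduces the direct solve bit-for-bit
  ax <- toy_table5$axes
  for (k in c(1L, 2L)) for (trial in 1:6) {
    set.seed(trial + 10 * k)
    node <- vapply(ax, function(a) sample(a, 1), 0)
    q <- query_flux_table(toy_table5, toy_states[[k]]$id, node)
    d <- solve_fba(toy_model, toy_states[[k]], node)
    expect_equal(q$g, d$g, tolerance = 1e-10)
    expect_equal(q$v_exchange, d$v_exchange, tolerance = 1e-9)
  }
  # the (0,0,0) node carries zero growth in every state
  for (k in c(1L, 2L))
    expect_equal(query_flux_table(toy_table5, toy_states[[k]]$id,
                                  c(glc = 0, o2 = 0, ace = 0))$g, 0)
  # midpoint on one axis = mean of the flanking node solutions
  c1 <- c(glc = 2.6, o2 = 0, ace = 0); c2 <- c(glc = 5.2, o2 = 0, ace = 0)
  mid <- c(glc = 3.9, o2 = 0, ace = 0)
  g1 <- query_flux_table(toy_table5, "glc", c1)$g
  g2 <- query_flux_table(toy_table5, "glc", c2)$g
  expect_equal(query_flux_table(toy_table5, "glc", mid)$g, (g1 + g2) / 2)
  # out-of-range queries clamp to the axis range, and interpolated uptake
  # never exceeds the queried availability
  q <- query_flux_table(toy_table5, "glc", c(glc = 99, o2 = 99, ace = 99))
  expect_equal(q$g, query_flux_table(toy_table5, "glc",
                                     c(glc = 10.4, o2 = 31.8, ace = 16))$g)
  q2 <- query_flux_table(toy_table5, "glc", c(glc = 1.2, o2 = 31.8, ace = 0))
  expect_lte(q2$v_exchange[["glc"]], 1.2 + 1e-12)
})

test_that("the fermentation screen ranks secreted products", {
  scr <- fermentation_screen(toy_model, aerobic = FALSE)
  expect_identical(scr$reaction[1], "EX_ace")    # sole anaerobic product
  expect_equal(scr$flux[1], 20.8, tolerance = 1e-6)
  expect_false("EX_co2" %in% scr$reaction)
  aer <- fermentation_screen(toy_model, aerobic = TRUE)
  expect_true("EX_co2" %in% aer$reaction)
  expect_false("EX_ace" %in% aer$reaction)
  # nothing to eat, nothing secreted
  none <- build_toy_model()
  none$lb["EX_glc"] <- 0
  expect_identical(nrow(fermentation_screen(none, aerobic = FALSE)), 0L)
})
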