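test_that("switching rates evaluate the clamped quadratic polynomial", {
  sm <- switching_model(list(
    list(from = "a", to = "b", subs = c("glc", "ace"),
         alpha = c(0, 2, 0, 100, 0, 0))), time_unit = "s")
  # 2 * 0.003 + 100 * 9e-6 = 6.9e-3
  expect_equal(switching_rate(sm, "a->b", 0.003, 0.42), 6.9e-3)
  zero <- switching_model(list(
    list(from = "a", to = "b", subs = c("glc", "ace"), alpha = rep(0, 6))),
    time_unit = "s")
  expect_equal(switching_rate(zero, "a->b", 0.1, 0.2), 0)
  neg <- switching_model(list(
    list(from = "a", to = "b", subs = c("glc", "ace"),
         alpha = c(-1, 0, 0, 0, 0, 0))), time_unit = "s")
  expect_equal(switching_rate(neg, "a->b", 0.5, 0.5), 0)  # outer clamp
  expect_error(switching_rate(sm, "b->a", 0, 0), "unknown")
  expect_error(switching_rate(sm, "a->b", -0.1, 0))
  # continuity across the clamp boundary
  fine <- seq(0, 1e-3, length.out = 200)
  r <- switching_rate(switching_model(list(
    list(from = "a", to = "b", subs = c("glc", "ace"),
         alpha = c(-1e-4, 1, 0, 0, 0, 0))), "s"), "a->b", fine, 0)
  expect_true(all(r >= 0) && max(abs(diff(r))) < 1e-5)
})

make_two_state_lattice <- function(rho1 = 0.3, rho2 = 0.1) {
  lat <- small_colony(dims = c(6, 6, 6), agar_layers = 2, seed_rho = 0.3)
  ctr <- c(3L, 3L, 2L)
  lat <- seed_colony(lat, "ace", 1e-6, ctr)
  idx <- colonyFBA:::site_index(lat, ctr)
  lat$rho$glc[idx] <- rho1
  lat$rho$ace[idx] <- rho2
  list(lat = lat, idx = idx)
}

test_that("the regulation step conserves per-site state totals exactly", {
  x <- make_two_state_lattice()
  sm <- default_switching_model("s")
  tot0 <- x$lat$rho$glc + x$lat$rho$ace
  out <- regulation_step(x$lat, sm, t_grow = 60)
  expect_equal(out$rho$glc + out$rho$ace, tot0)
  expect_true(all(out$rho$glc >= 0) && all(out$rho$ace >= 0))
})

test_that("first-order switching moves the Euler increment", {
  x <- make_two_state_lattice(rho1 = 0.6, rho2 = 0)
  lat <- x$lat; idx <- x$idx
  lat$rho$ace[idx] <- 0
  # one transition at fixed rate 1e-4 s^-1 over 60 s: 0.6 * 6e-3 = 0.0036
  sm <- switching_model(list(
    list(from = "glc", to = "ace", subs = c("glc", "ace"),
         alpha = c(1e-4, 0, 0, 0, 0, 0))), time_unit = "s")
  out <- regulation_step(lat, sm, t_grow = 60)
  expect_equal(out$rho$glc[idx], 0.5964)
  expect_equal(out$rho$ace[idx], 0.0036)
  # zero rates: untouched
  zero <- switching_model(list(
    list(from = "glc", to = "ace", subs = c("glc", "ace"), alpha = rep(0, 6))),
    time_unit = "s")
  out0 <- regulation_step(lat, zero, t_grow = 60)
  expect_equal(out0$rho$glc, lat$rho$glc)
})

test_that("symmetric rates make the even split a fixed point", {
  x <- make_two_state_lattice(rho1 = 0.2, rho2 = 0.2)
  sm <- switching_model(list(
    list(from = "glc", to = "ace", subs = c("glc", "ace"),
         alpha = c(5e-4, 0, 0, 0, 0, 0)),
    list(from = "ace", to = "glc", subs = c("glc", "ace"),
         alpha = c(5e-4, 0, 0, 0, 0, 0))), time_unit = "s")
  out <- regulation_step(x$lat, sm, t_grow = 60)
  expect_equal(out$rho$glc[x$idx], 0.2)
  expect_equal(out$rho$ace[x$idx], 0.2)
})

test_that("overdraining transitions are capped with mass restored to the donor", {
  x <- make_two_state_lattice(rho1 = 0.3, rho2 = 0)
  lat <- x$lat; idx <- x$idx
  lat$rho$ace[idx] <- 0
  sm <- switching_model(list(
    list(from = "glc", to = "ace", subs = c("glc", "ace"),
         alpha = c(0.05, 0, 0, 0, 0, 0))), time_unit = "s")  # k t = 3 > 1
  expect_warning(out <- regulation_step(lat, sm, t_grow = 60), "Euler")
  expect_equal(out$rho$glc[idx], 0)           # fully drained, not negative
  expect_equal(out$rho$ace[idx], 0.3)         # all mass arrived
})

test_that("the batch model reduces to clean exponentials when decoupled", {
  p <- default_batch_params()
  none <- switching_model(list(
    list(from = "glc", to = "ace", subs = c("glc", "ace"), alpha = rep(0, 6)),
    list(from = "ace", to = "glc", subs = c("glc", "ace"), alpha = rep(0, 6))),
    time_unit = "hr")
  p$switching <- none
  glc <- simulate_batch(p, c(M_glc = 0.01, M_ace = 0, glc = 1, ace = 0),
                        duration = 2)
  expect_equal(tail(glc$M_glc, 1), 0.01 * exp(0.9 * 2), tolerance = 1e-6)
  expect_true(all(diff(glc$glc) < 0))
  ace <- simulate_batch(p, c(M_glc = 0, M_ace = 0.01, glc = 0, ace = 1),
                        duration = 2)
  expect_equal(tail(ace$M_ace, 1), 0.01 * exp(0.4 * 2), tolerance = 1e-6)
  expect_equal(tail(ace$M_glc, 1), 0)
})

test_that("the mixed culture shows the diauxic acetate switch", {
  p <- default_batch_params()
  out <- simulate_batch(p, c(M_glc = 0.01, M_ace = 0, glc = 1.39e-2,
                             ace = 2e-3), duration = 12)
  t_exhaust <- out$time[min(which(out$glc <= 0))]
  expect_true(is.finite(t_exhaust))
  # acetate-state biomass appears essentially only after glucose runs out
  before <- max(out$M_ace[out$time <= t_exhaust - 0.5])
  after <- max(out$M_ace)
  expect_gt(after, 50 * max(before, 1e-12))
  # acetate rises during overflow, then falls while being consumed
  expect_gt(max(out$ace), 2e-3)
  expect_lt(tail(out$ace, 1), max(out$ace) / 10)
  # concentrations stay floored at zero
  expect_true(all(out$glc >= 0) && all(out$ace >= 0))
})

test_that("single-substrate data leaves stage 3 under-determined", {
  dat <- synthetic_batch_data(noise_cv = 0)
  dat$mixed <- NULL
  fit <- calibrate_switching(dat)
  expect_match(attr(fit, "stage3"), "under-determined")
  # stages 1-2 still recover the generator truth
  expect_equal(fit$g_glc, 0.9, tolerance = 1e-6)
  expect_equal(fit$g_ace, 0.4, tolerance = 1e-6)
})
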