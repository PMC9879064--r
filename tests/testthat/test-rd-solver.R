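test_that("acellular steady states are exact: uniform and linear profiles", {
  # both ends held at 20% -> uniform 20%
  st <- hydrogel_stack(500, with_membrane = FALSE,
                       top = top_fixed_fraction(0.20))
  g <- build_grid(st, um(10))
  f <- simulate_stack(st, g, solver_settings(dt = 1), bottom = 0.20,
                      duration = 1000)
  expect_equal(f$values[, ncol(f$values)], rep(152, g$n), tolerance = 1e-9)

  # 20% bottom / 0% top -> linear partial-pressure profile
  st2 <- hydrogel_stack(500, with_membrane = FALSE,
                        top = top_fixed_fraction(0))
  f2 <- simulate_stack(st2, g, solver_settings(dt = 1), bottom = 0.20,
                       duration = 2000)
  u <- f2$values[, ncol(f2$values)]
  lin <- 152 * (max(g$z) - g$z) / max(g$z)
  expect_lt(max(abs(u - lin)) / 152, 1e-6)
})

test_that("early-time step response matches the half-space erfc solution", {
  st <- hydrogel_stack(2000, with_membrane = FALSE)
  g <- build_grid(st, um(10))
  f <- simulate_stack(st, g, solver_settings(dt = 0.01), bottom = 0.20,
                      duration = 20, init = 0)
  erfc <- function(x) 2 * pnorm(-x * sqrt(2))
  for (tt in c(5, 10, 20)) {
    i <- which.min(abs(f$times - tt))
    pred <- erfc(g$z / (2 * sqrt(D_O2_HYDROGEL * f$times[i])))
    expect_lt(max(abs(f$values[, i] / 152 - pred)), 0.01)
  }
})

test_that("periodic response matches the closed-form sinusoidal slab gain", {
  W <- um(500); D <- D_O2_HYDROGEL; Tp <- 60; om <- 2 * pi / Tp
  st <- hydrogel_stack(500, with_membrane = FALSE)
  g <- build_grid(st, W / 100)
  f <- simulate_stack(st, g, solver_settings(dt = Tp / 200, theta = 0.5),
                      bottom = function(t) 0.10 + 0.10 * sin(om * t),
                      duration = 12 * Tp, init = 0.10)
  attr(f, "period") <- Tp
  for (z in um(c(100, 250, 400, 500))) {
    amp <- oxcycle:::harmonic_amplitude(f, z, Tp)
    expect_equal(amp, 10 * sinusoid_gain(z, om, D, W)$gain, tolerance = 0.01)
  }
})

test_that("halving the grid spacing reduces the oracle error ~4x (2nd order)", {
  W <- um(500); D <- D_O2_HYDROGEL; Tp <- 60; om <- 2 * pi / Tp
  amp_err <- function(nint) {
    st <- hydrogel_stack(500, with_membrane = FALSE)
    g <- build_grid(st, W / nint, min_nodes = 4)
    f <- simulate_stack(st, g, solver_settings(dt = Tp / 2000, theta = 0.5),
                        bottom = function(t) 0.10 + 0.10 * sin(om * t),
                        duration = 12 * Tp, init = 0.10)
    attr(f, "period") <- Tp
    max(vapply(um(c(150, 300, 450)), function(z)
      abs(oxcycle:::harmonic_amplitude(f, z, Tp) -
          10 * sinusoid_gain(z, om, D, W)$gain), numeric(1)))
  }
  ratio <- amp_err(16) / amp_err(32)
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.5)
})

test_that("dissolved mass is conserved in a sealed acellular slab", {
  st <- hydrogel_stack(500, with_membrane = FALSE)
  g <- build_grid(st, um(10))
  init <- 152 * g$z / max(g$z)          # linear initial profile, mmHg
  f <- simulate_stack(st, g, solver_settings(dt = 0.1), bottom = 0.2,
                      duration = 600, init = init, bottom_mode = "sealed")
  sys <- oxcycle:::build_system(st, g)
  mass <- colSums(sys$aV * f$values)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-8)
})

test_that("maximum principle holds without consumption", {
  st <- hydrogel_stack(500)
  g <- build_grid(st, um(10))
  f <- simulate_stack(st, g, solver_settings(dt = 0.1),
                      bottom = osa_schedule(), duration = 120, init = 0.10)
  expect_gte(min(f$values), 0)
  expect_lte(max(f$values), 152 + 1e-9)
})

test_that("consumption never raises oxygen above the acellular solution", {
  g <- build_grid(hydrogel_stack(500), um(10))
  set <- solver_settings(dt = 0.1)
  f0 <- simulate_stack(hydrogel_stack(500), g, set,
                       bottom = osa_schedule(), duration = 120)
  fc <- simulate_stack(hydrogel_stack(500, rho_cell = 5e6, sOCR = 1.22e-16,
                                      K_m = 4.1e-6), g, set,
                       bottom = osa_schedule(), duration = 120)
  expect_true(all(fc$values <= f0$values + 1e-9))
})

test_that("splitting a layer in two leaves the solution unchanged", {
  st1 <- o2_stack(layer("gel", um(500), medium_hydrogel()))
  st2 <- o2_stack(layer("a", um(200), medium_hydrogel()),
                  layer("b", um(300), medium_hydrogel()))
  g1 <- build_grid(st1, um(10))
  g2 <- build_grid(st2, um(10))
  expect_equal(g1$z, g2$z, tolerance = 1e-12)
  set <- solver_settings(dt = 0.1)
  f1 <- simulate_stack(st1, g1, set, bottom = osa_schedule(), duration = 120)
  f2 <- simulate_stack(st2, g2, set, bottom = osa_schedule(), duration = 120)
  expect_lt(max(abs(f1$values - f2$values)) / 152, 1e-8)
})

test_that("Michaelis-Menten sink approaches its kinetic limits", {
  W <- um(500); D <- D_O2_HYDROGEL; a <- ALPHA_O2_WATER / 760
  # saturated (zero-order) regime: steady profile is the parabola
  q <- 6.5e-10  # rho_cell * sOCR, mol/(cm3 s)
  stz <- hydrogel_stack(500, with_membrane = FALSE, rho_cell = 6.5e5,
                        sOCR = 1e-15, K_m = 1e-12)
  gz <- build_grid(stz, um(5))
  fz <- simulate_stack(stz, gz, solver_settings(dt = 1), bottom = 0.2,
                       duration = 1500)
  uz <- fz$values[, ncol(fz$values)]
  pred <- 152 - (q / (D * a)) * (W * gz$z - gz$z^2 / 2)
  expect_lt(max(abs(uz - pred) / pred), 0.02)

  # dilute (first-order) regime: cosh profile with Thiele-type decay
  k1 <- 1.68e-2  # rho_cell * sOCR / K_m, 1/s
  stf <- hydrogel_stack(500, with_membrane = FALSE, rho_cell = 1e8,
                        sOCR = 1.68e-13, K_m = 1e-3)
  ff <- simulate_stack(stf, gz, solver_settings(dt = 1), bottom = 0.2,
                       duration = 1500)
  uf <- ff$values[, ncol(ff$values)]
  phi <- sqrt(k1 / D)
  predf <- 152 * cosh(phi * (W - gz$z)) / cosh(phi * W)
  expect_lt(max(abs(uf - predf) / predf), 0.02)
})

test_that("periodic steady state converges and its stopping rule is monotone", {
  # constant schedule: flat solution, max = min at every node
  stc <- hydrogel_stack(500)
  gc <- build_grid(stc, um(10))
  sc <- ih_schedule(0.1, 0.1, period = 60)
  pc <- run_to_periodic_steady_state(stc, sc, gc, solver_settings(dt = 0.5))
  expect_lte(attr(pc, "cycles"), 5)
  expect_lt(max(apply(pc$values, 1, max) - apply(pc$values, 1, min)) / 7.6,
            1e-3)

  # amplitude decays with depth at the standard 500 um scenario
  p <- pss_hydrogel(500)
  env <- envelope_profile(p, um(c(100, 400)))
  expect_gt(env$amplitude[2], 0)
  expect_gt(env$amplitude[1], env$amplitude[2])

  # doubling the tolerance never increases the cycle count
  st <- hydrogel_stack(500)
  g <- build_grid(st, um(20))
  cyc <- function(tol) attr(run_to_periodic_steady_state(
    st, osa_schedule(), g, solver_settings(dt = 0.5, psss_tol = tol)), "cycles")
  expect_lte(cyc(2e-3), cyc(1e-3))
})

test_that("field sampling interpolates linearly and validates depth", {
  p <- pss_hydrogel(500)
  iz <- 30; it <- 100
  tr <- sample_field(p, p$z[iz], times = p$times[it])
  expect_equal(tr$o2_percent, p$values[iz, it] / 7.6, tolerance = 1e-12)
  zmid <- (p$z[iz] + p$z[iz + 1]) / 2
  trm <- sample_field(p, zmid, times = p$times[it])
  expect_equal(trm$o2_percent,
               mean(p$values[iz:(iz + 1), it]) / 7.6, tolerance = 1e-12)
  expect_error(sample_field(p, um(600)), "<=")
})
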