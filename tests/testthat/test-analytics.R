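test_that("flux estimates reproduce direct hand calculations", {
  # consumption flux with the hepatocyte benchmark parameters
  sp <- hepatocyte_flux_spec()
  expect_equal(consumption_flux(sp), 7.97e-14, tolerance = 1e-3)
  # diffusion flux, independent arithmetic: D*alpha*dP/W
  sp2 <- flux_spec(rho_cell = 0, sOCR = 0, K_m = 4.1e-6, W = 0.05,
                   D = 1.2e-5, alpha = 1.1e-6, delta_P_mmHg = 152)
  expect_equal(diffusion_flux(sp2), 5.28e-11, tolerance = 1e-12)
  expect_equal(consumption_flux(sp2), 0)

  # Michaelis-Menten saturation: C_mean -> Inf gives rho*sOCR*W
  spsat <- flux_spec(rho_cell = 5e5, sOCR = 1.22e-16, K_m = 4.1e-6,
                     W = 0.05, D = 1.2e-5, C_mean = 1)
  expect_equal(consumption_flux(spsat), 5e5 * 1.22e-16 * 0.05,
               tolerance = 1e-5)
})

test_that("flux ratio equals the quotient and scales quadratically in W", {
  set.seed(11)
  for (i in 1:25) {
    sp <- flux_spec(rho_cell = 10^runif(1, 4, 7),
                    sOCR = 10^runif(1, -17, -15),
                    K_m = 10^runif(1, -7, -5),
                    W = runif(1, 0.01, 0.1),
                    D = 10^runif(1, -5.5, -4.5),
                    delta_P_mmHg = runif(1, 10, 700),
                    mean_fraction = runif(1, 0.01, 0.95))
    expect_equal(flux_ratio(sp), consumption_flux(sp) / diffusion_flux(sp),
                 tolerance = 1e-12)
    # closed form
    expect_equal(flux_ratio(sp),
                 sp$rho_cell * sp$sOCR * sp$C_mean * sp$W^2 /
                   (sp$D * sp$alpha * sp$delta_P_atm * (sp$K_m + sp$C_mean)),
                 tolerance = 1e-12)
    sp2 <- sp; sp2$W <- 2 * sp$W
    expect_equal(flux_ratio(sp2), 4 * flux_ratio(sp), tolerance = 1e-12)
  }
  expect_equal(flux_ratio(flux_spec(rho_cell = 0, sOCR = 0, K_m = 1e-6,
                                    W = 0.05, D = 1e-5)), 0)
  expect_error(flux_ratio(flux_spec(rho_cell = 1, sOCR = 1e-16, K_m = 1e-6,
                                    W = 0.05, D = 1e-5, delta_P_mmHg = 0)),
               "undefined")
})

test_that("hepatocyte benchmark: consumption is negligible against diffusion", {
  r <- flux_ratio(hepatocyte_flux_spec())
  expect_equal(r, 1.51e-3, tolerance = 1e-2)
  expect_lte(r, 0.015)
})

test_that("envelopes summarise constant and sinusoidal fields exactly", {
  # hand-built constant field
  f <- structure(list(z = um(c(0, 500)), times = seq(0, 60, 0.5),
                      values = matrix(76, 2, 121)),
                 class = "o2_field", period = 60)
  env <- envelope_profile(f, um(c(100, 400)))
  expect_equal(env$o2_max, env$o2_min)
  expect_equal(env$cycle_mean, c(10, 10))

  # pure sinusoid amplitude A about mean m: max - min = 2A, mean = m
  tt <- seq(0, 60, by = 0.05)
  fs <- structure(list(z = um(c(0, 500)), times = tt,
                       values = rbind(76 + 15.2 * sin(2 * pi * tt / 60),
                                      76 + 15.2 * sin(2 * pi * tt / 60))),
                  class = "o2_field", period = 60)
  es <- envelope_profile(fs, um(250))
  expect_equal(es$amplitude, 4, tolerance = 1e-3)
  expect_equal(es$cycle_mean, 10, tolerance = 1e-6)

  short <- structure(list(z = um(c(0, 500)), times = seq(0, 30, 0.5),
                          values = matrix(76, 2, 61)),
                     class = "o2_field", period = 60)
  expect_error(envelope_profile(short, um(100)), "less than one full cycle")
})

test_that("homogeneity spread is a range in %O2 with a pass threshold", {
  env <- data.frame(z_um = c(100, 400), o2_max = c(19, 18),
                    o2_min = c(1, 1.8))
  h <- homogeneity_metrics(env, threshold = 2)
  expect_equal(h$spread_max, 1)
  expect_equal(h$spread_min, 0.8)
  expect_true(h$pass)
  expect_false(homogeneity_metrics(env, threshold = 0.5)$pass)
  env2 <- env; env2$o2_max <- c(18, 18); env2$o2_min <- c(1, 1)
  h2 <- homogeneity_metrics(env2)
  expect_equal(c(h2$spread_max, h2$spread_min), c(0, 0))
  expect_error(homogeneity_metrics(env[1, , drop = FALSE]), ">= 2 depths")
})

test_that("sinusoidal slab gain has the right limits and monotonicity", {
  W <- um(500); D <- D_O2_HYDROGEL
  g0 <- sinusoid_gain(0, 2 * pi / 60, D, W)
  expect_equal(g0$gain, 1)
  expect_equal(g0$phase, 0)
  expect_equal(sinusoid_gain(um(300), 0, D, W)$gain, 1)

  zs <- um(seq(50, 500, by = 50))
  oms <- 2 * pi / c(300, 120, 60, 30, 15)
  for (om in oms) {
    gains <- sinusoid_gain(zs, om, D, W)$gain
    expect_true(all(diff(gains) < 0))  # decreasing in z
  }
  for (z in zs) {
    gw <- vapply(oms, function(om) sinusoid_gain(z, om, D, W)$gain, numeric(1))
    expect_true(all(diff(gw) < 0))     # decreasing in omega
  }
})

test_that("solver envelope matches square-wave Fourier synthesis within 2%", {
  W <- um(500); Tp <- 60
  st <- hydrogel_stack(500, with_membrane = FALSE)
  g <- build_grid(st, um(10))
  p <- run_to_periodic_steady_state(st, osa_schedule(), g,
                                    solver_settings(dt = 0.02))
  for (z in um(c(100, 300, 500))) {
    sim <- envelope_profile(p, z)$amplitude
    oracle <- 20 * square_wave_depth_gain(z, Tp, D_O2_HYDROGEL, W)
    expect_equal(sim, oracle, tolerance = 0.02)
  }
})

test_that("design verdicts degrade with thickness and honour the threshold", {
  g5 <- build_grid(hydrogel_stack(500), um(10))
  g8 <- build_grid(hydrogel_stack(800), um(10))
  r5 <- design_report(hydrogel_stack(500), osa_schedule(), g5,
                      solver_settings(dt = 0.1), fidelity_threshold = 0.05,
                      homogeneity_threshold = Inf)
  r8 <- design_report(hydrogel_stack(800), osa_schedule(), g8,
                      solver_settings(dt = 0.1), fidelity_threshold = 0.05,
                      homogeneity_threshold = Inf)
  # monotone: thicker at fixed settings never flips unsuitable -> suitable
  expect_gt(r5$fidelity, r8$fidelity)
  expect_true(r5$suitable)
  expect_false(r8$suitable)
  # amplitude decreases with depth in both
  expect_true(all(diff(r5$envelopes$amplitude) < 0))
  expect_true(all(diff(r8$envelopes$amplitude) < 0))
  # threshold 0 with homogeneity ignored is always suitable
  r0 <- design_report(hydrogel_stack(800), osa_schedule(), g8,
                      solver_settings(dt = 0.1), fidelity_threshold = 0,
                      homogeneity_threshold = Inf)
  expect_true(r0$suitable)
})
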