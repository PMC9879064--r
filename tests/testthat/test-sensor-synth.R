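# A hand-built two-node field carrying a bottom-to-top uniform signal lets
# sensor properties be tested against exact expectations.
flat_field <- function(times, percent, period = NULL) {
  v <- matrix(rep(percent * 7.6, each = 2), nrow = 2)
  structure(list(z = um(c(0, 500)), times = times, values = v),
            class = "o2_field", period = period)
}

test_that("a fast noiseless sensor reproduces the ideal trace", {
  p <- pss_hydrogel(500)
  tr <- emulate_sensor(p, um(200), sensor_spec(t90 = 1e-6, noise_sd = 0))
  ideal <- sample_field(p, um(200), times = tr$times)
  expect_equal(tr$values, ideal$o2_percent, tolerance = 1e-9)
})

test_that("step response reaches 90% at t90 after the transition", {
  tt <- seq(0, 30, by = 0.01)
  x <- ifelse(tt < 10, 0, 20)
  f <- flat_field(tt, x)
  tr <- emulate_sensor(f, um(250),
                       sensor_spec(t90 = 2, noise_sd = 0, sample_rate = 20))
  i90 <- which(tr$values >= 0.9 * 20)[1]
  expect_equal(tr$times[i90], 10 + 2, tolerance = 0.06)  # within one sample
})

test_that("noise is seeded, reproducible, and mean-preserving", {
  p <- pss_hydrogel(500)
  t1 <- emulate_sensor(p, um(200), sensor_spec(seed = 42))
  t2 <- emulate_sensor(p, um(200), sensor_spec(seed = 42))
  t3 <- emulate_sensor(p, um(200), sensor_spec(seed = 43))
  expect_identical(t1$values, t2$values)
  expect_false(identical(t1$values, t3$values))
  expect_equal(mean(t1$values), mean(t3$values), tolerance = 0.2)
  # the sensor path does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(emulate_sensor(p, um(200), sensor_spec(seed = 7)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noiseless sensor emulation is linear in the field", {
  p <- pss_hydrogel(500)
  half <- p; half$values <- p$values / 2
  sp <- sensor_spec(noise_sd = 0)
  tr <- emulate_sensor(p, um(300), sp)
  trh <- emulate_sensor(half, um(300), sp)
  expect_equal(trh$values, tr$values / 2, tolerance = 1e-12)
})

test_that("the first-order lag strictly shrinks the cycle amplitude", {
  p <- field_tile(pss_hydrogel(500), 3)
  for (z in um(c(100, 400))) {
    ideal <- sample_field(p, z)
    lagged <- emulate_sensor(p, z, sensor_spec(t90 = 2, noise_sd = 0,
                                               sample_rate = 10))
    expect_lt(diff(range(lagged$values[lagged$times >= 60])),
              diff(range(ideal$o2_percent)))
  }
})

test_that("benchmark suite is reproducible and documented by its manifest", {
  scen <- benchmark_scenarios()["hydrogel_500um_20_0"]
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_benchmark_suite(d1, seed = 5, scenarios = scen,
                                 target_dz = um(20),
                                 settings = solver_settings(dt = 0.2))
  m2 <- generate_benchmark_suite(d2, seed = 5, scenarios = scen,
                                 target_dz = um(20),
                                 settings = solver_settings(dt = 0.2))
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  expect_true("manifest.yaml" %in% f1)
  # regeneration is bit-identical
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  sc1 <- m1$scenarios$hydrogel_500um_20_0
  expect_equal(sc1$D_sample_cm2_s, D_O2_HYDROGEL)
  expect_equal(length(sc1$traces), 4)
  # each trace re-reads with the depth recorded in the manifest
  tr <- read_sensor_trace(file.path(d1, sc1$traces[[1]]$file),
                          z = um(sc1$traces[[1]]$z_um))
  expect_equal(length(tr$values), 181)  # 3 cycles at 1 Hz, inclusive ends

  # cycle-averaged trace amplitude vs the ideal amplitude: strictly below
  # for noise-free traces (the lag is a pure attenuator); for noisy traces
  # the exceedance is bounded by the residual averaged-noise floor
  st <- hydrogel_stack(500)
  g <- build_grid(st, um(20))
  pss <- run_to_periodic_steady_state(st, osa_schedule(), g,
                                      solver_settings(dt = 0.2))
  tiled <- field_tile(pss, 3)
  avg_amp <- function(times, values) {
    avg <- tapply(values, round(times %% 60, 6), mean)
    max(avg) - min(avg)
  }
  for (ti in sc1$traces) {
    z <- um(ti$z_um)
    ideal_amp <- diff(range(sample_field(pss, z)$o2_percent))
    clean <- emulate_sensor(tiled, z, sensor_spec(noise_sd = 0))
    expect_lt(avg_amp(clean$times, clean$values), ideal_amp)
    tr <- read_sensor_trace(file.path(d1, ti$file), z = z)
    noise_floor <- 4 * m1$sensor$noise_sd / sqrt(m1$n_cycles)
    expect_lte(avg_amp(tr$times, tr$values), ideal_amp + noise_floor)
  }
})
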