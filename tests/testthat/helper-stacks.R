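# Shared builders and a cache for expensive periodic-steady-state runs and
# fit studies, so several test files can reuse the same solves.

.oxcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.oxcache[[key]])) .oxcache[[key]] <- force(expr)
  .oxcache[[key]]
}

hydrogel_stack <- function(W_um, with_membrane = TRUE, rho_cell = 0,
                           sOCR = 0, K_m = NA, D = D_O2_HYDROGEL,
                           top = top_no_flux()) {
  gel <- layer("hydrogel", um(W_um), medium("hydrogel", D),
               rho_cell = rho_cell, sOCR = sOCR, K_m = K_m)
  if (with_membrane) o2_stack(membrane_layer(), gel, top_boundary = top)
  else o2_stack(gel, top_boundary = top)
}

osa_schedule <- function(high = 0.20, low = 0.00)
  schedule_from_events_per_hour(60, high, low)

# Converged cycle for the standard acellular hydrogel scenarios.
pss_hydrogel <- function(W_um) {
  cached(paste0("pss", W_um), {
    st <- hydrogel_stack(W_um)
    g <- build_grid(st, um(10))
    run_to_periodic_steady_state(st, osa_schedule(), g, solver_settings(dt = 0.1))
  })
}

# The diffusivity-recovery study conditions: 500 um hydrogel on the
# membrane, 60 events/h 20%/0%, traces at 4 depths, t90 = 2 s sensor.
fit_truth_field <- function() {
  cached("fit_truth", {
    pss <- pss_hydrogel(500)
    pss
  })
}

fit_study_traces <- function(seed, n_cycles = 3, noise_sd = 0.2) {
  tiled <- field_tile(fit_truth_field(), n_cycles)
  depths <- um(c(100, 200, 300, 400))
  lapply(seq_along(depths), function(i)
    emulate_sensor(tiled, depths[i],
                   sensor_spec(noise_sd = noise_sd, seed = seed * 10L + i)))
}

fit_one_seed <- function(seed, n_cycles = 3, noise_sd = 0.2) {
  st <- hydrogel_stack(500)
  pr <- fit_problem(fit_study_traces(seed, n_cycles, noise_sd), st,
                    osa_schedule(), settings = solver_settings(dt = 0.1))
  fit_parameters(pr)$estimates[["D"]]
}

# Memoised seed study: returns the vector of D-hats for the given seeds.
fit_seed_study <- function(seeds, n_cycles = 3) {
  key <- paste0("study_c", n_cycles, "_", paste(seeds, collapse = "-"))
  cached(key, vapply(seeds, fit_one_seed, numeric(1), n_cycles = n_cycles))
}
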