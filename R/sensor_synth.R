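#' Optical microsensor specification
#'
#' Emulation model for a fibre-optic O2 microsensor: a first-order response
#' with 90% response time `t90` (probe spec: below 2 s), so time constant
#' `tau = t90 / ln(10)`, plus additive Gaussian read noise on the recorded
#' samples. The ~40 um tip is treated as a point. Noise magnitude and
#' sampling rate are synthetic-only defaults (not instrument-measured) and
#' are deliberately small relative to the driving swings.
#'
#' @param t90 90% response time, s (default 2).
#' @param noise_sd additive noise, %O2 (default 0.2).
#' @param sample_rate recording rate, Hz (default 1).
#' @param seed integer seed governing the noise.
#' @return A list of class `sensor_spec`; `tau` is derived.
#' @export
sensor_spec <- function(t90 = 2, noise_sd = 0.2, sample_rate = 1, seed = 1L) {
  check_number(t90, "t90", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  structure(list(t90 = t90, tau = t90 / log(10), noise_sd = noise_sd,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "sensor_spec")
}

# First-order low-pass with exact exponential update per sample, treating
# the input as constant over each inter-sample interval.
lowpass_first_order <- function(times, x, tau) {
  if (tau <= 0) return(x)
  y <- numeric(length(x))
  y[1] <- x[1]
  a <- exp(-diff(times) / tau)
  for (i in seq_along(a)) y[i + 1] <- x[i + 1] + (y[i] - x[i + 1]) * a[i]
  y
}

#' Emulate a depth-positioned microsensor on a simulated field
#'
#' Pipeline: ideal depth trace (linear interpolation of the field) ->
#' first-order lag with time constant `tau` at the field's time resolution
#' -> resampling onto the sensor's sampling grid -> additive Gaussian noise
#' on the recorded samples, drawn under the spec's seed. Applying the noise
#' to the recorded samples (rather than before resampling) keeps `noise_sd`
#' equal to the sd of the stored readings.
#'
#' @param field an `o2_field` (e.g. a tiled periodic-steady-state cycle).
#' @param z sensor depth, cm (inside the stack).
#' @param spec a [sensor_spec()].
#' @return A list of class `sensor_trace`: `z`, `times` (s), `values`
#'   (%O2), `spec`, and `provenance` (config hash of the ground truth, if
#'   available).
#' @export
emulate_sensor <- function(field, z, spec = sensor_spec()) {
  stopifnot(inherits(field, "o2_field"), inherits(spec, "sensor_spec"))
  ideal <- sample_field(field, z)
  lagged <- lowpass_first_order(ideal$time_s, ideal$o2_percent, spec$tau)
  ts <- seq(min(ideal$time_s), max(ideal$time_s), by = 1 / spec$sample_rate)
  v <- approx(ideal$time_s, lagged, xout = ts)$y
  if (spec$noise_sd > 0)
    v <- v + with_seed(spec$seed, rnorm(length(v), 0, spec$noise_sd))
  structure(list(z = z, times = ts, values = v, spec = spec,
                 provenance = attr(field, "config_hash") %||% NA_character_),
            class = "sensor_trace")
}

#' @export
as.data.frame.sensor_trace <- function(x, ...) {
  data.frame(time_s = x$times, o2_percent = x$values)
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("<sensor_trace> z = %.0f um, %d samples at %.3g Hz, noise %.2g %%O2\n",
              x$z * 1e4, length(x$times), x$spec$sample_rate, x$spec$noise_sd))
  invisible(x)
}

#' Default benchmark scenarios
#'
#' The measurement situations the synthetic suite emulates: 500 and 800 um
#' acellular ECM hydrogels under 20%/0% cycling, a 500 um hydrogel under
#' 15%/5%, and 300/500 um brain-like tissue slices under 95%/50%, all at 60
#' events/h through a 165 um PDMS membrane. Slice layers carry a
#' consumption term with brain-like cell density; the slice diffusivity
#' (1.4e-5 cm^2/s) reflects that tissue D is below hydrogel D.
#'
#' @return Named list of scenario descriptions (stack, schedule, depths).
#' @export
benchmark_scenarios <- function() {
  hydrogel <- function(W) o2_stack(membrane_layer(),
                                   layer("hydrogel", W, medium_hydrogel()))
  slice <- function(W) o2_stack(
    membrane_layer(),
    layer("slice", W, medium("tissue", D = 1.4e-5),
          rho_cell = 1e8, sOCR = 2e-16, K_m = 4.1e-6))
  list(
    hydrogel_500um_20_0 = list(stack = hydrogel(um(500)),
      schedule = schedule_from_events_per_hour(60, 0.20, 0.00),
      depths = um(c(100, 200, 300, 400))),
    hydrogel_800um_20_0 = list(stack = hydrogel(um(800)),
      schedule = schedule_from_events_per_hour(60, 0.20, 0.00),
      depths = um(c(100, 300, 500, 700))),
    hydrogel_500um_15_5 = list(stack = hydrogel(um(500)),
      schedule = schedule_from_events_per_hour(60, 0.15, 0.05),
      depths = um(c(100, 200, 300, 400))),
    slice_300um_95_50 = list(stack = slice(um(300)),
      schedule = schedule_from_events_per_hour(60, 0.95, 0.50),
      depths = um(c(50, 150, 250))),
    slice_500um_95_50 = list(stack = slice(um(500)),
      schedule = schedule_from_events_per_hour(60, 0.95, 0.50),
      depths = um(c(100, 200, 300, 400)))
  )
}

#' Generate the synthetic benchmark suite
#'
#' For each scenario, solves the stack to periodic steady state, tiles
#' `n_cycles` cycles, and writes one sensor trace per depth (CSV:
#' `time_s,o2_percent`) plus a `manifest.yaml` recording ground truth
#' (diffusivities, lumped consumption), per-trace seeds, and the config
#' hash. Regenerating from the same arguments is bit-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed; per-trace seeds derive from it.
#' @param scenarios scenario list as from [benchmark_scenarios()].
#' @param n_cycles cycles of data per trace.
#' @param spec base [sensor_spec()] (its seed field is replaced per trace).
#' @param target_dz grid spacing, cm.
#' @param settings [solver_settings()].
#' @return Invisibly, the manifest as a list.
#' @export
generate_benchmark_suite <- function(out_dir, seed = 1L,
                                     scenarios = benchmark_scenarios(),
                                     n_cycles = 3L,
                                     spec = sensor_spec(),
                                     target_dz = um(10),
                                     settings = solver_settings()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = as.integer(seed), n_cycles = as.integer(n_cycles),
                   sensor = list(t90_s = spec$t90, noise_sd = spec$noise_sd,
                                 sample_rate_hz = spec$sample_rate),
                   scenarios = list())
  for (si in seq_along(scenarios)) {
    nm <- names(scenarios)[si]
    sc <- scenarios[[si]]
    grid <- build_grid(sc$stack, target_dz)
    pss <- run_to_periodic_steady_state(sc$stack, sc$schedule, grid, settings)
    tiled <- field_tile(pss, n_cycles)
    sample_layers <- Filter(function(l) l$role != "membrane", sc$stack$layers)
    truth <- list(
      schedule = list(high = sc$schedule$high, low = sc$schedule$low,
                      period_s = sc$schedule$period),
      D_sample_cm2_s = sample_layers[[1]]$medium$D,
      rho_socr_mol_cm3_s = sample_layers[[1]]$rho_cell * sample_layers[[1]]$sOCR,
      K_m_mol_cm3 = if (sample_layers[[1]]$rho_cell > 0)
        sample_layers[[1]]$K_m else NA,
      W_um = sum(vapply(sample_layers, `[[`, numeric(1), "thickness")) * 1e4,
      cycles_to_pss = attr(pss, "cycles"))
    traces <- list()
    for (di in seq_along(sc$depths)) {
      z <- sc$depths[di]
      tseed <- as.integer(seed) * 1000L + si * 100L + di
      sp <- spec; sp$seed <- tseed
      tr <- emulate_sensor(tiled, z, sp)
      fname <- sprintf("%s_z%03.0fum.csv", nm, z * 1e4)
      write_o2_table(as.data.frame(tr), file.path(out_dir, fname),
                     seed = tseed)
      traces[[length(traces) + 1L]] <-
        list(file = fname, z_um = z * 1e4, seed = tseed)
    }
    manifest$scenarios[[nm]] <- c(truth, list(traces = traces))
  }
  manifest$config_hash <- hash_object(manifest)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
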