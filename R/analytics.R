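#' Specification for the consumed-versus-diffused flux estimate
#'
#' Collects the quantities entering the closed-form per-area flux estimates
#' for a membrane-like construct of thickness `W`: a Michaelis-Menten cell
#' sink (`rho_cell`, `sOCR`, `K_m`), the average dissolved O2 concentration
#' `C_mean` across the construct, and the diffusive drive `D * alpha *
#' deltaP / W`.
#'
#' `C_mean` defaults, by the package's documented convention, to the
#' concentration at the arithmetic mean of the two driving fractions
#' (e.g. 10% O2 for a 20%/0% schedule), converted through `alpha`.
#'
#' @param rho_cell cells/cm^3 (>= 0).
#' @param sOCR mol/(cell s).
#' @param K_m mol/cm^3.
#' @param W construct thickness, cm.
#' @param D diffusivity, cm^2/s.
#' @param alpha solubility, mol/(cm^3 atm).
#' @param delta_P_mmHg partial-pressure difference across the construct,
#'   mmHg (converted internally to atm).
#' @param C_mean average O2 concentration, mol/cm^3; `NULL` to use
#'   `mean_fraction`.
#' @param mean_fraction O2 fraction at which `C_mean` is evaluated when not
#'   given explicitly (default 0.10).
#' @return A list of class `flux_spec`.
#' @export
#' @examples
#' flux_ratio(hepatocyte_flux_spec())   # ~1.5e-3
flux_spec <- function(rho_cell, sOCR, K_m, W, D, alpha = ALPHA_O2_WATER,
                      delta_P_mmHg = 152, C_mean = NULL,
                      mean_fraction = 0.10) {
  check_number(rho_cell, "rho_cell", lower = 0)
  check_number(sOCR, "sOCR", lower = 0)
  check_number(K_m, "K_m", lower = 0, strict_lower = TRUE)
  check_number(W, "W", lower = 0, strict_lower = TRUE)
  check_number(D, "D", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_number(delta_P_mmHg, "delta_P_mmHg", lower = 0)
  if (is.null(C_mean)) {
    check_number(mean_fraction, "mean_fraction", lower = 0, upper = 1)
    C_mean <- alpha * mean_fraction
  }
  check_number(C_mean, "C_mean", lower = 0)
  structure(list(rho_cell = rho_cell, sOCR = sOCR, K_m = K_m, W = W, D = D,
                 alpha = alpha, delta_P_atm = delta_P_mmHg / .MMHG_PER_ATM,
                 C_mean = C_mean),
            class = "flux_spec")
}

#' @rdname flux_spec
#' @details `hepatocyte_flux_spec()` is the literature hepatocyte benchmark
#'   (collagen hydrogel seeded at 5e5 cells/cm^3, sOCR = 1.22e-16
#'   mol/(cell s), K_m = 4.1e-6 mol/cm^3, D = 1.2e-5 cm^2/s) for a 500 um
#'   construct under a 152 mmHg (20% to 0%) drive.
#' @export
hepatocyte_flux_spec <- function(W = um(500), delta_P_mmHg = 152,
                                 C_mean = NULL, mean_fraction = 0.10) {
  flux_spec(rho_cell = 5e5, sOCR = 1.22e-16, K_m = 4.1e-6,
            W = W, D = 1.2e-5, alpha = ALPHA_O2_WATER,
            delta_P_mmHg = delta_P_mmHg, C_mean = C_mean,
            mean_fraction = mean_fraction)
}

#' Per-area consumption and diffusion flux estimates, and their ratio
#'
#' `consumption_flux()` estimates the O2 consumed per unit area in the
#' construct volume, `rho_cell * sOCR * C_mean * W / (K_m + C_mean)`.
#' `diffusion_flux()` is the diffusive flow sustained by the drive,
#' `D * alpha * deltaP / W`. `flux_ratio()` is their quotient,
#' `rho_cell * sOCR * C_mean * W^2 / (D * alpha * deltaP * (K_m + C_mean))`;
#' a small ratio means consumption is negligible against delivery, and the
#' ratio grows quadratically with `W`.
#'
#' @param spec a [flux_spec()].
#' @return mol/(cm^2 s) for the fluxes; dimensionless for the ratio.
#' @export
consumption_flux <- function(spec) {
  stopifnot(inherits(spec, "flux_spec"))
  spec$rho_cell * spec$sOCR * spec$C_mean * spec$W / (spec$K_m + spec$C_mean)
}

#' @rdname consumption_flux
#' @export
diffusion_flux <- function(spec) {
  stopifnot(inherits(spec, "flux_spec"))
  spec$D * spec$alpha * spec$delta_P_atm / spec$W
}

#' @rdname consumption_flux
#' @export
flux_ratio <- function(spec) {
  stopifnot(inherits(spec, "flux_spec"))
  if (spec$delta_P_atm == 0)
    stop_domain("flux ratio undefined for delta_P = 0")
  consumption_flux(spec) / diffusion_flux(spec)
}

#' Depth-resolved cycle envelope of a field
#'
#' For each requested depth, the maximum, minimum, amplitude (max - min) and
#' time-averaged mean of %O2 over the final full cycle of the field. The
#' field must cover at least one period (typically the converged cycle from
#' [run_to_periodic_steady_state()]).
#'
#' @param field an `o2_field`.
#' @param depths depths, cm.
#' @param period cycle period, s; defaults to the field's schedule period.
#' @return A data.frame with `z_um`, `o2_max`, `o2_min`, `amplitude`,
#'   `cycle_mean` (all %O2).
#' @export
envelope_profile <- function(field, depths, period = NULL) {
  stopifnot(inherits(field, "o2_field"))
  period <- period %||% attr(field, "period")
  if (is.null(period)) stop_domain("'period' is required for a schedule-less field")
  span <- diff(range(field$times))
  if (span < period - 1e-9)
    stop_domain("field covers less than one full cycle")
  t1 <- max(field$times)
  keep <- field$times >= t1 - period - 1e-9
  out <- lapply(depths, function(z) {
    tr <- sample_field(field, z)
    v <- tr$o2_percent[keep]
    tt <- tr$time_s[keep]
    # trapezoidal time average over the cycle
    mu <- sum(diff(tt) * (head(v, -1) + v[-1]) / 2) / diff(range(tt))
    data.frame(z_um = z * 1e4, o2_max = max(v), o2_min = min(v),
               amplitude = max(v) - min(v), cycle_mean = mu)
  })
  do.call(rbind, out)
}

#' Homogeneity of the envelope across depths
#'
#' The field criterion for "uniform" intermittent hypoxia across a sample:
#' the spread (max across depths minus min across depths, in %O2) of the
#' envelope maxima and of the envelope minima, each compared against a
#' threshold (default 2 %O2). The spread is used rather than a literal
#' variance so that the metric carries the %O2 unit.
#'
#' @param envelopes data.frame from [envelope_profile()] (>= 2 depths).
#' @param threshold pass threshold, %O2.
#' @return List with `spread_max`, `spread_min` (both %O2) and `pass`.
#' @export
homogeneity_metrics <- function(envelopes, threshold = 2) {
  if (nrow(envelopes) < 2L) stop_domain("need envelopes at >= 2 depths")
  spread_max <- max(envelopes$o2_max) - min(envelopes$o2_max)
  spread_min <- max(envelopes$o2_min) - min(envelopes$o2_min)
  list(spread_max = spread_max, spread_min = spread_min,
       threshold = threshold,
       pass = spread_max <= threshold && spread_min <= threshold)
}

#' Closed-form periodic slab response (solver oracle)
#'
#' For an acellular slab of diffusivity `D` and thickness `W`, driven at
#' z = 0 by a sinusoid of angular frequency `omega` with a sealed (no-flux)
#' top, the complex transfer to depth `z` is
#' `cosh(gamma (W - z)) / cosh(gamma W)` with `gamma = sqrt(i omega / D)`.
#'
#' @param z depth, cm, in `[0, W]`.
#' @param omega angular frequency, rad/s.
#' @param D diffusivity, cm^2/s.
#' @param W slab thickness, cm.
#' @return List with `gain` (amplitude ratio) and `phase` (radians, lag
#'   negative).
#' @export
sinusoid_gain <- function(z, omega, D, W) {
  if (any(z < 0) || any(z > W + 1e-12)) stop_domain("'z' must lie in [0, W]")
  if (omega == 0) return(list(gain = rep(1, length(z)), phase = rep(0, length(z))))
  g <- sqrt(1i * omega / D)
  H <- cosh(g * (W - z)) / cosh(g * W)
  list(gain = Mod(H), phase = Arg(H))
}

#' Square-wave envelope transfer by Fourier synthesis (solver oracle)
#'
#' Synthesises the periodic steady state at depth `z` for an ideal
#' square-wave drive (duty 0.5) from the odd harmonics of
#' [sinusoid_gain()], and returns the predicted envelope amplitude at depth
#' relative to the driving amplitude.
#'
#' @inheritParams sinusoid_gain
#' @param period drive period, s.
#' @param n_harmonics number of odd harmonics (default 51).
#' @param n_t time resolution of the synthesis.
#' @return Relative envelope amplitude (dimensionless, in `(0, 1]`).
#' @export
square_wave_depth_gain <- function(z, period, D, W, n_harmonics = 51,
                                   n_t = 2000) {
  omega <- 2 * pi / period
  tt <- seq(0, period, length.out = n_t + 1)[-1]
  ks <- seq(1, by = 2, length.out = n_harmonics)
  vapply(z, function(zz) {
    x <- numeric(length(tt))
    for (k in ks) {
      H <- sinusoid_gain(zz, k * omega, D, W)
      # square wave (swing 1): sum over odd k of (2/(pi k)) sin(k w t)
      x <- x + (2 / (pi * k)) * H$gain * sin(k * omega * tt + H$phase)
    }
    max(x) - min(x)
  }, numeric(1))
}

# First-harmonic amplitude of a field at depth z over its final cycle
# (discrete Fourier projection; used to compare the solver against
# sinusoid_gain without max/min sampling error).
harmonic_amplitude <- function(field, z, period = NULL, harmonic = 1) {
  period <- period %||% attr(field, "period")
  t1 <- max(field$times)
  keep <- field$times >= t1 - period - 1e-9
  tr <- sample_field(field, z)
  tt <- tr$time_s[keep]; v <- tr$o2_percent[keep]
  w <- 2 * pi * harmonic / period
  f <- v * exp(-1i * w * tt)
  # trapezoid over one period
  z1 <- sum(diff(tt) * (head(f, -1) + f[-1]) / 2)
  2 * Mod(z1) / period
}

#' Design report: is a stack suitable for uniform intermittent hypoxia?
#'
#' Runs the stack to periodic steady state, extracts the depth envelope over
#' the sample (z >= 0), and issues a verdict: suitable iff the envelope
#' amplitude at the top of the sample is at least `fidelity_threshold` times
#' the driving amplitude AND the envelope homogeneity criterion passes.
#'
#' @inheritParams run_to_periodic_steady_state
#' @param fidelity_threshold required fraction of the driving amplitude at
#'   the sample top (default 0.5).
#' @param depths depths for the envelope, cm; default 11 equally spaced
#'   positions across the sample.
#' @param homogeneity_threshold %O2 threshold for [homogeneity_metrics()];
#'   set to `Inf` to ignore homogeneity.
#' @return A list of class `design_report` with the envelope table,
#'   homogeneity metrics, top-of-sample amplitude, driving amplitude, and
#'   the logical verdict `suitable`.
#' @export
design_report <- function(stack, schedule, grid = NULL,
                          settings = solver_settings(),
                          fidelity_threshold = 0.5, depths = NULL,
                          homogeneity_threshold = 2) {
  check_number(fidelity_threshold, "fidelity_threshold", lower = 0)
  if (is.null(grid)) grid <- build_grid(stack, target_dz = um(10))
  fld <- run_to_periodic_steady_state(stack, schedule, grid, settings)
  ztop <- max(fld$z)
  if (is.null(depths)) depths <- seq(0, ztop, length.out = 11L)[-1L]
  env <- envelope_profile(fld, depths)
  hom <- homogeneity_metrics(env, threshold = homogeneity_threshold)
  driving_amp <- (schedule$high - schedule$low) * 100
  amp_top <- envelope_profile(fld, ztop)$amplitude
  amp_ok <- amp_top >= fidelity_threshold * driving_amp
  structure(list(envelopes = env, homogeneity = hom,
                 amplitude_top = amp_top, driving_amplitude = driving_amp,
                 fidelity = amp_top / driving_amp,
                 fidelity_threshold = fidelity_threshold,
                 cycles = attr(fld, "cycles"),
                 suitable = amp_ok && hom$pass),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> top amplitude %.2f %%O2 (%.0f%% of driving %.1f %%O2)\n",
              x$amplitude_top, 100 * x$fidelity, x$driving_amplitude))
  cat(sprintf("  homogeneity: spread(max) %.2f, spread(min) %.2f %%O2 [%s]\n",
              x$homogeneity$spread_max, x$homogeneity$spread_min,
              if (x$homogeneity$pass) "pass" else "fail"))
  cat(sprintf("  verdict: %s (threshold %.2f, %d cycles to steady cycling)\n",
              if (x$suitable) "suitable" else "unsuitable",
              x$fidelity_threshold, x$cycles))
  invisible(x)
}
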