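#' Solver settings
#'
#' Controls for the theta-weighted implicit finite-volume time stepper.
#' Backward Euler (`theta = 1`) is the robust default for square-wave
#' driving; `theta = 0.5` (trapezoidal) is second order in time and is the
#' right choice against smooth (sinusoidal) oracles.
#'
#' @param dt target time step, s. Square-wave phase changes are always
#'   aligned exactly onto step boundaries; within a phase the step is
#'   uniform and never larger than `dt`.
#' @param theta implicitness weight in `[0.5, 1]`.
#' @param newton_tol relative Newton tolerance on the update (scaled by one
#'   atmosphere).
#' @param newton_max_iter maximum Newton iterations per step.
#' @param psss_tol periodic-steady-state tolerance, %O2: iteration stops
#'   when no node's cycle maximum or minimum moves by more than this between
#'   consecutive cycles.
#' @param psss_max_cycles cycle budget for [run_to_periodic_steady_state()].
#' @return A list of class `solver_settings`.
#' @export
solver_settings <- function(dt = 0.1, theta = 1, newton_tol = 1e-10,
                            newton_max_iter = 25L, psss_tol = 1e-3,
                            psss_max_cycles = 200L) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_number(theta, "theta", lower = 0.5, upper = 1)
  check_number(newton_tol, "newton_tol", lower = 0, strict_lower = TRUE)
  check_number(psss_tol, "psss_tol", lower = 0, strict_lower = TRUE)
  structure(list(dt = dt, theta = theta, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 psss_tol = psss_tol,
                 psss_max_cycles = as.integer(psss_max_cycles)),
            class = "solver_settings")
}

# Assemble the finite-volume arrays for the C++ stepper. Everything is per
# unit area; `a = alpha / 760` converts mmHg to mol/cm3 so that face
# conductance D*a/dz is the interfacial permeability (harmonic averaging of
# D*alpha across an interface arises from the series of the two half-edges
# meeting at the interface node).
build_system <- function(stack, grid) {
  n <- grid$n
  Dv <- vapply(stack$layers, function(l) l$medium$D, numeric(1))
  av <- vapply(stack$layers, function(l) l$medium$alpha, numeric(1)) / .MMHG_PER_ATM
  rho <- vapply(stack$layers, `[[`, numeric(1), "rho_cell")
  socr <- vapply(stack$layers, `[[`, numeric(1), "sOCR")
  km <- vapply(stack$layers, `[[`, numeric(1), "K_m")

  eL <- grid$edge_layer
  edge_k <- Dv[eL] * av[eL] / grid$edge_dz

  aV <- numeric(n)
  r_lo <- a_lo <- km_lo <- numeric(n)
  r_hi <- a_hi <- km_hi <- numeric(n)
  km_lo[] <- 1; km_hi[] <- 1
  for (j in seq_len(n)) {
    if (j > 1) {           # lower half-cell, edge j-1
      e <- j - 1L; l <- eL[e]; h <- grid$edge_dz[e] / 2
      aV[j] <- aV[j] + av[l] * h
      r_lo[j] <- rho[l] * socr[l] * h
      a_lo[j] <- av[l]                   # C = (alpha/760) * u  [mol/cm3]
      km_lo[j] <- km[l]
    }
    if (j < n) {           # upper half-cell, edge j
      e <- j; l <- eL[e]; h <- grid$edge_dz[e] / 2
      aV[j] <- aV[j] + av[l] * h
      r_hi[j] <- rho[l] * socr[l] * h
      a_hi[j] <- av[l]
      km_hi[j] <- km[l]
    }
  }
  list(edge_k = edge_k, aV = aV,
       r_lo = r_lo, a_lo = a_lo, km_lo = km_lo,
       r_hi = r_hi, a_hi = a_hi, km_hi = km_hi)
}

# Step times for a schedule-driven run: phase changes fall exactly on step
# boundaries; each phase segment is subdivided uniformly with step <= dt.
schedule_times <- function(schedule, duration, dt) {
  Tp <- schedule$period; th <- schedule$duty * Tp
  brk <- sort(unique(c(
    seq(0, duration, by = Tp),
    seq(th, duration + Tp, by = Tp),
    duration)))
  brk <- brk[brk <= duration + 1e-12]
  times <- 0
  for (i in seq_len(length(brk) - 1L)) {
    seg <- brk[i + 1L] - brk[i]
    ns <- max(1L, ceiling(seg / dt - 1e-9))
    times <- c(times, brk[i] + seq_len(ns) * (seg / ns))
  }
  times
}

#' Simulate the oxygen field on a stack
#'
#' Solves the multilayer reaction-diffusion equation in partial pressure,
#' with a Michaelis-Menten consumption sink per cell-laden layer, a
#' Dirichlet bottom boundary driven by the gas schedule, and the stack's top
#' boundary condition. Partial pressure is taken continuous across material
#' interfaces (Henry-law interface condition); concentration jumps with each
#' layer's solubility.
#'
#' @param stack an [o2_stack()].
#' @param grid an [build_grid()] grid for `stack`.
#' @param settings [solver_settings()].
#' @param bottom the driving boundary: an [ih_schedule()], a function of
#'   time returning an O2 fraction, or a single fraction for a constant
#'   boundary. Use `bottom_mode = "sealed"` for a no-flux bottom (closed
#'   system; diagnostic use).
#' @param duration run length, s (defaults to the schedule's
#'   `total_duration`).
#' @param init initial condition: a single O2 fraction (uniform), a numeric
#'   vector of nodal partial pressures in mmHg, or an `o2_field` whose final
#'   state is reused. Default: uniform at the schedule's high fraction
#'   (samples equilibrate in normoxia before cycling starts).
#' @param bottom_mode `"dirichlet"` (default) or `"sealed"`.
#' @return An `o2_field`: list with `z` (cm), `times` (s), `values`
#'   (nodes x times matrix of partial pressure, mmHg), plus the grid and
#'   stack used.
#' @export
simulate_stack <- function(stack, grid, settings = solver_settings(),
                           bottom = NULL, duration = NULL, init = NULL,
                           bottom_mode = c("dirichlet", "sealed")) {
  stopifnot(inherits(stack, "o2_stack"), inherits(grid, "o2_grid"))
  bottom_mode <- match.arg(bottom_mode)
  sched <- NULL
  if (inherits(bottom, "ih_schedule")) sched <- bottom

  if (is.null(duration)) {
    if (is.null(sched)) stop_domain("'duration' is required without a schedule")
    duration <- sched$total_duration
  }
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)

  times <- if (!is.null(sched)) schedule_times(sched, duration, settings$dt)
  else {
    ns <- max(1L, ceiling(duration / settings$dt - 1e-9))
    seq(0, duration, length.out = ns + 1L)
  }

  bottom_dirichlet <- bottom_mode == "dirichlet"
  bvals <- numeric(length(times))
  if (bottom_dirichlet) {
    frac <- if (!is.null(sched)) evaluate_schedule(sched, times)
    else if (is.function(bottom)) bottom(times)
    else if (is.numeric(bottom) && length(bottom) == 1L) rep(bottom, length(times))
    else stop_domain("'bottom' must be a schedule, a function, or a fraction")
    if (any(!is.finite(frac)) || any(frac < 0) || any(frac > 1))
      stop_domain("bottom boundary fractions must lie in [0, 1]")
    bvals <- frac * .MMHG_PER_ATM
  }

  top <- stack$top_boundary
  top_dirichlet <- identical(top$type, "fixed_fraction")
  top_val <- if (top_dirichlet) top$fraction * .MMHG_PER_ATM else 0

  u0 <- if (is.null(init)) {
    f0 <- if (!is.null(sched)) sched$high else
      if (is.numeric(bottom) && length(bottom) == 1L) bottom else 0.2
    rep(f0 * .MMHG_PER_ATM, grid$n)
  } else if (inherits(init, "o2_field")) {
    init$values[, ncol(init$values)]
  } else if (is.numeric(init) && length(init) == 1L) {
    check_number(init, "init", lower = 0, upper = 1)
    rep(init * .MMHG_PER_ATM, grid$n)
  } else if (is.numeric(init) && length(init) == grid$n) {
    init
  } else stop_domain("'init' must be a fraction, a nodal vector (mmHg), or an o2_field")

  sys <- build_system(stack, grid)
  vals <- rd_march_cpp(u0, diff(times), bvals, bottom_dirichlet,
                       top_dirichlet, top_val,
                       sys$edge_k, sys$aV,
                       sys$r_lo, sys$a_lo, sys$km_lo,
                       sys$r_hi, sys$a_hi, sys$km_hi,
                       settings$theta, settings$newton_tol,
                       settings$newton_max_iter)
  structure(list(z = grid$z, times = times, values = vals,
                 grid = grid, stack = stack,
                 schedule = sched),
            class = "o2_field",
            period = if (!is.null(sched)) sched$period else NULL)
}

#' Iterate whole cycles to the periodic steady state
#'
#' Runs the schedule cycle by cycle, starting from a uniform normoxic field,
#' until the per-node cycle maxima and minima change by less than
#' `settings$psss_tol` (%O2) between consecutive cycles. Returns the
#' converged final cycle with the number of cycles used in
#' `attr(, "cycles")`.
#'
#' @inheritParams simulate_stack
#' @param schedule an [ih_schedule()].
#' @return An `o2_field` spanning exactly one period.
#' @export
run_to_periodic_steady_state <- function(stack, schedule, grid,
                                         settings = solver_settings(),
                                         init = NULL) {
  stopifnot(inherits(schedule, "ih_schedule"))
  state <- init
  prev <- NULL
  resid <- Inf
  for (cyc in seq_len(settings$psss_max_cycles)) {
    fld <- simulate_stack(stack, grid, settings, bottom = schedule,
                          duration = schedule$period, init = state)
    env <- cbind(apply(fld$values, 1, max), apply(fld$values, 1, min))
    if (!is.null(prev)) {
      resid <- max(abs(env - prev)) / .MMHG_PER_ATM * 100
      if (resid < settings$psss_tol) {
        attr(fld, "cycles") <- cyc
        attr(fld, "psss_residual") <- resid
        return(fld)
      }
    }
    prev <- env
    state <- fld$values[, ncol(fld$values)]
  }
  stop_domain(sprintf(
    "periodic steady state not reached in %d cycles (residual %.3g %%O2)",
    settings$psss_max_cycles, resid))
}

#' Sample an ideal depth trace from a field
#'
#' Linear interpolation in depth between adjacent nodes and in time between
#' stored steps; no sensor lag or noise (see [emulate_sensor()] for those).
#'
#' @param field an `o2_field`.
#' @param z depth, cm (inside the stack).
#' @param times times, s (default: the field's stored times).
#' @return A data.frame with `time_s` and `o2_percent`.
#' @export
sample_field <- function(field, z, times = NULL) {
  stopifnot(inherits(field, "o2_field"))
  check_number(z, "z", lower = min(field$z), upper = max(field$z))
  times <- times %||% field$times
  if (any(times < min(field$times) - 1e-9) ||
      any(times > max(field$times) + 1e-9))
    stop_domain("'times' outside the simulated span")
  i <- findInterval(z, field$z, rightmost.closed = TRUE)
  i <- min(max(i, 1L), length(field$z) - 1L)
  w <- (z - field$z[i]) / (field$z[i + 1L] - field$z[i])
  vz <- (1 - w) * field$values[i, ] + w * field$values[i + 1L, ]
  vt <- approx(field$times, vz, xout = times, rule = 2)$y
  data.frame(time_s = times, o2_percent = vt / .MMHG_PER_ATM * 100)
}

#' Repeat a periodic-steady-state cycle
#'
#' Tiles a one-cycle field end to end `n` times, producing a field spanning
#' `n` periods (used to feed multi-cycle sensor emulation and fitting).
#'
#' @param field a one-period `o2_field` from [run_to_periodic_steady_state()].
#' @param n number of cycles.
#' @return An `o2_field` spanning `n` periods.
#' @export
field_tile <- function(field, n) {
  stopifnot(inherits(field, "o2_field"))
  Tp <- attr(field, "period") %||% diff(range(field$times))
  n <- as.integer(n)
  if (n < 1L) stop_domain("'n' must be >= 1")
  nt <- length(field$times)
  # drop the duplicated cycle-start column when concatenating
  times <- field$times
  vals <- field$values
  for (k in seq_len(n - 1L)) {
    times <- c(times, field$times[-1L] + k * Tp)
    vals <- cbind(vals, field$values[, -1L, drop = FALSE])
  }
  out <- field
  out$times <- times
  out$values <- vals
  attr(out, "period") <- Tp
  attr(out, "cycles") <- attr(field, "cycles")
  out
}

#' Export a field as a tidy table
#'
#' @param field an `o2_field`.
#' @return A data.frame with columns `time_s`, `z_um`, `o2_percent`,
#'   `o2_mmHg`.
#' @export
field_to_df <- function(field) {
  stopifnot(inherits(field, "o2_field"))
  data.frame(
    time_s = rep(field$times, each = length(field$z)),
    z_um = rep(field$z * 1e4, times = length(field$times)),
    o2_percent = as.vector(field$values) / .MMHG_PER_ATM * 100,
    o2_mmHg = as.vector(field$values)
  )
}

#' @export
print.o2_field <- function(x, ...) {
  cat(sprintf("<o2_field> %d nodes x %d times, z %.0f..%.0f um, t %.1f..%.1f s\n",
              length(x$z), length(x$times), min(x$z) * 1e4, max(x$z) * 1e4,
              min(x$times), max(x$times)))
  cy <- attr(x, "cycles")
  if (!is.null(cy)) cat(sprintf("  periodic steady state after %d cycles\n", cy))
  invisible(x)
}
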