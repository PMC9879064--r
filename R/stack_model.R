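#' Define a diffusing medium
#'
#' A medium is a phase through which oxygen diffuses, characterised by a
#' diffusivity `D` (cm^2/s) and a Henry-law solubility `alpha`
#' (mol/(cm^3 atm)).
#'
#' PDMS solubility is not independently required by the model (partial
#' pressure, not concentration, is continuous across material interfaces);
#' [medium_pdms()] defaults `alpha` to the water value and flags it so
#' downstream code can warn that the value was defaulted.
#'
#' @param name label for the medium.
#' @param D diffusivity, cm^2/s.
#' @param alpha solubility, mol/(cm^3 atm).
#' @return A list of class `o2_medium`.
#' @export
medium <- function(name, D, alpha = ALPHA_O2_WATER) {
  check_number(D, "D", lower = 0, strict_lower = TRUE)
  check_number(alpha, "alpha", lower = 0, strict_lower = TRUE)
  structure(list(name = as.character(name), D = D, alpha = alpha),
            class = "o2_medium")
}

#' @rdname medium
#' @param species gas species, `"O2"` or `"CO2"`.
#' @export
medium_pdms <- function(species = "O2") {
  m <- medium("pdms", gas_constants(species)$D_pdms, ALPHA_O2_WATER)
  attr(m, "alpha_defaulted") <- TRUE
  m
}

#' @rdname medium
#' @export
medium_water <- function(species = "O2") {
  medium("water", gas_constants(species)$D_water, ALPHA_O2_WATER)
}

#' @rdname medium
#' @param fraction_of_water optional; if given, the hydrogel diffusivity is
#'   computed as `fraction_of_water * D_water` instead of the default printed
#'   value `D_O2_HYDROGEL`.
#' @export
medium_hydrogel <- function(fraction_of_water = NULL) {
  D <- if (is.null(fraction_of_water)) D_O2_HYDROGEL
  else {
    check_number(fraction_of_water, "fraction_of_water", lower = 0, upper = 1,
                 strict_lower = TRUE)
    fraction_of_water * gas_constants("O2")$D_water
  }
  medium("hydrogel", D, ALPHA_O2_WATER)
}

#' Define a layer of the culture stack
#'
#' A layer is a slab of one medium, optionally carrying cells that consume
#' oxygen with Michaelis-Menten kinetics: volumetric sink
#' `rho_cell * sOCR * C / (K_m + C)`.
#'
#' @param name label.
#' @param thickness slab thickness, cm (use [um()] for micrometre inputs).
#' @param medium an [medium()] object.
#' @param rho_cell cell density, cells/cm^3 (0 = acellular).
#' @param sOCR maximal single-cell O2 consumption rate, mol/(cell s).
#' @param K_m Michaelis constant, mol/cm^3.
#' @param role `"sample"`, `"membrane"` or `"media"`. Membrane layers must
#'   sit at the bottom of the stack; the coordinate origin z = 0 is placed at
#'   the membrane-sample interface.
#' @return A list of class `o2_layer`.
#' @export
#' @examples
#' layer("gel", um(500), medium_hydrogel())
layer <- function(name, thickness, medium, rho_cell = 0, sOCR = 0, K_m = NA,
                  role = c("sample", "membrane", "media")) {
  role <- match.arg(role)
  check_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  check_number(rho_cell, "rho_cell", lower = 0)
  if (!inherits(medium, "o2_medium")) stop_domain("'medium' must be an o2_medium")
  if (rho_cell > 0) {
    check_number(sOCR, "sOCR", lower = 0, strict_lower = TRUE)
    check_number(K_m, "K_m", lower = 0, strict_lower = TRUE)
  } else {
    sOCR <- 0; K_m <- 1  # inert placeholders, never used when rho_cell = 0
  }
  structure(list(name = as.character(name), thickness = thickness,
                 medium = medium, rho_cell = rho_cell, sOCR = sOCR,
                 K_m = K_m, role = role),
            class = "o2_layer")
}

#' @rdname layer
#' @export
membrane_layer <- function(thickness = um(165), species = "O2") {
  layer("membrane", thickness, medium_pdms(species), role = "membrane")
}

#' Assemble a layer stack
#'
#' Layers are ordered bottom (gas side) to top. The bottom boundary is a
#' Dirichlet partial pressure driven by an intermittent-hypoxia schedule (see
#' [simulate_stack()]); the top boundary is one of
#' `top_no_flux()` (sealed; the default), `top_fixed_fraction(f)` (held at a
#' fixed O2 fraction), or an explicit media layer added as the last layer
#' with `role = "media"` (with a sealed top above it).
#'
#' @param ... layers, bottom to top.
#' @param top_boundary [top_no_flux()] or [top_fixed_fraction()].
#' @return A list of class `o2_stack`.
#' @export
#' @examples
#' o2_stack(membrane_layer(), layer("gel", um(500), medium_hydrogel()))
o2_stack <- function(..., top_boundary = top_no_flux()) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) &&
      !inherits(layers[[1L]], "o2_layer"))
    layers <- layers[[1L]]
  if (length(layers) < 1L) stop_domain("a stack needs at least one layer")
  ok <- vapply(layers, inherits, logical(1), "o2_layer")
  if (!all(ok)) stop_domain("all stack elements must be o2_layer objects")
  roles <- vapply(layers, `[[`, character(1), "role")
  memb <- which(roles == "membrane")
  if (length(memb) && !identical(memb, seq_along(memb)))
    stop_domain("membrane layers must be the bottom-most layers of the stack")
  if (!is.list(top_boundary) || is.null(top_boundary$type))
    stop_domain("'top_boundary' must be top_no_flux() or top_fixed_fraction()")
  structure(list(layers = layers, top_boundary = top_boundary),
            class = "o2_stack")
}

#' @rdname o2_stack
#' @export
top_no_flux <- function() list(type = "no_flux")

#' @rdname o2_stack
#' @param fraction O2 fraction held at the top surface.
#' @export
top_fixed_fraction <- function(fraction) {
  check_number(fraction, "fraction", lower = 0, upper = 1)
  list(type = "fixed_fraction", fraction = fraction)
}

stack_thickness <- function(stack) {
  sum(vapply(stack$layers, `[[`, numeric(1), "thickness"))
}

# Thickness of the bottom membrane block; z = 0 sits at its top.
stack_membrane_offset <- function(stack) {
  roles <- vapply(stack$layers, `[[`, character(1), "role")
  memb <- which(roles == "membrane")
  if (!length(memb)) 0 else
    sum(vapply(stack$layers[memb], `[[`, numeric(1), "thickness"))
}

#' Intermittent-hypoxia gas schedule
#'
#' A square wave of O2 fraction in the gas chamber beneath the membrane: each
#' cycle starts with the high (normoxic) phase for `duty * period` seconds,
#' followed by the low (hypoxic) phase; phase intervals are half-open
#' `[start, end)`. An optional first-order gas-chamber lag `lag_tau` models
#' finite chamber washout: the delivered fraction relaxes exponentially
#' toward the current plateau, evaluated in its cycle-steady (periodic)
#' regime.
#'
#' @param high O2 fraction of the normoxic phase.
#' @param low O2 fraction of the hypoxic phase (`low <= high`).
#' @param period cycle period, s.
#' @param duty fraction of the period spent at `high` (default 0.5).
#' @param total_duration default run length, s (default one period).
#' @param lag_tau gas-chamber washout time constant, s (0 = ideal square wave).
#' @return A list of class `ih_schedule`.
#' @export
#' @examples
#' ih_schedule(0.20, 0.0, period = 60)           # severe-OSA-like 60 events/h
ih_schedule <- function(high, low, period, duty = 0.5,
                        total_duration = NULL, lag_tau = 0) {
  check_number(high, "high", lower = 0, upper = 1)
  check_number(low, "low", lower = 0, upper = 1)
  if (low > high) stop_domain("'low' must not exceed 'high'")
  check_number(period, "period", lower = 0, strict_lower = TRUE)
  check_number(duty, "duty", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(lag_tau, "lag_tau", lower = 0)
  total_duration <- total_duration %||% period
  check_number(total_duration, "total_duration", lower = period)
  structure(list(high = high, low = low, period = period, duty = duty,
                 total_duration = total_duration, lag_tau = lag_tau),
            class = "ih_schedule")
}

#' Build a schedule from an events-per-hour rate
#'
#' The clinical convention: `rate` events/h gives a period of `3600/rate`
#' seconds split half/half between the normoxic and hypoxic phase (60
#' events/h is 30 s high + 30 s low).
#'
#' @param rate events per hour (> 0).
#' @param high,low O2 fractions of the two phases.
#' @param total_duration default run length, s.
#' @param lag_tau optional gas-chamber lag, s.
#' @return An [ih_schedule()].
#' @export
schedule_from_events_per_hour <- function(rate, high, low,
                                          total_duration = NULL, lag_tau = 0) {
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  ih_schedule(high, low, period = 3600 / rate, duty = 0.5,
              total_duration = total_duration, lag_tau = lag_tau)
}

#' Evaluate a schedule's delivered O2 fraction at given times
#'
#' With `lag_tau = 0` this is the ideal square wave; with a positive lag the
#' chamber fraction follows the periodic steady state of a first-order
#' low-pass response to the square wave (closed form, so the waveform is
#' exactly periodic).
#'
#' @param s an [ih_schedule()].
#' @param t times, s (non-negative).
#' @return O2 fraction(s) at `t`.
#' @export
evaluate_schedule <- function(s, t) {
  stopifnot(inherits(s, "ih_schedule"))
  if (any(t < 0)) stop_domain("'t' must be non-negative")
  tm <- t %% s$period
  th <- s$duty * s$period
  if (s$lag_tau <= 0) {
    return(ifelse(tm < th, s$high, s$low))
  }
  tau <- s$lag_tau
  tl <- s$period - th
  eh <- exp(-th / tau); el <- exp(-tl / tau)
  # periodic steady state of the first-order filter
  v0 <- (s$low * (1 - el) + s$high * el * (1 - eh)) / (1 - eh * el)
  v1 <- s$high + (v0 - s$high) * eh
  ifelse(tm < th,
         s$high + (v0 - s$high) * exp(-tm / tau),
         s$low + (v1 - s$low) * exp(-(tm - th) / tau))
}

#' Discretize a stack into a spatial grid
#'
#' Node-centred grid with nodes at every layer interface; each layer is
#' subdivided uniformly with spacing at most `target_dz` and at least
#' `min_nodes` nodes. Coordinates follow the measurement convention: z = 0
#' at the membrane-sample interface, negative inside the membrane, positive
#' into the sample.
#'
#' @param stack an [o2_stack()].
#' @param target_dz desired node spacing, cm.
#' @param min_nodes minimum nodes per layer (default 20).
#' @return A list of class `o2_grid` with node positions `z` (cm), per-edge
#'   widths `edge_dz` and layer indices `edge_layer`.
#' @export
#' @examples
#' g <- build_grid(o2_stack(membrane_layer(),
#'                          layer("gel", um(500), medium_hydrogel())),
#'                 target_dz = um(10))
#' range(g$z)  # -0.0165 .. 0.05 cm
build_grid <- function(stack, target_dz, min_nodes = 20) {
  stopifnot(inherits(stack, "o2_stack"))
  check_number(target_dz, "target_dz", lower = 0, strict_lower = TRUE)
  th <- vapply(stack$layers, `[[`, numeric(1), "thickness")
  if (target_dz >= min(th))
    stop_domain("'target_dz' must be smaller than the thinnest layer")
  z <- 0; edge_dz <- numeric(0); edge_layer <- integer(0)
  pos <- 0
  for (i in seq_along(th)) {
    nint <- max(ceiling(th[i] / target_dz - 1e-9), min_nodes - 1L)
    dz <- th[i] / nint
    z <- c(z, pos + seq_len(nint) * dz)
    edge_dz <- c(edge_dz, rep(dz, nint))
    edge_layer <- c(edge_layer, rep(i, nint))
    pos <- pos + th[i]
  }
  z <- z - stack_membrane_offset(stack)
  # snap the final node onto the exact stack top to kill accumulation error
  z[length(z)] <- sum(th) - stack_membrane_offset(stack)
  structure(list(z = z, edge_dz = edge_dz, edge_layer = edge_layer,
                 n = length(z)),
            class = "o2_grid")
}
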