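CONFIG_SCHEMA_VERSION <- 1L

config_known_keys <- list(
  top = c("schema_version", "seed", "output_dir", "stack", "schedule",
          "grid", "solver", "sensor"),
  layer = c("name", "role", "thickness_um", "D_cm2_s", "alpha_mol_cm3_atm",
            "rho_cell_per_cm3", "sOCR_mol_cell_s", "K_m_mol_cm3"),
  stack = c("layers", "top_boundary"),
  top_boundary = c("type", "fraction"),
  schedule = c("events_per_hour", "period_s", "high_fraction", "low_fraction",
               "duty", "total_duration_s", "lag_tau_s"),
  grid = c("dz_um", "min_nodes"),
  solver = c("dt_s", "theta", "newton_tol", "newton_max_iter", "psss_tol",
             "psss_max_cycles"),
  sensor = c("t90_s", "noise_sd_percent", "sample_rate_hz", "seed")
)

check_keys <- function(x, allowed, section) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop_domain(sprintf("unknown key(s) in '%s': %s", section,
                        paste(extra, collapse = ", ")))
}

#' Parse and validate a run configuration
#'
#' A single YAML file drives a run: the layer stack, the gas schedule, grid
#' and solver controls, and the sensor model. Unknown keys are rejected,
#' every fraction is checked against `[0, 1]`, and defaulted physical
#' parameters (notably PDMS solubility, taken equal to water's) are
#' reported with a warning so silent defaults never enter an analysis.
#'
#' @param path path to a YAML config file.
#' @param quiet suppress default-value warnings.
#' @return A list of class `run_config` with components `stack`, `schedule`,
#'   `grid_dz`, `grid_min_nodes`, `settings`, `sensor`, `seed`,
#'   `output_dir`, and the normalised raw list in `$config` (hashable and
#'   serialisable).
#' @export
#' @examples
#' cfg <- parse_config(system.file("extdata", "example_config.yaml",
#'                                 package = "oxcycle"))
#' cfg$schedule$period
parse_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_domain(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_known_keys$top, "config")
  sv <- raw$schema_version %||% CONFIG_SCHEMA_VERSION
  if (!identical(as.integer(sv), CONFIG_SCHEMA_VERSION))
    stop_domain(sprintf("unrecognised schema_version: %s", sv))
  if (is.null(raw$stack) || is.null(raw$stack$layers))
    stop_domain("config must define stack: layers")
  if (is.null(raw$schedule)) stop_domain("config must define a schedule")
  check_keys(raw$stack, config_known_keys$stack, "stack")

  layers <- lapply(seq_along(raw$stack$layers), function(i) {
    ly <- raw$stack$layers[[i]]
    check_keys(ly, config_known_keys$layer, sprintf("stack.layers[%d]", i))
    if (is.null(ly$thickness_um))
      stop_domain(sprintf("stack.layers[%d].thickness_um is required", i))
    role <- ly$role %||% "sample"
    name <- ly$name %||% sprintf("layer%d", i)
    D <- ly$D_cm2_s %||% switch(role,
      membrane = gas_constants("O2")$D_pdms,
      media = gas_constants("O2")$D_water,
      D_O2_HYDROGEL)
    alpha <- ly$alpha_mol_cm3_atm
    if (is.null(alpha)) {
      alpha <- ALPHA_O2_WATER
      if (!quiet && identical(role, "membrane"))
        warning(sprintf("stack.layers[%d]: PDMS solubility defaulted to the water value %g",
                        i, ALPHA_O2_WATER), call. = FALSE)
    }
    layer(name, um(ly$thickness_um), medium(name, D, alpha),
          rho_cell = ly$rho_cell_per_cm3 %||% 0,
          sOCR = ly$sOCR_mol_cell_s %||% 0,
          K_m = ly$K_m_mol_cm3 %||% NA,
          role = role)
  })
  tb_raw <- raw$stack$top_boundary %||% list(type = "no_flux")
  check_keys(tb_raw, config_known_keys$top_boundary, "stack.top_boundary")
  tb <- switch(tb_raw$type %||% "no_flux",
    no_flux = top_no_flux(),
    fixed_fraction = {
      if (is.null(tb_raw$fraction))
        stop_domain("stack.top_boundary.fraction is required for fixed_fraction")
      top_fixed_fraction(tb_raw$fraction)
    },
    stop_domain(sprintf("unknown top_boundary type: %s", tb_raw$type)))
  stack <- o2_stack(layers, top_boundary = tb)

  sc <- raw$schedule
  check_keys(sc, config_known_keys$schedule, "schedule")
  for (k in c("high_fraction", "low_fraction"))
    if (is.null(sc[[k]])) stop_domain(sprintf("schedule.%s is required", k))
  for (k in c("high_fraction", "low_fraction")) {
    v <- sc[[k]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_domain(sprintf("schedule.%s must lie in [0, 1] (got %s)", k, v))
  }
  period <- if (!is.null(sc$events_per_hour)) 3600 / sc$events_per_hour
  else sc$period_s %||% 60
  schedule <- ih_schedule(sc$high_fraction, sc$low_fraction, period,
                          duty = sc$duty %||% 0.5,
                          total_duration = sc$total_duration_s %||% NULL,
                          lag_tau = sc$lag_tau_s %||% 0)

  gr <- raw$grid %||% list()
  check_keys(gr, config_known_keys$grid, "grid")
  so <- raw$solver %||% list()
  check_keys(so, config_known_keys$solver, "solver")
  settings <- solver_settings(
    dt = so$dt_s %||% (schedule$period / 600),
    theta = so$theta %||% 1,
    newton_tol = so$newton_tol %||% 1e-10,
    newton_max_iter = so$newton_max_iter %||% 25L,
    psss_tol = so$psss_tol %||% 1e-3,
    psss_max_cycles = so$psss_max_cycles %||% 200L)
  se <- raw$sensor %||% list()
  check_keys(se, config_known_keys$sensor, "sensor")
  sensor <- sensor_spec(t90 = se$t90_s %||% 2,
                        noise_sd = se$noise_sd_percent %||% 0.2,
                        sample_rate = se$sample_rate_hz %||% 1,
                        seed = se$seed %||% raw$seed %||% 1L)

  norm <- normalise_config(stack, schedule, gr, settings, sensor,
                           raw$seed %||% 1L, raw$output_dir %||% ".")
  structure(list(stack = stack, schedule = schedule,
                 grid_dz = um(gr$dz_um %||% 10),
                 grid_min_nodes = gr$min_nodes %||% 20,
                 settings = settings, sensor = sensor,
                 seed = as.integer(raw$seed %||% 1L),
                 output_dir = raw$output_dir %||% ".",
                 config = norm),
            class = "run_config")
}

# Fully-defaulted canonical form of a configuration (what gets hashed and
# what serialize_config() writes).
normalise_config <- function(stack, schedule, gr, settings, sensor, seed,
                             output_dir) {
  list(
    schema_version = CONFIG_SCHEMA_VERSION,
    seed = as.integer(seed),
    output_dir = output_dir,
    stack = list(
      layers = lapply(stack$layers, function(l) list(
        name = l$name, role = l$role, thickness_um = l$thickness * 1e4,
        D_cm2_s = l$medium$D, alpha_mol_cm3_atm = l$medium$alpha,
        rho_cell_per_cm3 = l$rho_cell, sOCR_mol_cell_s = l$sOCR,
        K_m_mol_cm3 = l$K_m)),
      top_boundary = stack$top_boundary),
    schedule = list(period_s = schedule$period,
                    high_fraction = schedule$high,
                    low_fraction = schedule$low, duty = schedule$duty,
                    total_duration_s = schedule$total_duration,
                    lag_tau_s = schedule$lag_tau),
    grid = list(dz_um = gr$dz_um %||% 10, min_nodes = gr$min_nodes %||% 20),
    solver = list(dt_s = settings$dt, theta = settings$theta,
                  newton_tol = settings$newton_tol,
                  newton_max_iter = settings$newton_max_iter,
                  psss_tol = settings$psss_tol,
                  psss_max_cycles = settings$psss_max_cycles),
    sensor = list(t90_s = sensor$t90, noise_sd_percent = sensor$noise_sd,
                  sample_rate_hz = sensor$sample_rate, seed = sensor$seed))
}

#' Serialise a run configuration back to YAML
#'
#' Writes the fully-defaulted canonical form; `parse_config()` on the
#' result reproduces an equal configuration (round trip).
#'
#' @param cfg a `run_config` from [parse_config()].
#' @param path output path; if `NULL`, the YAML text is returned.
#' @export
serialize_config <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  txt <- yaml::as.yaml(cfg$config)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

# MD5 of the canonical YAML serialisation of any list-like object.
hash_object <- function(x) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  writeLines(yaml::as.yaml(x), tf)
  unname(tools::md5sum(tf))
}

#' @rdname serialize_config
#' @return `config_hash()`: the MD5 hash of the canonical serialisation.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  hash_object(cfg$config)
}

#' Write and read delimited tables with a provenance header
#'
#' All package outputs are comma-separated UTF-8 text with `.` decimal
#' marks, LF line endings, a header row, and `#`-prefixed provenance lines
#' (package version, config hash, seed) so every artifact can be traced to
#' the configuration that produced it. No timestamps are written: identical
#' inputs give byte-identical files.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param config_hash hash string from [config_hash()] (optional).
#' @param seed seed used for any stochastic content (optional).
#' @export
write_o2_table <- function(df, path, config_hash = NA, seed = NA) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  hdr <- c(sprintf("# oxcycle %s", as.character(packageVersion("oxcycle"))),
           sprintf("# config_hash: %s", config_hash),
           sprintf("# seed: %s", seed))
  writeLines(hdr, con, sep = "\n")
  write.table(df, con, sep = ",", dec = ".", row.names = FALSE,
              col.names = TRUE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_o2_table
#' @export
read_o2_table <- function(path) {
  read.csv(path, comment.char = "#")
}

#' @rdname write_o2_table
#' @param z depth of the trace, cm (stored traces carry depth in their
#'   manifest, not in the table).
#' @param spec [sensor_spec()] to attach to the re-read trace.
#' @export
read_sensor_trace <- function(path, z, spec = sensor_spec()) {
  df <- read_o2_table(path)
  if (!all(c("time_s", "o2_percent") %in% names(df)))
    stop_domain("trace file must have columns time_s, o2_percent")
  structure(list(z = z, times = df$time_s, values = df$o2_percent,
                 spec = spec, provenance = NA_character_),
            class = "sensor_trace")
}
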