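#' Simulation configuration
#'
#' Flat key-value configuration with strict validation. Unknown keys are
#' rejected so that typos in physical parameters cannot pass silently.
#' Defaults describe the standard 15 x 1 cell-network strand with the
#' default tissue parameters and an S1 stimulus.
#'
#' @format Recognized keys (all numeric unless noted): `model` ("knm" or
#'   "bd"), `nx`, `ny` (cells), `dx`, `dy` (bidomain spacings, um),
#'   `cell_length`, `end_radius`, `center_radius`, `margin`, `l_y`, `l_z`
#'   (um), `sigma_i`, `sigma_e` (mS/cm), `c_m` (uF/cm2), `r_g` (kOhm cm2),
#'   `rg_multiplier`, `membrane` (model name), `protocol` ("s1" or "s1s2"),
#'   `s2_delay`, `stim_amplitude`, `stim_duration`, `dt`, `duration`,
#'   `cadence`, `threshold`, `solver_tol`, `out_prefix` (character).
#' @name sim_config
NULL

config_defaults <- function() {
  list(model = "knm", nx = 15, ny = 1, dx = NA_real_, dy = NA_real_,
       cell_length = 120, end_radius = 6, center_radius = 7, margin = 2,
       l_y = NA_real_, l_z = NA_real_,
       sigma_i = 4, sigma_e = 20, c_m = 1, r_g = 0.0015, rg_multiplier = 1,
       membrane = "mitchell_schaeffer",
       protocol = "s1", s2_delay = 240,
       stim_amplitude = 40, stim_duration = 2,
       dt = 0.01, duration = 50, cadence = 1, threshold = -20,
       solver_tol = 1e-10, out_prefix = "knm_run")
}

config_character_keys <- c("model", "membrane", "protocol", "out_prefix")

#' Load and validate a simulation configuration
#'
#' Reads a plain-text file of `key = value` lines (`#` starts a comment;
#' empty files are allowed and yield the all-defaults configuration), fills
#' in defaults, and validates every value. Unknown keys and invalid values
#' raise errors naming the offending key.
#'
#' @param path Path to the configuration file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A validated configuration list of class `sim_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  entries <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE))
        stop(sprintf("config line is not 'key = value': '%s'", ln), call. = FALSE)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      entries[[key]] <- val
    }
  }
  for (nm in names(overrides)) entries[[nm]] <- overrides[[nm]]

  for (key in names(entries)) {
    if (!key %in% names(cfg))
      stop(sprintf("unknown configuration key '%s'", key), call. = FALSE)
    val <- entries[[key]]
    if (key %in% config_character_keys) {
      cfg[[key]] <- as.character(val)
    } else if (identical(as.character(val), "NA") &&
               key %in% c("dx", "dy", "l_y", "l_z")) {
      cfg[[key]] <- NA_real_     # "use the geometry default"
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num))
        stop(sprintf("configuration key '%s' must be numeric, got '%s'", key, val),
             call. = FALSE)
      cfg[[key]] <- num
    }
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!cfg$model %in% c("knm", "bd"))
    stop("config 'model' must be \"knm\" or \"bd\"", call. = FALSE)
  if (!cfg$protocol %in% c("s1", "s1s2"))
    stop("config 'protocol' must be \"s1\" or \"s1s2\"", call. = FALSE)
  positive <- c("nx", "ny", "cell_length", "end_radius", "center_radius",
                "sigma_i", "sigma_e", "c_m", "r_g", "rg_multiplier",
                "stim_amplitude", "stim_duration", "dt", "cadence", "solver_tol")
  for (key in positive)
    if (!is.finite(cfg[[key]]) && key != "cadence" || isTRUE(cfg[[key]] <= 0))
      stop(sprintf("configuration key '%s' must be strictly positive", key),
           call. = FALSE)
  for (key in c("duration", "s2_delay", "margin"))
    if (!is.finite(cfg[[key]]) || cfg[[key]] < 0)
      stop(sprintf("configuration key '%s' must be non-negative", key),
           call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Serialize a configuration back to its text format
#'
#' @param cfg A `sim_config`.
#' @param path Output path; `NULL` returns the lines.
#' @return The lines, invisibly when written.
#' @export
save_config <- function(cfg, path = NULL) {
  fmt <- function(v) if (is.character(v)) v else format(v, digits = 17)
  lines <- sprintf("%s = %s", names(cfg), vapply(unclass(cfg), fmt, character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

config_geometry <- function(cfg) {
  cell_geometry(length = cfg$cell_length, end_radius = cfg$end_radius,
                center_radius = cfg$center_radius, margin = cfg$margin,
                l_y = if (is.na(cfg$l_y)) NULL else cfg$l_y,
                l_z = if (is.na(cfg$l_z)) NULL else cfg$l_z)
}

config_params <- function(cfg) {
  tissue_params(sigma_i = cfg$sigma_i, sigma_e = cfg$sigma_e, C_m = cfg$c_m,
                R_g = cfg$r_g, rg_multiplier = cfg$rg_multiplier)
}

config_network <- function(cfg) {
  geom <- config_geometry(cfg)
  params <- config_params(cfg)
  if (cfg$model == "knm")
    build_grid_network(cfg$nx, cfg$ny, geom, params)
  else
    bd_grid(cfg$nx, cfg$ny,
            dx = if (is.na(cfg$dx)) NULL else cfg$dx,
            dy = if (is.na(cfg$dy)) NULL else cfg$dy,
            geom = geom, params = params)
}

config_protocol <- function(cfg, net) {
  if (cfg$protocol == "s1")
    s1_protocol(net, cfg$stim_amplitude, cfg$stim_duration)
  else
    s1_s2_protocol(net, cfg$s2_delay, cfg$stim_amplitude, cfg$stim_duration)
}

#' Run a simulation from a configuration
#'
#' @param cfg A `sim_config` from [load_config()].
#' @return A `knm_trace`.
#' @export
run_config <- function(cfg) {
  net <- config_network(cfg)
  simulate_knm(net, model = get_membrane_model(cfg$membrane),
               protocol = config_protocol(cfg, net),
               dt = cfg$dt, duration = cfg$duration, cadence = cfg$cadence,
               threshold = cfg$threshold, solver_tol = cfg$solver_tol)
}

#' Write trace outputs
#'
#' Writes `<prefix>_activations.csv` (per-node activation times),
#' `<prefix>_trace.rds` (the full trace container, R serialization,
#' including the resolved configuration echo) and `<prefix>_manifest.json`
#' (run summary and resolved configuration).
#'
#' @param trace A `knm_trace`.
#' @param prefix Output path prefix.
#' @return Invisibly, the written file paths.
#' @export
write_trace <- function(trace, prefix) {
  acts <- data.frame(
    node = rep(seq_along(trace$activations), lengths(trace$activations)),
    t_activation_ms = if (length(unlist(trace$activations)))
      unlist(trace$activations) else numeric(0))
  paths <- c(activations = paste0(prefix, "_activations.csv"),
             trace = paste0(prefix, "_trace.rds"),
             manifest = paste0(prefix, "_manifest.json"))
  utils::write.csv(acts, paths["activations"], row.names = FALSE)
  saveRDS(trace, paths["trace"], version = 3)
  jsonlite::write_json(
    list(container = "knm_trace", schema_version = "1",
         n_nodes = trace$net$n_nodes, n_snapshots = length(trace$times),
         t_end_ms = max(trace$times), dt_ms = trace$dt,
         max_kirchhoff_residual_uA = trace$max_residual,
         n_activated = sum(lengths(trace$activations) > 0),
         config = trace$config),
    paths["manifest"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
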