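## Experiment configuration and orchestration: one reproducible run from a
## declarative YAML config through landscape generation, the Monte Carlo
## ensemble, GHG accounting, attribution and risk tables, to files on disk.

default_experiment_config <- function() {
  list(
    master_seed = 1L,
    landscape = list(n_regions = 4L, segments_per_region = 1000L, n_pool = 300L),
    scenarios = list(rcps = "RCP4.5",
                     harvests = c("NoHarv", "LowHarv", "BaseHarv", "MaxHarv")),
    simulation = list(n_sim = 50L, n_pixels = 500L,
                      years = c(2015L, 2050L),
                      spin_up_tolerance = 1e-4, spin_up_max_cycles = 300L),
    attribution = list(years = c(2015L, 2035L, 2050L),
                       outputs = c("nbe", "nee", "ecosystem_c")),
    risk = list(year = 2035L, output = "nbe")
  )
}

merge_defaults <- function(cfg, defaults, path = "", strict = TRUE) {
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    msg <- paste0("unknown config key(s): ",
                  paste0(path, unknown, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out <- defaults
  for (k in intersect(names(cfg), names(defaults))) {
    if (is.list(defaults[[k]]) && is.list(cfg[[k]])) {
      out[[k]] <- merge_defaults(cfg[[k]], defaults[[k]],
                                 paste0(path, k, "."), strict)
    } else {
      out[[k]] <- cfg[[k]]
    }
  }
  out
}

validate_experiment_config <- function(cfg) {
  if (cfg$simulation$n_sim < 1) {
    stop("config field simulation.n_sim must be >= 1", call. = FALSE)
  }
  if (cfg$landscape$n_regions < 1) {
    stop("config field landscape.n_regions must be >= 1", call. = FALSE)
  }
  if (length(cfg$simulation$years) != 2 ||
      cfg$simulation$years[1] > cfg$simulation$years[2]) {
    stop("config field simulation.years must be c(first, last)", call. = FALSE)
  }
  if (!all(cfg$scenarios$rcps %in% RCP_LABELS)) {
    stop("config field scenarios.rcps has unknown labels", call. = FALSE)
  }
  invisible(cfg)
}

#' Load an experiment configuration
#'
#' Reads a YAML config, merges it over the documented defaults (so a minimal
#' file resolves fully), validates it and returns the resolved configuration.
#' Unknown keys are an error in strict mode, a warning otherwise.
#'
#' @param path YAML file path.
#' @param strict error on unknown keys (default) instead of warning.
#' @return resolved config list of class `fc_experiment_config`.
#' @export
load_config <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg <- merge_defaults(cfg, default_experiment_config(), strict = strict)
  validate_experiment_config(cfg)
  structure(cfg, class = "fc_experiment_config")
}

#' Dump a resolved configuration
#'
#' @param config resolved config.
#' @param path output YAML file.
#' @return the path, invisibly. Load-dump-load round-trips losslessly.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a full experiment
#'
#' Executes generate (landscape) -> simulate (Monte Carlo ensemble) ->
#' attribute (redundancy indices) -> risk (eCDF tables) from one resolved
#' configuration. The bundle is a pure function of the configuration.
#'
#' @param config an `fc_experiment_config` (or a path to one).
#' @return list of class `fc_bundle`: `landscape`, `ensemble`,
#'   `attribution`, `risk`, `config`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- load_config(config)
  validate_experiment_config(config)
  landscape <- generate_landscape(
    n_regions = config$landscape$n_regions,
    segments_per_region = config$landscape$segments_per_region,
    seed = config$master_seed,
    n_pool = config$landscape$n_pool)
  sim_cfg <- simulation_config(
    n_sim = config$simulation$n_sim,
    n_pixels = config$simulation$n_pixels,
    years = config$simulation$years[1]:config$simulation$years[2],
    master_seed = config$master_seed,
    spin_up_tolerance = config$simulation$spin_up_tolerance,
    spin_up_max_cycles = config$simulation$spin_up_max_cycles)
  grid <- scenario_grid(config$scenarios$rcps, config$scenarios$harvests)
  ensemble <- run_monte_carlo(landscape, grid, sim_cfg)
  attribution <- attribute_sources(
    ensemble,
    years = intersect(config$attribution$years, sim_cfg$years),
    outputs = config$attribution$outputs,
    regions = names(ensemble$region_areas))
  risk <- risk_curves(ensemble, year = config$risk$year,
                      output = config$risk$output)
  structure(list(landscape = landscape, ensemble = ensemble,
                 attribution = attribution, risk = risk, config = config),
            class = "fc_bundle")
}

#' Write experiment outputs
#'
#' Writes the tidy CSV tables (ensemble outputs, feature records,
#' attribution, risk curves and widths), the resolved configuration, and a
#' manifest with MD5 checksums.
#'
#' @param bundle an `fc_bundle`.
#' @param directory output directory (created if missing).
#' @return data.frame manifest (file, md5), invisibly written as
#'   `manifest.csv`.
#' @export
write_outputs <- function(bundle, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    ensemble_outputs = bundle$ensemble$outputs,
    ensemble_features = bundle$ensemble$features,
    attribution = bundle$attribution,
    risk_curves = bundle$risk$curves,
    risk_widths = bundle$risk$widths)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(directory, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  cfgf <- file.path(directory, "config.yml")
  dump_config(bundle$config, cfgf)
  files <- c(files, cfgf)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
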