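#' Default configuration tree
#'
#' The canonical nested configuration with every recognized key and its
#' default. [load_config()] validates user YAML against this schema.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    schema_version = 1L,
    flow = list(
      spectrum = "karman-obukhov",
      k_max = 8,
      u_mean = 0.5,
      decorrelation_exponent = 2 / 3,
      seed = 1L
    ),
    resource = list(
      width = 0.1,
      rate = 1,
      grid_n = 256L,
      dt = 0.05,
      kernel = "exponential"
    ),
    agents = list(
      speed = 0.2,
      angular_noise = 1,
      interaction_range = 0.1,
      half_saturation = NULL,
      search_gain = 0
    ),
    evolution = list(
      population_size = 512L,
      initial_signallers = 8L,
      generations = 100L,
      cost = 0,
      mutation_rate = 0,
      season_length = NULL,
      spinup_time = 10
    ),
    reduced = list(
      R = 0.05,
      T_persist = 50,
      v = 0.1,
      N_S = 8L,
      N_NS = 8L,
      angular_noise = 1,
      duration = 2000
    )
  )
}

validate_against <- function(user, defaults, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults)) {
      stop("unknown configuration key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]]) && !is.list(user[[key]])) {
      stop("configuration key ", full, " must be a mapping", call. = FALSE)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- validate_against(user[[key]], defaults[[key]], full)
    } else if (!is.null(user[[key]])) {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_config_values <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!ok) stop("invalid value for ", key, ": ", msg, call. = FALSE)
  }
  chk(cfg$flow$u_mean >= 0, "flow.u_mean", "must be nonnegative")
  chk(cfg$flow$k_max >= 1, "flow.k_max", "must be at least 1")
  chk(cfg$resource$width > 0 && cfg$resource$width < 0.5,
    "resource.width", "must be in (0, 0.5)"
  )
  chk(cfg$resource$rate >= 0, "resource.rate", "must be nonnegative")
  chk(cfg$resource$grid_n >= 8, "resource.grid_n", "must be at least 8")
  chk(cfg$resource$dt > 0 && cfg$resource$dt <= 0.5, "resource.dt",
    "must be in (0, 0.5]"
  )
  chk(cfg$resource$kernel %in% c("exponential", "gaussian"),
    "resource.kernel", "must be 'exponential' or 'gaussian'"
  )
  chk(cfg$agents$speed >= 0, "agents.speed", "must be nonnegative")
  chk(cfg$agents$interaction_range >= 0 &&
    cfg$agents$interaction_range <= sqrt(2) / 2,
  "agents.interaction_range", "must be in [0, sqrt(2)/2]"
  )
  chk(cfg$evolution$cost >= 0, "evolution.cost", "must be nonnegative")
  chk(cfg$evolution$mutation_rate >= 0 && cfg$evolution$mutation_rate <= 1,
    "evolution.mutation_rate", "must be in [0, 1]"
  )
  chk(cfg$evolution$initial_signallers <= cfg$evolution$population_size,
    "evolution.initial_signallers", "cannot exceed population_size"
  )
  chk(cfg$reduced$R > 0 && cfg$reduced$R < 0.5, "reduced.R", "must be in (0, 0.5)")
  chk(cfg$reduced$T_persist > 0, "reduced.T_persist", "must be positive")
  chk(cfg$reduced$v > 0, "reduced.v", "must be positive")
  invisible(cfg)
}

#' Load and validate a YAML configuration file
#'
#' Unknown keys are rejected with an error naming the offending key;
#' recognized keys override the [default_config()] values, which are also
#' range-checked. An empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- validate_against(user, default_config())
  check_config_values(cfg)
  cfg
}

#' Serialize a configuration to canonical YAML
#'
#' @param cfg configuration list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' Derive a deterministic per-component child seed
#'
#' Combines the master seed with a polynomial hash of the component name
#' modulo a Mersenne prime, giving stable, well-separated streams for the
#' flow, the agents, and each generation.
#'
#' @param master_seed integer master seed.
#' @param component_name character label of the consuming component.
#' @return integer child seed in `[1, 2^31 - 2]`.
#' @export
seed_spawn <- function(master_seed, component_name) {
  p <- 2147483647 # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(component_name)) {
    h <- (h * 131 + code) %% p
  }
  s <- (as.numeric(master_seed) %% p + 1) %% p
  # two multiplicative mixes keep nearby master seeds / names apart
  child <- (s * 48271) %% p
  child <- (child + h * 16807) %% p
  as.integer(child %% (p - 2) + 1)
}

#' Write simulation records to disk
#'
#' Lossless round-trip serialization of record tables (CSV or JSON). A CSV
#' of an empty record set keeps the header line.
#'
#' @param records a data.frame.
#' @param path output file.
#' @param format `"csv"` or `"json"`. (`"netcdf"` is not supported by this
#'   build; field grids can be dumped as CSV.)
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = c("csv", "json")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unsupported record format: ", format[1], call. = FALSE)
  })
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else {
    jsonlite::write_json(records, path, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' Read records written by [write_records()]
#'
#' @param path input file.
#' @param format `"csv"` or `"json"`.
#' @return data.frame.
#' @export
read_records <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' Build a reproducibility manifest for a run
#'
#' Captures the configuration snapshot, the master seed, the derived
#' component seeds, and the package version, so a run can be replayed
#' bit-identically.
#'
#' @param cfg configuration list.
#' @param master_seed integer master seed.
#' @param components character vector of component names to derive seeds
#'   for.
#' @return manifest list (write with [write_manifest()]).
#' @export
run_manifest <- function(cfg, master_seed,
                         components = c("flow", "agents", "reduced")) {
  seeds <- vapply(components, function(nm) seed_spawn(master_seed, nm), integer(1))
  list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("coopsignal")),
    master_seed = as.integer(master_seed),
    component_seeds = as.list(seeds),
    config = cfg,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}

#' @rdname run_manifest
#' @param manifest a manifest list.
#' @param path output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Frozen small test scenarios
#'
#' Named, seeded parameter sets used by the test-suite and examples; their
#' regeneration is deterministic.
#'
#' @param name one of `"fig4-small"` (reduced-model uptake curves over a
#'   signaller-count grid), `"flow-small"` (flow diagnostics), and
#'   `"evolve-small"` (a scaled-down evolutionary run).
#' @return a named parameter list.
#' @export
scenario_fixture <- function(name = c("fig4-small", "flow-small", "evolve-small")) {
  name <- match.arg(name)
  switch(name,
    "fig4-small" = list(
      name = name, R = 0.05, T_persist = 50, v = 0.1,
      N_S_grid = c(2L, 4L, 8L, 16L, 32L), N_NS = 8L,
      duration = 2000, seed = 41L
    ),
    "flow-small" = list(
      name = name, k_max = 8, U_target = 0.5, grid_n = 64L,
      dt = 0.05, seed = 42L
    ),
    "evolve-small" = list(
      name = name, population_size = 128L, initial_signallers = 8L,
      generations = 30L, season_length = 15, dt = 0.05, grid_n = 64L,
      width = 0.1, u_mean = 0.3, speed = 0.2, interaction_range = 0.1,
      seed = 43L
    )
  )
}
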