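#' Configuration for the generational evolutionary simulation
#'
#' Each generation is one foraging season in a fresh realization of the
#' turbulent resource environment, after which individuals reproduce in
#' proportion to fitness (normalized uptake rate minus signalling cost) via
#' roulette-wheel selection. Phenotypes are inherited (optionally with
#' mutation); the population size is constant.
#'
#' @param population_size total agents per generation (default 512).
#' @param initial_signallers signallers seeded into generation one
#'   (default 8: signalling needs a small critical threshold to be viable,
#'   so a handful of founders is required).
#' @param generations number of generations to simulate.
#' @param cost signalling cost per unit time as a fraction of the mean
#'   resource concentration (levied at a constant rate on the signalling
#'   phenotype, not per signal).
#' @param mutation_rate per-offspring phenotype flip probability
#'   (default 0: pure selection on standing variation).
#' @param season_length foraging time per generation. The default lets a
#'   solitary agent cross the domain about 50 times
#'   (`50 / behaviour$speed` time units).
#' @param dt integration time step.
#' @param spinup_time field spin-up time before agents are released each
#'   season (the field mean reaches `1 - exp(-t)` of its asymptote).
#' @param grid_n resource grid resolution.
#' @param flow a [spectrum_spec()] describing the carrier flow (its
#'   `U_target` is the environmental mean-speed parameter).
#' @param source a [source_spec()] (its `width` is the environmental
#'   source-scale parameter psi).
#' @param behaviour a [behaviour_params()].
#' @param seed master seed; per-generation flow/agent seeds are derived
#'   from it with [seed_spawn()].
#' @return an object of class `"evolution_config"`.
#' @export
evolution_config <- function(population_size = 512,
                             initial_signallers = 8,
                             generations = 100,
                             cost = 0,
                             mutation_rate = 0,
                             season_length = NULL,
                             dt = 0.05,
                             spinup_time = 10,
                             grid_n = 256L,
                             flow = spectrum_spec(),
                             source = source_spec(),
                             behaviour = behaviour_params(),
                             seed = 1L) {
  if (initial_signallers < 0 || initial_signallers > population_size) {
    stop("initial_signallers must lie in [0, population_size]")
  }
  if (cost < 0) stop("cost must be nonnegative")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate must be in [0, 1]")
  if (is.null(season_length)) season_length <- 50 / max(behaviour$speed, 0.01)
  structure(list(
    population_size = as.integer(population_size),
    initial_signallers = as.integer(initial_signallers),
    generations = as.integer(generations),
    cost = cost, mutation_rate = mutation_rate,
    season_length = season_length, dt = dt,
    spinup_time = spinup_time, grid_n = as.integer(grid_n),
    flow = flow, source = source, behaviour = behaviour,
    seed = as.integer(seed)
  ), class = "evolution_config")
}

#' Fitness from foraging uptake and signalling cost
#'
#' Fitness is the uptake rate normalized by the mean resource concentration
#' (so a baseline random-walk forager scores 1), minus the constant-rate
#' signalling cost for the signalling phenotype, floored at zero for
#' selection:
#' \deqn{w_i = \max\!\big(u_i / (\bar\phi\, L) - c\,[i \in S],\ 0\big)}
#' with `u_i` the accumulated uptake, `L` the season length and `c` the
#' cost as a fraction of the mean concentration per unit time.
#'
#' @param uptake per-agent accumulated uptake (concentration x time).
#' @param phenotype per-agent `"S"`/`"NS"`.
#' @param cost signalling cost rate (fraction of mean concentration).
#' @param mean_resource season-mean resource concentration (> 0).
#' @param season_length season duration (> 0).
#' @return per-agent nonnegative fitness.
#' @export
fitness <- function(uptake, phenotype, cost, mean_resource, season_length) {
  if (mean_resource <= 0) stop("mean_resource must be positive for normalization")
  stopifnot(season_length > 0)
  norm_rate <- uptake / (mean_resource * season_length)
  pmax(norm_rate - cost * (phenotype == "S"), 0)
}

#' Roulette-wheel selection
#'
#' Draws parents i.i.d. with probability proportional to fitness. If every
#' fitness is zero the generation is degenerate; parents are then drawn
#' uniformly and the condition is flagged with a warning.
#'
#' @param fitnesses nonnegative weights.
#' @param n_offspring number of parents to draw.
#' @return integer parent indices.
#' @export
roulette_select <- function(fitnesses, n_offspring) {
  if (any(fitnesses < 0)) stop("fitnesses must be nonnegative")
  if (sum(fitnesses) == 0) {
    warning("all-zero fitness: degenerate generation, selecting uniformly")
    fitnesses <- rep(1, length(fitnesses))
  }
  sample.int(length(fitnesses), n_offspring, replace = TRUE, prob = fitnesses)
}

#' Simulate one generation: season, fitness, selection
#'
#' Draws a fresh flow realization and spins the resource field up to its
#' statistical steady state, releases the population at uniform random
#' positions, simulates the foraging season, computes fitness, and selects
#' offspring phenotypes by roulette wheel (with optional mutation).
#'
#' @param config an [evolution_config()].
#' @param phenotypes character vector of `"S"`/`"NS"` for this generation.
#' @param generation generation index (used to derive per-generation seeds).
#' @return list with `record` (one-row data.frame: signaller count, mean
#'   normalized uptake and fitness per phenotype, relative uptake
#'   `F_S/F_NS`, flagged `NA` when undefined) and `offspring` (next
#'   generation's phenotypes).
#' @export
run_generation <- function(config, phenotypes, generation = 1L) {
  stopifnot(inherits(config, "evolution_config"))
  n <- config$population_size
  stopifnot(length(phenotypes) == n)
  flow_seed <- seed_spawn(config$seed, paste0("flow-", generation))
  agent_seed <- seed_spawn(config$seed, paste0("agents-", generation))

  modes <- init_flow(config$flow, flow_seed,
    calibration_n = max(128L, config$grid_n)
  )
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(agent_seed)

  src <- config$source
  src$centre <- stats::runif(2)
  field <- resource_field(config$grid_n, 0)
  dt <- config$dt
  for (i in seq_len(ceiling(config$spinup_time / dt))) {
    modes <- step_flow(modes, dt)
    st <- step_resource(field, modes, src, dt)
    field <- st$field
    src <- st$src
  }

  n_sig <- sum(phenotypes == "S")
  ord <- order(phenotypes != "S") # signallers first, stable
  pop <- make_population(n, n_sig)
  pop$phenotype <- phenotypes[ord]
  mean_start <- field$mean_integral
  n_steps <- ceiling(config$season_length / dt)
  for (i in seq_len(n_steps)) {
    modes <- step_flow(modes, dt)
    vel <- velocity_grid(modes, config$grid_n)
    st <- step_resource(field, modes, src, dt, vel = vel)
    field <- st$field
    src <- st$src
    pop <- step_population(pop, modes, field, config$behaviour, dt, vel = vel)
  }
  season <- n_steps * dt
  mean_resource <- (field$mean_integral - mean_start) / season

  w <- fitness(pop$uptake, pop$phenotype, config$cost, mean_resource, season)
  norm_rate <- pop$uptake / (mean_resource * season)
  is_s <- pop$phenotype == "S"
  up_s <- if (any(is_s)) mean(norm_rate[is_s]) else NA_real_
  up_ns <- if (any(!is_s)) mean(norm_rate[!is_s]) else NA_real_
  rel <- if (!is.na(up_s) && !is.na(up_ns) && up_ns > 0) up_s / up_ns else NA_real_

  parents <- roulette_select(w, n)
  offspring <- pop$phenotype[parents]
  if (config$mutation_rate > 0) {
    flip <- stats::runif(n) < config$mutation_rate
    offspring[flip] <- ifelse(offspring[flip] == "S", "NS", "S")
  }
  record <- data.frame(
    generation = generation,
    n_signallers = n_sig,
    mean_uptake_S = up_s,
    mean_uptake_NS = up_ns,
    rel_uptake = rel,
    mean_fitness_S = if (any(is_s)) mean(w[is_s]) else NA_real_,
    mean_fitness_NS = if (any(!is_s)) mean(w[!is_s]) else NA_real_,
    mean_resource = mean_resource
  )
  list(record = record, offspring = offspring, population = pop)
}

#' Run the full evolutionary trajectory
#'
#' Iterates [run_generation()] from the seeded founder population and
#' returns the per-generation records plus an equilibrium summary (mean
#' signaller count over the last quarter of the run).
#'
#' @param config an [evolution_config()].
#' @return an object of class `"evolution_result"` with `records` (one row
#'   per generation) and `equilibrium_signallers`.
#' @export
run_evolution <- function(config) {
  stopifnot(inherits(config, "evolution_config"))
  phen <- rep(c("S", "NS"), c(
    config$initial_signallers,
    config$population_size - config$initial_signallers
  ))
  records <- vector("list", config$generations)
  for (g in seq_len(config$generations)) {
    out <- run_generation(config, phen, g)
    records[[g]] <- out$record
    phen <- out$offspring
  }
  records <- if (config$generations > 0) {
    do.call(rbind, records)
  } else {
    data.frame()
  }
  eq <- if (config$generations > 0) {
    tail_n <- max(1L, ceiling(config$generations / 4))
    mean(utils::tail(records$n_signallers, tail_n))
  } else {
    NA_real_
  }
  structure(list(
    config = config, records = records,
    equilibrium_signallers = eq,
    final_phenotypes = phen
  ), class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat("<evolution_result> ", nrow(x$records), " generations, population ",
    x$config$population_size, "\n",
    sep = ""
  )
  if (nrow(x$records) > 0) {
    cat(
      "  signallers: start", x$records$n_signallers[1],
      "-> end", utils::tail(x$records$n_signallers, 1),
      "; equilibrium (last quarter) =", signif(x$equilibrium_signallers, 4), "\n"
    )
  }
  invisible(x)
}
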