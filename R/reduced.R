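#' Parameters of the reduced moving-patch model
#'
#' The analytically tractable caricature of the turbulent foraging world: a
#' single circular patch of uniform concentration 1 (0 outside) and radius
#' `R` that persists for `T_persist` time units before relocating uniformly
#' at random on the unit torus. Agents move at constant speed `v` and cannot
#' stop -- the surrogate for the relative velocity imposed by advection in
#' the full model -- so holding the patch requires being repeatedly called
#' back by signalling conspecifics.
#'
#' Inside the patch the concentration is saturating, so the stochastic
#' behavioural rules of the full model degenerate to deterministic ones:
#' signallers inside the patch always signal, agents inside never respond,
#' and agents outside always respond to an available signal.
#'
#' @param R patch radius, `0 < R < 0.5`.
#' @param T_persist patch persistence time.
#' @param v agent speed.
#' @param N_S,N_NS signaller / non-signaller counts.
#' @param angular_noise heading-noise standard deviation (rad per sqrt
#'   time) of the correlated random walk.
#' @param duration total simulated time (should be many times `T_persist`).
#' @param dt integration step; default `0.1 * (2R / v)` resolves the patch
#'   crossing time with ten substeps.
#' @param seed integer seed for the run.
#' @param signals_enabled set `FALSE` to sever all interaction (used for
#'   exchangeability checks).
#' @param interaction_range signal perception radius; `Inf` (default)
#'   matches the analytic treatment in which any agent perceives the signal.
#' @return an object of class `"reduced_params"`.
#' @export
reduced_params <- function(R = 0.05, T_persist = 50, v = 0.1,
                           N_S = 8, N_NS = 8,
                           angular_noise = 1, duration = 2000,
                           dt = NULL, seed = 1L,
                           signals_enabled = TRUE,
                           interaction_range = Inf) {
  if (R <= 0 || R >= 0.5) stop("R must be in (0, 0.5)")
  if (T_persist <= 0 || v <= 0) stop("T_persist and v must be positive")
  if (N_S < 0 || N_NS < 0) stop("agent counts must be nonnegative")
  if (is.null(dt)) dt <- 0.1 * (2 * R / v)
  structure(list(
    R = R, T_persist = T_persist, v = v,
    N_S = as.integer(N_S), N_NS = as.integer(N_NS),
    angular_noise = angular_noise, duration = duration,
    dt = dt, seed = as.integer(seed),
    signals_enabled = signals_enabled,
    interaction_range = interaction_range
  ), class = "reduced_params")
}

#' Patch world state for the reduced model
#'
#' @param params a [reduced_params()].
#' @param centre initial patch centre; drawn uniformly if `NULL`.
#' @return list with `centre`, `clock` (time since last relocation) and the
#'   radius/persistence copied from `params`; class `"reduced_world"`.
#' @export
reduced_world <- function(params, centre = NULL) {
  if (is.null(centre)) centre <- stats::runif(2)
  structure(list(
    centre = wrap_torus(centre), clock = 0,
    R = params$R, T_persist = params$T_persist
  ), class = "reduced_world")
}

#' Relocate the patch to a uniformly random position
#'
#' Resets the relocation clock; radius and persistence are untouched.
#'
#' @param world a `"reduced_world"`.
#' @return the relocated world.
#' @export
relocate_patch <- function(world) {
  world$centre <- stats::runif(2)
  world$clock <- 0
  world
}

# One step of the reduced dynamics on bare state vectors. Order: sample
# (uptake accrues to agents currently inside), signal, respond/turn, move,
# relocate if due. `reloc_queue` supplies pre-drawn relocation centres so
# that signaller trajectories are bit-identical across runs that differ
# only in the number of (dynamically inert) non-signallers.
reduced_step_core <- function(x, y, heading, uptake, centre, clock,
                              params, dt, reloc_queue, reloc_i,
                              noise = NULL) {
  n <- length(x)
  N_S <- params$N_S
  R2 <- params$R^2
  dx <- centre[1] - x
  dx <- dx - round(dx)
  dy <- centre[2] - y
  dy <- dy - round(dy)
  inside <- (dx * dx + dy * dy) <= R2
  uptake[inside] <- uptake[inside] + dt

  if (is.null(noise)) {
    noise <- stats::rnorm(n, 0, params$angular_noise * sqrt(dt))
  }

  sig <- if (params$signals_enabled && N_S > 0) which(inside[seq_len(N_S)]) else integer(0)
  if (length(sig) > 0) {
    # responders: outside agents (inside agents are saturated and ignore
    # signals); perception limited to interaction_range if finite
    sx <- x[sig]
    sy <- y[sig]
    resp <- which(!inside)
    turned <- logical(n)
    if (length(resp) > 0) {
      # minimum-image centroid of signalling agents, per responder
      hx <- numeric(length(resp))
      hy <- numeric(length(resp))
      near <- if (is.finite(params$interaction_range)) {
        logical(length(resp))
      } else {
        rep(TRUE, length(resp))
      }
      r2 <- params$interaction_range^2
      for (kk in seq_along(sig)) {
        ddx <- sx[kk] - x[resp]
        ddx <- ddx - round(ddx)
        ddy <- sy[kk] - y[resp]
        ddy <- ddy - round(ddy)
        if (is.finite(params$interaction_range)) {
          hear <- (ddx * ddx + ddy * ddy) <= r2
          near <- near | hear
          hx <- hx + ddx * hear
          hy <- hy + ddy * hear
        } else {
          hx <- hx + ddx
          hy <- hy + ddy
        }
      }
      ok <- near & (hx * hx + hy * hy) > 1e-24
      heading[resp[ok]] <- atan2(hy[ok], hx[ok])
      turned[resp[ok]] <- TRUE
    }
    walkers <- which(!turned)
    heading[walkers] <- heading[walkers] + noise[walkers]
  } else {
    heading <- heading + noise
  }

  step_len <- params$v * dt
  x <- x + step_len * cos(heading)
  y <- y + step_len * sin(heading)
  x <- x - floor(x)
  y <- y - floor(y)

  clock <- clock + dt
  relocated <- FALSE
  if (clock >= params$T_persist - 1e-12) {
    centre <- reloc_queue[reloc_i, ]
    reloc_i <- reloc_i + 1L
    clock <- 0
    relocated <- TRUE
  }
  list(
    x = x, y = y, heading = heading, uptake = uptake,
    centre = centre, clock = clock, reloc_i = reloc_i,
    relocated = relocated, inside = inside
  )
}

#' Advance the reduced model by one step
#'
#' Sampling (uptake for agents inside the patch), deterministic
#' signal/response (see [reduced_params()]), correlated-random-walk turning
#' for non-responders, constant-speed movement, and clock-driven patch
#' relocation.
#'
#' @param world a `"reduced_world"`.
#' @param pop list with vectors `x`, `y`, `heading`, `uptake` (signallers
#'   are the first `params$N_S` agents).
#' @param params a [reduced_params()].
#' @param dt time step.
#' @return list `(world, pop, inside, relocated)`.
#' @export
step_reduced <- function(world, pop, params, dt = params$dt) {
  st <- reduced_step_core(
    pop$x, pop$y, pop$heading, pop$uptake,
    world$centre, world$clock, params, dt,
    reloc_queue = matrix(stats::runif(2), 1, 2), reloc_i = 1L
  )
  world$centre <- st$centre
  world$clock <- st$clock
  pop$x <- st$x
  pop$y <- st$y
  pop$heading <- st$heading
  pop$uptake <- st$uptake
  list(world = world, pop = pop, inside = st$inside, relocated = st$relocated)
}

#' Run the reduced moving-patch simulation
#'
#' Simulates `duration / dt` steps covering at least `duration / T_persist`
#' relocation cycles and summarizes per-strategy uptake rates (the fraction
#' of time spent inside the patch), their ratio, and the per-cycle
#' transient lengths (time from relocation until two or more signallers
#' first co-occupy the patch).
#'
#' @param params a [reduced_params()].
#' @return an object of class `"reduced_result"`: `uptake_rate_S`,
#'   `uptake_rate_NS`, `rel_uptake` (`NA`, flagged, if the non-signaller
#'   uptake is zero), standard errors across agents, per-agent uptake
#'   rates, per-cycle transient lengths, and the cycle count.
#' @export
run_reduced <- function(params) {
  stopifnot(inherits(params, "reduced_params"))
  n <- params$N_S + params$N_NS
  if (n == 0) stop("no agents")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  n_steps <- ceiling(params$duration / params$dt)
  n_cycles <- ceiling(params$duration / params$T_persist) + 1L

  # RNG layout keeps the signallers' randomness independent of how many
  # (dynamically inert) non-signallers are present: relocation centres
  # first, then all signaller draws, then all non-signaller draws. Adding
  # non-signallers therefore leaves signaller trajectories bit-identical.
  reloc_queue <- matrix(stats::runif(2 * (n_cycles + 1L)), ncol = 2, byrow = TRUE)
  N_Sp <- params$N_S
  init_s <- matrix(stats::runif(3 * N_Sp), ncol = 3, byrow = TRUE)
  noise_s <- matrix(stats::rnorm(N_Sp * n_steps), nrow = N_Sp, ncol = n_steps)
  init_ns <- matrix(stats::runif(3 * params$N_NS), ncol = 3, byrow = TRUE)
  noise_ns <- matrix(stats::rnorm(params$N_NS * n_steps),
    nrow = params$N_NS, ncol = n_steps
  )
  init <- rbind(init_s, init_ns)
  x <- init[, 1]
  y <- init[, 2]
  heading <- 2 * pi * init[, 3]
  uptake <- numeric(n)
  noise_all <- rbind(noise_s, noise_ns) * params$angular_noise * sqrt(params$dt)

  centre <- reloc_queue[1, ]
  reloc_i <- 2L
  clock <- 0

  transients <- rep(NA_real_, n_cycles)
  cycle <- 1L
  cycle_found <- FALSE
  N_S <- params$N_S
  dt <- params$dt

  for (step in seq_len(n_steps)) {
    st <- reduced_step_core(
      x, y, heading, uptake, centre, clock,
      params, dt, reloc_queue, reloc_i,
      noise = noise_all[, step]
    )
    if (!cycle_found && N_S >= 2 && sum(st$inside[seq_len(N_S)]) >= 2) {
      transients[cycle] <- st$clock - dt + if (st$relocated) params$T_persist else 0
      cycle_found <- TRUE
    }
    x <- st$x
    y <- st$y
    heading <- st$heading
    uptake <- st$uptake
    centre <- st$centre
    clock <- st$clock
    reloc_i <- st$reloc_i
    if (st$relocated) {
      if (!cycle_found) transients[cycle] <- params$T_persist
      cycle <- cycle + 1L
      cycle_found <- FALSE
    }
  }

  total_t <- n_steps * dt
  rate <- uptake / total_t
  is_s <- seq_len(n) <= N_S
  rate_s <- if (N_S > 0) mean(rate[is_s]) else NA_real_
  rate_ns <- if (params$N_NS > 0) mean(rate[!is_s]) else NA_real_
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  structure(list(
    params = params,
    uptake_rate_S = rate_s,
    uptake_rate_NS = rate_ns,
    se_S = se(rate[is_s]),
    se_NS = se(rate[!is_s]),
    rel_uptake = if (!is.na(rate_ns) && rate_ns > 0) rate_s / rate_ns else NA_real_,
    agent_rates = rate,
    is_signaller = is_s,
    transients = transients[seq_len(max(cycle - 1L, 1L))],
    n_cycles = cycle - 1L,
    duration = total_t
  ), class = "reduced_result")
}

#' @export
print.reduced_result <- function(x, ...) {
  p <- x$params
  cat("<reduced_result> R = ", p$R, ", T = ", p$T_persist, ", v = ", p$v,
    ", N_S = ", p$N_S, ", N_NS = ", p$N_NS, ", duration = ", x$duration,
    "\n",
    sep = ""
  )
  cat(sprintf(
    "  uptake S = %.4g (se %.2g)   uptake NS = %.4g (se %.2g)   F_S/F_NS = %.4g\n",
    x$uptake_rate_S, x$se_S, x$uptake_rate_NS, x$se_NS, x$rel_uptake
  ))
  cat(sprintf(
    "  %d relocation cycles; mean transient %.4g time units\n",
    x$n_cycles, mean(x$transients, na.rm = TRUE)
  ))
  invisible(x)
}
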