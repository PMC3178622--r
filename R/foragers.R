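#' Behavioural parameters for foraging agents
#'
#' @param speed constant self-propulsion speed `v` (dimensionless, domain
#'   widths per unit time). Agents are additionally advected by the flow.
#' @param angular_noise standard deviation of the correlated-random-walk
#'   heading increments, rad per sqrt time.
#' @param interaction_range signal perception radius `r_int` in torus
#'   units; must not exceed `sqrt(2)/2` (the torus diameter).
#' @param half_saturation constant `K` of the concentration normalization
#'   `C = phi / (phi + K)`. `NULL` (default) uses the field's running mean
#'   concentration, so "high concentration" is judged relative to what the
#'   environment typically offers.
#' @param search_gain asocial (klinokinetic) search strength; 0 (default)
#'   recovers the pure correlated random walk baseline whose mean uptake
#'   equals the mean resource concentration.
#' @return an object of class `"behaviour_params"`.
#' @export
behaviour_params <- function(speed = 0.2, angular_noise = 1,
                             interaction_range = 0.1,
                             half_saturation = NULL,
                             search_gain = 0) {
  if (speed < 0 || angular_noise < 0 || search_gain < 0) {
    stop("speed, angular_noise and search_gain must be nonnegative")
  }
  if (interaction_range < 0 || interaction_range > sqrt(2) / 2) {
    stop("interaction_range must lie in [0, sqrt(2)/2]")
  }
  if (!is.null(half_saturation) && half_saturation <= 0) {
    stop("half_saturation must be positive")
  }
  structure(list(
    speed = speed, angular_noise = angular_noise,
    interaction_range = interaction_range,
    half_saturation = half_saturation,
    search_gain = search_gain
  ), class = "behaviour_params")
}

#' Create an agent population
#'
#' Positions and headings are drawn uniformly (three consecutive draws per
#' agent); the first `n_signallers` agents carry the signalling phenotype.
#'
#' @param n population size.
#' @param n_signallers number of signaller-phenotype agents (`0..n`).
#' @return an object of class `"population"`: coordinate vectors `x`, `y`,
#'   `heading`, `phenotype` (`"S"`/`"NS"`), logical `signalling`, normalized
#'   concentration `C` (with previous-step `C_prev`), and cumulative
#'   `uptake` (concentration x time).
#' @export
make_population <- function(n, n_signallers = 0) {
  stopifnot(n >= 1, n_signallers >= 0, n_signallers <= n)
  init <- matrix(stats::runif(3 * n), ncol = 3, byrow = TRUE)
  structure(list(
    x = init[, 1], y = init[, 2], heading = 2 * pi * init[, 3],
    phenotype = rep(c("S", "NS"), c(n_signallers, n - n_signallers)),
    signalling = rep(FALSE, n),
    C = numeric(n), C_prev = numeric(n),
    uptake = numeric(n), n = as.integer(n)
  ), class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population> ", x$n, " agents (", sum(x$phenotype == "S"),
    " signallers), ", sum(x$signalling), " currently signalling, ",
    "total uptake = ", signif(sum(x$uptake), 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Saturating concentration normalization
#'
#' `C = phi / (phi + K)`: zero at zero concentration, one half at the
#' half-saturation constant `K`, approaching one in saturating resource.
#' All signal and response probabilities are functions of `C`.
#'
#' @param phi raw concentration (>= 0, vectorized).
#' @param K half-saturation constant (> 0).
#' @return `C` in `[0, 1]`.
#' @export
normalize_concentration <- function(phi, K) {
  if (any(phi < 0)) stop("concentration must be nonnegative")
  if (any(K <= 0)) stop("half_saturation K must be positive")
  phi / (phi + K)
}

#' Stochastic signalling decision
#'
#' A signaller emits a recruitment signal with probability equal to its
#' normalized concentration `C`; a non-signaller never signals.
#'
#' @param C normalized concentration in `[0, 1]` (vectorized).
#' @param phenotype `"S"` or `"NS"` (vectorized).
#' @return logical: signalling this step.
#' @export
signal_decision <- function(C, phenotype) {
  stopifnot(all(C >= 0 & C <= 1))
  (phenotype == "S") & (stats::runif(length(C)) < C)
}

#' Stochastic response decision
#'
#' Both phenotypes respond to a perceived signal with probability `1 - C`:
#' an individual already experiencing high concentration readily ignores
#' signals, while a deprived one readily follows them.
#'
#' @param C normalized concentration in `[0, 1]` (vectorized).
#' @return logical: willing to respond this step.
#' @export
response_decision <- function(C) {
  stopifnot(all(C >= 0 & C <= 1))
  stats::runif(length(C)) < (1 - C)
}

#' Preferred direction toward accepted signallers
#'
#' The heading toward the centroid of the minimum-image displacement
#' vectors from the focal agent to the signallers it responds to.
#'
#' @param focal length-2 coordinate of the focal agent.
#' @param signallers `m x 2` matrix of signaller coordinates.
#' @return heading angle in radians, or `NA` if the set is empty (caller
#'   keeps the random walk) or the centroid is degenerate.
#' @export
preferred_direction <- function(focal, signallers) {
  signallers <- matrix(signallers, ncol = 2)
  if (nrow(signallers) == 0) {
    return(NA_real_)
  }
  dx <- torus_delta(focal[1], signallers[, 1])
  dy <- torus_delta(focal[2], signallers[, 2])
  mx <- mean(dx)
  my <- mean(dy)
  if (mx * mx + my * my < 1e-24) {
    return(NA_real_)
  }
  atan2(my, mx)
}

#' Klinokinetic turning-noise modulation (asocial search)
#'
#' Multiplies the heading-noise amplitude by
#' `exp(search_gain * (C_prev - C))`: turning is amplified when the
#' experienced concentration is falling and suppressed (runs lengthen) when
#' it is rising. `search_gain = 0` returns 1 and recovers the pure
#' correlated random walk.
#'
#' @param C_now,C_prev normalized concentrations at this and the previous
#'   step.
#' @param search_gain modulation strength (>= 0).
#' @return multiplicative factor on the heading-noise standard deviation.
#' @export
asocial_search_turn <- function(C_now, C_prev, search_gain) {
  stopifnot(search_gain >= 0)
  exp(search_gain * (C_prev - C_now))
}

#' Advance the agent population by one time step
#'
#' Per agent: sample the local concentration, update the normalized value
#' `C`, draw the signalling state (signallers only, probability `C`), draw
#' willingness to respond (probability `1 - C`); an agent that is willing
#' and perceives at least one *other* signalling agent within
#' `interaction_range` turns toward the centroid of those signallers,
#' otherwise its heading receives a Gaussian correlated-random-walk
#' increment (optionally modulated by the asocial search gain). All agents
#' then move with the local flow velocity plus self-propulsion, and uptake
#' accrues as raw concentration x `dt`.
#'
#' RNG consumption is fixed at three draws per agent per step (signal,
#' response, heading noise) regardless of outcomes, so trajectories are
#' reproducible and comparable across variant runs.
#'
#' @param pop a [make_population()] object.
#' @param modes a `"flow_modes"` object.
#' @param field a [resource_field()].
#' @param params a [behaviour_params()].
#' @param dt time step.
#' @param vel optional precomputed [velocity_grid()] at `field$n`; when
#'   supplied, agent advection velocities are interpolated from it.
#' @return the updated population (with `last_phi` attached for
#'   uptake-accounting checks).
#' @export
step_population <- function(pop, modes, field, params, dt, vel = NULL) {
  stopifnot(inherits(pop, "population"), dt > 0)
  n <- pop$n
  phi <- concentration_at(field, cbind(pop$x, pop$y))
  if (anyNA(phi)) stop("NaN concentration sampled at t = ", field$t)
  K <- params$half_saturation
  if (is.null(K)) K <- max(field$running_mean, .Machine$double.eps)
  C <- normalize_concentration(phi, K)

  pop$signalling <- signal_decision(C, pop$phenotype)
  responds <- response_decision(C)
  noise <- stats::rnorm(n, 0, params$angular_noise * sqrt(dt))
  if (params$search_gain > 0) {
    noise <- noise * asocial_search_turn(C, pop$C_prev, params$search_gain)
  }

  sig <- which(pop$signalling)
  turned <- logical(n)
  if (length(sig) > 0 && params$interaction_range > 0) {
    r2 <- params$interaction_range^2
    hx <- numeric(n)
    hy <- numeric(n)
    cnt <- integer(n)
    for (s in sig) {
      ddx <- torus_delta(pop$x, pop$x[s])
      ddy <- torus_delta(pop$y, pop$y[s])
      in_range <- (ddx * ddx + ddy * ddy) <= r2
      in_range[s] <- FALSE # no self-recruitment
      hx[in_range] <- hx[in_range] + ddx[in_range]
      hy[in_range] <- hy[in_range] + ddy[in_range]
      cnt[in_range] <- cnt[in_range] + 1L
    }
    turned <- responds & cnt > 0L & (hx * hx + hy * hy) > 1e-24
    heading_new <- atan2(hy[turned], hx[turned])
    pop$heading[turned] <- heading_new
  }
  pop$heading[!turned] <- pop$heading[!turned] + noise[!turned]

  u <- if (!is.null(vel)) {
    cbind(
      interp_bilinear(vel$ux, pop$x, pop$y),
      interp_bilinear(vel$uy, pop$x, pop$y)
    )
  } else {
    velocity_at(modes, cbind(pop$x, pop$y))
  }
  pop$x <- wrap_torus(pop$x + dt * (u[, 1] + params$speed * cos(pop$heading)))
  pop$y <- wrap_torus(pop$y + dt * (u[, 2] + params$speed * sin(pop$heading)))

  pop$uptake <- pop$uptake + phi * dt
  pop$C_prev <- C
  pop$C <- C
  pop$last_phi <- phi
  pop
}
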