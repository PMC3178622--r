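#' Parameters for the analytic moving-patch approximation
#'
#' @param R patch radius (torus units); the annulus construction requires
#'   `3R < 0.5` so the planar geometry is valid on the unit torus.
#' @param v agent speed.
#' @param T_persist patch persistence time.
#' @param N number of signallers.
#' @return an object of class `"analytic_params"`.
#' @export
analytic_params <- function(R, v, T_persist, N) {
  if (R <= 0 || v <= 0 || T_persist <= 0) stop("R, v and T_persist must be positive")
  if (N < 0) stop("N must be nonnegative")
  if (3 * R >= 0.5) stop("geometry invalid: need 3*R < 0.5 on the unit torus")
  structure(list(R = R, v = v, T_persist = T_persist, N = as.integer(N)),
    class = "analytic_params"
  )
}

#' Patch crossing time: the natural discrete time step
#'
#' The analysis discretizes time into intervals of length
#' `tau = 2R / v`, the time to cross the patch at its widest point (the
#' diameter). Within one step an agent can move from outside the patch to
#' inside and vice versa.
#'
#' @param R patch radius.
#' @param v agent speed.
#' @return the step length `tau`.
#' @export
crossing_time <- function(R, v) {
  stopifnot(R > 0, v > 0)
  2 * R / v
}

#' Entry probability when a signal is given
#'
#' An agent anywhere in the annulus between radii `R` and `3R` (width
#' `v * tau = 2R`) that turns straight toward the signal enters the patch
#' within one step. On the unit-area domain the entry probability is the
#' annulus area:
#' \deqn{p_s = \pi ((3R)^2 - R^2) = 8 \pi R^2.}
#'
#' @param R patch radius; requires `3R < 0.5`.
#' @return `p_s`.
#' @export
entry_prob_signalled <- function(R) {
  if (any(3 * R >= 0.5)) stop("geometry invalid: need 3*R < 0.5")
  if (any(R <= 0)) stop("R must be positive")
  8 * pi * R^2
}

#' Chance-entry probability profile across the outer ring
#'
#' Without a signal, an agent at distance `d` from the patch edge
#' (`0 <= d <= 2R`) enters by chance with probability `1/2` at the edge
#' (it moves either toward or away), falling linearly to `0` at the outer
#' rim of the ring:
#' \deqn{p_0(d) = (1 - d / (2R)) / 2.}
#'
#' @param d distance to the patch edge.
#' @param R patch radius.
#' @return `p_0(d)`.
#' @export
chance_entry_profile <- function(d, R) {
  if (any(d < 0 | d > 2 * R)) stop("d must lie in [0, 2R]")
  0.5 * (1 - d / (2 * R))
}

#' Mean chance-entry probability
#'
#' Averages [chance_entry_profile()] over a uniformly distributed position
#' in the outer ring (area element `2 pi (R + d) dd` on the unit-area
#' domain):
#' \deqn{p_{ns} = \int_0^{2R} p_0(d)\, 2\pi (R + d)\, dd = \frac{5 \pi R^2}{3}.}
#' For all valid `R`, `p_ns / p_s = 5/24`.
#'
#' @param R patch radius; requires `3R < 0.5`.
#' @return `p_ns`.
#' @export
entry_prob_chance <- function(R) {
  if (any(3 * R >= 0.5)) stop("geometry invalid: need 3*R < 0.5")
  if (any(R <= 0)) stop("R must be positive")
  5 * pi * R^2 / 3
}

#' Three-state patch-occupancy chain
#'
#' States of the whole signaller cohort after a patch relocation:
#' `U` (patch unoccupied by signallers), `O1` (occupied by exactly one
#' signaller, unstable: it will leave unless another signaller enters), and
#' the absorbing `A` (two or more signallers, stable: mutual recruitment
#' holds the cohort on the patch). With `N` signallers entering
#' independently:
#' \itemize{
#'   \item from `U`: stay with `(1 - p_ns)^N`, to `O1` when exactly one
#'     enters by chance, to `A` when two or more do;
#'   \item from `O1`: to `A` when the present signaller recruits at least
#'     one of the other `N - 1` (each enters with `p_s`), otherwise the
#'     lone signaller is swept off and the chain returns to `U`.
#' }
#'
#' @param p_s entry probability given a signal.
#' @param p_ns chance entry probability.
#' @param N signaller count.
#' @return a 3 x 3 row-stochastic matrix with dimnames `U`, `O1`, `A`.
#' @export
three_state_chain <- function(p_s, p_ns, N) {
  stopifnot(p_s >= 0, p_s <= 1, p_ns >= 0, p_ns <= 1, N >= 0)
  N <- as.integer(N)
  stay_u <- (1 - p_ns)^N
  to_o1 <- if (N >= 1) N * p_ns * (1 - p_ns)^(N - 1) else 0
  to_a <- 1 - stay_u - to_o1
  o1_a <- if (N >= 1) 1 - (1 - p_s)^(N - 1) else 0
  P <- rbind(
    U = c(stay_u, to_o1, max(to_a, 0)),
    O1 = c(1 - o1_a, 0, o1_a),
    A = c(0, 0, 1)
  )
  colnames(P) <- rownames(P)
  P
}

#' Initial state distribution on patch reappearance
#'
#' Agents are assumed uniformly distributed when the patch relocates, so
#' each of the `N` signallers is inside the new patch independently with
#' probability `a = pi R^2` (the patch area on the unit-area domain):
#' binomial occupancy over `{U, O1, A}`.
#'
#' @param R patch radius.
#' @param N signaller count.
#' @return named probability vector `(U, O1, A)`.
#' @export
initial_distribution <- function(R, N) {
  a <- pi * R^2
  stopifnot(a <= 1, N >= 0)
  N <- as.integer(N)
  q_u <- (1 - a)^N
  q_o1 <- if (N >= 1) N * a * (1 - a)^(N - 1) else 0
  c(U = q_u, O1 = q_o1, A = max(1 - q_u - q_o1, 0))
}

#' Mean first-passage time to the stable (absorbing) state
#'
#' Solves the standard linear system for the expected number of steps to
#' absorption from each transient state, `(I - Q) t = 1` with `Q` the
#' transient block, and averages over the initial distribution `q`
#' (the absorbing state contributes zero). When the absorbing state is
#' unreachable (fewer than two signallers) the passage time is infinite and
#' is returned as `Inf`.
#'
#' @param chain a 3 x 3 matrix from [three_state_chain()].
#' @param q initial distribution from [initial_distribution()].
#' @return list with `T1` (mean first-passage steps), and the per-state
#'   passage times `t_states`.
#' @export
transient_time <- function(chain, q) {
  stopifnot(all(dim(chain) == c(3, 3)), length(q) == 3)
  if (abs(sum(q) - 1) > 1e-9) stop("q must sum to 1")
  trans <- c("U", "O1")
  if (chain["O1", "A"] <= 0 && chain["U", "A"] <= 0) {
    t_states <- c(U = Inf, O1 = Inf)
    T1 <- if (q[3] >= 1) 0 else Inf
    return(list(T1 = T1, t_states = t_states))
  }
  Q <- chain[trans, trans]
  t_states <- solve(diag(2) - Q, rep(1, 2))
  names(t_states) <- trans
  list(T1 = sum(q[1:2] * t_states), t_states = t_states)
}

#' Transient-regime occupancy probabilities for focal agents
#'
#' During the transient regime the patch is reduced to a two-state
#' enter/leave chain for a focal individual of each phenotype:
#' \itemize{
#'   \item focal signaller: enters by chance with `p_ns`; once inside it
#'     stays only if it recruits at least one of the other `N - 1`
#'     signallers, so it leaves with `(1 - p_s)^(N-1)`; stationary occupancy
#'     \deqn{Q_S = \frac{p_{ns}}{p_{ns} + (1 - p_s)^{N-1}}.}
#'   \item focal non-signaller: enters by chance with `p_ns`; giving no
#'     recruitment call it relies on one of the `N` signallers entering by
#'     chance, so it leaves with `(1 - p_ns)^N`; stationary occupancy
#'     \deqn{Q_{NS} = \frac{p_{ns}}{p_{ns} + (1 - p_{ns})^N}.}
#' }
#' The gap between `p_s` and `p_ns` is the sole driver of the signaller
#' advantage.
#'
#' @param p_s entry probability given a signal.
#' @param p_ns chance entry probability.
#' @param N signaller count (>= 1 for `Q_S`).
#' @return named vector `(Q_S, Q_NS)`.
#' @export
occupancy_probs <- function(p_s, p_ns, N) {
  stopifnot(p_s >= 0, p_s <= 1, p_ns >= 0, p_ns <= 1)
  if (N < 1) stop("Q_S undefined for N < 1")
  N <- as.integer(N)
  q_s <- p_ns / (p_ns + (1 - p_s)^(N - 1))
  q_ns <- p_ns / (p_ns + (1 - p_ns)^N)
  c(Q_S = q_s, Q_NS = q_ns)
}

#' Analytic relative uptake of signallers over non-signallers
#'
#' Assembles the full approximation: entry probabilities from the patch
#' geometry, the three-state cohort chain and its mean first-passage time
#' `T1` to the stable regime, the transient-regime focal occupancies, and
#' the weighting of the two regimes by the fraction of each persistence
#' interval spent in the transient,
#' \deqn{\alpha = \min(T_1 \tau, T) / T.}
#' In the stable regime both phenotypes enjoy the common occupancy `Q2`
#' (default 1: the recruitment signal is continuously available), so
#' \deqn{F_S / F_{NS} = \frac{\alpha Q_S + (1-\alpha) Q_2}
#'                           {\alpha Q_{NS} + (1-\alpha) Q_2},}
#' and the uptake differential is `delta = alpha (Q_S - Q_NS)`.
#' `delta_normalized` divides by the domain-mean concentration `pi R^2`, the
#' scale on which signalling cost is specified.
#'
#' @param params an [analytic_params()].
#' @param Q2 stable-regime occupancy shared by both phenotypes.
#' @return an object of class `"analytic_result"`.
#' @export
relative_uptake_analytic <- function(params, Q2 = 1) {
  stopifnot(inherits(params, "analytic_params"))
  R <- params$R
  N <- params$N
  tau <- crossing_time(R, params$v)
  p_s <- entry_prob_signalled(R)
  p_ns <- entry_prob_chance(R)
  chain <- three_state_chain(p_s, p_ns, N)
  q <- initial_distribution(R, N)
  ft <- transient_time(chain, q)
  alpha <- min(ft$T1 * tau, params$T_persist) / params$T_persist
  occ <- if (N >= 1) {
    occupancy_probs(p_s, p_ns, N)
  } else {
    c(Q_S = NA_real_, Q_NS = p_ns / (p_ns + 1))
  }
  num <- alpha * occ["Q_S"] + (1 - alpha) * Q2
  den <- alpha * occ["Q_NS"] + (1 - alpha) * Q2
  delta <- alpha * (occ["Q_S"] - occ["Q_NS"])
  structure(list(
    params = params,
    tau = tau, p_s = p_s, p_ns = p_ns,
    chain = chain, q = q,
    T1 = ft$T1, t_states = ft$t_states,
    Q_S = unname(occ["Q_S"]), Q_NS = unname(occ["Q_NS"]),
    Q2 = Q2, alpha = alpha,
    delta = unname(delta),
    delta_normalized = unname(delta) / (pi * R^2),
    rel_uptake = unname(num / den)
  ), class = "analytic_result")
}

#' @export
print.analytic_result <- function(x, ...) {
  p <- x$params
  cat("<analytic_result> R = ", p$R, ", v = ", p$v, ", T = ", p$T_persist,
    ", N = ", p$N, "\n", sep = ""
  )
  cat(sprintf(
    "  tau = %.4g  p_s = %.4g  p_ns = %.4g  T1 = %.4g steps  alpha = %.4g\n",
    x$tau, x$p_s, x$p_ns, x$T1, x$alpha
  ))
  cat(sprintf(
    "  Q_S = %.4g  Q_NS = %.4g  rel uptake = %.4g  delta = %.4g\n",
    x$Q_S, x$Q_NS, x$rel_uptake, x$delta
  ))
  invisible(x)
}

#' Analytic sweep over the signaller count
#'
#' @param R,v,T_persist reduced-model parameters.
#' @param N_grid integer signaller counts to evaluate.
#' @param Q2 stable-regime occupancy.
#' @return data.frame with one row per `N` and the assembled quantities.
#' @export
analytic_sweep <- function(R, v, T_persist, N_grid = 1:64, Q2 = 1) {
  rows <- lapply(N_grid, function(N) {
    a <- relative_uptake_analytic(analytic_params(R, v, T_persist, N), Q2 = Q2)
    data.frame(
      N = N, tau = a$tau, p_s = a$p_s, p_ns = a$p_ns, T1 = a$T1,
      Q_S = a$Q_S, Q_NS = a$Q_NS, alpha = a$alpha,
      delta = a$delta, delta_normalized = a$delta_normalized,
      rel_uptake = a$rel_uptake
    )
  })
  do.call(rbind, rows)
}

#' Invasion threshold and stable signaller number for a given cost
#'
#' Sweeps the analytic uptake differential `delta(N)` (normalized by the
#' mean resource concentration `pi R^2`, the scale on which cost is
#' specified) over signaller counts and locates where it crosses the cost:
#' the smallest upcrossing is the invasion threshold (unstable equilibrium)
#' and the largest downcrossing is the evolutionarily stable signaller
#' number. If the differential never reaches the cost there are no
#' equilibria and signalling cannot invade at any density.
#'
#' @param cost signalling cost per unit time, as a fraction of the mean
#'   resource concentration.
#' @param R,v,T_persist reduced-model parameters.
#' @param N_grid signaller counts to sweep.
#' @param Q2 stable-regime occupancy.
#' @return list with `N_threshold`, `N_stable` (both `NA` if no crossing)
#'   and the sweep table.
#' @export
equilibrium_points <- function(cost, R, v, T_persist, N_grid = 1:256, Q2 = 1) {
  stopifnot(cost >= 0)
  sw <- analytic_sweep(R, v, T_persist, N_grid = N_grid, Q2 = Q2)
  excess <- sw$delta_normalized - cost
  above <- which(excess > 0)
  if (length(above) == 0) {
    return(list(N_threshold = NA_integer_, N_stable = NA_integer_, sweep = sw))
  }
  list(
    N_threshold = sw$N[min(above)],
    N_stable = sw$N[max(above)],
    sweep = sw
  )
}
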