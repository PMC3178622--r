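# Independent Monte-Carlo / quadrature oracles used to validate the
# closed-form results. These deliberately avoid the code paths they check.

# fraction of uniform points on the unit square lying in the annulus
# R < d <= 3R around the centre (planar geometry; valid while 3R < 0.5)
mc_annulus_prob <- function(R, n = 1e6, seed = 1) {
  withr::with_seed(seed, {
    px <- runif(n) - 0.5
    py <- runif(n) - 0.5
    d <- sqrt(px^2 + py^2)
    mean(d > R & d <= 3 * R)
  })
}

# Monte-Carlo estimate of the ring-averaged chance-entry probability:
# E[p0(d) * 1{in ring}] over uniform positions, p0 evaluated independently
mc_chance_entry <- function(R, n = 1e6, seed = 1) {
  withr::with_seed(seed, {
    px <- runif(n) - 0.5
    py <- runif(n) - 0.5
    r <- sqrt(px^2 + py^2)
    inring <- r > R & r <= 3 * R
    d <- pmax(r - R, 0)
    vals <- ifelse(inring, 0.5 * (1 - d / (2 * R)), 0)
    list(mean = mean(vals), se = sd(vals) / sqrt(n))
  })
}

# simulate the three-state cohort chain to absorption, many replicates;
# returns mean steps (replicates starting absorbed contribute 0)
sim_three_state_mfpt <- function(P, q, reps = 1e5, seed = 1, max_steps = 1e5) {
  withr::with_seed(seed, {
    state <- sample.int(3, reps, replace = TRUE, prob = q)
    steps <- numeric(reps)
    alive <- state != 3L
    iter <- 0
    while (any(alive) && iter < max_steps) {
      iter <- iter + 1
      u <- runif(sum(alive))
      s <- state[alive]
      cum1 <- P[s, 1]
      cum2 <- cum1 + P[s, 2]
      ns <- ifelse(u < cum1, 1L, ifelse(u < cum2, 2L, 3L))
      steps[alive] <- steps[alive] + 1
      state[alive] <- ns
      alive[alive] <- ns != 3L
    }
    list(mean = mean(steps), se = sd(steps) / sqrt(reps))
  })
}

# stationary occupancy of a two-state enter/leave chain via simulated
# geometric sojourns (independent of the closed-form ratio)
sim_two_state_occupancy <- function(p_enter, p_leave, cycles = 2e4, seed = 1) {
  withr::with_seed(seed, {
    t_out <- rgeom(cycles, p_enter) + 1
    t_in <- rgeom(cycles, p_leave) + 1
    occ <- sum(t_in) / (sum(t_in) + sum(t_out))
    # delta-method standard error on the ratio of means
    mi <- mean(t_in); mo <- mean(t_out)
    vi <- var(t_in) / cycles; vo <- var(t_out) / cycles
    g <- c(mo, -mi) / (mi + mo)^2
    list(occ = occ, se = sqrt(g[1]^2 * vi + g[2]^2 * vo))
  })
}

# quick steady flow + field used by several tests
make_test_env <- function(seed = 1, U = 0.5, width = 0.1, n = 64,
                          spin_t = 5, dt = 0.05, k_max = 8) {
  spec <- spectrum_spec(k_max = k_max, U_target = U)
  fl <- init_flow(spec, seed)
  src <- source_spec(1, width)
  f <- resource_field(n, 0)
  withr::with_seed(seed, {
    for (i in seq_len(ceiling(spin_t / dt))) {
      fl <- step_flow(fl, dt)
      st <- step_resource(f, fl, src, dt)
      f <- st$field
      src <- st$src
    }
  })
  list(flow = fl, field = f, src = src, dt = dt)
}
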