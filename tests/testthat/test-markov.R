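# The closed-form moving-patch approximation, checked against geometry,
# quadrature, and direct chain simulation.

test_that("crossing time is the patch diameter over the speed", {
  expect_equal(crossing_time(0.05, 0.1), 1.0)
  expect_equal(crossing_time(0.05, 0.2), 0.5) # doubling v halves tau
  for (R in c(0.02, 0.07, 0.12)) {
    expect_equal(crossing_time(R, 0.13) * 0.13, 2 * R)
  }
})

test_that("signalled entry probability is the annulus area, vs Monte-Carlo", {
  expect_equal(entry_prob_signalled(0.05), 8 * pi * 0.05^2)
  for (R in c(0.02, 0.05, 0.1)) {
    p <- entry_prob_signalled(R)
    n <- 1e6
    phat <- mc_annulus_prob(R, n, seed = round(1000 * R))
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), 3 * se)
    # p_s / R^2 is the constant 8*pi
    expect_equal(p / R^2, 8 * pi)
  }
  expect_error(entry_prob_signalled(0.2), "geometry")
  expect_lt(entry_prob_signalled(1e-6), 1e-10) # vanishes with patch size
})

test_that("chance entry profile is linear from 1/2 at the edge to 0", {
  R <- 0.05
  expect_equal(chance_entry_profile(0, R), 0.5)
  expect_equal(chance_entry_profile(2 * R, R), 0)
  expect_equal(chance_entry_profile(R, R), 0.25)
  expect_error(chance_entry_profile(2.1 * R, R), "0, 2R")
})

test_that("mean chance entry matches ring quadrature and the 5/24 ratio", {
  for (R in c(0.02, 0.05, 0.1)) {
    # independent numerical quadrature of the ring integral
    quad <- stats::integrate(
      function(d) 0.5 * (1 - d / (2 * R)) * 2 * pi * (R + d),
      0, 2 * R,
      rel.tol = 1e-10
    )$value
    expect_equal(entry_prob_chance(R), quad, tolerance = 1e-8)
    expect_equal(entry_prob_chance(R) / entry_prob_signalled(R), 5 / 24)
    expect_lte(entry_prob_chance(R), entry_prob_signalled(R))
  }
  mc <- mc_chance_entry(0.05, 1e6, seed = 7)
  expect_lt(abs(mc$mean - entry_prob_chance(0.05)), 3 * mc$se)
})

test_that("three-state chain rows are stochastic and honour the N = 0, 1 cases", {
  P0 <- three_state_chain(0.3, 0.1, 0)
  expect_equal(P0["U", "U"], 1) # no signallers: unoccupied forever
  P1 <- three_state_chain(0.3, 0.1, 1)
  expect_equal(P1["O1", "A"], 0) # a lone signaller cannot stabilize the patch
  withr::with_seed(11, {
    for (i in 1:20) {
      p_s <- runif(1)
      p_ns <- runif(1, 0, p_s)
      N <- sample(0:40, 1)
      P <- three_state_chain(p_s, p_ns, N)
      expect_equal(unname(rowSums(P)), c(1, 1, 1))
      expect_true(all(P >= 0))
    }
  })
})

test_that("initial distribution is binomial patch occupancy", {
  expect_equal(unname(initial_distribution(0.1, 0)["U"]), 1)
  q <- initial_distribution(0.05, 8)
  a <- pi * 0.05^2
  expect_equal(unname(q["U"]), (1 - a)^8)
  expect_equal(unname(q["O1"]), 8 * a * (1 - a)^7)
  expect_equal(sum(q), 1)
  withr::with_seed(3, {
    for (i in 1:10) {
      q <- initial_distribution(runif(1, 0.01, 0.15), sample(0:30, 1))
      expect_equal(sum(q), 1)
      expect_true(all(q >= 0))
    }
  })
})

test_that("mean first-passage time solves the linear system and matches chain simulation", {
  # hand-solvable case: p_ns = 0.5, p_s = 1, N = 2
  P <- three_state_chain(1, 0.5, 2)
  ft <- transient_time(P, c(1, 0, 0))
  expect_equal(unname(ft$t_states["U"]), 2)
  expect_equal(unname(ft$t_states["O1"]), 1)
  expect_equal(ft$T1, 2)

  # absorbed start: zero passage time
  expect_equal(transient_time(P, c(0, 0, 1))$T1, 0)

  # unreachable absorbing state (N = 1) is flagged as infinite
  P1 <- three_state_chain(0.3, 0.1, 1)
  expect_equal(transient_time(P1, initial_distribution(0.05, 1))$T1, Inf)

  # Monte-Carlo chain oracle on random parameter triples
  withr::with_seed(5, {
    triples <- replicate(4, {
      p_s <- runif(1, 0.2, 0.9)
      c(p_s, runif(1, 0.05, p_s), sample(2:12, 1))
    })
  })
  for (j in seq_len(ncol(triples))) {
    p_s <- triples[1, j]
    p_ns <- triples[2, j]
    N <- triples[3, j]
    P <- three_state_chain(p_s, p_ns, N)
    q <- initial_distribution(0.05, N)
    ft <- transient_time(P, q)
    mc <- sim_three_state_mfpt(P, q, reps = 2e4, seed = 100 + j)
    expect_lt(abs(mc$mean - ft$T1), 3 * mc$se + 1e-9)
  }

  # T1 decreases with the signaller count at fixed entry probabilities
  t1s <- vapply(2:32, function(N) {
    transient_time(
      three_state_chain(0.0628, 0.0131, N),
      initial_distribution(0.05, N)
    )$T1
  }, numeric(1))
  expect_true(all(diff(t1s) < 0))
})

test_that("occupancy probabilities are the 2-state stationary laws", {
  p_s <- entry_prob_signalled(0.05)
  p_ns <- entry_prob_chance(0.05)

  # N = 1: a lone signaller is worse off than a non-signaller near it
  occ1 <- occupancy_probs(p_s, p_ns, 1)
  expect_equal(unname(occ1["Q_S"]), p_ns / (p_ns + 1))
  expect_equal(unname(occ1["Q_NS"]), p_ns)
  expect_lt(occ1["Q_S"], occ1["Q_NS"])

  # signallers dominate for N >= 2 whenever p_s > p_ns
  for (N in 2:32) {
    occ <- occupancy_probs(p_s, p_ns, N)
    expect_gt(occ["Q_S"], occ["Q_NS"])
  }

  # stationary law matches sojourn-time simulation
  withr::with_seed(9, {
    for (i in 1:5) {
      ps <- runif(1, 0.2, 0.9)
      pns <- runif(1, 0.05, ps)
      N <- sample(2:10, 1)
      occ <- occupancy_probs(ps, pns, N)
      ms <- sim_two_state_occupancy(pns, (1 - ps)^(N - 1), cycles = 2e4, seed = i)
      expect_lt(abs(ms$occ - occ["Q_S"]), 3 * ms$se + 1e-9)
      mn <- sim_two_state_occupancy(pns, (1 - pns)^N, cycles = 2e4, seed = 50 + i)
      expect_lt(abs(mn$occ - occ["Q_NS"]), 3 * mn$se + 1e-9)
    }
  })

  # saturation: both occupancies approach 1 as the cohort grows
  occ_big <- occupancy_probs(0.3, 0.05, 500)
  expect_gt(occ_big["Q_S"], 0.99)
  expect_gt(occ_big["Q_NS"], 0.9999 * 0.05 / (0.05 + (1 - 0.05)^500))
  expect_error(occupancy_probs(0.3, 0.05, 0), "N < 1")
})

test_that("assembled relative uptake honours the limiting regimes", {
  # patch that never relocates: transient fraction vanishes, uptakes equalize
  a_static <- relative_uptake_analytic(analytic_params(0.05, 0.1, 1e9, 8))
  expect_equal(a_static$alpha, 0, tolerance = 1e-6)
  expect_equal(a_static$rel_uptake, 1, tolerance = 1e-6)

  # a lone signaller never profits from its own signals
  a1 <- relative_uptake_analytic(analytic_params(0.05, 0.1, 50, 1))
  expect_lte(a1$rel_uptake, 1)

  # transient-dominated regime reduces to the occupancy ratio
  a_short <- relative_uptake_analytic(analytic_params(0.05, 0.1, 10, 8))
  expect_equal(a_short$alpha, 1)
  expect_equal(a_short$rel_uptake, a_short$Q_S / a_short$Q_NS)

  # entry ordering invariant over the sweep
  sw <- analytic_sweep(0.05, 0.1, 50, 1:40)
  expect_true(all(sw$p_ns <= sw$p_s))
  expect_true(all(sw$alpha >= 0 & sw$alpha <= 1))
})

test_that("equilibrium points bracket the cost crossing of the uptake differential", {
  sw <- analytic_sweep(0.05, 0.1, 50, 1:128)
  # the differential rises past a threshold then decays: at most two crossings
  for (cost in c(0.005, 0.02, 0.05)) {
    excess <- sw$delta_normalized - cost
    sign_changes <- sum(diff(sign(excess)) != 0)
    expect_lte(sign_changes, 2)
  }
  eq <- equilibrium_points(0.02, 0.05, 0.1, 50, N_grid = 1:128)
  expect_true(is.finite(eq$N_threshold))
  expect_true(is.finite(eq$N_stable))
  expect_lte(eq$N_threshold, eq$N_stable)
  # cost exceeding the maximal differential: no viable signalling density
  eq_none <- equilibrium_points(10, 0.05, 0.1, 50, N_grid = 1:128)
  expect_true(is.na(eq_none$N_threshold))
  # zero cost: threshold at first positive differential, stable point at the
  # sweep boundary where the differential has decayed toward zero
  eq0 <- equilibrium_points(0, 0.05, 0.1, 50, N_grid = 1:128)
  expect_equal(eq0$N_stable, 128)
  expect_lte(eq0$N_threshold, 3)
})
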