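# Agent behavioural rules: normalization, signal/response statistics,
# torus-aware recruitment geometry, motion, uptake accounting.

test_that("concentration normalization is saturating and monotone", {
  expect_equal(normalize_concentration(0, 1), 0)
  expect_equal(normalize_concentration(2, 2), 0.5) # half-saturation anchor
  expect_error(normalize_concentration(-1, 1), "nonnegative")
  expect_error(normalize_concentration(1, 0), "positive")
  withr::with_seed(2, {
    phi <- sort(runif(50, 0, 10))
    for (K in c(0.1, 1, 7)) {
      C <- normalize_concentration(phi, K)
      expect_true(all(diff(C) > 0))
      expect_true(all(C >= 0 & C < 1))
    }
  })
})

test_that("signalling happens at rate C for signallers and never for others", {
  n <- 1e5
  withr::with_seed(3, {
    s <- signal_decision(rep(0.7, n), rep("S", n))
    expect_false(any(signal_decision(runif(n), rep("NS", n))))
    expect_false(any(signal_decision(rep(0, n), rep("S", n))))
  })
  se <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(mean(s) - 0.7), 3 * se)
})

test_that("response rate is 1 - C for everyone", {
  n <- 1e5
  withr::with_seed(4, {
    r <- response_decision(rep(0.25, n))
    expect_true(all(response_decision(rep(0, 100))))
    expect_false(any(response_decision(rep(1, 100))))
  })
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(mean(r) - 0.75), 3 * se)
})

test_that("preferred direction is the torus-aware signaller centroid", {
  expect_equal(preferred_direction(c(0.5, 0.5), c(0.6, 0.5)), 0)
  # two signallers symmetric about north
  expect_equal(
    preferred_direction(c(0.5, 0.5), rbind(c(0.45, 0.6), c(0.55, 0.6))),
    pi / 2
  )
  # wraparound: nearest image of (0.05, .) from (0.95, .) lies east
  expect_equal(preferred_direction(c(0.95, 0.5), c(0.05, 0.5)), 0)
  expect_true(is.na(preferred_direction(c(0.5, 0.5), matrix(numeric(0), ncol = 2))))
})

test_that("ballistic and stationary motion limits are exact", {
  still <- init_flow(spectrum_spec(k_max = 2, U_target = 0), 1)
  f <- resource_field(16, matrix(0.3, 16, 16))
  withr::with_seed(1, pop <- make_population(1, 0))
  pop$x <- 0.2
  pop$y <- 0.5
  pop$heading <- 0
  bp <- behaviour_params(speed = 0.1, angular_noise = 0, interaction_range = 0, half_saturation = 1)
  pop2 <- step_population(pop, still, f, bp, 0.1)
  expect_equal(pop2$x, 0.21)
  expect_equal(pop2$y, 0.5)

  # v = 0: stationary agent accumulates c * t on a constant field
  bp0 <- behaviour_params(speed = 0, angular_noise = 0, interaction_range = 0, half_saturation = 1)
  for (i in 1:50) pop <- step_population(pop, still, f, bp0, 0.1)
  expect_equal(pop$x, 0.2)
  expect_equal(pop$uptake, 0.3 * 5, tolerance = 1e-12)
})

test_that("uptake accounting matches sampled concentrations exactly and positions stay wrapped", {
  env <- make_test_env(seed = 6, n = 64, spin_t = 3)
  withr::with_seed(8, pop <- make_population(40, 20))
  bp <- behaviour_params(speed = 0.3, interaction_range = 0.2)
  fl <- env$flow
  f <- env$field
  src <- env$src
  total <- 0
  withr::with_seed(9, {
    for (i in 1:30) {
      fl <- step_flow(fl, 0.05)
      st <- step_resource(f, fl, src, 0.05)
      f <- st$field
      src <- st$src
      pop <- step_population(pop, fl, f, bp, 0.05)
      total <- total + sum(pop$last_phi) * 0.05
      expect_true(all(pop$x >= 0 & pop$x < 1 & pop$y >= 0 & pop$y < 1))
      expect_false(any(pop$signalling[pop$phenotype == "NS"]))
    }
  })
  expect_equal(sum(pop$uptake), total, tolerance = 1e-12)
  expect_true(all(pop$C >= 0 & pop$C <= 1))
})

test_that("with signalling severed, phenotypes behave identically", {
  # interaction_range = 0 and an all-NS population consume the same RNG
  # stream and produce identical trajectories under matched seeds
  env <- make_test_env(seed = 10, n = 64, spin_t = 3)
  run_pop <- function(n_sig, rint) {
    fl <- env$flow
    f <- env$field
    src <- env$src
    withr::with_seed(31, pop <- make_population(30, n_sig))
    pop$phenotype <- rep(c("S", "NS"), c(n_sig, 30 - n_sig))
    bp <- behaviour_params(speed = 0.2, interaction_range = rint)
    withr::with_seed(32, {
      for (i in 1:40) {
        fl <- step_flow(fl, 0.05)
        st <- step_resource(f, fl, src, 0.05)
        f <- st$field
        src <- st$src
        pop <- step_population(pop, fl, f, bp, 0.05)
      }
    })
    pop
  }
  a <- run_pop(15, 0) # signallers present, nobody can hear them
  b <- run_pop(0, 0.2) # nobody signals
  expect_equal(a$x, b$x)
  expect_equal(a$y, b$y)
  expect_equal(a$uptake, b$uptake)
})

test_that("asocial search modulation lengthens runs up gradients", {
  expect_equal(asocial_search_turn(0.8, 0.2, 0), 1)
  expect_lt(asocial_search_turn(0.8, 0.2, 2), 1) # climbing: suppress turning
  expect_gt(asocial_search_turn(0.2, 0.8, 2), 1) # falling: amplify turning
  # lone-agent uptake on a static localized field is nondecreasing in the
  # search gain (klinokinesis exploits the gradient)
  still <- init_flow(spectrum_spec(k_max = 2, U_target = 0), 1)
  g <- source_field(source_spec(1, 0.15, kernel = "gaussian"), 64)
  uptake_at_gain <- function(gain) {
    mean(vapply(1:20, function(s) {
      f <- resource_field(64, g)
      withr::with_seed(400 + s, pop <- make_population(1, 0))
      bp <- behaviour_params(
        speed = 0.1, interaction_range = 0,
        half_saturation = 0.2, search_gain = gain
      )
      withr::with_seed(500 + s, {
        for (i in 1:600) pop <- step_population(pop, still, f, bp, 0.1)
      })
      pop$uptake
    }, numeric(1)))
  }
  u <- vapply(c(0, 4, 10), uptake_at_gain, numeric(1))
  expect_gt(u[2], u[1])
  expect_gte(u[3], u[2] * 0.95) # allow saturation, not reversal
})
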