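# Aquila Optimizer: Levy flights, phase schedule, the four update rules
# (checked against hand-computed arithmetic under frozen randomness), and the
# optimizer-level invariants.

sphere <- function(v) sum(v^2)

test_that("levy flight is shaped, deterministic and heavy-tailed", {
  expect_length(levy_flight(5, seed = 1), 5)
  expect_identical(levy_flight(7, seed = 2), levy_flight(7, seed = 2))
  expect_error(levy_flight(3, beta = 2.5), "beta")
  withr::with_seed(3, {
    draws <- levy_flight(1e5, beta = 1.5)
    kurt <- mean((draws - mean(draws))^4) / stats::var(draws)^2
    expect_gt(kurt, 10)  # far beyond the normal value of 3
  })
})

test_that("phase selection follows the two-thirds exploration schedule", {
  expect_true(select_phase(0, 25, seed = 1) %in% 1:2)
  expect_true(select_phase(24, 25, seed = 1) %in% 3:4)
  withr::with_seed(4, {
    early <- replicate(600, select_phase(0, 25))
    late <- replicate(600, select_phase(24, 25))
    expect_true(all(early %in% 1:2) && all(late %in% 3:4))
    expect_lt(abs(mean(early == 1) - 0.5), 0.07)
    expect_lt(abs(mean(late == 3) - 0.5), 0.07)
  })
  expect_error(select_phase(25, 25), "t must satisfy")
})

# frozen-randomness oracles: replicate the exact RNG draw order of each rule
test_that("update rules match hand-computed equations under frozen randomness", {
  D <- 2
  cfg <- ao_config(dimension = D, population_size = 4, iterations = 10,
                   lower = 0, upper = 1)
  state <- list(X = matrix(c(0.1, 0.9, 0.3, 0.7, 0.5, 0.2, 0.8, 0.4), 4, 2),
                X_best = c(0.2, 0.6), X_m = c(0.425, 0.55), t = 3, T_total = 10)
  member <- c(0.3, 0.7)
  clip01 <- function(v) pmin(pmax(v, 0), 1)
  mantegna <- function(D, beta = 1.5) {
    sigma <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
    u <- rnorm(D) * sigma
    v <- rnorm(D)
    0.01 * u / abs(v)^(1 / beta)
  }

  # phase 1: X_best (1 - t/T) + (X_m - X_best rand)
  expected1 <- withr::with_seed(11, {
    r <- runif(1)
    clip01(state$X_best * (1 - 3 / 10) + (state$X_m - state$X_best * r))
  })
  expect_equal(update_position(1, member, state, cfg, seed = 11), expected1)

  # phase 2: X_best Levy(D) + X_R + (y - x) rand
  expected2 <- withr::with_seed(12, {
    X_R <- state$X[sample.int(4, 1), ]
    r1 <- runif(1, 1, 20)
    D1 <- 1:D
    rr <- r1 + 0.00565 * D1
    theta <- -0.005 * D1 + 3 * pi / 2
    y <- rr * cos(theta); x <- rr * sin(theta)
    lev <- mantegna(D)
    clip01(state$X_best * lev + X_R + (y - x) * runif(1))
  })
  expect_equal(update_position(2, member, state, cfg, seed = 12), expected2)

  # phase 3: (X_best - X_m) alpha - rand + ((UB - LB) rand + LB) gamma
  expected3 <- withr::with_seed(13, {
    r1 <- runif(1); r2 <- runif(1)
    clip01((state$X_best - state$X_m) * 0.1 - r1 + ((1 - 0) * r2 + 0) * 0.1)
  })
  expect_equal(update_position(3, member, state, cfg, seed = 13), expected3)

  # phase 4: QF X_best - G1 X rand - G2 Levy(D) + rand G1
  expected4 <- withr::with_seed(14, {
    QF <- (3 + 1)^((2 * runif(1) - 1) / (1 - 10)^2)
    G1 <- 2 * runif(1) - 1
    G2 <- 2 * (1 - 3 / 10)
    r3 <- runif(1)
    lev <- mantegna(D)
    clip01(QF * state$X_best - (G1 * member * r3) - G2 * lev + runif(1) * G1)
  })
  expect_equal(update_position(4, member, state, cfg, seed = 14), expected4)

  expect_error(update_position(5, member, state, cfg), "phase")
})

test_that("phase 1 collapses toward the origin at t = T with rand suppressed", {
  # as t -> T the (1 - t/T) factor vanishes; with X_m = X_best * rand the
  # update is exactly 0 before clipping
  cfg <- ao_config(dimension = 3, population_size = 2, iterations = 10,
                   lower = -1, upper = 1)
  state <- list(X = matrix(0, 2, 3), X_best = c(0.5, -0.5, 0.2),
                X_m = c(0, 0, 0), t = 10, T_total = 10)
  r <- withr::with_seed(21, runif(1))
  state$X_m <- state$X_best * r
  out <- update_position(1, c(0.1, 0.1, 0.1), state, cfg, seed = 21)
  expect_equal(out, c(0, 0, 0), tolerance = 1e-12)
})

test_that("optimizer honours budget, bounds, monotonicity and determinism", {
  calls <- 0L
  counted <- function(v) { calls <<- calls + 1L; sphere(v) }
  cfg <- ao_config(dimension = 5, population_size = 10, iterations = 25,
                   lower = -1, upper = 1, seed = 31)
  res <- ao_optimize(counted, cfg)
  expect_equal(calls, 250)                    # budget conservation
  expect_equal(nrow(res$history), 250)
  cand <- as.matrix(res$history[, paste0("x", 1:5)])
  expect_true(all(cand >= -1 & cand <= 1))    # containment
  expect_true(all(diff(res$trajectory) <= 1e-12))  # monotone best-so-far
  res2 <- ao_optimize(sphere, cfg)
  expect_identical(res$history, res2$history) # seed determinism
})

test_that("a constant objective and non-finite returns are handled", {
  cfg <- ao_config(dimension = 3, population_size = 4, iterations = 3, seed = 32)
  res <- ao_optimize(function(v) 7, cfg)
  expect_equal(res$best_value, 7)
  cfg2 <- ao_config(dimension = 2, population_size = 3, iterations = 2, seed = 33)
  w <- capture_warnings(
    res2 <- ao_optimize(function(v) if (v[1] > 0.5) NaN else sum(v), cfg2))
  expect_true(any(grepl("non-finite", w)))
  expect_true(is.finite(res2$best_value))
})

test_that("AO beats a 250-sample random-search baseline on the sphere (median of 20 seeds)", {
  ao_best <- numeric(20); rs_best <- numeric(20)
  for (s in 1:20) {
    cfg <- ao_config(dimension = 5, population_size = 10, iterations = 25,
                     lower = -1, upper = 1, seed = 100 + s)
    ao_best[s] <- ao_optimize(sphere, cfg)$best_value
    rs_best[s] <- withr::with_seed(200 + s, {
      min(apply(matrix(runif(250 * 5, -1, 1), 250), 1, sphere))
    })
  }
  expect_lt(median(ao_best), median(rs_best))
})

test_that("maximize mode flips the search direction", {
  cfg <- ao_config(dimension = 3, population_size = 6, iterations = 10,
                   mode = "maximize", seed = 41)
  res <- ao_optimize(function(v) -sphere(v - 0.5), cfg)
  expect_gt(res$best_value, -0.05)
  expect_true(all(diff(res$trajectory) >= -1e-12))
})
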