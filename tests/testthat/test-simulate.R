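q3 <- cda_fixture("q3_20")
p_high <- cda_fixture("params_high_20")

test_that("ideal responses follow the conjunctive rule", {
  q <- q_matrix(rbind(c(1, 1, 0)), quiet = TRUE)
  expect_identical(as.integer(ideal_responses(c(1, 1, 0), q)), 1L)
  expect_identical(as.integer(ideal_responses(c(1, 0, 0), q)), 0L)
  # a master of everything answers everything correctly
  expect_true(all(ideal_responses(c(1, 1, 1), q3) == 1))
  # no item isolates attribute 3, so 000 and 001 share the zero vector
  iv <- ideal_responses(decode_pattern(0:1, 3), q3)
  expect_true(all(iv == 0))
  expect_error(ideal_responses(c(1, 0), q3), "attributes")
})

test_that("the DINA kernel degenerates correctly at its noise limits", {
  profiles <- decode_pattern(rep(0:7, 10), 3)
  zero <- tibble::tibble(item = 1:20, slip = 0, guess = 0)
  x <- sim_item_responses(profiles, q3, zero, seed = 1)
  expect_identical(unname(x), unname(ideal_responses(profiles, q3)))
  # s = g = 0.5 makes every cell a fair coin regardless of profile
  half <- tibble::tibble(item = 1:20, slip = 0.5, guess = 0.5)
  xh <- sim_item_responses(decode_pattern(rep(0, 4000), 3), q3, half, seed = 2)
  expect_lt(abs(mean(xh) - 0.5), 3 * sqrt(0.25 / length(xh)))
})

test_that("simulated response rates match the closed-form DINA probabilities", {
  n <- 1e5
  masters <- matrix(rep(c(1L, 1L, 0L), each = n), ncol = 3)
  x <- sim_item_responses(masters, q3, p_high, seed = 3)
  # item 1 requires A1, A2; masters succeed at 1 - s = 0.84
  expect_lt(abs(mean(x[, 1]) - 0.84), 3 * sqrt(0.84 * 0.16 / n))
  none <- matrix(0L, n, 3)
  x0 <- sim_item_responses(none, q3, p_high, seed = 4)
  expect_lt(abs(mean(x0[, 1]) - 0.04), 3 * sqrt(0.04 * 0.96 / n))
  bad <- tibble::tibble(item = 1:20, slip = 1.2, guess = 0)
  expect_error(sim_item_responses(masters[1:2, ], q3, bad), "\\[0, 1\\]")
})

test_that("initial profiles have exact marginals and copula association", {
  expect_true(all(sim_initial_profiles(50, c(1, 1, 1), 0, seed = 1) == 1))
  n <- 1e5
  p <- c(0.4, 0.4, 0.2)
  m <- sim_initial_profiles(n, p, 0.5, seed = 5)
  for (k in 1:3) {
    expect_lt(abs(mean(m[, k]) - p[k]), 3 * sqrt(p[k] * (1 - p[k]) / n))
  }
  # P(both mastered) at p = 0.5 thresholds equals the closed-form orthant
  # probability of a standard bivariate normal with rho = 0.5
  m2 <- sim_initial_profiles(n, c(0.5, 0.5), 0.5, seed = 6)
  both <- mean(m2[, 1] == 1 & m2[, 2] == 1)
  expect_lt(abs(both - orthant_upper(0.5)), 3 * sqrt(1 / 3 * 2 / 3 / n))
  expect_error(sim_initial_profiles(10, p, -0.2), "correlation")
})

test_that("profile advancement follows the per-attribute generators", {
  tk3 <- cda_fixture("transitions_k3")[["T1-T2"]]
  id2 <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  m <- decode_pattern(sample(0:7, 50, replace = TRUE), 3)
  expect_identical(advance_profiles(m, list(id2, id2, id2), seed = 1), m)
  n <- 1e5
  none <- matrix(0L, n, 3)
  adv <- advance_profiles(none, tk3, seed = 7)
  expect_lt(abs(mean(adv[, 1]) - 0.45), 3 * sqrt(0.45 * 0.55 / n))  # A1 gain
  all1 <- matrix(1L, n, 3)
  adv1 <- advance_profiles(all1, tk3, seed = 8)
  expect_lt(abs(mean(adv1[, 3]) - 0.13), 3 * sqrt(0.13 * 0.87 / n)) # A3 retention
  bad <- list(id2, id2, matrix(c(0.5, 0.4, 0, 1), 2, byrow = TRUE))
  expect_error(advance_profiles(m, bad), "sum to 1")
})

test_that("longitudinal simulation composes its parts and is reproducible", {
  d1 <- study_design(k = 3, j = 20, n = 30, t_points = 1)
  s1 <- sim_longitudinal(d1, q3, p_high, seed = 9)
  expect_identical(nrow(s1), 1L)

  d <- study_design(k = 3, j = 20, n = 1e5)
  s <- sim_longitudinal(d, q3, p_high, seed = 10)
  # Chapman-Kolmogorov: wave-2 A1 mastery = 0.6 * 0.45 + 0.4 * 0.97 = 0.658
  expect_lt(abs(mean(s$profiles[[2]][, 1]) - 0.658), 3 * sqrt(0.658 * 0.342 / 1e5))

  d_small <- study_design(k = 3, j = 20, n = 40)
  a <- sim_longitudinal(d_small, q3, p_high, seed = 11)
  b <- sim_longitudinal(d_small, q3, p_high, seed = 11)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$responses, b$responses)
})

test_that("mastery growth is monotone when no attribute can be lost", {
  gain_only <- lapply(1:3, function(k) matrix(c(0.6, 0.4, 0, 1), 2, byrow = TRUE))
  d <- study_design(k = 3, j = 20, n = 5000, t_points = 3,
                    transitions = list(gain_only, gain_only))
  s <- sim_longitudinal(d, q3, p_high, seed = 12)
  rates <- sapply(s$profiles, colMeans)
  expect_true(all(diff(t(rates)) >= 0))
})

test_that("attribute chains evolve independently given the current state", {
  tk3 <- cda_fixture("transitions_k3")[["T1-T2"]]
  n <- 2e4
  start <- matrix(0L, n, 3)
  adv <- advance_profiles(start, tk3, seed = 13)
  # transitions of different attributes are uncorrelated from a common state
  expect_lt(abs(cor(adv[, 1], adv[, 2])), 3 / sqrt(n))
})

test_that("training sets stratify, collide, and weight as specified", {
  ts <- build_training_set(q3, size = 40, weights = "uniform")
  expect_identical(as.integer(table(ts$labels)), rep(5L, 8))  # exact stratification
  # Table 7's Q is complete: all 8 ideal vectors are mutually distinct
  qe <- cda_fixture("q_empirical")
  ive <- ideal_responses(decode_pattern(0:7, 3), qe)
  expect_identical(nrow(unique(ive)), 8L)
  # the simulation Q has exactly one colliding pair among its 8 patterns
  iv3 <- ideal_responses(decode_pattern(0:7, 3), q3)
  expect_identical(nrow(unique(iv3)), 7L)
  expect_error(build_training_set(q3, 10, weights = rep(0, 8)), "positive sum")
  # population draws follow the copula-implied pattern distribution
  pd <- pattern_distribution(c(0.4, 0.4, 0.2), 0.5)
  expect_equal(sum(pd$probability), 1, tolerance = 1e-9)
  tsp <- build_training_set(q3, 2e4, weights = "population",
                            initial_mastery = c(0.4, 0.4, 0.2), seed = 14)
  freq <- tabulate(tsp$labels + 1, 8) / 2e4
  expect_true(all(abs(freq - pd$probability) <
                    3 * sqrt(pd$probability * (1 - pd$probability) / 2e4) + 1e-3))
})

test_that("the copula pattern distribution matches Monte-Carlo sampling", {
  p <- c(0.3, 0.6)
  pd <- pattern_distribution(p, 0.5)
  n <- 1e5
  m <- sim_initial_profiles(n, p, 0.5, seed = 15)
  emp <- tabulate(encode_pattern(m) + 1, 4) / n
  expect_true(all(abs(emp - pd$probability) < 0.006))
})
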