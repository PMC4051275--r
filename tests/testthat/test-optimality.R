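test_that("expected gain follows the payoff arithmetic", {
  m <- utility_model(u_plus = 1, u_minus = 5, epsilon = 1)
  # p = 0.9 at some time t: G = 6 * 0.9 - 5 = 0.4
  t9 <- -log(1 - 2 * (0.9 - 0.5))  # p(t) = 0.9 for the exponential form
  expect_equal(expected_gain(t9, m), 0.4, tolerance = 1e-12)
  # certainty limit: G -> u_plus
  expect_equal(expected_gain(80, m), 1, tolerance = 1e-10)
  # break-even accuracy: G = 0 exactly at p = 1/(U+/U- + 1)
  p_be <- 1 / (1 / 5 + 1)
  t_be <- -log(1 - 2 * (p_be - 0.5))
  expect_equal(expected_gain(t_be, m), 0, tolerance = 1e-12)
  expect_error(expected_gain(-0.1, m), ">= 0")
  expect_error(utility_model(u_plus = -1), "u_plus")
})

test_that("the break-even time has its closed form and limits", {
  # U+ = 1, U- = 5, eps = 1: solve 1/2 + (1 - e^-t)/2 = 5/6 -> t = ln 3
  expect_equal(min_profitable_time(utility_model(1, 5, 1)), log(3),
               tolerance = 1e-9)
  # equal payoffs: chance accuracy already breaks even
  expect_equal(min_profitable_time(utility_model(1, 1, 1)), 0)
  # vanishing loss: t_min -> 0
  expect_lt(min_profitable_time(utility_model(1, 1e-9, 1)), 1e-6)
})

test_that("the optimal time solves the tangent condition", {
  sol <- solve_optimal_time(utility_model(1, 5, 1, t_nd = 0))
  # independent oracle: dense grid search over G(t)/t
  tg <- seq(1.2, 8, by = 1e-4)
  g <- (1 + 5) * (0.5 + (1 - exp(-tg)) / 2) - 5
  t_grid <- tg[which.max(g / tg)]
  expect_equal(sol$t_star, t_grid, tolerance = 1e-3)
  expect_equal(sol$t_star, 2.2893, tolerance = 1e-4)
  expect_true(sol$converged)
  expect_gt(sol$t_star, sol$t_min)
  expect_gt(sol$gain_at_opt, 0)
  # tangent of G at t* passes through -t_nd (here the origin)
  gp <- (1 + 5) * 0.5 * exp(-sol$t_star)
  intercept_t <- sol$t_star - sol$gain_at_opt / gp
  expect_equal(intercept_t, 0, tolerance = 1e-8)
})

test_that("t* scales exactly with the accuracy scale when t_nd = 0", {
  t1 <- solve_optimal_time(utility_model(1, 5, 1, 0))$t_star
  t2 <- solve_optimal_time(utility_model(1, 5, 2, 0))$t_star
  expect_equal(t2, t1 / 2, tolerance = 1e-9)
  # eps * t* constant across the scale
  eps <- c(0.05, 0.2, 1, 4)
  prod <- vapply(eps, function(e) {
    e * solve_optimal_time(utility_model(1, 5, e, 0))$t_star
  }, numeric(1))
  expect_lt(diff(range(prod)) / mean(prod), 1e-6)
})

test_that("t* responds monotonically to payoffs, scale and delays", {
  # increasing reward shortens the optimal time
  t_low <- solve_optimal_time(utility_model(1, 5, 1, 0))$t_star
  t_high <- solve_optimal_time(utility_model(2, 5, 1, 0))$t_star
  expect_lt(t_high, t_low)
  # larger loss lengthens it
  expect_gt(solve_optimal_time(utility_model(1, 10, 1, 0))$t_star, t_low)
  # t* strictly increasing in non-decision time
  ts <- vapply(c(0, 10, 100, 1000), function(tnd) {
    solve_optimal_time(utility_model(1, 5, 1, tnd))$t_star
  }, numeric(1))
  expect_true(all(diff(ts) > 0))
  # t* strictly decreasing in the accuracy scale at fixed payoffs
  td <- vapply(c(0.2, 0.5, 1, 2), function(e) {
    solve_optimal_time(utility_model(1, 5, e, 5))$t_star
  }, numeric(1))
  expect_true(all(diff(td) < 0))
  # second-order condition: the rate of gain is a local maximum
  sol <- solve_optimal_time(utility_model(1, 5, 1, 10))
  rate <- function(t) expected_gain(t, utility_model(1, 5, 1, 10)) / (t + 10)
  expect_gt(rate(sol$t_star), rate(sol$t_star * 1.01))
  expect_gt(rate(sol$t_star), rate(sol$t_star * 0.99))
})

test_that("power-law fits behave as the scaling analysis predicts", {
  # no non-decision time: exact power law with exponent 1 and a = t1
  pl0 <- power_law_fit(1, 5, t_nd = 0)
  expect_equal(pl0$k, 1, tolerance = 1e-8)
  t1 <- solve_optimal_time(utility_model(1, 5, 1, 0))$t_star
  expect_equal(pl0$a_coef, t1, tolerance = 1e-6)
  expect_equal(pl0$r_squared, 1, tolerance = 1e-10)
  # positive non-decision time: near power law with exponent in (0, 1)
  # (the exact value, and its ordering in t_nd, depend on the epsilon grid)
  ks <- vapply(c(10, 100, 1000), function(tnd) {
    power_law_fit(1, 5, t_nd = tnd)$k
  }, numeric(1))
  expect_true(all(ks > 0 & ks < 1))
  expect_true(all(vapply(c(10, 100, 1000), function(tnd) {
    power_law_fit(1, 5, t_nd = tnd)$r_squared
  }, numeric(1)) > 0.99))  # still very close to a power law
})

test_that("optimal-rate predictions inherit the epsilon distribution", {
  # t_nd = 0: r* = epsilon / t1 exactly
  pr <- predict_rate_distribution(1, 5, t_nd = 0, epsilon_mean = 1,
                                  epsilon_sd = 0.15, n_draws = 500,
                                  seed = 42)
  t1 <- solve_optimal_time(utility_model(1, 5, 1, 0))$t_star
  expect_equal(pr$r_star, pr$epsilon / t1, tolerance = 1e-9)
  # cross-check a few draws against the per-draw solver
  for (i in c(1, 50, 200)) {
    sol <- solve_optimal_time(utility_model(1, 5, pr$epsilon[i], 0))
    expect_equal(pr$t_star[i], sol$t_star, tolerance = 1e-8)
  }
  expect_identical(pr$r_star,
                   predict_rate_distribution(1, 5, 0, 1, 0.15, 500,
                                             seed = 42)$r_star)
  # large delay, mild spread: the map stays locally linear, rate ~ Normal
  pr_nd <- predict_rate_distribution(1, 5, t_nd = 100, epsilon_mean = 1,
                                     epsilon_sd = 0.05, n_draws = 2000,
                                     seed = 7)
  expect_lt(abs(pr_nd$moments["skewness"]), 0.1)
})
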