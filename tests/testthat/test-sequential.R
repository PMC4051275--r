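test_that("PACF recovers known dependency structure", {
  # white noise: no lag significant beyond the noise band
  wn <- withr::with_seed(1, rnorm(1e4))
  p_wn <- rate_pacf(wn, max_lag = 20, skip_initial = 10)
  expect_true(all(abs(p_wn$mean) < 3 / sqrt(1e4 - 10)))
  # AR(1) with weight 0.5: first partial 0.5, higher ones negligible
  ar1 <- generate_block_rates(1, 0.3, 0.5, n_trials = 1e4, seed = 2)
  p1 <- rate_pacf(ar1$rate_latent, max_lag = 10)
  expect_equal(p1$mean[1], 0.5, tolerance = 0.05)
  expect_true(all(abs(p1$mean[3:10]) < 4 / sqrt(1e4)))
  # AR(3) at the reference weights: PACF(1) equals the Yule-Walker value
  ar3 <- generate_block_rates(2, 0.3, printed_ar_weights, n_trials = 5e4,
                              seed = 3)
  p3 <- rate_pacf(ar3$rate_latent, max_lag = 5)
  rho1 <- yule_walker_gain(printed_ar_weights)$acf[1]
  expect_equal(rho1, 0.26324, tolerance = 1e-4)
  expect_equal(p3$mean[1], rho1, tolerance = 0.02)
  expect_error(rate_pacf(rnorm(25), max_lag = 20), "too short")
})

test_that("within-block shuffling destroys dependency, preserves marginals", {
  blocks <- lapply(1:8, function(i) {
    generate_block_rates(2, 0.3, printed_ar_weights, 200, seed = i)$rate_latent
  })
  sh <- shuffle_control(blocks, seed = 44)
  n_eff <- 8 * 190
  expect_true(all(abs(sh$mean) < 3 / sqrt(n_eff)))
  expect_identical(sh$mean, shuffle_control(blocks, seed = 44)$mean)
  # marginal histogram preserved exactly under permutation
  one <- with_seed_for_test(44, sample(blocks[[1]]))
  expect_identical(sort(one), sort(blocks[[1]]))
})

test_that("pooled conditional-ML AR fitting recovers generating weights", {
  # study scale: 96 blocks of 200 trials at the reference weights
  blocks <- lapply(1:96, function(i) {
    generate_block_rates(2, 0.3, printed_ar_weights, 200,
                         seed = 1000 + i)$rate_latent
  })
  fit <- fit_ar_ml(blocks, order = 3)
  expect_true(fit$stable)
  expect_true(all(abs(fit$weights - printed_ar_weights) < 0.03))
  expect_equal(fit$sigma_u, 0.3, tolerance = 0.02)
  expect_equal(fit$mu_u, 2, tolerance = 0.1)
  # iid input: all weights within 2 SE of zero
  iid <- lapply(1:20, function(i) withr::with_seed(i, rnorm(500, 2, 0.3)))
  fit0 <- fit_ar_ml(iid, order = 3)
  expect_true(all(abs(fit0$weights) < 2.5 * fit0$se))
  # long AR(1): tight recovery
  long1 <- generate_block_rates(1, 0.3, 0.5, n_trials = 5e4, seed = 5)
  fit1 <- fit_ar_ml(long1$rate_latent, order = 1)
  expect_equal(fit1$weights, 0.5, tolerance = 0.01)
})

test_that("decorrelation inverts the AR recursion exactly", {
  blk <- generate_block_rates(2, 0.3, printed_ar_weights, 300, seed = 7)
  u_hat <- decorrelate(blk$rate_latent, printed_ar_weights)
  # zero pre-history convention matches the generator for every trial
  expect_lt(max(abs(u_hat - blk$u)), 1e-10)
  u_drop <- decorrelate(blk$rate_latent, printed_ar_weights,
                        prehistory = "drop")
  expect_true(all(is.na(u_drop[1:3])))
  expect_lt(max(abs(u_drop[-(1:3)] - blk$u[-(1:3)])), 1e-10)
  # zero weights: identity
  expect_identical(decorrelate(blk$rate_latent, numeric(0)),
                   blk$rate_latent)
  # whiteness: residual input has no remaining sequential dependency
  p_u <- rate_pacf(u_hat, max_lag = 20, skip_initial = 10)
  n_sig <- sum(abs(p_u$mean) > 1.96 / sqrt(290))
  expect_lte(n_sig, 2)  # at most chance level among 20 lags
})

test_that("refitting the decorrelated input finds no structure", {
  blocks <- lapply(1:30, function(i) {
    generate_block_rates(2, 0.3, printed_ar_weights, 200,
                         seed = 300 + i)$rate_latent
  })
  fit <- fit_ar_ml(blocks, order = 3)
  resid <- lapply(blocks, decorrelate, weights = fit$weights)
  refit <- fit_ar_ml(resid, order = 3)
  expect_true(all(abs(refit$weights) < 2.5 * refit$se))
})

test_that("AR-to-MA conversion matches closed forms and the recursion", {
  # geometric closed form for AR(1)
  ma1 <- ar_to_ma(0.5)
  expect_equal(ma1$b, 0.5^(0:(length(ma1$b) - 1)), tolerance = 1e-12)
  # degenerate system
  ma0 <- ar_to_ma(numeric(0))
  expect_equal(ma0$b, 1)
  expect_equal(unname(steady_state_gains(ma0)), c(1, 1))
  # reference weights: leading MA weights from the recursion oracle
  ma3 <- ar_to_ma(printed_ar_weights)
  expect_equal(ma3$b[2:4], c(0.2220, 0.153284, 0.133117), tolerance = 1e-6)
  b_oracle <- local({
    b <- numeric(201); b[1] <- 1
    for (i in 1:200) {
      j <- seq_len(min(i, 3))
      b[i + 1] <- sum(printed_ar_weights[j] * b[i + 1 - j])
    }
    b
  })
  n <- length(ma3$b)
  expect_lt(max(abs(ma3$b - b_oracle[seq_len(n)])), 1e-10)
  expect_true(all(abs(b_oracle[(n + 1):201]) < 1e-9))
  expect_true(all(Mod(ma3$poles) < 1))
  # independent cross-check against the standard ARMA impulse response
  expect_equal(ma3$b[-1], ARMAtoMA(ar = printed_ar_weights, lag.max = n - 1),
               tolerance = 1e-12)
  expect_error(ar_to_ma(c(0.9, 0.3)), "unstable")
})

test_that("repeated AR roots fall back to the exact recursion", {
  # a1 = 1, a2 = -0.25 has the double root 0.5
  w <- c(1, -0.25)
  ma <- ar_to_ma(w)
  b_oracle <- (1 + 0:(length(ma$b) - 1)) * 0.5^(0:(length(ma$b) - 1))
  expect_equal(ma$b, b_oracle, tolerance = 1e-10)
})

test_that("steady-state gains agree across three independent routes", {
  gains <- steady_state_gains(printed_ar_weights)
  expect_equal(unname(gains["mean_gain"]), 1 / (1 - 0.402), tolerance = 1e-12)
  expect_equal(round(unname(gains["mean_gain"]), 2), 1.67)
  expect_equal(round(unname(gains["sd_gain"]), 2), 1.05)
  yw <- yule_walker_gain(printed_ar_weights)
  expect_equal(unname(gains["sd_gain"]), yw$sd_gain, tolerance = 1e-6)
  # sum of MA weights identity, generic stable systems
  for (w in list(0.3, c(0.2, 0.1), c(-0.3, 0.2), printed_ar_weights)) {
    ma <- ar_to_ma(w)
    expect_equal(sum(ma$b), 1 / (1 - sum(w)), tolerance = 1e-8)
    expect_equal(ma$sd_gain, yule_walker_gain(w)$sd_gain, tolerance = 1e-6)
  }
})

test_that("the step response rises to the gain within ten trials", {
  sr <- step_response(printed_ar_weights, 30)
  expect_equal(sr[1], 1)  # b0
  expect_true(all(diff(sr) >= 0))
  gain <- 1 / (1 - sum(printed_ar_weights))
  expect_equal(sr[30], gain, tolerance = 1e-4)
  expect_gte(sr[9] / gain, 0.99)
  expect_lt(sr[8] / gain, 0.99)
  # asymptote identity
  expect_equal(step_response(printed_ar_weights, 400)[400], 1.672241,
               tolerance = 1e-6)
})

test_that("steady-state density convolution matches its closed form", {
  ma <- ar_to_ma(printed_ar_weights)
  # identity system passes the input through
  ident <- ar_to_ma(numeric(0))
  d0 <- steady_state_density(function(u) dnorm(u, 2, 0.3), ident,
                             c(2 - 8 * 0.3, 2 + 8 * 0.3))
  expect_lt(max(abs(d0$density - dnorm(d0$r, 2, 0.3))), 1e-9)
  # Normal input: output is exactly Normal with the gain-scaled moments
  d <- steady_state_density(function(u) dnorm(u, 2, 0.3), ma,
                            c(2 - 8 * 0.3, 2 + 8 * 0.3))
  expect_lt(max(abs(d$density -
                      dnorm(d$r, 2 * ma$mean_gain, 0.3 * ma$sd_gain))),
            5e-3)
  # zero-truncated input: smoothing removes the truncation; the output
  # density at the origin is exactly zero although the input is not
  dt <- steady_state_density(function(u) dtrunc_normal(u, 0, 0.3, 0), ma,
                             c(0, 8 * 0.3))
  expect_gt(dtrunc_normal(0, 0, 0.3, 0), 1)
  expect_identical(dt$density[1], 0)
  expect_error(
    steady_state_density(function(u) dnorm(u, 2, 0.3), ma, c(1.4, 2.6),
                         n_grid = 64),
    "refine the grid")
})

test_that("the convolved density matches Monte-Carlo stationary draws", {
  ma <- ar_to_ma(printed_ar_weights)
  dt <- steady_state_density(function(u) dtrunc_normal(u, 0, 0.3, 0), ma,
                             c(0, 8 * 0.3))
  # 1e5 independent stationary realisations (burn-in 60 trials each)
  n <- 1e5
  draws <- with_seed_for_test(77, {
    r1 <- r2 <- r3 <- numeric(n)
    for (step in 1:60) {
      u <- rtrunc_normal(n, 0, 0.3, 0)
      r <- printed_ar_weights[1] * r1 + printed_ar_weights[2] * r2 +
        printed_ar_weights[3] * r3 + u
      r3 <- r2; r2 <- r1; r1 <- r
    }
    r1
  })
  brk <- quantile(draws, seq(0, 1, length.out = 31))
  brk[1] <- -Inf; brk[31] <- Inf
  counts <- as.numeric(table(cut(draws, brk)))
  cdf_grid <- cumsum(dt$density) * diff(dt$r[1:2])
  p_at <- approxfun(dt$r, cdf_grid, yleft = 0, yright = 1)
  probs <- diff(c(0, p_at(brk[2:30]), 1))
  chi <- suppressWarnings(chisq.test(counts, p = probs / sum(probs)))
  expect_gt(chi$p.value, 0.01)
})

test_that("repeat/alternate codes follow the binary scheme", {
  expect_identical(spatial_code(transitions = c("R", "R", "R", "R")), 0L)
  expect_identical(spatial_code(transitions = c("R", "R", "A", "R")), 2L)
  expect_identical(spatial_code(transitions = c("A", "A", "R", "A")), 13L)
  expect_identical(spatial_code(transitions = c("A", "A", "A", "A")), 15L)
  # side sequences: all-same = RRRR = 0; strict alternation = AAAA = 15
  expect_identical(spatial_code(c("L", "L", "L", "L", "L")), 0L)
  expect_identical(spatial_code(c("R", "L", "R", "L", "R")), 15L)
  expect_identical(spatial_code(c("L", "L", "R", "L", "L")),
                   spatial_code(transitions = c("R", "A", "A", "R")))
  expect_error(spatial_code(c("L", "R")), "5 consecutive")
  expect_error(spatial_code(transitions = c("R", "R", "X", "R")), "R")
})

test_that("the history analysis recovers an injected laterality effect", {
  deltas <- default_spatial_deltas()
  cfg <- synth_config(n_subjects = 24, n_trials = 200,
                      spatial_deltas = deltas, seed = 5)
  tab <- generate_experiment(cfg)
  sp <- spatial_summary(tab, conditions = c("AE", "UE"), dither_seed = 9)
  expect_lt(sp$p_value, 0.001)
  expect_equal(sp$df1, 15)
  # injected ordering: codes 0 and 15 fast, codes 1/6/14 slow
  pc <- sp$per_code
  fast <- mean(pc$mean_rate[pc$code %in% c(0, 15)])
  slow <- mean(pc$mean_rate[pc$code %in% c(1, 6, 14)])
  mid <- mean(pc$mean_rate[!pc$code %in% c(0, 1, 6, 14, 15)])
  expect_gt(fast, mid)
  expect_lt(slow, mid)
  # bookkeeping: code cell counts sum to the analysed trials
  expect_equal(sum(pc$n), sp$n_trials_used)
  n_blocks_easy <- length(unique(tab$block[tab$condition %in% c("AE", "UE")]))
  expect_equal(sp$n_trials_used, n_blocks_easy * (200 - 4))
})
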