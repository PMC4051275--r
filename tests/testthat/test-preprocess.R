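test_that("dithering is bounded, centred, and removes rate-histogram gaps", {
  rt <- rep(100:120, each = 500)
  d <- dither_rts(rt, seed = 4)
  expect_true(all(abs(d - rt) < 0.5))
  expect_lt(abs(mean(d - rt)), 3 * (1 / sqrt(12)) / sqrt(length(rt)))
  expect_identical(d, dither_rts(rt, seed = 4))
  # reciprocals of integer ms cluster on isolated values ("clumping");
  # between them the raw rate histogram has empty bins, the dithered not
  raw_rate <- 1000 / rt
  dit_rate <- 1000 / d
  breaks <- seq(1000 / 120.5, 1000 / 99.5, length.out = 80)
  raw_counts <- hist(raw_rate, breaks = breaks, plot = FALSE)$counts
  dit_counts <- hist(dit_rate, breaks = breaks, plot = FALSE)$counts
  expect_gt(sum(raw_counts == 0), 0)
  expect_equal(sum(dit_counts == 0), 0)
})

test_that("dithering leaves time-domain moments unchanged in distribution", {
  # continuous ground truth -> quantise -> dither: moments come back
  true_rt <- withr::with_seed(12, rnorm(1e4, 400, 40))
  quant <- round(true_rt)
  d <- dither_rts(quant, seed = 13)
  expect_lt(abs(mean(d) - mean(true_rt)), 3 * sd(true_rt) / sqrt(1e4))
  expect_lt(abs(sd(d) - sd(true_rt)), 3 * sd(true_rt) / sqrt(2e4))
})

test_that("reciprocal transform, masking, and bound arithmetic are exact", {
  out <- to_rates(c(500, 60000, 149, 151))
  expect_equal(out$rate[1], 2.0)
  expect_equal(out$rate[2], 1/60)
  expect_true(out$anticipatory[3])   # 149 ms < 0.15 s -> masked
  expect_false(out$anticipatory[4])
  expect_true(is.na(out$rate[3]))
  expect_error(to_rates(c(100, 0)), "positive")
  # round trip rate -> RT -> rate
  r <- c(0.5, 2, 6.5)
  expect_equal(to_rates(1000 / r)$rate, r, tolerance = 1e-12)
})

test_that("block moments follow the stated conventions", {
  expect_error(block_moments(c(1, 2, 3)), "at least 4")
  m <- block_moments(rep(2, 10))
  expect_equal(m$sd, 0)
  expect_true(is.na(m$skewness) && is.na(m$excess_kurtosis))
  # large Normal sample: skew and excess kurtosis near 0
  x <- withr::with_seed(3, rnorm(1e5, 2, 0.3))
  mn <- block_moments(x)
  expect_lt(abs(mn$skewness), 3 * sqrt(6 / 1e5))
  expect_lt(abs(mn$excess_kurtosis), 3 * sqrt(24 / 1e5))
  # median rate is the reciprocal of median RT for odd-length positive data
  rt <- c(300, 350, 400, 500, 800) / 1000
  expect_equal(block_moments(1 / rt)$median, 1 / block_moments(rt, "time")$median)
})

test_that("CV classification uses the documented boundary rule", {
  expect_equal(classify_blocks(2, 0.3), "untruncated")   # cv 0.15
  expect_equal(classify_blocks(1, 0.5), "truncated")     # cv 0.5
  expect_equal(classify_blocks(1, 0.4), "truncated")     # boundary
  expect_equal(classify_blocks(c(2, 1), c(0.3, 0.5)),
               c("untruncated", "truncated"))
})

test_that("standardise-and-collapse pools z-scores per contract", {
  x <- withr::with_seed(6, rnorm(2000, 3, 0.4))
  fits <- list(b1 = list(mu_hat = mean(x), sigma_hat = sd(x)))
  pool <- standardize_and_collapse(list(b1 = x), fits)
  expect_lt(abs(mean(pool$z)), 1e-10)
  expect_equal(sd(pool$z), 1, tolerance = 1e-10)
  # truncated group keeps only positive z
  pool_t <- standardize_and_collapse(list(b1 = x), fits, group = "truncated")
  expect_true(all(pool_t$z > 0))
  expect_error(
    standardize_and_collapse(list(b1 = x),
                             list(b1 = list(mu_hat = 0, sigma_hat = 0))),
    "sigma")
  expect_error(standardize_and_collapse(list(b2 = x), fits), "missing fit")
})

test_that("probit diagnostics are self-consistent and discriminate shape", {
  # exact Normal quantiles reproduce the identity line
  n <- 2000
  pp <- (seq_len(n) - 3/8) / (n + 1/4)
  pr <- probit_coordinates(qnorm(pp))
  expect_equal(pr$slope, 1, tolerance = 1e-6)
  expect_equal(pr$intercept, 0, tolerance = 1e-6)
  expect_equal(pr$r_squared, 1, tolerance = 1e-9)
  # Monte-Carlo contrast: truncated-Normal rates are band-linear,
  # reciprocal-inverse-Gaussian rates are not
  z_trn <- scale(sample_rates("trN", 1e5, list(mu = 2, sigma = 0.3),
                              seed = 17))
  z_rig <- scale(sample_rates("recIG", 1e5, list(mean = 0.5, sigma2 = 0.04),
                              seed = 17))
  r2_trn <- probit_coordinates(as.numeric(z_trn))$r_squared
  r2_rig <- probit_coordinates(as.numeric(z_rig))$r_squared
  expect_gt(r2_trn, 0.999)
  expect_lt(r2_rig, r2_trn)
  expect_error(probit_coordinates(rnorm(50)), "at least 100")
})

test_that("the preprocessing chain reconciles every trial count", {
  tab <- generate_experiment(small_config(9))
  pp <- preprocess_experiment(tab, dither_seed = 2)
  bs <- pp$block_stats
  expect_equal(bs$n_used + bs$n_excluded_anticipatory, bs$n_input)
  expect_equal(sum(bs$n_input), nrow(tab))
  expect_equal(sum(bs$n_timed_out),
               sum(tab$timed_out))
  # timed-out trials enter the rate series at the bound
  for (b in names(pp$rates_by_block)) {
    r <- pp$rates_by_block[[b]]
    to <- attr(r, "timed_out")
    if (any(to)) expect_true(all(r[to] == 1/60))
  }
})
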