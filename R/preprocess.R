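#' Dither integer-millisecond reaction times
#'
#' Adds an independent uniform perturbation on (-0.5, +0.5) ms to each
#' recorded reaction time before the reciprocal transform. Millisecond
#' quantisation is magnified by taking reciprocals and produces artifactual
#' clumps and gaps in rate histograms at high rates; sub-quantum uniform
#' dither removes them while having no statistical effect in the time
#' domain.
#'
#' @param rt_ms Numeric vector of reaction times in integer milliseconds
#'   (`>= 1`).
#' @param seed Optional integer seed.
#' @return Numeric vector of dithered reaction times (ms).
#' @export
dither_rts <- function(rt_ms, seed = NULL) {
  if (any(rt_ms < 1)) stop("reaction times must be >= 1 ms", call. = FALSE)
  with_seed(seed, rt_ms + stats::runif(length(rt_ms), -0.5, 0.5))
}

#' Reciprocal transform with anticipation masking
#'
#' Converts reaction times (ms) to rates (s^-1) as `rate = 1000 / rt_ms` and
#' masks anticipatory responses: strictly `rt < anticipation_bound` seconds
#' (default 0.15 s, i.e. rate above 6.67 s^-1) is considered a guess, not a
#' stimulus-driven response, and excluded from analysis.
#'
#' @param rt_ms Positive numeric vector of (dithered) reaction times in ms.
#' @param anticipation_bound Bound in seconds (default 0.15).
#' @return Data.frame with columns `rate` (s^-1; `NA` where masked) and
#'   `anticipatory` (logical mask).
#' @export
to_rates <- function(rt_ms, anticipation_bound = 0.15) {
  if (any(rt_ms <= 0)) stop("reaction times must be positive", call. = FALSE)
  anticipatory <- (rt_ms / 1000) < anticipation_bound
  rate <- 1000 / rt_ms
  rate[anticipatory] <- NA_real_
  data.frame(rate = rate, anticipatory = anticipatory)
}

#' Sample central moments of a block
#'
#' Mean, standard deviation, skewness, excess kurtosis and median of one
#' block's values (in either domain). Skewness and kurtosis are the
#' conventional moment ratios `m3 / m2^(3/2)` and `m4 / m2^2 - 3` with
#' central moments computed with divisor `n`; the median uses the midpoint
#' convention, so for positive data the median of rate is exactly the
#' reciprocal of the median of reaction time.
#'
#' @param values Numeric vector, at least 4 finite values.
#' @param domain `"rate"` or `"time"`, a bookkeeping tag.
#' @return One-row data.frame: `domain`, `n`, `mean`, `sd`, `skewness`,
#'   `excess_kurtosis`, `median`, `cv`. Skewness and kurtosis are `NA` for
#'   constant data.
#' @export
block_moments <- function(values, domain = c("rate", "time")) {
  domain <- match.arg(domain)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("need at least 4 values for moment estimation",
                  call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  ctr <- values - m
  m2 <- mean(ctr^2)
  if (m2 > 0) {
    skew <- mean(ctr^3) / m2^1.5
    exkurt <- mean(ctr^4) / m2^2 - 3
  } else {
    skew <- NA_real_
    exkurt <- NA_real_
  }
  data.frame(domain = domain, n = n, mean = m, sd = s, skewness = skew,
             excess_kurtosis = exkurt, median = stats::median(values),
             cv = s / m, stringsAsFactors = FALSE)
}

#' Classify blocks by truncation severity
#'
#' A block whose coefficient of variation (SD/mean, from the
#' maximum-likelihood moments when available, otherwise sample moments)
#' reaches the threshold is labelled `"truncated"`; below it,
#' `"untruncated"`. The boundary value is assigned to the truncated side.
#' At the default threshold 0.4 the bound sits 2.5 SDs below the mean, the
#' point at which left truncation starts to distort sample moments
#' appreciably.
#'
#' @param mean,sd Numeric vectors of per-block means and SDs (s^-1).
#' @param cv_threshold Classification threshold (default 0.4).
#' @return Character vector, `"truncated"` or `"untruncated"` per block.
#' @export
classify_blocks <- function(mean, sd, cv_threshold = 0.4) {
  cv <- sd / mean
  ifelse(cv >= cv_threshold | mean <= 0, "truncated", "untruncated")
}

#' Standardise per block and collapse into one pool
#'
#' Converts each block's rates to z-scores using that block's
#' maximum-likelihood mean and SD, then pools blocks of the given
#' truncation class. For the truncated pool only positive z-scores are
#' retained, because left truncation under-represents the negative half.
#'
#' @param rates_by_block Named list of numeric rate vectors, one per block.
#' @param fits Named list of fits (with `mu_hat`, `sigma_hat`), same names.
#' @param group `"untruncated"` (keep all z) or `"truncated"` (keep `z > 0`).
#' @return Data.frame with columns `block` and `z`.
#' @export
standardize_and_collapse <- function(rates_by_block, fits,
                                     group = c("untruncated", "truncated")) {
  group <- match.arg(group)
  out <- lapply(names(rates_by_block), function(b) {
    fit <- fits[[b]]
    if (is.null(fit)) stop(sprintf("missing fit for block %s", b),
                           call. = FALSE)
    if (!is.finite(fit$sigma_hat) || fit$sigma_hat <= 0) {
      stop(sprintf("non-positive fitted sigma for block %s", b),
           call. = FALSE)
    }
    r <- rates_by_block[[b]]
    r <- r[is.finite(r)]
    z <- (r - fit$mu_hat) / fit$sigma_hat
    if (group == "truncated") z <- z[z > 0]
    if (length(z)) data.frame(block = b, z = z, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Probit (Normal quantile) coordinates and band linearity
#'
#' Orders the pooled z-scores against theoretical Normal quantiles at
#' plotting positions `(i - 3/8) / (n + 1/4)` and fits a least-squares line
#' restricted to the 5th-95th percentile band. A Normal pool gives slope 1,
#' intercept 0 and band R-squared essentially 1; skewed alternatives (such
#' as reciprocal-inverse-Gaussian rates) bend the plot and depress the band
#' R-squared.
#'
#' @param z Numeric vector of pooled z-scores, at least 100 values.
#' @param band Quantile band over which the line is fitted
#'   (default `c(0.05, 0.95)`).
#' @param half Set `TRUE` for a pool restricted to positive z-scores (the
#'   truncated group): theoretical quantiles are then taken from the upper
#'   half of the Normal, `qnorm((1 + p)/2)`, so a half-Normal sample plots
#'   as a straight line.
#' @return List of class `"probit_fit"`: `coordinates` (data.frame
#'   `theoretical`, `empirical`), `slope`, `intercept`, `r_squared`
#'   (band-restricted), `band`, `n`.
#' @export
probit_coordinates <- function(z, band = c(0.05, 0.95), half = FALSE) {
  z <- z[is.finite(z)]
  n <- length(z)
  if (n < 100) stop("need at least 100 values for the probit diagnostic",
                    call. = FALSE)
  emp <- sort(z)
  pp <- (seq_len(n) - 3/8) / (n + 1/4)
  theo <- if (half) stats::qnorm((1 + pp) / 2) else stats::qnorm(pp)
  in_band <- pp >= band[1] & pp <= band[2]
  x <- theo[in_band]
  y <- emp[in_band]
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(
    coordinates = data.frame(theoretical = theo, empirical = emp),
    slope = slope,
    intercept = intercept,
    r_squared = 1 - ss_res / ss_tot,
    band = band,
    n = n
  ), class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf(
    "Probit fit over the %.0f-%.0f%% band (n = %d):\n",
    100 * x$band[1], 100 * x$band[2], x$n))
  cat(sprintf("  slope = %.4f, intercept = %.4f, R^2 = %.6f\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Preprocess a full trial table into rate series and group pools
#'
#' Runs the standard chain on a canonical trial table: dither reaction
#' times, transform to rates, mask anticipatory trials, compute per-block
#' sample moments and truncated-Normal ML fits, classify blocks by CV of the
#' ML moments, and build the standardised z-pools of both truncation
#' classes (with probit summaries when a pool is large enough). Timed-out
#' trials enter the rate series at the truncation bound (left-censoring)
#' but are flagged so downstream analyses can drop them; they are retained
#' for moments and fits here.
#'
#' @param table Canonical trial table.
#' @param truncation_bound Rate bound (s^-1) used for the ML fits.
#' @param anticipation_bound Seconds; strict lower bound for analysable RTs.
#' @param cv_threshold Truncation classification threshold.
#' @param dither_seed Seed for the dither draws.
#' @return List of class `"preprocessed"`: `rates_by_block` (list of rate
#'   vectors with `timed_out` attribute), `block_stats` (data.frame of
#'   sample moments, ML moments, classification and exclusion counts),
#'   `fits` (per-block ML fits), `pools` (list of `untruncated` /
#'   `truncated` z-pool data.frames), `probit` (list of probit fits, `NULL`
#'   where a pool is too small).
#' @export
preprocess_experiment <- function(table, truncation_bound = 1/60,
                                  anticipation_bound = 0.15,
                                  cv_threshold = 0.4,
                                  dither_seed = 1L) {
  blocks <- unique(table$block)
  seeds <- derive_seeds(dither_seed, length(blocks))
  rates_by_block <- list()
  fits <- list()
  stats_rows <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[i]
    rows <- table[table$block == b, ]
    rt_d <- dither_rts(rows$rt_ms, seed = seeds[i])
    # the 60 s time-out is exact, not quantised: keep censored trials at the bound
    rt_d[rows$timed_out] <- rows$rt_ms[rows$timed_out]
    rr <- to_rates(rt_d, anticipation_bound)
    keep <- !rr$anticipatory
    rate <- rr$rate[keep]
    # censored rates may dither marginally below the bound; clamp
    rate[rows$timed_out[keep]] <- pmax(rate[rows$timed_out[keep]],
                                       truncation_bound)
    attr(rate, "timed_out") <- rows$timed_out[keep]
    rates_by_block[[as.character(b)]] <- rate
    mom <- block_moments(rate, "rate")
    fit <- fit_truncated_normal(rate, a = truncation_bound)
    fits[[as.character(b)]] <- fit
    stats_rows[[i]] <- data.frame(
      block = b,
      condition = rows$condition[1],
      subject = rows$subject[1],
      n_input = nrow(rows),
      n_used = mom$n,
      n_excluded_anticipatory = sum(rr$anticipatory),
      n_timed_out = sum(rows$timed_out),
      mean = mom$mean, sd = mom$sd, cv = mom$cv,
      skewness = mom$skewness, excess_kurtosis = mom$excess_kurtosis,
      median = mom$median,
      mu_ml = fit$mu_hat, sigma_ml = fit$sigma_hat,
      cv_ml = fit$sigma_hat / fit$mu_hat,
      stringsAsFactors = FALSE
    )
  }
  block_stats <- do.call(rbind, stats_rows)
  block_stats$truncation_class <- classify_blocks(
    block_stats$mu_ml, block_stats$sigma_ml, cv_threshold)
  pools <- list()
  probit <- list()
  for (grp in c("untruncated", "truncated")) {
    ids <- as.character(block_stats$block[block_stats$truncation_class == grp])
    if (!length(ids)) {
      pools[[grp]] <- NULL
      probit[[grp]] <- NULL
      next
    }
    pools[[grp]] <- standardize_and_collapse(rates_by_block[ids], fits[ids],
                                             group = grp)
    probit[[grp]] <- if (!is.null(pools[[grp]]) && nrow(pools[[grp]]) >= 100) {
      probit_coordinates(pools[[grp]]$z, half = grp == "truncated")
    }
  }
  structure(list(
    rates_by_block = rates_by_block,
    block_stats = block_stats,
    fits = fits,
    pools = pools,
    probit = probit
  ), class = "preprocessed")
}
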