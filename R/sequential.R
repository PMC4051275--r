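#' Partial autocorrelation of rate series, averaged over blocks
#'
#' Computes the partial autocorrelation function of each block's de-meaned
#' steady-state rate series (Durbin-Levinson on autocovariances with
#' divisor `n`) and averages coefficients across blocks. The first
#' `skip_initial` trials of each block are omitted to avoid contamination
#' from the start-of-block transient, and timed-out trials may be excluded
#' by the caller before the call.
#'
#' @param series A numeric vector or a list of numeric vectors (blocks).
#' @param max_lag Number of lags (default 20).
#' @param skip_initial Trials dropped from the start of each block
#'   (default 10).
#' @return List of class `"pacf_result"`: `lags`, `mean` (averaged
#'   coefficients), `per_block` (matrix, lags x blocks), `se` (standard
#'   error of the mean across blocks, `NA` for a single block), `n_blocks`,
#'   `n_per_block`.
#' @export
rate_pacf <- function(series, max_lag = 20, skip_initial = 10) {
  if (is.numeric(series)) series <- list(series)
  per_block <- vapply(series, function(x) {
    x <- x[-seq_len(min(skip_initial, length(x)))]
    x <- x[is.finite(x)]
    if (length(x) <= max_lag + 10) {
      stop("series too short for the requested number of lags",
           call. = FALSE)
    }
    as.numeric(stats::pacf(x, lag.max = max_lag, plot = FALSE,
                           demean = TRUE)$acf)
  }, numeric(max_lag))
  per_block <- matrix(per_block, nrow = max_lag)
  nb <- ncol(per_block)
  structure(list(
    lags = seq_len(max_lag),
    mean = rowMeans(per_block),
    per_block = per_block,
    se = if (nb > 1) apply(per_block, 1, stats::sd) / sqrt(nb) else
      rep(NA_real_, max_lag),
    n_blocks = nb,
    n_per_block = vapply(series, length, integer(1)) -
      pmin(skip_initial, vapply(series, length, integer(1)))
  ), class = "pacf_result")
}

#' Within-block shuffle control for sequential dependency
#'
#' Permutes trials randomly within each block (preserving every marginal
#' exactly) and recomputes the averaged PACF. Genuine sequential dependency
#' disappears under shuffling; surviving structure would indicate an
#' artefact of the estimator.
#'
#' @inheritParams rate_pacf
#' @param seed Integer seed for the permutations.
#' @return A `"pacf_result"` for the shuffled series.
#' @export
shuffle_control <- function(series, max_lag = 20, skip_initial = 10,
                            seed = 1L) {
  if (is.numeric(series)) series <- list(series)
  shuffled <- with_seed(seed, lapply(series, function(x) x[sample.int(length(x))]))
  rate_pacf(shuffled, max_lag = max_lag, skip_initial = skip_initial)
}

#' Fit a pure autoregressive model by conditional Gaussian ML
#'
#' Fits `r_n = a_1 r_(n-1) + ... + a_m r_(n-m) + u_n` with `u_n` iid Normal,
#' pooling blocks: each block contributes its own lagged regression rows
#' (no lag pairs cross a block boundary), each block is de-meaned by its
#' own steady-state mean (absorbing the block-specific input mean), and the
#' stacked regression is solved by least squares, which is the conditional
#' Gaussian maximum-likelihood estimate of the weights. The innovation SD
#' is the ML (divisor `n`) residual SD, and the pooled input mean is
#' inferred from the grand mean via the gain identity
#' `mu_u = mean(r) * (1 - sum(a))`.
#'
#' @param series Numeric vector or list of numeric vectors (blocks), already
#'   restricted to usable trials.
#' @param order AR order `m` (default 6).
#' @param skip_initial Trials dropped from the start of each block
#'   (default 10) to remove the transient.
#' @return List of class `"ar_model"`: `order`, `weights`, `se` (per-weight
#'   standard errors), `mu_u`, `sigma_u`, `loglik` (conditional Gaussian),
#'   `n_effective`, `stable`.
#' @export
fit_ar_ml <- function(series, order = 6, skip_initial = 10) {
  if (is.numeric(series)) series <- list(series)
  m <- as.integer(order)
  X <- list()
  y <- list()
  grand <- unlist(lapply(series, function(x) {
    x[-seq_len(min(skip_initial, length(x)))]
  }))
  for (x in series) {
    x <- x[-seq_len(min(skip_initial, length(x)))]
    x <- x[is.finite(x)]
    if (length(x) <= m + 2) next
    x <- x - mean(x)
    n <- length(x)
    yy <- x[(m + 1):n]
    xx <- sapply(seq_len(m), function(j) x[(m + 1 - j):(n - j)])
    X[[length(X) + 1L]] <- matrix(xx, ncol = m)
    y[[length(y) + 1L]] <- yy
  }
  if (!length(X)) stop("no block long enough to fit", call. = FALSE)
  X <- do.call(rbind, X)
  y <- unlist(y)
  fit <- stats::lm.fit(X, y)
  a <- unname(fit$coefficients)
  res <- fit$residuals
  n_eff <- length(y)
  sigma_u <- sqrt(sum(res^2) / n_eff)
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtX_inv)) * sqrt(sum(res^2) / (n_eff - m))
  stable <- tryCatch({ check_ar_stability(a); TRUE },
                     error = function(e) FALSE)
  if (!stable) {
    warning("estimated AR weights are non-stationary", call. = FALSE)
  }
  ll <- -n_eff / 2 * (log(2 * pi) + 1) - n_eff * log(sigma_u)
  structure(list(
    order = m,
    weights = a,
    se = se,
    mu_u = mean(grand, na.rm = TRUE) * (1 - sum(a)),
    sigma_u = sigma_u,
    loglik = ll,
    n_effective = n_eff,
    stable = stable
  ), class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("AR(%d) fit (conditional ML, %d effective obs)\n",
              x$order, x$n_effective))
  print(data.frame(lag = seq_len(x$order), weight = x$weights, se = x$se))
  cat(sprintf("  mu_u = %.4f, sigma_u = %.4f, stable = %s\n",
              x$mu_u, x$sigma_u, x$stable))
  invisible(x)
}

#' Invert the AR model to recover the input sequence
#'
#' `u_n = r_n - sum_j a_j r_(n-j)`. With `prehistory = "zero"` (the
#' convention of the synthetic generator, which starts each block from rest)
#' the inversion is exact for every trial of a generated block; with
#' `prehistory = "drop"` the first `m` values, which depend on unobserved
#' history, are returned as `NA`.
#'
#' @param series Numeric rate vector (one block).
#' @param weights AR weights `a_j`.
#' @param prehistory `"zero"` or `"drop"`.
#' @return Numeric vector of recovered inputs, same length as `series`.
#' @export
decorrelate <- function(series, weights, prehistory = c("zero", "drop")) {
  prehistory <- match.arg(prehistory)
  m <- length(weights)
  n <- length(series)
  u <- series
  if (m == 0 || n == 0) return(u)
  padded <- c(rep(0, m), series)
  for (j in seq_len(m)) {
    u <- u - weights[j] * padded[(m - j + 1):(m - j + n)]
  }
  if (prehistory == "drop" && n >= 1) u[seq_len(min(m, n))] <- NA_real_
  u
}

#' Convert an AR model to its moving-average representation
#'
#' The AR system `r_n = sum_j a_j r_(n-j) + u_n` has transfer function
#' `B(z) = 1 / (1 - a_1 z^-1 - ... - a_m z^-m)`. Its poles are the roots of
#' the characteristic polynomial; a partial-fraction expansion gives
#' residues `rho_k`, and the impulse-response (MA) weights are
#' `b_0 = 1`, `b_i = sum_k rho_k lambda_k^i`. Complex conjugate pole pairs
#' combine so the reported weights are real (the residual imaginary part is
#' asserted below 1e-10). Weights are truncated at the first index where
#' `|b_i|` falls below `tol`, capped at `max_len`. When two poles (nearly)
#' coincide the residue expansion is ill-conditioned and the weights are
#' instead computed by the exact recursion `b_i = sum_j a_j b_(i-j)`, which
#' handles repeated roots implicitly.
#'
#' @param weights Stable AR weights (or an `"ar_model"` object).
#' @param tol Truncation tolerance on `|b_i|` (default 1e-10).
#' @param max_len Hard cap on the number of MA weights (default 1e4).
#' @return List of class `"ma_system"`: `b` (MA weights, `b[1]` is `b_0`),
#'   `poles`, `residues`, `mean_gain`, `sd_gain`, `ar_weights`.
#' @export
ar_to_ma <- function(weights, tol = 1e-10, max_len = 1e4) {
  if (inherits(weights, "ar_model")) weights <- weights$weights
  check_ar_stability(weights)
  m <- length(weights)
  if (m == 0 || all(weights == 0)) {
    return(structure(list(
      b = 1, poles = complex(0), residues = complex(0),
      mean_gain = 1, sd_gain = 1, ar_weights = weights
    ), class = "ma_system"))
  }
  lam <- polyroot(c(-rev(weights), 1))
  distinct <- m == 1 ||
    min(stats::dist(cbind(Re(lam), Im(lam)))) > 1e-8 * max(Mod(lam), 1)
  if (distinct) {
    # residues of B(z) = sum_k rho_k / (1 - lambda_k z^-1)
    rho <- vapply(seq_len(m), function(k) {
      denom <- prod(1 - lam[-k] / lam[k])
      1 / denom
    }, complex(1))
    b_at <- function(i) {
      v <- sum(rho * lam^i)
      if (abs(Im(v)) > 1e-10 * max(abs(Re(v)), 1)) {
        stop("residue reconstruction produced a non-real weight",
             call. = FALSE)
      }
      Re(v)
    }
  } else {
    rho <- complex(0)
    b_rec <- ma_recursion(weights, max_len)
    b_at <- function(i) if (i < length(b_rec)) b_rec[i + 1] else 0
  }
  b <- numeric(0)
  b[1] <- 1
  i <- 1L
  repeat {
    bi <- b_at(i)
    if (abs(bi) < tol || i >= max_len) break
    b[i + 1L] <- bi
    i <- i + 1L
  }
  structure(list(
    b = b,
    poles = lam,
    residues = rho,
    mean_gain = 1 / (1 - sum(weights)),
    sd_gain = sqrt(sum(b^2)),
    ar_weights = weights
  ), class = "ma_system")
}

# brute-force impulse response: b_0 = 1, b_i = sum_{j<=min(i,m)} a_j b_{i-j}
ma_recursion <- function(weights, length_out) {
  m <- length(weights)
  b <- numeric(length_out)
  b[1] <- 1
  for (i in seq_len(length_out - 1)) {
    j <- seq_len(min(i, m))
    b[i + 1] <- sum(weights[j] * b[i + 1 - j])
  }
  b
}

#' @export
print.ma_system <- function(x, ...) {
  cat(sprintf(
    "MA system: %d weights (b0 = 1), mean gain %.4f, SD gain %.4f\n",
    length(x$b), x$mean_gain, x$sd_gain))
  invisible(x)
}

#' Steady-state mean and SD gains of the AR system
#'
#' The stationary output of the AR system scales the input moments: the
#' mean gain is `sum(b_i) = 1 / (1 - sum(a_j))` and the SD gain is
#' `sqrt(sum(b_i^2))`. For the reference weights `{0.222, 0.104, 0.076}`
#' these are 1.67 and 1.05 (2 dp): sequential dependency shifts the rate
#' distribution to the right with only a small change in spread.
#'
#' @param ma An `"ma_system"` (or AR weights, converted internally).
#' @return Named numeric vector `c(mean_gain, sd_gain)`.
#' @export
steady_state_gains <- function(ma) {
  if (!inherits(ma, "ma_system")) ma <- ar_to_ma(ma)
  c(mean_gain = ma$mean_gain, sd_gain = ma$sd_gain)
}

#' Stationary variance of a pure AR process via Yule-Walker
#'
#' Independent route to the SD gain: solves the Yule-Walker equations for
#' the autocorrelations `rho_j` and returns
#' `sd_gain = sqrt(1 / (1 - sum(a_j rho_j)))` (unit innovation SD).
#'
#' @param weights Stable AR weights.
#' @param lag_max Number of autocorrelations to return.
#' @return List with `acf` (autocorrelations at lags 1..`lag_max`) and
#'   `sd_gain`.
#' @export
yule_walker_gain <- function(weights, lag_max = length(weights)) {
  check_ar_stability(weights)
  m <- length(weights)
  if (m == 0) return(list(acf = numeric(0), sd_gain = 1))
  lag_max <- max(lag_max, m)
  # solve rho_k = sum_j a_j rho_{k-j}, k = 1..m, with rho_0 = 1, rho_{-k} = rho_k
  A <- matrix(0, m, m)
  rhs <- numeric(m)
  for (k in seq_len(m)) {
    for (j in seq_len(m)) {
      l <- abs(k - j)
      if (l == 0) rhs[k] <- rhs[k] - weights[j]
      else A[k, l] <- A[k, l] + weights[j]
    }
    A[k, k] <- A[k, k] - 1
  }
  rho <- solve(A, rhs)
  if (lag_max > m) {
    rho <- c(rho, numeric(lag_max - m))
    for (k in (m + 1):lag_max) {
      prev <- rho[k - seq_len(m)]
      rho[k] <- sum(weights * prev)
    }
  }
  list(acf = rho, sd_gain = sqrt(1 / (1 - sum(weights * rho[seq_len(m)]))))
}

#' Step response of the AR system
#'
#' Output of the system to a sustained constant input `mu_u` from rest:
#' `mu_u * cumsum(b_i)`. This is the model's prediction for the
#' start-of-block transient; for the reference weights it climbs
#' monotonically and reaches 99% of the asymptote `mean_gain * mu_u` within
#' 9 trials, matching a transient that dies out in under 10 trials.
#'
#' @param ma An `"ma_system"` (or AR weights).
#' @param n_trials Length of the response.
#' @param mu_u Input level (default 1).
#' @return Numeric vector of length `n_trials`.
#' @export
step_response <- function(ma, n_trials, mu_u = 1) {
  if (!inherits(ma, "ma_system")) ma <- ar_to_ma(ma)
  b <- ma$b
  if (n_trials > length(b)) b <- c(b, numeric(n_trials - length(b)))
  mu_u * cumsum(b)[seq_len(n_trials)]
}

#' Steady-state output density by convolution
#'
#' The stationary output of the MA system is `sum_i b_i u_(n-i)` with iid
#' inputs, so its density is the convolution of scaled copies
#' `(1/|b_i|) p_u(. / b_i)`, one per retained weight. The convolution is
#' evaluated numerically on a uniform grid with trapezoidal quadrature
#' (FFT-accelerated), so a density supported on `[0, Inf)` with a positive
#' value at 0 yields an output density exactly 0 at the origin: truncation
#' is smoothed away by the memory of the system.
#'
#' @param input_density Vectorised density function of the input `u`.
#' @param ma An `"ma_system"` (or AR weights).
#' @param input_support Numeric length-2 vector bracketing the effective
#'   support of `input_density`.
#' @param n_grid Number of grid points per copy (power of two recommended,
#'   default 4096).
#' @param weight_tol Copies with `|b_i|` below this are dropped
#'   (default 1e-4; their contribution to the output is below grid
#'   resolution).
#' @param norm_tol Maximum tolerated deviation of the output mass from 1
#'   (default 1e-3); a larger deviation signals too coarse a grid.
#' @return Data.frame with columns `r` (output grid) and `density`
#'   (normalised).
#' @export
steady_state_density <- function(input_density, ma, input_support,
                                 n_grid = 4096, weight_tol = 1e-4,
                                 norm_tol = 1e-3) {
  if (!inherits(ma, "ma_system")) ma <- ar_to_ma(ma)
  stopifnot(is.function(input_density), length(input_support) == 2,
            input_support[2] > input_support[1])
  b <- ma$b[abs(ma$b) >= weight_tol]
  if (!length(b)) stop("no MA weights above `weight_tol`", call. = FALSE)
  span <- input_support[2] - input_support[1]
  dx <- span / (n_grid - 1)
  u_grid <- input_support[1] + dx * (seq_len(n_grid) - 1)
  u_dens <- input_density(u_grid)
  mu_in <- sum(u_grid * u_dens) * dx / (sum(u_dens) * dx)
  # A copy narrower than a few grid steps cannot be sampled on the shared
  # grid; its variance contribution is below resolution, so treat it as a
  # point mass at b_i * E[u] (an exact shift of the running convolution).
  narrow <- abs(b) * span < 32 * dx
  shift <- sum(b[narrow] * mu_in)
  b <- b[!narrow]
  if (!length(b)) stop("all MA weights below grid resolution", call. = FALSE)
  copy_vals <- lapply(b, function(bi) {
    lo <- min(bi * input_support)
    npt <- ceiling(abs(bi) * span / dx) + 1
    x <- lo + dx * (seq_len(npt) - 1)
    list(lo = lo, y = input_density(x / bi) / abs(bi))
  })
  acc <- copy_vals[[1]]
  acc$lo <- acc$lo + shift
  conv_trap <- function(f, g) {
    nf <- length(f); ng <- length(g)
    nn <- nf + ng - 1
    # linear convolution via FFT, then trapezoid end-point correction
    NFFT <- stats::nextn(nn, 2)
    F <- stats::fft(c(f, numeric(NFFT - nf)))
    G <- stats::fft(c(g, numeric(NFFT - ng)))
    h <- Re(stats::fft(F * G, inverse = TRUE)) / NFFT
    h <- h[seq_len(nn)]
    idx <- seq_len(nn)
    # subtract half the end points of each Riemann sum (trapezoid rule)
    f_at <- function(i) ifelse(i >= 1 & i <= nf, f[pmax(pmin(i, nf), 1)], 0)
    g_at <- function(i) ifelse(i >= 1 & i <= ng, g[pmax(pmin(i, ng), 1)], 0)
    corr <- 0.5 * (f_at(1) * g_at(idx) + f_at(idx) * g_at(1))
    (h - corr) * dx
  }
  for (cv in copy_vals[-1]) {
    acc <- list(lo = acc$lo + cv$lo, y = conv_trap(acc$y, cv$y))
  }
  r <- acc$lo + dx * (seq_along(acc$y) - 1)
  dens <- pmax(acc$y, 0)
  mass <- sum(dens) * dx
  if (abs(mass - 1) > norm_tol) {
    stop(sprintf(
      "output mass %.4f deviates from 1 beyond `norm_tol`; refine the grid",
      mass), call. = FALSE)
  }
  data.frame(r = r, density = dens / mass)
}

#' Binary repeat/alternate code of a laterality history
#'
#' Encodes the last four side-to-side transitions leading up to the current
#' trial: each transition is R (repeat, binary 0) if the stimulus stayed on
#' the same side, A (alternate, binary 1) if it switched, and the four bits
#' form an integer 0..15 with the earliest transition most significant. So
#' RRRR = 0, RRAR = 2, AARA = 13, AAAA = 15.
#'
#' @param sides Character vector of 5 consecutive side labels (e.g.
#'   `c("L","L","R","L","L")`), the last being the current trial. Ignored
#'   when `transitions` is given.
#' @param transitions Character vector of 4 transition labels `"R"`/`"A"`,
#'   earliest first.
#' @return Integer in 0..15.
#' @examples
#' spatial_code(transitions = c("R", "R", "A", "R"))  # 2
#' spatial_code(c("L", "L", "L", "L", "L"))           # RRRR = 0
#' @export
spatial_code <- function(sides = NULL, transitions = NULL) {
  if (is.null(transitions)) {
    if (is.null(sides) || length(sides) != 5) {
      stop("need 5 consecutive side labels (or 4 transitions)",
           call. = FALSE)
    }
    transitions <- ifelse(sides[-1] == sides[-5], "R", "A")
  }
  if (length(transitions) != 4 || !all(transitions %in% c("R", "A"))) {
    stop("`transitions` must be 4 labels 'R'/'A'", call. = FALSE)
  }
  bits <- as.integer(transitions == "A")
  sum(bits * c(8L, 4L, 2L, 1L))
}

#' Repeat/alternate history analysis of a trial table
#'
#' Codes every trial (from the 5th of each block) by the binary
#' repeat/alternate weighting of its previous four side transitions and
#' summarises mean reaction time and mean rate per code with
#' within-subject standard errors (per-subject centring before pooling).
#' A one-way repeated-measures F test over the 16 codes (subject x code
#' cell means; code against the code-by-subject interaction) tests whether
#' the laterality history modulates speed.
#'
#' @param table Canonical trial table.
#' @param conditions Conditions to include (default the easy pair).
#' @param domain `"rate"` or `"time"`; the domain on which the F test runs.
#' @param dither_seed Seed for the dither applied before rates are formed.
#' @return List of class `"spatial_summary"`: `per_code` (data.frame with
#'   code, n, mean_rt_ms, mean_rate, se_rt_ms, se_rate), `f_statistic`,
#'   `df1`, `df2`, `p_value`, `n_trials_used`.
#' @export
spatial_summary <- function(table, conditions = c("AE", "UE"),
                            domain = c("rate", "time"), dither_seed = 1L) {
  domain <- match.arg(domain)
  tab <- table[table$condition %in% conditions, ]
  if (!nrow(tab)) stop("no trials in the requested conditions", call. = FALSE)
  blocks <- unique(tab$block)
  seeds <- derive_seeds(dither_seed, length(blocks))
  rows <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    br <- tab[tab$block == blocks[i], ]
    br <- br[order(br$trial_index), ]
    codes <- side_history_codes(br$side)
    rt_d <- dither_rts(br$rt_ms, seed = seeds[i])
    rt_d[br$timed_out] <- br$rt_ms[br$timed_out]
    use <- !is.na(codes)
    rows[[i]] <- data.frame(
      subject = br$subject[use],
      code = codes[use],
      rt_ms = rt_d[use],
      rate = 1000 / rt_d[use]
    )
  }
  d <- do.call(rbind, rows)
  value <- if (domain == "rate") d$rate else d$rt_ms
  # within-subject centring for the standard errors
  subj_mean <- stats::ave(d$rate, d$subject)
  rate_w <- d$rate - subj_mean + mean(d$rate)
  subj_mean_rt <- stats::ave(d$rt_ms, d$subject)
  rt_w <- d$rt_ms - subj_mean_rt + mean(d$rt_ms)
  agg <- function(v) {
    mean_ <- tapply(v, d$code, mean)
    se_ <- tapply(v, d$code, function(x) stats::sd(x) / sqrt(length(x)))
    list(mean = mean_, se = se_)
  }
  a_rt <- agg(rt_w)
  a_rate <- agg(rate_w)
  codes_present <- sort(unique(d$code))
  per_code <- data.frame(
    code = codes_present,
    n = as.integer(table(factor(d$code, levels = codes_present))),
    mean_rt_ms = as.numeric(tapply(d$rt_ms, d$code, mean)),
    mean_rate = as.numeric(tapply(d$rate, d$code, mean)),
    se_rt_ms = as.numeric(a_rt$se),
    se_rate = as.numeric(a_rate$se)
  )
  # repeated-measures one-way F on subject x code cell means
  cell <- stats::aggregate(value, list(subject = d$subject, code = d$code),
                           mean)
  names(cell)[3] <- "y"
  complete <- table(cell$subject)
  keep_subj <- names(complete)[complete == length(codes_present)]
  cell <- cell[cell$subject %in% keep_subj, ]
  if (length(keep_subj) >= 2) {
    cell$subject <- factor(cell$subject)
    cell$code <- factor(cell$code)
    fit <- stats::aov(y ~ code + subject, data = cell)
    an <- stats::anova(fit)
    # code tested against the code:subject interaction = residual of this fit
    f_stat <- an["code", "Mean Sq"] / an["Residuals", "Mean Sq"]
    df1 <- an["code", "Df"]
    df2 <- an["Residuals", "Df"]
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  } else {
    f_stat <- df1 <- df2 <- p <- NA_real_
  }
  structure(list(
    per_code = per_code,
    f_statistic = f_stat, df1 = df1, df2 = df2, p_value = p,
    n_trials_used = nrow(d),
    domain = domain
  ), class = "spatial_summary")
}

#' @export
print.spatial_summary <- function(x, ...) {
  cat(sprintf(
    "Repeat/alternate history summary (%s domain, %d trials): F(%d, %d) = %.2f, p = %.3g\n",
    x$domain, x$n_trials_used, x$df1, x$df2, x$f_statistic, x$p_value))
  invisible(x)
}
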