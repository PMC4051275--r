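#' Left-truncated Normal density
#'
#' Density of a Normal(`mu`, `sigma^2`) variate restricted to `[a, Inf)` and
#' renormalised by the survival mass `1 - Phi((a - mu)/sigma)`. This is the
#' working model for the distribution of response *rate* (reciprocal reaction
#' time, in s^-1): the underlying Normal describes trial-to-trial rate
#' variability, and the left bound `a` is the smallest observable rate,
#' conventionally the reciprocal of the trial time-out (1/60 s^-1 for a 60 s
#' time-out).
#'
#' @param x Numeric vector of rates (s^-1) at which to evaluate the density.
#' @param mu Mean of the underlying (un-truncated) Normal (s^-1).
#' @param sigma Standard deviation of the underlying Normal (s^-1), `> 0`.
#' @param a Left truncation bound (s^-1); default `1/60`. May be `-Inf` for
#'   the untruncated limit.
#' @return Numeric vector of density values; `0` for `x < a`.
#' @examples
#' dtrunc_normal(0, mu = 0, sigma = 1, a = 0)  # half-Normal at the bound
#' @export
dtrunc_normal <- function(x, mu, sigma, a = 1/60) {
  check_trunc_params(mu, sigma, a)
  out <- numeric(length(x))
  ok <- x >= a
  # log-space survival normaliser; stable even for deep truncation
  log_surv <- stats::pnorm((a - mu) / sigma, lower.tail = FALSE, log.p = TRUE)
  out[ok] <- exp(stats::dnorm(x[ok], mu, sigma, log = TRUE) - log_surv)
  out
}

check_trunc_params <- function(mu, sigma, a) {
  stop_if_not_scalar_pos(sigma, "sigma")
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu)) {
    stop("`mu` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(a) || length(a) != 1L || is.nan(a) || a == Inf) {
    stop("`a` must be finite or -Inf", call. = FALSE)
  }
  if (is.finite(a) &&
      stats::pnorm((a - mu) / sigma, lower.tail = FALSE) <= 0) {
    stop("truncation removes essentially all probability mass", call. = FALSE)
  }
  invisible(NULL)
}

#' Sample from the left-truncated Normal
#'
#' Inverse-CDF sampling restricted to `[a, Inf)`: draw `u` uniform on
#' `[Phi((a-mu)/sigma), 1)` and map through the Normal quantile function.
#'
#' @inheritParams dtrunc_normal
#' @param n Number of draws.
#' @param seed Optional integer seed; when given, draws are reproducible and
#'   the caller's RNG state is untouched.
#' @return Numeric vector of `n` rates `>= a`.
#' @export
rtrunc_normal <- function(n, mu, sigma, a = 1/60, seed = NULL) {
  check_trunc_params(mu, sigma, a)
  stop_if_not_scalar_pos(n, "n")
  p_lo <- stats::pnorm(a, mu, sigma)
  with_seed(seed, {
    u <- p_lo + stats::runif(n) * (1 - p_lo)
    stats::qnorm(pmin(u, 1 - 1e-16), mu, sigma)
  })
}

#' Reciprocal transform of a density
#'
#' Given a density `f` on a positive variable, returns the density of the
#' reciprocal variable evaluated at `x`: `f(1/x) / x^2` (change of variables).
#' Applying the transform twice recovers the original density. This is the
#' bridge between the time domain (reaction time) and the rate domain
#' (reciprocal reaction time).
#'
#' @param f A vectorised density function of one argument.
#' @param x Positive numeric vector at which to evaluate the reciprocal
#'   density.
#' @return Numeric vector of density values.
#' @examples
#' # density of rate when reaction time is inverse Gaussian:
#' reciprocal_density(function(t) dinvgauss(t, mean = 0.5, sigma2 = 0.04), 2)
#' @export
reciprocal_density <- function(f, x) {
  stopifnot(is.function(f))
  if (any(x <= 0)) stop("`x` must be positive", call. = FALSE)
  f(1 / x) / x^2
}

#' Reciprocal truncated Normal density (closed form)
#'
#' Density of reaction time `t` when rate `1/t` follows a left-truncated
#' Normal. Equal to `dtrunc_normal(1/t, ...) / t^2`, written out in closed
#' form; the general bound `a` specialises to the zero-truncation case.
#'
#' @param t Positive numeric vector of reaction times (s).
#' @inheritParams dtrunc_normal
#' @export
drec_trunc_normal <- function(t, mu, sigma, a = 1/60) {
  check_trunc_params(mu, sigma, a)
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  log_surv <- stats::pnorm((a - mu) / sigma, lower.tail = FALSE, log.p = TRUE)
  r <- 1 / t
  out <- numeric(length(t))
  ok <- r >= a
  out[ok] <- exp(-((r[ok] - mu)^2) / (2 * sigma^2) -
                   log(sigma) - 0.5 * log(2 * pi) - log_surv) / t[ok]^2
  out
}

#' Inverse Gaussian density
#'
#' First-passage-time density of drifting Brownian motion through a single
#' constant boundary, in the mean/variance parameterisation: the distribution
#' has mean `mean` and variance `sigma2` (so the conventional shape parameter
#' is `mean^3 / sigma2`).
#'
#' @param chi Positive numeric vector of times (s).
#' @param mean Distribution mean (s), `> 0`.
#' @param sigma2 Distribution variance (s^2), `> 0`.
#' @export
dinvgauss <- function(chi, mean, sigma2) {
  stop_if_not_scalar_pos(mean, "mean")
  stop_if_not_scalar_pos(sigma2, "sigma2")
  if (any(chi <= 0)) stop("`chi` must be positive", call. = FALSE)
  sqrt(mean^3 / (2 * pi * sigma2 * chi^3)) *
    exp(-mean * (chi - mean)^2 / (2 * sigma2 * chi))
}

#' Reciprocal inverse Gaussian density (closed form)
#'
#' Density of rate `x = 1/chi` when `chi` is inverse Gaussian with mean
#' `mean` and variance `sigma2`.
#'
#' @param x Positive numeric vector of rates (s^-1).
#' @inheritParams dinvgauss
#' @export
drec_invgauss <- function(x, mean, sigma2) {
  stop_if_not_scalar_pos(mean, "mean")
  stop_if_not_scalar_pos(sigma2, "sigma2")
  if (any(x <= 0)) stop("`x` must be positive", call. = FALSE)
  sqrt(mean^3 / (2 * pi * sigma2 * x)) *
    exp(-mean * (1 / x - mean)^2 * x / (2 * sigma2))
}

#' Sample from the inverse Gaussian
#'
#' Michael-Schucany-Haas transformation sampler, parameterised by mean and
#' variance (shape `lambda = mean^3 / sigma2`).
#'
#' @inheritParams dinvgauss
#' @inheritParams rtrunc_normal
#' @export
rinvgauss <- function(n, mean, sigma2, seed = NULL) {
  stop_if_not_scalar_pos(mean, "mean")
  stop_if_not_scalar_pos(sigma2, "sigma2")
  stop_if_not_scalar_pos(n, "n")
  lambda <- mean^3 / sigma2
  with_seed(seed, {
    y <- stats::rnorm(n)^2
    x <- mean + mean^2 * y / (2 * lambda) -
      mean / (2 * lambda) * sqrt(4 * mean * lambda * y + mean^2 * y^2)
    u <- stats::runif(n)
    ifelse(u <= mean / (mean + x), x, mean^2 / x)
  })
}

#' Two-boundary first-passage-time density (drift diffusion)
#'
#' Density of the time at which a Wiener process with drift `xi` and
#' diffusion constant `s`, started at `z` between absorbing boundaries
#' `b_lo < z < a_up`, is first absorbed at the chosen boundary. Evaluated by
#' the classical sine series; the density for the other boundary follows by
#' reflecting drift and start point. The series is summed in increasing `k`
#' until two successive terms fall below `tol` times the partial sum.
#'
#' @param t Positive numeric vector of times (s).
#' @param xi Drift rate.
#' @param a_up,b_lo Upper and lower absorbing boundaries.
#' @param z Start point, strictly between the boundaries.
#' @param s Diffusion constant, `> 0` (default 1).
#' @param boundary Which boundary's absorption density to return.
#' @param tol Relative truncation tolerance for the series.
#' @param max_terms Hard cap on series terms (`>= 10`); exceeding it is a
#'   convergence error.
#' @return Numeric vector of (defective) density values; the density for one
#'   boundary integrates to that boundary's absorption probability.
#' @export
ddm_fpt_density <- function(t, xi, a_up, b_lo, z, s = 1,
                            boundary = c("upper", "lower"),
                            tol = 1e-10, max_terms = 1e4) {
  boundary <- match.arg(boundary)
  if (!(b_lo < z && z < a_up)) stop("need b_lo < z < a_up", call. = FALSE)
  stop_if_not_scalar_pos(s, "s")
  stop_if_not_scalar_pos(tol, "tol")
  if (max_terms < 10) stop("`max_terms` must be >= 10", call. = FALSE)
  if (any(t <= 0)) stop("`t` must be positive", call. = FALSE)
  w <- a_up - b_lo
  if (boundary == "lower") {
    x0 <- z - b_lo
    drift <- xi
  } else {
    x0 <- a_up - z
    drift <- -xi
  }
  vapply(t, function(tt) {
    if (tt < 1e-6) return(0)   # series converges too slowly; density ~ 0
    pref <- (pi * s^2 / w^2) *
      exp(-drift * x0 / s^2 - xi^2 * tt / (2 * s^2))
    acc <- 0
    small <- 0L
    for (k in seq_len(max_terms)) {
      term <- k * exp(-k^2 * pi^2 * s^2 * tt / (2 * w^2)) * sin(k * pi * x0 / w)
      acc <- acc + term
      # sine factor oscillates, so require two consecutive small terms
      small <- if (abs(term) < tol * max(abs(acc), 1e-300)) small + 1L else 0L
      if (small >= 2L) return(max(pref * acc, 0))
    }
    stop("first-passage series did not converge within `max_terms`",
         call. = FALSE)
  }, numeric(1))
}

#' Absorption probability at one boundary
#'
#' Integrates [ddm_fpt_density()] over `(0, Inf)`; for a symmetric start the
#' two boundaries each receive mass 1/2.
#'
#' @inheritParams ddm_fpt_density
#' @export
ddm_absorption_prob <- function(xi, a_up, b_lo, z, s = 1,
                                boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  stats::integrate(function(tt) {
    ddm_fpt_density(tt, xi, a_up, b_lo, z, s, boundary)
  }, 0, Inf, rel.tol = 1e-8)$value
}

#' Seeded sampling from the rate/time model families
#'
#' Reproducible draws from the four families used throughout the package:
#' `"trN"` (left-truncated Normal rate), `"rectrN"` (its reciprocal, i.e. a
#' reaction time), `"IG"` (inverse Gaussian time) and `"recIG"` (its
#' reciprocal, a rate). Reciprocal families are generated by transforming
#' draws from the parent family, so `rectrN` draws are element-wise
#' reciprocals of `trN` draws under the same seed.
#'
#' @param family One of `"trN"`, `"rectrN"`, `"IG"`, `"recIG"`.
#' @param n Number of draws.
#' @param params Named list of parameters: `mu`, `sigma`, `a` for the
#'   truncated-Normal families; `mean`, `sigma2` for the inverse-Gaussian
#'   families.
#' @param seed Optional integer seed.
#' @export
sample_rates <- function(family = c("trN", "rectrN", "IG", "recIG"),
                         n, params, seed = NULL) {
  family <- match.arg(family)
  switch(family,
    trN = rtrunc_normal(n, params$mu, params$sigma,
                        if (is.null(params$a)) 1/60 else params$a, seed),
    rectrN = 1 / rtrunc_normal(n, params$mu, params$sigma,
                               if (is.null(params$a)) 1/60 else params$a, seed),
    IG = rinvgauss(n, params$mean, params$sigma2, seed),
    recIG = 1 / rinvgauss(n, params$mean, params$sigma2, seed)
  )
}
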