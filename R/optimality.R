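#' Expected-rate-of-reward decision model
#'
#' Bundles the ingredients of the optimal-timing account of reaction times:
#' a correct response at time `t` earns utility `u_plus`, an error costs
#' `u_minus`, and the probability of being correct given a response at `t`
#' is a concave, non-decreasing accuracy function `p(t)` starting at chance
#' `1/n_alternatives`. Time is accelerated by a scale `epsilon` (the
#' subjective stimulus-strength estimate): the accuracy function is
#' evaluated at `epsilon * t`. A non-decision time `t_nd` (foreperiod,
#' sensorimotor delays) counts toward the trial duration but not toward the
#' decision.
#'
#' The default accuracy function is the saturating exponential
#' `p(t) = 1/n + (1 - 1/n) (1 - exp(-epsilon t))`, which for two
#' alternatives is `1/2 + (1 - exp(-epsilon t))/2`.
#'
#' @param u_plus Utility gain for a correct response, `> 0`.
#' @param u_minus Utility loss for an error, `> 0`.
#' @param epsilon Time-acceleration scale `> 0`.
#' @param t_nd Non-decision time, `>= 0`, in the same units as `t`.
#' @param n_alternatives Number of response alternatives (default 2).
#' @param p_fun Optional accuracy function of the *scaled* time
#'   `epsilon * t`; must be non-decreasing and concave with
#'   `p_fun(0) = 1/n_alternatives`. `NULL` selects the exponential form,
#'   for which derivatives are analytic.
#' @return List of class `"utility_model"`.
#' @export
utility_model <- function(u_plus = 1, u_minus = 5, epsilon = 1, t_nd = 0,
                          n_alternatives = 2, p_fun = NULL) {
  stop_if_not_scalar_pos(u_plus, "u_plus")
  stop_if_not_scalar_pos(u_minus, "u_minus")
  stop_if_not_scalar_pos(epsilon, "epsilon")
  if (t_nd < 0) stop("`t_nd` must be >= 0", call. = FALSE)
  stop_if_not_scalar_pos(n_alternatives, "n_alternatives")
  structure(list(
    u_plus = u_plus, u_minus = u_minus, epsilon = epsilon, t_nd = t_nd,
    n_alternatives = n_alternatives, p_fun = p_fun
  ), class = "utility_model")
}

model_p <- function(model, t) {
  tau <- model$epsilon * t
  if (is.null(model$p_fun)) {
    n <- model$n_alternatives
    1 / n + (1 - 1 / n) * (1 - exp(-tau))
  } else {
    model$p_fun(tau)
  }
}

model_p_prime <- function(model, t) {
  if (is.null(model$p_fun)) {
    n <- model$n_alternatives
    model$epsilon * (1 - 1 / n) * exp(-model$epsilon * t)
  } else {
    h <- 1e-6 * pmax(abs(t), 1)
    (model_p(model, t + h) - model_p(model, t - h)) / (2 * h)
  }
}

#' Expected gain in utility for a response at time t
#'
#' `G(t) = u_plus * p(t) - u_minus * (1 - p(t))
#'       = (u_plus + u_minus) * p(t) - u_minus`.
#'
#' @param t Non-negative numeric vector of decision times.
#' @param model A [utility_model()].
#' @export
expected_gain <- function(t, model) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  (model$u_plus + model$u_minus) * model_p(model, t) - model$u_minus
}

expected_gain_prime <- function(t, model) {
  (model$u_plus + model$u_minus) * model_p_prime(model, t)
}

#' Break-even response time
#'
#' The time `t_min` at which expected gain crosses zero:
#' `p(t_min) = 1 / (u_plus/u_minus + 1)`. Responding earlier incurs an
#' expected loss. Returns 0 when gain is already non-negative at `t = 0`;
#' errors when the accuracy function never reaches break-even (no
#' profitable response exists).
#'
#' @param model A [utility_model()].
#' @param t_upper Initial upper bracket, grown geometrically as needed.
#' @export
min_profitable_time <- function(model, t_upper = 1) {
  g0 <- expected_gain(0, model)
  if (g0 >= 0) return(0)
  hi <- t_upper
  for (i in 1:60) {
    if (expected_gain(hi, model) > 0) {
      return(stats::uniroot(function(t) expected_gain(t, model),
                            c(0, hi), tol = 1e-12)$root)
    }
    hi <- hi * 2
  }
  stop("expected gain never becomes positive: no profitable response time",
       call. = FALSE)
}

#' Optimal response time maximising expected rate of reward
#'
#' Maximises `R(t) = G(t) / (t + t_nd)`, the expected gain per unit trial
#' time. The first-order condition is
#' `(t* + t_nd) G'(t*) = G(t*)`, i.e. geometrically the tangent to `G` at
#' `t*` passes through `-t_nd` on the time axis. The root is bracketed on
#' `(t_min, Inf)` and solved by bisection/secant (`uniroot`), then verified
#' as a maximum by comparing `R` at `t* (1 +/- 0.01)`.
#'
#' @param model A [utility_model()].
#' @return List of class `"optimal_solution"`: `t_star`, `t_min`,
#'   `rate_star` (`1 / t_star`), `gain_at_opt`, `rate_of_gain`
#'   (`G(t*) / (t* + t_nd)`), `converged`.
#' @export
solve_optimal_time <- function(model) {
  t_min <- min_profitable_time(model)
  h <- function(t) {
    (t + model$t_nd) * expected_gain_prime(t, model) - expected_gain(t, model)
  }
  lo <- max(t_min, 1e-12) * (1 + 1e-9) + 1e-12
  if (h(lo) <= 0) {
    # rate of gain is maximised at the left edge; no interior optimum
    return(structure(list(
      t_star = NA_real_, t_min = t_min, rate_star = NA_real_,
      gain_at_opt = NA_real_, rate_of_gain = NA_real_, converged = FALSE
    ), class = "optimal_solution"))
  }
  hi <- max(2 * lo, 1)
  found <- FALSE
  for (i in 1:60) {
    if (h(hi) < 0) { found <- TRUE; break }
    hi <- hi * 2
  }
  if (!found) {
    return(structure(list(
      t_star = NA_real_, t_min = t_min, rate_star = NA_real_,
      gain_at_opt = NA_real_, rate_of_gain = NA_real_, converged = FALSE
    ), class = "optimal_solution"))
  }
  t_star <- stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
  rate_of_gain <- function(t) expected_gain(t, model) / (t + model$t_nd)
  ok <- rate_of_gain(t_star) >= rate_of_gain(t_star * 1.01) &&
    rate_of_gain(t_star) >= rate_of_gain(t_star * 0.99)
  structure(list(
    t_star = t_star,
    t_min = t_min,
    rate_star = 1 / t_star,
    gain_at_opt = expected_gain(t_star, model),
    rate_of_gain = rate_of_gain(t_star),
    converged = ok
  ), class = "optimal_solution")
}

#' @export
print.optimal_solution <- function(x, ...) {
  cat(sprintf(
    "Optimal response time: t* = %.4f (t_min = %.4f, rate* = %.4f, G(t*) = %.4f)\n",
    x$t_star, x$t_min, x$rate_star, x$gain_at_opt))
  invisible(x)
}

#' Power-law fit of optimal time against the accuracy scale
#'
#' Solves for `t*` across a grid of accuracy scales `epsilon` at fixed
#' payoffs and non-decision time, then regresses `log10 t*` on
#' `log10 epsilon`. With `t_nd = 0` the relation `t* = t_1 / epsilon` is an
#' exact power law with exponent 1; positive non-decision time bends it,
#' leaving a near power law `t* ~ a * epsilon^(-k)` with `0 < k < 1`.
#' Together with a sensorimotor delay `gamma`,
#' `RT = a * epsilon^(-k) + gamma` has the form of Pieron's law.
#'
#' @param u_plus,u_minus,t_nd,n_alternatives,p_fun Passed to
#'   [utility_model()] at each grid point.
#' @param epsilon_grid Scales at which to solve; default 50 log-spaced
#'   points on `[0.01, 1]`.
#' @param gamma Added sensorimotor delay, reported alongside the fit.
#' @return List of class `"power_law_fit"`: `k` (`-slope`), `a_coef`
#'   (`10^intercept`), `gamma`, `r_squared`, `epsilon_grid`, `t_star`
#'   (solved times; grid points with no optimum are dropped with a
#'   warning).
#' @export
power_law_fit <- function(u_plus = 1, u_minus = 5, t_nd = 0,
                          epsilon_grid = 10^seq(log10(0.01), log10(1),
                                                length.out = 50),
                          n_alternatives = 2, p_fun = NULL, gamma = 0) {
  t_star <- vapply(epsilon_grid, function(eps) {
    sol <- solve_optimal_time(utility_model(u_plus, u_minus, eps, t_nd,
                                            n_alternatives, p_fun))
    if (isTRUE(sol$converged)) sol$t_star else NA_real_
  }, numeric(1))
  ok <- is.finite(t_star)
  if (!all(ok)) {
    warning(sprintf("%d grid point(s) had no optimum and were excluded",
                    sum(!ok)), call. = FALSE)
  }
  if (sum(ok) < 3) stop("too few grid points with an optimum", call. = FALSE)
  lx <- log10(epsilon_grid[ok])
  ly <- log10(t_star[ok])
  slope <- stats::cov(lx, ly) / stats::var(lx)
  intercept <- mean(ly) - slope * mean(lx)
  ss_res <- sum((ly - intercept - slope * lx)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(list(
    k = -slope,
    a_coef = 10^intercept,
    gamma = gamma,
    r_squared = 1 - ss_res / ss_tot,
    epsilon_grid = epsilon_grid[ok],
    t_star = t_star[ok]
  ), class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit t* ~ a * epsilon^-k: k = %.3f, a = %.3f (R^2 = %.5f, %d points)\n",
    x$k, x$a_coef, x$r_squared, length(x$epsilon_grid)))
  invisible(x)
}

#' Predicted distribution of optimal rates
#'
#' Draws the accuracy scale `epsilon` from a Normal distribution truncated
#' to positive values, solves the optimal time per draw, and returns the
#' optimal rates `r* = 1 / (t* + gamma)`. With `t_nd = 0`,
#' `t* = t_1 / epsilon` exactly, so `r*` inherits the (truncated) Normal
#' shape of `epsilon` scaled by `1 / t_1`; with non-decision time the map is
#' locally quasi-linear and `r*` stays close to Normal for modest `epsilon`
#' spread.
#'
#' @param u_plus,u_minus,t_nd,n_alternatives,p_fun Model ingredients, as in
#'   [utility_model()].
#' @param epsilon_mean,epsilon_sd Mean and SD of the Normal `epsilon`
#'   distribution (draws are rejected until positive).
#' @param n_draws Number of draws.
#' @param gamma Added sensorimotor delay before the reciprocal.
#' @param seed Integer seed.
#' @return List of class `"rate_prediction"`: `epsilon`, `t_star`, `r_star`,
#'   and `moments` (mean, sd, skewness of `r_star`).
#' @export
predict_rate_distribution <- function(u_plus = 1, u_minus = 5, t_nd = 0,
                                      epsilon_mean = 1, epsilon_sd = 0.15,
                                      n_draws = 1000, gamma = 0,
                                      n_alternatives = 2, p_fun = NULL,
                                      seed = 1L) {
  eps <- with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n_draws) {
      draw <- stats::rnorm(n_draws, epsilon_mean, epsilon_sd)
      out <- c(out, draw[draw > 0])
    }
    out[seq_len(n_draws)]
  })
  base_sol <- solve_optimal_time(utility_model(u_plus, u_minus, 1, 0,
                                               n_alternatives, p_fun))
  t_star <- if (t_nd == 0) {
    # exact scaling: the optimality condition depends on t only through eps*t
    base_sol$t_star / eps
  } else {
    vapply(eps, function(e) {
      sol <- solve_optimal_time(utility_model(u_plus, u_minus, e, t_nd,
                                              n_alternatives, p_fun))
      sol$t_star
    }, numeric(1))
  }
  r_star <- 1 / (t_star + gamma)
  ctr <- r_star - mean(r_star)
  m2 <- mean(ctr^2)
  structure(list(
    epsilon = eps, t_star = t_star, r_star = r_star,
    moments = c(mean = mean(r_star), sd = stats::sd(r_star),
                skewness = mean(ctr^3) / m2^1.5)
  ), class = "rate_prediction")
}
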