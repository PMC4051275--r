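#' Default per-condition generator parameters
#'
#' The four block types cross task instruction (Accurate/Urgent) with
#' stimulus difficulty (Easy/Difficult). `mu_u` and `sigma_u` are the mean
#' and SD of the Normal *input* to the autoregressive rate process (s^-1);
#' the stationary observed rate has mean `mean_gain * mu_u` and SD
#' `sd_gain * sigma_u` (about 1.67 and 1.05 for the default AR weights).
#' Defaults are chosen so easy blocks sit around 3 s^-1 (reaction times near
#' 300 ms, CV well under the 0.4 truncation threshold) and difficult blocks
#' drift toward zero rate (reaction times of the order of a second or more,
#' CV near or above 0.4, occasional 60 s time-outs), with error rates of 1%
#' (easy) and 24% (difficult).
#'
#' @return A data.frame with one row per condition (`AE`, `AD`, `UE`, `UD`)
#'   and columns `condition`, `mu_u`, `sigma_u`, `error_rate`, `easy`.
#' @export
default_condition_params <- function() {
  data.frame(
    condition = c("AE", "AD", "UE", "UD"),
    mu_u = c(1.85, 0.40, 2.00, 0.50),
    sigma_u = c(0.30, 0.30, 0.30, 0.30),
    error_rate = c(0.01, 0.24, 0.01, 0.24),
    easy = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default laterality-history rate offsets
#'
#' Additive offsets (s^-1) on observed rate, keyed by the 4-lag binary
#' repeat/alternate code of the stimulus-side sequence (0 = RRRR .. 15 =
#' AAAA). The defaults mimic the empirical pattern in easy blocks: pure
#' repetition (RRRR) and pure alternation (AAAA) are fastest, while
#' sequences that break a long run on the current trial (RRRA = 1,
#' AAAR = 14, ARRA = 6) are slowest.
#'
#' @return Numeric vector of length 16, named "0".."15".
#' @export
default_spatial_deltas <- function() {
  d <- stats::setNames(numeric(16), as.character(0:15))
  d[c("0", "15")] <- 0.08
  d[c("1", "14", "6")] <- -0.08
  d
}

#' Synthetic-experiment configuration
#'
#' Bundles every knob of the trial-table generator. Defaults reproduce the
#' study design the analysis assumes: 24 subjects x 4 blocks x 200 trials,
#' conditions AE/AD/UE/UD (each subject receives one block per condition, in
#' one of the 24 possible orders), rates following a stationary Gaussian
#' AR(3) process with weights `{0.222, 0.104, 0.076}`, left-censoring of
#' rate at the 60 s time-out bound, millisecond quantisation of recorded
#' reaction times, and a laterality-history effect confined to the easy
#' conditions.
#'
#' @param n_subjects,n_blocks_per_subject,n_trials Design counts.
#' @param condition_params Data.frame as returned by
#'   [default_condition_params()].
#' @param ar_weights Autoregressive weights; must define a stable system
#'   (all characteristic roots strictly inside the unit circle).
#' @param truncation_bound Smallest observable rate (s^-1), the reciprocal
#'   of the time-out.
#' @param anticipation_bound Reaction times below this (s) are anticipatory.
#' @param spatial_deltas Length-16 named numeric vector of rate offsets, or
#'   `NULL` for none.
#' @param quantize_ms Round recorded reaction times to integer milliseconds.
#' @param seed Integer seed; the full table is a deterministic function of
#'   the configuration.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_subjects = 24,
                         n_blocks_per_subject = 4,
                         n_trials = 200,
                         condition_params = default_condition_params(),
                         ar_weights = c(0.222, 0.104, 0.076),
                         truncation_bound = 1/60,
                         anticipation_bound = 0.15,
                         spatial_deltas = default_spatial_deltas(),
                         quantize_ms = TRUE,
                         seed = 1L) {
  stop_if_not_scalar_pos(n_subjects, "n_subjects")
  stop_if_not_scalar_pos(n_blocks_per_subject, "n_blocks_per_subject")
  stop_if_not_scalar_pos(n_trials, "n_trials")
  stopifnot(is.data.frame(condition_params),
            all(c("condition", "mu_u", "sigma_u", "error_rate", "easy") %in%
                  names(condition_params)))
  if (any(condition_params$sigma_u <= 0)) {
    stop("`sigma_u` must be positive for every condition", call. = FALSE)
  }
  check_ar_stability(ar_weights)
  if (!is.null(spatial_deltas)) {
    stopifnot(length(spatial_deltas) == 16)
    if (is.null(names(spatial_deltas))) {
      names(spatial_deltas) <- as.character(0:15)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_blocks_per_subject = as.integer(n_blocks_per_subject),
    n_trials = as.integer(n_trials),
    condition_params = condition_params,
    ar_weights = ar_weights,
    truncation_bound = truncation_bound,
    anticipation_bound = anticipation_bound,
    spatial_deltas = spatial_deltas,
    quantize_ms = isTRUE(quantize_ms),
    seed = as.integer(seed)
  ), class = "synth_config")
}

check_ar_stability <- function(weights) {
  if (length(weights) == 0) return(invisible(TRUE))
  if (!is.numeric(weights) || any(!is.finite(weights))) {
    stop("AR weights must be finite numbers", call. = FALSE)
  }
  if (any(weights != 0)) {
    # roots of z^m - a1 z^(m-1) - ... - am
    lam <- polyroot(c(-rev(weights), 1))
    if (any(Mod(lam) >= 1)) {
      stop("AR weights define an unstable system (root on/outside unit circle)",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Generate one block of rates from the AR process
#'
#' Simulates `r_n = sum_j a_j r_(n-j) + u_n` with `u_n` iid
#' Normal(`mu_u`, `sigma_u^2`) and zero pre-history, so the first handful of
#' trials show the start-of-block transient (the step response of the AR
#' system) before settling into the stationary regime. Latent rates that
#' fall below the truncation bound are censored to the bound and flagged as
#' timed out, mirroring what a 60 s time-out records.
#'
#' @param mu_u,sigma_u Mean and SD of the Normal input (s^-1). `sigma_u = 0`
#'   gives the deterministic step response.
#' @param ar_weights Stable AR weights.
#' @param n_trials Number of trials.
#' @param truncation_bound Censoring bound on observed rate (s^-1).
#' @param seed Optional integer seed.
#' @return Data.frame with columns `rate` (censored, observed), `rate_latent`
#'   (uncensored AR output), `u` (the Normal input actually drawn) and
#'   `timed_out`.
#' @export
generate_block_rates <- function(mu_u, sigma_u, ar_weights = c(0.222, 0.104, 0.076),
                                 n_trials = 200, truncation_bound = 1/60,
                                 seed = NULL) {
  check_ar_stability(ar_weights)
  if (sigma_u < 0) stop("`sigma_u` must be >= 0", call. = FALSE)
  m <- length(ar_weights)
  u <- if (sigma_u == 0) {
    rep(mu_u, n_trials)
  } else {
    with_seed(seed, stats::rnorm(n_trials, mu_u, sigma_u))
  }
  r <- numeric(n_trials)
  hist <- numeric(m)  # zero pre-history, most recent first
  for (n in seq_len(n_trials)) {
    r[n] <- if (m > 0) sum(ar_weights * hist) + u[n] else u[n]
    if (m > 0) hist <- c(r[n], hist[-m])
  }
  timed_out <- r < truncation_bound
  data.frame(
    rate = ifelse(timed_out, truncation_bound, r),
    rate_latent = r,
    u = u,
    timed_out = timed_out
  )
}

# All 24 orderings of 4 conditions; subject i receives permutation
# ((i - 1) mod 24) + 1, the counterbalancing of the emulated design.
condition_orders <- function(conds) {
  perm <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  perm(conds)
}

#' Generate a full synthetic choice reaction-time experiment
#'
#' Produces the canonical trial table: one row per trial with subject,
#' block, condition, trial index, stimulus side, recorded reaction time in
#' (integer) milliseconds, correctness, and time-out flag. Stimulus side is
#' Bernoulli(1/2); in easy conditions the observed rate additionally
#' receives the configured laterality-history offset keyed by the 4-lag
#' repeat/alternate code of the side sequence; correctness is
#' Bernoulli(1 - error rate). Reaction time is the reciprocal of observed
#' rate, quantised to the nearest millisecond when configured (floor 1 ms);
#' timed-out trials record exactly 60 s.
#'
#' @param config A [synth_config()] object.
#' @return Data.frame of `n_subjects * n_blocks_per_subject * n_trials` rows
#'   with columns `subject`, `block`, `condition`, `trial_index`, `side`,
#'   `rt_ms`, `correct`, `timed_out`.
#' @export
generate_experiment <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cp <- config$condition_params
  conds <- cp$condition
  if (config$n_blocks_per_subject > length(conds)) {
    stop("more blocks per subject than conditions available", call. = FALSE)
  }
  orders <- condition_orders(conds)
  n_blocks <- config$n_subjects * config$n_blocks_per_subject
  seeds <- derive_seeds(config$seed, n_blocks)
  out <- vector("list", n_blocks)
  blk <- 0L
  for (subj in seq_len(config$n_subjects)) {
    ord <- orders[[(subj - 1L) %% length(orders) + 1L]]
    for (b in seq_len(config$n_blocks_per_subject)) {
      blk <- blk + 1L
      cond <- ord[b]
      row <- cp[cp$condition == cond, ]
      if (nrow(row) != 1L) {
        stop(sprintf("unknown condition key: %s", cond), call. = FALSE)
      }
      out[[blk]] <- with_seed(seeds[blk], {
        rates <- generate_block_rates(row$mu_u, row$sigma_u, config$ar_weights,
                                      config$n_trials, config$truncation_bound,
                                      seed = NULL)
        side <- sample(c("L", "R"), config$n_trials, replace = TRUE)
        r_obs <- rates$rate_latent
        if (row$easy && !is.null(config$spatial_deltas) &&
            config$n_trials >= 5) {
          codes <- side_history_codes(side)
          idx <- which(!is.na(codes))
          r_obs[idx] <- r_obs[idx] +
            config$spatial_deltas[as.character(codes[idx])]
        }
        timed_out <- r_obs < config$truncation_bound
        r_obs[timed_out] <- config$truncation_bound
        rt_ms <- 1000 / r_obs
        if (config$quantize_ms) rt_ms <- pmax(1, round(rt_ms))
        data.frame(
          subject = subj,
          block = blk,
          condition = cond,
          trial_index = seq_len(config$n_trials),
          side = side,
          rt_ms = rt_ms,
          correct = stats::rbinom(config$n_trials, 1, 1 - row$error_rate) == 1,
          timed_out = timed_out,
          stringsAsFactors = FALSE
        )
      })
    }
  }
  do.call(rbind, out)
}

# 4-lag repeat/alternate code for each trial of a side sequence; NA for the
# first four trials (insufficient history).
side_history_codes <- function(side) {
  n <- length(side)
  codes <- rep(NA_integer_, n)
  if (n >= 5) {
    trans <- as.integer(side[-1] != side[-n])      # 1 = alternate
    for (i in 5:n) {
      tr <- trans[(i - 4):(i - 1)]
      codes[i] <- sum(tr * c(8L, 4L, 2L, 1L))
    }
  }
  codes
}

#' Replace reaction times with parametric draws, block by block
#'
#' Keeps every design column of a trial table but replaces each block's
#' reaction times with draws from a chosen family at that block's fitted (or
#' sample) moments, preserving the block's trial count exactly. This is the
#' device used to check that the standardise-and-collapse probit analysis
#' recovers the generating family: a reciprocal-truncated-Normal clone
#' yields a linear rate probit, an inverse-Gaussian clone a visibly
#' non-linear one.
#'
#' @param table Canonical trial table.
#' @param fits For `family = "rectrN"`, a named list of
#'   [fit_truncated_normal()] objects (or lists with `mu_hat`, `sigma_hat`,
#'   `a`), one per block id. Ignored for `family = "IG"`, which uses each
#'   block's sample moments of reaction time in seconds, as the reference
#'   analysis did.
#' @param family `"rectrN"` or `"IG"`.
#' @param seed Integer seed.
#' @param quantize_ms Round cloned reaction times to integer milliseconds.
#' @return A trial table of identical shape with new `rt_ms` (and `timed_out`
#'   recomputed for rectrN draws at the truncation bound).
#' @export
clone_parametric <- function(table, fits = NULL, family = c("rectrN", "IG"),
                             seed = 1L, quantize_ms = TRUE) {
  family <- match.arg(family)
  blocks <- unique(table$block)
  seeds <- derive_seeds(seed, length(blocks))
  out <- table
  for (i in seq_along(blocks)) {
    idx <- which(table$block == blocks[i])
    n <- length(idx)
    if (family == "rectrN") {
      fit <- fits[[as.character(blocks[i])]]
      if (is.null(fit)) {
        stop(sprintf("missing fit for block %s", blocks[i]), call. = FALSE)
      }
      rate <- rtrunc_normal(n, fit$mu_hat, fit$sigma_hat, fit$a,
                            seed = seeds[i])
      rt_s <- 1 / rate
      out$timed_out[idx] <- rate <= fit$a
    } else {
      rt_obs <- table$rt_ms[idx] / 1000
      m <- mean(rt_obs)
      v <- stats::var(rt_obs)
      rt_s <- rinvgauss(n, m, v, seed = seeds[i])
      # draws beyond the time-out would not be observed; censor like the task
      over <- rt_s > 60
      rt_s[over] <- 60
      out$timed_out[idx] <- over
    }
    rt_ms <- 1000 * rt_s
    if (quantize_ms) rt_ms <- pmax(1, round(rt_ms))
    out$rt_ms[idx] <- rt_ms
  }
  out
}

#' Write / read the canonical trial table
#'
#' Tab-delimited text with a header row and columns exactly `subject`,
#' `block`, `condition`, `trial_index`, `side`, `rt_ms`, `correct`,
#' `timed_out`.
#'
#' @param table Trial table data.frame.
#' @param path File path.
#' @export
write_trial_table <- function(table, path) {
  cols <- c("subject", "block", "condition", "trial_index", "side",
            "rt_ms", "correct", "timed_out")
  stopifnot(all(cols %in% names(table)))
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param path File path.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c("subject", "block", "condition", "trial_index", "side",
            "rt_ms", "correct", "timed_out")
  missing <- setdiff(cols, names(tab))
  if (length(missing)) {
    stop(sprintf("trial table is missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tab$correct <- as.logical(tab$correct)
  tab$timed_out <- as.logical(tab$timed_out)
  tab
}
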