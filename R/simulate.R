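# Stochastic simulation of Bayes-optimal agents applying a solved policy to
# accumulating evidence. Trials are advanced in lock-step and vectorized
# across the batch; the per-trial stream is still reproducible from the seed.

# Expected choice rewards for a matrix of posterior means (rows = trials).
reward_matrix <- function(cfg, mu, t) {
  if (cfg$utility_mode == "expected") {
    pv <- posterior_var(config_belief(cfg, t))
    matrix(expected_utility(cfg$utility, as.vector(mu), pv), nrow(mu))
  } else {
    matrix(evaluate_utility(cfg$utility, as.vector(mu)), nrow(mu))
  }
}

# Core engine: n trials against one policy, identical true values.
# The stop/continue decision at each simulation step interpolates the signed
# stop-continue gap of the nearest policy time slice multilinearly in
# estimate space; posterior means outside the grid are clamped to the edge.
run_trials <- function(p, true_values, n, sim_dt = 5e-3) {
  stopifnot(inherits(p, "policy_grid"))
  cfg <- p$config
  d <- cfg$n_options
  if (length(true_values) != d)
    stop(sprintf("true_values must have length %d", d), call. = FALSE)
  if (!is.numeric(sim_dt) || length(sim_dt) != 1L || sim_dt <= 0)
    stop("sim_dt must be > 0", call. = FALSE)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)

  max_steps <- as.integer(ceiling(cfg$horizon / sim_dt - 1e-9))
  sd_step <- sqrt(cfg$obs_var * sim_dt)
  drift <- true_values * sim_dt

  sumx <- matrix(0, n, d)
  rt <- numeric(n)
  choice <- integer(n)
  censored <- logical(n)
  steps <- integer(n)
  active <- rep(TRUE, n)

  for (step in 0:max_steps) {
    t <- step * sim_dt
    idx <- which(active)
    mu <- (cfg$prior_mean * cfg$obs_var + cfg$prior_var *
             sumx[idx, , drop = FALSE]) /
          (cfg$obs_var + cfg$prior_var * t)
    k <- which.min(abs(p$times - t))
    gap <- interp_grid(p$gap[[k]], p$grid, mu)
    at_horizon <- step == max_steps
    stop_now <- gap >= 0 | at_horizon
    if (any(stop_now)) {
      sel <- idx[stop_now]
      rt[sel] <- t
      r <- reward_matrix(cfg, mu[stop_now, , drop = FALSE], t)
      choice[sel] <- max.col(r, ties.method = "random")
      censored[sel] <- at_horizon & gap[stop_now] < 0
      steps[sel] <- step
      active[sel] <- FALSE
    }
    if (at_horizon || !any(active)) break
    idx <- which(active)
    m <- length(idx)
    sumx[idx, ] <- sumx[idx, ] +
      matrix(drift, m, d, byrow = TRUE) +
      matrix(stats::rnorm(m * d, sd = sd_step), m, d)
  }
  data.frame(trial = seq_len(n), rt = rt, choice = choice,
             censored = censored, steps = steps)
}

#' Simulate a single decision trial
#'
#' Accumulates evidence at step `sim_dt`, updates the conjugate posterior
#' means, and stops the first time the policy's stop region is reached
#' (multilinear interpolation of the signed stop-continue gap at the nearest
#' policy time slice). A trial reaching the horizon is resolved by a forced
#' choice and flagged as censored. Seed the R random stream with
#' [set.seed()] for reproducibility.
#'
#' @param p A `policy_grid` from [solve_policy()].
#' @param true_values True value rates, one per option.
#' @param sim_dt Simulation time step (default 5e-3, much finer than the
#'   dynamic-programming step).
#' @return An object of class `trial_result`: list with `rt`, `choice`,
#'   `censored` and `trajectory_len` (number of evidence steps taken).
#' @export
simulate_trial <- function(p, true_values, sim_dt = 5e-3) {
  tr <- run_trials(p, true_values, 1L, sim_dt)
  structure(list(rt = tr$rt, choice = tr$choice, censored = tr$censored,
                 trajectory_len = tr$steps),
            class = "trial_result")
}

#' Simulate a batch of trials and summarize reaction times
#'
#' @param p A `policy_grid`.
#' @param true_values True value rates, one per option.
#' @param n Number of independent trials (>= 1).
#' @param sim_dt Simulation time step.
#' @return An object of class `rt_summary`: `n`, `mean_rt`, `ci95`
#'   (mean +/- 1.96 standard errors), `choice_freq` (per-option fractions),
#'   `censored_frac`, and the per-trial `trials` data frame
#'   (columns trial, rt, choice, censored, steps).
#' @export
simulate_batch <- function(p, true_values, n, sim_dt = 5e-3) {
  tr <- run_trials(p, true_values, n, sim_dt)
  mean_rt <- mean(tr$rt)
  se <- if (n > 1L) stats::sd(tr$rt) / sqrt(n) else 0
  structure(list(
    n = n,
    mean_rt = mean_rt,
    se = se,
    ci95 = c(mean_rt - 1.96 * se, mean_rt + 1.96 * se),
    choice_freq = tabulate(tr$choice, p$config$n_options) / n,
    censored_frac = mean(tr$censored),
    trials = tr), class = "rt_summary")
}

#' @export
print.rt_summary <- function(x, ...) {
  cat(sprintf("rt summary: n = %d, mean RT = %.4f [%.4f, %.4f]\n",
              x$n, x$mean_rt, x$ci95[1L], x$ci95[2L]))
  cat(sprintf("  choice frequencies: %s; censored: %.3f\n",
              paste(sprintf("%.3f", x$choice_freq), collapse = " "),
              x$censored_frac))
  invisible(x)
}

#' Mean reaction time across equal-value option sets
#'
#' Solves (or reuses) the policy for `cfg` and simulates batches of trials
#' with all options at a common true value `v`, for each `v` in `values`.
#' This is the magnitude-sensitivity probe: under linear (Bayes-Risk) time
#' costs the mean-RT curve is near-flat, while geometric discounting
#' postpones decisions for low-value sets, producing a decreasing curve.
#'
#' @param cfg A [bellman_config()].
#' @param values Sorted vector of common option values to sweep.
#' @param n_per_value Trials per value (0 gives a dry run: an empty curve
#'   carrying the solved policy as attribute).
#' @param sim_dt Simulation time step.
#' @param policy Optionally a pre-solved `policy_grid` for `cfg`.
#' @return A `data.frame` of class `rt_curve` with columns `v`, `n`,
#'   `mean_rt`, `se`, `ci_lo`, `ci_hi`, `censored_frac`; the solved policy is
#'   attached as attribute `"policy"` and the full summaries as
#'   `"summaries"`.
#' @export
magnitude_sweep <- function(cfg, values, n_per_value, sim_dt = 5e-3,
                            policy = NULL) {
  if (is.unsorted(values)) stop("values must be sorted", call. = FALSE)
  if (is.null(policy)) policy <- solve_policy(cfg)
  n_per_value <- as.integer(n_per_value)
  if (n_per_value == 0L) {
    out <- data.frame(v = numeric(0), n = integer(0), mean_rt = numeric(0),
                      se = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), censored_frac = numeric(0))
    attr(out, "policy") <- policy
    class(out) <- c("rt_curve", "data.frame")
    return(out)
  }
  d <- policy$config$n_options
  sums <- lapply(values, function(v)
    simulate_batch(policy, rep(v, d), n_per_value, sim_dt))
  out <- data.frame(
    v = values,
    n = n_per_value,
    mean_rt = vapply(sums, `[[`, numeric(1), "mean_rt"),
    se = vapply(sums, `[[`, numeric(1), "se"),
    ci_lo = vapply(sums, function(s) s$ci95[1L], numeric(1)),
    ci_hi = vapply(sums, function(s) s$ci95[2L], numeric(1)),
    censored_frac = vapply(sums, `[[`, numeric(1), "censored_frac"))
  attr(out, "policy") <- policy
  attr(out, "summaries") <- sums
  class(out) <- c("rt_curve", "data.frame")
  out
}

#' Magnitude-sensitivity slope of a mean-RT curve
#'
#' Ordinary least-squares slope of mean reaction time against the common
#' option value. The attached standard error is pooled from the per-point
#' standard errors of the means when available (each mean enters the OLS
#' slope linearly), otherwise taken from the residual fit.
#'
#' @param curve An [magnitude_sweep()] result, or any data frame with
#'   columns `v` and `mean_rt` (and optionally `se`).
#' @return The slope (time per value unit), with attribute `"se"`.
#' @export
magnitude_slope <- function(curve) {
  if (nrow(curve) < 2L)
    stop("at least 2 sweep points are required", call. = FALSE)
  v <- curve$v
  y <- curve$mean_rt
  w <- (v - mean(v)) / sum((v - mean(v))^2)
  slope <- sum(w * y)
  se <- if (!is.null(curve$se) && all(is.finite(curve$se)) &&
            any(curve$se > 0)) {
    sqrt(sum(w^2 * curve$se^2))
  } else if (nrow(curve) > 2L) {
    resid <- y - mean(y) - slope * (v - mean(v))
    sqrt(sum(resid^2) / (nrow(curve) - 2L) / sum((v - mean(v))^2))
  } else {
    NA_real_
  }
  structure(slope, se = se)
}

#' @export
plot.rt_curve <- function(x, ...) {
  plot(x$v, x$mean_rt, type = "b", pch = 16,
       ylim = range(c(x$ci_lo, x$ci_hi)),
       xlab = "common option value v", ylab = "mean reaction time", ...)
  graphics::arrows(x$v, x$ci_lo, x$v, x$ci_hi, angle = 90, code = 3,
                   length = 0.03, col = "red")
  invisible(x)
}
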