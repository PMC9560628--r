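# Conjugate Gaussian belief over option values accumulated from momentary
# evidence. Evidence at step length dt for option i is drawn
# X_i ~ N(xbar_i * dt, sigma_a^2 * dt); the belief tracks only the running
# sum of momentary evidence, which is sufficient.

#' Gaussian belief state
#'
#' Represents the conjugate-Gaussian belief about one option's (or, with
#' vector `cum_evidence`, several options') true value rate: a Normal prior
#' `N(prior_mean, prior_var)` updated by momentary evidence with per-unit-time
#' observation variance `obs_var`.
#'
#' The posterior mean used throughout is the conjugate form
#' \deqn{\hat{x}(t) = \frac{\bar{x}_p \sigma_a^2 + \sigma_p^2 \sum_\tau x_\tau}
#'                         {\sigma_a^2 + \sigma_p^2 t},}
#' which satisfies both the no-data limit (returns the prior mean at t = 0)
#' and the flat-prior limit (returns the evidence sample mean as
#' \eqn{\sigma_p^2 \to \infty}).
#'
#' @param prior_mean Prior mean of the value rate.
#' @param prior_var Prior variance (> 0; `Inf` selects the flat-prior limit).
#' @param obs_var Observation noise variance per unit time (> 0).
#' @param t Elapsed observation time (>= 0).
#' @param cum_evidence Running sum of momentary evidence samples (value x time
#'   units); scalar or one entry per option.
#' @return An object of class `gaussian_belief`.
#' @examples
#' b <- gaussian_belief(prior_mean = 1.5, prior_var = 5, obs_var = 2)
#' posterior_mean(b)
#' @export
gaussian_belief <- function(prior_mean = 1.5, prior_var = 5, obs_var = 2,
                            t = 0, cum_evidence = 0) {
  stopifnot(is.numeric(prior_mean), length(prior_mean) == 1L,
            is.finite(prior_mean))
  if (!is.numeric(prior_var) || length(prior_var) != 1L || prior_var <= 0)
    stop("prior_var must be > 0", call. = FALSE)
  if (!is.numeric(obs_var) || length(obs_var) != 1L || !is.finite(obs_var) ||
      obs_var <= 0)
    stop("obs_var must be finite and > 0", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("t must be >= 0", call. = FALSE)
  structure(list(prior_mean = prior_mean, prior_var = prior_var,
                 obs_var = obs_var, t = t, cum_evidence = cum_evidence),
            class = "gaussian_belief")
}

#' Sample momentary evidence
#'
#' Draws one step of momentary evidence for each option:
#' independent \eqn{N(\bar{x}_i\, dt, \sigma_a^2\, dt)} draws.
#' Uses the current R random stream (seed with [set.seed()]).
#'
#' @param true_values Numeric vector of true value rates, one per option.
#' @param obs_var Observation noise variance per unit time (>= 0; 0 gives the
#'   deterministic limiting mode).
#' @param dt Step length (> 0).
#' @return Numeric vector of evidence increments, one per option.
#' @export
sample_evidence <- function(true_values, obs_var, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(obs_var) || length(obs_var) != 1L || obs_var < 0)
    stop("obs_var must be >= 0", call. = FALSE)
  true_values * dt + stats::rnorm(length(true_values),
                                  sd = sqrt(obs_var * dt))
}

#' Update a belief with one evidence step
#'
#' @param b A `gaussian_belief`.
#' @param evidence Evidence increment(s), as returned by [sample_evidence()].
#' @param dt Step length (> 0).
#' @return The updated `gaussian_belief`.
#' @export
update_belief <- function(b, evidence, dt) {
  stopifnot(inherits(b, "gaussian_belief"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  b$cum_evidence <- b$cum_evidence + evidence
  b$t <- b$t + dt
  b
}

#' Posterior mean of the value rate
#'
#' @param b A `gaussian_belief`.
#' @return Posterior mean(s), one per entry of `cum_evidence`.
#' @export
posterior_mean <- function(b) {
  stopifnot(inherits(b, "gaussian_belief"))
  if (is.infinite(b$prior_var)) {
    if (b$t == 0) stop("flat prior with no data has no posterior mean",
                       call. = FALSE)
    return(b$cum_evidence / b$t)
  }
  (b$prior_mean * b$obs_var + b$prior_var * b$cum_evidence) /
    (b$obs_var + b$prior_var * b$t)
}

#' Posterior variance of the value rate
#'
#' Returns \eqn{(1/\sigma_p^2 + t/\sigma_a^2)^{-1}}; equals the prior
#' variance at t = 0 and decreases monotonically to 0.
#'
#' @param b A `gaussian_belief`.
#' @return Posterior variance (scalar).
#' @export
posterior_var <- function(b) {
  stopifnot(inherits(b, "gaussian_belief"))
  1 / (1 / b$prior_var + b$t / b$obs_var)
}

#' One-step transition standard deviation of the posterior mean
#'
#' Under the current belief the posterior mean after a further `dt` of
#' observation is distributed Normal(current mean, s^2) with
#' \eqn{s(t, dt) = \sqrt{v(t) - v(t + dt)}} where v is the posterior
#' variance: posterior means form a martingale whose increments carry
#' exactly the variance the posterior loses. This is the kernel width used
#' by the dynamic-programming expectation over next estimates.
#'
#' @param b A `gaussian_belief`.
#' @param dt Look-ahead interval (> 0).
#' @return The transition standard deviation (scalar, >= 0).
#' @export
transition_std <- function(b, dt) {
  stopifnot(inherits(b, "gaussian_belief"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be > 0", call. = FALSE)
  v_now <- posterior_var(b)
  b2 <- b
  b2$t <- b$t + dt
  sqrt(max(v_now - posterior_var(b2), 0))
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf(
    "gaussian belief: prior N(%g, %g), obs_var %g, t = %g\n",
    x$prior_mean, x$prior_var, x$obs_var, x$t))
  invisible(x)
}
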