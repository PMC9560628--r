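# Generators for the two experimental designs the simulations are matched
# against (a three-patch brightness psychophysics task and a slime-mould
# foraging assay), plus a parametric reaction-time dataset generator for
# end-to-end pipeline tests.

#' Generate a psychophysics trial schedule
#'
#' Enumerates all ordered brightness triples over the given levels, repeats
#' every equal triple `equal_repeats` times and every unequal triple
#' `unequal_repeats` times, pseudo-randomises the order, and assigns each
#' trial an inter-trial interval drawn uniformly from {0.5, 1, 1.5} seconds.
#' With 4 levels there are 4^3 = 64 ordered triples; 10 equal repeats plus 1
#' unequal repeat gives the standard 100-trial session.
#'
#' @param levels Brightness levels (nonempty numeric vector;
#'   default `c(0.3, 0.4, 0.5, 0.6)`).
#' @param equal_repeats Repeats of each equal triple (default 10).
#' @param unequal_repeats Repeats of each unequal triple (default 1).
#' @return A `data.frame` with columns `trial`, `b1`, `b2`, `b3`,
#'   `is_equal`, `iti`. Seed the R random stream with [set.seed()]; the
#'   composition is deterministic, only order and ITIs are random.
#' @export
generate_trial_schedule <- function(levels = c(0.3, 0.4, 0.5, 0.6),
                                    equal_repeats = 10L,
                                    unequal_repeats = 1L) {
  if (length(levels) == 0L) stop("levels must be nonempty", call. = FALSE)
  if (equal_repeats < 0L || unequal_repeats < 0L)
    stop("repeats must be >= 0", call. = FALSE)
  triples <- expand.grid(b1 = levels, b2 = levels, b3 = levels,
                         KEEP.OUT.ATTRS = FALSE)
  is_equal <- triples$b1 == triples$b2 & triples$b2 == triples$b3
  reps <- ifelse(is_equal, equal_repeats, unequal_repeats)
  idx <- rep(seq_len(nrow(triples)), times = reps)
  out <- triples[idx, , drop = FALSE]
  out$is_equal <- is_equal[idx]
  if (nrow(out) > 1L) out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$iti <- sample(c(0.5, 1, 1.5), nrow(out), replace = TRUE)
  out <- cbind(trial = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Per-frame luminance noise
#'
#' Adds the frame noise of the psychophysics display: a Gaussian draw with
#' mean 0 and standard deviation `0.25 * mean_brightness`, so the
#' signal-to-noise ratio is constant across magnitudes. Output is not
#' clipped to [0, 1] by default, since clipping would break the
#' constant-SNR property.
#'
#' @param mean_brightness Mean luminance(s), >= 0 (vectorized).
#' @param noise_sd_factor SD as a fraction of the mean (default 0.25).
#' @param clip Clip the noisy luminance to [0, 1] (default `FALSE`).
#' @return Noisy luminance values, one per entry of `mean_brightness`.
#' @export
frame_noise <- function(mean_brightness, noise_sd_factor = 0.25,
                        clip = FALSE) {
  if (any(mean_brightness < 0))
    stop("mean_brightness must be >= 0", call. = FALSE)
  out <- mean_brightness +
    stats::rnorm(length(mean_brightness),
                 sd = noise_sd_factor * mean_brightness)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Balanced slime-mould foraging design
#'
#' Full design crossing food-quality conditions (egg-yolk concentration,
#' g/L) with replicates: 4 concentrations x 50 replicates gives the standard
#' 200-row design.
#'
#' @param concentrations Food-quality levels (default `c(20, 40, 60, 80)`
#'   g/L).
#' @param replicates Replicates per concentration (>= 1; default 50).
#' @return A `data.frame` with columns `replicate` and `concentration`,
#'   `replicates` rows per concentration.
#' @export
slime_design <- function(concentrations = c(20, 40, 60, 80),
                         replicates = 50L) {
  if (length(concentrations) == 0L)
    stop("concentrations must be nonempty", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  out <- expand.grid(replicate = seq_len(replicates),
                     concentration = concentrations,
                     KEEP.OUT.ATTRS = FALSE)
  out[order(out$concentration, out$replicate), c("replicate",
                                                 "concentration")]
}

#' Synthetic reaction-time dataset with a linear magnitude effect
#'
#' Stand-in generator for unavailable raw behavioural data: reaction times
#' follow `intercept + slope * magnitude` plus a per-subject random
#' intercept and a mean-zero lognormal residual (rescaled to `noise_sd`) to
#' mimic RT skewness. Used for parameter-recovery tests of the
#' magnitude-sensitivity analysis.
#'
#' @param magnitudes Magnitude of each within-subject trial (vector, one
#'   entry per trial).
#' @param n_subjects Number of subjects (default 117).
#' @param slope Change of mean RT per magnitude unit (default -1.95).
#' @param intercept Mean RT at magnitude 0 (default 2.4).
#' @param subject_sd SD of the subject random intercept (>= 0; default 0.3).
#' @param noise_sd SD of the trial residual (>= 0; default 0.3).
#' @return A `data.frame` with columns `subject`, `magnitude`, `rt` and
#'   `n_subjects * length(magnitudes)` rows.
#' @export
generate_synthetic_rt_dataset <- function(magnitudes,
                                          n_subjects = 117L,
                                          slope = -1.95,
                                          intercept = 2.4,
                                          subject_sd = 0.3,
                                          noise_sd = 0.3) {
  if (subject_sd < 0 || noise_sd < 0)
    stop("subject_sd and noise_sd must be >= 0", call. = FALSE)
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  n_trials <- length(magnitudes)
  if (n_trials == 0L) stop("magnitudes must be nonempty", call. = FALSE)
  subj_int <- stats::rnorm(n_subjects, sd = subject_sd)
  n <- n_subjects * n_trials
  subject <- rep(seq_len(n_subjects), each = n_trials)
  magnitude <- rep(magnitudes, times = n_subjects)
  # lognormal shifted to mean 0 and rescaled to sd = noise_sd
  sdlog <- 0.5
  raw <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
  mu_ln <- exp(sdlog^2 / 2)
  sd_ln <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
  resid <- if (noise_sd > 0) noise_sd * (raw - mu_ln) / sd_ln else 0
  data.frame(subject = subject, magnitude = magnitude,
             rt = intercept + slope * magnitude + subj_int[subject] + resid)
}
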