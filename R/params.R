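# Parameter containers for the synthetic cohort generator.

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("swayval_validation_error", "error")))
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation(name, " must be a single finite number")
  if (strict && x <= lower) abort_validation(name, " must be > ", lower)
  if (!strict && x < lower) abort_validation(name, " must be >= ", lower)
  as.numeric(x)
}

#' Sway-process parameters
#'
#' Parameters of the latent postural-sway process and of the paired-device
#' study design. Each medial-lateral (ML) or anterior-posterior (AP) channel
#' of a trial is an exactly discretized stationary Ornstein--Uhlenbeck (OU)
#' process: mean-reverting noise whose stationary standard deviation is the
#' trial's sway amplitude and whose correlation time is `1/theta` seconds.
#' Per-trial amplitudes follow a log-normal random-effects model with
#' between-subject log-variance `tau2` and within-subject (trial-to-trial)
#' log-variance `omega2`, so the test-retest intraclass correlation of log
#' sway amplitude targets `tau2 / (tau2 + omega2)`.
#'
#' @param theta Mean-reversion rate of the OU sway process (1/s, > 0).
#'   The default 8/s gives a correlation time of 0.125 s, short relative to
#'   a 20-s trial, so per-trial amplitude estimates are stable.
#' @param sigma_base Baseline (eyes-open, ML) sway amplitude, i.e. the
#'   stationary SD of the COP excursion (cm).
#' @param ec_multiplier Eyes-closed amplitude multiplier (unitless, >= 1);
#'   quiet-standing sway increases when vision is removed.
#' @param tau2 Between-subject variance of log sway amplitude (>= 0).
#' @param omega2 Within-subject (trial) variance of log sway amplitude
#'   (>= 0).
#' @param duration Trial length in seconds.
#' @param fp_rate Force-plate sampling rate (Hz).
#' @param vr_rate Headset sampling rate (Hz); must be below `fp_rate`.
#' @param ap_anisotropy Multiplier applied to AP amplitudes relative to ML
#'   (AP sway is typically the larger in quiet standing).
#'
#' @return An object of class `sway_process_params`.
#' @examples
#' sway_process_params(sigma_base = 0.5, ec_multiplier = 1.5)
#' @export
sway_process_params <- function(theta = 8, sigma_base = 0.3, ec_multiplier = 1.4,
                                tau2 = 0.06, omega2 = 0.04, duration = 20,
                                fp_rate = 200, vr_rate = 10,
                                ap_anisotropy = 1.2) {
  p <- list(
    theta = check_scalar(theta, "theta", 0, strict = TRUE),
    sigma_base = check_scalar(sigma_base, "sigma_base", 0, strict = TRUE),
    ec_multiplier = check_scalar(ec_multiplier, "ec_multiplier", 1),
    tau2 = check_scalar(tau2, "tau2", 0),
    omega2 = check_scalar(omega2, "omega2", 0),
    duration = check_scalar(duration, "duration", 0, strict = TRUE),
    fp_rate = check_scalar(fp_rate, "fp_rate", 0, strict = TRUE),
    vr_rate = check_scalar(vr_rate, "vr_rate", 0, strict = TRUE),
    ap_anisotropy = check_scalar(ap_anisotropy, "ap_anisotropy", 0, strict = TRUE)
  )
  if (p$fp_rate <= p$vr_rate)
    abort_validation("fp_rate must exceed vr_rate")
  structure(p, class = "sway_process_params")
}

#' Headset observation parameters
#'
#' How the head-mounted tracker observes the latent sway. The head rides
#' above the center of gravity, so its excursion is a mechanically smoothed,
#' amplified copy of the COP path (`gain` times a low-passed COP), on top of
#' which sit two motion components of the head itself that the force plate
#' never sees: high-frequency head micro-motion ("tremor" jitter) and slow
#' drift of the headset on the wearer.
#'
#' The amplitude of the head micro-motion varies across wearers and trials
#' independently of sway amplitude: the per-trial jitter SD is
#' `jitter_sd * exp(b_i + v_it)` with `b_i ~ N(0, jitter_subj_sd^2)` per
#' subject and `v_it ~ N(0, jitter_trial_sd^2)` per trial. This independent
#' head-motion channel is what decouples the headset's path-length
#' fluctuations from the COP path length while leaving amplitude measures
#' (RMS, peak-to-peak) coupled.
#'
#' @param gain Amplification of head excursion relative to COP excursion
#'   (unitless, >= 1).
#' @param smooth_cutoff Low-pass cutoff (Hz) applied to the COP path before
#'   the gain; models the trunk/head acting as a mechanical low-pass filter.
#'   Must lie below the headset Nyquist frequency.
#' @param jitter_sd Nominal SD of the additive high-frequency head
#'   micro-motion (cm, >= 0), applied at the headset rate.
#' @param drift_sd Scale of slow headset drift (cm, >= 0): SD of the random
#'   walk drift at the end of a trial.
#' @param jitter_subj_sd SD of the per-subject log jitter multiplier.
#' @param jitter_trial_sd SD of the per-trial log jitter multiplier.
#'
#' @return An object of class `headset_params`.
#' @examples
#' headset_params(gain = 2, jitter_sd = 0)
#' @export
headset_params <- function(gain = 1.5, smooth_cutoff = 1, jitter_sd = 0.25,
                           drift_sd = 0.1, jitter_subj_sd = 0.25,
                           jitter_trial_sd = 0.34) {
  structure(list(
    gain = check_scalar(gain, "gain", 1),
    smooth_cutoff = check_scalar(smooth_cutoff, "smooth_cutoff", 0, strict = TRUE),
    jitter_sd = check_scalar(jitter_sd, "jitter_sd", 0),
    drift_sd = check_scalar(drift_sd, "drift_sd", 0),
    jitter_subj_sd = check_scalar(jitter_subj_sd, "jitter_subj_sd", 0),
    jitter_trial_sd = check_scalar(jitter_trial_sd, "jitter_trial_sd", 0)
  ), class = "headset_params")
}

#' Cohort configuration
#'
#' Full specification of a synthetic paired-device cohort: who is measured
#' (subjects, trials, eyes-open/eyes-closed conditions, sway directions),
#' the latent sway process, the headset observation model, and the root
#' random seed. A fixed configuration regenerates an identical cohort.
#'
#' @param n_subjects Number of subjects (>= 2). Default 20.
#' @param n_trials Trials per condition (>= 2). Default 3.
#' @param conditions Subset of `c("EO", "EC")` (eyes open / eyes closed).
#' @param directions Subset of `c("ML", "AP")`.
#' @param seed Integer root seed; every random stream in the cohort is
#'   derived from it deterministically.
#' @param process A [sway_process_params()] object.
#' @param headset A [headset_params()] object.
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(n_subjects = 5, seed = 7)
#' @export
cohort_config <- function(n_subjects = 20, n_trials = 3,
                          conditions = c("EO", "EC"),
                          directions = c("ML", "AP"),
                          seed = 1,
                          process = sway_process_params(),
                          headset = headset_params()) {
  if (!is.numeric(n_subjects) || n_subjects < 2 || n_subjects != round(n_subjects))
    abort_validation("n_subjects must be an integer >= 2")
  if (!is.numeric(n_trials) || n_trials < 2 || n_trials != round(n_trials))
    abort_validation("n_trials must be an integer >= 2")
  conditions <- match.arg(conditions, c("EO", "EC"), several.ok = TRUE)
  directions <- match.arg(directions, c("ML", "AP"), several.ok = TRUE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_validation("seed must be a single integer")
  if (!inherits(process, "sway_process_params"))
    abort_validation("process must be a sway_process_params object")
  if (!inherits(headset, "headset_params"))
    abort_validation("headset must be a headset_params object")
  if (headset$smooth_cutoff >= process$vr_rate / 2)
    abort_validation("smooth_cutoff must be below the headset Nyquist frequency")
  structure(list(
    n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
    conditions = conditions, directions = directions,
    seed = as.integer(seed), process = process, headset = headset
  ), class = "cohort_config")
}
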