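# Synthetic paired-device sway cohort generator.
#
# Latent model: per (subject, condition, trial, direction) the COP excursion
# is a stationary Ornstein-Uhlenbeck process with amplitude
#   A = sigma_base * cond_mult * aniso * exp(u_i + w_it),
# u_i ~ N(0, tau2) between subjects, w_it ~ N(0, omega2) between trials.
# The headset sees gain * lowpass(COP) decimated to its own rate, plus slow
# drift and high-frequency head micro-motion whose amplitude has its own
# independent subject/trial random effects.

# Deterministic per-entity seed derivation: each (purpose, subject,
# condition, trial, direction) tuple hashes to its own 31-bit seed, so
# enlarging a cohort never perturbs the streams of existing records.
split_seed <- function(root, ...) {
  keys <- c(...)
  h <- (as.numeric(root) %% 2147483646) + 1
  for (k in keys) {
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
    h <- (h * 40692 + 13) %% 2147483647
  }
  as.integer(h)
}

cond_code <- function(x) match(x, c("EO", "EC"))
dir_code <- function(x) match(x, c("ML", "AP"))

scalar_draw <- function(seed, sd) {
  if (sd == 0) return(0)
  withr::with_seed(seed, stats::rnorm(1, 0, sd))
}

#' Simulate a force-plate COP trace
#'
#' Draws one channel of a quiet-standing center-of-pressure excursion as an
#' exactly discretized stationary Ornstein--Uhlenbeck process at the force
#' plate's sampling rate. With step `d = 1/fp_rate` the update is
#' `x[t+1] = x[t] * exp(-theta * d) + s * e[t]` with
#' `s^2 = amplitude_scale^2 * (1 - exp(-2 * theta * d))` and the initial
#' value drawn from the stationary distribution, so the marginal SD equals
#' `amplitude_scale` at every sample and there is no integration error.
#'
#' @param params A [sway_process_params()] object.
#' @param amplitude_scale Stationary SD of the trace (cm, > 0).
#' @param seed Integer seed; the same seed reproduces the trace exactly and
#'   the trace is linear in `amplitude_scale` at fixed seed.
#'
#' @return A [trial_trace()] of length `round(duration * fp_rate) + 1`
#'   (the grid includes the t = 0 sample), device `"FP"`.
#' @examples
#' tr <- simulate_cop_trace(sway_process_params(), 0.3, seed = 1)
#' sd(tr$values)
#' @export
simulate_cop_trace <- function(params, amplitude_scale, seed) {
  if (!inherits(params, "sway_process_params"))
    abort_validation("params must be a sway_process_params object")
  amplitude_scale <- check_scalar(amplitude_scale, "amplitude_scale", 0,
                                  strict = TRUE)
  n <- round(params$duration * params$fp_rate) + 1
  phi <- exp(-params$theta / params$fp_rate)
  innov_sd <- amplitude_scale * sqrt(1 - phi^2)
  vals <- withr::with_seed(as.integer(seed), {
    e <- stats::rnorm(n)
    e[1] <- e[1] * amplitude_scale          # stationary start
    e[-1] <- e[-1] * innov_sd
    as.numeric(stats::filter(e, phi, method = "recursive"))
  })
  trial_trace(vals, rate = params$fp_rate, duration = params$duration,
              device = "FP")
}

# Zero-phase Butterworth low-pass, order 2, cutoff in Hz.
lowpass_trace <- function(values, rate, cutoff) {
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, values))
}

# Decimate a series on the t=0-inclusive grid of `rate_in` to `rate_out`.
# Exact subsampling when the rates are commensurate; otherwise linear
# interpolation with a message.
resample_trace <- function(values, rate_in, rate_out, duration) {
  n_out <- round(duration * rate_out) + 1
  step <- rate_in / rate_out
  if (abs(step - round(step)) < 1e-9) {
    idx <- 1 + round(step) * (seq_len(n_out) - 1)
    values[idx]
  } else {
    message("headset rate does not divide the plate rate; ",
            "falling back to linear interpolation")
    t_in <- (seq_along(values) - 1) / rate_in
    t_out <- (seq_len(n_out) - 1) / rate_out
    stats::approx(t_in, values, xout = t_out, rule = 2)$y
  }
}

#' Observe a COP trace through the headset
#'
#' Applies the headset observation model to a force-plate COP trace: the
#' head excursion is `gain` times a zero-phase low-passed copy of the COP
#' path, decimated to the headset rate, plus slow random-walk drift and
#' additive high-frequency head micro-motion. With `gain = 1` and
#' `jitter_sd = drift_sd = 0` the output is exactly the low-passed,
#' decimated COP.
#'
#' @param cop A [trial_trace()] sampled at the force-plate rate.
#' @param params A [headset_params()] object. `jitter_sd` and `drift_sd`
#'   are used as given; the cohort generator passes per-trial jitter scales
#'   through this argument.
#' @param seed Integer seed for the jitter and drift streams.
#' @param vr_rate Headset sampling rate (Hz); must be below `cop$rate` and
#'   above twice `smooth_cutoff`.
#'
#' @return A [trial_trace()] of length `round(duration * vr_rate) + 1` at
#'   `vr_rate`, device `"VR"`, inheriting the COP trace's metadata.
#' @examples
#' pp <- sway_process_params()
#' cop <- simulate_cop_trace(pp, 0.3, seed = 1)
#' vr <- observe_headset_trace(cop, headset_params(), seed = 2)
#' length(vr$values)
#' @export
observe_headset_trace <- function(cop, params, seed, vr_rate = 10) {
  if (!inherits(cop, "trial_trace"))
    abort_validation("cop must be a trial_trace")
  if (!inherits(params, "headset_params"))
    abort_validation("params must be a headset_params object")
  vr_rate <- check_scalar(vr_rate, "vr_rate", 0, strict = TRUE)
  if (vr_rate >= cop$rate)
    abort_validation("vr_rate must be below the COP sampling rate")
  if (params$smooth_cutoff >= vr_rate / 2)
    abort_validation("smooth_cutoff must be below the headset Nyquist frequency")
  smoothed <- lowpass_trace(cop$values, cop$rate, params$smooth_cutoff)
  head_path <- params$gain * resample_trace(smoothed, cop$rate, vr_rate,
                                            cop$duration)
  m <- length(head_path)
  noise <- withr::with_seed(as.integer(seed), {
    jitter <- stats::rnorm(m) * params$jitter_sd
    drift <- if (params$drift_sd > 0) {
      c(0, cumsum(stats::rnorm(m - 1))) * params$drift_sd / sqrt(m - 1)
    } else {
      numeric(m)
    }
    jitter + drift
  })
  trial_trace(head_path + noise, rate = vr_rate, duration = cop$duration,
              subject_id = cop$subject_id, condition = cop$condition,
              trial = cop$trial, direction = cop$direction, device = "VR")
}

#' Per-trial sway amplitude from the random-effects model
#'
#' Combines the condition effect with the subject and trial log-normal
#' random effects:
#' `sigma_base * (ec_multiplier if EC) * exp(subject_effect + trial_effect)`.
#' With `subject_effect ~ N(0, tau2)` and `trial_effect ~ N(0, omega2)` the
#' intraclass correlation of log amplitude across trials is
#' `tau2 / (tau2 + omega2)`, which is the dial the reliability analysis is
#' validated against.
#'
#' @param condition `"EO"` or `"EC"`.
#' @param subject_effect Subject-level log-amplitude effect (drawn once per
#'   subject).
#' @param trial_effect Trial-level log-amplitude effect (drawn per trial).
#' @param params A [sway_process_params()] object.
#'
#' @return A positive amplitude in cm.
#' @examples
#' subject_amplitude("EC", 0.1, -0.05, sway_process_params())
#' @export
subject_amplitude <- function(condition, subject_effect, trial_effect, params) {
  condition <- match.arg(condition, c("EO", "EC"))
  if (!inherits(params, "sway_process_params"))
    abort_validation("params must be a sway_process_params object")
  mult <- if (condition == "EC") params$ec_multiplier else 1
  params$sigma_base * mult * exp(subject_effect + trial_effect)
}

#' Generate a complete paired-device cohort
#'
#' Simulates, for every (subject, condition, trial, direction), one
#' force-plate COP trace and the paired headset trace observed from the
#' same latent sway path. ML and AP sway paths are independent; AP
#' amplitudes carry the `ap_anisotropy` factor. Every random stream is
#' derived from the root seed per record, so regeneration is exact and
#' adding subjects leaves existing subjects' traces unchanged.
#'
#' @param config A [cohort_config()] object.
#'
#' @return An object of class `sway_cohort`: a list with `config`, a
#'   `manifest` data frame (one row per stored trace) and a named list
#'   `traces` of [trial_trace()] objects keyed
#'   `S<id>_<EO|EC>_T<n>_<ML|AP>_<FP|VR>`.
#' @seealso [write_cohort()] to store it on disk, [metrics_table()] to
#'   summarize it.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 2, seed = 1))
#' nrow(coh$manifest)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    abort_validation("config must be a cohort_config object")
  pp <- config$process
  hp <- config$headset
  root <- config$seed
  traces <- list()
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", i)
    u_i <- scalar_draw(split_seed(root, 1, i), sqrt(pp$tau2))
    b_i <- scalar_draw(split_seed(root, 2, i), hp$jitter_subj_sd)
    for (cond in config$conditions) {
      cc <- cond_code(cond)
      for (t in seq_len(config$n_trials)) {
        w_it <- scalar_draw(split_seed(root, 3, i, cc, t), sqrt(pp$omega2))
        v_it <- scalar_draw(split_seed(root, 4, i, cc, t), hp$jitter_trial_sd)
        hp_trial <- hp
        hp_trial$jitter_sd <- hp$jitter_sd * exp(b_i + v_it)
        for (d in config$directions) {
          dc <- dir_code(d)
          amp <- subject_amplitude(cond, u_i, w_it, pp) *
            if (d == "AP") pp$ap_anisotropy else 1
          cop <- simulate_cop_trace(pp, amp, split_seed(root, 5, i, cc, t, dc))
          cop$subject_id <- sid; cop$condition <- cond
          cop$trial <- as.integer(t); cop$direction <- d
          vr <- observe_headset_trace(cop, hp_trial,
                                      split_seed(root, 6, i, cc, t, dc),
                                      vr_rate = pp$vr_rate)
          for (tr in list(cop, vr)) {
            key <- trace_key(sid, cond, t, d, tr$device)
            traces[[key]] <- tr
            rows[[key]] <- data.frame(
              subject_id = sid, condition = cond, trial = as.integer(t),
              direction = d, device = tr$device, rate_hz = tr$rate,
              trace_id = key, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  structure(list(config = config,
                 manifest = do.call(rbind, c(rows, make.row.names = FALSE)),
                 traces = traces),
            class = "sway_cohort")
}

#' @export
print.sway_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<sway_cohort> %d traces: %d subjects x %d conditions",
                     " x %d trials x %d directions x 2 devices\n"),
              nrow(m), length(unique(m$subject_id)),
              length(unique(m$condition)), max(m$trial),
              length(unique(m$direction))))
  invisible(x)
}

#' Calibrate the headset jitter scale to a target device correlation
#'
#' Finds the nominal `jitter_sd` at which the subject-level (3-trial mean)
#' RMS amplitudes of the two devices correlate at a requested level `rho`.
#' The headset RMS is expanded exactly in its three additive components
#' (gain-scaled smoothed sway, jitter, drift) over a large Monte Carlo
#' cohort of latent draws, so the correlation can be re-evaluated for any
#' candidate jitter scale without re-simulating traces, and the root is
#' solved by bisection. Everything else (gain, cutoff, drift, the jitter
#' random effects) is taken from `headset` as given.
#'
#' @param rho Target Pearson correlation(s) in (0, 1); may be a vector.
#' @param process A [sway_process_params()] object.
#' @param headset A [headset_params()] object supplying all non-jitter
#'   settings.
#' @param n_subjects Monte Carlo cohort size used for calibration.
#' @param n_trials Trials averaged per subject (default 3).
#' @param seed Seed for the calibration cohort.
#'
#' @return Numeric vector of calibrated `jitter_sd` values, one per `rho`.
#' @export
calibrate_headset_jitter <- function(rho, process, headset,
                                     n_subjects = 6000, n_trials = 3,
                                     seed = 1) {
  if (any(rho <= 0 | rho >= 1)) abort_validation("rho must lie in (0, 1)")
  pp <- process; hp <- headset
  n_vr <- round(pp$duration * pp$vr_rate) + 1
  ns <- n_subjects * n_trials
  A <- J <- Rc <- numeric(ns)
  G <- matrix(0, ns, 6)   # Sss, Szz, Sww, Ssz, Ssw, Szw (centered, /N)
  k <- 0
  for (i in seq_len(n_subjects)) {
    u_i <- scalar_draw(split_seed(seed, 11, i), sqrt(pp$tau2))
    b_i <- scalar_draw(split_seed(seed, 12, i), hp$jitter_subj_sd)
    for (t in seq_len(n_trials)) {
      k <- k + 1
      w_it <- scalar_draw(split_seed(seed, 13, i, t), sqrt(pp$omega2))
      v_it <- scalar_draw(split_seed(seed, 14, i, t), hp$jitter_trial_sd)
      A[k] <- subject_amplitude("EO", u_i, w_it, pp)
      J[k] <- exp(b_i + v_it)
      cop <- simulate_cop_trace(pp, 1, split_seed(seed, 15, i, t))
      Rc[k] <- A[k] * sqrt(mean((cop$values - mean(cop$values))^2))
      s <- resample_trace(lowpass_trace(cop$values, pp$fp_rate,
                                        hp$smooth_cutoff),
                          pp$fp_rate, pp$vr_rate, pp$duration)
      zw <- withr::with_seed(split_seed(seed, 16, i, t), {
        z <- stats::rnorm(n_vr)
        w <- c(0, cumsum(stats::rnorm(n_vr - 1))) / sqrt(n_vr - 1)
        list(z, w)
      })
      s <- s - mean(s); z <- zw[[1]] - mean(zw[[1]]); w <- zw[[2]] - mean(zw[[2]])
      G[k, ] <- c(sum(s * s), sum(z * z), sum(w * w),
                  sum(s * z), sum(s * w), sum(z * w)) / n_vr
    }
  }
  subj <- rep(seq_len(n_subjects), each = n_trials)
  cop_mean <- tapply(Rc, subj, mean)
  cor_at <- function(j) {
    a <- hp$gain * A; jj <- j * J; d <- hp$drift_sd
    vr_rms <- sqrt(a^2 * G[, 1] + jj^2 * G[, 2] + d^2 * G[, 3] +
                     2 * a * jj * G[, 4] + 2 * a * d * G[, 5] +
                     2 * jj * d * G[, 6])
    stats::cor(cop_mean, tapply(vr_rms, subj, mean))
  }
  vapply(rho, function(r) {
    if (cor_at(0) <= r)
      abort_validation("target rho exceeds the jitter-free correlation")
    stats::uniroot(function(j) cor_at(j) - r, c(0, 50),
                   extendInt = "downX", tol = 1e-4)$root
  }, numeric(1))
}
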