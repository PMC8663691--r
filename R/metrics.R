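# Stabilogram summary measures. Each trace is analyzed at its native rate:
# COP at 200 Hz, headset at 10 Hz, with no resampling or filtering before
# the metrics. NPL therefore depends systematically on the sampling rate
# (finer sampling accumulates more path), which is a property of the
# measure, not of the implementation.

#' Normalized path length of a trace
#'
#' Total excursion divided by trial duration:
#' `NPL = (1/t) * sum_j |p[j+1] - p[j]|` (cm/s), a sway-velocity-like
#' measure. Translation invariant and sensitive to sampling rate and
#' high-frequency noise.
#'
#' @param trace A [trial_trace()] (length >= 2, positive duration).
#' @return Normalized path length in cm/s.
#' @examples
#' normalized_path_length(trial_trace(c(0, 1, 0, 1, 0), rate = 0.2))
#' @export
normalized_path_length <- function(trace) {
  stopifnot(inherits(trace, "trial_trace"))
  if (length(trace$values) < 2) abort_validation("NPL needs >= 2 samples")
  if (trace$duration <= 0) abort_validation("NPL needs a positive duration")
  sum(abs(diff(trace$values))) / trace$duration
}

#' Root mean square of a trace about its mean
#'
#' `RMS = sqrt(mean((p - mean(p))^2))` (cm), the population convention with
#' divisor N. A sway-amplitude measure.
#'
#' @param trace A [trial_trace()].
#' @return RMS in cm.
#' @examples
#' root_mean_square(trial_trace(c(1, -1, 1, -1), rate = 1))
#' @export
root_mean_square <- function(trace) {
  stopifnot(inherits(trace, "trial_trace"))
  p <- trace$values
  if (length(p) < 1) abort_validation("RMS needs a non-empty trace")
  sqrt(mean((p - mean(p))^2))
}

#' Peak-to-peak excursion of a trace
#'
#' `P2P = max(p) - min(p)` (cm), a sway-range measure.
#'
#' @param trace A [trial_trace()].
#' @return Peak-to-peak range in cm.
#' @examples
#' peak_to_peak(trial_trace(c(0.3, -0.2, 0.5), rate = 1))
#' @export
peak_to_peak <- function(trace) {
  stopifnot(inherits(trace, "trial_trace"))
  p <- trace$values
  if (length(p) < 1) abort_validation("P2P needs a non-empty trace")
  max(p) - min(p)
}

#' Sway-metric table for a cohort
#'
#' Computes NPL, RMS and P2P for every trace in a cohort, one row per
#' trace, each trace at its native sampling rate.
#'
#' @param cohort A `sway_cohort` from [generate_cohort()] or
#'   [load_cohort()].
#' @return A data frame with columns `subject_id`, `condition`, `trial`,
#'   `direction`, `device`, `npl_cm_per_s`, `rms_cm`, `p2p_cm`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 2, seed = 1))
#' head(metrics_table(coh))
#' @export
metrics_table <- function(cohort) {
  if (!inherits(cohort, "sway_cohort"))
    abort_validation("cohort must be a sway_cohort")
  m <- cohort$manifest
  rows <- lapply(seq_len(nrow(m)), function(r) {
    tr <- cohort$traces[[m$trace_id[r]]]
    res <- tryCatch(
      data.frame(subject_id = m$subject_id[r], condition = m$condition[r],
                 trial = m$trial[r], direction = m$direction[r],
                 device = m$device[r],
                 npl_cm_per_s = normalized_path_length(tr),
                 rms_cm = root_mean_square(tr),
                 p2p_cm = peak_to_peak(tr), stringsAsFactors = FALSE),
      error = function(e) {
        stop("metrics failed for trace ", m$trace_id[r], ": ",
             conditionMessage(e), call. = FALSE)
      })
    res
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

metric_column <- function(metric_name) {
  cols <- c(NPL = "npl_cm_per_s", RMS = "rms_cm", P2P = "p2p_cm")
  if (!metric_name %in% names(cols))
    abort_validation("unknown metric '", metric_name,
                     "' (expected NPL, RMS or P2P)")
  cols[[metric_name]]
}
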