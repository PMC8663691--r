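# The single-trial, single-channel position trace container.

#' A single-device, single-channel trial trace
#'
#' Container for one device's position series for one trial and one sway
#' direction: the ordered positions (cm), the sampling rate (Hz), the
#' nominal trial duration (s) and the identifying metadata.
#'
#' @param values Numeric vector of positions (cm), length >= 2, all finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param duration Nominal trial length in seconds; defaults to
#'   `(length(values) - 1) / rate` (grids include the t = 0 sample).
#' @param subject_id,condition,trial,direction,device Optional metadata:
#'   subject label, `"EO"`/`"EC"`, trial index, `"ML"`/`"AP"`, `"FP"`/`"VR"`.
#'
#' @return An object of class `trial_trace`.
#' @examples
#' tr <- trial_trace(sin(seq(0, 2 * pi, length.out = 201)), rate = 10)
#' tr
#' @export
trial_trace <- function(values, rate, duration = NULL,
                        subject_id = NA_character_, condition = NA_character_,
                        trial = NA_integer_, direction = NA_character_,
                        device = NA_character_) {
  if (!is.numeric(values) || length(values) < 2L)
    abort_validation("trace must contain at least 2 numeric samples")
  if (!all(is.finite(values)))
    abort_validation("trace values must all be finite")
  rate <- check_scalar(rate, "rate", 0, strict = TRUE)
  if (is.null(duration)) duration <- (length(values) - 1) / rate
  duration <- check_scalar(duration, "duration", 0, strict = TRUE)
  if (abs(length(values) - (duration * rate + 1)) > 1)
    abort_validation("trace length inconsistent with duration * rate + 1")
  structure(list(
    values = as.numeric(values), rate = rate, duration = duration,
    subject_id = subject_id,
    condition = if (is.na(condition)) NA_character_ else match.arg(condition, c("EO", "EC")),
    trial = as.integer(trial),
    direction = if (is.na(direction)) NA_character_ else match.arg(direction, c("ML", "AP")),
    device = if (is.na(device)) NA_character_ else match.arg(device, c("FP", "VR"))
  ), class = "trial_trace")
}

#' @export
print.trial_trace <- function(x, ...) {
  cat(sprintf("<trial_trace> %d samples @ %g Hz, %g s\n",
              length(x$values), x$rate, x$duration))
  meta <- c(subject = x$subject_id, condition = x$condition,
            trial = as.character(x$trial), direction = x$direction,
            device = x$device)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = "=", collapse = " "), "\n", sep = "")
  cat(sprintf("  range [%.4f, %.4f] cm\n", min(x$values), max(x$values)))
  invisible(x)
}

trace_key <- function(subject_id, condition, trial, direction, device) {
  sprintf("%s_%s_T%d_%s_%s", subject_id, condition, as.integer(trial),
          direction, device)
}
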