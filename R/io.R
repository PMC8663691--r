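# On-disk cohort format: one CSV per trace (`time_s,position_cm`) plus a
# manifest CSV indexing them. Comma separator, '.' decimal, UTF-8;
# positions stored to 6 decimal places (sub-micrometer, beyond either
# instrument's resolution).

abort_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("swayval_parse_error", "error")))
}

MANIFEST_COLS <- c("subject_id", "condition", "trial", "direction",
                   "device", "rate_hz", "path")

#' Write a single trace CSV
#'
#' @param trace A [trial_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "trial_trace"))
    abort_validation("trace must be a trial_trace")
  tt <- (seq_along(trace$values) - 1) / trace$rate
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("time_s,position_cm", con)
  writeLines(sprintf("%.6f,%.6f", tt, trace$values), con)
  invisible(path)
}

#' Read a single trace CSV
#'
#' Parses a two-column `time_s,position_cm` file. The sampling rate is
#' inferred from the median time step (rounded to the nearest 0.1 Hz);
#' time-step jitter above 0.5% of the median step, non-monotonic time,
#' non-numeric rows and missing values are rejected with the offending
#' line number.
#'
#' @param path File to read.
#' @param subject_id,condition,trial,direction,device Optional metadata to
#'   attach (the manifest, not the trace file, carries identity).
#' @return A [trial_trace()].
#' @export
read_trace <- function(path, subject_id = NA_character_,
                       condition = NA_character_, trial = NA_integer_,
                       direction = NA_character_, device = NA_character_) {
  if (!file.exists(path)) abort_parse("trace file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || trimws(lines[1]) != "time_s,position_cm")
    abort_parse(path, ": malformed header (expected 'time_s,position_cm')")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2)
    abort_parse(path, ": fewer than 2 data rows")
  parts <- strsplit(body, ",", fixed = TRUE)
  bad_shape <- which(lengths(parts) != 2L)
  if (length(bad_shape))
    abort_parse(path, ": line ", bad_shape[1] + 1, " does not have 2 fields")
  tt <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  pp <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is.finite(tt) | !is.finite(pp))
  if (length(bad))
    abort_parse(path, ": non-numeric or missing value at line ", bad[1] + 1)
  dt <- diff(tt)
  nonmono <- which(dt <= 0)
  if (length(nonmono))
    abort_parse(path, ": non-monotonic time at line ", nonmono[1] + 2)
  med <- stats::median(dt)
  if (max(abs(dt - med)) > 0.005 * med)
    abort_parse(path, ": time-step jitter exceeds 0.5% of the median step")
  rate <- round(10 / med) / 10
  trial_trace(pp, rate = rate, duration = tt[length(tt)] - tt[1],
              subject_id = subject_id, condition = condition, trial = trial,
              direction = direction, device = device)
}

#' Write a cohort to a directory
#'
#' Stores every trace as `S{id}_{EO|EC}_T{n}_{ML|AP}_{FP|VR}.csv` plus a
#' `manifest.csv` indexing them. Refuses to touch a directory that already
#' holds a manifest unless `overwrite = TRUE`.
#'
#' @param cohort A `sway_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param overwrite Overwrite an existing cohort in `dir`?
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (!inherits(cohort, "sway_cohort"))
    abort_validation("cohort must be a sway_cohort")
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    abort_validation("cohort already exists at ", dir,
                     " (set overwrite = TRUE to replace it)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- cohort$manifest
  m$path <- paste0(m$trace_id, ".csv")
  for (k in seq_len(nrow(m)))
    write_trace(cohort$traces[[m$trace_id[k]]], file.path(dir, m$path[k]))
  utils::write.csv(m[, MANIFEST_COLS], manifest_path, row.names = FALSE,
                   quote = FALSE)
  invisible(manifest_path)
}

#' Load and validate a cohort directory
#'
#' Reads a `manifest.csv`, parses every referenced trace and checks the
#' structural invariants: no duplicate (subject, condition, trial,
#' direction, device) keys, every force-plate record paired with a headset
#' record and vice versa, every file present and parseable. All violations
#' are collected and reported together.
#'
#' @param manifest_path Path to `manifest.csv` (or to the directory
#'   containing it).
#' @return A `sway_cohort` (without a generating config).
#' @export
load_cohort <- function(manifest_path) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, "manifest.csv")
  if (!file.exists(manifest_path))
    abort_parse("manifest not found: ", manifest_path)
  root <- dirname(manifest_path)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(m) == 0) abort_validation("cohort manifest has no records")
  missing_cols <- setdiff(MANIFEST_COLS, names(m))
  if (length(missing_cols))
    abort_validation("manifest lacks columns: ",
                     paste(missing_cols, collapse = ", "))
  violations <- character()
  key <- with(m, paste(subject_id, condition, trial, direction, sep = "/"))
  full_key <- paste(key, m$device, sep = "/")
  dup <- unique(full_key[duplicated(full_key)])
  if (length(dup))
    violations <- c(violations, paste0("duplicate record: ", dup))
  for (k in unique(key)) {
    dev <- m$device[key == k]
    if (!"FP" %in% dev) violations <- c(violations, paste0("missing FP pair for ", k))
    if (!"VR" %in% dev) violations <- c(violations, paste0("missing VR pair for ", k))
  }
  traces <- list()
  for (r in seq_len(nrow(m))) {
    p <- file.path(root, m$path[r])
    tr <- tryCatch(
      read_trace(p, subject_id = m$subject_id[r], condition = m$condition[r],
                 trial = m$trial[r], direction = m$direction[r],
                 device = m$device[r]),
      error = function(e) conditionMessage(e))
    if (is.character(tr)) {
      violations <- c(violations, paste0(full_key[r], ": ", tr))
    } else {
      traces[[trace_key(m$subject_id[r], m$condition[r], m$trial[r],
                        m$direction[r], m$device[r])]] <- tr
    }
  }
  if (length(violations))
    abort_validation("invalid cohort:\n",
                     paste0("  - ", violations, collapse = "\n"))
  m$trace_id <- names(traces)[match(full_key, names(traces))]
  m$trace_id <- trace_key(m$subject_id, m$condition, m$trial, m$direction,
                          m$device)
  structure(list(config = NULL, manifest = m, traces = traces),
            class = "sway_cohort")
}
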