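# Test-retest reliability: two-way mixed-effects ANOVA (rows = subjects,
# columns = trials) and the consistency intraclass correlation with its
# F-pivot confidence interval.

#' Build a subjects-by-trials rating matrix
#'
#' Extracts one (device, metric, condition, direction) cell of the metric
#' table as an `n_subjects x n_trials` matrix, rows ordered by subject id.
#' Subjects with incomplete trials are dropped with a message.
#'
#' @param metrics A data frame from [metrics_table()].
#' @param device `"FP"` or `"VR"`.
#' @param metric_name `"NPL"`, `"RMS"` or `"P2P"`.
#' @param condition `"EO"` or `"EC"`.
#' @param direction `"ML"` or `"AP"`.
#' @param transform Optional function applied to the values (e.g. `log`).
#' @return A numeric matrix with subject-id row names and trial column
#'   names.
#' @export
build_rating_matrix <- function(metrics, device, metric_name, condition,
                                direction, transform = identity) {
  col <- metric_column(metric_name)
  sel <- metrics[metrics$device == device & metrics$condition == condition &
                   metrics$direction == direction, ]
  if (nrow(sel) == 0)
    abort_validation("no rows for (", device, ", ", metric_name, ", ",
                     condition, ", ", direction, ")")
  trials <- sort(unique(sel$trial))
  subjects <- sort(unique(sel$subject_id))
  mat <- matrix(NA_real_, length(subjects), length(trials),
                dimnames = list(subjects, paste0("T", trials)))
  mat[cbind(match(sel$subject_id, subjects), match(sel$trial, trials))] <-
    transform(sel[[col]])
  complete <- stats::complete.cases(mat)
  if (any(!complete))
    message("dropping ", sum(!complete), " subject(s) with incomplete trials: ",
            paste(subjects[!complete], collapse = ", "))
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 2)
    abort_validation("fewer than 2 complete subjects in cell")
  mat
}

#' Two-way mixed-effects intraclass correlation
#'
#' Decomposes an `n x k` subjects-by-trials matrix by two-way ANOVA
#' (subjects random, trials fixed) and returns the consistency ICC. The
#' single-measure form is
#' `(MS_rows - MS_err) / (MS_rows + (k - 1) * MS_err)` (ICC(3,1)); the
#' average-measure form (ICC(3,k)) is `(MS_rows - MS_err) / MS_rows`.
#' The `100(1-alpha)%` confidence interval uses the F pivot: with
#' `F = MS_rows / MS_err`, `df1 = n - 1`, `df2 = (n - 1)(k - 1)`,
#' `FL = F / qf(1 - alpha/2, df1, df2)` and
#' `FU = F * qf(1 - alpha/2, df2, df1)`, the single-measure bounds are
#' `(FL - 1) / (FL + k - 1)` and `(FU - 1) / (FU + k - 1)`. Reported lower
#' bounds are floored at 0 (the untruncated bound is kept in
#' `ci_low_raw`); point estimates are reported as computed, including
#' negative ones.
#'
#' Degenerate inputs: `MS_err = 0` with subject variation gives ICC 1 with
#' interval `[1, 1]`; a wholly constant matrix is flagged not estimable.
#'
#' @param mat Numeric matrix, subjects in rows (n >= 2), trials in columns
#'   (k >= 2), no missing cells.
#' @param alpha Two-sided interval level (default 0.05 for a 95% CI).
#' @param type `"single"` (default) or `"average"` measures.
#' @return An object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `ci_low_raw`, `classification`, the mean squares
#'   (`ms_rows`, `ms_cols`, `ms_error`), degrees of freedom, `n`, `k`,
#'   `type` and `estimable`.
#' @examples
#' m <- matrix(rnorm(60), 20, 3)
#' icc_two_way_mixed(m)
#' @export
icc_two_way_mixed <- function(mat, alpha = 0.05, type = c("single", "average")) {
  type <- match.arg(type)
  if (!is.matrix(mat) || !is.numeric(mat))
    abort_validation("mat must be a numeric matrix")
  if (anyNA(mat)) abort_validation("rating matrix has missing cells")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) abort_validation("need n >= 2 subjects and k >= 2 trials")
  grand <- mean(mat)
  row_means <- rowMeans(mat); col_means <- colMeans(mat)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  df_rows <- n - 1; df_cols <- k - 1; df_err <- (n - 1) * (k - 1)
  ms_rows <- ss_rows / df_rows
  ms_cols <- ss_cols / df_cols
  ms_err <- max(ss_err, 0) / df_err
  base <- list(ms_rows = ms_rows, ms_cols = ms_cols, ms_error = ms_err,
               df_rows = df_rows, df_cols = df_cols, df_error = df_err,
               n = n, k = k, alpha = alpha, type = type)
  finish <- function(icc, lo_raw, hi, estimable = TRUE) {
    structure(c(list(
      icc = icc, ci_low = if (estimable) max(lo_raw, 0) else NA_real_,
      ci_high = hi, ci_low_raw = lo_raw,
      classification = if (estimable) classify_icc(icc) else NA_character_,
      estimable = estimable), base), class = "icc_result")
  }
  if (ms_err <= 0) {
    if (ms_rows <= 0) {
      res <- finish(NA_real_, NA_real_, NA_real_, estimable = FALSE)
      return(res)
    }
    return(finish(1, 1, 1))
  }
  f_obs <- ms_rows / ms_err
  f_crit <- stats::qf(1 - alpha / 2, df_rows, df_err)
  f_crit_rev <- stats::qf(1 - alpha / 2, df_err, df_rows)
  fl <- f_obs / f_crit
  fu <- f_obs * f_crit_rev
  if (type == "single") {
    icc <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    icc <- (ms_rows - ms_err) / ms_rows
    lo <- 1 - 1 / fl
    hi <- 1 - 1 / fu
  }
  finish(icc, lo, hi)
}

#' @export
print.icc_result <- function(x, ...) {
  if (!x$estimable) {
    cat("<icc_result> not estimable (no variance in matrix)\n")
    return(invisible(x))
  }
  cat(sprintf("<icc_result> ICC(3,%s) = %.3f (95%% CI %.3f-%.3f), %s\n",
              if (x$type == "single") "1" else "k", x$icc, x$ci_low,
              x$ci_high, x$classification))
  cat(sprintf("  n = %d subjects, k = %d trials; MS_rows = %.4g, MS_err = %.4g\n",
              x$n, x$k, x$ms_rows, x$ms_error))
  invisible(x)
}

#' Classify an ICC into the standard reliability bands
#'
#' Bands: poor below 0.5; moderate in [0.5, 0.75); good in [0.75, 0.90];
#' excellent above 0.90. Negative estimates are poor.
#'
#' @param icc ICC point estimate (<= 1).
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @examples
#' classify_icc(0.448)
#' classify_icc(0.95)
#' @export
classify_icc <- function(icc) {
  if (!is.numeric(icc) || length(icc) != 1L || is.na(icc) || icc > 1 + 1e-12)
    abort_validation("icc must be a single number <= 1")
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc <= 0.90) "good"
  else "excellent"
}

#' Reliability table across all cells
#'
#' Runs [icc_two_way_mixed()] on every (condition, direction) x (device,
#' metric) cell of a metric table — with the default full design, a 4-row
#' by 6-column grid of ICCs. Per-cell failures are returned as flagged
#' rows, never aborting the rest of the table.
#'
#' @param metrics A data frame from [metrics_table()].
#' @param devices,conditions,directions,metric_names Cells to compute
#'   (defaults: everything present / all three metrics).
#' @param alpha Interval level.
#' @param type `"single"` or `"average"` measures.
#' @return A data frame with one row per cell: `condition`, `direction`,
#'   `device`, `metric`, `icc`, `ci_low`, `ci_high`, `classification`,
#'   `n`, `k`.
#' @export
reliability_table <- function(metrics, devices = c("FP", "VR"),
                              conditions = unique(metrics$condition),
                              directions = unique(metrics$direction),
                              metric_names = c("NPL", "RMS", "P2P"),
                              alpha = 0.05, type = "single") {
  grid <- expand.grid(condition = conditions, direction = directions,
                      device = devices, metric = metric_names,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- data.frame(condition = g$condition, direction = g$direction,
                      device = g$device, metric = g$metric,
                      icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      classification = NA_character_, n = NA_integer_,
                      k = NA_integer_, note = "", stringsAsFactors = FALSE)
    res <- tryCatch({
      mat <- build_rating_matrix(metrics, g$device, g$metric, g$condition,
                                 g$direction)
      icc_two_way_mixed(mat, alpha = alpha, type = type)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$note <- res
    } else if (!res$estimable) {
      out$n <- res$n; out$k <- res$k; out$note <- "not estimable"
    } else {
      out$icc <- res$icc; out$ci_low <- res$ci_low; out$ci_high <- res$ci_high
      out$classification <- res$classification
      out$n <- res$n; out$k <- res$k
    }
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
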