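# Device agreement: ordinary least squares of each COP-derived metric on
# the paired headset-derived metric, per (metric, condition, direction),
# for the first trial and for 3-trial averages.

#' Subject-aligned paired metric vectors for one cell
#'
#' Builds the (headset predictor, COP response) pairs for one (metric,
#' condition, direction) cell. `"first_trial"` uses trial 1 only;
#' `"mean_of_3"` averages all available trials per subject (subjects
#' missing any trial on either device are dropped with a message).
#'
#' @param metrics A data frame from [metrics_table()].
#' @param metric_name `"NPL"`, `"RMS"` or `"P2P"`.
#' @param condition `"EO"` or `"EC"`.
#' @param direction `"ML"` or `"AP"`.
#' @param aggregation `"first_trial"` or `"mean_of_3"`.
#' @return A list of class `paired_metrics`: `x` (VR values), `y` (FP
#'   values), `subject_id`, and the cell key.
#' @export
aggregate_pairs <- function(metrics, metric_name, condition, direction,
                            aggregation = c("mean_of_3", "first_trial")) {
  aggregation <- match.arg(aggregation)
  col <- metric_column(metric_name)
  sel <- metrics[metrics$condition == condition &
                   metrics$direction == direction, ]
  if (nrow(sel) == 0)
    abort_validation("no rows for (", metric_name, ", ", condition, ", ",
                     direction, ")")
  n_trials <- length(unique(sel$trial))
  one_device <- function(device) {
    d <- sel[sel$device == device, ]
    if (aggregation == "first_trial") {
      d <- d[d$trial == 1L, ]
      if (nrow(d) == 0) abort_validation("no trial-1 records for device ", device)
      stats::setNames(d[[col]], d$subject_id)
    } else {
      counts <- table(d$subject_id)
      keep <- names(counts)[counts == n_trials]
      d <- d[d$subject_id %in% keep, ]
      vapply(split(d[[col]], d$subject_id), mean, numeric(1))
    }
  }
  x <- one_device("VR"); y <- one_device("FP")
  common <- sort(intersect(names(x), names(y)))
  dropped <- length(union(names(x), names(y))) - length(common)
  if (dropped > 0)
    message("dropping ", dropped, " subject(s) without complete pairs")
  if (length(common) < 3)
    abort_validation("fewer than 3 complete subject pairs in cell")
  structure(list(x = unname(x[common]), y = unname(y[common]),
                 subject_id = common, metric = metric_name,
                 condition = condition, direction = direction,
                 aggregation = aggregation), class = "paired_metrics")
}

#' Univariate agreement regression for one cell
#'
#' Ordinary least squares of the COP metric on the headset metric,
#' `y = a + b x`, reporting the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (equal to the squared Pearson correlation),
#' the regression F-test p-value (`F = (n - 2) R^2 / (1 - R^2)` on
#' (1, n - 2) df, equivalent to the slope t-test), and the printed
#' significance tier: `"p<.001"`, `"p<.05"` or `"ns"`.
#'
#' @param pairs A `paired_metrics` object from [aggregate_pairs()].
#' @param alpha Significance level for the `"p<.05"` tier (fixed tiers at
#'   .001 and .05 are reported regardless).
#' @return A list of class `agreement_result`: `slope`, `intercept`, `r2`,
#'   `p_value`, `tier`, `n`, `estimable`, plus the cell key.
#' @examples
#' p <- structure(list(x = 1:5, y = c(1.2, 1.9, 3.3, 3.8, 5.1),
#'                     subject_id = paste0("S", 1:5), metric = "RMS",
#'                     condition = "EO", direction = "ML",
#'                     aggregation = "mean_of_3"), class = "paired_metrics")
#' fit_univariate(p)
#' @export
fit_univariate <- function(pairs, alpha = 0.05) {
  if (!inherits(pairs, "paired_metrics"))
    abort_validation("pairs must come from aggregate_pairs()")
  x <- pairs$x; y <- pairs$y; n <- length(x)
  if (n < 3) abort_validation("need at least 3 pairs")
  key <- pairs[c("metric", "condition", "direction", "aggregation")]
  if (stats::var(x) == 0) {
    return(structure(c(list(slope = NA_real_, intercept = NA_real_,
                            r2 = NA_real_, p_value = NA_real_, tier = NA_character_,
                            n = n, estimable = FALSE,
                            note = "predictor has zero variance"), key),
                     class = "agreement_result"))
  }
  if (stats::var(y) == 0) {
    return(structure(c(list(slope = 0, intercept = y[1], r2 = 0,
                            p_value = NA_real_, tier = NA_character_, n = n,
                            estimable = FALSE,
                            note = "response has zero variance"), key),
                     class = "agreement_result"))
  }
  fit <- stats::lm(y ~ x)
  r2 <- stats::cor(x, y)^2
  f_stat <- (n - 2) * r2 / (1 - r2)
  p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  tier <- if (p < 0.001) "p<.001" else if (p < alpha) "p<.05" else "ns"
  structure(c(list(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r2 = r2, p_value = p, tier = tier, n = n,
                   estimable = TRUE, note = ""), key),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> %s %s/%s (%s)\n", x$metric, x$condition,
              x$direction, x$aggregation))
  if (!x$estimable) {
    cat("  not estimable: ", x$note, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  COP = %.4f + %.4f * VR, R2 = %.3f, p = %.3g (%s), n = %d\n",
              x$intercept, x$slope, x$r2, x$p_value, x$tier, x$n))
  invisible(x)
}

#' Agreement table across all cells
#'
#' Runs [fit_univariate()] on every (metric, aggregation, condition,
#' direction) cell — with the full design, 3 metrics x 2 aggregations x 4
#' condition-direction cells = 24 regressions. Per-cell failures become
#' flagged rows.
#'
#' @param metrics A data frame from [metrics_table()].
#' @param conditions,directions,metric_names,aggregations Cells to compute.
#' @param alpha Significance level.
#' @return A data frame with one row per cell: `metric`, `aggregation`,
#'   `condition`, `direction`, `n`, `slope`, `intercept`, `r2`, `p_value`,
#'   `tier`.
#' @export
agreement_table <- function(metrics,
                            conditions = unique(metrics$condition),
                            directions = unique(metrics$direction),
                            metric_names = c("NPL", "RMS", "P2P"),
                            aggregations = c("first_trial", "mean_of_3"),
                            alpha = 0.05) {
  if (is.null(metrics) || nrow(metrics) == 0)
    abort_validation("metrics table is empty")
  grid <- expand.grid(metric = metric_names, aggregation = aggregations,
                      condition = conditions, direction = directions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    out <- data.frame(metric = g$metric, aggregation = g$aggregation,
                      condition = g$condition, direction = g$direction,
                      n = NA_integer_, slope = NA_real_, intercept = NA_real_,
                      r2 = NA_real_, p_value = NA_real_, tier = NA_character_,
                      note = "", stringsAsFactors = FALSE)
    res <- tryCatch(
      fit_univariate(aggregate_pairs(metrics, g$metric, g$condition,
                                     g$direction, g$aggregation),
                     alpha = alpha),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$note <- res
    } else {
      out$n <- res$n; out$slope <- res$slope; out$intercept <- res$intercept
      out$r2 <- res$r2; out$p_value <- res$p_value; out$tier <- res$tier
      out$note <- res$note
    }
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
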