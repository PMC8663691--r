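# One-command orchestration: cohort -> metrics -> reliability -> agreement
# -> report bundle.

#' Pipeline run configuration
#'
#' Exactly one cohort source must be given: either a simulation
#' configuration (`cohort`) or an existing cohort directory (`cohort_dir`).
#'
#' @param out_dir Output directory for the report bundle.
#' @param cohort A [cohort_config()] to simulate, or `NULL`.
#' @param cohort_dir Directory holding an existing cohort, or `NULL`.
#' @param alpha Significance / interval level.
#' @param icc_type `"single"` or `"average"` measures.
#' @param report_format `"markdown"` or `"csv"` (CSV tables are always
#'   written; `"markdown"` additionally renders `report.md`).
#' @param plots Write per-trial FP/VR overlay plots for the first subject?
#' @param overwrite Overwrite existing pipeline outputs in `out_dir`?
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, cohort = NULL, cohort_dir = NULL,
                       alpha = 0.05, icc_type = c("single", "average"),
                       report_format = c("markdown", "csv"),
                       plots = FALSE, overwrite = FALSE) {
  if (is.null(cohort) == is.null(cohort_dir))
    abort_validation("give exactly one of cohort (a cohort_config) or cohort_dir")
  if (!is.null(cohort) && !inherits(cohort, "cohort_config"))
    abort_validation("cohort must be a cohort_config object")
  structure(list(out_dir = out_dir, cohort = cohort, cohort_dir = cohort_dir,
                 alpha = check_scalar(alpha, "alpha", 0, strict = TRUE),
                 icc_type = match.arg(icc_type),
                 report_format = match.arg(report_format),
                 plots = isTRUE(plots), overwrite = isTRUE(overwrite)),
            class = "run_config")
}

#' Run the full validation pipeline
#'
#' Simulates (or loads) a cohort, computes the sway-metric table, the
#' reliability (ICC) table and the device-agreement (regression) table,
#' and writes the bundle to `out_dir`: `metrics.csv`, `reliability.csv`,
#' `agreement.csv`, `run_log.json`, a `report.md` laying the two result
#' tables out in the conventional wide shapes, and optional overlay plots.
#' Any stage failure aborts the run with the stage named and removes the
#' partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the three tables, the headline summary
#'   and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    abort_validation("config must come from run_config()")
  out <- config$out_dir
  outputs <- file.path(out, c("metrics.csv", "reliability.csv",
                              "agreement.csv", "report.md", "run_log.json"))
  if (any(file.exists(outputs)) && !config$overwrite)
    abort_validation("pipeline outputs already exist in ", out,
                     " (set overwrite = TRUE)")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("cohort", {
    if (!is.null(config$cohort)) generate_cohort(config$cohort)
    else load_cohort(config$cohort_dir)
  })
  metrics <- stage("metrics", metrics_table(cohort))
  rel <- stage("reliability",
               reliability_table(metrics, alpha = config$alpha,
                                 type = config$icc_type))
  agr <- stage("agreement", agreement_table(metrics, alpha = config$alpha))
  headline <- stage("report", report_headline(rel, agr))
  stage("write", {
    utils::write.csv(metrics, outputs[1], row.names = FALSE)
    written <<- c(written, outputs[1])
    utils::write.csv(rel, outputs[2], row.names = FALSE)
    written <<- c(written, outputs[2])
    utils::write.csv(agr, outputs[3], row.names = FALSE)
    written <<- c(written, outputs[3])
    if (config$report_format == "markdown") {
      writeLines(render_report(rel, agr, headline), outputs[4])
      written <<- c(written, outputs[4])
    }
    log <- list(
      package_version = as.character(utils::packageVersion("swayval")),
      timestamp = format(Sys.time(), tz = "UTC"),
      seed = if (!is.null(config$cohort)) config$cohort$seed else NA,
      cohort_source = if (!is.null(config$cohort)) "simulated" else config$cohort_dir,
      alpha = config$alpha, icc_type = config$icc_type,
      parameters = if (!is.null(config$cohort))
        c(unclass(config$cohort$process), unclass(config$cohort$headset))
      else NULL,
      n_traces = nrow(cohort$manifest),
      dropped_or_flagged = c(rel$note[nzchar(rel$note)],
                             agr$note[nzchar(agr$note)]))
    jsonlite::write_json(log, outputs[5], auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    written <<- c(written, outputs[5])
    if (config$plots) write_overlay_plots(cohort, out)
  })
  invisible(list(metrics = metrics, reliability = rel, agreement = agr,
                 headline = headline, paths = outputs))
}

# Qualitative summary of the run: which measures agree across devices and
# which device is the more repeatable, stated as orderings of cell means.
report_headline <- function(rel, agr) {
  m3 <- agr[agr$aggregation == "mean_of_3" & !is.na(agr$r2), ]
  mean_r2 <- tapply(m3$r2, m3$metric, mean)
  npl_weakest_all_cells <- all(vapply(split(m3, paste(m3$condition, m3$direction)),
    function(cell) {
      npl <- cell$r2[cell$metric == "NPL"]
      length(npl) == 1 &&
        all(npl < cell$r2[cell$metric != "NPL"])
    }, logical(1)))
  npl_icc <- rel[rel$metric == "NPL" & !is.na(rel$icc), ]
  icc_by_dev <- tapply(npl_icc$icc, npl_icc$device, mean)
  list(
    mean_r2 = mean_r2,
    npl_agreement_weakest = isTRUE(npl_weakest_all_cells),
    amplitude_metrics_agree = isTRUE(all(mean_r2[c("RMS", "P2P")] >
                                           mean_r2["NPL"])),
    fp_npl_more_reliable = isTRUE(icc_by_dev["FP"] > icc_by_dev["VR"]),
    mean_npl_icc = icc_by_dev)
}

fmt_icc_cell <- function(row) {
  if (is.na(row$icc)) return("---")
  sprintf("%.3f (%.3f-%.3f)", row$icc, row$ci_low, row$ci_high)
}

fmt_r2_cell <- function(row) {
  if (is.na(row$r2)) return("---")
  mark <- switch(row$tier, "p<.001" = "^a^", "p<.05" = "^b^", "")
  sprintf("%.3f%s", row$r2, mark)
}

md_table <- function(header, rows) {
  c(paste0("| ", paste(header, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(header)), collapse = "|"), "|"),
    vapply(rows, function(r) paste0("| ", paste(r, collapse = " | "), " |"),
           character(1)))
}

# Wide reliability layout: condition (direction) rows, device-by-metric
# columns.
format_reliability_md <- function(rel) {
  conds <- unique(rel[, c("condition", "direction")])
  cols <- expand.grid(device = c("FP", "VR"), metric = c("NPL", "RMS", "P2P"),
                      stringsAsFactors = FALSE)[, 2:1]
  header <- c("Condition (direction)",
              sprintf("%s of %s outputs", cols$metric, cols$device))
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    cells <- vapply(seq_len(nrow(cols)), function(j) {
      r <- rel[rel$condition == conds$condition[i] &
                 rel$direction == conds$direction[i] &
                 rel$device == cols$device[j] & rel$metric == cols$metric[j], ]
      if (nrow(r) == 1) fmt_icc_cell(r) else "---"
    }, character(1))
    c(sprintf("%s (%s)", conds$condition[i],
              sub("ML", "M-L", sub("AP", "A-P", conds$direction[i]))), cells)
  })
  md_table(header, rows)
}

# Wide agreement layout: metric x aggregation row groups, condition x
# direction columns.
format_agreement_md <- function(agr) {
  cells <- unique(agr[, c("condition", "direction")])
  header <- c("COP ~ VR outcome",
              sprintf("%s, %s sway", cells$condition,
                      sub("ML", "M-L", sub("AP", "A-P", cells$direction))))
  rows <- list()
  for (m in unique(agr$metric)) {
    for (a in c("first_trial", "mean_of_3")) {
      vals <- vapply(seq_len(nrow(cells)), function(j) {
        r <- agr[agr$metric == m & agr$aggregation == a &
                   agr$condition == cells$condition[j] &
                   agr$direction == cells$direction[j], ]
        if (nrow(r) == 1) fmt_r2_cell(r) else "---"
      }, character(1))
      lab <- if (a == "first_trial") "first trial" else "3-trial average"
      rows[[length(rows) + 1]] <- c(sprintf("%s, %s", m, lab), vals)
    }
  }
  md_table(header, rows)
}

render_report <- function(rel, agr, headline) {
  c("# Headset vs force-plate validation report", "",
    "## Test-retest reliability, ICC (95% CI)", "",
    format_reliability_md(rel), "",
    "## Device agreement, R-squared of COP predicted from headset output", "",
    format_agreement_md(agr), "",
    "^a^ p < .001; ^b^ p < .05.", "",
    "## Headline", "",
    sprintf("- Mean 3-trial-average agreement R^2 by measure: %s.",
            paste(sprintf("%s = %.3f", names(headline$mean_r2),
                          headline$mean_r2), collapse = ", ")),
    sprintf("- Path-length (NPL) agreement weakest in every cell: %s.",
            headline$npl_agreement_weakest),
    sprintf("- Force-plate NPL more repeatable than headset NPL (mean ICC %.3f vs %.3f): %s.",
            headline$mean_npl_icc["FP"], headline$mean_npl_icc["VR"],
            headline$fp_npl_more_reliable))
}

#' Overlay plot of paired traces
#'
#' Diagnostic plot in the style of raw-trajectory figures: force-plate and
#' headset position series for one subject, condition and trial, one panel
#' per sway direction.
#'
#' @param cohort A `sway_cohort`.
#' @param subject_id,condition,trial Which record to draw.
#' @return Invisibly `NULL`; draws on the current device.
#' @export
plot_trace_overlay <- function(cohort, subject_id, condition = "EO",
                               trial = 1) {
  dirs <- intersect(c("ML", "AP"), unique(cohort$manifest$direction))
  old <- graphics::par(mfrow = c(length(dirs), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (d in dirs) {
    fp <- cohort$traces[[trace_key(subject_id, condition, trial, d, "FP")]]
    vr <- cohort$traces[[trace_key(subject_id, condition, trial, d, "VR")]]
    if (is.null(fp) || is.null(vr))
      abort_validation("no such record: ", subject_id, " ", condition,
                       " T", trial, " ", d)
    t_fp <- (seq_along(fp$values) - 1) / fp$rate
    t_vr <- (seq_along(vr$values) - 1) / vr$rate
    graphics::plot(t_fp, fp$values, type = "l", col = "darkgreen",
                   xlab = "time (s)", ylab = "position (cm)",
                   main = sprintf("%s %s trial %d, %s sway", subject_id,
                                  condition, trial, d),
                   ylim = range(fp$values, vr$values))
    graphics::lines(t_vr, vr$values, col = "blue")
    graphics::legend("topright", legend = c("force plate", "headset"),
                     col = c("darkgreen", "blue"), lty = 1, bty = "n")
  }
  invisible(NULL)
}

write_overlay_plots <- function(cohort, out_dir) {
  m <- cohort$manifest
  sid <- sort(unique(m$subject_id))[1]
  for (cond in unique(m$condition)) {
    f <- file.path(out_dir, sprintf("overlay_%s_%s_T1.png", sid, cond))
    grDevices::png(f, width = 900, height = 600)
    plot_trace_overlay(cohort, sid, cond, 1)
    grDevices::dev.off()
  }
}

#' Read a flat key = value run configuration file
#'
#' Parses a plain-text configuration mirroring [cohort_config()] /
#' [run_config()] fields (`n_subjects = 20`, `sigma_base = 0.3`,
#' `gain = 1.5`, ...; `#` starts a comment). Unknown keys are rejected.
#'
#' @param path Configuration file.
#' @return A named list of parsed values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_parse("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  known_num <- c("n_subjects", "n_trials", "seed", "theta", "sigma_base",
                 "ec_multiplier", "tau2", "omega2", "duration", "fp_rate",
                 "vr_rate", "ap_anisotropy", "gain", "smooth_cutoff",
                 "jitter_sd", "drift_sd", "jitter_subj_sd", "jitter_trial_sd",
                 "alpha")
  known_chr <- c("conditions", "directions", "icc_type", "report_format")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      abort_parse("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (key %in% known_num) {
      out[[key]] <- as.numeric(val)
    } else if (key %in% known_chr) {
      out[[key]] <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else {
      abort_parse("unknown config key: '", key, "'")
    }
  }
  out
}

#' Build a cohort_config from a parsed flat configuration
#'
#' @param cfg A named list from [read_run_config()].
#' @param seed Optional override of the configured seed.
#' @return A [cohort_config()].
#' @export
config_from_flat <- function(cfg, seed = NULL) {
  take <- function(keys) cfg[intersect(keys, names(cfg))]
  process <- do.call(sway_process_params,
                     take(c("theta", "sigma_base", "ec_multiplier", "tau2",
                            "omega2", "duration", "fp_rate", "vr_rate",
                            "ap_anisotropy")))
  headset <- do.call(headset_params,
                     take(c("gain", "smooth_cutoff", "jitter_sd", "drift_sd",
                            "jitter_subj_sd", "jitter_trial_sd")))
  args <- take(c("n_subjects", "n_trials", "conditions", "directions", "seed"))
  if (!is.null(seed)) args$seed <- seed
  do.call(cohort_config, c(args, list(process = process, headset = headset)))
}
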