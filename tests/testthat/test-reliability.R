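# Two-way mixed-effects ICC: ANOVA decomposition, F-pivot interval,
# classification bands, table assembly.

test_that("rating matrices have the right shape and drop incomplete subjects", {
  met <- metrics_table(small_cohort(n_subjects = 4, seed = 14))
  m <- build_rating_matrix(met, "FP", "RMS", "EC", "ML")
  expect_equal(dim(m), c(4, 3))
  expect_identical(rownames(m), sprintf("S%02d", 1:4))
  # remove one subject's trial 3 -> that subject is dropped with a message
  met2 <- met[!(met$subject_id == "S02" & met$trial == 3), ]
  expect_message(m2 <- build_rating_matrix(met2, "FP", "RMS", "EC", "ML"),
                 "S02")
  expect_equal(dim(m2), c(3, 3))
  expect_error(build_rating_matrix(met, "FP", "AREA", "EC", "ML"),
               class = "swayval_validation_error")
})

test_that("consistency ICC is 1 when trials agree up to a column shift", {
  ident <- matrix(rep(c(1, 2, 3, 7), 3), 4, 3)
  r <- icc_two_way_mixed(ident)
  expect_equal(r$icc, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  # pure additive trial effect: consistency ignores column main effects
  shifted <- outer(1:4, 0:2, `+`)
  expect_equal(icc_two_way_mixed(shifted)$icc, 1)
})

test_that("a wholly constant matrix is flagged not estimable", {
  r <- icc_two_way_mixed(matrix(2, 5, 3))
  expect_false(r$estimable)
  expect_true(is.na(r$icc))
})

test_that("ICC and CI match the explicit sums-of-squares oracle", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      n <- sample(4:30, 1); k <- sample(2:5, 1)
      mat <- matrix(rnorm(n * k), n, k) +
        rnorm(n, 0, runif(1, 0, 2))          # random subject effects
      r <- icc_two_way_mixed(mat)
      o <- icc_oracle(mat)
      expect_equal(r$icc, o$icc, tolerance = 1e-10)
      expect_equal(r$ci_low_raw, o$lo, tolerance = 1e-10)
      expect_equal(r$ci_high, o$hi, tolerance = 1e-10)
    }
  })
})

test_that("mean squares agree with R's two-way ANOVA decomposition", {
  for (s in 1:10) {
    mat <- sim_icc_matrix(12, 3, 0.6, seed = 500 + s)
    r <- icc_two_way_mixed(mat)
    d <- data.frame(y = as.vector(mat),
                    subject = factor(row(mat)), trial = factor(col(mat)))
    ms <- summary(stats::aov(y ~ subject + trial, data = d))[[1]][["Mean Sq"]]
    expect_equal(r$ms_rows, ms[1], tolerance = 1e-10)
    expect_equal(r$ms_cols, ms[2], tolerance = 1e-10)
    expect_equal(r$ms_error, ms[3], tolerance = 1e-10)
  }
})

test_that("ICC3 estimates match pingouin's reference implementation", {
  # batch a handful of matrices through the Python reference in one call
  mats <- lapply(1:5, function(s) sim_icc_matrix(10, 3, 0.5, seed = 700 + s))
  dir <- withr::local_tempdir()
  for (i in seq_along(mats)) {
    m <- mats[[i]]
    utils::write.csv(data.frame(subject = as.vector(row(m)),
                                trial = as.vector(col(m)),
                                y = as.vector(m)),
                     file.path(dir, sprintf("m%d.csv", i)), row.names = FALSE)
  }
  script <- paste(
    "import sys, glob, pandas as pd, pingouin as pg",
    "for f in sorted(glob.glob(sys.argv[1] + '/m*.csv')):",
    "    d = pd.read_csv(f)",
    "    icc = pg.intraclass_corr(d, targets='subject', raters='trial',",
    "                             ratings='y')",
    "    sel = icc.Type.isin(['ICC3', 'ICC(C,1)'])",
    "    print(icc.loc[sel, 'ICC'].values[0])",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(dir)),
            stdout = TRUE, stderr = FALSE))
  ref <- as.numeric(out)
  ours <- vapply(mats, function(m) icc_two_way_mixed(m)$icc, numeric(1))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("consistency ICC is invariant under affine transforms", {
  mat <- sim_icc_matrix(15, 3, 0.7, seed = 31)
  r <- icc_two_way_mixed(mat)
  r2 <- icc_two_way_mixed(-3.2 * mat + 11)
  expect_equal(r2$icc, r$icc, tolerance = 1e-12)
  expect_equal(r2$ci_low_raw, r$ci_low_raw, tolerance = 1e-12)
  expect_equal(r2$ci_high, r$ci_high, tolerance = 1e-12)
})

test_that("ICC increases with between-subject spread at fixed error", {
  base <- sim_icc_matrix(20, 3, 0.3, seed = 131)
  stretch <- function(c) base + (c - 1) * rowMeans(base)
  iccs <- vapply(c(1, 2, 4), function(c) icc_two_way_mixed(stretch(c))$icc,
                 numeric(1))
  expect_true(all(diff(iccs) > 0))
})

test_that("average-measure ICC exceeds single-measure ICC", {
  mat <- sim_icc_matrix(20, 3, 0.5, seed = 41)
  single <- icc_two_way_mixed(mat, type = "single")
  avg <- icc_two_way_mixed(mat, type = "average")
  expect_gt(avg$icc, single$icc)
  k <- ncol(mat)
  expect_equal(avg$icc, k * single$icc / (1 + (k - 1) * single$icc),
               tolerance = 1e-10)
})

test_that("classification bands use the printed cut-points", {
  expect_identical(classify_icc(0.448), "poor")
  expect_identical(classify_icc(-0.2), "poor")
  expect_identical(classify_icc(0.5), "moderate")
  expect_identical(classify_icc(0.7499), "moderate")
  expect_identical(classify_icc(0.75), "good")
  expect_identical(classify_icc(0.90), "good")
  expect_identical(classify_icc(0.9001), "excellent")
  expect_identical(classify_icc(0.95), "excellent")
  expect_error(classify_icc(1.2), class = "swayval_validation_error")
})

test_that("negative point estimates are reported but lower bounds floored", {
  # columns strongly anticorrelated across subjects -> negative ICC
  mat <- cbind(1:6, 6:1, c(3, 1, 5, 2, 6, 4))
  r <- icc_two_way_mixed(mat)
  expect_lt(r$icc, 0)
  expect_identical(r$classification, "poor")
  expect_lt(r$ci_low_raw, 0)
  expect_equal(r$ci_low, 0)
})

test_that("reliability_table covers every cell and never aborts wholesale", {
  met <- metrics_table(small_cohort(n_subjects = 5, seed = 17))
  tab <- reliability_table(met)
  expect_equal(nrow(tab), 2 * 2 * 2 * 3)
  expect_false(anyNA(tab$icc))
  expect_true(all(tab$classification %in%
                    c("poor", "moderate", "good", "excellent")))
  # a constant metric column yields a flagged cell, not an error
  met2 <- met
  met2$p2p_cm[met2$device == "VR"] <- 1
  tab2 <- reliability_table(met2)
  bad <- tab2[tab2$device == "VR" & tab2$metric == "P2P", ]
  expect_true(all(bad$note == "not estimable"))
  expect_false(anyNA(tab2$icc[tab2$metric != "P2P" | tab2$device != "VR"]))
})

test_that("overwhelming trial variance drives classifications to poor", {
  proc <- sway_process_params(tau2 = 0.001, omega2 = 0.5)
  met <- metrics_table(generate_cohort(
    cohort_config(n_subjects = 12, conditions = "EO", directions = "ML",
                  seed = 19, process = proc)))
  tab <- reliability_table(met, conditions = "EO", directions = "ML",
                           metric_names = "RMS")
  expect_true(all(tab$classification == "poor"))
})
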