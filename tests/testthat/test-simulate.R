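# The synthetic cohort generator: OU sway process, headset observation
# model, amplitude random effects, cohort assembly.

pp <- sway_process_params()

test_that("COP traces are deterministic under seed and linear in amplitude", {
  a <- simulate_cop_trace(pp, 0.3, seed = 11)
  b <- simulate_cop_trace(pp, 0.3, seed = 11)
  expect_identical(a$values, b$values)
  doubled <- simulate_cop_trace(pp, 0.6, seed = 11)
  expect_equal(doubled$values, 2 * a$values, tolerance = 1e-12)
  expect_length(a$values, round(pp$duration * pp$fp_rate) + 1)
  expect_equal(a$rate, pp$fp_rate)
})

test_that("OU process approaches white noise for large mean reversion", {
  fast <- sway_process_params(theta = 1000)
  tr <- simulate_cop_trace(fast, 1, seed = 3)
  r1 <- stats::cor(tr$values[-1], tr$values[-length(tr$values)])
  expect_lt(abs(r1), 0.1)
})

test_that("OU marginal SD tracks amplitude_scale", {
  # pool several trials; stationary SD should match the requested scale
  sds <- vapply(1:10, function(s) sd(simulate_cop_trace(pp, 0.5, s)$values),
                numeric(1))
  expect_equal(mean(sds), 0.5, tolerance = 0.1)
})

test_that("COP simulation rejects bad inputs", {
  expect_error(simulate_cop_trace(pp, -1, 1), class = "swayval_validation_error")
  expect_error(simulate_cop_trace(list(), 1, 1),
               class = "swayval_validation_error")
  expect_error(sway_process_params(theta = -1),
               class = "swayval_validation_error")
  expect_error(sway_process_params(fp_rate = 10, vr_rate = 10),
               class = "swayval_validation_error")
})

test_that("identity headset observation reproduces the decimated COP", {
  # a slow process (theta = 2/s) keeps nearly all its power below a
  # near-Nyquist cutoff, so the identity observation preserves amplitude
  slow <- sway_process_params(theta = 2)
  ident <- headset_params(gain = 1, jitter_sd = 0, drift_sd = 0,
                          smooth_cutoff = 4.5)
  rms_ratio <- vapply(1:10, function(s) {
    cop <- simulate_cop_trace(slow, 0.3, seed = s)
    root_mean_square(observe_headset_trace(cop, ident, seed = 1)) /
      root_mean_square(cop)
  }, numeric(1))
  expect_equal(mean(rms_ratio), 1, tolerance = 0.05)
  cop <- simulate_cop_trace(slow, 0.3, seed = 5)
  vr <- observe_headset_trace(cop, ident, seed = 1)
  expect_length(vr$values, round(slow$duration * slow$vr_rate) + 1)
  # exact linearity in gain when noise-free
  vr3 <- observe_headset_trace(cop, headset_params(gain = 3, jitter_sd = 0,
                                                   drift_sd = 0,
                                                   smooth_cutoff = 4.5),
                               seed = 1)
  expect_equal(vr3$values, 3 * vr$values, tolerance = 1e-12)
})

test_that("headset jitter adds path length", {
  quiet <- headset_params(gain = 1, jitter_sd = 0, drift_sd = 0)
  noisy <- headset_params(gain = 1, jitter_sd = 0.3, drift_sd = 0)
  wins <- vapply(1:100, function(s) {
    cop <- simulate_cop_trace(pp, 0.3, seed = 1000 + s)
    normalized_path_length(observe_headset_trace(cop, noisy, seed = s)) >
      normalized_path_length(observe_headset_trace(cop, quiet, seed = s))
  }, logical(1))
  expect_true(all(wins))
})

test_that("non-divisor headset rate falls back to interpolation", {
  cop <- simulate_cop_trace(pp, 0.3, seed = 2)
  expect_message(
    vr <- observe_headset_trace(cop, headset_params(smooth_cutoff = 1),
                                seed = 1, vr_rate = 7),
    "interpolation")
  expect_length(vr$values, round(pp$duration * 7) + 1)
})

test_that("subject_amplitude implements the log-normal random-effects model", {
  flat <- sway_process_params(tau2 = 0, omega2 = 0)
  expect_equal(subject_amplitude("EO", 0, 0, flat), flat$sigma_base)
  expect_equal(subject_amplitude("EC", 0, 0, flat),
               flat$sigma_base * flat$ec_multiplier)
  expect_equal(subject_amplitude("EO", 0.2, -0.1, pp),
               pp$sigma_base * exp(0.1))
})

test_that("log-amplitude ICC dial is recovered at tau2 = omega2", {
  # equal variance components target ICC 0.5 for log sway amplitude
  dial <- sway_process_params(tau2 = 0.04, omega2 = 0.04)
  cfg <- cohort_config(n_subjects = 500, conditions = "EO",
                       directions = "ML", seed = 77, process = dial)
  met <- metrics_table(generate_cohort(cfg))
  m <- build_rating_matrix(met, "FP", "RMS", "EO", "ML", transform = log)
  expect_lt(abs(icc_two_way_mixed(m)$icc - 0.5), 0.05)
})

test_that("cohort has the full paired design and is reproducible", {
  coh <- generate_cohort(cohort_config(seed = 9))
  expect_equal(nrow(coh$manifest), 20 * 2 * 2 * 3 * 2)
  key <- with(coh$manifest,
              paste(subject_id, condition, trial, direction, sep = "/"))
  expect_true(all(table(key) == 2))       # FP + VR for every record
  coh2 <- generate_cohort(cohort_config(seed = 9))
  expect_identical(lapply(coh$traces, `[[`, "values"),
                   lapply(coh2$traces, `[[`, "values"))
})

test_that("adding subjects leaves existing subjects' traces untouched", {
  coh4 <- small_cohort(n_subjects = 4, seed = 13)
  coh6 <- small_cohort(n_subjects = 6, seed = 13)
  shared <- names(coh4$traces)
  expect_identical(lapply(coh4$traces[shared], `[[`, "values"),
                   lapply(coh6$traces[shared], `[[`, "values"))
})

test_that("sigma_base rescales every trace (scale equivariance)", {
  base <- small_cohort(seed = 21)
  scaled <- generate_cohort(cohort_config(
    n_subjects = 4, seed = 21,
    process = sway_process_params(sigma_base = 2 * pp$sigma_base)))
  fp_keys <- base$manifest$trace_id[base$manifest$device == "FP"]
  for (k in fp_keys[1:6])
    expect_equal(scaled$traces[[k]]$values, 2 * base$traces[[k]]$values,
                 tolerance = 1e-12)
})

test_that("eyes-closed multiplier raises cohort-mean RMS by its factor", {
  proc <- sway_process_params(ec_multiplier = 1.5)
  cfg <- cohort_config(n_subjects = 20, directions = "ML", seed = 31,
                       process = proc)
  met <- metrics_table(generate_cohort(cfg))
  fp <- met[met$device == "FP", ]
  ratio <- mean(fp$rms_cm[fp$condition == "EC"]) /
    mean(fp$rms_cm[fp$condition == "EO"])
  expect_lt(abs(ratio - 1.5), 0.1 * 1.5)
})

test_that("AP amplitudes carry the anisotropy factor", {
  met <- metrics_table(small_cohort(n_subjects = 10, seed = 41))
  fp <- met[met$device == "FP", ]
  ratio <- mean(fp$rms_cm[fp$direction == "AP"]) /
    mean(fp$rms_cm[fp$direction == "ML"])
  expect_lt(abs(ratio - pp$ap_anisotropy), 0.15)
})

test_that("paired-device amplitude coupling tightens as headset noise vanishes", {
  clean <- headset_params(jitter_sd = 0, drift_sd = 0,
                          jitter_subj_sd = 0, jitter_trial_sd = 0,
                          smooth_cutoff = 4.5)
  cfg <- cohort_config(n_subjects = 15, conditions = "EO", directions = "ML",
                       seed = 51, headset = clean)
  met <- metrics_table(generate_cohort(cfg))
  fp <- met[met$device == "FP", ]; vr <- met[met$device == "VR", ]
  ord <- order(fp$subject_id, fp$trial)
  ord2 <- order(vr$subject_id, vr$trial)
  expect_gt(stats::cor(fp$rms_cm[ord], vr$rms_cm[ord2]), 0.99)
})

test_that("jitter calibration hits a requested device correlation", {
  hp <- headset_params()
  j <- calibrate_headset_jitter(0.9, pp, hp, n_subjects = 800, seed = 3)
  cfg <- cohort_config(n_subjects = 400, conditions = "EO", directions = "ML",
                       seed = 61, headset = headset_params(jitter_sd = j))
  met <- metrics_table(generate_cohort(cfg))
  p <- aggregate_pairs(met, "RMS", "EO", "ML", "mean_of_3")
  expect_lt(abs(stats::cor(p$x, p$y) - 0.9), 0.06)
  expect_error(calibrate_headset_jitter(0.9999, pp, hp, n_subjects = 100,
                                        seed = 3),
               class = "swayval_validation_error")
})
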