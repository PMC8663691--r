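# Independent brute-force oracles used to check the package's statistics,
# plus small simulation helpers. The oracles deliberately use explicit
# element-by-element summation, not the package's code paths.

loop_npl <- function(p, duration) {
  total <- 0
  for (j in seq_len(length(p) - 1)) total <- total + abs(p[j + 1] - p[j])
  total / duration
}

loop_rms <- function(p) {
  m <- 0
  for (v in p) m <- m + v
  m <- m / length(p)
  s <- 0
  for (v in p) s <- s + (v - m)^2
  sqrt(s / length(p))
}

loop_p2p <- function(p) {
  lo <- hi <- p[1]
  for (v in p) {
    if (v < lo) lo <- v
    if (v > hi) hi <- v
  }
  hi - lo
}

# Two-way ANOVA consistency ICC by explicit sums of squares, with the
# F-pivot interval, written straight from the definitions.
icc_oracle <- function(mat, alpha = 0.05) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- sum(mat) / (n * k)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(mat[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(mat[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (mat[i, j] - grand)^2
  msr <- ss_rows / (n - 1)
  mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  f_obs <- msr / mse
  fl <- f_obs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
  fu <- f_obs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
  list(icc = (msr - mse) / (msr + (k - 1) * mse),
       lo = (fl - 1) / (fl + k - 1),
       hi = (fu - 1) / (fu + k - 1))
}

# Closed-form simple OLS from the raw sums.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y)
  sxx <- sum(x^2); syy <- sum(y^2)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  r2 <- (n * sxy - sx * sy)^2 / ((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = b, intercept = a, r2 = r2)
}

# Subjects-by-trials matrix from the additive random-effects model with a
# known intraclass correlation (unit total variance).
sim_icc_matrix <- function(n, k, icc, seed) {
  withr::with_seed(seed, {
    u <- rnorm(n, 0, sqrt(icc))
    matrix(u, n, k) + matrix(rnorm(n * k, 0, sqrt(1 - icc)), n, k)
  })
}

rand_trace <- function(seed, n = 50, rate = 10) {
  withr::with_seed(seed, trial_trace(rnorm(n), rate = rate))
}

small_cohort <- function(n_subjects = 4, seed = 1, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects, seed = seed, ...))
}
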