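# Psychophysical summary statistics against brute-force oracles.

test_that("absolute error summaries match hand computation and a brute force", {
  d <- data.frame(err = c(1, 2, 9), cond = "a", unit = "s1")
  expect_equal(absolute_error_summary(d$err, d$cond, d$unit,
                                      "median_then_mean")$value, 2)
  expect_equal(absolute_error_summary(d$err, d$cond, d$unit,
                                      "mean_then_mean")$value, 4)
  set.seed(1)
  tab <- data.frame(err = abs(rnorm(300)),
                    cond = sample(c("a", "b", "c"), 300, TRUE),
                    unit = sample(c("u1", "u2", "u3", "u4"), 300, TRUE))
  got <- absolute_error_summary(tab$err, tab$cond, tab$unit, "median_then_mean")
  for (cn in c("a", "b", "c")) {
    per_unit <- sapply(unique(tab$unit), function(u) {
      v <- tab$err[tab$cond == cn & tab$unit == u]
      if (length(v)) median(v) else NA
    })
    expect_equal(got$value[got$condition == cn], mean(per_unit, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("MAD precision matches its definition", {
  expect_equal(mad_precision(rep(5, 10), rep("a", 10))$mad, 0)
  expect_equal(mad_precision(c(-1, 1), c("a", "a"))$mad, 1)
  set.seed(2)
  x <- rnorm(100)
  expect_equal(mad_precision(x, rep("a", 100))$mad,
               sum(abs(x - mean(x))) / 100, tolerance = 1e-12)
})

test_that("d-prime matches the inverse-normal oracle and clips extremes", {
  expect_equal(dprime(84, 16, 16, 84), qnorm(0.84) - qnorm(0.16),
               tolerance = 1e-12)
  expect_equal(dprime(84, 16, 16, 84), 1.9889, tolerance = 1e-3)
  expect_equal(dprime(50, 50, 50, 50), 0)
  # perfect performance with n = 10 per class engages the clipping rule
  expect_equal(dprime(10, 0, 0, 10), 2 * qnorm(0.95), tolerance = 1e-12)
  expect_equal(dprime(10, 0, 0, 10), 3.2897, tolerance = 1e-4)
  # antisymmetry
  expect_equal(dprime(70, 30, 20, 80), -dprime(20, 80, 70, 30),
               tolerance = 1e-12)
  expect_error(dprime(0, 0, 5, 5), "at least one")
})

test_that("psychometric threshold is recovered from synthetic 2AFC data", {
  set.seed(3)
  m_true <- log(2); s_true <- 0.6
  deltas <- c(0.25, 0.5, 1, 2, 4, 8, 16)
  pc <- sapply(deltas, function(d) {
    p <- 0.5 + 0.5 * pnorm((log(d) - m_true) / s_true)
    rbinom(1, 500, p) / 500
  })
  fit <- fit_psychometric(deltas, pc)
  thr_true <- exp(m_true + s_true * qnorm(2 * 0.707 - 1))
  expect_equal(fit$threshold_pct, thr_true, tolerance = 0.1 * thr_true)
  expect_identical(fit$flag, "ok")
})

test_that("degenerate psychometric data hit the cap or the ceiling flag", {
  deltas <- c(0.5, 1, 2, 4)
  f_chance <- fit_psychometric(deltas, rep(0.5, 4))
  expect_equal(f_chance$threshold_pct, 100)
  expect_identical(f_chance$flag, "degenerate")
  f_ceiling <- fit_psychometric(deltas, rep(1, 4))
  expect_identical(f_ceiling$flag, "ceiling")
  expect_lte(f_ceiling$threshold_pct, min(deltas))
})

test_that("threshold is invariant to the units of the difference axis", {
  set.seed(4)
  deltas <- c(0.5, 1, 2, 4, 8)
  pc <- 0.5 + 0.5 * pnorm((log(deltas) - log(2)) / 0.5)
  t_pct <- fit_psychometric(deltas, pc)$threshold_pct
  t_prop <- fit_psychometric(deltas / 100, pc)$threshold_pct
  expect_equal(t_pct, t_prop * 100, tolerance = 1e-4 * t_pct)
})

test_that("bootstrap CIs are seeded, degenerate on constants, and calibrated", {
  z <- bootstrap_ci(rep(3, 20), mean, n_boot = 128, seed = 1)
  expect_equal(z$low, 3); expect_equal(z$high, 3); expect_equal(z$sd, 0)
  x <- rnorm(30)
  expect_identical(bootstrap_ci(x, mean, n_boot = 256, seed = 9),
                   bootstrap_ci(x, mean, n_boot = 256, seed = 9))
  # coverage of the 95% interval for a normal mean
  set.seed(10)
  hits <- replicate(400, {
    x <- rnorm(40, 1, 1)
    ci <- bootstrap_ci(x, mean, n_boot = 400, seed = sample.int(1e6, 1))
    ci$low <= 1 && ci$high >= 1
  })
  expect_equal(mean(hits), 0.95, tolerance = 0.04)
})

test_that("Spearman-Brown and attenuation correction follow the formulas", {
  expect_equal(spearman_brown(1 / 3), 0.5, tolerance = 1e-12)
  expect_equal(reliability_corrected_correlation(0.5, 1, 1), 0.5)
  expect_equal(reliability_corrected_correlation(0.5, 0.8, 0.5),
               0.5 / sqrt(0.4), tolerance = 1e-12)
  expect_equal(reliability_corrected_correlation(0.99, 0.5, 0.5), 1)
  expect_error(reliability_corrected_correlation(0.5, 0, 1), "positive")
})

test_that("attenuation correction recovers a known generative correlation", {
  set.seed(11)
  n <- 200; n_trials <- 40
  t1 <- rnorm(n); t2 <- 0.8 * t1 + sqrt(1 - 0.64) * rnorm(n)
  # per-unit measures are trial means corrupted by measurement noise
  x <- replicate(n_trials, t1 + rnorm(n, sd = 1.5))
  y <- replicate(n_trials, t2 + rnorm(n, sd = 1.5))
  mx <- rowMeans(x); my <- rowMeans(y)
  rxx <- spearman_brown(cor(rowMeans(x[, seq(1, n_trials, 2)]),
                            rowMeans(x[, seq(2, n_trials, 2)])))
  ryy <- spearman_brown(cor(rowMeans(y[, seq(1, n_trials, 2)]),
                            rowMeans(y[, seq(2, n_trials, 2)])))
  corrected <- reliability_corrected_correlation(cor(mx, my), rxx, ryy)
  expect_equal(corrected, 0.8, tolerance = 0.05)
})

test_that("split-half reliability uses alternating parity within condition", {
  set.seed(12)
  cond <- rep(letters[1:6], each = 20)
  true_m <- rep(rnorm(6), each = 20)
  v <- true_m + rnorm(120, sd = 0.2)
  r <- split_half_reliability(v, cond)
  expect_gt(r$reliability, r$r_split)
  expect_gt(r$reliability, 0.9)
})

test_that("pooled similarity z-scores within experiment and the paired test works", {
  h <- c(1, 2, 3, 10, 20, 30)
  expt <- c("a", "a", "a", "b", "b", "b")
  expect_equal(aggregate_similarity(h, h, expt), 1)
  # adding a constant to one experiment's block changes nothing
  m <- h + ifelse(expt == "b", 100, 0)
  expect_equal(aggregate_similarity(h, m, expt), 1, tolerance = 1e-12)
  set.seed(13)
  n <- 40
  human <- rnorm(n)
  expt2 <- rep(c("a", "b"), each = n / 2)
  goodm <- human + rnorm(n, sd = 0.2)
  badm <- sample(human)
  res <- paired_delta_r_test(human, goodm, badm, expt2, n_boot = 512, seed = 14)
  expect_gt(res$delta_r, 0)
  expect_lt(res$p, 0.05)
})
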