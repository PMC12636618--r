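# Experiment protocols exercised with stub models (fixed posteriors), plus
# screening and table-level invariants.

test_that("the localization protocol produces 399 well-formed trials", {
  tab <- run_exp3(loc_stub_at_truth(), toy_exp3_protocol(n_map = 2000),
                  repeats = 3, seed = 1)
  expect_identical(nrow(tab), 399L)
  expect_identical(nrow(tab), unname(protocol_trial_counts()["exp3"]))
  expect_true(all(tab$response_az >= -180 & tab$response_az < 180))
  # a narrow stub at the truth localizes nearly perfectly
  expect_lte(median(tab$error_az), 1)
  expect_true(all(tab$bet %in% 1:5))
  # bets respect the pooled monotonicity invariant
  ord <- order(tab$uncertainty, decreasing = TRUE)
  expect_true(all(diff(tab$bet[ord]) >= 0))
})

test_that("an untrained model is refused by the protocols", {
  fake <- structure(list(trained = FALSE), class = "percept_model")
  expect_error(run_exp3(fake), "not trained")
  expect_error(run_exp4(fake), "not trained")
})

test_that("the front/back protocol produces 360 fully crossed trials", {
  tab <- run_exp4(loc_stub_at_truth(), toy_exp4_protocol(n_map = 2000),
                  seed = 2)
  expect_identical(nrow(tab), 360L)
  expect_identical(nrow(unique(tab[, c("condition", "azimuth", "elevation")])),
                   360L)
  # truth-following stub: all correct, and d-prime engages the clipping rule
  expect_true(all(tab$correct))
  hits <- sum(tab$truth == "front" & tab$response == "front")
  fa <- sum(tab$truth == "back" & tab$response == "front")
  n_front <- sum(tab$truth == "front"); n_back <- sum(tab$truth == "back")
  d <- dprime(hits, n_front - hits, fa, n_back - fa)
  expect_true(is.finite(d))
  expect_equal(d, qnorm(1 - 1 / (2 * n_front)) - qnorm(1 / (2 * n_back)),
               tolerance = 1e-12)
})

test_that("a front/back-symmetric stub yields d-prime near zero", {
  b0 <- modifyList(readout_bounds(), list(conc_lb = 0))
  sym_stub <- stub_model(function(truth) {
    az <- deg2rad_t(truth$azimuth)
    mirror <- pi - az   # the front/back image across the interaural axis
    von_mises_mixture(c(0.5, 0.5),
                      rbind(c(az, 0), c(mirror, 0)),
                      rbind(c(100, 100), c(100, 100)), bounds = b0)
  })
  tab <- run_exp4(sym_stub, toy_exp4_protocol(n_map = 4000), seed = 3)
  hits <- sum(tab$truth == "front" & tab$response == "front")
  fa <- sum(tab$truth == "back" & tab$response == "front")
  d <- dprime(hits, sum(tab$truth == "front") - hits,
              fa, sum(tab$truth == "back") - fa)
  expect_lt(abs(d), 0.35)
  # and its entropy confidence is pinned near the 1-bit maximum
  expect_gt(mean(tab$uncertainty), 0.95)
})

test_that("uncertainty screening anchors at percentiles, not extremes", {
  # extreme outliers are avoided because the lists anchor at percentiles
  vals <- c(-500, 2:99, 1000)
  ids <- sprintf("s%03d", 1:100)
  res <- screen_by_uncertainty(vals, ids, k = 10)
  expect_false("s001" %in% res$low)      # not the minimum
  expect_false("s100" %in% res$high)     # not the maximum
  expect_length(intersect(res$low, res$high), 0)
  expect_true(all(abs(vals[match(res$low, ids)] - quantile(vals, 0.05)) <= 8))
  expect_error(screen_by_uncertainty(vals, ids, k = 200), "exceeds")
  set.seed(4)
  for (i in 1:5) {
    u <- runif(300); id <- sample(sprintf("x%02d", 1:30), 300, TRUE)
    r <- screen_by_uncertainty(u, id, k = 5)
    expect_length(intersect(r$low, r$high), 0)
  }
})

test_that("pitch discrimination protocol arithmetic and stub behavior", {
  expect_identical(length(seq(0.2, 6, 0.2)), 30L)
  exact_stub <- stub_model(function(truth)
    gaussian_mixture_1d(1, log(truth$f0), 1e-9), kind = "pitch")
  tab <- run_exp6(exact_stub, f0_diff_pct = c(0.5, 1, 2, 4), n_targets = 5,
                  stimulus_types = "pure", n_map = 1500,
                  compute_uncertainty = FALSE, seed = 5)
  expect_identical(nrow(tab), 4L * 5L * 2L)
  expect_true(all(tab$correct))
  # an f0-independent posterior performs at chance
  flat_stub <- stub_model(function(truth)
    gaussian_mixture_1d(1, log(truth$nominal_f0), 0.04), kind = "pitch")
  tab2 <- run_exp6(flat_stub, f0_diff_pct = seq(1, 6, 1), n_targets = 40,
                   stimulus_types = c("pure", "harm_low"), n_map = 400,
                   compute_uncertainty = FALSE, seed = 6)
  expect_equal(mean(tab2$correct), 0.5, tolerance = 0.035)
})

test_that("threshold fits from an experiment table vary with stub acuity", {
  noisy_stub <- function(sd_log) stub_model(function(truth) {
    old <- set.seed(truth$seed)
    gaussian_mixture_1d(1, min(max(log(truth$f0) + rnorm(1, 0, sd_log), 3), 10),
                        1e-7)
  }, kind = "pitch")
  tab_sharp <- run_exp6(noisy_stub(0.005), f0_diff_pct = c(0.5, 1, 2, 4, 8),
                        n_targets = 15, stimulus_types = "sharp",
                        n_map = 800, compute_uncertainty = FALSE, seed = 7)
  tab_blur <- run_exp6(noisy_stub(0.05), f0_diff_pct = c(0.5, 1, 2, 4, 8),
                       n_targets = 15, stimulus_types = "blur",
                       n_map = 800, compute_uncertainty = FALSE, seed = 7)
  th <- exp6_thresholds(rbind(tab_sharp, tab_blur))
  expect_lt(th$threshold_pct[th$stimulus_type == "sharp"],
            th$threshold_pct[th$stimulus_type == "blur"])
})

test_that("protocol metadata matches the documented counts", {
  counts <- protocol_trial_counts()
  expect_identical(unname(counts["natural_localization"]), 1120L)
  expect_identical(unname(counts["exp3"]), 399L)
  expect_identical(unname(counts["exp4"]), 360L)
  expect_identical(unname(counts["exp6_human_main"]), 300L)
  grid <- f0_training_grid(80, 1000, 16)
  expect_identical(grid$n_bins, 700L)
  expect_equal(grid$bin_width_pct, 0.36, tolerance = 0.01)
})

test_that("trial tables are reproducible from (model, protocol, seed)", {
  stub <- loc_stub_at_truth(kappa = 100)
  t1 <- run_exp3(stub, toy_exp3_protocol(n_map = 500), repeats = 1, seed = 9)
  t2 <- run_exp3(stub, toy_exp3_protocol(n_map = 500), repeats = 1, seed = 9)
  expect_identical(t1, t2)
})
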