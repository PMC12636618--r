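# Summary statistics and fits used to compare conditions across virtual (and
# human) psychophysics: absolute error, MAD precision, d-prime, cumulative
# normal psychometric fits with a 0.707 threshold criterion, bootstrap
# confidence intervals, split-half reliability with Spearman-Brown and
# attenuation correction, and z-scored cross-experiment correlations.

#' Per-condition absolute error summaries
#'
#' For human-style analyses the median absolute error is computed per unit
#' (participant) and then averaged across units; for model-style analyses the
#' per-unit mean absolute error is averaged.
#'
#' @param error numeric vector of absolute errors (or signed errors; absolute
#'   values are taken).
#' @param condition factor-like condition labels.
#' @param unit participant or model identifiers.
#' @param estimator `"median_then_mean"` or `"mean_then_mean"`.
#' @return data.frame with columns `condition`, `value`.
#' @export
absolute_error_summary <- function(error, condition, unit,
                                   estimator = c("median_then_mean",
                                                 "mean_then_mean")) {
  estimator <- match.arg(estimator)
  fn <- if (estimator == "median_then_mean") stats::median else mean
  e <- abs(error)
  per_unit <- tapply(e, list(condition = condition, unit = unit), fn)
  data.frame(condition = rownames(per_unit),
             value = rowMeans(per_unit, na.rm = TRUE),
             row.names = NULL)
}

#' Mean absolute deviation (MAD) response precision
#'
#' The mean absolute deviation of responses about their mean, a precision
#' measure independent of constant bias. With `pooling = "pooled_units"` all
#' responses in a condition are pooled before computing the MAD; with
#' `"per_unit"` the MAD is computed per unit and averaged.
#'
#' @param response numeric responses (e.g., reported azimuths in degrees).
#' @param condition condition labels.
#' @param unit unit identifiers (required for `"per_unit"`).
#' @param pooling `"pooled_units"` or `"per_unit"`.
#' @return data.frame with columns `condition`, `mad`.
#' @export
mad_precision <- function(response, condition, unit = NULL,
                          pooling = c("pooled_units", "per_unit")) {
  pooling <- match.arg(pooling)
  mad1 <- function(x) mean(abs(x - mean(x)))
  if (pooling == "pooled_units") {
    v <- tapply(response, condition, mad1)
  } else {
    per <- tapply(response, list(condition, unit), mad1)
    v <- rowMeans(per, na.rm = TRUE)
  }
  data.frame(condition = names(v), mad = as.numeric(v), row.names = NULL)
}

#' Signal-detection sensitivity d-prime
#'
#' `z(hit rate) - z(false-alarm rate)`, with rates clipped to
#' `[1/(2n), 1 - 1/(2n)]` per class so perfect performance yields a finite
#' value.
#'
#' @param hits,misses counts of "front" responses to front trials and
#'   "back" responses to front trials (signal class).
#' @param false_alarms,correct_rejections counts for the noise class.
#' @return d-prime.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_sig < 1 || n_noise < 1) stop("need at least one trial per class")
  clip <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hits / n_sig, n_sig)) -
    stats::qnorm(clip(false_alarms / n_noise, n_noise))
}

#' Fit a cumulative-normal psychometric function
#'
#' Fits `p(delta) = 0.5 + 0.5 * pnorm((log(delta) - m)/s)` to
#' proportion-correct data by least squares (2AFC chance floor at 0.5). The
#' threshold is the percent difference at which the fitted proportion correct
#' reaches 0.707, capped at 100%. Degenerate data (no measurable rise of the
#' fitted curve, or performance pinned at chance) yield a threshold of 100
#' with `flag = "degenerate"`; performance at ceiling everywhere yields a
#' threshold at or below the smallest tested difference with
#' `flag = "ceiling"`.
#'
#' @param pct_diff stimulus differences in percent (> 0).
#' @param prop_correct mean proportion correct per difference level.
#' @param criterion proportion correct defining the threshold (0.707).
#' @return list of class `psychometric_fit`: `location`, `scale` (of the
#'   normal CDF in log-percent units), `threshold_pct`, `flag`.
#' @export
fit_psychometric <- function(pct_diff, prop_correct, criterion = 0.707) {
  stopifnot(length(pct_diff) == length(prop_correct))
  if (length(unique(pct_diff)) < 3) stop("need at least 3 difference levels")
  ld <- log(pct_diff)
  obj <- function(par) {
    pred <- 0.5 + 0.5 * stats::pnorm((ld - par[1]) / exp(par[2]))
    sum((pred - prop_correct)^2)
  }
  init <- c(stats::median(ld), 0)
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  m <- fit$par[1]; s <- exp(fit$par[2])
  thr <- exp(m + s * stats::qnorm(2 * criterion - 1))
  flag <- "ok"
  pr <- range(prop_correct)
  if (diff(pr) < 0.05 && pr[2] < 0.55) { thr <- 100; flag <- "degenerate" }
  if (pr[1] > 0.95) flag <- "ceiling"
  if (!is.finite(thr) || thr > 100) { thr <- 100; if (flag == "ok") flag <- "capped" }
  structure(list(location = m, scale = s, threshold_pct = thr, flag = flag),
            class = "psychometric_fit")
}

#' Bootstrap confidence interval of a statistic across units
#'
#' Resamples units (participants, models, conditions) with replacement and
#' recomputes the statistic; 1024 bootstrap samples by default.
#'
#' @param units list (or vector) of resampling units; `statistic` receives a
#'   resampled list/vector of the same length.
#' @param statistic function mapping resampled units to a scalar.
#' @param n_boot number of bootstrap samples (default 1024).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95, percentile method).
#' @return list `low`, `high`, `sd`, `estimates`.
#' @export
bootstrap_ci <- function(units, statistic, n_boot = 1024, seed = 1,
                         conf = 0.95) {
  old <- local_seed(seed); on.exit(restore_seed(old))
  n <- if (is.list(units)) length(units) else length(units)
  est <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    statistic(if (is.list(units)) units[idx] else units[idx])
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(est, c(a, 1 - a), names = FALSE, type = 7)
  list(low = q[1], high = q[2], sd = stats::sd(est), estimates = est)
}

#' Spearman-Brown prophecy correction
#'
#' Corrects a split-half correlation for halving the number of trials:
#' `2r / (1 + r)`.
#'
#' @param r split-half correlation.
#' @return corrected reliability.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Split-half reliability of a condition-level measure
#'
#' Trials are split by alternating parity within each condition (deterministic
#' and balanced); the measure is computed per condition in each half, the
#' halves are correlated across conditions, and the correlation is
#' Spearman-Brown corrected.
#'
#' @param value per-trial values.
#' @param condition condition labels.
#' @param measure function summarizing the trials of a condition (default
#'   mean).
#' @return list `r_split`, `reliability` (Spearman-Brown corrected).
#' @export
split_half_reliability <- function(value, condition, measure = mean) {
  condition <- as.character(condition)
  idx <- stats::ave(seq_along(value), condition, FUN = seq_along)
  h1 <- tapply(value[idx %% 2 == 1], condition[idx %% 2 == 1], measure)
  h2 <- tapply(value[idx %% 2 == 0], condition[idx %% 2 == 0], measure)
  common <- intersect(names(h1), names(h2))
  r <- stats::cor(h1[common], h2[common])
  list(r_split = r, reliability = spearman_brown(r))
}

#' Attenuation-corrected correlation
#'
#' `r_xy / sqrt(r_xx * r_yy)`, clipped to `[-1, 1]`; the reliabilities are
#' typically split-half estimates corrected by [spearman_brown()].
#'
#' @param r_xy observed correlation.
#' @param r_xx,r_yy reliabilities of the two measures.
#' @return disattenuated correlation.
#' @export
reliability_corrected_correlation <- function(r_xy, r_xx, r_yy) {
  if (r_xx <= 0 || r_yy <= 0) stop("reliabilities must be positive")
  pmin(pmax(r_xy / sqrt(r_xx * r_yy), -1), 1)
}

#' Pooled human-model similarity across experiments
#'
#' Values are z-scored within each experiment (so experiments with different
#' units and scales contribute comparably), pooled, and correlated (Pearson).
#'
#' @param human,model numeric vectors of condition-level values, aligned.
#' @param experiment experiment labels used for within-experiment z-scoring.
#' @return Pearson correlation of the pooled z-scored vectors.
#' @export
aggregate_similarity <- function(human, model, experiment) {
  z <- function(x) stats::ave(x, experiment, FUN = function(v) {
    s <- stats::sd(v)
    if (s == 0) v * 0 else (v - mean(v)) / s
  })
  stats::cor(z(human), z(model))
}

#' One-tailed paired bootstrap test on a correlation difference
#'
#' Conditions are resampled with replacement (identically for both models);
#' for each bootstrap sample the difference
#' `delta_r = r(human, modelA) - r(human, modelB)` of the pooled z-scored
#' correlations is computed, and the one-tailed p-value is the fraction of
#' bootstrap samples with `delta_r <= 0`.
#'
#' @param human,modelA,modelB aligned condition-level vectors.
#' @param experiment experiment labels.
#' @param n_boot bootstrap iterations (default 1024).
#' @param seed integer seed.
#' @return list `delta_r` (point estimate), `p` (one-tailed), `boot`
#'   (bootstrap distribution).
#' @export
paired_delta_r_test <- function(human, modelA, modelB, experiment,
                                n_boot = 1024, seed = 1) {
  old <- local_seed(seed); on.exit(restore_seed(old))
  n <- length(human)
  delta <- aggregate_similarity(human, modelA, experiment) -
    aggregate_similarity(human, modelB, experiment)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    aggregate_similarity(human[idx], modelA[idx], experiment[idx]) -
      aggregate_similarity(human[idx], modelB[idx], experiment[idx])
  }, numeric(1))
  list(delta_r = delta, p = mean(boot <= 0), boot = boot)
}
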