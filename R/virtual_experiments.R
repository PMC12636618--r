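# Virtual psychophysics: run the model-side experimental protocols on a
# trained (or stub) model and emit trial tables. Bets are assigned once per
# experiment over the pooled uncertainty column.

#' Protocol for the absolute localization experiment
#'
#' Seven stimulus conditions (broadband noise; 600/2000/4000 Hz tones;
#' one-octave narrowband noise at the same centers) x 19 frontal azimuths
#' (-90..90 in 10-degree steps) x `repeats` repetitions, elevation drawn
#' uniformly from 0-40 degrees per trial; with 3 repetitions this yields the
#' protocol's 399 judgments per virtual participant.
#'
#' @param rate stimulus sample rate in Hz.
#' @param duration stimulus duration in seconds.
#' @param ramp_ms on/off ramps in ms.
#' @param snr_db SNR of the diffuse background during model presentation.
#' @param jitter_octaves center-frequency jitter range (total octaves).
#' @param n_map Monte Carlo samples for MAP/HPD extraction.
#' @return protocol list.
#' @export
exp3_protocol <- function(rate = 44100, duration = 0.75, ramp_ms = 250,
                          snr_db = 20, jitter_octaves = 0.5, n_map = 5000) {
  list(conditions = toy_conditions(),
       azimuths = speaker_grid("frontal19")$azimuth,
       elevations = seq(0, 40, 10),
       rate = rate, duration = duration, ramp_ms = ramp_ms, snr_db = snr_db,
       jitter_octaves = jitter_octaves, n_map = n_map)
}

#' Desk-scale protocol variants matched to the toy periphery
#'
#' Same condition/position structure as the full protocols, with stimulus
#' rate and duration matched to the reduced binaural periphery used for
#' desk-scale training.
#'
#' @param periphery a binaural [periphery_config()].
#' @param n_map Monte Carlo samples for posterior extraction.
#' @return protocol list.
#' @export
toy_exp3_protocol <- function(periphery = periphery_config("toy_binaural"),
                              n_map = 5000) {
  exp3_protocol(rate = periphery$input_rate,
                duration = periphery$crop_duration + 0.04,
                ramp_ms = 20, n_map = n_map)
}

trial_stimulus <- function(model, condition, azimuth, elevation, protocol,
                           seed) {
  if (inherits(model, "stub_model")) return(NULL)
  toy_scene(condition, azimuth, elevation, protocol$snr_db,
            duration = protocol$duration, rate = protocol$rate, seed = seed)
}

#' Run the absolute localization experiment
#'
#' For each condition x azimuth x repetition: synthesize the stimulus,
#' render it binaurally, pass it through the periphery and model, extract
#' the MAP azimuth response and the width of the 50% HPD interval of the
#' azimuthal posterior, then map pooled HPD widths to bets.
#'
#' @param model a trained `percept_model` (or a [stub_model()] receiving the
#'   trial truth).
#' @param protocol an [exp3_protocol()].
#' @param repeats repetitions per condition/azimuth cell (default 3).
#' @param seed integer seed.
#' @return data.frame of trial records: `condition`, `azimuth`, `elevation`,
#'   `rep`, `response_az`, `error_az`, `uncertainty` (HPD width, degrees),
#'   `bet`.
#' @export
run_exp3 <- function(model, protocol = exp3_protocol(), repeats = 3,
                     seed = 1) {
  if (!isTRUE(model$trained)) stop("refusing to run: model is not trained")
  grid <- expand.grid(rep = seq_len(repeats),
                      azimuth = protocol$azimuths,
                      condition = protocol$conditions,
                      stringsAsFactors = FALSE)
  old <- local_seed(derive_seed(seed, "exp3-elev")); on.exit(restore_seed(old))
  grid$elevation <- sample(protocol$elevations, nrow(grid), replace = TRUE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tseed <- derive_seed(seed, paste0("exp3-", i))
    stim <- trial_stimulus(model, g$condition, g$azimuth, g$elevation,
                           protocol, tseed)
    m <- predict_posterior(model, stim,
                           truth = list(azimuth = g$azimuth,
                                        elevation = g$elevation,
                                        condition = g$condition))
    mp <- map_estimate(m, n = protocol$n_map, seed = derive_seed(tseed, "map"))
    hw <- hpd_width(attr(mp, "posterior"), 0.5, "azimuth")
    out[[i]] <- data.frame(condition = g$condition, azimuth = g$azimuth,
                           elevation = g$elevation, rep = g$rep,
                           response_az = as.numeric(mp["azimuth"]),
                           error_az = abs(wrap_deg_180(mp["azimuth"] - g$azimuth)),
                           uncertainty = hw)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$bet <- assign_bets(tab$uncertainty)
  tab$experiment <- "exp3"
  tab
}

#' Protocol for the front/back experiment
#'
#' Four stimulus conditions (broadband noise; 600/2000/4000 Hz tones) x 18
#' azimuths (0..180 in 10-degree steps omitting 90) x 5 elevations (0-40),
#' fully crossed: 360 trials per block.
#'
#' @inheritParams exp3_protocol
#' @return protocol list.
#' @export
exp4_protocol <- function(rate = 44100, duration = 0.75, ramp_ms = 250,
                          snr_db = 20, jitter_octaves = 0.5, n_map = 5000) {
  list(conditions = c("broadband", "tone600", "tone2000", "tone4000"),
       azimuths = speaker_grid("semicircle18")$azimuth,
       elevations = seq(0, 40, 10),
       rate = rate, duration = duration, ramp_ms = ramp_ms, snr_db = snr_db,
       jitter_octaves = jitter_octaves, n_map = n_map)
}

#' @rdname toy_exp3_protocol
#' @export
toy_exp4_protocol <- function(periphery = periphery_config("toy_binaural"),
                              n_map = 5000) {
  exp4_protocol(rate = periphery$input_rate,
                duration = periphery$crop_duration + 0.04, ramp_ms = 20,
                n_map = n_map)
}

#' Run the front/back experiment
#'
#' Binary front/back judgments: the azimuthal posterior is integrated over
#' the front hemifield; the response is the more probable hemifield and the
#' confidence measure is the entropy of the front/back distribution (1 bit
#' when maximally uncertain). Bets are assigned from pooled entropies.
#'
#' @inheritParams run_exp3
#' @param protocol an [exp4_protocol()].
#' @return data.frame of trial records: `condition`, `azimuth`, `elevation`,
#'   `truth` ("front"/"back"), `response`, `correct`, `p_front`,
#'   `uncertainty` (bits), `bet`.
#' @export
run_exp4 <- function(model, protocol = exp4_protocol(), seed = 1) {
  if (!isTRUE(model$trained)) stop("refusing to run: model is not trained")
  grid <- expand.grid(elevation = protocol$elevations,
                      azimuth = protocol$azimuths,
                      condition = protocol$conditions,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tseed <- derive_seed(seed, paste0("exp4-", i))
    stim <- trial_stimulus(model, g$condition, g$azimuth, g$elevation,
                           protocol, tseed)
    m <- predict_posterior(model, stim,
                           truth = list(azimuth = g$azimuth,
                                        elevation = g$elevation,
                                        condition = g$condition))
    ep <- empirical_posterior(m, n = protocol$n_map,
                              seed = derive_seed(tseed, "map"))
    fb <- front_back_entropy(ep)
    truth <- if (abs(wrap_deg_180(g$azimuth)) <= 90) "front" else "back"
    out[[i]] <- data.frame(condition = g$condition, azimuth = g$azimuth,
                           elevation = g$elevation, truth = truth,
                           response = fb$response,
                           correct = fb$response == truth,
                           p_front = fb$p_front,
                           uncertainty = fb$entropy_bits)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$bet <- assign_bets(tab$uncertainty)
  tab$experiment <- "exp4"
  tab
}

#' Percentile-based stimulus screening by model uncertainty
#'
#' Computes a mean uncertainty per stimulus (averaging over presentations:
#' azimuths, elevations, repeats, model instances) and selects the `k`
#' stimuli whose means are nearest the `low_pct` and `high_pct` percentiles
#' of the stimulus-level distribution. Percentile anchoring (rather than
#' taking the extremes) avoids floor and ceiling effects in downstream
#' accuracy and bets.
#'
#' @param uncertainty per-presentation uncertainty values.
#' @param stimulus stimulus identifiers aligned with `uncertainty`.
#' @param low_pct,high_pct anchor percentiles (default 5 and 95).
#' @param k stimuli per list (default 10).
#' @return list with `low` and `high` character vectors of stimulus ids
#'   (disjoint), and `means` (named stimulus-level mean uncertainties).
#' @export
screen_by_uncertainty <- function(uncertainty, stimulus, low_pct = 5,
                                  high_pct = 95, k = 10) {
  means <- tapply(uncertainty, stimulus, mean)
  if (k > length(means)) stop("k exceeds the number of distinct stimuli")
  q_lo <- stats::quantile(means, low_pct / 100, names = FALSE)
  q_hi <- stats::quantile(means, high_pct / 100, names = FALSE)
  low <- names(sort(abs(means - q_lo)))[seq_len(k)]
  rest <- setdiff(names(means), low)
  high <- rest[order(abs(means[rest] - q_hi))][seq_len(min(k, length(rest)))]
  if (length(high) < k) stop("k too large for disjoint lists")
  list(low = low, high = high, means = means)
}

#' Run the pitch discrimination experiment
#'
#' For each nominal f0 (150 and 300 Hz), target f0s uniformly spaced over
#' +/-6% of the nominal, and f0 differences from 0.2% to 6% in 0.2% steps:
#' the model produces posteriors for the target and a probe shifted up or
#' down (at random) by the difference; the response selects the stimulus
#' with the higher octave-constrained MAP estimate. Trial uncertainty is the
#' mean of the two mode-local posterior variances (optional, as it dominates
#' run time).
#'
#' @param model a pitch `percept_model` or [stub_model()] receiving
#'   `truth = list(f0, nominal_f0, stimulus_type)`.
#' @param f0_diff_pct difference grid in percent (default
#'   `seq(0.2, 6, 0.2)`).
#' @param nominal_f0s nominal f0s in Hz (default 150 and 300).
#' @param n_targets targets per nominal (default 121, uniform over +/-6%).
#' @param stimulus_types labels passed through to the model (default the
#'   five pitch stimulus classes).
#' @param n_map Monte Carlo samples per posterior.
#' @param compute_uncertainty compute mode-local variances (default TRUE).
#' @param seed integer seed.
#' @return data.frame of trial records: `stimulus_type`, `nominal_f0`,
#'   `f0_diff_pct`, `target_f0`, `probe_f0`, `direction`, `response_higher`,
#'   `correct`, `uncertainty`, `bet`.
#' @export
run_exp6 <- function(model, f0_diff_pct = seq(0.2, 6, 0.2),
                     nominal_f0s = c(150, 300), n_targets = 121,
                     stimulus_types = c("pure", "harm_low", "harm_mid",
                                        "harm_high_sine", "harm_high_rand"),
                     n_map = 5000, compute_uncertainty = TRUE, seed = 1) {
  if (!isTRUE(model$trained)) stop("refusing to run: model is not trained")
  grid <- expand.grid(target_idx = seq_len(n_targets),
                      f0_diff_pct = f0_diff_pct,
                      nominal_f0 = nominal_f0s,
                      stimulus_type = stimulus_types,
                      stringsAsFactors = FALSE)
  old <- local_seed(derive_seed(seed, "exp6-dir")); on.exit(restore_seed(old))
  grid$direction <- sample(c(-1, 1), nrow(grid), replace = TRUE)
  rel <- if (n_targets == 1) 0 else seq(-0.06, 0.06, length.out = n_targets)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    tseed <- derive_seed(seed, paste0("exp6-", i))
    f_t <- g$nominal_f0 * (1 + rel[g$target_idx])
    f_p <- f_t * (1 + g$direction * g$f0_diff_pct / 100)
    post <- function(f0, tag) predict_posterior(
      model, NULL, truth = list(f0 = f0, nominal_f0 = g$nominal_f0,
                                stimulus_type = g$stimulus_type, tag = tag,
                                seed = derive_seed(tseed, tag)))
    m_t <- post(f_t, "target"); m_p <- post(f_p, "probe")
    map_t <- constrained_map_f0(m_t, g$nominal_f0, n = n_map,
                                seed = derive_seed(tseed, "map-t"))
    map_p <- constrained_map_f0(m_p, g$nominal_f0, n = n_map,
                                seed = derive_seed(tseed, "map-p"))
    unc <- if (compute_uncertainty)
      mean(c(mode_local_variance(m_t), mode_local_variance(m_p))) else NA_real_
    resp_higher <- map_p > map_t
    out[[i]] <- data.frame(stimulus_type = g$stimulus_type,
                           nominal_f0 = g$nominal_f0,
                           f0_diff_pct = g$f0_diff_pct,
                           target_f0 = f_t, probe_f0 = f_p,
                           direction = g$direction,
                           response_higher = resp_higher,
                           correct = resp_higher == (g$direction > 0),
                           uncertainty = unc)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab$bet <- if (compute_uncertainty) assign_bets(tab$uncertainty) else NA_integer_
  tab$experiment <- "exp6"
  tab
}

#' Trial counts of the experimental protocols
#'
#' Structural arithmetic of the protocols, computed from their definitions:
#' absolute localization of natural sounds (160 sounds x 7 locations = 1120
#' trials), absolute localization of controlled stimuli (7 conditions x 19
#' azimuths x 3 repetitions = 399), front/back judgments (4 conditions x 18
#' azimuths x 5 elevations = 360), and the analyzed pitch discrimination
#' trials (5 stimulus types x 6 differences x 2 nominal f0s x 5 repetitions
#' = 300).
#'
#' @return named integer vector.
#' @export
protocol_trial_counts <- function() {
  c(natural_localization = 160L * 7L,
    exp3 = length(toy_conditions()) * nrow(speaker_grid("frontal19")) * 3L,
    exp4 = 4L * nrow(speaker_grid("semicircle18")) * 5L,
    exp6_human_main = 5L * 6L * 2L * 5L)
}

#' Log-spaced f0 training grid
#'
#' Bins of width `1/bins_per_semitone` semitones spanning `fmin` to `fmax`;
#' at 16 bins per semitone between 80 and 1000 Hz this yields 700 bins of
#' width ~0.36% f0.
#'
#' @param fmin,fmax grid range in Hz.
#' @param bins_per_semitone subdivision (default 16).
#' @return list with `edges_hz`, `n_bins`, `bin_width_pct`.
#' @export
f0_training_grid <- function(fmin = 80, fmax = 1000, bins_per_semitone = 16) {
  per_octave <- 12 * bins_per_semitone
  n <- ceiling(log2(fmax / fmin) * per_octave)
  list(edges_hz = fmin * 2^(seq(0, n) / per_octave), n_bins = as.integer(n),
       bin_width_pct = (2^(1 / per_octave) - 1) * 100)
}

#' Pitch discrimination psychometrics from an experiment table
#'
#' Collapses a [run_exp6()] table to a mean psychometric function per
#' stimulus type and fits the cumulative-normal threshold (0.707 criterion).
#'
#' @param tab a [run_exp6()] trial table.
#' @return data.frame with `stimulus_type`, `threshold_pct`, `flag`.
#' @export
exp6_thresholds <- function(tab) {
  res <- lapply(split(tab, tab$stimulus_type), function(d) {
    pc <- tapply(d$correct, d$f0_diff_pct, mean)
    fit <- fit_psychometric(as.numeric(names(pc)), as.numeric(pc))
    data.frame(stimulus_type = d$stimulus_type[1],
               threshold_pct = fit$threshold_pct, flag = fit$flag)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
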