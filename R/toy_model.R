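# Desk-scale localization model: a fixed binaural cue-extraction stage
# (per-channel energies, interaural level differences, interaural
# cross-correlation lags and peaks) feeding the trainable MDN, plus seeded
# generation of toy binaural training scenes rendered with the schematic
# spatializer.

#' Binaural cue features from a cochleagram
#'
#' For each frequency channel: mean log energy across ears, interaural level
#' difference (log-energy difference), the interaural cross-correlation lag
#' (ms, restricted to `+/- max_itd_ms`) and its normalized peak value; plus
#' the overall log energy. This fixed cue-extraction stage stands in for a
#' learned convolutional front end at desk scale.
#'
#' @param coch a binaural `cochleagram` (ears x channels x time).
#' @param max_itd_ms cross-correlation lag range in ms (default 1).
#' @return numeric feature vector of length `4 * n_channels + 1`.
#' @export
binaural_features <- function(coch, max_itd_ms = 1) {
  stopifnot(length(dim(coch)) == 3)
  rate <- attr(coch, "rate")
  L <- t(coch[1, , ]); R <- t(coch[2, , ])       # time x channels
  n <- nrow(L); nc <- ncol(L)
  eL <- colMeans(L^2); eR <- colMeans(R^2)
  fL <- log(eL + 1e-12); fR <- log(eR + 1e-12)
  # interaural cross-correlation via FFT
  nfft <- stats::nextn(2 * n, c(2, 3, 5))
  FL <- stats::mvfft(rbind(L, matrix(0, nfft - n, nc)))
  FR <- stats::mvfft(rbind(R, matrix(0, nfft - n, nc)))
  cc <- Re(stats::mvfft(FL * Conj(FR), inverse = TRUE)) / nfft
  maxlag <- min(n - 1, max(1L, round(max_itd_ms / 1000 * rate)))
  lags <- c(0:maxlag, -(maxlag:1))
  idx <- c(1:(maxlag + 1), (nfft - maxlag + 1):nfft)
  ccw <- cc[idx, , drop = FALSE]
  denom <- sqrt(pmax(colSums(L^2) * colSums(R^2), 1e-24))
  ccn <- sweep(ccw, 2, denom, "/")
  best <- apply(ccn, 2, which.max)
  itd_ms <- lags[best] / rate * 1000
  peak <- ccn[cbind(best, seq_len(nc))]
  c((fL + fR) / 2, fL - fR, itd_ms, peak, log(sum(eL) + sum(eR) + 1e-12))
}

toy_conditions <- function() c("broadband", "tone600", "tone2000", "tone4000",
                               "narrow600", "narrow2000", "narrow4000")

#' Synthesize one toy target sound
#'
#' @param condition one of `"broadband"`, `"toneF"`, `"narrowF"` with F in
#'   {600, 2000, 4000} Hz.
#' @param duration,rate clip parameters.
#' @param seed integer seed (tone/narrowband center frequencies are jittered
#'   within `jitter_octaves`).
#' @param jitter_octaves total jitter range in octaves (default 0.5).
#' @param ramp_ms on/off ramps in ms.
#' @return a mono [audio_clip()].
#' @export
toy_target_sound <- function(condition, duration, rate, seed,
                             jitter_octaves = 0.5, ramp_ms = 20) {
  if (condition == "broadband") {
    hi_max <- min(16000, 0.45 * rate)
    return(broadband_noise(duration, rate, seed = seed,
                           low_range = c(20, 60),
                           high_range = c(min(8000, 0.8 * hi_max), hi_max),
                           ramp_ms = ramp_ms))
  }
  cf0 <- as.numeric(sub("^(tone|narrow)", "", condition))
  cf <- jitter_frequency(cf0, jitter_octaves, derive_seed(seed, "jitter"))
  if (startsWith(condition, "tone")) {
    pure_tone(cf, duration, ramp_ms = ramp_ms, rate = rate)
  } else {
    narrowband_noise(cf, 1, duration = duration, rate = rate, seed = seed,
                     ramp_ms = ramp_ms)
  }
}

#' Render a toy binaural scene
#'
#' Target sound spatialized at (azimuth, elevation) with the schematic cue
#' model, superimposed on spatially diffuse background noise (independent
#' noise at each ear) at the given SNR.
#'
#' @param condition target sound condition (see [toy_target_sound()]).
#' @param azimuth_deg,elevation_deg source position in degrees.
#' @param snr_db signal-to-noise ratio in dB.
#' @param duration,rate clip parameters.
#' @param seed integer seed.
#' @return a stereo [audio_clip()] with RMS 0.1.
#' @export
toy_scene <- function(condition, azimuth_deg, elevation_deg, snr_db,
                      duration = 0.24, rate = 16000, seed = 1) {
  tgt <- toy_target_sound(condition, duration, rate, derive_seed(seed, "target"))
  st <- toy_spatialize(tgt, azimuth_deg, elevation_deg)
  # rear sources reach the ears with slightly less direct energy relative to
  # the ambient background (head/torso shadowing): a weak, probabilistic
  # front/back cue that tilts rather than resolves the ambiguity
  if (abs(wrap_deg_180(azimuth_deg)) > 90) snr_db <- snr_db - 3
  old <- local_seed(derive_seed(seed, "background")); on.exit(restore_seed(old))
  bg <- audio_clip(matrix(stats::rnorm(2 * n_samples(st)), ncol = 2), rate)
  set_rms(mix_at_snr(st, bg, snr_db), 0.1)
}

#' Generate a toy training set of labeled binaural scenes
#'
#' Conditions, azimuths (full circle, 10-degree steps), elevations (0-40
#' degrees) and SNRs (uniform in `snr_range`, default -15..30 dB) are sampled
#' independently per scene; each scene is rendered, passed through the
#' periphery, and reduced to binaural cue features.
#'
#' @param n_scenes number of scenes.
#' @param seed integer seed.
#' @param periphery a binaural [periphery_config()].
#' @param snr_range SNR range in dB.
#' @param azimuths,elevations candidate positions in degrees.
#' @param conditions candidate target conditions.
#' @return list with `features` (n x d), `labels_rad` (n x 2, radians,
#'   azimuth in the (-pi, pi] convention), `meta` (data.frame).
#' @export
make_toy_training_set <- function(n_scenes, seed = 1,
                                  periphery = periphery_config("toy_binaural"),
                                  snr_range = c(-15, 30),
                                  azimuths = seq(0, 350, 10),
                                  elevations = seq(0, 40, 10),
                                  conditions = toy_conditions()) {
  old <- local_seed(derive_seed(seed, "scene-draw")); on.exit(restore_seed(old))
  cond <- sample(conditions, n_scenes, replace = TRUE)
  az <- sample(azimuths, n_scenes, replace = TRUE)
  el <- sample(elevations, n_scenes, replace = TRUE)
  snr <- stats::runif(n_scenes, snr_range[1], snr_range[2])
  feats <- NULL
  dur <- periphery$crop_duration + 0.04
  for (i in seq_len(n_scenes)) {
    sc <- toy_scene(cond[i], az[i], el[i], snr[i], duration = dur,
                    rate = periphery$input_rate,
                    seed = derive_seed(seed, paste0("scene", i)))
    f <- binaural_features(cochleagram(sc$waveform, sc$rate, periphery))
    if (is.null(feats)) feats <- matrix(0, n_scenes, length(f))
    feats[i, ] <- f
  }
  list(features = feats,
       labels_rad = cbind(deg2rad(wrap_deg_180(az)), deg2rad(el)),
       meta = data.frame(condition = cond, azimuth = az, elevation = el,
                         snr_db = snr))
}

#' Train the desk-scale localization model
#'
#' Generates toy binaural scenes, extracts cue features, standardizes them,
#' and trains a von Mises mixture MDN by maximum likelihood. Five such models
#' trained from different seeds form the "virtual participants" of the
#' localization experiments.
#'
#' @param n_scenes number of training scenes (default 3000).
#' @param seed integer seed (controls scenes, initialization, data order).
#' @param periphery a binaural [periphery_config()].
#' @param hidden hidden-layer widths of the MDN backbone.
#' @param K mixture components (default 5).
#' @param max_epochs training epochs.
#' @param snr_range training SNR range in dB.
#' @return object of class `percept_model` with the trained network, the
#'   periphery configuration, and feature standardization constants.
#' @export
train_toy_localizer <- function(n_scenes = 3000, seed = 1,
                                periphery = periphery_config("toy_binaural"),
                                hidden = c(64, 48), K = 5, max_epochs = 60,
                                snr_range = c(-15, 30)) {
  ds <- make_toy_training_set(n_scenes, seed, periphery, snr_range)
  mu <- colMeans(ds$features)
  sd_ <- pmax(apply(ds$features, 2, stats::sd), 1e-6)
  X <- sweep(sweep(ds$features, 2, mu), 2, sd_, "/")
  net <- mdn_network(ncol(X), hidden = hidden, K = K,
                     readout = "von_mises_mixture",
                     seed = derive_seed(seed, "init"))
  cfg <- train_config("localization", max_epochs = max_epochs,
                      seed = derive_seed(seed, "train"))
  tr <- train_mdn(net, X, ds$labels_rad, cfg)
  structure(list(kind = "localization", net = tr$net, periphery = periphery,
                 feat_mu = mu, feat_sd = sd_, trace = tr$epoch_loss,
                 trained = TRUE, seed = seed),
            class = "percept_model")
}

#' Predict the posterior mixture for a stimulus
#'
#' Generic over model types: trained `percept_model`s run the full
#' periphery -> features -> network chain on an audio clip or cochleagram;
#' `stub_model`s (fixed-response harnesses used in tests and protocol
#' checks) compute a mixture directly from the trial's ground truth.
#'
#' @param model a `percept_model` or [stub_model()].
#' @param stimulus an [audio_clip()] or `cochleagram` (may be `NULL` for
#'   stubs).
#' @param truth list describing the trial's ground truth (used by stubs).
#' @return a [von_mises_mixture()] or [gaussian_mixture_1d()].
#' @export
predict_posterior <- function(model, stimulus = NULL, truth = NULL) {
  UseMethod("predict_posterior")
}

#' @export
predict_posterior.percept_model <- function(model, stimulus = NULL,
                                            truth = NULL) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (inherits(stimulus, "audio_clip"))
    stimulus <- cochleagram(stimulus$waveform, stimulus$rate, model$periphery)
  if (!inherits(stimulus, "cochleagram")) stop("stimulus required")
  f <- binaural_features(stimulus)
  x <- (f - model$feat_mu) / model$feat_sd
  mdn_predict_mixture(model$net, x)
}

#' Fixed-response stub model
#'
#' Wraps a function of the trial ground truth returning a mixture; used to
#' exercise the experiment protocols independently of training.
#'
#' @param fn function `(truth) -> mixture`.
#' @param kind `"localization"` or `"pitch"`.
#' @return object of class `stub_model`.
#' @export
stub_model <- function(fn, kind = "localization") {
  structure(list(fn = fn, kind = kind, trained = TRUE), class = "stub_model")
}

#' @export
predict_posterior.stub_model <- function(model, stimulus = NULL, truth = NULL) {
  model$fn(truth)
}
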