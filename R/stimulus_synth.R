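# Seeded synthesis of the stimuli used for training and virtual experiments:
# ramped tones, narrowband/broadband noise, harmonic complexes with
# trapezoidal spectral filtering and threshold-equalizing masking noise, RMS
# level / SNR arithmetic, a toy binaural spatializer, and speaker grids.

#' Construct an audio clip
#'
#' @param waveform numeric vector (mono) or samples x 2 matrix (stereo).
#' @param rate sample rate in Hz.
#' @return list of class `audio_clip` with `waveform` and `rate`.
#' @export
audio_clip <- function(waveform, rate) {
  stopifnot(rate > 0)
  structure(list(waveform = waveform, rate = rate), class = "audio_clip")
}

n_samples <- function(clip) NROW(clip$waveform)

#' RMS of an audio clip
#' @param clip an [audio_clip()] (stereo clips use the RMS over both
#'   channels).
#' @return root-mean-square amplitude re full scale 1.0.
#' @export
clip_rms <- function(clip) sqrt(mean(as.matrix(clip$waveform)^2))

# linear or half-Hanning on/off amplitude envelope
apply_ramps <- function(x, rate, ramp_ms, shape = c("linear", "hann")) {
  shape <- match.arg(shape)
  nr <- round(ramp_ms / 1000 * rate)
  nr <- min(nr, floor(NROW(x) / 2))   # ramps never overlap
  if (nr < 1) return(x)
  r <- seq(0, 1, length.out = nr)
  if (shape == "hann") r <- (1 - cos(pi * r)) / 2
  n <- NROW(x)
  env <- rep(1, n)
  env[seq_len(nr)] <- r
  env[(n - nr + 1):n] <- rev(r)
  if (is.matrix(x)) x * env else x * env
}

#' Ramped pure tone
#'
#' @param freq frequency in Hz (below Nyquist).
#' @param duration seconds (default 0.75).
#' @param ramp_ms linear on/off ramp duration in ms (default 250).
#' @param ramp_shape `"linear"` or `"hann"`.
#' @param rate sample rate in Hz (default 44100).
#' @param phase starting phase in radians.
#' @return an [audio_clip()] with RMS 0.1.
#' @export
pure_tone <- function(freq, duration = 0.75, ramp_ms = 250,
                      ramp_shape = "linear", rate = 44100, phase = 0) {
  if (freq >= rate / 2) stop("tone frequency must be below Nyquist")
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- sin(2 * pi * freq * t + phase)
  set_rms(audio_clip(apply_ramps(x, rate, ramp_ms, ramp_shape), rate), 0.1)
}

#' Jitter a frequency within a log2-uniform range
#'
#' Uniform on log2-frequency over a total range of `range_octaves` centered
#' on `freq` (i.e., +/- `range_octaves/2`).
#'
#' @param freq center frequency in Hz.
#' @param range_octaves total jitter range in octaves (default 0.5).
#' @param seed integer seed.
#' @return jittered frequency in Hz.
#' @export
jitter_frequency <- function(freq, range_octaves = 0.5, seed = 1) {
  stopifnot(freq > 0)
  old <- local_seed(seed); on.exit(restore_seed(old))
  freq * 2^stats::runif(1, -range_octaves / 2, range_octaves / 2)
}

#' Butterworth-filtered narrowband noise
#'
#' White noise passed through a Butterworth bandpass with cutoffs
#' `cf * 2^(+/- bandwidth_octaves/2)`.
#'
#' @param cf center frequency in Hz.
#' @param bandwidth_octaves bandwidth in octaves (default 1).
#' @param order filter order (default 4).
#' @param duration seconds.
#' @param rate sample rate in Hz.
#' @param seed integer seed.
#' @param ramp_ms on/off ramp in ms.
#' @return an [audio_clip()] with RMS 0.1.
#' @export
narrowband_noise <- function(cf, bandwidth_octaves = 1, order = 4,
                             duration = 0.75, rate = 44100, seed = 1,
                             ramp_ms = 250) {
  lo <- cf * 2^(-bandwidth_octaves / 2)
  hi <- cf * 2^(bandwidth_octaves / 2)
  if (hi >= rate / 2) stop("band upper edge must be below Nyquist")
  old <- local_seed(seed); on.exit(restore_seed(old))
  x <- stats::rnorm(round(duration * rate))
  bf <- signal::butter(order, c(lo, hi) / (rate / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  set_rms(audio_clip(apply_ramps(y, rate, ramp_ms), rate), 0.1)
}

#' Broadband noise with randomized band edges
#'
#' White noise band-limited between a lower cutoff drawn uniformly from
#' `low_range` and an upper cutoff drawn uniformly from `high_range`.
#'
#' @param duration seconds.
#' @param rate sample rate in Hz.
#' @param seed integer seed.
#' @param low_range range of the lower cutoff in Hz (default 20-60).
#' @param high_range range of the upper cutoff in Hz (default 8000-16000).
#' @param order Butterworth order (default 4).
#' @param ramp_ms on/off ramp in ms.
#' @return an [audio_clip()] with RMS 0.1; attributes `low_cut`, `high_cut`.
#' @export
broadband_noise <- function(duration = 0.75, rate = 44100, seed = 1,
                            low_range = c(20, 60),
                            high_range = c(8000, 16000), order = 4,
                            ramp_ms = 250) {
  old <- local_seed(seed); on.exit(restore_seed(old))
  lo <- stats::runif(1, low_range[1], low_range[2])
  hi <- stats::runif(1, high_range[1], high_range[2])
  if (hi >= rate / 2) stop("upper cutoff must be below Nyquist")
  x <- stats::rnorm(round(duration * rate))
  bf <- signal::butter(order, c(lo, hi) / (rate / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  out <- set_rms(audio_clip(apply_ramps(y, rate, ramp_ms), rate), 0.1)
  attr(out, "low_cut") <- lo; attr(out, "high_cut") <- hi
  out
}

#' Equal-amplitude harmonic complex tone
#'
#' Partials at `n * f0` for `n` in `harmonics`, with phases set by
#' `phase_mode`: `"sine"` (all zero), `"cosine"` (all pi/2), `"random"`
#' (uniform per partial), or `"alternating"` (sine/cosine alternating with
#' harmonic number, which doubles the envelope periodicity of complexes made
#' of high-numbered harmonics).
#'
#' @param f0 fundamental frequency in Hz.
#' @param harmonics integer vector of harmonic numbers.
#' @param phase_mode phase rule.
#' @param duration seconds.
#' @param rate sample rate in Hz.
#' @param seed integer seed (used by `"random"`).
#' @param ramp_ms on/off ramp in ms.
#' @return an [audio_clip()] with RMS 0.1.
#' @export
harmonic_complex <- function(f0, harmonics = 1:10,
                             phase_mode = c("sine", "cosine", "random",
                                            "alternating"),
                             duration = 0.2, rate = 44100, seed = 1,
                             ramp_ms = 10) {
  phase_mode <- match.arg(phase_mode)
  if (f0 * max(harmonics) >= rate / 2)
    stop("highest harmonic must be below Nyquist")
  old <- local_seed(seed); on.exit(restore_seed(old))
  phases <- switch(phase_mode,
    sine = rep(0, length(harmonics)),
    cosine = rep(pi / 2, length(harmonics)),
    random = stats::runif(length(harmonics), 0, 2 * pi),
    alternating = ifelse(seq_along(harmonics) %% 2 == 1, 0, pi / 2))
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  x <- numeric(n)
  for (j in seq_along(harmonics))
    x <- x + sin(2 * pi * harmonics[j] * f0 * t + phases[j])
  set_rms(audio_clip(apply_ramps(x, rate, ramp_ms), rate), 0.1)
}

#' Trapezoidal spectral filter
#'
#' Frequency-domain gain: 0 dB inside the passband, falling at
#' `slope_db_per_octave` outside it; applied by FFT multiplication.
#'
#' @param clip an [audio_clip()] (mono).
#' @param passband numeric length-2 vector of passband edges in Hz.
#' @param slope_db_per_octave attenuation slope (default 50).
#' @return the filtered [audio_clip()].
#' @export
trapezoid_spectral_filter <- function(clip, passband,
                                      slope_db_per_octave = 50) {
  x <- as.numeric(clip$waveform)
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * clip$rate
  f[f > clip$rate / 2] <- clip$rate - f[f > clip$rate / 2]  # fold to +freqs
  gain_db <- numeric(n)
  lowf <- f < passband[1] & f > 0
  hif <- f > passband[2]
  gain_db[lowf] <- -slope_db_per_octave * log2(passband[1] / f[lowf])
  gain_db[hif] <- -slope_db_per_octave * log2(f[hif] / passband[2])
  gain_db[f == 0] <- -300
  y <- Re(stats::fft(X * 10^(gain_db / 20), inverse = TRUE)) / n
  audio_clip(y, clip$rate)
}

#' Threshold-equalizing masking noise
#'
#' Noise spectrally shaped so that power per ERB-wide band is constant across
#' frequency (power spectral density proportional to `1/ERB(f)`), the
#' operational core of threshold-equalizing noise; used to mask cochlear
#' distortion products and equate audibility across frequency.
#'
#' @param duration seconds.
#' @param rate sample rate in Hz.
#' @param level_per_erb_db target level per ERB band in dB re full-scale
#'   RMS 1.0 (default -50).
#' @param seed integer seed.
#' @return an [audio_clip()]; attribute `level_per_erb_db` records the
#'   calibrated per-ERB level.
#' @export
masking_noise_ten <- function(duration = 0.75, rate = 44100,
                              level_per_erb_db = -50, seed = 1) {
  old <- local_seed(seed); on.exit(restore_seed(old))
  n <- round(duration * rate)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  f[f > rate / 2] <- rate - f[f > rate / 2]
  shape <- 1 / sqrt(erb_bandwidth(pmax(f, 1)))
  shape[f == 0] <- 0
  shape[f < 20 | f > 0.45 * rate] <- 0
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  # calibrate so that power within one ERB at 1 kHz matches the target level
  p_erb <- erb_band_power(y, rate, 1000)
  target <- (10^(level_per_erb_db / 20))^2
  y <- y * sqrt(target / p_erb)
  out <- audio_clip(y, rate)
  attr(out, "level_per_erb_db") <- level_per_erb_db
  out
}

# power of a signal within one ERB centered at f0 (periodogram integration)
erb_band_power <- function(x, rate, f0) {
  n <- length(x)
  X <- stats::fft(x)
  p <- Mod(X)^2 / n^2
  f <- (seq_len(n) - 1) / n * rate
  half <- erb_bandwidth(f0) / 2
  band <- which(f >= f0 - half & f <= f0 + half)
  2 * sum(p[band])    # one-sided
}

#' Component level rule for tones in masking noise
#'
#' Returns the amplitude a sinusoidal component should have to sit
#' `margin_db` above the masked-threshold proxy (the noise power within one
#' ERB around the component frequency).
#'
#' @param noise an [audio_clip()] of masking noise.
#' @param freq component frequency in Hz.
#' @param margin_db margin above the audibility proxy (default 10; pure
#'   tones use 20).
#' @return peak amplitude for the component.
#' @export
component_level_above_threshold <- function(noise, freq, margin_db = 10) {
  p <- erb_band_power(as.numeric(noise$waveform), noise$rate, freq)
  rms <- sqrt(p) * 10^(margin_db / 20)
  rms * sqrt(2)
}

#' Set clip level in dB re full-scale RMS 1.0
#'
#' @param clip an [audio_clip()].
#' @param level_db target level in dB (`20*log10(rms)`).
#' @return the rescaled clip.
#' @export
set_level <- function(clip, level_db) set_rms(clip, 10^(level_db / 20))

#' Set clip RMS
#' @param clip an [audio_clip()].
#' @param rms target RMS amplitude.
#' @return the rescaled clip.
#' @export
set_rms <- function(clip, rms) {
  r0 <- clip_rms(clip)
  if (r0 == 0) return(clip)
  clip$waveform <- clip$waveform * (rms / r0)
  clip
}

#' Mix a target and background at a given SNR
#'
#' SNR is defined as the ratio of target RMS to background RMS, both measured
#' before mixing; the background is rescaled, the target left untouched.
#' Clips are trimmed/zero-padded to the target length.
#'
#' @param target,background [audio_clip()]s at the same rate.
#' @param snr_db signal-to-noise ratio in dB.
#' @return the mixed [audio_clip()].
#' @export
mix_at_snr <- function(target, background, snr_db) {
  if (target$rate != background$rate) stop("rates must match")
  tw <- as.matrix(target$waveform); bw <- as.matrix(background$waveform)
  n <- nrow(tw)
  if (nrow(bw) < n) bw <- rbind(bw, matrix(0, n - nrow(bw), ncol(bw)))
  bw <- bw[seq_len(n), , drop = FALSE]
  if (ncol(bw) == 1 && ncol(tw) == 2) bw <- cbind(bw, bw)
  g <- clip_rms(target) / (clip_rms(background) * 10^(snr_db / 20))
  mixed <- tw + bw * g
  if (ncol(mixed) == 1) mixed <- as.numeric(mixed)
  audio_clip(mixed, target$rate)
}

#' Toy binaural spatializer
#'
#' Renders a mono clip at a spherical position using schematic, lawful
#' binaural cues in place of measured head-related transfer functions:
#' a Woodworth interaural time difference
#' `tau(lambda) = (r/c) (lambda + sin lambda)` applied as a fractional delay
#' (lambda is the lateral angle, so front/back pairs share the ITD), a
#' frequency-dependent interaural level difference growing with lateral angle
#' and frequency, an elevation-dependent spectral notch, and a gentle
#' high-frequency shelf attenuation for rear locations as the only front/back
#' cue (preserving the front/back ambiguity of narrowband sources).
#'
#' @param clip a mono [audio_clip()].
#' @param azimuth_deg azimuth in degrees (0 front, 90 left, +/-180 back).
#' @param elevation_deg elevation in degrees.
#' @param head_radius head radius in meters (default 0.0875).
#' @param notch_base_hz,notch_octaves_per_40deg elevation-notch parameters
#'   (the notch band sits below the rear-shelf band so the two spectral cues
#'   remain separable).
#' @return a stereo [audio_clip()] (columns: left, right).
#' @export
toy_spatialize <- function(clip, azimuth_deg, elevation_deg = 0,
                           head_radius = 0.0875, notch_base_hz = 4200,
                           notch_octaves_per_40deg = 0.35) {
  x <- as.numeric(clip$waveform)
  rate <- clip$rate
  n <- length(x)
  az <- deg2rad(wrap_deg_180(azimuth_deg))
  el <- deg2rad(elevation_deg)
  lambda <- asin(pmin(pmax(sin(az) * cos(el), -1), 1))   # lateral angle
  itd <- (head_radius / 343) * (lambda + sin(lambda))    # + means left leads
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * rate
  fold <- f > rate / 2
  fpos <- f; fpos[fold] <- rate - f[fold]
  sgn <- ifelse(fold, -1, 1)                            # conjugate symmetry
  # frequency-dependent ILD (dB), positive toward the leading (left) ear
  ild <- pmin(12, pmax(0, 6 * log2(pmax(fpos, 1) / 500))) * sin(lambda)
  # elevation notch (applied to both ears)
  fn <- notch_base_hz * 2^(elevation_deg / 40 * notch_octaves_per_40deg)
  notch <- 1 - 0.85 * exp(-((fpos - fn) / (0.12 * fn))^2)
  # rear shelf: broad -12 dB attenuation above ~3 kHz (pinna/torso shadow),
  # the spectral front/back cue; spectrally flat sources express it as a
  # high-frequency roll-off while a pure tone (renormalized) does not
  behind <- abs(wrap_deg_180(azimuth_deg)) > 90
  shelf <- if (behind) 10^(-12 / 20 * stats::plogis((fpos - 3000) / 800)) else 1
  common <- notch * shelf
  delay <- function(tau) exp(-2i * pi * sgn * fpos * tau)
  gl <- 10^(+ild / 40); gr <- 10^(-ild / 40)            # split ILD across ears
  L <- Re(stats::fft(X * common * gl * delay(-itd / 2), inverse = TRUE)) / n
  R <- Re(stats::fft(X * common * gr * delay(+itd / 2), inverse = TRUE)) / n
  audio_clip(cbind(L, R), rate)
}

#' Loudspeaker grids used by the protocols
#'
#' `"array133"`: azimuths -90..90 and elevations -20..40 in 10-degree steps
#' (133 positions). `"grid504"`: the categorical training grid (see
#' [location_grid_504()]). `"frontal19"`: azimuths -90..90, elevation 0.
#' `"semicircle18"`: azimuths 0..180 in 10-degree steps omitting 90 (which
#' lacks an unambiguous front/back label).
#'
#' @param kind grid name.
#' @return data.frame with columns `azimuth`, `elevation` in degrees.
#' @export
speaker_grid <- function(kind = c("array133", "grid504", "frontal19",
                                  "semicircle18")) {
  kind <- match.arg(kind)
  switch(kind,
    array133 = expand.grid(azimuth = seq(-90, 90, 10),
                           elevation = seq(-20, 40, 10)),
    grid504 = location_grid_504(),
    frontal19 = data.frame(azimuth = seq(-90, 90, 10), elevation = 0),
    semicircle18 = data.frame(azimuth = setdiff(seq(0, 180, 10), 90),
                              elevation = 0))
}

#' Independent noise tokens at adjacent loudspeakers
#'
#' @param width_speakers odd number of adjacent 10-degree-spaced speakers
#'   (1, 3, 5, or 7).
#' @param center_az center azimuth in degrees.
#' @param duration,rate token duration and sample rate.
#' @param seed integer seed.
#' @return list of `list(clip, azimuth)` entries with independently sampled
#'   white-noise tokens.
#' @export
multi_speaker_noise <- function(width_speakers = 1, center_az = 0,
                                duration = 0.2, rate = 44100, seed = 1) {
  stopifnot(width_speakers %in% c(1, 3, 5, 7))
  half <- (width_speakers - 1) / 2
  azs <- center_az + seq(-half, half) * 10
  lapply(seq_along(azs), function(i) {
    old <- local_seed(derive_seed(seed, paste0("msn", i))); on.exit(restore_seed(old))
    x <- stats::rnorm(round(duration * rate))
    list(clip = set_rms(audio_clip(apply_ramps(x, rate, 10), rate), 0.1),
         azimuth = azs[i])
  })
}
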