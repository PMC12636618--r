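# Cochleagram front ends: ERB-spaced gammatone filterbank, half-wave
# rectification, power-law compression, lowpass/downsampling via a
# Kaiser-windowed sinc resampler, and center cropping.

#' Equivalent rectangular bandwidth (Glasberg-Moore)
#'
#' @param f frequency in Hz.
#' @return ERB in Hz: `24.7 * (0.00437*f + 1)`.
#' @export
erb_bandwidth <- function(f) 24.7 * (0.00437 * f + 1)

#' ERB-number scale and its inverse
#'
#' @param f frequency in Hz.
#' @return ERB-number: `21.4 * log10(0.00437*f + 1)`.
#' @export
erb_number <- function(f) 21.4 * log10(0.00437 * f + 1)

#' @rdname erb_number
#' @param n ERB-number value(s).
#' @export
erb_number_inverse <- function(n) (10^(n / 21.4) - 1) / 0.00437

#' Characteristic frequencies uniformly spaced on the ERB-number scale
#'
#' @param n number of channels (>= 2).
#' @param fmin,fmax endpoints in Hz (included exactly).
#' @return strictly increasing vector of n center frequencies.
#' @export
erb_spaced_cfs <- function(n, fmin, fmax) {
  if (n < 2 || fmin <= 0 || fmin >= fmax)
    stop("need n >= 2 and 0 < fmin < fmax")
  erb_number_inverse(seq(erb_number(fmin), erb_number(fmax), length.out = n))
}

#' Gammatone FIR kernel
#'
#' Fourth-order gammatone impulse response
#' `t^3 exp(-2*pi*b*t) cos(2*pi*cf*t)` with `b = 1.019 * ERB(cf)`, truncated
#' to `duration` and normalized to unit magnitude response at `cf`.
#'
#' @param cf characteristic frequency in Hz (must be below Nyquist).
#' @param rate sample rate in Hz.
#' @param duration kernel duration in seconds.
#' @return numeric kernel of length `round(duration * rate)`.
#' @export
gammatone_fir <- function(cf, rate, duration) {
  if (cf >= rate / 2) stop("gammatone cf must be below Nyquist (rate/2)")
  L <- round(duration * rate)
  t <- (seq_len(L) - 1) / rate
  b <- 1.019 * erb_bandwidth(cf)
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * cf * t)
  # normalize |H(cf)| = 1
  resp <- sum(g * exp(-2i * pi * cf * t))
  g / Mod(resp)
}

#' Kaiser window
#'
#' @param x positions in `[-1, 1]`.
#' @param beta shape parameter.
#' @return window values `I0(beta*sqrt(1-x^2)) / I0(beta)`.
#' @keywords internal
kaiser_window <- function(x, beta) {
  x <- pmin(pmax(x, -1), 1)
  exp(log_i0(beta * sqrt(pmax(0, 1 - x^2))) - log_i0(beta))
}

#' Kaiser-windowed sinc lowpass kernel
#'
#' @param fc cutoff frequency in Hz.
#' @param rate sample rate in Hz.
#' @param width number of sinc zero-crossings per side (64 by default).
#' @param beta Kaiser shape parameter.
#' @return symmetric odd-length kernel with unity DC gain.
#' @export
kaiser_sinc_kernel <- function(fc, rate, width = 64, beta = 14.76965) {
  h <- ceiling(width * rate / (2 * fc))
  n <- seq(-h, h)
  x <- 2 * fc * n / rate
  k <- (2 * fc / rate) * ifelse(n == 0, 1, sin(pi * x) / (pi * x))
  k <- k * kaiser_window(n / h, beta)
  k / sum(k)
}

# FFT convolution, centered ("same") alignment for odd-length symmetric
# kernels, causal alignment otherwise; operates on a matrix column-wise.
fft_filter <- function(x, kernel, align = c("causal", "centered")) {
  align <- match.arg(align)
  x <- as.matrix(x)
  n <- nrow(x); L <- length(kernel)
  nfft <- stats::nextn(n + L - 1, c(2, 3, 5))
  K <- stats::fft(c(kernel, numeric(nfft - L)))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  Y <- Re(stats::mvfft(X * K, inverse = TRUE)) / nfft
  off <- if (align == "centered") (L - 1) / 2 else 0
  Y[seq_len(n) + off, , drop = FALSE]
}

#' Resample audio with a Kaiser-windowed sinc anti-alias filter
#'
#' Rational-ratio polyphase resampling: zero-stuff by `p = to/gcd`, convolve
#' with a Kaiser-sinc lowpass (cutoff `fc`, default `rolloff * min(from,to)/2`),
#' and keep every `q = from/gcd`-th sample.
#'
#' @param x numeric vector or matrix (samples x channels).
#' @param from,to sample rates in Hz.
#' @param fc anti-alias cutoff in Hz (default from `rolloff`).
#' @param width,rolloff,beta resampler parameters (defaults 64, 0.94759,
#'   14.76965).
#' @return resampled signal of length `ceiling(n * to / from)`.
#' @export
resample_audio <- function(x, from, to, fc = NULL, width = 64,
                           rolloff = 0.94759, beta = 14.76965) {
  if (from == to && is.null(fc)) return(x)
  was_vec <- is.null(dim(x))
  x <- as.matrix(x)
  g <- gcd_int(round(from), round(to))
  p <- round(to) / g; q <- round(from) / g
  if (is.null(fc)) fc <- rolloff * min(from, to) / 2
  up_rate <- from * p
  if (p > 1) {
    xs <- matrix(0, nrow(x) * p, ncol(x))
    xs[seq(1, nrow(xs), by = p), ] <- x * p
  } else xs <- x
  k <- kaiser_sinc_kernel(fc, up_rate, width, beta)
  y <- fft_filter(xs, k, align = "centered")
  out <- y[seq(1, nrow(y), by = q), , drop = FALSE]
  n_out <- ceiling(nrow(x) * to / from)
  out <- out[seq_len(min(n_out, nrow(out))), , drop = FALSE]
  if (was_vec) as.numeric(out) else out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Periphery configuration presets
#'
#' Three presets are provided. `"localization"`: binaural, 40 ERB-spaced
#' channels between 40 Hz and 20 kHz, 25-ms FIR kernels at a 48 kHz native
#' rate, half-wave rectification, 0.3 power-law compression, then lowpass
#' (~3.79 kHz, the anti-alias cutoff of the 8 kHz resampler at the configured
#' rolloff) and downsampling to 8 kHz, center-cropped to 1 s (output
#' 2 x 40 x 8000). `"pitch"`: monaural, 100 channels between 60 Hz and
#' 16 kHz at a 40 kHz native rate, rectification, 3 kHz lowpass, compression,
#' downsampling to 20 kHz, center-cropped to 50 ms (output 100 x 1000).
#' `"toy_binaural"`: a reduced binaural configuration for desk-scale training
#' (24 channels, 16 kHz, no downsampling) used by the toy localization
#' studies.
#'
#' @param preset one of `"localization"`, `"pitch"`, `"toy_binaural"`.
#' @param ... named overrides of individual fields.
#' @return a list of class `periphery_config`.
#' @export
periphery_config <- function(preset = c("localization", "pitch", "toy_binaural"),
                             ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    localization = list(
      preset = "localization", ears = 2L, n_channels = 40L,
      cf_min = 40, cf_max = 20000, fir_duration = 0.025,
      compression_exponent = 0.3, lowpass_cutoff = 0.94759 * 8000 / 2,
      output_rate = 8000, crop_duration = 1.0,
      stage_order = "compress_then_lowpass", input_rate = 48000),
    pitch = list(
      preset = "pitch", ears = 1L, n_channels = 100L,
      cf_min = 60, cf_max = 16000, fir_duration = 0.050,
      compression_exponent = 0.3, lowpass_cutoff = 3000,
      output_rate = 20000, crop_duration = 0.050,
      stage_order = "lowpass_then_compress", input_rate = 40000),
    toy_binaural = list(
      preset = "toy_binaural", ears = 2L, n_channels = 24L,
      cf_min = 150, cf_max = 7000, fir_duration = 0.02,
      compression_exponent = 0.3, lowpass_cutoff = 0.94759 * 8000 / 2,
      output_rate = 16000, crop_duration = 0.20,
      stage_order = "compress_then_lowpass", input_rate = 16000))
  cfg$resampler <- list(width = 64, rolloff = 0.94759, beta = 14.76965)
  over <- list(...)
  cfg[names(over)] <- over
  if (cfg$cf_min >= cfg$cf_max) stop("cf_min must be < cf_max")
  nt <- cfg$crop_duration * cfg$output_rate
  if (abs(nt - round(nt)) > 1e-9)
    stop("crop_duration * output_rate must be integral")
  class(cfg) <- "periphery_config"
  cfg
}

#' Compute a cochleagram
#'
#' Pipeline per ear and channel: gammatone bandpass -> half-wave rectification
#' -> compression and lowpass in the order given by `config$stage_order` ->
#' Kaiser-sinc downsampling to `output_rate` -> center crop. Values are
#' clipped at zero after filtering, so the output is nonnegative.
#'
#' @param waveform numeric vector (mono) or samples x 2 matrix (stereo);
#'   channel count must match the preset's `ears`.
#' @param rate input sample rate in Hz; inputs at rates other than the
#'   preset's native `input_rate` are resampled first.
#' @param config a [periphery_config()].
#' @return An object of class `cochleagram`: a 3-d array ears x channels x
#'   time for binaural presets, or a channels x time matrix for monaural,
#'   with attributes `cfs` (Hz) and `rate` (output rate, Hz).
#' @export
cochleagram <- function(waveform, rate, config = periphery_config("localization")) {
  x <- as.matrix(waveform)
  if (ncol(x) != config$ears)
    stop("expected ", config$ears, " audio channel(s), got ", ncol(x))
  if (rate != config$input_rate)
    x <- resample_audio(x, rate, config$input_rate,
                        width = config$resampler$width,
                        rolloff = config$resampler$rolloff,
                        beta = config$resampler$beta)
  fs <- config$input_rate
  n_time_out <- as.integer(round(config$crop_duration * config$output_rate))
  min_in <- ceiling(config$crop_duration * fs)
  if (nrow(x) < min_in)
    stop("input too short: need at least ", config$crop_duration,
         " s (", min_in, " samples at ", fs, " Hz) after resampling")
  cfs <- erb_spaced_cfs(config$n_channels, config$cf_min, config$cf_max)
  kernels <- lapply(cfs, gammatone_fir, rate = fs, duration = config$fir_duration)
  rs <- config$resampler
  out <- array(0, dim = c(config$ears, config$n_channels, n_time_out))
  for (ear in seq_len(config$ears)) {
    # filterbank: one FFT of the input, multiply per-channel kernel spectra
    sub <- filterbank_apply(x[, ear], kernels)
    sub[sub < 0] <- 0                          # half-wave rectification
    if (config$stage_order == "compress_then_lowpass") {
      sub <- sub^config$compression_exponent
      sub <- resample_audio(sub, fs, config$output_rate,
                            fc = config$lowpass_cutoff,
                            width = rs$width, rolloff = rs$rolloff,
                            beta = rs$beta)
    } else {
      lp <- kaiser_sinc_kernel(config$lowpass_cutoff, fs, rs$width, rs$beta)
      sub <- fft_filter(sub, lp, align = "centered")
      sub[sub < 0] <- 0
      sub <- sub^config$compression_exponent
      sub <- resample_audio(sub, fs, config$output_rate,
                            width = rs$width, rolloff = rs$rolloff,
                            beta = rs$beta)
    }
    sub[sub < 0] <- 0                          # clip filtering undershoot
    # center crop
    n_have <- nrow(sub)
    start <- floor((n_have - n_time_out) / 2) + 1
    if (start < 1) stop("input too short for the configured crop window")
    out[ear, , ] <- t(sub[start:(start + n_time_out - 1), , drop = FALSE])
  }
  if (config$ears == 1L) {
    out <- out[1, , ]
    dim(out) <- c(config$n_channels, n_time_out)
  }
  structure(out, cfs = cfs, rate = config$output_rate, class = "cochleagram")
}

filterbank_apply <- function(x, kernels) {
  n <- length(x)
  L <- max(vapply(kernels, length, 1L))
  nfft <- stats::nextn(n + L - 1, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  KF <- vapply(kernels, function(k) stats::fft(c(k, numeric(nfft - length(k)))),
               complex(nfft))
  Y <- Re(stats::mvfft(X * KF, inverse = TRUE)) / nfft
  Y[seq_len(n), , drop = FALSE]
}
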