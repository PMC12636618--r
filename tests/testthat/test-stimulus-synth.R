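# Stimulus generators: spectral content, level arithmetic, determinism,
# binaural rendering.

test_that("pure tones have the right length, spectrum, and ramp", {
  tone <- pure_tone(600, duration = 0.75, rate = 44100)
  expect_identical(length(tone$waveform), as.integer(round(0.75 * 44100)))
  expect_equal(spectrum_peak_hz(tone$waveform, 44100), 600,
               tolerance = 44100 / length(tone$waveform) + 1e-9)
  # linear 250 ms ramp: envelope at 125 ms is 0.5
  i <- round(0.125 * 44100) + 1
  seg <- (i - 40):(i + 40)
  mid <- round(0.375 * 44100) + (-40:40)   # plateau reference
  ratio <- sqrt(mean(tone$waveform[seg]^2) / mean(tone$waveform[mid]^2))
  expect_equal(ratio, 0.5, tolerance = 0.01)
  expect_error(pure_tone(30000, rate = 44100), "Nyquist")
})

test_that("frequency jitter is log2-uniform within a half-octave total range", {
  draws <- sapply(1:10000, function(s) jitter_frequency(1000, 0.5, seed = s))
  expect_true(all(draws >= 1000 * 2^-0.25 & draws <= 1000 * 2^0.25))
  ks <- suppressWarnings(ks.test((log2(draws / 1000) + 0.25) / 0.5, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_identical(jitter_frequency(1000, 0.5, seed = 7),
                   jitter_frequency(1000, 0.5, seed = 7))
})

test_that("narrowband noise concentrates power in its band and is seeded", {
  nb <- narrowband_noise(2000, 1, duration = 0.5, rate = 44100, seed = 1)
  expect_gt(band_power_fraction(nb$waveform, 44100,
                                2000 * 2^-0.5, 2000 * 2^0.5), 0.9)
  nb2 <- narrowband_noise(2000, 1, duration = 0.5, rate = 44100, seed = 2)
  expect_lt(abs(cor(nb$waveform, nb2$waveform)), 0.05)
  expect_identical(narrowband_noise(2000, seed = 3)$waveform,
                   narrowband_noise(2000, seed = 3)$waveform)
})

test_that("broadband noise draws cutoffs in range with a flat mid spectrum", {
  los <- numeric(50); his <- numeric(50)
  for (s in 1:50) {
    bb <- broadband_noise(0.1, 44100, seed = s)
    los[s] <- attr(bb, "low_cut"); his[s] <- attr(bb, "high_cut")
  }
  expect_true(all(los >= 20 & los <= 60))
  expect_true(all(his >= 8000 & his <= 16000))
  bb <- broadband_noise(2, 44100, seed = 99)
  n <- length(bb$waveform)
  p <- Mod(fft(bb$waveform))[1:(n %/% 2)]^2
  f <- (0:(n %/% 2 - 1)) * 44100 / n
  sel <- f >= 2 * attr(bb, "low_cut") & f <= attr(bb, "high_cut") / 2
  # average in coarse bands; flat within +/- 3 dB
  band <- cut(f[sel], 20)
  lev <- 10 * log10(tapply(p[sel], band, mean))
  expect_lt(max(lev) - min(lev), 6)
})

test_that("harmonic complexes place partials at multiples of f0", {
  hc <- harmonic_complex(200, 1:10, "sine", duration = 0.2, rate = 44100,
                         ramp_ms = 0)
  n <- length(hc$waveform)
  mag <- Mod(fft(hc$waveform))[1:(n %/% 2)]
  f <- (0:(n %/% 2 - 1)) * 44100 / n
  peaks <- f[mag > 0.2 * max(mag)]
  dist_to_harm <- apply(abs(outer(peaks, 200 * (1:10), "-")), 1, min)
  expect_true(all(dist_to_harm < 44100 / n + 1e-9))
  expect_true(max(peaks) <= 2000 + 5)
  # phase pattern leaves the magnitude spectrum unchanged
  hr <- harmonic_complex(200, 1:10, "random", duration = 0.2, rate = 44100,
                         seed = 5, ramp_ms = 0)
  magr <- Mod(fft(hr$waveform))[1:(n %/% 2)]
  pk <- which(mag > 0.2 * max(mag))
  expect_equal(magr[pk] / mag[pk], rep(1, length(pk)), tolerance = 1e-6)
  expect_error(harmonic_complex(2000, 1:30, rate = 44100), "Nyquist")
})

test_that("alternating phase doubles the envelope rate of high harmonics", {
  rate <- 44100
  alt <- harmonic_complex(100, 18:30, "alternating", duration = 0.3,
                          rate = rate, ramp_ms = 0)
  sin_ <- harmonic_complex(100, 18:30, "sine", duration = 0.3, rate = rate,
                           ramp_ms = 0)
  env_acf <- function(x, lag) {
    e <- abs(x) - mean(abs(x))
    sum(e[1:(length(e) - lag)] * e[(lag + 1):length(e)]) / sum(e^2)
  }
  l_half <- round(rate / 200)    # one period of 2*f0
  l_full <- round(rate / 100)    # one period of f0
  # alternating phase: envelope repeats at 2*f0, so the half-period
  # autocorrelation approaches the full-period one; sine phase does not
  gap_alt <- env_acf(alt$waveform, l_full) - env_acf(alt$waveform, l_half)
  gap_sin <- env_acf(sin_$waveform, l_full) - env_acf(sin_$waveform, l_half)
  expect_lt(gap_alt, gap_sin - 0.1)
})

test_that("the trapezoidal filter attenuates at its stated slope", {
  rate <- 44100
  probe <- function(freq, pb) {
    tone <- pure_tone(freq, 0.5, ramp_ms = 10, rate = rate)
    filt <- trapezoid_spectral_filter(tone, pb, 50)
    20 * log10(clip_rms(filt) / clip_rms(tone))
  }
  expect_equal(probe(500, c(1000, 4000)), -50, tolerance = 1)
  expect_equal(probe(2000, c(1000, 4000)), 0, tolerance = 0.1)
  # cascading doubles the slope
  tone <- pure_tone(500, 0.5, ramp_ms = 10, rate = rate)
  once <- trapezoid_spectral_filter(tone, c(1000, 4000), 50)
  twice <- trapezoid_spectral_filter(once, c(1000, 4000), 50)
  expect_equal(20 * log10(clip_rms(twice) / clip_rms(tone)), -100,
               tolerance = 2)
})

test_that("threshold-equalizing noise has constant power per ERB", {
  ten <- masking_noise_ten(1, 44100, level_per_erb_db = -50, seed = 1)
  ebp <- getFromNamespace("erb_band_power", "percept")
  freqs <- c(100, 250, 500, 1000, 2000, 4000, 8000, 10000)
  lev <- sapply(freqs, function(f)
    10 * log10(ebp(as.numeric(ten$waveform), 44100, f)))
  expect_lt(max(lev) - min(lev), 4)   # +/- 2 dB around the mean
  expect_equal(lev[freqs == 1000], -50, tolerance = 0.5)  # calibrated at 1 kHz
  # margin helper: +20 dB exceeds +10 dB by exactly 10 dB
  a10 <- component_level_above_threshold(ten, 1000, 10)
  a20 <- component_level_above_threshold(ten, 1000, 20)
  expect_equal(20 * log10(a20 / a10), 10, tolerance = 1e-9)
  expect_identical(masking_noise_ten(0.2, 44100, seed = 5)$waveform,
                   masking_noise_ten(0.2, 44100, seed = 5)$waveform)
})

test_that("level setting and SNR mixing follow RMS arithmetic", {
  bb <- broadband_noise(0.2, 44100, seed = 1)
  expect_equal(clip_rms(set_rms(bb, 0.1)), 0.1, tolerance = 1e-6)
  expect_equal(clip_rms(set_level(bb, -20)), 0.1, tolerance = 1e-6)
  tgt <- pure_tone(1000, 0.2, ramp_ms = 0, rate = 44100)
  bg <- broadband_noise(0.2, 44100, seed = 2)
  mix0 <- mix_at_snr(tgt, bg, 0)
  # at 0 dB the scaled background RMS equals the target RMS
  g <- clip_rms(tgt) / clip_rms(bg)
  expect_equal(clip_rms(audio_clip(bg$waveform * g, 44100)), clip_rms(tgt),
               tolerance = 1e-6)
  g6 <- clip_rms(tgt) / (clip_rms(bg) * 10^(6.02 / 20))
  expect_equal((clip_rms(tgt) / (clip_rms(bg) * g6)), 2, tolerance = 1e-3)
  expect_identical(length(mix0$waveform), length(tgt$waveform))
})

test_that("the toy spatializer produces lawful ITD and mirror symmetry", {
  rate <- 48000
  bb <- broadband_noise(0.3, rate, seed = 3, high_range = c(9000, 10000))
  xcl <- function(st) {
    L <- st$waveform[, 1]; R <- st$waveform[, 2]
    n <- length(L)
    cc <- Re(fft(fft(c(L, rep(0, n))) * Conj(fft(c(R, rep(0, n)))),
                 inverse = TRUE))
    lags <- c(0:(n - 1), -(n:1))
    lags[which.max(cc)]
  }
  expect_lte(abs(xcl(toy_spatialize(bb, 0))), 1)
  # positive azimuth = left: the left channel leads by the Woodworth ITD
  lag90 <- xcl(toy_spatialize(bb, 90)) / rate
  expect_lt(abs(abs(lag90) - (0.0875 / 343) * (pi / 2 + 1)), 1.5 / rate)
  s30 <- toy_spatialize(bb, 30)
  sm30 <- toy_spatialize(bb, -30)
  expect_lt(max(abs(s30$waveform - sm30$waveform[, c(2, 1)])), 1e-6)
})

test_that("speaker grids have the documented counts", {
  expect_identical(nrow(speaker_grid("array133")), 133L)
  expect_identical(nrow(speaker_grid("grid504")), 504L)
  expect_identical(nrow(speaker_grid("frontal19")), 19L)
  sg <- speaker_grid("semicircle18")
  expect_identical(nrow(sg), 18L)
  expect_false(90 %in% sg$azimuth)
})

test_that("multi-speaker noise produces independent adjacent tokens", {
  ms <- multi_speaker_noise(7, 0, duration = 0.2, rate = 16000, seed = 4)
  expect_identical(sapply(ms, `[[`, "azimuth"), seq(-30, 30, 10))
  w <- sapply(ms, function(e) e$clip$waveform)
  cors <- abs(cor(w)[upper.tri(diag(7))])
  expect_true(all(cors < 0.05))
  expect_identical(length(multi_speaker_noise(1, 0, seed = 1)), 1L)
})
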