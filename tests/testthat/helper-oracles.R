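# Independent oracles used across tests.

# log I0 via its power series in log space (converged, stable for large kappa)
series_log_i0 <- function(kappa) {
  vapply(kappa, function(k) {
    if (k == 0) return(0)
    m <- 0:max(200, ceiling(3 * k))
    terms <- 2 * m * log(k / 2) - 2 * lgamma(m + 1)
    mx <- max(terms)
    mx + log(sum(exp(terms - mx)))
  }, numeric(1))
}

# midpoint-rule quadrature of exp(logpdf) on (-pi, pi]
circle_quadrature <- function(logpdf_fn, n = 4096) {
  h <- 2 * pi / n
  th <- -pi + (seq_len(n) - 0.5) * h
  sum(exp(logpdf_fn(th))) * h
}

# random valid von Mises mixture (concentrations kept moderate so that the
# quadrature grid resolves every component)
random_vm_mixture <- function(K = 3, max_kappa = 64) {
  w <- stats::runif(K); w <- w / sum(w)
  von_mises_mixture(w,
                    cbind(stats::runif(K, -pi, pi), stats::runif(K, -pi, pi)),
                    matrix(stats::runif(2 * K, 1, max_kappa), K, 2))
}

random_gm_mixture <- function(K = 3) {
  w <- stats::runif(K); w <- w / sum(w)
  gaussian_mixture_1d(w, stats::runif(K, 4, 9), stats::runif(K, 0.001, 0.5))
}

# amplitude spectrum helpers
spectrum_peak_hz <- function(x, rate) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[1:(n %/% 2)]
  (which.max(mag) - 1) * rate / n
}

band_power_fraction <- function(x, rate, flo, fhi) {
  n <- length(x)
  p <- Mod(stats::fft(x))[1:(n %/% 2)]^2
  f <- (0:(n %/% 2 - 1)) * rate / n
  sum(p[f >= flo & f <= fhi]) / sum(p)
}

# narrow delta-like posterior stubs
loc_stub_at_truth <- function(kappa = 512) {
  stub_model(function(truth) {
    von_mises_mixture(1, cbind(deg2rad_t(truth$azimuth), deg2rad_t(truth$elevation)),
                      cbind(kappa, kappa))
  })
}

deg2rad_t <- function(x) x * pi / 180
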