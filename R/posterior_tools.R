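# Decision and uncertainty extraction from predicted posteriors: Monte Carlo
# MAP estimates, highest-posterior-density interval widths, front/back
# entropy, octave-constrained f0 MAP, and mode-local posterior variance.

#' Empirical posterior from mixture samples
#'
#' Draws samples from a von Mises mixture and bins the azimuth and elevation
#' marginals into 1-degree histograms (the spatial decisions studied here are
#' azimuthal or hemifield-based, so per-dimension marginals are used rather
#' than a joint 2-d histogram, which the sample budget could not populate).
#'
#' @param m a [von_mises_mixture()].
#' @param n number of Monte Carlo samples (default 5000).
#' @param bin_deg histogram bin width in degrees (default 1).
#' @param seed integer seed.
#' @return list of class `empirical_posterior` with `samples` (n x 2,
#'   degrees in `[-180, 180)`), `az_mass`, `el_mass` (normalized histogram
#'   masses), `breaks_deg`, `n`, `seed`.
#' @export
empirical_posterior <- function(m, n = 5000, bin_deg = 1, seed = 1) {
  stopifnot(n >= 1)
  s <- sample_von_mises_mixture(m, n, seed)
  deg <- wrap_deg_180(rad2deg(s))
  breaks <- seq(-180, 180, by = bin_deg)
  az <- tabulate(findInterval(deg[, 1], breaks, rightmost.closed = TRUE),
                 nbins = length(breaks) - 1)
  el <- tabulate(findInterval(deg[, 2], breaks, rightmost.closed = TRUE),
                 nbins = length(breaks) - 1)
  structure(list(samples = deg, az_mass = az / n, el_mass = el / n,
                 breaks_deg = breaks, n = n, seed = seed),
            class = "empirical_posterior")
}

# mode of a binned marginal with deterministic tie-breaking: maximal mass,
# ties broken by smallest |bin center| (toward the midline), then lowest index
hist_mode_center <- function(mass, breaks) {
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mx <- max(mass)
  cand <- which(mass >= mx - 1e-15)
  cand <- cand[order(abs(centers[cand]), cand)]
  centers[cand[1]]
}

#' Monte Carlo MAP estimate of a von Mises mixture
#'
#' Draws `n` samples, builds 1-degree marginal histograms, and returns the
#' centers of the modal bins.
#'
#' @inheritParams empirical_posterior
#' @return named numeric vector `c(azimuth, elevation)` in degrees
#'   (`[-180, 180)` convention), with the `empirical_posterior` attached as
#'   attribute `posterior`.
#' @export
map_estimate <- function(m, n = 5000, bin_deg = 1, seed = 1) {
  ep <- empirical_posterior(m, n, bin_deg, seed)
  out <- c(azimuth = hist_mode_center(ep$az_mass, ep$breaks_deg),
           elevation = hist_mode_center(ep$el_mass, ep$breaks_deg))
  attr(out, "posterior") <- ep
  out
}

#' Width of the circular highest-posterior-density interval
#'
#' The narrowest contiguous arc of histogram bins containing at least `mass`
#' of the posterior, found by scanning all circular windows of every length.
#'
#' @param posterior an `empirical_posterior`, or a normalized histogram mass
#'   vector over equal-width circular bins.
#' @param mass target probability mass (default 0.5).
#' @param dimension `"azimuth"` or `"elevation"` when an
#'   `empirical_posterior` is given.
#' @return interval width in degrees.
#' @export
hpd_width <- function(posterior, mass = 0.5,
                      dimension = c("azimuth", "elevation")) {
  dimension <- match.arg(dimension)
  if (inherits(posterior, "empirical_posterior")) {
    p <- if (dimension == "azimuth") posterior$az_mass else posterior$el_mass
    bin <- diff(posterior$breaks_deg[1:2])
  } else {
    p <- posterior / sum(posterior)
    bin <- 360 / length(p)
  }
  nb <- length(p)
  cs <- cumsum(c(0, p, p))      # doubled for circular windows
  for (L in seq_len(nb)) {
    w <- cs[(L + 1):(L + nb)] - cs[1:nb]
    if (max(w) >= mass - 1e-12) return(L * bin)
  }
  nb * bin
}

#' HPD interval of one-dimensional samples
#'
#' Narrowest interval containing `mass` of the samples (order-statistics
#' scan); used for linear variables such as log-f0 and for calibration
#' coverage checks.
#'
#' @param samples numeric vector.
#' @param mass target probability mass (default 0.5).
#' @return named vector `c(lower, upper, width)`.
#' @export
hpd_interval_1d <- function(samples, mass = 0.5) {
  s <- sort(samples)
  n <- length(s)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(lower = s[1], upper = s[n], width = s[n] - s[1]))
  widths <- s[(m + 1):n] - s[1:(n - m)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m], width = widths[i])
}

#' Front/back posterior mass and binary entropy
#'
#' Integrates the azimuthal posterior over the front hemifield
#' (`|azimuth| <= 90` degrees in the `[-180, 180)` convention; the boundary
#' is assigned to "front") and returns the entropy of the resulting binomial
#' distribution in bits. This is the model's confidence measure for binary
#' front/back judgments: 1 bit at `p_front = 0.5`, 0 bits at certainty.
#'
#' @param posterior an `empirical_posterior`, or a vector of azimuth samples
#'   in degrees (`[-180, 180)`).
#' @return list with `p_front`, `entropy_bits`, and the implied `response`
#'   (`"front"` if `p_front >= 0.5` else `"back"`).
#' @export
front_back_entropy <- function(posterior) {
  az <- if (inherits(posterior, "empirical_posterior"))
    posterior$samples[, 1] else as.numeric(posterior)
  p <- mean(abs(az) <= 90)
  list(p_front = p, entropy_bits = binary_entropy_bits(p),
       response = if (p >= 0.5) "front" else "back")
}

#' Binary entropy in bits
#' @param p probability in `[0, 1]`.
#' @return `-p*log2(p) - (1-p)*log2(1-p)` with `0*log(0) := 0`.
#' @export
binary_entropy_bits <- function(p) {
  term <- function(q) ifelse(q <= 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Octave-constrained MAP f0 estimate
#'
#' MAP over the log-f0 posterior restricted to a +/- 1 octave window centered
#' on the nominal f0 (mirroring the assumption that the two tones of a
#' discrimination trial have nearby f0s). Samples inside
#' `[log(nominal/2), log(2*nominal))` (half-open upper edge) are binned at
#' 1/16-semitone resolution; if no sample lands in the window the density is
#' evaluated on a grid over the window instead.
#'
#' @param m a [gaussian_mixture_1d()].
#' @param nominal_f0 nominal f0 in Hz.
#' @param n number of Monte Carlo samples (default 5000).
#' @param seed integer seed.
#' @return MAP estimate in Hz.
#' @export
constrained_map_f0 <- function(m, nominal_f0, n = 5000, seed = 1) {
  stopifnot(nominal_f0 > 0)
  s <- sample_gaussian_mixture(m, n, seed)
  lo <- log(nominal_f0 / 2); hi <- log(2 * nominal_f0)
  bin <- log(2) / 12 / 16                     # 1/16 semitone in natural log
  inw <- s[s >= lo & s < hi]
  if (length(inw) > 0) {
    breaks <- seq(lo, hi + bin, by = bin)
    counts <- tabulate(findInterval(inw, breaks), nbins = length(breaks) - 1)
    centers <- breaks[-length(breaks)] + bin / 2
    mx <- max(counts)
    cand <- which(counts == mx)
    cand <- cand[order(abs(centers[cand] - log(nominal_f0)), cand)]
    return(exp(centers[cand[1]]))
  }
  # fallback: window-restricted density grid evaluation
  grid <- seq(lo, hi - 1e-12, length.out = 4096)
  exp(grid[which.max(gm_mixture_logpdf(grid, m))])
}

#' Posterior variance within a one-octave window around the mode
#'
#' Locates the posterior mode by dense grid search, restricts the density to
#' `[mode - ln2/2, mode + ln2/2]`, renormalizes, and returns its variance by
#' grid quadrature. A summary of the width of the dominant posterior mode in
#' squared log-f0 units, used as the uncertainty measure for pitch
#' discrimination.
#'
#' @param m a [gaussian_mixture_1d()].
#' @param window window width in log-f0 units (default `log(2)`, one octave).
#' @return variance of the windowed, renormalized density.
#' @export
mode_local_variance <- function(m, window = log(2)) {
  b <- m$bounds
  sd_min <- sqrt(min(m$variances))
  # coarse mode search over the support, then local refinement
  coarse <- seq(b$mean_lb_logf0 - 0.5, b$mean_ub_logf0 + 0.5,
                by = min(2e-4, sd_min / 5 + 1e-9))
  i <- which.max(gm_mixture_logpdf(coarse, m))
  step <- diff(coarse[1:2])
  fine <- seq(coarse[i] - 2 * step, coarse[i] + 2 * step, length.out = 801)
  mode <- fine[which.max(gm_mixture_logpdf(fine, m))]
  # quadrature on the window
  npts <- max(4001L, min(200001L, ceiling(window / (sd_min / 20))))
  g <- seq(mode - window / 2, mode + window / 2, length.out = npts)
  w <- exp(gm_mixture_logpdf(g, m))
  w <- w / sum(w)
  mu <- sum(w * g)
  sum(w * (g - mu)^2)
}
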