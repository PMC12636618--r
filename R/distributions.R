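# Mixture distributions and constrained parameter transforms for the
# uncertainty readouts: von Mises mixtures over (azimuth, elevation) and
# univariate Gaussian mixtures over s = log f0 (natural-log Hz).

#' Default readout parameter bounds
#'
#' Bounds used by the constraint transforms of the mixture readouts: the
#' concentration parameters of the von Mises readout are clipped to
#' `[conc_lb, conc_ub]`, the component means of the log-f0 readout to
#' `[mean_lb_logf0, mean_ub_logf0]` (natural-log Hz, spanning roughly the
#' audible range e^3 ~ 20 Hz to e^10 ~ 22 kHz), and variances are floored at
#' `var_epsilon` after the softplus transform.
#'
#' @return A list with elements `conc_lb`, `conc_ub`, `mean_lb_logf0`,
#'   `mean_ub_logf0`, `var_epsilon`.
#' @export
readout_bounds <- function() {
  list(conc_lb = 1, conc_ub = 512,
       mean_lb_logf0 = 3, mean_ub_logf0 = 10,
       var_epsilon = 1e-9)
}

#' Wrap angles into (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return Angles wrapped into the half-open interval (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi to -pi; the convention here is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Spherical location (azimuth, elevation)
#'
#' @param azimuth,elevation angles in radians; wrapped into (-pi, pi].
#' @return An object of class `spherical_location`: a named numeric vector.
#' @export
spherical_location <- function(azimuth, elevation) {
  structure(c(azimuth = wrap_angle(azimuth), elevation = wrap_angle(elevation)),
            class = "spherical_location")
}

simplex_check <- function(w, tol = 1e-9) {
  if (any(w < 0)) stop("mixture weights must be nonnegative")
  if (abs(sum(w) - 1) > tol) stop("mixture weights must sum to 1 (tol 1e-9)")
  invisible(w)
}

#' Von Mises mixture over azimuth and elevation
#'
#' A finite mixture of K factorized bivariate von Mises components; each
#' component has a circular mean and concentration per coordinate.
#'
#' @param weights simplex vector of length K.
#' @param means K x 2 matrix of circular means in radians
#'   (columns: azimuth, elevation); wrapped into (-pi, pi].
#' @param concentrations K x 2 matrix of concentrations, each within the
#'   readout bounds.
#' @param bounds readout bounds, see [readout_bounds()].
#' @return Object of class `von_mises_mixture`.
#' @export
von_mises_mixture <- function(weights, means, concentrations,
                              bounds = readout_bounds()) {
  means <- matrix(means, ncol = 2)
  concentrations <- matrix(concentrations, ncol = 2)
  K <- length(weights)
  stopifnot(nrow(means) == K, nrow(concentrations) == K)
  simplex_check(weights)
  if (any(concentrations < bounds$conc_lb - 1e-12) ||
      any(concentrations > bounds$conc_ub + 1e-12))
    stop("concentrations outside [", bounds$conc_lb, ", ", bounds$conc_ub, "]")
  structure(list(K = K, weights = as.numeric(weights),
                 means = wrap_angle(means), concentrations = concentrations,
                 bounds = bounds),
            class = "von_mises_mixture")
}

#' Univariate Gaussian mixture over log-f0
#'
#' @param weights simplex vector of length K.
#' @param means K component means in natural-log Hz, within `[3, 10]`.
#' @param variances K positive component variances (>= var_epsilon).
#' @param bounds readout bounds, see [readout_bounds()].
#' @return Object of class `gaussian_mixture_1d`.
#' @export
gaussian_mixture_1d <- function(weights, means, variances,
                                bounds = readout_bounds()) {
  K <- length(weights)
  stopifnot(length(means) == K, length(variances) == K)
  simplex_check(weights)
  if (any(variances < bounds$var_epsilon * (1 - 1e-6)))
    stop("variances must be >= var_epsilon")
  if (any(means < bounds$mean_lb_logf0 - 1e-12) ||
      any(means > bounds$mean_ub_logf0 + 1e-12))
    stop("means outside [", bounds$mean_lb_logf0, ", ", bounds$mean_ub_logf0, "]")
  structure(list(K = K, weights = as.numeric(weights), means = as.numeric(means),
                 variances = as.numeric(variances), bounds = bounds),
            class = "gaussian_mixture_1d")
}

#' Negative log-likelihood of y under a univariate Gaussian
#'
#' The heteroscedastic regression loss: when the variance is held constant it
#' is an affine function of the squared error, so minimizing it reduces to
#' ordinary least squares; when the variance is predicted from the input it
#' couples accuracy of the mean with calibration of the spread.
#'
#' @param y observed value(s).
#' @param mu predicted mean(s).
#' @param sigma2 predicted variance(s), strictly positive.
#' @return `log(2*pi)/2 + log(sigma2)/2 + (y - mu)^2 / (2*sigma2)`.
#' @export
univariate_gaussian_nll <- function(y, mu, sigma2) {
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  log(2 * pi) / 2 + log(sigma2) / 2 + (y - mu)^2 / (2 * sigma2)
}

# Abramowitz & Stegun piecewise polynomial coefficients for I0 and I1,
# split at the textbook switch point 3.75.
.i0_small <- c(1, 3.5156229, 3.0899424, 1.2067492, 0.2659732, 0.0360768,
               0.0045813)
.i0_large <- c(0.39894228, 0.01328592, 0.00225319, -0.00157565, 0.00916281,
               -0.02057706, 0.02635537, -0.01647633, 0.00392377)
.i1_small <- c(0.5, 0.87890594, 0.51498869, 0.15084934, 0.02658733,
               0.00301532, 0.00032411)
.i1_large <- c(0.39894228, -0.03988024, -0.00362018, 0.00163801, -0.01031555,
               0.02282967, -0.02895312, 0.01787654, -0.00420059)

.polyval_asc <- function(coef, x) {
  # coefficients in ascending powers
  acc <- 0
  for (c_i in rev(coef)) acc <- acc * x + c_i
  acc
}

#' Log of the modified Bessel function I0
#'
#' Piecewise polynomial implementation: for `kappa < 3.75` the standard
#' small-argument expansion of I0 is evaluated and logged; for larger
#' arguments the asymptotic form `I0(k) ~ exp(k)/sqrt(k) * P(3.75/k)` is used
#' in log space, which is stable up to and beyond the concentration upper
#' bound of 512.
#'
#' @param kappa nonnegative concentration value(s).
#' @return `log(I0(kappa))`, vectorized.
#' @export
log_i0 <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  out <- numeric(length(kappa))
  small <- kappa < 3.75
  if (any(small)) {
    t2 <- (kappa[small] / 3.75)^2
    out[small] <- log(.polyval_asc(.i0_small, t2))
  }
  if (any(!small)) {
    k <- kappa[!small]
    out[!small] <- k - 0.5 * log(k) + log(.polyval_asc(.i0_large, 3.75 / k))
  }
  out
}

#' Log of the modified Bessel function I1
#'
#' Companion to [log_i0()], used for the derivative of the von Mises
#' normalizer: `d/dk log I0(k) = I1(k)/I0(k)`.
#'
#' @param kappa nonnegative value(s).
#' @return `log(I1(kappa))`; `-Inf` at 0.
#' @export
log_i1 <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be nonnegative")
  out <- numeric(length(kappa))
  small <- kappa < 3.75
  if (any(small)) {
    k <- kappa[small]
    t2 <- (k / 3.75)^2
    out[small] <- log(k) + log(.polyval_asc(.i1_small, t2))
  }
  if (any(!small)) {
    k <- kappa[!small]
    out[!small] <- k - 0.5 * log(k) + log(.polyval_asc(.i1_large, 3.75 / k))
  }
  out
}

#' Ratio I1(kappa)/I0(kappa)
#'
#' The derivative of `log I0`; needed by gradient-based training of the von
#' Mises readout.
#'
#' @param kappa nonnegative value(s).
#' @return `I1(kappa)/I0(kappa)` in `[0, 1)`.
#' @export
bessel_ratio_i1_i0 <- function(kappa) {
  out <- numeric(length(kappa))
  pos <- kappa > 0
  out[pos] <- exp(log_i1(kappa[pos]) - log_i0(kappa[pos]))
  out
}

#' Von Mises log-density
#'
#' @param theta angle(s) in radians.
#' @param mu circular mean in radians.
#' @param kappa nonnegative concentration.
#' @return `kappa*cos(theta - mu) - log(2*pi) - log_i0(kappa)`.
#' @export
von_mises_logpdf <- function(theta, mu, kappa) {
  kappa * cos(theta - mu) - log(2 * pi) - log_i0(kappa)
}

#' Numerically stable log-sum-exp
#' @param x numeric vector (or matrix with `rows = TRUE` reduction by row).
#' @return `log(sum(exp(x)))` computed stably.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

row_logsumexp <- function(x) {
  m <- apply(x, 1, max)
  m + log(rowSums(exp(x - m)))
}

#' Log-density of a von Mises mixture at spherical locations
#'
#' Evaluates `log sum_k alpha_k p_k(theta_az) p_k(theta_el)` by log-sum-exp.
#'
#' @param y a `spherical_location`, or an n x 2 matrix of
#'   (azimuth, elevation) radians.
#' @param m a [von_mises_mixture()].
#' @return numeric vector of log-densities.
#' @export
vm_mixture_logpdf <- function(y, m) {
  y <- matrix(y, ncol = 2)
  n <- nrow(y)
  # n x K matrices of per-coordinate log-densities
  terms <- matrix(log(pmax(m$weights, .Machine$double.xmin)),
                  nrow = n, ncol = m$K, byrow = TRUE)
  for (k in seq_len(m$K)) {
    terms[, k] <- terms[, k] +
      von_mises_logpdf(y[, 1], m$means[k, 1], m$concentrations[k, 1]) +
      von_mises_logpdf(y[, 2], m$means[k, 2], m$concentrations[k, 2])
  }
  if (m$K == 1) as.numeric(terms) else row_logsumexp(terms)
}

#' Log-density of a univariate Gaussian mixture
#'
#' @param s value(s) on the log-f0 axis (natural-log Hz).
#' @param m a [gaussian_mixture_1d()].
#' @return numeric vector of log-densities.
#' @export
gm_mixture_logpdf <- function(s, m) {
  n <- length(s)
  terms <- matrix(log(pmax(m$weights, .Machine$double.xmin)),
                  nrow = n, ncol = m$K, byrow = TRUE)
  for (k in seq_len(m$K)) {
    terms[, k] <- terms[, k] +
      stats::dnorm(s, m$means[k], sqrt(m$variances[k]), log = TRUE)
  }
  if (m$K == 1) as.numeric(terms) else row_logsumexp(terms)
}

#' Softmax constraint for mixture weights
#'
#' @param logits finite numeric vector.
#' @return simplex vector of the same length.
#' @export
constrain_weights <- function(logits) {
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Circular mean constraint
#'
#' Raw head outputs (u, v) are squashed by tanh so they are legitimate sine
#' and cosine components, then mapped to the circle by atan2.
#'
#' @param u,v finite reals (sine-component and cosine-component raw outputs).
#' @return angle in (-pi, pi]; the degenerate case tanh(u) = tanh(v) = 0
#'   returns 0 by convention (with a warning).
#' @export
constrain_circular_mean <- function(u, v) {
  s <- tanh(u)
  c <- tanh(v)
  out <- atan2(s, c)
  deg <- (s == 0 & c == 0)
  if (any(deg)) {
    warning("degenerate circular mean (tanh(u) = tanh(v) = 0); returning 0")
    out[deg] <- 0
  }
  out
}

#' Bounded rectifier ("relux")
#'
#' Rectifying nonlinearity bounded below and above:
#' `min(max(x, lb), ub)`. Used to keep von Mises concentrations in
#' `[1, 512]` and log-f0 component means in `[3, 10]`.
#'
#' @param x numeric.
#' @param lb,ub bounds with `lb < ub`.
#' @return clipped values.
#' @export
relux <- function(x, lb, ub) {
  if (lb >= ub) stop("relux requires lb < ub")
  pmin(pmax(x, lb), ub)
}

#' Softplus variance constraint
#'
#' @param v raw head output(s).
#' @param epsilon small positive floor (default 1e-9).
#' @return `softplus(v) + epsilon`, strictly positive.
#' @export
constrain_variance <- function(v, epsilon = 1e-9) {
  # numerically stable softplus
  sp <- ifelse(v > 30, v, log1p(exp(-abs(v))) + pmax(v, 0))
  sp + epsilon
}

# --- sampling -------------------------------------------------------------

#' Draw from a von Mises distribution (Best-Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu circular mean (radians).
#' @param kappa nonnegative concentration; 0 gives the uniform circle.
#' @return n angles in (-pi, pi]. Uses the current RNG stream.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(wrap_angle(stats::runif(n, -pi, pi)))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.4))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  wrap_angle(mu + out[seq_len(n)])
}

#' Sample from a von Mises mixture
#'
#' Component membership drawn from the mixture weights; each coordinate drawn
#' independently by the rejection sampler.
#'
#' @param m a [von_mises_mixture()].
#' @param n number of samples.
#' @param seed integer seed (the draw is a pure function of `(m, n, seed)`).
#' @return n x 2 matrix of (azimuth, elevation) radians; attribute
#'   `component` records component membership.
#' @export
sample_von_mises_mixture <- function(m, n, seed) {
  stopifnot(n >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  comp <- sample.int(m$K, n, replace = TRUE, prob = m$weights)
  out <- matrix(0, n, 2)
  for (k in unique(comp)) {
    idx <- which(comp == k)
    out[idx, 1] <- rvonmises(length(idx), m$means[k, 1], m$concentrations[k, 1])
    out[idx, 2] <- rvonmises(length(idx), m$means[k, 2], m$concentrations[k, 2])
  }
  colnames(out) <- c("azimuth", "elevation")
  attr(out, "component") <- comp
  out
}

#' Sample from a univariate Gaussian mixture
#'
#' @inheritParams sample_von_mises_mixture
#' @param m a [gaussian_mixture_1d()].
#' @return numeric vector of n draws on the log-f0 axis; attribute
#'   `component` records component membership.
#' @export
sample_gaussian_mixture <- function(m, n, seed) {
  stopifnot(n >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  comp <- sample.int(m$K, n, replace = TRUE, prob = m$weights)
  out <- stats::rnorm(n, m$means[comp], sqrt(m$variances[comp]))
  attr(out, "component") <- comp
  out
}

# --- JSON serialization ---------------------------------------------------

#' Serialize a mixture to JSON
#'
#' Keys: `kind`, `K`, `weights`, `means`, `concentrations` or `variances`,
#' `bounds`. Angles in radians; f0 means in natural-log Hz; matrices
#' row-major.
#'
#' @param m a mixture object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
mixture_to_json <- function(m, path = NULL) {
  if (inherits(m, "von_mises_mixture")) {
    obj <- list(kind = "von_mises_mixture", K = m$K, weights = m$weights,
                means = as.vector(t(m$means)),
                concentrations = as.vector(t(m$concentrations)),
                bounds = m$bounds)
  } else if (inherits(m, "gaussian_mixture_1d")) {
    obj <- list(kind = "gaussian_mixture_1d", K = m$K, weights = m$weights,
                means = m$means, variances = m$variances, bounds = m$bounds)
  } else stop("unsupported mixture class")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Deserialize a mixture from JSON
#'
#' @param x JSON string or path to a JSON file.
#' @return the mixture object.
#' @export
mixture_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  bounds <- if (!is.null(obj$bounds)) obj$bounds else readout_bounds()
  if (obj$kind == "von_mises_mixture") {
    von_mises_mixture(obj$weights,
                      matrix(obj$means, ncol = 2, byrow = TRUE),
                      matrix(obj$concentrations, ncol = 2, byrow = TRUE),
                      bounds)
  } else if (obj$kind == "gaussian_mixture_1d") {
    gaussian_mixture_1d(obj$weights, obj$means, obj$variances, bounds)
  } else stop("unknown mixture kind: ", obj$kind)
}
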