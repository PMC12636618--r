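# Mixture distributions, constraint transforms, and samplers.

test_that("univariate Gaussian NLL matches the closed form and the density", {
  expect_equal(univariate_gaussian_nll(0, 0, 1), 0.5 * log(2 * pi),
               tolerance = 1e-12)
  set.seed(42)
  y <- rnorm(50); mu <- rnorm(50); s2 <- runif(50, 0.1, 4)
  expect_equal(univariate_gaussian_nll(y, mu, s2),
               -dnorm(y, mu, sqrt(s2), log = TRUE), tolerance = 1e-12)
  expect_error(univariate_gaussian_nll(0, 0, -1), "positive")
})

test_that("with fixed variance the batch NLL is an affine map of the MSE", {
  set.seed(1)
  y <- rnorm(200); mu <- rnorm(200); s2 <- 0.7
  nll <- mean(univariate_gaussian_nll(y, mu, s2))
  mse <- mean((y - mu)^2)
  intercept <- log(2 * pi) / 2 + log(s2) / 2
  expect_equal(nll, intercept + mse / (2 * s2), tolerance = 1e-12)
})

test_that("log_i0 matches a converged power-series oracle over [0, 512]", {
  expect_identical(log_i0(0), 0)
  expect_equal(log_i0(1), series_log_i0(1), tolerance = 1e-4)
  kap <- c(seq(0, 4, 0.25), seq(5, 50, 5), 100, 256, 512)
  expect_lt(max(abs(log_i0(kap) - series_log_i0(kap))), 1e-4)
  # branch continuity at the 3.75 switch point
  d <- 1e-6
  expect_lt(abs(log_i0(3.75 - d) - log_i0(3.75 + d)), 1e-4)
  expect_error(log_i0(-1), "nonnegative")
})

test_that("I1/I0 ratio is the derivative of log_i0", {
  kap <- c(0.5, 2, 5, 50, 400)
  h <- 1e-5
  num <- (log_i0(kap + h) - log_i0(kap - h)) / (2 * h)
  expect_equal(bessel_ratio_i1_i0(kap), num, tolerance = 1e-4)
})

test_that("von Mises log-density: uniform limit, normal limit, normalization", {
  expect_equal(von_mises_logpdf(1.3, 0, 0), -log(2 * pi), tolerance = 1e-12)
  # large-concentration (wrapped normal) limit at the mean
  expect_equal(von_mises_logpdf(0.4, 0.4, 512), -0.5 * log(2 * pi / 512),
               tolerance = 1e-3)
  for (kappa in c(0, 1, 20, 512)) {
    z <- circle_quadrature(function(th) von_mises_logpdf(th, 0.7, kappa),
                           n = 65536)
    expect_equal(z, 1, tolerance = 1e-6)
  }
})

test_that("von Mises mixture density normalizes and matches a naive sum", {
  m0 <- von_mises_mixture(1, cbind(0, 0), cbind(0, 0),
                          bounds = modifyList(readout_bounds(), list(conc_lb = 0)))
  expect_equal(vm_mixture_logpdf(c(0.3, -2), m0), -2 * log(2 * pi),
               tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:3) {
    m <- random_vm_mixture()
    # 2-d quadrature on the torus
    n <- 1024
    h <- 2 * pi / n
    th <- -pi + (seq_len(n) - 0.5) * h
    az_d <- vapply(seq_len(m$K), function(k)
      exp(von_mises_logpdf(th, m$means[k, 1], m$concentrations[k, 1])),
      numeric(n))
    el_d <- vapply(seq_len(m$K), function(k)
      exp(von_mises_logpdf(th, m$means[k, 2], m$concentrations[k, 2])),
      numeric(n))
    integral <- sum((az_d * h) %*% (m$weights * t(el_d * h)))
    expect_equal(integral, 1, tolerance = 1e-3)
    # log-sum-exp path equals the naive sum where no underflow occurs
    y <- cbind(runif(20, -pi, pi), runif(20, -pi, pi))
    naive <- sapply(seq_len(20), function(i) {
      log(sum(sapply(seq_len(m$K), function(k)
        m$weights[k] *
          exp(von_mises_logpdf(y[i, 1], m$means[k, 1], m$concentrations[k, 1])) *
          exp(von_mises_logpdf(y[i, 2], m$means[k, 2], m$concentrations[k, 2])))))
    })
    ok <- is.finite(naive)
    expect_equal(vm_mixture_logpdf(y, m)[ok], naive[ok], tolerance = 1e-10)
  }
})

test_that("mixture density is invariant to a joint azimuthal rotation", {
  set.seed(11)
  m <- random_vm_mixture()
  y <- cbind(runif(30, -pi, pi), runif(30, -pi, pi))
  for (off in c(0.5, -2.1, pi)) {
    m2 <- von_mises_mixture(m$weights,
                            cbind(wrap_angle(m$means[, 1] + off), m$means[, 2]),
                            m$concentrations)
    y2 <- cbind(wrap_angle(y[, 1] + off), y[, 2])
    expect_lt(max(abs(vm_mixture_logpdf(y2, m2) - vm_mixture_logpdf(y, m))),
              1e-9)
  }
})

test_that("Gaussian mixture density normalizes and is symmetric when built so", {
  m1 <- gaussian_mixture_1d(1, 6, 1)
  expect_equal(gm_mixture_logpdf(6, m1), -0.5 * log(2 * pi), tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:3) {
    m <- random_gm_mixture()
    g <- seq(3 - 6, 10 + 6, length.out = 200001)
    z <- sum(exp(gm_mixture_logpdf(g, m))) * diff(g[1:2])
    expect_equal(z, 1, tolerance = 1e-6)
  }
  ms <- gaussian_mixture_1d(c(0.5, 0.5), c(5, 7), c(0.04, 0.04))
  x <- seq(0, 0.9, length.out = 101)
  expect_lt(max(abs(gm_mixture_logpdf(6 + x, ms) - gm_mixture_logpdf(6 - x, ms))),
            1e-12)
})

test_that("constraint transforms behave as specified", {
  expect_equal(constrain_weights(c(2, 2, 2, 2)), rep(0.25, 4))
  set.seed(3)
  l <- rnorm(5)
  expect_equal(constrain_weights(l + 13.7), constrain_weights(l),
               tolerance = 1e-12)
  expect_equal(constrain_weights(c(0, log(3))), c(0.25, 0.75),
               tolerance = 1e-12)
  expect_equal(constrain_circular_mean(0, 100), 0)
  expect_equal(constrain_circular_mean(100, 0), pi / 2)
  u <- rnorm(50); v <- rnorm(50)
  expect_equal(constrain_circular_mean(u, v), Arg(tanh(v) + 1i * tanh(u)),
               tolerance = 1e-12)
  expect_warning(z <- constrain_circular_mean(0, 0), "degenerate")
  expect_identical(z, 0)
  expect_equal(relux(0, 1, 512), 1)
  expect_equal(relux(1000, 1, 512), 512)
  expect_equal(relux(7, 1, 512), 7)
  expect_error(relux(0, 2, 1), "lb < ub")
  expect_equal(constrain_variance(-40), 1e-9, tolerance = 1e-6)
  expect_equal(constrain_variance(0), log(2) + 1e-9, tolerance = 1e-12)
  expect_equal(constrain_variance(20), 20, tolerance = 1e-6)
})

test_that("von Mises mixture sampler has the right marginals and occupancy", {
  m <- von_mises_mixture(1, cbind(0, 0), cbind(512, 512))
  s <- sample_von_mises_mixture(m, 50000, seed = 9)
  expect_equal(sd(s[, 1]), 1 / sqrt(512), tolerance = 0.1)
  # uniform at zero concentration
  mu0 <- von_mises_mixture(1, cbind(0, 0), cbind(0, 0),
                           bounds = modifyList(readout_bounds(), list(conc_lb = 0)))
  su <- sample_von_mises_mixture(mu0, 10000, seed = 10)
  ks <- suppressWarnings(ks.test((su[, 1] + pi) / (2 * pi), "punif"))
  expect_gt(ks$p.value, 0.01)
  m2 <- von_mises_mixture(c(0.8, 0.2), rbind(c(0, 0), c(pi, 0)),
                          rbind(c(100, 100), c(100, 100)))
  s2 <- sample_von_mises_mixture(m2, 10000, seed = 11)
  occ <- tabulate(attr(s2, "component"), 2) / 10000
  expect_lt(max(abs(occ - c(0.8, 0.2))), 0.02)
  # reproducibility
  expect_identical(sample_von_mises_mixture(m2, 100, seed = 4),
                   sample_von_mises_mixture(m2, 100, seed = 4))
})

test_that("Gaussian mixture sampler matches analytic moments", {
  m1 <- gaussian_mixture_1d(1, 6, 0.25)
  s <- sample_gaussian_mixture(m1, 50000, seed = 2)
  expect_lt(abs(mean(s) - 6), 3 * 0.5 / sqrt(50000) * 3)
  expect_equal(var(s), 0.25, tolerance = 0.1)
  m <- gaussian_mixture_1d(c(0.3, 0.7), c(5, 7.5), c(0.1, 0.3))
  mom_mean <- sum(m$weights * m$means)
  mom_var <- sum(m$weights * (m$variances + m$means^2)) - mom_mean^2
  s2 <- sample_gaussian_mixture(m, 50000, seed = 3)
  expect_equal(mean(s2), mom_mean, tolerance = 0.05 * abs(mom_mean))
  expect_equal(var(s2), mom_var, tolerance = 0.05 * mom_var)
})

test_that("Gaussian NLL over a sample is minimized at the sample mean", {
  set.seed(8)
  y <- rnorm(500, 2, 1)
  f <- function(mu) mean(univariate_gaussian_nll(y, mu, 1.3))
  h <- 1e-6
  grad_at_mean <- (f(mean(y) + h) - f(mean(y) - h)) / (2 * h)
  expect_lt(abs(grad_at_mean), 1e-6)
  expect_gt(f(mean(y) + 0.3), f(mean(y)))
  expect_gt(f(mean(y) - 0.3), f(mean(y)))
})

test_that("mixtures serialize to JSON and back", {
  set.seed(21)
  m <- random_vm_mixture()
  m2 <- mixture_from_json(mixture_to_json(m))
  expect_equal(m2$weights, m$weights, tolerance = 1e-12)
  expect_equal(m2$means, m$means, tolerance = 1e-12)
  expect_equal(m2$concentrations, m$concentrations, tolerance = 1e-12)
  g <- random_gm_mixture()
  g2 <- mixture_from_json(mixture_to_json(g))
  expect_equal(g2$means, g$means, tolerance = 1e-12)
  expect_equal(g2$variances, g$variances, tolerance = 1e-12)
})

test_that("mixture constructors validate their invariants", {
  expect_error(von_mises_mixture(c(0.5, 0.6), rbind(c(0, 0), c(1, 1)),
                                 rbind(c(1, 1), c(1, 1))), "sum to 1")
  expect_error(von_mises_mixture(1, cbind(0, 0), cbind(600, 1)), "outside")
  expect_error(gaussian_mixture_1d(1, 11, 0.1), "outside")
  expect_error(gaussian_mixture_1d(1, 5, 0), "var_epsilon")
})
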