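test_that("pb_params validates its arguments", {
  expect_error(pb_params(0, 1, 1), "alpha")
  expect_error(pb_params(1, -1, 1), "beta")
  expect_error(pb_params(1, 1, Inf), "gamma")
  p <- pb_params(1, 2, 3, lambda = 0.5)
  expect_equal(as.numeric(p), c(alpha = 1, beta = 2, gamma = 3))
})

test_that("analytic pmf normalizes and matches quadrature", {
  p <- pb_params(1, 10, 100)
  expect_equal(sum(dpb(0:500, p)), 1, tolerance = 1e-6)

  # independent oracle: adaptive quadrature of the Beta mixture integral
  quad <- vapply(0:300, function(n)
    integrate(function(x) dpois(n, 100 * x) * dbeta(x, 1, 10),
              0, 1, rel.tol = 1e-12)$value, numeric(1))
  expect_equal(dpb(0:300, p), quad, tolerance = 1e-8)
})

test_that("analytic pmf approaches the Poisson limit for large alpha", {
  p <- pb_params(1e6, 1, 5)
  expect_equal(dpb(0, p), exp(-5), tolerance = 1e-4)
  expect_equal(dpb(0:30, p), dpois(0:30, 5), tolerance = 1e-4)
})

test_that("Monte-Carlo pmf is normalized, seeded, and tracks the analytic pmf", {
  p <- pb_params(0.1, 0.5, 20)
  pm <- dpb_mc(0:150, p, N = 2000, seed = 3)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_equal(sum(pm), 1, tolerance = 1e-6) # shared draws: exact normalization
  expect_identical(pm, dpb_mc(0:150, p, N = 2000, seed = 3))

  # agreement with the analytic pmf within Monte-Carlo error
  pa <- dpb(0:50, p)
  se <- sqrt(pa * (1 - pa) / 2000) + 1e-8
  expect_true(all(abs(dpb_mc(0:50, p, N = 2000, seed = 11) - pa) < 4 * se))
})

test_that("sampling matches the analytic mean", {
  expect_equal(mean(rpb(1e5, pb_params(1, 1, 10), seed = 1)), 5,
               tolerance = 0.02)
  expect_equal(mean(rpb(1e5, pb_params(1e6, 1, 5), seed = 2)), 5,
               tolerance = 0.02)
  expect_identical(rpb(100, pb_params(1, 1, 10), seed = 9),
                   rpb(100, pb_params(1, 1, 10), seed = 9))
  expect_error(rpb(0, pb_params(1, 1, 1)), "positive")
})

test_that("factorial moments follow the closed form", {
  m <- pb_moments(pb_params(1, 1, 10))
  # gamma^i * E[c^i] with c ~ Beta(1,1): E[c] = 1/2, E[c^2] = 1/3, E[c^3] = 1/4
  expect_equal(m$e1, 5)
  expect_equal(m$e2, 100 / 3)
  expect_equal(m$e3, 250)
  expect_equal(m$mean, 5)
  expect_equal(m$variance, m$e2 + m$e1 - m$e1^2)

  # over-dispersion holds across a parameter grid
  for (a in c(0.01, 0.1, 1)) for (b in c(0.1, 1, 10)) for (g in c(1, 10, 100)) {
    mm <- pb_moments(pb_params(a, b, g))
    expect_gte(mm$variance, mm$mean - 1e-12)
  }
})

test_that("derived quantities match their definitions and scale correctly", {
  d <- pb_derived(pb_params(1, 10, 100))
  expect_equal(d$burst_size, 10)
  expect_equal(d$duty_cycle, 1 / 11)
  expect_equal(d$mean_expression, 100 / 11)
  expect_equal(pb_derived(pb_params(2, 2, 5))$duty_cycle, 0.5)
  expect_equal(pb_derived(pb_params(0.3, 0.7, 10),
                          frequency_convention = "activation")$burst_frequency,
               0.3)

  # identities: duty_cycle * gamma = mean = burst_size * burst_frequency
  for (a in c(0.05, 0.5)) for (b in c(0.2, 2)) {
    d1 <- pb_derived(pb_params(a, b, 30))
    expect_equal(d1$duty_cycle * 30, d1$mean_expression)
    expect_equal(d1$burst_size * d1$burst_frequency, d1$mean_expression)
  }

  # joint scaling of (alpha, beta, gamma) by c: duty cycle and burst size
  # fixed, burst frequency scales by c
  d1 <- pb_derived(pb_params(0.2, 0.8, 40))
  d3 <- pb_derived(pb_params(0.6, 2.4, 120))
  expect_equal(d3$duty_cycle, d1$duty_cycle)
  expect_equal(d3$burst_size, d1$burst_size)
  expect_equal(d3$burst_frequency, 3 * d1$burst_frequency)
})

test_that("autocorrelation at lag zero equals the stationary variance", {
  p <- pb_params(1, 10, 100, lambda = 1)
  expect_equal(pb_autocorrelation(p, 0), pb_moments(p)$variance,
               tolerance = 1e-8)
  expect_equal(pb_autocorrelation(p, 2.5), pb_autocorrelation(p, -2.5))
  expect_lt(pb_autocorrelation(p, 30), 1e-8)
})

test_that("spectral density is even, decays, and integrates the autocorrelation", {
  p <- pb_params(1, 10, 100, lambda = 1)
  expect_equal(pb_spectral_density(p, 3), pb_spectral_density(p, -3))
  expect_lt(pb_spectral_density(p, 1e4), 1e-4)
  # Wiener-Khinchin at omega = 0: S(0) = 2 * integral of R
  quad <- integrate(function(t) pb_autocorrelation(p, t), 0, Inf,
                    rel.tol = 1e-10)$value
  expect_equal(pb_spectral_density(p, 0), 2 * quad, tolerance = 1e-8)
})

test_that("the removable singularity at alpha + beta = lambda is continuous", {
  ps <- pb_params(0.4, 0.6, 50, lambda = 1) # alpha + beta = lambda exactly
  pn <- pb_params(0.4, 0.6 + 1e-4, 50, lambda = 1)
  expect_equal(pb_autocorrelation(ps, 1.3), pb_autocorrelation(pn, 1.3),
               tolerance = 1e-3)
  expect_equal(pb_spectral_density(ps, 0.7), pb_spectral_density(pn, 0.7),
               tolerance = 1e-3)
  expect_equal(pb_autocorrelation(ps, 0), pb_moments(ps)$variance,
               tolerance = 1e-10)
})

test_that("autocorrelation time has the expected limits and time scaling", {
  # promoter always on: plain birth-death process, tau_c = 1/lambda
  expect_equal(pb_autocorrelation_time(pb_params(1e7, 1, 5, lambda = 2)),
               0.5, tolerance = 1e-4)
  # rescaling absolute time by lambda
  t1 <- pb_autocorrelation_time(pb_params(1, 10, 100, lambda = 1))
  t2 <- pb_autocorrelation_time(pb_params(1, 10, 100, lambda = 4))
  expect_equal(t2, t1 / 4, tolerance = 1e-12)
})

test_that("Gillespie simulation reproduces the stationary mean and variance", {
  p <- pb_params(1, 10, 100, lambda = 1)
  x <- simulate_telegraph(p, t_end = 20000, dt = 0.1, seed = 5)
  expect_equal(mean(x), pb_moments(p)$mean, tolerance = 0.1)
  expect_equal(var(x), pb_moments(p)$variance, tolerance = 0.15)
  expect_identical(simulate_telegraph(p, 100, 0.1, seed = 3),
                   simulate_telegraph(p, 100, 0.1, seed = 3))
})
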