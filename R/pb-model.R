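#' Transcriptional bursting (Poisson-Beta) model parameters
#'
#' The two-state (telegraph) model of gene expression: a promoter switches
#' from inactive to active at rate `alpha`, back at rate `beta`, transcribes
#' at rate `gamma` while active, and transcripts degrade at rate
#' `lambda`. At stationarity the transcript count follows a Poisson-Beta
#' mixture whose shape depends on the rates only through the
#' degradation-normalized parameters, so `alpha`, `beta` and `gamma` are
#' expressed in units of `lambda` throughout, and `lambda` (default 1) is
#' only needed for quantities carrying absolute time units (burst frequency
#' in real time, autocorrelation time).
#'
#' @param alpha Promoter activation rate (units of `lambda`); > 0.
#' @param beta Promoter inactivation rate (units of `lambda`); > 0.
#' @param gamma Transcription rate in the active state (units of `lambda`); > 0.
#' @param lambda Absolute transcript degradation rate (1/time); > 0.
#' @return An object of class `pb_params`.
#' @examples
#' p <- pb_params(1, 10, 100)
#' pb_derived(p)
#' @export
pb_params <- function(alpha, beta, gamma, lambda = 1) {
  stopifnot(
    is.numeric(alpha), is.numeric(beta), is.numeric(gamma), is.numeric(lambda),
    length(alpha) == 1, length(beta) == 1, length(gamma) == 1, length(lambda) == 1
  )
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be finite and > 0")
  if (!is.finite(beta) || beta <= 0) stop("'beta' must be finite and > 0")
  if (!is.finite(gamma) || gamma <= 0) stop("'gamma' must be finite and > 0")
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be finite and > 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
            class = "pb_params")
}

#' @export
print.pb_params <- function(x, ...) {
  cat(sprintf(
    "Poisson-Beta (telegraph) parameters: alpha = %.4g, beta = %.4g, gamma = %.4g (units of lambda = %.4g)\n",
    x$alpha, x$beta, x$gamma, x$lambda))
  invisible(x)
}

#' @export
as.double.pb_params <- function(x, ...) {
  c(alpha = x$alpha, beta = x$beta, gamma = x$gamma)
}

#' Sample stationary transcript counts from the bursting model
#'
#' Draws a latent promoter activity `c ~ Beta(alpha, beta)` per cell and then
#' a count `x ~ Poisson(c * gamma)`.
#'
#' @param n Number of cells to draw; positive integer.
#' @param params A [pb_params()] object.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Integer vector of length `n`.
#' @export
rpb <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "pb_params"))
  if (length(n) != 1 || n <= 0 || n != round(n)) stop("'n' must be a positive integer")
  with_seed(seed, {
    cc <- rbeta(n, params$alpha, params$beta)
    rpois(n, cc * params$gamma)
  })
}

# log 1F1(b; c; g) for b, c, g > 0 by the ascending series in log space.
# All terms are positive; the series converges like exp(g). Returns NA when
# the term count cap is hit without convergence (caller falls back).
log_kummer <- function(b, cc, g, max_terms = 20000L) {
  if (g == 0) return(0)
  lt <- 0 # log of current term, k = 0
  m <- 0
  acc <- 1 # sum of exp(log term - m)
  k <- 0
  repeat {
    lt <- lt + log(b + k) - log(cc + k) + log(g) - log(k + 1)
    k <- k + 1
    if (lt > m) {
      acc <- acc * exp(m - lt) + 1
      m <- lt
    } else {
      acc <- acc + exp(lt - m)
    }
    if (k > g && lt < m - 40) return(m + log(acc))
    if (k >= max_terms) return(NA_real_)
  }
}

#' Analytic Poisson-Beta probability mass function
#'
#' Evaluates the stationary transcript-count distribution of the bursting
#' model exactly, in log space, through its confluent-hypergeometric
#' representation; if the series fails to converge the density is computed
#' by adaptive quadrature of the Beta mixture integral.
#'
#' @param n Vector of non-negative integer counts.
#' @param params A [pb_params()] object.
#' @param log Return log-probabilities?
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' sum(dpb(0:400, pb_params(1, 10, 100))) # ~1
#' @export
dpb <- function(n, params, log = FALSE) {
  stopifnot(inherits(params, "pb_params"))
  if (any(n < 0 | n != round(n))) stop("'n' must contain non-negative integers")
  a <- params$alpha; b <- params$beta; g <- params$gamma
  lp <- vapply(n, function(ni) {
    lf <- log_kummer(b, a + b + ni, g)
    if (is.na(lf)) {
      val <- tryCatch(
        integrate(function(x) dpois(ni, g * x) * dbeta(x, a, b),
                  lower = 0, upper = 1, rel.tol = 1e-10)$value,
        error = function(e) NA_real_)
      if (is.na(val)) stop("Poisson-Beta pmf evaluation failed for n = ", ni)
      return(base::log(val))
    }
    ni * base::log(g) - g + lgamma(a + ni) + lgamma(a + b) -
      lgamma(ni + 1) - lgamma(a + b + ni) - lgamma(a) + lf
  }, numeric(1))
  if (log) lp else exp(lp)
}

#' Monte-Carlo Poisson-Beta probability mass function
#'
#' Rao-Blackwellized estimate: the pmf at each count is the average of
#' Poisson pmfs over `N` shared Beta draws of the latent promoter activity.
#' One draw set is used for every count queried, so the estimated pmf is a
#' proper (normalized) distribution and likelihoods within a test are
#' deterministic given the seed.
#'
#' @param n Vector of non-negative integer counts.
#' @param params A [pb_params()] object.
#' @param N Number of Monte-Carlo draws (default 1000).
#' @param seed Optional integer seed for the draw set.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
dpb_mc <- function(n, params, N = 1000, seed = NULL) {
  stopifnot(inherits(params, "pb_params"), N >= 1)
  if (any(n < 0 | n != round(n))) stop("'n' must contain non-negative integers")
  cc <- with_seed(seed, rbeta(N, params$alpha, params$beta))
  rate <- cc * params$gamma
  vapply(n, function(ni) mean(dpois(ni, rate)), numeric(1))
}

#' Analytic moments of the Poisson-Beta distribution
#'
#' Factorial moments `e_i = E[X(X-1)...(X-i+1)]` of the mixture are the raw
#' moments of the mixing rate: `e_i = gamma^i * prod_{j<i} (alpha+j)/(alpha+beta+j)`.
#'
#' @param params A [pb_params()] object.
#' @return List with `mean`, `variance` and factorial moments `e1`, `e2`, `e3`.
#' @export
pb_moments <- function(params) {
  stopifnot(inherits(params, "pb_params"))
  a <- params$alpha; b <- params$beta; g <- params$gamma
  e <- vapply(1:3, function(i) {
    j <- 0:(i - 1)
    g^i * prod((a + j) / (a + b + j))
  }, numeric(1))
  list(mean = e[1], variance = e[2] + e[1] - e[1]^2,
       e1 = e[1], e2 = e[2], e3 = e[3])
}

#' Biologically interpretable quantities of the bursting model
#'
#' @param params A [pb_params()] object.
#' @param frequency_convention `"stationary"` (default) defines the burst
#'   frequency as the stationary rate of burst initiations,
#'   `alpha*beta/(alpha+beta)`; `"activation"` uses the activation rate
#'   `alpha` (the two agree in the bursty regime `beta >> alpha`).
#' @return List of class `pb_derived`: `duty_cycle` (fraction of time active,
#'   dimensionless), `burst_size` (mean transcripts per active period,
#'   `gamma/beta`), `burst_frequency` (units of `lambda`), `mean_expression`
#'   (counts), `cv` (sd/mean of the stationary count), and `tau_c`
#'   (autocorrelation time, absolute time units via `lambda`).
#' @export
pb_derived <- function(params, frequency_convention = c("stationary", "activation")) {
  stopifnot(inherits(params, "pb_params"))
  frequency_convention <- match.arg(frequency_convention)
  a <- params$alpha; b <- params$beta; g <- params$gamma
  m <- pb_moments(params)
  structure(list(
    duty_cycle = a / (a + b),
    burst_size = g / b,
    burst_frequency = if (frequency_convention == "stationary") a * b / (a + b) else a,
    mean_expression = g * a / (a + b),
    cv = sqrt(m$variance) / m$mean,
    tau_c = pb_autocorrelation_time(params)
  ), class = "pb_derived")
}

#' @export
print.pb_derived <- function(x, ...) {
  cat(sprintf(
    paste0("duty cycle %.4g | burst size %.4g | burst frequency %.4g",
           " | mean %.4g | CV %.4g | tau_c %.4g\n"),
    x$duty_cycle, x$burst_size, x$burst_frequency, x$mean_expression,
    x$cv, x$tau_c))
  invisible(x)
}

# Exponential-decomposition coefficients of the stationary autocovariance:
# R(t) = A exp(-l|t|) + B exp(-(a+b)|t|) with absolute rates, derived from
# the moment ODEs of the telegraph model. Near the removable singularity
# a+b == l the representation switches to R(t) = exp(-l|t|) (V + K|t|).
.acov_coefs <- function(params) {
  l <- params$lambda
  a <- params$alpha * l; b <- params$beta * l; g <- params$gamma * l
  d <- a / (a + b)
  mu <- g * d / l
  v <- g^2 * d * (1 - d) # d(1-d) gamma^2 in absolute rates
  V <- mu + v / (l * (a + b + l)) # stationary variance (= PB variance)
  K <- g * (g * d * (1 - d) / (l + a + b)) # gamma * Cov(promoter, count)
  singular <- abs((a + b) - l) < 1e-6 * l
  if (singular) {
    list(singular = TRUE, V = V, K = K, l = l, ab = a + b)
  } else {
    B <- -v / ((a + b)^2 - l^2)
    list(singular = FALSE, A = V - B, B = B, V = V, l = l, ab = a + b)
  }
}

#' Power spectral density of the bursting model
#'
#' Spectral density `S(omega)` of the stationary transcript-count
#' fluctuations of the two-state model; the Fourier transform of
#' [pb_autocorrelation()]. The removable singularity at
#' `alpha + beta = lambda` (in absolute rates) is evaluated by its
#' continuous limit.
#'
#' @param params A [pb_params()] object.
#' @param omega Angular frequency (vectorized).
#' @return Numeric vector, same length as `omega`.
#' @export
pb_spectral_density <- function(params, omega) {
  stopifnot(inherits(params, "pb_params"))
  co <- .acov_coefs(params)
  l <- co$l
  if (co$singular) {
    2 * co$V * l / (l^2 + omega^2) + co$K * 2 * (l^2 - omega^2) / (l^2 + omega^2)^2
  } else {
    2 * co$A * l / (l^2 + omega^2) + 2 * co$B * co$ab / (co$ab^2 + omega^2)
  }
}

#' Stationary autocorrelation function of the bursting model
#'
#' Autocovariance `R(t)` of the transcript count at lag `t` (absolute time);
#' `R(0)` equals the stationary Poisson-Beta variance.
#'
#' @param params A [pb_params()] object.
#' @param t Time lag (vectorized); `R(t) = R(-t)`.
#' @return Numeric vector, same length as `t`.
#' @export
pb_autocorrelation <- function(params, t) {
  stopifnot(inherits(params, "pb_params"))
  co <- .acov_coefs(params)
  at <- abs(t)
  if (co$singular) {
    exp(-co$l * at) * (co$V + co$K * at)
  } else {
    co$A * exp(-co$l * at) + co$B * exp(-co$ab * at)
  }
}

#' Autocorrelation time of transcript-count fluctuations
#'
#' The characteristic timescale `tau_c = S(0) / (2 R(0))`, i.e. the
#' integral of the normalized autocorrelation function. Requires a positive
#' degradation rate `lambda` in `params` to carry absolute time units.
#'
#' @param params A [pb_params()] object.
#' @return Autocorrelation time (time units, `1/lambda` scale).
#' @export
pb_autocorrelation_time <- function(params) {
  stopifnot(inherits(params, "pb_params"))
  R0 <- pb_autocorrelation(params, 0)
  if (R0 <= 0) stop("invalid parameters: stationary variance is not positive")
  pb_spectral_density(params, 0) / (2 * R0)
}

#' Stochastic (Gillespie) simulation of the telegraph model
#'
#' Exact stochastic simulation of the two-state model in absolute time,
#' sampled on a regular grid after a burn-in period. Used as an independent
#' check of the analytic autocorrelation results.
#'
#' @param params A [pb_params()] object (absolute rates are
#'   `alpha*lambda`, `beta*lambda`, `gamma*lambda`, `lambda`).
#' @param t_end Length of the recorded trajectory (time units).
#' @param dt Sampling interval.
#' @param burnin Time discarded before recording (default `10/lambda`).
#' @param seed Optional integer seed.
#' @return Integer vector of transcript counts at the grid times.
#' @export
simulate_telegraph <- function(params, t_end, dt, burnin = 10 / params$lambda,
                               seed = NULL) {
  stopifnot(inherits(params, "pb_params"), t_end > 0, dt > 0, burnin >= 0)
  l <- params$lambda
  with_seed(seed,
    telegraph_gillespie_cpp(params$alpha * l, params$beta * l,
                            params$gamma * l, l, t_end, dt, burnin))
}
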