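#' Sample factorial moments of a count vector
#'
#' `e_i = mean(x * (x-1) * ... * (x-i+1))`, the sample analogue of
#' `E[X(X-1)...(X-i+1)]`.
#'
#' @param x Non-empty count vector.
#' @param order Highest moment order (<= 3 is all the moments-matching
#'   estimator needs).
#' @return Numeric vector `e1..e_order`.
#' @export
factorial_moments <- function(x, order = 3) {
  if (length(x) < 1) stop("'x' must be non-empty")
  stopifnot(order >= 1)
  vapply(seq_len(order), function(i) {
    v <- x
    if (i > 1) for (j in 1:(i - 1)) v <- v * (x - j)
    mean(v)
  }, numeric(1))
}

# Successive ratios r_i = e_i / e_{i-1}, e_0 = 1
.moment_ratios <- function(e) {
  if (any(e[-length(e)] == 0))
    stop("moment degeneracy: a factorial moment needed as a ratio denominator is zero")
  e / c(1, e[-length(e)])
}

#' Method-of-moments estimator for the bursting parameters
#'
#' Inverts the first three factorial moments of the Poisson-Beta
#' distribution into `(alpha, beta, gamma)` (degradation-normalized).
#' Writing `r_i = e_i / e_{i-1}`:
#' \deqn{\alpha = 2 r_1 (r_3 - r_2) / (r_1 r_2 - 2 r_1 r_3 + r_2 r_3)}
#' \deqn{\beta = 2 (r_2 - r_1)(r_1 - r_3)(r_3 - r_2) /
#'   ((r_1 r_2 - 2 r_1 r_3 + r_2 r_3)(r_1 - 2 r_2 + r_3))}
#' \deqn{\gamma = (-r_1 r_2 + 2 r_1 r_3 - r_2 r_3) / (r_1 - 2 r_2 + r_3)}
#' Fast but fragile: sampling noise routinely produces degenerate
#' denominators (the Poisson-like case `r_1 = r_2 = r_3`) or non-positive
#' estimates; these raise errors rather than being clipped, and callers
#' that need a fit regardless fall back to [fit_pb_bayes()].
#'
#' @param x Count vector. Real-valued (normalized) input is rounded
#'   half-to-even first.
#' @return A [pb_params()] object.
#' @examples
#' fit_pb_moments(rpb(5000, pb_params(1, 1, 10), seed = 1))
#' @export
fit_pb_moments <- function(x) {
  x <- round(x)
  e <- factorial_moments(x, 3)
  fit_pb_moments_exact(.moment_ratios(e))
}

#' Invert exact moment ratios into bursting parameters
#'
#' The deterministic core of [fit_pb_moments()], taking the ratios
#' `r = (r1, r2, r3)` directly so analytic moments (e.g. from
#' [pb_moments()]) can be inverted without sampling.
#'
#' @param r Numeric vector `(r1, r2, r3)` of successive factorial-moment
#'   ratios.
#' @return A [pb_params()] object.
#' @export
fit_pb_moments_exact <- function(r) {
  stopifnot(length(r) == 3)
  r1 <- r[1]; r2 <- r[2]; r3 <- r[3]
  den1 <- r1 * r2 - 2 * r1 * r3 + r2 * r3
  den2 <- r1 - 2 * r2 + r3
  if (den1 == 0 || den2 == 0)
    stop("moment degeneracy: estimator denominator is zero (Poisson-like sample)")
  alpha <- 2 * r1 * (r3 - r2) / den1
  beta <- 2 * (r2 - r1) * (r1 - r3) * (r3 - r2) / (den1 * den2)
  gamma <- (-r1 * r2 + 2 * r1 * r3 - r2 * r3) / den2
  if (!all(is.finite(c(alpha, beta, gamma))) || alpha <= 0 || beta <= 0 || gamma <= 0)
    stop(sprintf(
      "infeasible moment estimates (alpha=%.3g, beta=%.3g, gamma=%.3g)",
      alpha, beta, gamma))
  pb_params(alpha, beta, gamma)
}

#' Bayesian inference for the bursting parameters
#'
#' Collapsed Gibbs sampler with slice sampling. Priors are
#' `Gamma(shape = 1, scale = theta)` with `theta_alpha = theta_beta = 100`
#' (weakly informative) and `theta_gamma = max(x)` (floored at 1 so an
#' all-zero gene is still proper). Each sweep slice-samples every latent
#' per-cell promoter activity `c_i` in (0,1) (logit scale) from
#' `Beta(c_i | alpha, beta) Pois(x_i | c_i gamma)` and then each parameter
#' (log scale) from its full conditional; step-out width 1 in log/logit
#' units with unbounded expansion.
#'
#' @param x Count vector (real-valued input is rounded half-to-even).
#' @param n_iter Total sweeps (default 3000).
#' @param n_burnin Discarded initial sweeps (default 1000).
#' @param thin Keep every `thin`-th sweep (default 1).
#' @param seed Optional integer seed; identical seeds give identical chains.
#' @param theta_alpha,theta_beta Prior scales for `alpha`, `beta`.
#' @param theta_gamma Prior scale for `gamma`; default `max(x)` (>= 1).
#' @param width Slice-sampler step-out width (log units).
#' @return An object of class `pb_posterior`: `draws` (kept x 3 matrix of
#'   `(alpha, beta, gamma)`), `latent_c` (final per-cell activities),
#'   `n_burnin`, `n_kept`, `seed`.
#' @export
fit_pb_bayes <- function(x, n_iter = 3000, n_burnin = 1000, thin = 1,
                         seed = NULL, theta_alpha = 100, theta_beta = 100,
                         theta_gamma = NULL, width = 1) {
  if (length(x) < 1) stop("'x' must be non-empty")
  stopifnot(n_iter > n_burnin, n_burnin >= 0, thin >= 1)
  x <- as.integer(round(x))
  if (any(x < 0)) stop("counts must be non-negative")
  if (is.null(theta_gamma)) theta_gamma <- max(max(x), 1)
  g0 <- max(mean(x) * 2, 1)
  res <- with_seed(seed,
    pb_gibbs_cpp(x, as.integer(n_iter), as.integer(n_burnin),
                 as.integer(thin), theta_alpha, theta_beta, theta_gamma,
                 width, 1, 1, g0))
  colnames(res$draws) <- c("alpha", "beta", "gamma")
  structure(list(draws = res$draws, latent_c = res$latent_c,
                 n_burnin = n_burnin, n_kept = nrow(res$draws), seed = seed),
            class = "pb_posterior")
}

#' @export
print.pb_posterior <- function(x, ...) {
  med <- apply(x$draws, 2, median)
  cat(sprintf("pb_posterior: %d kept draws (burn-in %d)\n", x$n_kept, x$n_burnin))
  cat(sprintf("posterior medians: alpha = %.4g, beta = %.4g, gamma = %.4g\n",
              med[1], med[2], med[3]))
  invisible(x)
}

#' Point estimate from posterior draws
#'
#' @param post A `pb_posterior` from [fit_pb_bayes()].
#' @param type Per-parameter posterior `"median"` (default) or `"mean"`.
#' @return A [pb_params()] object.
#' @export
point_estimate <- function(post, type = c("median", "mean")) {
  stopifnot(inherits(post, "pb_posterior"))
  if (nrow(post$draws) < 1) stop("no posterior draws")
  type <- match.arg(type)
  f <- if (type == "median") median else mean
  est <- apply(post$draws, 2, f)
  pb_params(est[1], est[2], est[3])
}

#' @export
coef.pb_posterior <- function(object, ...) as.numeric(point_estimate(object))

# Fit with the method of moments, falling back to a short Gibbs run when
# the moment estimate is degenerate or infeasible. Used wherever a
# parameter set is required no matter what (e.g. the LR test).
fit_pb_any <- function(x, seed = NULL, n_iter = 1200, n_burnin = 400) {
  fit <- tryCatch(fit_pb_moments(x), error = function(e) NULL)
  status <- "mom"
  if (is.null(fit)) {
    fit <- point_estimate(fit_pb_bayes(x, n_iter = n_iter, n_burnin = n_burnin,
                                       seed = seed))
    status <- "bayes_fallback"
  }
  attr(fit, "fit_status") <- status
  fit
}

#' Fit the transcriptional bursting model to a count vector
#'
#' The front-end estimator: method of moments (fast, exact on exact
#' moments, fragile on noisy data) or the collapsed Gibbs sampler
#' (accurate, slower). Returns a fitted-model object with the usual
#' accessor methods (`coef`, `print`, `summary`, `simulate`, `predict`,
#' `logLik`, `plot`, `residuals`).
#'
#' @param x Non-empty count vector.
#' @param method `"moments"` or `"bayes"`.
#' @param lambda Degradation rate attached to the fitted parameters
#'   (absolute time units; default 1).
#' @param seed Optional integer seed (Bayesian method).
#' @param ... Further arguments passed to [fit_pb_bayes()].
#' @return An object of class `pb_fit`.
#' @examples
#' x <- rpb(200, pb_params(0.5, 0.5, 50), seed = 7)
#' fit <- pb_fit(x, method = "moments")
#' coef(fit)
#' @export
pb_fit <- function(x, method = c("moments", "bayes"), lambda = 1,
                   seed = NULL, ...) {
  method <- match.arg(method)
  if (length(x) < 1) stop("'x' must be non-empty")
  posterior <- NULL
  if (method == "moments") {
    params <- fit_pb_moments(x)
  } else {
    posterior <- fit_pb_bayes(x, seed = seed, ...)
    params <- point_estimate(posterior)
  }
  params <- pb_params(params$alpha, params$beta, params$gamma, lambda = lambda)
  structure(list(params = params, method = method, posterior = posterior,
                 data = x, n = length(x)),
            class = "pb_fit")
}

#' @export
coef.pb_fit <- function(object, ...) as.numeric(object$params)

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("Poisson-Beta fit (%s), n = %d cells\n", x$method, x$n))
  print(x$params)
  invisible(x)
}

#' @export
summary.pb_fit <- function(object, ...) {
  out <- list(fit = object, derived = pb_derived(object$params),
              moments = pb_moments(object$params),
              empirical_mean = mean(object$data),
              empirical_var = stats::var(object$data))
  class(out) <- "summary.pb_fit"
  out
}

#' @export
print.summary.pb_fit <- function(x, ...) {
  print(x$fit)
  print(x$derived)
  cat(sprintf("model mean %.4g (empirical %.4g), model variance %.4g (empirical %.4g)\n",
              x$moments$mean, x$empirical_mean, x$moments$variance, x$empirical_var))
  if (!is.null(x$fit$posterior)) {
    qs <- apply(x$fit$posterior$draws, 2, quantile, c(.025, .5, .975))
    cat("posterior quantiles (2.5/50/97.5%):\n")
    print(round(qs, 4))
  }
  invisible(x)
}

#' @export
simulate.pb_fit <- function(object, nsim = 1, seed = NULL, ...) {
  rpb(nsim * object$n, object$params, seed = seed)
}

#' @export
predict.pb_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- 0:max(object$data)
  dpb(newdata, object$params)
}

#' @export
logLik.pb_fit <- function(object, ...) {
  val <- sum(dpb(round(object$data), object$params, log = TRUE))
  structure(val, df = 3, nobs = object$n, class = "logLik")
}

#' @export
residuals.pb_fit <- function(object, seed = NULL, ...) {
  # randomized quantile residuals: u ~ U(F(x-1), F(x)) mapped through qnorm
  x <- round(object$data)
  Fup <- cumsum(dpb(0:max(x), object$params))
  Flo <- c(0, Fup[-length(Fup)])
  with_seed(seed, {
    u <- runif(length(x), Flo[x + 1], pmin(Fup[x + 1], 1))
    qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
  })
}

#' @export
plot.pb_fit <- function(x, max_n = NULL, ...) {
  d <- round(x$data)
  if (is.null(max_n)) max_n <- max(d)
  emp <- tabulate(d + 1, nbins = max_n + 1) / length(d)
  fitp <- dpb(0:max_n, x$params)
  bp <- barplot(emp, names.arg = 0:max_n, col = "grey85", border = NA,
                xlab = "transcript count", ylab = "probability",
                ylim = c(0, max(emp, fitp) * 1.05), ...)
  lines(bp, fitp, type = "b", pch = 16, col = "firebrick")
  legend("topright", bty = "n", pch = c(15, 16),
         col = c("grey85", "firebrick"), legend = c("empirical", "fitted"))
  invisible(x)
}
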