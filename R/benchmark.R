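#' Parameter ranges representative of single-cell RNA-seq data
#'
#' The degradation-normalized bursting-parameter ranges used throughout the
#' synthetic benchmarks: `alpha` in \[0.01, 0.1\], `beta` in \[0.1, 1\],
#' `gamma` in \[1, 100\].
#'
#' @return Named list of length-2 ranges.
#' @export
pb_ranges <- function() {
  list(alpha = c(0.01, 0.1), beta = c(0.1, 1), gamma = c(1, 100))
}

# Log-uniform parameter triplets over the benchmark ranges; the sampling
# distribution stands in for fits to real data, which are out of scope.
sample_triplets <- function(n, ranges = pb_ranges()) {
  draw <- function(rg) exp(runif(n, log(rg[1]), log(rg[2])))
  data.frame(alpha = draw(ranges$alpha), beta = draw(ranges$beta),
             gamma = draw(ranges$gamma))
}

# One two-sample p-value for any of the three tests; the LR route fits
# both samples first (moment fit with short-Gibbs fallback).
.test_p <- function(x, y, test, n_mc = 1000) {
  if (test == "cvm") return(cvm_test(x, y)$p.value)
  if (test == "ks") return(ks_test(x, y)$p.value)
  px <- fit_pb_any(round(x))
  py <- fit_pb_any(round(y))
  lr_test(round(y), params_control = px, params_test = py, N = n_mc)$p.value
}

#' Sensitivity grid of p-values for one varied parameter
#'
#' Two of the bursting parameters are fixed and the third sweeps 10
#' log-spaced values over its benchmark range; for every ordered pair of
#' grid values, two independent 50-cell Poisson-Beta samples are generated
#' and tested. High p-values are expected on the diagonal (no change) and
#' low ones away from it.
#'
#' @param fixed Named numeric of the two fixed parameters, e.g.
#'   `c(alpha = .05, beta = .5)`.
#' @param varied Which parameter sweeps: `"alpha"`, `"beta"` or `"gamma"`.
#' @param n_cells Cells per condition (default 50).
#' @param test `"cvm"`, `"ks"` or `"lr"`.
#' @param seed Optional integer seed.
#' @param n_mc Monte-Carlo draws for the LR likelihood.
#' @return Object of class `pvalue_matrix`: `grid` (10 values), `fixed`,
#'   `varied`, `p` (10 x 10 matrix), `score` (see [sensitivity_score()]).
#' @export
sensitivity_matrix <- function(fixed, varied = c("alpha", "beta", "gamma"),
                               n_cells = 50, test = c("cvm", "ks", "lr"),
                               seed = NULL, n_mc = 1000) {
  varied <- match.arg(varied); test <- match.arg(test)
  ranges <- pb_ranges()
  need <- setdiff(names(ranges), varied)
  if (!all(need %in% names(fixed)))
    stop("'fixed' must name the two non-varied parameters: ",
         paste(need, collapse = ", "))
  rg <- ranges[[varied]]
  grid <- exp(seq(log(rg[1]), log(rg[2]), length.out = 10))
  par_at <- function(v) {
    vals <- c(fixed[need], setNames(v, varied))
    pb_params(vals[["alpha"]], vals[["beta"]], vals[["gamma"]])
  }
  p <- with_seed(seed, {
    m <- matrix(NA_real_, 10, 10)
    for (i in 1:10) for (j in 1:10) {
      xi <- rpb(n_cells, par_at(grid[i]))
      xj <- rpb(n_cells, par_at(grid[j]))
      m[i, j] <- .test_p(xi, xj, test, n_mc)
    }
    m
  })
  out <- structure(list(grid = grid, fixed = fixed[need], varied = varied,
                        p = p, test = test, score = NA_real_),
                   class = "pvalue_matrix")
  out$score <- sensitivity_score(out)
  out
}

#' Composite sensitivity score of a p-value grid
#'
#' With `I` the indicator function over the 10 x 10 grid,
#' \deqn{S = 1 - |{\sum_i I(p_{ii} > .05) - 10}| / 100 +
#'   \sum_{i \ne j} I(p_{ij} > .05) / 100.}
#' The ideal pattern — all diagonal p-values above 0.05 and all
#' off-diagonal ones below — gives `S = 1`. Note the formula is not
#' confined to \[0, 1\]: a grid with every p-value above 0.05 scores 1.9
#' and one with every p-value at or below 0.05 scores 0.9. The score is
#' reported verbatim rather than renormalized.
#'
#' @param m A `pvalue_matrix` (or a bare 10 x 10 matrix of p-values).
#' @return The score `S` (single number).
#' @export
sensitivity_score <- function(m) {
  p <- if (inherits(m, "pvalue_matrix")) m$p else m
  if (!is.matrix(p) || any(dim(p) != c(10, 10)))
    stop("a 10 x 10 p-value matrix is required")
  diag_hits <- sum(diag(p) > 0.05)
  off <- p[row(p) != col(p)]
  1 - abs(diag_hits - 10) / 100 + sum(off > 0.05) / 100
}

#' @export
print.pvalue_matrix <- function(x, ...) {
  cat(sprintf(
    "pvalue_matrix: %s varied over [%.3g, %.3g] (%s test), fixed %s\n",
    x$varied, min(x$grid), max(x$grid), x$test,
    paste(sprintf("%s = %.3g", names(x$fixed), x$fixed), collapse = ", ")))
  cat(sprintf("score S = %.3f; diagonal p > .05: %d/10; off-diagonal p <= .05: %d/90\n",
              x$score, sum(diag(x$p) > 0.05), sum(x$p[row(x$p) != col(x$p)] <= 0.05)))
  invisible(x)
}

#' @export
plot.pvalue_matrix <- function(x, ...) {
  image(1:10, 1:10, t(x$p)[, 10:1], zlim = c(0, 1),
        col = grey.colors(64, start = 0, end = 1),
        xlab = paste(x$varied, "(column index)"),
        ylab = paste(x$varied, "(row index)"), ...)
  invisible(x)
}

#' Null-control calibration experiment
#'
#' Generates pairs of same-parameter 50-cell samples — no gene is truly
#' differentially expressed — applies the chosen test to every pair, and
#' derives the empirical threshold from a split negative control: one
#' sample of each pair is split into halves, the same test is applied, the
#' lowest control p-value is `p*`, and pairs with `p < a * p*` are called
#' significant. Returns the fraction of pairs correctly called not DE.
#'
#' @param n_pairs Number of parameter triplets / sample pairs (default 1000).
#' @param n_cells Cells per sample (default 50).
#' @param test `"cvm"`, `"ks"` or `"lr"`.
#' @param a Threshold multiplier (default 0.1).
#' @param seed Optional integer seed.
#' @param n_mc Monte-Carlo draws for the LR likelihood.
#' @return List of class `null_control`: `fraction` (not called DE),
#'   `p_star`, `critical_p`, `p_values`, `control_p`.
#' @export
null_control_experiment <- function(n_pairs = 1000, n_cells = 50,
                                    test = c("cvm", "ks", "lr"), a = 0.1,
                                    seed = NULL, n_mc = 1000) {
  test <- match.arg(test)
  with_seed(seed, {
    tri <- sample_triplets(n_pairs)
    p_main <- numeric(n_pairs)
    p_ctrl <- numeric(n_pairs)
    half <- floor(n_cells / 2)
    for (k in seq_len(n_pairs)) {
      pars <- pb_params(tri$alpha[k], tri$beta[k], tri$gamma[k])
      x <- rpb(n_cells, pars)
      y <- rpb(n_cells, pars)
      p_main[k] <- .test_p(x, y, test, n_mc)
      split_idx <- sample(n_cells, half)
      p_ctrl[k] <- .test_p(x[split_idx], x[-split_idx], test, n_mc)
    }
    p_star <- min(p_ctrl)
    critical_p <- a * p_star
    structure(list(fraction = mean(p_main >= critical_p), p_star = p_star,
                   critical_p = critical_p, p_values = p_main,
                   control_p = p_ctrl),
              class = "null_control")
  })
}

#' @export
print.null_control <- function(x, ...) {
  cat(sprintf(
    "null control: %.1f%% of %d same-parameter pairs not called DE (p* = %.3g, cut-off %.3g)\n",
    100 * x$fraction, length(x$p_values), x$p_star, x$critical_p))
  invisible(x)
}

#' Mean-preserving variance-change experiment
#'
#' Scaling `alpha` and `beta` jointly by a factor leaves the mean
#' expression `gamma * alpha / (alpha + beta)` exactly unchanged while
#' changing the variance (faster promoter switching averages the bursts
#' out). Each replicate draws a triplet from the benchmark ranges and
#' compares a sample from `PB(alpha, beta, gamma)` against one from
#' `PB(scale*alpha, scale*beta, gamma)` with the Cramér-von Mises test —
#' the regime where mean-based DE methods are blind.
#'
#' @param scale Joint factor on `alpha` and `beta` (default 2).
#' @param n_cells Cells per sample (default 50).
#' @param n_reps Number of replicates (default 100).
#' @param seed Optional integer seed.
#' @return List: `p_values`, `median_p`, `frac_below_05`.
#' @export
mean_fixed_variance_experiment <- function(scale = 2, n_cells = 50,
                                           n_reps = 100, seed = NULL) {
  stopifnot(scale > 0, n_reps >= 1)
  p <- with_seed(seed, {
    tri <- sample_triplets(n_reps)
    vapply(seq_len(n_reps), function(k) {
      x <- rpb(n_cells, pb_params(tri$alpha[k], tri$beta[k], tri$gamma[k]))
      y <- rpb(n_cells, pb_params(scale * tri$alpha[k], scale * tri$beta[k],
                                  tri$gamma[k]))
      cvm_test(x, y)$p.value
    }, numeric(1))
  })
  list(p_values = p, median_p = median(p), frac_below_05 = mean(p < 0.05))
}

#' Apply dropout noise to a count vector
#'
#' Each cell's count is independently set to zero with probability
#' `1 - exp(-mu^2 / b)`, where `mu` is the gene's (pre-dropout) mean
#' expression in that condition and `b` controls the dropout strength
#' (larger `b`, less dropout). Below a probability of `1e-12` the vector
#' is returned unchanged exactly.
#'
#' @param x Count vector.
#' @param mu Mean expression driving the dropout probability (default: the
#'   sample mean of `x`).
#' @param b Dropout scale parameter (> 0).
#' @param seed Optional integer seed.
#' @return Count vector with dropout applied.
#' @export
apply_dropout <- function(x, mu = mean(x), b, seed = NULL) {
  stopifnot(b > 0, mu >= 0)
  p_drop <- 1 - exp(-mu^2 / b)
  if (p_drop < 1e-12) return(x)
  drop <- with_seed(seed, runif(length(x)) < p_drop)
  x[drop] <- 0
  x
}

#' Parameter-recovery experiment under dropout
#'
#' For each random triplet from the benchmark ranges, one parameter is
#' perturbed by a log-uniform factor of up to `max_fold` in either
#' direction, 50-cell samples are generated for both conditions,
#' optionally corrupted by dropout, and the bursting parameters are
#' re-estimated per condition. Reports the geometric mean of the squared
#' relative estimation errors per parameter and the Pearson correlations
#' between true and estimated log2 changes of the derived quantities.
#'
#' @param n_triplets Number of parameter triplets (default 1000).
#' @param n_cells Cells per condition (default 50).
#' @param b Dropout scale (`NULL` for no dropout; the study uses 10, 100,
#'   200).
#' @param max_fold Maximum fold change of the perturbed parameter (default 4).
#' @param estimator `"bayes"` (collapsed Gibbs), `"mom"` (moments, may fail
#'   per gene), or `"oracle"` (returns the true parameters; zero error by
#'   construction, for harness checks).
#' @param seed Optional integer seed.
#' @param n_iter,n_burnin Gibbs settings for the Bayesian estimator.
#' @return List of class `dropout_report`: `gmsre` (named geometric-mean
#'   squared relative errors for alpha, beta, gamma), `correlations`
#'   (true-vs-estimated log2 changes of derived quantities), `n_failed`,
#'   `n_used`, `b`.
#' @export
dropout_recovery_experiment <- function(n_triplets = 1000, n_cells = 50,
                                        b = NULL, max_fold = 4,
                                        estimator = c("bayes", "mom", "oracle"),
                                        seed = NULL, n_iter = 1500,
                                        n_burnin = 500) {
  estimator <- match.arg(estimator)
  stopifnot(max_fold >= 1)
  with_seed(seed, {
    tri <- sample_triplets(n_triplets)
    est_fn <- switch(estimator,
      oracle = function(x, truth) truth,
      mom = function(x, truth) tryCatch(fit_pb_moments(x),
                                        error = function(e) NULL),
      bayes = function(x, truth) point_estimate(
        fit_pb_bayes(x, n_iter = n_iter, n_burnin = n_burnin)))
    sq_err <- matrix(NA_real_, 0, 3)
    true_chg <- est_chg <- matrix(NA_real_, 0, 5)
    n_failed <- 0L
    for (k in seq_len(n_triplets)) {
      pa <- pb_params(tri$alpha[k], tri$beta[k], tri$gamma[k])
      which_par <- sample(3, 1)
      fold <- exp(runif(1, -log(max_fold), log(max_fold)))
      vb <- as.numeric(pa); vb[which_par] <- vb[which_par] * fold
      pbp <- pb_params(vb[1], vb[2], vb[3])
      sim <- function(p) {
        x <- rpb(n_cells, p)
        if (!is.null(b)) x <- apply_dropout(x, mean(x), b) else x
      }
      xa <- sim(pa); xb <- sim(pbp)
      ea <- est_fn(xa, pa); eb <- est_fn(xb, pbp)
      if (is.null(ea) || is.null(eb)) { n_failed <- n_failed + 1L; next }
      sq_err <- rbind(sq_err,
                      ((as.numeric(ea) - as.numeric(pa)) / as.numeric(pa))^2,
                      ((as.numeric(eb) - as.numeric(pbp)) / as.numeric(pbp))^2)
      dq <- function(p) {
        d <- pb_derived(p)
        c(d$burst_size, d$burst_frequency, d$duty_cycle, d$mean_expression, d$cv)
      }
      true_chg <- rbind(true_chg, log2(dq(pbp) / dq(pa)))
      est_chg <- rbind(est_chg, log2(dq(eb) / dq(ea)))
    }
    qnames <- c("burst_size", "burst_frequency", "duty_cycle", "mean", "cv")
    cors <- if (estimator == "oracle") setNames(rep(1, 5), qnames) else
      setNames(vapply(1:5, function(j) {
        suppressWarnings(cor(true_chg[, j], est_chg[, j]))
      }, numeric(1)), qnames)
    gmsre <- if (estimator == "oracle")
      setNames(rep(0, 3), c("alpha", "beta", "gamma")) else
      setNames(exp(colMeans(log(pmax(sq_err, 1e-300)))),
               c("alpha", "beta", "gamma"))
    structure(list(gmsre = gmsre, correlations = cors,
                   n_failed = n_failed, n_used = n_triplets - n_failed, b = b),
              class = "dropout_report")
  })
}

#' @export
print.dropout_report <- function(x, ...) {
  cat(sprintf("dropout recovery (%s): %d triplets used, %d failed\n",
              if (is.null(x$b)) "no dropout" else paste0("b = ", x$b),
              x$n_used, x$n_failed))
  cat("geometric-mean squared relative error:",
      paste(sprintf("%s %.3g", names(x$gmsre), x$gmsre), collapse = ", "), "\n")
  cat("log2-change correlations:",
      paste(sprintf("%s %.2f", names(x$correlations), x$correlations),
            collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth DE labels from parameter fold changes
#'
#' A gene counts as truly differentially expressed when its parameter fold
#' change, in either direction, reaches `threshold_fold`; the resulting
#' labels feed ROC/AUC evaluation of any DE score.
#'
#' @param fold_changes Positive fold changes (condition b over a).
#' @param threshold_fold Fold threshold (the study uses 1.5, 2 and 4).
#' @return Logical vector of labels.
#' @export
roc_labels <- function(fold_changes, threshold_fold) {
  stopifnot(all(fold_changes > 0), threshold_fold >= 1)
  pmax(fold_changes, 1 / fold_changes) >= threshold_fold
}
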