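test_that("sensitivity grids span the stated ranges and behave at the corners", {
  m <- sensitivity_matrix(c(alpha = 0.1, beta = 0.1), "gamma", test = "ks",
                          seed = 1)
  expect_length(m$grid, 10)
  expect_equal(range(m$grid), c(1, 100))
  expect_true(all(m$p >= 0 & m$p <= 1))
  expect_equal(dim(m$p), c(10L, 10L))

  # diagonal pairs share parameters: mostly insignificant
  diag_p <- c(diag(m$p),
              diag(sensitivity_matrix(c(alpha = 0.05, beta = 0.5), "gamma",
                                      test = "cvm", seed = 2)$p))
  expect_gte(mean(diag_p > 0.05), 0.8)

  # extreme separation: gamma = 1 vs gamma = 100 at a workable duty cycle
  set.seed(3)
  corner <- replicate(20, cvm_test(rpb(50, pb_params(0.1, 0.1, 1)),
                                   rpb(50, pb_params(0.1, 0.1, 100)))$p.value)
  expect_gte(mean(corner < 0.05), 0.95)

  expect_error(sensitivity_matrix(c(alpha = 0.1, beta = 0.1), "delta"))
  expect_error(sensitivity_matrix(c(alpha = 0.1), "gamma"), "fixed")
})

test_that("the composite score follows the stated formula verbatim", {
  ideal <- matrix(0.01, 10, 10); diag(ideal) <- 0.9
  expect_equal(sensitivity_score(ideal), 1)
  expect_equal(sensitivity_score(matrix(0.01, 10, 10)), 0.9)
  expect_equal(sensitivity_score(matrix(0.9, 10, 10)), 1.9)
  # one diagonal miss, one off-diagonal miss
  m <- ideal; m[1, 1] <- 0.01; m[1, 2] <- 0.9
  expect_equal(sensitivity_score(m), 1 - 1 / 100 + 1 / 100)
  expect_error(sensitivity_score(matrix(0.5, 3, 3)), "10 x 10")
})

test_that("the null-control experiment returns a calibrated fraction", {
  nc <- null_control_experiment(n_pairs = 60, n_cells = 30, test = "cvm",
                                seed = 4)
  expect_true(nc$fraction >= 0 && nc$fraction <= 1)
  expect_equal(nc$critical_p, 0.1 * nc$p_star)
  expect_length(nc$p_values, 60)
  # a = 0: nothing can be significant
  nc0 <- null_control_experiment(n_pairs = 20, n_cells = 20, test = "cvm",
                                 a = 0, seed = 5)
  expect_equal(nc0$fraction, 1)
})

test_that("the variance experiment preserves the mean by construction", {
  p <- pb_derived(pb_params(0.04, 0.7, 33))
  p2 <- pb_derived(pb_params(2 * 0.04, 2 * 0.7, 33))
  expect_equal(p$mean_expression, p2$mean_expression)

  mv <- mean_fixed_variance_experiment(scale = 1, n_reps = 100, seed = 6)
  expect_lte(mv$frac_below_05, 0.1) # null behaviour at scale 1
  expect_length(mv$p_values, 100)
})

test_that("dropout zeroes counts at the modeled rate", {
  x <- rep(5L, 1e4)
  # mu^2 = b: dropout probability 1 - exp(-1)
  y <- apply_dropout(x, mu = 3, b = 9, seed = 7)
  expect_equal(mean(y == 0), 1 - exp(-1), tolerance = 0.02)
  # huge b: probability below threshold, vector returned unchanged exactly
  expect_identical(apply_dropout(x, mu = 3, b = 1e15, seed = 8), x)
  expect_identical(apply_dropout(x, mu = 0, b = 10, seed = 9), x)
})

test_that("dropout recovery reports sane errors and correlations", {
  oracle <- dropout_recovery_experiment(n_triplets = 10, n_cells = 20,
                                        estimator = "oracle", seed = 10)
  expect_equal(unname(oracle$gmsre), rep(0, 3))
  expect_equal(unname(oracle$correlations), rep(1, 5))

  rep_b <- dropout_recovery_experiment(n_triplets = 25, n_cells = 50, b = 10,
                                       estimator = "bayes", seed = 11,
                                       n_iter = 800, n_burnin = 300)
  expect_true(all(is.finite(rep_b$gmsre) & rep_b$gmsre >= 0))
  expect_true(all(abs(rep_b$correlations) <= 1, na.rm = TRUE))
  expect_equal(rep_b$n_used + rep_b$n_failed, 25)

  rep_m <- dropout_recovery_experiment(n_triplets = 25, n_cells = 50,
                                       estimator = "mom", seed = 11)
  expect_true(rep_m$n_failed >= 0)
})

test_that("dropout degrades parameter recovery smoothly, not catastrophically", {
  clean <- dropout_recovery_experiment(n_triplets = 100, n_cells = 50,
                                       estimator = "bayes", seed = 12,
                                       n_iter = 1000, n_burnin = 400)
  mild <- dropout_recovery_experiment(n_triplets = 100, n_cells = 50, b = 100,
                                      estimator = "bayes", seed = 12,
                                      n_iter = 1000, n_burnin = 400)
  # moderate dropout: no more than one order of magnitude degradation
  expect_true(all(mild$gmsre <= 10 * clean$gmsre + 1e-6))

  # severe dropout can only hurt the transcription-rate estimate (paired)
  harsh <- dropout_recovery_experiment(n_triplets = 100, n_cells = 50, b = 10,
                                       estimator = "bayes", seed = 12,
                                       n_iter = 1000, n_burnin = 400)
  expect_gte(harsh$gmsre[["gamma"]], clean$gmsre[["gamma"]])
})

test_that("ROC labels flag symmetric fold changes at each threshold", {
  expect_false(any(roc_labels(1, c(1.5))))
  expect_true(roc_labels(0.25, 4))
  expect_equal(vapply(c(1.5, 2, 4), function(th) roc_labels(1.6, th),
                      logical(1)),
               c(TRUE, FALSE, FALSE))
  expect_error(roc_labels(-1, 2), "fold_changes")
})
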