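#' Compare fitted bursting parameters between two conditions
#'
#' Log2 changes (condition b over condition a) of the derived quantities.
#' The bursting parameters are identifiable only up to the degradation
#' rate, so quantities carrying absolute time units (burst frequency in
#' real time, autocorrelation time) are reported only when the degradation
#' rates of both conditions are supplied; without them the
#' degradation-normalized burst-frequency ratio is still given (valid when
#' the rates are equal across conditions) and the `tau_c` change is `NA`.
#'
#' @param params_a,params_b [pb_params()] for the two conditions.
#' @param lambda_a,lambda_b Optional absolute degradation rates.
#' @return Named list of log2 changes: `burst_size`, `burst_frequency`,
#'   `duty_cycle`, `mean`, `cv`, `tau_c`.
#' @export
compare_params <- function(params_a, params_b, lambda_a = NULL, lambda_b = NULL) {
  stopifnot(inherits(params_a, "pb_params"), inherits(params_b, "pb_params"))
  have_rates <- !is.null(lambda_a) && !is.null(lambda_b)
  if (have_rates) {
    params_a <- pb_params(params_a$alpha, params_a$beta, params_a$gamma, lambda_a)
    params_b <- pb_params(params_b$alpha, params_b$beta, params_b$gamma, lambda_b)
  }
  da <- pb_derived(params_a); db <- pb_derived(params_b)
  rate_scale_a <- if (have_rates) lambda_a else 1
  rate_scale_b <- if (have_rates) lambda_b else 1
  list(
    burst_size = log2(db$burst_size / da$burst_size),
    burst_frequency = log2((db$burst_frequency * rate_scale_b) /
                           (da$burst_frequency * rate_scale_a)),
    duty_cycle = log2(db$duty_cycle / da$duty_cycle),
    mean = log2(db$mean_expression / da$mean_expression),
    cv = log2(db$cv / da$cv),
    tau_c = if (have_rates) log2(db$tau_c / da$tau_c) else NA_real_
  )
}

#' Distribution-based differential expression between two cell groups
#'
#' The four-step flow: (1) median-of-ratios size-factor normalization
#' (optional, spike-in aware), (2) removal of genes expressed in no cell,
#' (3) a per-gene two-sample test on the count distributions
#' (Cramér-von Mises, Kolmogorov-Smirnov, or Poisson-Beta likelihood
#' ratio), (4) a per-gene, per-group fit of the transcriptional bursting
#' model and the log2 changes of the derived quantities. Significance is
#' decided by Benjamini-Hochberg FDR control or by the empirical
#' split-control threshold `p < a * p*`.
#'
#' Group `a` is the control (the fold change is `mean_b / mean_a`, and the
#' LR test evaluates the test group's likelihood under both fits). Rank
#' tests run on the normalized real-valued counts; model fitting and the
#' LR likelihood round half-to-even at the point of use since the
#' Poisson-Beta support is integer. Per-gene seeds are derived by hashing
#' the master seed with the gene id, so results do not depend on gene
#' order.
#'
#' @param x A [count_matrix()] (raw counts).
#' @param group_a,group_b The two group labels to compare (>= 2 cells each;
#'   with more groups, compare one pair at a time).
#' @param test `"cvm"`, `"ks"` or `"lr"`.
#' @param method Parameter-estimation method, `"mom"` or `"bayes"`. For
#'   the LR test a gene whose moment fit is degenerate falls back to a
#'   short Gibbs run (the test cannot run without parameters);
#'   `fit_status_*` records which route produced each fit.
#' @param normalize Apply size-factor normalization? Default `TRUE`.
#' @param spike_in_ids Optional spike-in gene ids for the size factors.
#' @param threshold `"bh"` or `"empirical"`.
#' @param fdr FDR level for the BH threshold (default 0.05).
#' @param a Multiplier for the empirical threshold (default 0.1).
#' @param n_mc Monte-Carlo draws for the LR likelihood (default 1000).
#' @param rates Optional data frame `gene_id`, `lambda_a`, `lambda_b` of
#'   per-gene degradation rates (any consistent unit).
#' @param seed Master seed (default 1); the run is deterministic given it.
#' @param fit Fit the bursting model and report derived-quantity changes?
#'   Default `TRUE` (the LR test forces it).
#' @return An object of class `burst_de`; see [as.data.frame.burst_de()]
#'   for the per-gene table.
#' @examples
#' cm <- count_matrix(matrix(rpb(200, pb_params(1, 1, 20), seed = 1), 10, 20),
#'                    groups = rep(c("A", "B"), each = 10))
#' res <- burst_de(cm, "A", "B", test = "cvm", threshold = "bh", seed = 1)
#' head(as.data.frame(res))
#' @export
burst_de <- function(x, group_a, group_b, test = c("cvm", "ks", "lr"),
                     method = c("mom", "bayes"), normalize = TRUE,
                     spike_in_ids = NULL, threshold = c("bh", "empirical"),
                     fdr = 0.05, a = 0.1, n_mc = 1000, rates = NULL,
                     seed = 1, fit = TRUE) {
  stopifnot(inherits(x, "count_matrix"), n_mc >= 1)
  test <- match.arg(test); method <- match.arg(method)
  threshold <- match.arg(threshold)
  if (test == "lr") fit <- TRUE
  for (g in c(group_a, group_b)) {
    if (!g %in% levels(x$groups)) stop("group not present in the data: ", g)
    if (sum(x$groups == g) < 2) stop("group '", g, "' has fewer than 2 cells")
  }
  if (normalize) x <- normalize_counts(x, size_factors(x, spike_in_ids))
  x <- filter_unexpressed(x)
  if (nrow(x$counts) == 0) stop("all genes were filtered out (no expression)")
  genes <- rownames(x$counts)
  ca <- group_counts(x, group_a)
  cb <- group_counts(x, group_b)

  test_fn <- switch(test, cvm = cvm_test, ks = ks_test, lr = NULL)
  fit_one <- function(xv, sd) {
    if (method == "bayes")
      structure(point_estimate(fit_pb_bayes(xv, seed = sd)),
                fit_status = "bayes")
    else if (test == "lr") fit_pb_any(xv, seed = sd)
    else tryCatch(structure(fit_pb_moments(xv), fit_status = "mom"),
                  error = function(e)
                    structure(list(), fit_status = paste0("failed: ",
                                                          conditionMessage(e))))
  }

  rows <- lapply(seq_along(genes), function(i) {
    gid <- genes[i]
    xa <- ca[i, ]; xb <- cb[i, ]
    gseed <- gene_seed(seed, gid)
    fa <- fb <- NULL
    if (fit) {
      fa <- fit_one(round(xa), gseed)
      fb <- fit_one(round(xb), gseed + 1L)
    }
    if (test == "lr") {
      tr <- lr_test(round(xb), params_control = fa, params_test = fb,
                    N = n_mc, seed = gseed + 2L)
    } else {
      tr <- test_fn(xa, xb)
    }
    ok_a <- inherits(fa, "pb_params"); ok_b <- inherits(fb, "pb_params")
    la <- lb <- NULL
    if (!is.null(rates)) {
      ri <- match(gid, rates$gene_id)
      if (!is.na(ri)) { la <- rates$lambda_a[ri]; lb <- rates$lambda_b[ri] }
    }
    chg <- if (ok_a && ok_b) compare_params(fa, fb, la, lb) else
      list(burst_size = NA_real_, burst_frequency = NA_real_,
           duty_cycle = NA_real_, mean = NA_real_, cv = NA_real_,
           tau_c = NA_real_)
    dqa <- if (ok_a) pb_derived(fa) else NULL
    dqb <- if (ok_b) pb_derived(fb) else NULL
    pick <- function(obj, field) {
      v <- if (is.null(obj)) NULL else obj[[field]]
      if (is.null(v)) NA_real_ else v
    }
    data.frame(
      gene_id = gid, test = test,
      statistic = unname(tr$statistic), p_value = tr$p.value,
      significant = NA,
      mean_a = mean(xa), mean_b = mean(xb),
      fold_change = if (mean(xa) > 0) mean(xb) / mean(xa) else NA_real_,
      alpha_a = pick(fa, "alpha"), beta_a = pick(fa, "beta"),
      gamma_a = pick(fa, "gamma"),
      alpha_b = pick(fb, "alpha"), beta_b = pick(fb, "beta"),
      gamma_b = pick(fb, "gamma"),
      duty_cycle_a = pick(dqa, "duty_cycle"), duty_cycle_b = pick(dqb, "duty_cycle"),
      burst_size_a = pick(dqa, "burst_size"), burst_size_b = pick(dqb, "burst_size"),
      burst_freq_a = pick(dqa, "burst_frequency"),
      burst_freq_b = pick(dqb, "burst_frequency"),
      cv_a = pick(dqa, "cv"), cv_b = pick(dqb, "cv"),
      tau_c_a = if (ok_a && !is.null(la)) pb_autocorrelation_time(
        pb_params(fa$alpha, fa$beta, fa$gamma, la)) else NA_real_,
      tau_c_b = if (ok_b && !is.null(lb)) pb_autocorrelation_time(
        pb_params(fb$alpha, fb$beta, fb$gamma, lb)) else NA_real_,
      log2_change_burst_size = chg$burst_size,
      log2_change_burst_freq = chg$burst_frequency,
      log2_change_duty_cycle = chg$duty_cycle,
      log2_change_mean = chg$mean,
      log2_change_cv = chg$cv,
      log2_change_tau_c = chg$tau_c,
      fit_status_a = if (fit) attr(fa, "fit_status") else NA_character_,
      fit_status_b = if (fit) attr(fb, "fit_status") else NA_character_,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)

  if (threshold == "bh") {
    tab$significant <- bh_calls(tab$p_value, fdr)
    decision <- structure(list(method = "bh", fdr = fdr,
                               critical_p = suppressWarnings(
                                 max(tab$p_value[tab$significant], -Inf))),
                          class = "threshold_decision")
  } else {
    halves <- split_control(x, group_a, seed = seed)
    ctrl_test <- if (test == "lr") function(u, v) {
      pu <- fit_pb_any(round(u), seed = seed)
      pv <- fit_pb_any(round(v), seed = seed)
      lr_test(round(v), pu, pv, N = n_mc, seed = seed)
    } else test_fn
    decision <- empirical_threshold(halves[[1]], halves[[2]],
                                    test_fn = ctrl_test, a = a)
    tab$significant <- tab$p_value < decision$critical_p
  }
  rownames(tab) <- NULL
  structure(list(table = tab, threshold = decision,
                 config = list(test = test, method = method,
                               normalize = normalize, threshold = threshold,
                               fdr = fdr, a = a, n_mc = n_mc, seed = seed),
                 groups = c(a = group_a, b = group_b)),
            class = "burst_de")
}

#' @export
print.burst_de <- function(x, ...) {
  cat(sprintf("burst_de: %s vs %s, %d genes, test = %s, %d significant\n",
              x$groups["a"], x$groups["b"], nrow(x$table), x$config$test,
              sum(x$table$significant, na.rm = TRUE)))
  print(x$threshold)
  invisible(x)
}

#' @export
summary.burst_de <- function(object, n = 10, ...) {
  tab <- object$table[order(object$table$p_value), ]
  cat(sprintf("Top %d genes by p-value (%s test, %s vs %s):\n",
              min(n, nrow(tab)), object$config$test,
              object$groups["a"], object$groups["b"]))
  print(head(tab[, c("gene_id", "statistic", "p_value", "significant",
                     "fold_change", "log2_change_burst_size",
                     "log2_change_burst_freq", "log2_change_duty_cycle")], n),
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' Per-gene results table of a differential-expression run
#'
#' @param x A `burst_de` object.
#' @param row.names,optional,... Passed through for the generic; unused.
#' @return The per-gene `data.frame` (one row per post-filter gene).
#' @export
as.data.frame.burst_de <- function(x, row.names = NULL, optional = FALSE, ...) {
  x$table
}

#' @export
plot.burst_de <- function(x, ...) {
  tab <- x$table
  lfc <- log2(tab$fold_change)
  mlp <- -log10(pmax(tab$p_value, 1e-300))
  plot(lfc, mlp, pch = 16, cex = 0.6,
       col = ifelse(tab$significant %in% TRUE, "firebrick", "grey50"),
       xlab = "log2 fold change (mean)", ylab = "-log10 p-value", ...)
  if (is.finite(x$threshold$critical_p) && x$threshold$critical_p > 0)
    abline(h = -log10(x$threshold$critical_p), lty = 2)
  invisible(x)
}

#' Write a differential-expression results table as TSV
#'
#' Fixed column order (the table's own), header included, missing values
#' written as `NA`.
#'
#' @param x A `burst_de` object or its `data.frame`.
#' @param path Output file path.
#' @export
write_de_table <- function(x, path) {
  tab <- if (inherits(x, "burst_de")) x$table else as.data.frame(x)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
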