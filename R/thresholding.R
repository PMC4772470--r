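#' Benjamini-Hochberg significance calls
#'
#' Standard step-up FDR control: a gene is called significant when its
#' BH-adjusted p-value is at most `fdr`.
#'
#' @param pvalues Vector of p-values in \[0, 1\].
#' @param fdr Target false discovery rate in (0, 1).
#' @return Logical vector of calls (empty input gives an empty vector).
#' @export
bh_calls <- function(pvalues, fdr = 0.05) {
  stopifnot(fdr > 0, fdr < 1)
  if (length(pvalues) == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(pvalues, method = "BH") <= fdr
}

#' Split one cell group into two random halves
#'
#' Partitions the cells of a group into two disjoint subsets of sizes
#' `floor(m/2)` and `ceiling(m/2)`; the negative-control input for
#' [empirical_threshold()]. Uniform random, reproducible under `seed`.
#'
#' @param x A [count_matrix()].
#' @param group Group label whose cells are split (>= 4 cells).
#' @param seed Optional integer seed.
#' @return List of two `count_matrix` objects covering the group's cells.
#' @export
split_control <- function(x, group, seed = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  cells <- names(x$groups)[x$groups == group]
  m <- length(cells)
  if (m < 4) stop("group '", group, "' has fewer than 4 cells; cannot split")
  perm <- with_seed(seed, sample(cells))
  half <- floor(m / 2)
  list(x[, perm[seq_len(half)]], x[, perm[(half + 1):m]])
}

#' Empirical p-value threshold from a split negative control
#'
#' Runs a two-sample test per gene between the two halves of a split
#' control group — which by construction share a distribution for every
#' gene — and records the lowest p-value observed, `p*`. Genes in the real
#' comparison are later called significant iff `p < a * p*` (strict, with
#' default `a = 0.1`). Note the halves are smaller than the original
#' group, so the cut-off tends to be less stringent than a control of full
#' size would give; a warning says so.
#'
#' @param control_half_a,control_half_b The two halves from
#'   [split_control()] (matched gene sets).
#' @param test_fn Two-sample test taking `(x, y)` and returning an object
#'   with a `p.value` field (e.g. [cvm_test()], [ks_test()]).
#' @param a Threshold multiplier (> 0; default 0.1).
#' @param warn Emit the reduced-sample-size warning? Default `TRUE`.
#' @return List of class `threshold_decision`: `method = "empirical"`,
#'   `critical_p = a * p_star`, `a`, `p_star`, and the per-gene control
#'   p-values.
#' @export
empirical_threshold <- function(control_half_a, control_half_b, test_fn = cvm_test,
                                a = 0.1, warn = TRUE) {
  stopifnot(inherits(control_half_a, "count_matrix"),
            inherits(control_half_b, "count_matrix"), a >= 0)
  ga <- rownames(control_half_a$counts); gb <- rownames(control_half_b$counts)
  if (!identical(ga, gb)) stop("the two control halves must carry the same genes")
  if (length(ga) == 0) stop("zero genes in the control halves")
  p <- vapply(seq_along(ga), function(i) {
    test_fn(control_half_a$counts[i, ], control_half_b$counts[i, ])$p.value
  }, numeric(1))
  if (warn)
    warning("empirical threshold is derived from half-sized control samples; ",
            "the cut-off is likely less stringent than a full-size control would give",
            call. = FALSE)
  structure(list(method = "empirical", critical_p = a * min(p), a = a,
                 p_star = min(p), control_p = setNames(p, ga)),
            class = "threshold_decision")
}

#' @export
print.threshold_decision <- function(x, ...) {
  cat(sprintf("threshold_decision (%s): critical p = %.4g", x$method, x$critical_p))
  if (x$method == "empirical")
    cat(sprintf(" (a = %.3g, p* = %.4g over %d genes)", x$a, x$p_star,
                length(x$control_p)))
  cat("\n")
  invisible(x)
}
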