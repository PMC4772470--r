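# Write a small count TSV in the package's input dialect.
write_count_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Simulated two-group count matrix: one row per triplet, n cells per group,
# group B optionally perturbed via `perturb(params, i)`.
sim_count_matrix <- function(triplets, n = 20, perturb = NULL) {
  ngene <- nrow(triplets)
  cnt <- matrix(0L, ngene, 2 * n)
  for (i in seq_len(ngene)) {
    pa <- pb_params(triplets$alpha[i], triplets$beta[i], triplets$gamma[i])
    pb <- if (is.null(perturb)) pa else perturb(pa, i)
    cnt[i, ] <- c(rpb(n, pa), rpb(n, pb))
  }
  count_matrix(cnt, rep(c("A", "B"), each = n),
               gene_ids = sprintf("g%03d", seq_len(ngene)))
}
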