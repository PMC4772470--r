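test_that("read_counts parses header group labels and count rows", {
  path <- write_count_tsv(c("GeneID\tA\tA\tB\tB", "g1\t0\t1\t2\t3"))
  cm <- read_counts(path)
  expect_equal(dim(cm), c(1L, 4L))
  expect_equal(as.vector(cm$counts), c(0, 1, 2, 3))
  expect_equal(as.vector(table(cm$groups)), c(2L, 2L))
  expect_named(table(cm$groups), c("A", "B"))
})

test_that("read_counts accepts an empty body and rejects malformed input", {
  empty <- read_counts(write_count_tsv("GeneID\tA\tA\tB"))
  expect_equal(nrow(empty$counts), 0L)

  expect_error(read_counts(write_count_tsv(c("GeneID\tA\tB", "g1\t1"))),
               "line 2")
  expect_error(read_counts(write_count_tsv(c("GeneID\tA\tB", "g1\t1\t-2"))),
               "non-negative")
  expect_error(read_counts(write_count_tsv(c("GeneID\tA\tB", "g1\t1\t1.5"))),
               "integer")
  expect_error(read_counts(write_count_tsv(c("GeneID\tA\tB", "g1\t1\t0",
                                             "g1\t2\t0"))),
               "duplicate")
})

test_that("size factors follow the median-of-ratios rule", {
  cm <- count_matrix(matrix(c(1, 2, 2, 4), 2, byrow = TRUE), c("A", "A"))
  expect_equal(unname(size_factors(cm)), c(1 / sqrt(2), sqrt(2)))

  # identical positive columns are already on a common scale
  cm2 <- count_matrix(matrix(c(3, 3, 7, 7), 2, byrow = TRUE), c("A", "B"))
  expect_equal(unname(size_factors(cm2)), c(1, 1))

  # a gene with any zero is excluded from the median
  cm3 <- count_matrix(matrix(c(0, 2, 2, 4), 2, byrow = TRUE), c("A", "A"))
  expect_equal(unname(size_factors(cm3)), c(2 / sqrt(8), 4 / sqrt(8)))

  cm4 <- count_matrix(matrix(c(0, 2, 2, 0), 2, byrow = TRUE), c("A", "A"))
  expect_error(size_factors(cm4), "disable normalization")
})

test_that("size factors restrict to spike-in rows when given", {
  m <- matrix(c(1, 10, 2, 2), 2, byrow = TRUE,
              dimnames = list(c("gene1", "ERCC-1"), NULL))
  cm <- count_matrix(m, c("A", "B"))
  s <- size_factors(cm, spike_in_ids = "ERCC-1")
  expect_equal(unname(s), c(1, 1))
  expect_error(size_factors(cm, spike_in_ids = "ERCC-99"), "spike-in")
})

test_that("size factors respond to per-cell scaling as the formula dictates", {
  # scaling cell j by c enters its own ratios directly and every gene's
  # geometric mean through one of M factors, so s_j scales by c^((M-1)/M)
  # and every other cell's by c^(-1/M)
  set.seed(42)
  M <- 6
  m <- matrix(rpois(10 * M, 20) + 1, 10, M)
  cm <- count_matrix(m, rep("A", M))
  s0 <- size_factors(cm)
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  s1 <- size_factors(count_matrix(m2, rep("A", M)))
  expect_equal(s1[3], s0[3] * 5^((M - 1) / M))
  expect_equal(s1[-3], s0[-3] * 5^(-1 / M))
})

test_that("normalization divides by size factors and preserves structure", {
  cm <- count_matrix(matrix(c(1, 2, 2, 4), 2, byrow = TRUE), c("A", "B"))
  nm <- normalize_counts(cm, c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(nm$counts),
               matrix(c(sqrt(2), sqrt(2), 2 * sqrt(2), 2 * sqrt(2)),
                      2, byrow = TRUE))
  expect_true(nm$normalized)
  expect_equal(as.character(nm$groups), c("A", "B"))

  expect_equal(normalize_counts(cm, c(1, 1))$counts, cm$counts)

  cmz <- count_matrix(matrix(c(0, 0, 1, 2), 2, byrow = TRUE), c("A", "A"),
                      normalized = TRUE)
  expect_equal(unname(normalize_counts(cmz, c(2, 4))$counts[1, ]), c(0, 0))
})

test_that("normalization undoes column rescaling up to one global constant", {
  # rescaling columns by c_j leaves the normalized matrix unchanged except
  # for the single factor (prod c_j)^(1/M) coming from the geometric means
  set.seed(7)
  m <- matrix(rpois(50, 30) + 1, 10, 5)
  cm <- count_matrix(m, rep("A", 5))
  norm0 <- normalize_counts(cm, size_factors(cm))
  cj <- c(1, 3, 0.5, 2, 1)
  cm2 <- count_matrix(sweep(m, 2, cj, "*"), rep("A", 5), normalized = TRUE)
  norm1 <- normalize_counts(cm2, size_factors(cm2))
  expect_equal(norm1$counts, norm0$counts * prod(cj)^(1 / 5),
               tolerance = 1e-12)
  # hence per-gene count ratios between cells are fully invariant
  expect_equal(norm1$counts / norm1$counts[, 1],
               norm0$counts / norm0$counts[, 1], tolerance = 1e-12)
})

test_that("filter_unexpressed drops all-zero genes and is idempotent", {
  cm <- count_matrix(matrix(c(0, 0, 1, 0), 2, byrow = TRUE), c("A", "B"),
                     gene_ids = c("dead", "alive"))
  f <- filter_unexpressed(cm)
  expect_equal(rownames(f$counts), "alive")
  expect_equal(filter_unexpressed(f)$counts, f$counts)

  all_zero <- count_matrix(matrix(0, 3, 2), c("A", "B"))
  expect_equal(nrow(filter_unexpressed(all_zero)$counts), 0L)

  none_zero <- count_matrix(matrix(1, 3, 2), c("A", "B"))
  expect_equal(filter_unexpressed(none_zero)$counts, none_zero$counts)
})
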