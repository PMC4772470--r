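#' Construct a count matrix with cell group labels
#'
#' Container for a genes-by-cells read-count table plus a group label per
#' cell. Raw input counts must be non-negative integers; after
#' [normalize_counts()] entries are real-valued.
#'
#' @param counts Numeric matrix, genes in rows, cells in columns; all
#'   entries >= 0. Row and column names are used as gene/cell ids unless
#'   `gene_ids`/`cell_ids` are given.
#' @param groups Character or factor of group labels, one per cell.
#' @param gene_ids,cell_ids Optional explicit identifiers (unique).
#' @param normalized Logical; real-valued (size-factor corrected) entries
#'   are only allowed when `TRUE`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, groups, gene_ids = rownames(counts),
                         cell_ids = colnames(counts), normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids))
    gene_ids <- paste0("gene", seq_len(nrow(counts)), recycle0 = TRUE)
  if (is.null(cell_ids))
    cell_ids <- paste0("cell", seq_len(ncol(counts)), recycle0 = TRUE)
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length != number of rows")
  if (length(cell_ids) != ncol(counts)) stop("cell_ids length != number of columns")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids: ",
    paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (length(groups) != ncol(counts)) stop("one group label per cell is required")
  if (!is.numeric(counts) || anyNA(counts)) stop("counts must be numeric without NAs")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!normalized && any(counts != round(counts)))
    stop("raw counts must be integers")
  dimnames(counts) <- list(gene_ids, cell_ids)
  groups <- factor(as.character(groups))
  names(groups) <- cell_ids
  structure(list(counts = counts, groups = groups, normalized = normalized),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw"))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' @param x A `count_matrix`.
#' @param i Gene index (ids, positions or logical).
#' @param j Cell index.
#' @param ... Unused.
#' @return A `count_matrix` restricted to the selected genes/cells.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  m <- x$counts[i, j, drop = FALSE]
  count_matrix(m, groups = as.character(x$groups[colnames(m)]),
               normalized = x$normalized)
}

#' Read a count table with group labels in the header
#'
#' Expected dialect: UTF-8 tab-separated text; the first header field titles
#' the gene-id column and the remaining header fields are the group labels of
#' the cells (cells are identified by column position; ids `cell1`, `cell2`,
#' ... are assigned). Each body row is a gene id followed by one
#' non-negative integer count per cell.
#'
#' @param path Path to the TSV file.
#' @param sep Field separator (default tab).
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 1) stop("empty file: ", path)
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (length(header) < 2) stop("header must contain a gene-id column plus group labels")
  labels <- header[-1]
  m_cells <- length(labels)
  n_genes <- length(lines) - 1
  counts <- matrix(0, nrow = n_genes, ncol = m_cells)
  gene_ids <- character(n_genes)
  for (k in seq_len(n_genes)) {
    fields <- strsplit(lines[k + 1], sep, fixed = TRUE)[[1]]
    if (length(fields) != m_cells + 1)
      stop(sprintf("line %d: expected %d fields, found %d",
                   k + 1, m_cells + 1, length(fields)))
    gene_ids[k] <- fields[1]
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric count", k + 1))
    if (any(vals < 0) || any(vals != round(vals)))
      stop(sprintf("line %d: counts must be non-negative integers", k + 1))
    counts[k, ] <- vals
  }
  count_matrix(counts, groups = labels, gene_ids = gene_ids,
               cell_ids = paste0("cell", seq_len(m_cells)))
}

#' Per-cell size factors (median-of-ratios)
#'
#' For each cell `j` the size factor is the median over eligible genes of
#' `x_ij / geomean_k(x_ik)`. Only genes with strictly positive counts in
#' every cell are eligible (a single zero makes the gene's geometric mean
#' zero); when spike-in ids are supplied only spike-in rows are used.
#'
#' @param x A [count_matrix()].
#' @param spike_in_ids Optional character vector of spike-in gene ids.
#' @return Numeric vector of positive size factors, one per cell.
#' @export
size_factors <- function(x, spike_in_ids = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!is.null(spike_in_ids)) {
    keep <- rownames(m) %in% spike_in_ids
    if (!any(keep)) stop("none of the spike-in ids are present in the count matrix")
    m <- m[keep, , drop = FALSE]
  }
  eligible <- rowSums(m <= 0) == 0
  if (!any(eligible))
    stop("no gene has strictly positive counts in every cell; ",
         "size factors are undefined - disable normalization")
  m <- m[eligible, , drop = FALSE]
  log_geomean <- rowMeans(log(m))
  s <- apply(exp(log(m) - log_geomean), 2, median)
  names(s) <- colnames(x$counts)
  s
}

#' Apply size factors to a count matrix
#'
#' Divides each cell's column by its size factor; group labels are
#' preserved and the result is marked normalized (real-valued).
#'
#' @param x A [count_matrix()].
#' @param s Size factors from [size_factors()]; length = number of cells.
#' @return A normalized [count_matrix()].
#' @export
normalize_counts <- function(x, s = size_factors(x)) {
  stopifnot(inherits(x, "count_matrix"))
  if (length(s) != ncol(x$counts)) stop("length(s) must equal the number of cells")
  if (any(s <= 0)) stop("size factors must be positive")
  count_matrix(sweep(x$counts, 2, s, "/"), groups = as.character(x$groups),
               normalized = TRUE)
}

#' Remove genes that are expressed in no cell
#'
#' Drops rows whose counts are zero in every cell; gene order is otherwise
#' preserved. Idempotent.
#'
#' @param x A [count_matrix()].
#' @return A [count_matrix()] (possibly with zero genes).
#' @export
filter_unexpressed <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowSums(x$counts > 0) > 0
  count_matrix(x$counts[keep, , drop = FALSE],
               groups = as.character(x$groups), normalized = x$normalized)
}

# Counts of the cells belonging to one group, as a plain vector list per gene
group_counts <- function(x, group) {
  stopifnot(inherits(x, "count_matrix"))
  sel <- x$groups == group
  if (!any(sel)) stop("group not present: ", group)
  x$counts[, sel, drop = FALSE]
}
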