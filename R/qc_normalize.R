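#' QC thresholds
#'
#' The cell bounds are *strict* inequalities and the gene bound inclusive,
#' mirroring the conventional Seurat-style filter
#' `nFeature > 200, nFeature < 7000, percent.mt < 20, min.cells = 3`.
#'
#' @param min_features exclusive lower bound on detected genes per cell.
#' @param max_features exclusive upper bound on detected genes per cell.
#' @param max_percent_mt exclusive upper bound on the mitochondrial
#'   percentage, in \[0, 100\].
#' @param min_cells_per_gene inclusive lower bound on cells in which a gene
#'   is detected.
#' @export
qc_thresholds <- function(min_features = 200, max_features = 7000,
                          max_percent_mt = 20, min_cells_per_gene = 3) {
  stopifnot(min_features < max_features,
            max_percent_mt >= 0, max_percent_mt <= 100,
            min_cells_per_gene >= 0)
  structure(list(min_features = min_features, max_features = max_features,
                 max_percent_mt = max_percent_mt,
                 min_cells_per_gene = min_cells_per_gene),
            class = "QCThresholds")
}

#' Per-cell mitochondrial percentage
#'
#' `100 x mito counts / total counts` per cell, computed on the raw
#' matrix. Cells with zero total counts get 0 and are flagged in the
#' `"zero_total"` attribute.
#'
#' @param matrix a `CountMatrix` with its mito mask set.
#' @return named numeric vector (one value per cell).
#' @export
percent_mt <- function(matrix) {
  stopifnot(inherits(matrix, "CountMatrix"))
  tot <- Matrix::colSums(matrix$counts)
  mito <- Matrix::colSums(matrix$counts[matrix$mito_mask, , drop = FALSE])
  pct <- ifelse(tot > 0, 100 * mito / tot, 0)
  names(pct) <- matrix$cells
  attr(pct, "zero_total") <- matrix$cells[tot == 0]
  pct
}

#' Per-cell detected-gene count
#' @param matrix a `CountMatrix`.
#' @export
n_features <- function(matrix) {
  nf <- Matrix::colSums(matrix$counts > 0)
  names(nf) <- matrix$cells
  nf
}

#' Filter cells on detected genes and mitochondrial percentage
#'
#' Keeps exactly the cells with
#' `min_features < nFeature < max_features` and
#' `percent.mt < max_percent_mt` (all strict). Cell order is preserved.
#'
#' @param matrix a `CountMatrix`.
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `CountMatrix`; removal counts per criterion in the
#'   `"qc_removed"` attribute.
#' @export
filter_cells <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "CountMatrix"), inherits(thresholds, "QCThresholds"))
  nf <- n_features(matrix)
  mt <- percent_mt(matrix)
  low <- nf <= thresholds$min_features
  high <- nf >= thresholds$max_features
  mito <- mt >= thresholds$max_percent_mt
  keep <- !(low | high | mito)
  if (!any(keep)) stop("cell filter removed every cell", call. = FALSE)
  out <- subset_matrix(matrix, cells = which(keep))
  attr(out, "qc_removed") <- c(low_features = sum(low), high_features = sum(high),
                               high_mito = sum(mito & !low & !high))
  out
}

#' Filter genes on detection frequency
#'
#' Keeps genes detected (count > 0) in at least `min_cells_per_gene` cells
#' (inclusive). Applied after cell filtering; never touches cells.
#'
#' @inheritParams filter_cells
#' @export
filter_genes <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "CountMatrix"), inherits(thresholds, "QCThresholds"))
  ncells_detected <- Matrix::rowSums(matrix$counts > 0)
  keep <- ncells_detected >= thresholds$min_cells_per_gene
  if (!any(keep)) stop("gene filter removed every gene", call. = FALSE)
  out <- subset_matrix(matrix, genes = which(keep))
  attr(out, "qc_removed") <- c(low_detection = sum(!keep))
  out
}

#' Run the full QC sequence with a report
#'
#' Order is fixed: percent.mt on the raw matrix, then the cell filter, then
#' the gene filter.
#' @inheritParams filter_cells
#' @return list with `matrix` and a one-row `report` data frame
#'   (cells/genes before and after, per-filter removal counts).
#' @export
run_qc <- function(matrix, thresholds = qc_thresholds()) {
  before <- dim(matrix)
  cm <- filter_cells(matrix, thresholds)
  cell_rm <- attr(cm, "qc_removed")
  gm <- filter_genes(cm, thresholds)
  gene_rm <- attr(gm, "qc_removed")
  report <- data.frame(
    genes_before = before[1], cells_before = before[2],
    cells_removed_low_features = cell_rm[["low_features"]],
    cells_removed_high_features = cell_rm[["high_features"]],
    cells_removed_high_mito = cell_rm[["high_mito"]],
    genes_removed_low_detection = gene_rm[["low_detection"]],
    genes_after = dim(gm)[1], cells_after = dim(gm)[2])
  list(matrix = gm, report = report)
}

#' Depth-normalize and log-transform
#'
#' `value = ln(1 + scale x count / cell_total)` — the standard library-size
#' normalization. A deliberate substitution for variance-stabilizing batch
#' correction, which is out of scope here; zeros stay exactly zero and the
#' result is invariant to per-cell depth scaling by construction.
#'
#' @param matrix a QC-passed `CountMatrix`.
#' @param scale target depth (default 1e4).
#' @return a `NormalizedMatrix`: same identifiers, sparse values.
#' @export
normalize_counts <- function(matrix, scale = 1e4) {
  stopifnot(inherits(matrix, "CountMatrix"), scale > 0)
  tot <- Matrix::colSums(matrix$counts)
  if (any(tot == 0)) {
    stop(sprintf("%d cell(s) with zero total counts; run QC first", sum(tot == 0)),
         call. = FALSE)
  }
  m <- methods::as(matrix$counts, "TsparseMatrix")
  vals <- log1p(scale * m@x / tot[m@j + 1L])
  values <- Matrix::sparseMatrix(i = m@i + 1L, j = m@j + 1L, x = vals,
                                 dims = dim(m),
                                 dimnames = list(matrix$genes, matrix$cells))
  structure(list(values = values, genes = matrix$genes, cells = matrix$cells,
                 scale = scale),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (log1p, scale %g)\n",
              length(x$genes), length(x$cells), x$scale))
  invisible(x)
}

#' Subset a NormalizedMatrix by cells (barcodes, indices or logical)
#' @param x a `NormalizedMatrix`.
#' @param cells index vector.
#' @keywords internal
subset_norm_cells <- function(x, cells) {
  ci <- .resolve_idx(cells, x$cells, "cell")
  structure(list(values = x$values[, ci, drop = FALSE], genes = x$genes,
                 cells = x$cells[ci], scale = x$scale),
            class = "NormalizedMatrix")
}
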