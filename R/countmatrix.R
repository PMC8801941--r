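#' Sparse gene-by-cell UMI count container
#'
#' Wraps a sparse nonnegative-integer matrix (genes as rows, cells as
#' columns, the 10x orientation) together with its identifier lists and a
#' per-gene mitochondrial flag. This is the single source of truth every
#' downstream score is computed from.
#'
#' @param counts sparse or dense nonnegative integer matrix, genes x cells.
#' @param genes character vector of gene symbols (unique).
#' @param cells character vector of cell barcodes (unique).
#' @param mito_mask logical per-gene flag; if `NULL` it is derived from the
#'   case-insensitive `"mt-"` gene-symbol prefix (mouse mitochondrial
#'   nomenclature).
#' @return An object of class `CountMatrix` with elements `counts`
#'   (`dgCMatrix`), `genes`, `cells`, `mito_mask`.
#' @export
count_matrix <- function(counts, genes = rownames(counts),
                         cells = colnames(counts), mito_mask = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(genes) || is.null(cells)) {
    stop("gene and cell identifiers are required", call. = FALSE)
  }
  genes <- as.character(genes); cells <- as.character(cells)
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
    stop(sprintf("dimension mismatch: counts %d x %d vs %d genes, %d cells",
                 nrow(counts), ncol(counts), length(genes), length(cells)),
         call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("duplicate gene symbols", call. = FALSE)
  if (anyDuplicated(cells)) stop("duplicate cell barcodes", call. = FALSE)
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (is.null(mito_mask)) mito_mask <- is_mito_symbol(genes)
  stopifnot(length(mito_mask) == length(genes))
  dimnames(counts) <- list(genes, cells)
  structure(list(counts = counts, genes = genes, cells = cells,
                 mito_mask = as.logical(mito_mask)),
            class = "CountMatrix")
}

#' Mitochondrial-gene detection rule
#'
#' Case-insensitive gene-symbol prefix `"mt-"`, matching mouse nomenclature
#' (e.g. `mt-Nd1`, `MT-CO1`).
#' @param genes character vector of symbols.
#' @export
is_mito_symbol <- function(genes) {
  startsWith(tolower(genes), "mt-")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells, %d nonzero, %d mito genes\n",
              length(x$genes), length(x$cells),
              length(x$counts@x), sum(x$mito_mask)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by gene and/or cell identifiers or indices
#' @param x a `CountMatrix`.
#' @param genes,cells index vectors (character, integer or logical); `NULL`
#'   keeps everything, order is preserved as given.
#' @export
subset_matrix <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  gi <- if (is.null(genes)) seq_along(x$genes) else .resolve_idx(genes, x$genes, "gene")
  ci <- if (is.null(cells)) seq_along(x$cells) else .resolve_idx(cells, x$cells, "cell")
  count_matrix(x$counts[gi, ci, drop = FALSE], x$genes[gi], x$cells[ci],
               x$mito_mask[gi])
}

.resolve_idx <- function(idx, ids, what) {
  if (is.character(idx)) {
    pos <- match(idx, ids)
    if (anyNA(pos)) {
      stop(sprintf("unknown %s identifier(s): %s", what,
                   paste(utils::head(idx[is.na(pos)], 5), collapse = ", ")),
           call. = FALSE)
    }
    pos
  } else if (is.logical(idx)) {
    which(idx)
  } else {
    as.integer(idx)
  }
}

#' Cell annotation table
#'
#' Maps each barcode to its cluster, condition and sample labels. Cluster
#' labels are pipeline *inputs* here (graph clustering is upstream and out
#' of scope).
#'
#' @param barcode,cluster,condition,sample character vectors of equal length
#'   (`sample` defaults to the condition).
#' @return data.frame of class `CellAnnotation`.
#' @export
cell_annotation <- function(barcode, cluster, condition,
                            sample = condition) {
  if (anyDuplicated(barcode)) stop("duplicate barcodes in annotation", call. = FALSE)
  ann <- data.frame(barcode = as.character(barcode),
                    cluster = as.character(cluster),
                    condition = as.character(condition),
                    sample = as.character(sample),
                    stringsAsFactors = FALSE)
  class(ann) <- c("CellAnnotation", "data.frame")
  ann
}

#' Check that annotation and matrix agree on barcodes
#' @param matrix a `CountMatrix` (or `NormalizedMatrix`).
#' @param annotation a `CellAnnotation`.
#' @param require_complete if `TRUE` every matrix barcode must be annotated
#'   (needed before any cluster-wise operation).
#' @export
validate_annotation <- function(matrix, annotation, require_complete = TRUE) {
  missing_in_mat <- setdiff(annotation$barcode, matrix$cells)
  if (length(missing_in_mat)) {
    stop(sprintf("%d annotated barcode(s) not in matrix (e.g. %s)",
                 length(missing_in_mat), missing_in_mat[1]), call. = FALSE)
  }
  if (require_complete) {
    un <- setdiff(matrix$cells, annotation$barcode)
    if (length(un)) {
      stop(sprintf("%d matrix barcode(s) lack annotation (e.g. %s)",
                   length(un), un[1]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Signature definition: a named gene list
#' @param name signature name.
#' @param genes character vector; duplicates are dropped keeping first
#'   occurrence (with a warning), empty lists are an error.
#' @export
signature_definition <- function(name, genes) {
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop(sprintf("signature '%s' has an empty gene list", name),
                           call. = FALSE)
  if (anyDuplicated(genes)) {
    warning(sprintf("signature '%s': duplicate genes dropped", name), call. = FALSE)
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = as.character(name), genes = genes),
            class = "SignatureDefinition")
}
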