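#' Score a signature as the percentage of counts per cell
#'
#' The pipeline's sole pathway-activity measure:
#' `score(cell) = 100 x sum(counts over signature genes) / sum(all counts)`,
#' computed on *raw* counts (the definition is only meaningful on counts,
#' and it is exactly invariant to per-cell depth). Signature genes absent
#' from the matrix are excluded from the numerator and reported in
#' `n_genes_missing`; there is no renormalization by list length.
#'
#' @param matrix a `CountMatrix`.
#' @param signature a [signature_definition()].
#' @return a `ScoreVector`: numeric per-cell scores in \[0, 100\] with
#'   attributes `signature`, `n_genes_used`, `n_genes_missing`.
#' @export
score_signature <- function(matrix, signature) {
  stopifnot(inherits(matrix, "CountMatrix"),
            inherits(signature, "SignatureDefinition"))
  matched <- match_signature(signature, matrix$genes)
  tot <- Matrix::colSums(matrix$counts)
  if (any(tot == 0)) {
    stop(sprintf("%d cell(s) with zero total counts cannot be scored", sum(tot == 0)),
         call. = FALSE)
  }
  rows <- match(matched$signature$genes, matrix$genes)
  num <- Matrix::colSums(matrix$counts[rows, , drop = FALSE])
  score <- 100 * num / tot
  names(score) <- matrix$cells
  structure(score, signature = signature$name,
            n_genes_used = matched$n_used,
            n_genes_missing = matched$n_missing,
            class = "ScoreVector")
}

#' @export
print.ScoreVector <- function(x, ...) {
  cat(sprintf("ScoreVector '%s': %d cells, %d genes used (%d missing), mean %.3f%%\n",
              attr(x, "signature"), length(x), attr(x, "n_genes_used"),
              attr(x, "n_genes_missing"), mean(unclass(x))))
  invisible(x)
}

#' Score several signatures into one per-cell table
#'
#' One column per signature, aligned on cells, with cluster/condition
#' columns attached from the annotation — the direct input of every
#' correlation screen.
#'
#' @param matrix a `CountMatrix`.
#' @param signatures non-empty list of [signature_definition()].
#' @param annotation optional [cell_annotation()] covering all cells.
#' @return data frame: `barcode`, (`cluster`, `condition` if annotated),
#'   then one numeric column per signature.
#' @export
score_table <- function(matrix, signatures, annotation = NULL) {
  if (!length(signatures)) stop("at least one signature required", call. = FALSE)
  if (inherits(signatures, "SignatureDefinition")) signatures <- list(signatures)
  tab <- data.frame(barcode = matrix$cells, stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    validate_annotation(matrix, annotation)
    idx <- match(matrix$cells, annotation$barcode)
    tab$cluster <- annotation$cluster[idx]
    tab$condition <- annotation$condition[idx]
  }
  for (s in signatures) {
    if (s$name %in% names(tab)) {
      stop(sprintf("duplicate signature name '%s'", s$name), call. = FALSE)
    }
    tab[[s$name]] <- as.numeric(score_signature(matrix, s))
  }
  tab
}

#' Signature columns of a score table
#' @param scores output of [score_table()].
#' @keywords internal
score_columns <- function(scores) {
  setdiff(names(scores), c("barcode", "cluster", "condition"))
}
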