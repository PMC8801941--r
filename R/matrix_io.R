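#' Read a 10x-style MTX triplet directory
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate format, genes as rows),
#' `features.tsv` and `barcodes.tsv`. Transposed inputs are rejected, not
#' guessed; mitochondrial genes are flagged by the case-insensitive `"mt-"`
#' symbol prefix.
#'
#' @param dir directory containing the three files.
#' @return a [count_matrix()].
#' @export
read_mtx <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  feat_path <- file.path(dir, "features.tsv")
  bc_path <- file.path(dir, "barcodes.tsv")
  for (p in c(mtx_path, feat_path, bc_path)) {
    if (!file.exists(p)) stop(sprintf("missing file: %s", p), call. = FALSE)
  }
  m <- Matrix::readMM(mtx_path)
  feats <- utils::read.delim(feat_path, header = FALSE,
                             stringsAsFactors = FALSE)
  genes <- as.character(feats[[if (ncol(feats) >= 2) 2 else 1]])
  cells <- readLines(bc_path)
  cells <- cells[nzchar(cells)]
  if (nrow(m) != length(genes)) {
    stop(sprintf("dimension mismatch: matrix.mtx declares %d rows but features.tsv lists %d genes",
                 nrow(m), length(genes)), call. = FALSE)
  }
  if (ncol(m) != length(cells)) {
    stop(sprintf("dimension mismatch: matrix.mtx declares %d columns but barcodes.tsv lists %d barcodes",
                 ncol(m), length(cells)), call. = FALSE)
  }
  count_matrix(m, genes, cells)
}

#' Write a CountMatrix as a canonical MTX triplet
#'
#' Integer MatrixMarket coordinate format with triplets sorted
#' column-major, so identical matrices always produce byte-identical
#' files.
#'
#' @param x a `CountMatrix`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(x$counts, "TsparseMatrix")
  ord <- order(m@j, m@i)
  i <- m@i[ord] + 1L; j <- m@j[ord] + 1L; v <- as.integer(m@x[ord])
  con <- file(file.path(dir, "matrix.mtx"), "wb")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(v)),
               sprintf("%d %d %d", i, j, v)), con)
  writeLines(x$genes, file.path(dir, "features.tsv"))
  writeLines(x$cells, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read signature definitions from GMT or two-column TSV
#'
#' GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' TSV: header `signature<TAB>gene`, one gene per row.
#' Duplicate genes within a set are dropped (first occurrence kept, with a
#' warning); duplicate signature names or empty gene lists are errors.
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv"`; default guessed from the extension.
#' @return named list of [signature_definition()] objects.
#' @export
read_signatures <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sigs <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) stop(sprintf("malformed GMT line: %s", substr(l, 1, 40)),
                              call. = FALSE)
      signature_definition(f[1], f[-(1:2)])
    })
  } else {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("signature TSV needs two columns: signature, gene",
                            call. = FALSE)
    sigs <- lapply(split(tab[[2]], factor(tab[[1]], levels = unique(tab[[1]]))),
                   function(g) NULL)
    sigs <- Map(signature_definition, names(sigs),
                split(tab[[2]], factor(tab[[1]], levels = unique(tab[[1]]))))
  }
  nm <- vapply(sigs, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate signature name: %s", nm[duplicated(nm)][1]),
         call. = FALSE)
  }
  stats::setNames(sigs, nm)
}

#' Write signatures to a GMT file
#' @param signatures list of `SignatureDefinition`.
#' @param path output path.
#' @export
write_signatures <- function(signatures, path) {
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, "sigcorr", s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a cell-annotation TSV (barcode, cluster, condition[, sample])
#' @param path file path; tab-separated with header.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("barcode", "cluster", "condition")
  if (!all(need %in% names(tab))) {
    stop(sprintf("annotation TSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  cell_annotation(tab$barcode, tab$cluster, tab$condition,
                  sample = tab$sample %||% tab$condition)
}

#' Write a data frame as TSV with a fixed column order
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop signature genes absent from a matrix
#'
#' Unmeasured genes are routine in pathway lists: they are dropped with a
#' warning; a signature with *no* measured gene is an error.
#' @param signature a `SignatureDefinition`.
#' @param genes the matrix gene universe.
#' @return list with the pruned `signature`, `n_used`, `n_missing`.
#' @export
match_signature <- function(signature, genes) {
  present <- signature$genes %in% genes
  n_missing <- sum(!present)
  if (!any(present)) {
    stop(sprintf("signature '%s': none of its %d genes are in the matrix",
                 signature$name, length(signature$genes)), call. = FALSE)
  }
  if (n_missing > 0) {
    warning(sprintf("signature '%s': %d gene(s) not in matrix, dropped",
                    signature$name, n_missing), call. = FALSE)
  }
  list(signature = signature_definition(signature$name, signature$genes[present]),
       n_used = sum(present), n_missing = n_missing)
}
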