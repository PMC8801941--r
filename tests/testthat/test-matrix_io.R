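test_that("MTX round trip preserves the matrix exactly", {
  set.seed(1)
  m <- matrix(rpois(30 * 12, 0.8), 30, 12)
  cm <- toy_matrix(m, genes = c(sprintf("g%02d", 1:28), "mt-Nd1", "MT-CO1"))
  d <- tempfile()
  write_mtx(cm, d)
  back <- read_mtx(d)
  expect_identical(back$genes, cm$genes)
  expect_identical(back$cells, cm$cells)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts),
               ignore_attr = TRUE)
  expect_equal(sum(back$counts), sum(m))
  # stated mito prefix rule, case-insensitive
  expect_identical(which(back$mito_mask), c(29L, 30L))
})

test_that("reading rejects dimension mismatches and bad content", {
  set.seed(2)
  cm <- toy_matrix(matrix(rpois(100, 1), 10, 10))
  d <- tempfile()
  write_mtx(cm, d)
  feats <- readLines(file.path(d, "features.tsv"))
  writeLines(feats[1:9], file.path(d, "features.tsv"))
  expect_error(read_mtx(d), "dimension mismatch")
  writeLines(feats, file.path(d, "features.tsv"))
  bcs <- readLines(file.path(d, "barcodes.tsv"))
  writeLines(c(bcs, "extra"), file.path(d, "barcodes.tsv"))
  expect_error(read_mtx(d), "dimension mismatch")
  writeLines(bcs, file.path(d, "barcodes.tsv"))
  writeLines(rep(bcs[1], 10), file.path(d, "barcodes.tsv"))
  expect_error(read_mtx(d), "duplicate")
  expect_error(read_mtx(tempfile()), "missing file")
})

test_that("count_matrix enforces its invariants", {
  expect_error(count_matrix(matrix(-1, 1, 1), "g", "c"), "nonnegative")
  expect_error(count_matrix(matrix(1.5, 1, 1), "g", "c"), "integer")
  expect_error(count_matrix(matrix(1, 2, 1), c("g", "g"), "c"), "duplicate gene")
  expect_error(count_matrix(matrix(1, 1, 2), "g", c("c", "c")), "duplicate cell")
  expect_error(count_matrix(matrix(1, 2, 2), c("a", "b", "c"), c("x", "y")),
               "dimension mismatch")
})

test_that("GMT parsing matches the shipped signature fixtures", {
  gmt <- system.file("extdata", "default_signatures.gmt", package = "sigcorr")
  if (!nzchar(gmt)) gmt <- file.path("..", "..", "inst", "extdata", "default_signatures.gmt")
  sigs <- read_signatures(gmt)
  expect_named(sigs, c("Senescence_signature", "Androgen_synthesis_signature",
                       "mCRPs", "Collagen"))
  expect_identical(sigs$Senescence_signature$genes,
                   c("Cdkn1a", "Cdkn1b", "Cdkn1c", "Cdkn2a", "Cdkn2b",
                     "Cdkn2c", "Cdkn2d"))
  expect_identical(sigs$mCRPs$genes,
                   c("Cd59a", "Cd59b", "Cd55b", "Cd55", "Cd46"))
  expect_identical(sigs$Androgen_synthesis_signature$genes,
                   c("Star", "Cyp11a1", "Cyp17a1", "Hsd3b1"))
})

test_that("signature parsing dedups, warns and errors per contract", {
  f <- tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tCdkn1a\tCdkn1b\tCdkn1a", f)
  expect_warning(sigs <- read_signatures(f), "duplicate")
  expect_identical(sigs$S1$genes, c("Cdkn1a", "Cdkn1b"))

  writeLines(c("S1\tdesc\tA\tB", "S1\tdesc\tC\tD"), f)
  expect_error(read_signatures(f), "duplicate signature name")
  writeLines("S1\tdesc", f)
  expect_error(read_signatures(f), "malformed|empty")

  # TSV dialect, order preserved
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("signature\tgene", "S2\tZzz", "S2\tAaa", "S3\tQq"), f2)
  sigs2 <- read_signatures(f2)
  expect_identical(sigs2$S2$genes, c("Zzz", "Aaa"))
  expect_named(sigs2, c("S2", "S3"))

  expect_error(signature_definition("empty", character()), "empty")
})

test_that("match_signature drops unmeasured genes with warning; all-absent errors", {
  sig <- signature_definition("s", c("g01", "nope1", "g02", "nope2"))
  expect_warning(m <- match_signature(sig, sprintf("g%02d", 1:5)), "2 gene")
  expect_identical(m$signature$genes, c("g01", "g02"))
  expect_identical(m$n_missing, 2L)
  sig2 <- signature_definition("s2", c("x", "y"))
  expect_error(match_signature(sig2, sprintf("g%02d", 1:5)), "none of its")
})

test_that("annotation round trip and validation", {
  ann <- cell_annotation(c("c1", "c2"), c("Lc", "Im"), c("Nt", "Nt"))
  f <- tempfile()
  write_tsv(ann, f)
  back <- read_annotation(f)
  expect_equal(back$barcode, ann$barcode)
  expect_equal(back$cluster, ann$cluster)
  cm <- toy_matrix(matrix(1:4, 2, 2), cells = c("c1", "c2"))
  expect_true(validate_annotation(cm, ann))
  cm2 <- toy_matrix(matrix(1:6, 2, 3), cells = c("c1", "c2", "c3"))
  expect_error(validate_annotation(cm2, ann), "lack annotation")
  expect_silent(validate_annotation(cm2, ann, require_complete = FALSE))
  expect_error(cell_annotation(c("c1", "c1"), c("a", "a"), c("x", "x")),
               "duplicate")
})
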