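test_that("pearson_cor closed forms, errors and degenerate flagging", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  # hand-computed via the covariance formula: cov = 3, var_x = var_y = 5
  pc <- pearson_cor(x, c(2, 1, 4, 3))
  expect_equal(pc$r, 0.6)
  t_stat <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(pc$p, 2 * pt(-t_stat, df = 2))
  # one independent check against R's reference implementation
  set.seed(7); a <- rnorm(30); b <- rnorm(30)
  ct <- cor.test(a, b)
  mine <- pearson_cor(a, b)
  expect_equal(mine$r, unname(ct$estimate))
  expect_equal(mine$p, ct$p.value)

  expect_error(pearson_cor(1:2, 1:2), "insufficient cells")
  expect_error(pearson_cor(1:3, 1:4), "equal length")
  deg <- pearson_cor(c(1, 1, 1), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$r))
})

test_that("pearson properties: affine invariance and negation antisymmetry", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(40); y <- rnorm(40, x)
    r0 <- pearson_cor(x, y)$r
    expect_equal(pearson_cor(3.2 * x + 5, y)$r, r0)
    expect_equal(pearson_cor(x, 0.1 * y - 2)$r, r0)
    expect_equal(pearson_cor(-x, y)$r, -r0)
  }
})

test_that("screen_config validates bounds", {
  expect_error(screen_config(r_min_pos = -0.2), "r_min_pos")
  expect_error(screen_config(r_max_neg = 0.3), "r_max_neg")
  expect_silent(screen_config(r_min_pos = 0.6, r_max_neg = -0.45))
})

test_that("correlation_screen thresholds, ordering, self-exclusion", {
  set.seed(3)
  n <- 120
  z <- rnorm(n)
  scores <- data.frame(
    barcode = sprintf("c%03d", 1:n), cluster = "Lc", condition = "Nt",
    Tgt = z + rnorm(n, sd = 0.4),
    Hi = z + rnorm(n, sd = 0.4),          # strongly positive
    Nul = rnorm(n),                        # null
    Neg = -z + rnorm(n, sd = 0.4),         # strongly negative
    Flat = rep(1, n))                      # degenerate
  cfg <- screen_config(r_min_pos = 0.6, r_max_neg = -0.45)
  expect_warning(
    out <- correlation_screen(scores, "Tgt",
                              candidates = c("Tgt", "Hi", "Nul", "Neg", "Flat"),
                              cluster = "Lc", condition = "Nt", config = cfg),
    "self-correlation")
  expect_identical(out$candidate, c("Hi", "Neg"))
  expect_true(all(diff(out$r) <= 0))

  # unbounded screen keeps all candidates, flags the degenerate one
  open <- correlation_screen(scores, "Tgt", cluster = "Lc", condition = "Nt",
                             config = screen_config())
  expect_equal(nrow(open), 4)
  expect_true(open$degenerate[open$candidate == "Flat"])
  # BH column exists but filtering used r only
  expect_true("p_adj" %in% names(open))

  # ties broken lexicographically by candidate name
  scores$Hi2 <- scores$Hi
  tied <- correlation_screen(scores, "Tgt", candidates = c("Hi", "Hi2"),
                             cluster = "Lc", condition = "Nt",
                             config = screen_config(r_min_pos = 0.1))
  expect_equal(tied$r[1], tied$r[2])
  expect_identical(tied$candidate, c("Hi", "Hi2"))

  expect_error(correlation_screen(scores, "nope"), "not in score table")
  expect_error(correlation_screen(scores[1:4, ], "Tgt", cluster = "Lc",
                                  condition = "Nt"), "insufficient cells")
})

test_that("tf_screen ranks, filters on mean expression, honors exclusions", {
  # craft counts: target row and several TFs with known relationships
  set.seed(8)
  n <- 80
  base <- rpois(n, 5) + 1L
  tf_same <- base                       # identical to target -> r = 1
  noise <- matrix(rpois(5 * n, 5), 5, n)
  low <- integer(n); low[1:4] <- 1L     # rarely detected -> low mean expr
  hmgb4 <- base + rpois(n, 1)           # excluded despite high r
  filler <- matrix(rpois(20 * n, 6), 20, n)  # keeps library sizes stable
  m <- rbind(base, tf_same, noise, low, hmgb4, filler)
  genes <- c("Star", "TFsame", sprintf("TFn%d", 1:5), "TFlow", "Hmgb4",
             sprintf("bg%02d", 1:20))
  cm <- toy_matrix(m, genes = genes)
  ann <- cell_annotation(cm$cells, rep("Lc", n), rep("Nt", n))
  norm <- normalize_counts(cm)
  tfs <- c("TFsame", sprintf("TFn%d", 1:5), "TFlow", "Hmgb4", "Star")

  res <- suppressWarnings(
    tf_screen(norm, ann, "Star", tfs, cluster = "Lc", condition = "Nt",
              config = screen_config(top_k = 3)))
  expect_identical(res$positive$tf[1], "TFsame")
  expect_equal(res$positive$r[1], 1)
  expect_equal(res$positive$rank, seq_len(nrow(res$positive)))
  # excluded TF never appears even with near-perfect correlation
  expect_false("Hmgb4" %in% c(res$positive$tf, res$negative$tf))
  # target itself never appears
  expect_false("Star" %in% c(res$positive$tf, res$negative$tf))
  # low-expression TF filtered by the mean-expression floor
  expect_false("TFlow" %in% c(res$positive$tf, res$negative$tf))
  expect_lt(mean(as.matrix(norm$values)["TFlow", ]), 0.5)
  # within a direction r is monotone along rank
  expect_true(all(diff(res$positive$r) <= 0))
  if (nrow(res$negative) > 1) expect_true(all(diff(res$negative$r) >= 0))

  # shortfall: fewer survivors than top_k warns (per direction), not errors
  w <- testthat::capture_warnings(
    short <- tf_screen(norm, ann, "Star", c("TFsame", "TFn1"), cluster = "Lc",
                       condition = "Nt", config = screen_config(top_k = 20)))
  expect_true(any(grepl("only", w)))
  expect_lte(nrow(short$positive), 2)
})

test_that("correlation_shift deltas, floors and skipped pairs", {
  recs <- function(r) data.frame(target = "T", candidate = c("a", "b", "c"),
                                 r = r, stringsAsFactors = FALSE)
  # identical conditions: zero delta, no flips
  sh <- correlation_shift(recs(c(0.5, -0.3, 0.05)), recs(c(0.5, -0.3, 0.05)))
  expect_true(all(sh$delta_r == 0))
  expect_false(any(sh$sign_flip))
  # sign flip only above the floor on both sides
  a <- recs(c(0.6, 0.05, 0.5))
  b <- recs(c(-0.5, -0.05, 0.45))
  sh2 <- correlation_shift(a, b)
  expect_true(sh2$sign_flip[sh2$candidate == "a"])
  expect_false(sh2$sign_flip[sh2$candidate == "b"])  # below floor
  expect_false(sh2$sign_flip[sh2$candidate == "c"])  # no sign change
  expect_equal(sh2$delta_r, b$r - a$r)
  # pair missing in one condition -> skipped with warning
  expect_warning(sh3 <- correlation_shift(recs(c(0.1, 0.2, 0.3)),
                                          recs(c(0.1, 0.2, 0.3))[1:2, ]),
                 "skipped")
  expect_equal(nrow(sh3), 2)
})

test_that("a planted cross-condition loading flip is detected end-to-end", {
  cfg <- synthetic_config(
    n_genes = 1200, n_cells_per_cluster = c(Lc = 800),
    conditions = c("Nt", "O50t"),
    modules = list(
      module_spec("A", 40, loading = 0.42, latent_factor_id = "f"),
      module_spec("B", 40, loading = 0.42, latent_factor_id = "f",
                  condition_loading = c(O50t = -0.42))),
    seed = 31)
  sim <- generate_counts(cfg, compute_planted = FALSE)
  st <- score_table(sim$matrix, module_signatures(sim, c("A", "B")),
                    sim$annotation)
  open <- screen_config()
  ra <- correlation_screen(st, "A", cluster = "Lc", condition = "Nt",
                           config = open)
  rb <- correlation_screen(st, "A", cluster = "Lc", condition = "O50t",
                           config = open)
  sh <- correlation_shift(ra, rb)
  expect_true(sh$sign_flip[sh$candidate == "B"])
  expect_gt(sh$r_a[sh$candidate == "B"], 0.5)
  expect_lt(sh$r_b[sh$candidate == "B"], -0.5)
})
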