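test_that("config validation rejects malformed worlds", {
  expect_error(synthetic_config(mito_fraction = 1), "mito_fraction")
  expect_error(synthetic_config(n_cells_per_cluster = c(Lc = 0)),
               "at least one cell")
  expect_error(synthetic_config(n_cells_per_cluster = stats::setNames(5, "")),
               "named")
  expect_error(
    synthetic_config(modules = list(
      module_spec("A", 2, gene_names = c("x", "y")),
      module_spec("B", 2, gene_names = c("y", "z")))),
    "overlapping")
  expect_error(
    synthetic_config(n_genes = 5, mito_genes = 0, modules = list(
      module_spec("A", 3), module_spec("B", 3))),
    "exceed")
})

test_that("empirical gene means match the NB expectation (no modules)", {
  # one cluster, no modules, libsize_sigma = 0: pooled over 20 replicate
  # seeds the per-gene mean must sit within MC error of the stored
  # expected mean (3 SE per gene would give ~0.3% false alarms per gene,
  # so the family-level bound is 4 SE)
  n_genes <- 60; n_cells <- 150; n_seeds <- 20
  sums <- 0
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_genes = n_genes, mito_genes = 5,
                            n_cells_per_cluster = c(Lc = n_cells),
                            libsize_sigma = 0, cluster_sigma = 0, seed = s)
    sim <- generate_counts(cfg, compute_planted = FALSE)
    if (s == 1) mu <- sim$truth$expected_means[["Lc|Nt"]]
    # expected means differ across seeds (gene factors are seed-specific),
    # so standardize within seed and pool z-scores
    mu_s <- sim$truth$expected_means[["Lc|Nt"]]
    v_s <- mu_s + mu_s^2 / cfg$dispersion
    z_s <- (Matrix::rowMeans(sim$matrix$counts) - mu_s) / sqrt(v_s / n_cells)
    sums <- sums + z_s
  }
  z_pooled <- sums / sqrt(n_seeds)
  expect_lt(max(abs(z_pooled)), 4)
  expect_gt(mean(abs(z_pooled) < 3), 0.95)
  # pooled z should look standard normal, not biased
  expect_lt(abs(mean(z_pooled)), 3 / sqrt(n_genes))
})

test_that("co-loaded modules recover the planted score correlation", {
  cfg <- pair_world(0.6, n_cells = 800, seed = 11)
  target <- planted_correlation(cfg, "A", "B")
  r <- recovered_pair_r(cfg)
  # Fisher-z 99% interval around the planted target
  expect_lt(abs(atanh(r) - atanh(target)), 2.576 / sqrt(800 - 3))
  expect_gt(target, 0.5); expect_lt(target, 0.7)

  # opposite-sign loadings: same magnitude band, negative sign
  cfg_neg <- pair_world(-0.6, n_cells = 800, seed = 11)
  r_neg <- recovered_pair_r(cfg_neg)
  expect_lt(r_neg, 0)
  expect_lt(abs(atanh(abs(r_neg)) - atanh(target)), 2.576 / sqrt(800 - 3))
})

test_that("planted_correlation contract: zeros, monotonicity, sign flips", {
  cfg0 <- pair_world(0, seed = 2)
  expect_identical(planted_correlation(cfg0, "A", "B"), 0)
  expect_error(planted_correlation(cfg0, "A", "nope"), "unknown module")
  expect_error(planted_correlation(cfg0, "A", "B", condition = "xx"),
               "unknown condition")

  # monotone increasing in |loading| over a grid (finite differences)
  rhos <- vapply(c(0.15, 0.3, 0.5, 0.8), function(l) {
    cfg <- synthetic_config(
      n_genes = 600, n_cells_per_cluster = c(Lc = 10),
      modules = list(module_spec("A", 30, loading = l, latent_factor_id = "f"),
                     module_spec("B", 30, loading = l, latent_factor_id = "f")),
      seed = 5, planted_mc_cells = 5e4)
    planted_correlation(cfg, "A", "B")
  }, 0)
  expect_true(all(diff(rhos) > 0))
  expect_true(all(rhos > 0 & rhos <= 1))

  # condition_loading sign flip flips the target between conditions
  cfg_flip <- synthetic_config(
    n_genes = 600, n_cells_per_cluster = c(Lc = 10),
    conditions = c("Nt", "O50t"),
    modules = list(
      module_spec("A", 30, loading = 0.4, latent_factor_id = "f"),
      module_spec("B", 30, loading = 0.4, latent_factor_id = "f",
                  condition_loading = c(O50t = -0.4))),
    seed = 5, planted_mc_cells = 5e4)
  r_nt <- planted_correlation(cfg_flip, "A", "B", "Nt")
  r_o50 <- planted_correlation(cfg_flip, "A", "B", "O50t")
  expect_gt(r_nt, 0); expect_lt(r_o50, 0)
  expect_lt(abs(r_nt + r_o50), 0.03)  # sign symmetry of the construction
})

test_that("identical config + seed reproduces the MTX bytes", {
  cfg <- pair_world(0.6, n_cells = 60, n_genes = 300, seed = 7,
                    planted_mc_cells = 1e3)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_synthetic(generate_counts(cfg), d1)
  write_synthetic(generate_counts(cfg), d2)
  files <- c("matrix.mtx", "features.tsv", "barcodes.tsv", "annotation.tsv")
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  cfg2 <- pair_world(0.6, n_cells = 60, n_genes = 300, seed = 8,
                     planted_mc_cells = 1e3)
  write_synthetic(generate_counts(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "matrix.mtx"))),
                         unname(tools::md5sum(file.path(d3, "matrix.mtx")))))
})

test_that("mito fraction and condition shifts are realized", {
  cfg <- synthetic_config(n_genes = 800, n_cells_per_cluster = c(Lc = 600),
                          mito_genes = 12, mito_fraction = 0.08, seed = 3)
  sim <- generate_counts(cfg, compute_planted = FALSE)
  expect_equal(sum(sim$matrix$mito_mask), 12)
  expect_lt(abs(mean(percent_mt(sim$matrix)) - 8), 2)

  # planted condition mean shift appears in the raw module counts
  cfg2 <- synthetic_config(
    n_genes = 500, n_cells_per_cluster = c(Lc = 300),
    conditions = c("Nt", "O50t"),
    modules = list(module_spec("Sen", 30, loading = 0.2,
                               condition_mean_shift = c(O50t = 2))),
    seed = 4)
  sim2 <- generate_counts(cfg2, compute_planted = FALSE)
  rows <- which(!is.na(sim2$truth$genes$module))
  cond <- sim2$annotation$condition
  m_nt <- mean(Matrix::colSums(sim2$matrix$counts[rows, cond == "Nt"]))
  m_o <- mean(Matrix::colSums(sim2$matrix$counts[rows, cond == "O50t"]))
  expect_gt(m_o / m_nt, 1.5)
})

test_that("recovered correlation converges to the planted target with n", {
  ns <- c(200, 800, 3200)
  errs <- sapply(seq_len(20), function(s) {
    vapply(ns, function(n) {
      cfg <- pair_world(0.6, n_cells = n, seed = 100 + s)
      abs(recovered_pair_r(cfg) - 0.6)
    }, 0)
  })
  med <- apply(errs, 1, stats::median)
  # median error shrinks with n (small-n medians can tie within MC noise,
  # so the strict requirement is endpoint-to-endpoint)
  expect_gt(med[1], med[3])
  expect_gt(med[1], med[2])
  expect_lt(med[3], med[2] + 0.01)
})
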