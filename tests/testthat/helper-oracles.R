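# Independent exact Wilcoxon oracle: permutation distribution of the
# group-A rank sum over all C(n, n_a) label assignments, two-sided around
# its mean. Deliberately coded apart from the package's implementation.
enum_wilcox_p <- function(x, y) {
  na <- length(x)
  rk <- rank(c(x, y))
  combs <- utils::combn(length(rk), na)
  W <- colSums(matrix(rk[combs], nrow = na))
  obs <- sum(rk[seq_len(na)])
  mean(abs(W - mean(W)) >= abs(obs - mean(W)) - 1e-12)
}

# Two-condition normalized world for DE tests. Module genes get
# mean_scale = 2 (moderately expressed pathway genes), so detection is not
# the limiting factor when a fold change is planted.
de_world <- function(seed, n_per_group = 100, n_genes = 150, shift = NULL,
                     module_genes = 25) {
  mods <- if (is.null(shift)) list() else
    list(module_spec("M", module_genes, loading = 0.15, mean_scale = 2,
                     condition_mean_shift = c(O50t = shift)))
  cfg <- synthetic_config(n_genes = n_genes,
                          n_cells_per_cluster = c(Lc = n_per_group),
                          conditions = c("Nt", "O50t"), modules = mods,
                          seed = seed)
  sim <- generate_counts(cfg, compute_planted = FALSE)
  list(norm = normalize_counts(sim$matrix), ann = sim$annotation, sim = sim)
}

# 10-cell QC fixture with known violations: cells 1-7 clean, cell 8 sits
# exactly at min_features (boundary, removed), cell 9 exceeds max_features,
# cell 10 sits exactly at 20.0% mito (boundary, removed).
qc_fixture <- function() {
  n_genes <- 30
  thr <- qc_thresholds(min_features = 5, max_features = 25,
                       max_percent_mt = 20, min_cells_per_gene = 3)
  m <- matrix(0L, n_genes, 10)
  set.seed(42)
  for (c in 1:7) m[sample(3:28, 10), c] <- 1L + rpois(10, 2)
  m[3:7, 8] <- 1L                      # exactly 5 detected genes
  m[, 9] <- 1L                         # 30 detected genes > 25
  m[1, 10] <- 2L; m[10:17, 10] <- 1L   # mito 2 of 10 counts = 20.0%
  genes <- c("mt-Nd1", "mt-Co1", sprintf("g%02d", 3:n_genes))
  list(matrix = toy_matrix(m, genes = genes), thresholds = thr)
}
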