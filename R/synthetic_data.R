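#' Specify a planted gene module
#'
#' A module is a block of genes whose negative-binomial means are scaled by
#' `exp(loading * z - loading^2/2)` for a per-cell standard-normal latent
#' factor `z`. Modules that share a `latent_factor_id` co-vary: same-sign
#' loadings plant a positive correlation between their per-cell percentage
#' scores, opposite signs a negative one. The `- loading^2/2` term keeps the
#' expected mean loading-free, so `condition_mean_shift` is interpretable as
#' a pure fold change.
#'
#' @param name module name (also the default gene-name stem).
#' @param n_genes number of genes in the module.
#' @param loading real; latent-factor loading (0 = no covariation).
#' @param latent_factor_id identifier shared between co-varying modules;
#'   defaults to the module's own name (private factor).
#' @param condition_mean_shift named numeric, condition -> multiplicative
#'   mean shift (default 1 everywhere).
#' @param condition_loading named numeric, condition -> loading override
#'   (enables planted correlation flips between conditions).
#' @param mean_scale multiplies the baseline mean of the module's genes
#'   (use small values to plant low-expression genes).
#' @param gene_names optional explicit gene symbols (length `n_genes`).
#' @export
module_spec <- function(name, n_genes, loading = 0,
                        latent_factor_id = name,
                        condition_mean_shift = NULL,
                        condition_loading = NULL,
                        mean_scale = 1,
                        gene_names = NULL) {
  stopifnot(n_genes >= 1, mean_scale > 0)
  if (!is.null(gene_names) && length(gene_names) != n_genes) {
    stop("gene_names must have length n_genes", call. = FALSE)
  }
  structure(list(name = name, n_genes = as.integer(n_genes),
                 loading = loading, latent_factor_id = latent_factor_id,
                 condition_mean_shift = condition_mean_shift,
                 condition_loading = condition_loading,
                 mean_scale = mean_scale, gene_names = gene_names),
            class = "ModuleSpec")
}

#' Configuration for the synthetic scRNA-seq generator
#'
#' Describes a world of discrete cell clusters, log-normal per-cell library
#' factors, negative-binomial gene counts (variance `mu + mu^2/dispersion`,
#' one global size parameter), mitochondrial genes named with the `mt-`
#' prefix so QC detects them by the same rule as real data, and planted
#' gene modules (see [module_spec()]).
#'
#' @param n_genes total genes, including module and mito genes.
#' @param n_cells_per_cluster named integer vector: cluster name -> cells
#'   per cluster *per condition*.
#' @param conditions character vector of condition names.
#' @param baseline_mean mean count scale per gene before gene/cell factors.
#' @param dispersion NB size parameter (global).
#' @param libsize_sigma sdlog of the log-normal per-cell library factor.
#' @param mito_genes number of genes flagged mitochondrial.
#' @param mito_fraction target mean fraction of counts in mito genes, in
#'   `[0, 1)`.
#' @param cluster_sigma sdlog of per-cluster log-normal perturbations of
#'   background/mito gene means (module genes carry no cluster effect, so
#'   planted correlations are cluster-clean).
#' @param modules list of [module_spec()]; gene sets must be disjoint.
#' @param seed integer master seed.
#' @param planted_mc_cells Monte-Carlo cells used to evaluate planted
#'   score-correlation targets.
#' @export
synthetic_config <- function(n_genes = 1000,
                             n_cells_per_cluster = c(Lc = 500),
                             conditions = "Nt",
                             baseline_mean = 0.5,
                             dispersion = 2,
                             libsize_sigma = 0.35,
                             mito_genes = 10,
                             mito_fraction = 0.05,
                             cluster_sigma = 0.25,
                             modules = list(),
                             seed = 1,
                             planted_mc_cells = 1e5) {
  stopifnot(n_genes >= 1, baseline_mean > 0, dispersion > 0,
            libsize_sigma >= 0, mito_genes >= 0,
            mito_fraction >= 0, mito_fraction < 1, cluster_sigma >= 0)
  if (is.null(names(n_cells_per_cluster)) ||
      any(!nzchar(names(n_cells_per_cluster)))) {
    stop("n_cells_per_cluster must be a named vector", call. = FALSE)
  }
  if (any(n_cells_per_cluster < 1)) {
    stop("every cluster needs at least one cell", call. = FALSE)
  }
  if (!length(conditions)) stop("at least one condition required", call. = FALSE)
  mod_names <- vapply(modules, `[[`, "", "name")
  if (anyDuplicated(mod_names)) stop("duplicate module names", call. = FALSE)
  n_mod_genes <- sum(vapply(modules, `[[`, 1L, "n_genes"))
  if (n_mod_genes + mito_genes > n_genes) {
    stop("module + mito genes exceed n_genes", call. = FALSE)
  }
  explicit <- unlist(lapply(modules, `[[`, "gene_names"))
  if (anyDuplicated(explicit)) {
    stop("overlapping module gene sets (shared gene names)", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_cells_per_cluster = n_cells_per_cluster,
                 conditions = conditions, baseline_mean = baseline_mean,
                 dispersion = dispersion, libsize_sigma = libsize_sigma,
                 mito_genes = as.integer(mito_genes),
                 mito_fraction = mito_fraction,
                 cluster_sigma = cluster_sigma, modules = modules,
                 seed = as.integer(seed),
                 planted_mc_cells = planted_mc_cells),
            class = "SyntheticConfig")
}

# Deterministic gene-level parameters: identities, base mean factors,
# module membership, per-cluster perturbations. Same derived RNG stream is
# used by generate_counts() and planted_correlation(), so planted targets
# reflect the realized gene factors.
.gene_params <- function(config) {
  with_seed(derive_seed(config$seed, "gene-params"), {
    n <- config$n_genes
    mods <- config$modules
    n_mod <- sum(vapply(mods, `[[`, 1L, "n_genes"))
    gene <- character(n)
    module <- rep(NA_character_, n)
    pos <- 1L
    for (m in mods) {
      idx <- pos:(pos + m$n_genes - 1L)
      gene[idx] <- m$gene_names %||% sprintf("%s.g%03d", m$name, seq_len(m$n_genes))
      module[idx] <- m$name
      pos <- pos + m$n_genes
    }
    if (config$mito_genes > 0) {
      idx <- pos:(pos + config$mito_genes - 1L)
      gene[idx] <- sprintf("mt-Sim%d", seq_len(config$mito_genes))
      pos <- pos + config$mito_genes
    }
    if (pos <= n) gene[pos:n] <- sprintf("bg%04d", seq_len(n - pos + 1L))
    mito <- is_mito_symbol(gene)

    gf <- stats::rlnorm(n, meanlog = 0, sdlog = 0.7)
    for (m in mods) gf[which(module == m$name)] <- gf[which(module == m$name)] * m$mean_scale
    base_mean <- config$baseline_mean * gf

    # calibrate mito means so the expected mito share equals mito_fraction
    if (config$mito_genes > 0 && config$mito_fraction > 0) {
      tot_nm <- sum(base_mean[!mito])
      target <- config$mito_fraction / (1 - config$mito_fraction) * tot_nm
      base_mean[mito] <- base_mean[mito] * target / sum(base_mean[mito])
    } else if (config$mito_genes > 0) {
      base_mean[mito] <- 0
    }

    clusters <- names(config$n_cells_per_cluster)
    cluster_fac <- matrix(1, n, length(clusters),
                          dimnames = list(NULL, clusters))
    if (config$cluster_sigma > 0 && length(clusters) > 0) {
      bg <- is.na(module)
      for (cl in clusters) {
        cluster_fac[bg, cl] <- stats::rlnorm(sum(bg), 0, config$cluster_sigma)
      }
    }
    list(gene = gene, module = module, mito = mito,
         base_mean = base_mean, cluster_fac = cluster_fac)
  })
}

# effective loading of a module in a condition
.eff_loading <- function(m, condition) {
  cl <- m$condition_loading
  if (!is.null(cl) && condition %in% names(cl)) cl[[condition]] else m$loading
}

.eff_shift <- function(m, condition) {
  cs <- m$condition_mean_shift
  if (!is.null(cs) && condition %in% names(cs)) cs[[condition]] else 1
}

#' Generate a synthetic count matrix with planted structure
#'
#' Counts are negative-binomial draws with mean
#' `baseline_mean x gene factor x cluster factor x cell library factor x
#' exp(loading x z - loading^2/2) x condition shift`. Identical
#' config + seed reproduces the matrix bit-for-bit.
#'
#' @param config a [synthetic_config()].
#' @param compute_planted if `TRUE`, evaluate the planted score-correlation
#'   targets for all co-loaded module pairs (Monte-Carlo; see
#'   [planted_correlation()]) and store them in the truth ledger.
#' @return list with `matrix` (a [count_matrix()]), `annotation`
#'   (a [cell_annotation()]) and `truth` (class `PlantedTruth`: per-cell
#'   latent values and library factors, per-gene module membership and
#'   expected means, planted pairwise correlation targets).
#' @export
generate_counts <- function(config, compute_planted = TRUE) {
  stopifnot(inherits(config, "SyntheticConfig"))
  gp <- .gene_params(config)
  mods <- config$modules
  factor_ids <- unique(vapply(mods, `[[`, "", "latent_factor_id"))
  clusters <- names(config$n_cells_per_cluster)

  cells_df <- do.call(rbind, lapply(clusters, function(cl) {
    do.call(rbind, lapply(config$conditions, function(cd) {
      n <- config$n_cells_per_cluster[[cl]]
      data.frame(barcode = sprintf("%s_%s_c%04d", cl, cd, seq_len(n)),
                 cluster = cl, condition = cd, stringsAsFactors = FALSE)
    }))
  }))
  n_cells <- nrow(cells_df)
  n_genes <- config$n_genes

  counts <- with_seed(derive_seed(config$seed, "counts"), {
    cells_df$lib_factor <- stats::rlnorm(n_cells, 0, config$libsize_sigma)
    z <- matrix(stats::rnorm(n_cells * length(factor_ids)),
                nrow = n_cells, dimnames = list(NULL, factor_ids))
    if (length(factor_ids)) {
      for (f in factor_ids) cells_df[[paste0("z_", f)]] <- z[, f]
    }
    mod_rows <- lapply(mods, function(m) which(gp$module == m$name))
    trip_i <- vector("list", n_cells); trip_x <- vector("list", n_cells)
    for (c in seq_len(n_cells)) {
      cl <- cells_df$cluster[c]; cd <- cells_df$condition[c]
      mu <- gp$base_mean * gp$cluster_fac[, cl] * cells_df$lib_factor[c]
      for (k in seq_along(mods)) {
        m <- mods[[k]]
        l <- .eff_loading(m, cd)
        fac <- exp(l * z[c, m$latent_factor_id] - l^2 / 2) * .eff_shift(m, cd)
        mu[mod_rows[[k]]] <- mu[mod_rows[[k]]] * fac
      }
      x <- stats::rnbinom(n_genes, mu = mu, size = config$dispersion)
      nz <- which(x > 0)
      trip_i[[c]] <- nz; trip_x[[c]] <- x[nz]
    }
    nper <- lengths(trip_i)
    Matrix::sparseMatrix(i = unlist(trip_i),
                         j = rep.int(seq_len(n_cells), nper),
                         x = unlist(trip_x), dims = c(n_genes, n_cells))
  })

  mat <- count_matrix(counts, gp$gene, cells_df$barcode)
  ann <- cell_annotation(cells_df$barcode, cells_df$cluster,
                         cells_df$condition)

  planted <- NULL
  if (compute_planted && length(mods) >= 2) {
    planted <- do.call(rbind, lapply(config$conditions, function(cd) {
      pm <- .planted_matrix(config, cd, gp)
      if (is.null(pm)) return(NULL)
      pairs <- which(upper.tri(pm), arr.ind = TRUE)
      data.frame(module_a = rownames(pm)[pairs[, 1]],
                 module_b = colnames(pm)[pairs[, 2]],
                 condition = cd, rho = pm[pairs],
                 stringsAsFactors = FALSE)
    }))
  }

  # expected mean per gene per cluster x condition (library factor 1,
  # latent marginalized out) -- the oracle for moment tests
  mean_cols <- list()
  for (cl in clusters) for (cd in config$conditions) {
    mu <- gp$base_mean * gp$cluster_fac[, cl]
    for (k in seq_along(mods)) {
      rows <- which(gp$module == mods[[k]]$name)
      mu[rows] <- mu[rows] * .eff_shift(mods[[k]], cd)
    }
    mean_cols[[paste(cl, cd, sep = "|")]] <- mu
  }

  truth <- structure(list(
    cells = cells_df,
    genes = data.frame(gene = gp$gene, module = gp$module, mito = gp$mito,
                       base_mean = gp$base_mean, stringsAsFactors = FALSE),
    expected_means = as.data.frame(mean_cols, check.names = FALSE),
    planted = planted,
    config = config), class = "PlantedTruth")

  list(matrix = mat, annotation = ann, truth = truth)
}

# Monte-Carlo planted score-correlation matrix for one condition.
# Each module's count total is drawn as a single NB moment-matched to the
# sum of its genes' independent NB counts; the background (incl. mito) is
# moment-matched the same way. Pairs with no shared latent factor are 0 by
# construction.
.planted_matrix <- function(config, condition, gp = .gene_params(config),
                            n_mc = config$planted_mc_cells) {
  mods <- config$modules
  if (length(mods) < 2) return(NULL)
  nm <- vapply(mods, `[[`, "", "name")
  with_seed(derive_seed(config$seed, paste0("planted-", condition)), {
    size <- config$dispersion
    bg <- is.na(gp$module)
    Bmu <- sum(gp$base_mean[bg]); Bmu2 <- sum(gp$base_mean[bg]^2)
    lib <- stats::rlnorm(n_mc, 0, config$libsize_sigma)
    factor_ids <- unique(vapply(mods, `[[`, "", "latent_factor_id"))
    z <- matrix(stats::rnorm(n_mc * length(factor_ids)), nrow = n_mc,
                dimnames = list(NULL, factor_ids))
    S <- matrix(0, n_mc, length(mods), dimnames = list(NULL, nm))
    for (k in seq_along(mods)) {
      m <- mods[[k]]
      mu_g <- gp$base_mean[which(gp$module == m$name)] * .eff_shift(m, condition)
      l <- .eff_loading(m, condition)
      fac <- exp(l * z[, m$latent_factor_id] - l^2 / 2)
      M <- lib * fac * sum(mu_g)
      size_eff <- size * sum(mu_g)^2 / sum(mu_g^2)
      S[, k] <- stats::rnbinom(n_mc, mu = M, size = size_eff)
    }
    Bsize <- size * Bmu^2 / Bmu2
    B <- stats::rnbinom(n_mc, mu = lib * Bmu, size = Bsize)
    tot <- rowSums(S) + B
    keep <- tot > 0
    scores <- 100 * S[keep, , drop = FALSE] / tot[keep]
    pm <- stats::cor(scores)
    # exact zero when no factor is shared or either loading is zero
    for (a in seq_along(mods)) for (b in seq_along(mods)) {
      if (a == b) next
      la <- .eff_loading(mods[[a]], condition)
      lb <- .eff_loading(mods[[b]], condition)
      shared <- mods[[a]]$latent_factor_id == mods[[b]]$latent_factor_id
      if (!shared || la == 0 || lb == 0) pm[a, b] <- 0
    }
    pm
  })
}

#' Planted score-correlation target for a module pair
#'
#' The generator's analytic target is defined operationally: the large-n
#' Monte-Carlo limit of the Pearson correlation between the two modules'
#' percentage scores under the generative model (no closed form is claimed
#' for the correlation of compositional NB sums). Exactly 0 when the
#' modules share no latent factor or either effective loading is 0;
#' deterministic for a given config.
#'
#' @param config a [synthetic_config()].
#' @param module_a,module_b module names.
#' @param condition condition name.
#' @return the target Pearson correlation.
#' @export
planted_correlation <- function(config, module_a, module_b,
                                condition = config$conditions[1]) {
  nm <- vapply(config$modules, `[[`, "", "name")
  for (x in c(module_a, module_b)) {
    if (!x %in% nm) stop(sprintf("unknown module '%s'", x), call. = FALSE)
  }
  if (!condition %in% config$conditions) {
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  }
  ma <- config$modules[[match(module_a, nm)]]
  mb <- config$modules[[match(module_b, nm)]]
  la <- .eff_loading(ma, condition); lb <- .eff_loading(mb, condition)
  if (ma$latent_factor_id != mb$latent_factor_id || la == 0 || lb == 0) {
    return(0)
  }
  pm <- .planted_matrix(config, condition)
  pm[module_a, module_b]
}

#' Write a synthetic dataset to disk
#'
#' Emits the MTX triplet, the annotation TSV and the planted-truth ledger
#' as JSON.
#' @param sim result of [generate_counts()].
#' @param dir output directory.
#' @export
write_synthetic <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_mtx(sim$matrix, dir)
  write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(cells = truth$cells, genes = truth$genes,
         planted = truth$planted %||% list()),
    file.path(dir, "planted_truth.json"),
    dataframe = "columns", digits = NA)
  invisible(dir)
}
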