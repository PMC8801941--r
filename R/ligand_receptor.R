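#' Permutation test for ligand-receptor co-expression between clusters
#'
#' For each (ligand, receptor) pair the observed score is the unweighted
#' mean of \[mean ligand expression in the sender cluster, mean receptor
#' expression in the receiver cluster\] on normalized values. The null is
#' built by shuffling cluster labels across all cells `n_perm` times and
#' recomputing; `p = (1 + #\{null >= observed\}) / (1 + n_perm)` (add-one
#' rule, so `p >= 1/(n_perm+1)`). Same-cluster sender/receiver is allowed.
#' Pairs where either gene is detected in < `min_expr_frac` of its
#' cluster's cells are scored but flagged `non_expressed`. Shuffles are
#' shared across pairs within one call (the convention of the tool this
#' reimplements); seeded, hence deterministic.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param annotation a [cell_annotation()]; needs >= 2 distinct clusters.
#' @param pairs data frame (or 2-column matrix) with columns
#'   `ligand`, `receptor`.
#' @param sender,receiver cluster labels.
#' @param n_perm number of permutations (>= 1).
#' @param alpha significance level for the `significant` flag.
#' @param seed integer seed for the shuffles.
#' @param min_expr_frac expression floor (fraction of nonzero cells).
#' @param condition optional condition restriction.
#' @return data frame `ligand`, `receptor`, `sender`, `receiver`, `score`,
#'   `p_perm`, `significant`, `non_expressed`; unknown genes are skipped
#'   with a warning.
#' @export
lr_test <- function(normalized, annotation, pairs, sender, receiver,
                    n_perm = 1000, alpha = 0.05, seed = 1,
                    min_expr_frac = 0.1, condition = NULL) {
  stopifnot(inherits(normalized, "NormalizedMatrix"))
  if (n_perm < 1) stop("n_perm must be >= 1 (add-one rule undefined at 0)",
                       call. = FALSE)
  validate_annotation(normalized, annotation)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(pairs))) {
    names(pairs)[1:2] <- c("ligand", "receptor")
  }
  idx <- match(normalized$cells, annotation$barcode)
  labels <- annotation$cluster[idx]
  keep <- rep(TRUE, length(labels))
  if (!is.null(condition)) keep <- annotation$condition[idx] == condition
  labels <- labels[keep]
  nm <- subset_norm_cells(normalized, which(keep))
  if (length(unique(labels)) < 2) {
    stop("need >= 2 clusters to permute labels meaningfully", call. = FALSE)
  }
  for (cl in c(sender, receiver)) {
    if (!cl %in% labels) stop(sprintf("cluster '%s' absent", cl), call. = FALSE)
  }

  known <- pairs$ligand %in% nm$genes & pairs$receptor %in% nm$genes
  if (any(!known)) {
    warning(sprintf("%d pair(s) with unknown gene(s) skipped", sum(!known)),
            call. = FALSE)
    pairs <- pairs[known, , drop = FALSE]
  }
  if (!nrow(pairs)) {
    return(data.frame(ligand = character(), receptor = character(),
                      sender = character(), receiver = character(),
                      score = numeric(), p_perm = numeric(),
                      significant = logical(), non_expressed = logical()))
  }

  genes <- unique(c(pairs$ligand, pairs$receptor))
  expr <- as.matrix(nm$values[match(genes, nm$genes), , drop = FALSE])
  rownames(expr) <- genes
  s_cells <- labels == sender; r_cells <- labels == receiver
  mean_s <- rowMeans(expr[, s_cells, drop = FALSE])
  mean_r <- rowMeans(expr[, r_cells, drop = FALSE])
  frac_s <- rowMeans(expr[, s_cells, drop = FALSE] > 0)
  frac_r <- rowMeans(expr[, r_cells, drop = FALSE] > 0)
  obs <- (mean_s[pairs$ligand] + mean_r[pairs$receptor]) / 2

  ns <- sum(s_cells); nr <- sum(r_cells); n <- length(labels)
  exceed <- integer(nrow(pairs))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      ps <- perm[seq_len(ns)]
      # same cluster twice reuses the same permuted cell set, as a true
      # label shuffle would; distinct clusters get disjoint label blocks
      pr <- if (sender == receiver) ps else perm[(ns + 1):(ns + nr)]
      ms <- rowMeans(expr[, ps, drop = FALSE])
      mr <- rowMeans(expr[, pr, drop = FALSE])
      null_score <- (ms[pairs$ligand] + mr[pairs$receptor]) / 2
      exceed <- exceed + (null_score >= obs - 1e-12)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  data.frame(ligand = pairs$ligand, receptor = pairs$receptor,
             sender = sender, receiver = receiver,
             score = as.numeric(obs), p_perm = p,
             significant = p <= alpha,
             non_expressed = frac_s[pairs$ligand] < min_expr_frac |
               frac_r[pairs$receptor] < min_expr_frac,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Count significant pairs per ordered cluster pair
#'
#' Ordered pairs are distinct: sender -> receiver counts separately from
#' receiver -> sender.
#' @param results one or more [lr_test()] outputs (a data frame or list of
#'   them, possibly covering several sender/receiver combinations).
#' @param alpha significance level applied to `p_perm`.
#' @param include_non_expressed count pairs flagged `non_expressed`?
#' @return data frame `sender`, `receiver`, `n_significant`.
#' @export
pair_counts <- function(results, alpha = 0.05, include_non_expressed = FALSE) {
  if (is.data.frame(results)) results <- list(results)
  all <- do.call(rbind, results)
  if (!is.null(all) && nrow(all) && !include_non_expressed) {
    all <- all[!all$non_expressed, , drop = FALSE]
  }
  if (is.null(all) || !nrow(all)) {
    return(data.frame(sender = character(), receiver = character(),
                      n_significant = integer()))
  }
  sig <- all$p_perm <= alpha
  agg <- stats::aggregate(sig, by = list(sender = all$sender,
                                         receiver = all$receiver), FUN = sum)
  names(agg)[3] <- "n_significant"
  agg[order(agg$sender, agg$receiver), , drop = FALSE]
}
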