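# Two-sided Wilcoxon rank-sum p-value for group A (x) vs group B (y).
# Exact enumeration of all label assignments when both groups are small;
# otherwise the normal approximation with tie correction and continuity
# correction (the convention of the standard single-cell DE tool).
.wilcox_p <- function(x, y, exact_max = 8, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  na <- length(x); nb <- length(y)
  v <- c(x, y)
  rk <- rank(v)
  W <- sum(rk[seq_len(na)])
  use_exact <- switch(exact,
                      auto = na <= exact_max && nb <= exact_max,
                      never = FALSE, always = TRUE)
  if (use_exact) {
    # permutation null over all C(na+nb, na) label assignments
    combs <- utils::combn(na + nb, na)
    Wp <- colSums(matrix(rk[combs], nrow = na))
    mu <- mean(Wp)
    p <- mean(abs(Wp - mu) >= abs(W - mu) - 1e-12)
    return(min(1, p))
  }
  n <- na + nb
  mu <- na * (n + 1) / 2
  ties <- table(v)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  d <- W - mu
  d <- d - sign(d) * 0.5  # continuity correction
  z <- d / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum differential expression between two conditions
#'
#' For one cluster, tests every gene between condition A and condition B on
#' normalized expression. Genes are prefiltered on detection
#' (`max(pct_a, pct_b) >= min_pct`) and effect size
#' (`|log_fc| >= logfc_threshold`, with
#' `log_fc = ln(mean(expm1(norm_a)) + 1) - ln(mean(expm1(norm_b)) + 1)`,
#' natural log), then tested two-sided; survivors additionally satisfy
#' `p <= p_cutoff`. Prefiltering never alters a surviving gene's p-value.
#' No multiple-testing correction is applied to the reported filter —
#' `p_adj` (BH) is emitted for transparency only, matching the raw-p
#' filtering convention this mirrors; treat the output accordingly.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param annotation a [cell_annotation()].
#' @param cluster cluster to test within (`NULL` = all cells).
#' @param condition_a,condition_b the two condition labels; log_fc > 0
#'   means higher in `condition_a`.
#' @param logfc_threshold minimum |log fold change| (natural log).
#' @param min_pct minimum detection fraction in the better-detected group.
#' @param p_cutoff raw p-value filter.
#' @param return_all if `TRUE`, return every prefilter-passing gene with a
#'   `significant` flag instead of only survivors.
#' @param exact `"auto"` (exact enumeration when both groups <= 8 cells),
#'   `"never"`, or `"always"`.
#' @return data frame `gene`, `log_fc`, `pct_a`, `pct_b`, `p`, `p_adj`,
#'   `direction` (`up` = higher in A), sorted by p.
#' @export
wilcoxon_de <- function(normalized, annotation, cluster = NULL,
                        condition_a, condition_b,
                        logfc_threshold = 0.25, min_pct = 0.2,
                        p_cutoff = 0.05, return_all = FALSE,
                        exact = "auto") {
  stopifnot(inherits(normalized, "NormalizedMatrix"))
  validate_annotation(normalized, annotation)
  idx <- match(normalized$cells, annotation$barcode)
  in_cluster <- if (is.null(cluster)) rep(TRUE, length(idx)) else
    annotation$cluster[idx] == cluster
  ca <- in_cluster & annotation$condition[idx] == condition_a
  cb <- in_cluster & annotation$condition[idx] == condition_b
  if (sum(ca) < 3) stop(sprintf("group '%s' has %d cell(s); need >= 3",
                                condition_a, sum(ca)), call. = FALSE)
  if (sum(cb) < 3) stop(sprintf("group '%s' has %d cell(s); need >= 3",
                                condition_b, sum(cb)), call. = FALSE)
  A <- as.matrix(normalized$values[, ca, drop = FALSE])
  B <- as.matrix(normalized$values[, cb, drop = FALSE])
  pct_a <- rowMeans(A > 0); pct_b <- rowMeans(B > 0)
  log_fc <- log(rowMeans(expm1(A)) + 1) - log(rowMeans(expm1(B)) + 1)
  pre <- pmax(pct_a, pct_b) >= min_pct & abs(log_fc) >= logfc_threshold
  genes <- normalized$genes[pre]
  if (!length(genes)) {
    out <- data.frame(gene = character(), log_fc = numeric(), pct_a = numeric(),
                      pct_b = numeric(), p = numeric(), p_adj = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
    if (return_all) out$significant <- logical()
    return(out)
  }
  Ai <- A[pre, , drop = FALSE]; Bi <- B[pre, , drop = FALSE]
  p <- vapply(seq_along(genes), function(g) {
    .wilcox_p(Ai[g, ], Bi[g, ], exact = exact)
  }, 0)
  out <- data.frame(gene = genes, log_fc = log_fc[pre],
                    pct_a = pct_a[pre], pct_b = pct_b[pre], p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    direction = ifelse(log_fc[pre] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  if (return_all) {
    out$significant <- out$p <= p_cutoff
    out
  } else {
    out[out$p <= p_cutoff, , drop = FALSE]
  }
}

#' Count up/down DE genes per cluster
#'
#' @param results named list: cluster -> [wilcoxon_de()] output.
#' @return data frame `cluster`, `n_up`, `n_down`.
#' @export
deg_counts <- function(results) {
  do.call(rbind, lapply(names(results), function(cl) {
    r <- results[[cl]]
    if (!is.null(r$significant)) r <- r[r$significant, , drop = FALSE]
    data.frame(cluster = cl,
               n_up = sum(r$direction == "up"),
               n_down = sum(r$direction == "down"),
               stringsAsFactors = FALSE)
  }))
}
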