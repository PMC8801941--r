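#' Competitive gene-set test with inter-gene correlation adjustment
#'
#' Asks whether the genes of a set carry larger differential statistics
#' than the genes outside it, adjusting the variance of the set mean for
#' inter-gene correlation via the variance inflation factor
#' `VIF = 1 + (m - 1) * rho_bar`, where `rho_bar` is the mean pairwise
#' Pearson correlation of the set genes' normalized expression across the
#' tested cells (clipped at 0 so the VIF never deflates). The statistic is
#' \deqn{z = (mean_{in} - mean_{out}) / \sqrt{VIF \sigma^2_{pooled}
#'   (1/m + 1/(N - m))}}
#' with a two-sided normal p-value. This is a declared simplification of
#' the full CAMERA machinery: the competitive null, the VIF adjustment and
#' the two-sided normal test are kept; moderated-statistic estimation is
#' not.
#'
#' @param stats named numeric vector: gene -> standardized per-gene
#'   differential statistic (all tested genes, finite).
#' @param set a [signature_definition()] (>= 2 genes must be among the
#'   tested genes).
#' @param normalized optional `NormalizedMatrix` used to estimate
#'   `rho_bar` from the set genes across `cells`.
#' @param cells optional barcodes/indices restricting the rho estimation.
#' @param rho_bar directly supplied inter-gene correlation (overrides
#'   estimation; use 0 for an unadjusted-equivalent test on independent
#'   genes).
#' @return one-row data frame: `set`, `n_genes_in_set`, `mean_stat_in_set`,
#'   `rho_bar`, `vif`, `z_adjusted`, `p_two_sided`, `direction`,
#'   `degenerate`.
#' @export
competitive_test <- function(stats, set, normalized = NULL, cells = NULL,
                             rho_bar = NULL) {
  if (is.null(names(stats))) stop("stats must be a named vector", call. = FALSE)
  if (any(!is.finite(stats))) stop("stats must be finite", call. = FALSE)
  in_set <- names(stats) %in% set$genes
  m <- sum(in_set); N <- length(stats)
  if (m < 2) stop(sprintf("set '%s': %d gene(s) among tested genes; need >= 2",
                          set$name, m), call. = FALSE)
  if (m >= N) stop("set covers the whole tested universe", call. = FALSE)

  if (is.null(rho_bar)) {
    if (is.null(normalized)) {
      stop("supply either rho_bar or a normalized matrix for its estimation",
           call. = FALSE)
    }
    nm <- if (is.null(cells)) normalized else subset_norm_cells(normalized, cells)
    rows <- match(intersect(set$genes, nm$genes), nm$genes)
    expr <- t(as.matrix(nm$values[rows, , drop = FALSE]))
    expr <- expr[, apply(expr, 2, stats::sd) > 0, drop = FALSE]
    if (ncol(expr) < 2) {
      warning("fewer than 2 variable set genes; rho_bar set to 0", call. = FALSE)
      rho_bar <- 0
    } else {
      cm <- stats::cor(expr)
      rho_bar <- mean(cm[upper.tri(cm)])
    }
  }
  clipped <- rho_bar < 0
  if (clipped) {
    message(sprintf("set '%s': rho_bar %.3f clipped to 0", set$name, rho_bar))
    rho_bar <- 0
  }
  vif <- 1 + (m - 1) * rho_bar

  mean_in <- mean(stats[in_set]); mean_out <- mean(stats[!in_set])
  s2 <- ((m - 1) * stats::var(stats[in_set]) +
           (N - m - 1) * stats::var(stats[!in_set])) / (N - 2)
  if (s2 <= 0) {
    warning("all statistics identical; degenerate result", call. = FALSE)
    return(data.frame(set = set$name, n_genes_in_set = m,
                      mean_stat_in_set = mean_in, rho_bar = rho_bar, vif = vif,
                      z_adjusted = NA_real_, p_two_sided = NA_real_,
                      direction = NA_character_, degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  z <- (mean_in - mean_out) / sqrt(vif * s2 * (1 / m + 1 / (N - m)))
  p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  data.frame(set = set$name, n_genes_in_set = m, mean_stat_in_set = mean_in,
             rho_bar = rho_bar, vif = vif, z_adjusted = z, p_two_sided = p,
             direction = if (z > 0) "up" else "down", degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Run the competitive test over a collection of sets
#' @param stats named statistic vector (see [competitive_test()]).
#' @param sets list of [signature_definition()].
#' @param ... passed to [competitive_test()].
#' @return data frame, one row per set, sorted by p.
#' @export
enrichment_table <- function(stats, sets, ...) {
  out <- do.call(rbind, lapply(sets, function(s) competitive_test(stats, s, ...)))
  out <- out[order(out$p_two_sided, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene z statistics from a DE table
#'
#' Converts two-sided Wilcoxon p-values and directions into signed normal
#' quantiles — the default pluggable statistic source for
#' [competitive_test()].
#' @param de_table [wilcoxon_de()] output with `return_all = TRUE`.
#' @export
de_stats <- function(de_table) {
  p <- pmax(de_table$p, 1e-15)
  z <- stats::qnorm(p / 2, lower.tail = FALSE) *
    ifelse(de_table$direction == "up", 1, -1)
  stats::setNames(z, de_table$gene)
}
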