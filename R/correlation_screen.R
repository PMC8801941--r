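#' Pearson correlation with t-transform p-value
#'
#' Sample Pearson r with a two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Zero variance in either vector is an explicit degenerate result
#' (`r = NA`, flagged), never a silent 0.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list `r`, `p`, `n`, `degenerate`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop(sprintf("insufficient cells for correlation (n = %d < 3)", n),
                  call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n, degenerate = FALSE)
}

#' Screen configuration
#'
#' Houses the per-figure correlation cutoffs (e.g. `r_min_pos = 0.6`,
#' `r_max_neg = -0.45`), the top-k for TF ranking, and the TF filters:
#' mean normalized expression >= `min_tf_mean_expr` (default 0.5) and a
#' default exclusion list of Hmgb4, Spz1 and Tfam (delayed-transcription
#' background in elongating spermatids).
#'
#' @param r_min_pos positive lower bound for reported positive r, or `NULL`.
#' @param r_max_neg negative upper bound for reported negative r, or `NULL`.
#' @param top_k entries per direction in TF rankings.
#' @param min_cells minimum cells per correlation (hard floor 3; below 10 a
#'   low-n warning is attached to records).
#' @param min_tf_mean_expr mean normalized expression floor for TFs.
#' @param tf_exclusions genes never reported as TFs.
#' @export
screen_config <- function(r_min_pos = NULL, r_max_neg = NULL, top_k = 20,
                          min_cells = 10, min_tf_mean_expr = 0.5,
                          tf_exclusions = c("Hmgb4", "Spz1", "Tfam")) {
  if (!is.null(r_min_pos) && r_min_pos <= 0) {
    stop("r_min_pos must be > 0 when set", call. = FALSE)
  }
  if (!is.null(r_max_neg) && r_max_neg >= 0) {
    stop("r_max_neg must be < 0 when set", call. = FALSE)
  }
  stopifnot(top_k >= 1, min_cells >= 3)
  structure(list(r_min_pos = r_min_pos, r_max_neg = r_max_neg,
                 top_k = as.integer(top_k), min_cells = as.integer(min_cells),
                 min_tf_mean_expr = min_tf_mean_expr,
                 tf_exclusions = tf_exclusions),
            class = "ScreenConfig")
}

.subset_score_rows <- function(scores, cluster, condition) {
  keep <- rep(TRUE, nrow(scores))
  if (!is.null(cluster)) {
    if (is.null(scores$cluster)) stop("score table has no cluster column", call. = FALSE)
    keep <- keep & scores$cluster == cluster
  }
  if (!is.null(condition)) {
    if (is.null(scores$condition)) stop("score table has no condition column", call. = FALSE)
    keep <- keep & scores$condition == condition
  }
  scores[keep, , drop = FALSE]
}

#' Threshold-ranked correlation screen
#'
#' Correlates a target signature's per-cell score against every candidate
#' within one cluster x condition slice, keeps candidates with
#' `r >= r_min_pos` or `r <= r_max_neg` (whichever bounds are set; both
#' unset keeps everything), and ranks by r descending with lexicographic
#' tie-break. The target is excluded from its own candidate list with a
#' warning. p-values (and a Benjamini-Hochberg column, for transparency
#' only) are reported but never used for filtering.
#'
#' @param scores a [score_table()].
#' @param target target signature column name.
#' @param candidates candidate column names (default: all other
#'   signatures).
#' @param cluster,condition slice selectors (`NULL` = all rows).
#' @param config a [screen_config()].
#' @return data frame of correlation records: `target`, `candidate`,
#'   `cluster`, `condition`, `r`, `p`, `p_adj`, `n_cells`, `low_n`,
#'   `degenerate`.
#' @export
correlation_screen <- function(scores, target, candidates = NULL,
                               cluster = NULL, condition = NULL,
                               config = screen_config()) {
  sig_cols <- score_columns(scores)
  if (!target %in% sig_cols) stop(sprintf("target '%s' not in score table", target),
                                  call. = FALSE)
  candidates <- candidates %||% setdiff(sig_cols, target)
  if (target %in% candidates) {
    warning("target removed from candidate list (self-correlation excluded)",
            call. = FALSE)
    candidates <- setdiff(candidates, target)
  }
  missing <- setdiff(candidates, sig_cols)
  if (length(missing)) stop(sprintf("candidate(s) not in score table: %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  sub <- .subset_score_rows(scores, cluster, condition)
  n <- nrow(sub)
  if (n < config$min_cells) {
    stop(sprintf("insufficient cells in slice (%d < min_cells %d)",
                 n, config$min_cells), call. = FALSE)
  }
  recs <- lapply(candidates, function(cand) {
    pc <- pearson_cor(sub[[target]], sub[[cand]])
    data.frame(target = target, candidate = cand,
               cluster = cluster %||% "all", condition = condition %||% "all",
               r = pc$r, p = pc$p, n_cells = pc$n,
               low_n = pc$n < 10, degenerate = pc$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  if (is.null(config$r_min_pos) && is.null(config$r_max_neg)) {
    pass <- rep(TRUE, nrow(out))  # unbounded screen keeps all (degenerate stay flagged)
  } else {
    ok <- !out$degenerate
    pass <- rep(FALSE, nrow(out))
    if (!is.null(config$r_min_pos)) pass <- pass | (ok & out$r >= config$r_min_pos)
    if (!is.null(config$r_max_neg)) pass <- pass | (ok & out$r <= config$r_max_neg)
  }
  out <- out[pass, , drop = FALSE]
  out <- out[order(-out$r, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("target", "candidate", "cluster", "condition", "r", "p", "p_adj",
          "n_cells", "low_n", "degenerate")]
}

#' Top-k transcription-factor correlation ranking for a target gene
#'
#' Gene-gene correlations are computed on normalized expression within the
#' cluster x condition slice. TFs are filtered to mean normalized
#' expression >= `config$min_tf_mean_expr` in that slice, must not be in
#' `config$tf_exclusions`, and never include the target itself. The top
#' `top_k` by r descending form the positive list; the top `top_k` by r
#' ascending the negative list (only r > 0 / r < 0 respectively qualify).
#' Fewer than `top_k` survivors is a warning, not an error.
#'
#' @param normalized a `NormalizedMatrix`.
#' @param annotation a [cell_annotation()].
#' @param target_gene gene whose regulators are sought.
#' @param tf_universe character vector of TF gene symbols.
#' @param cluster,condition slice selectors.
#' @param config a [screen_config()].
#' @return list of two data frames `positive` and `negative` with columns
#'   `target`, `tf`, `r`, `p`, `mean_expr`, `direction`, `rank`.
#' @export
tf_screen <- function(normalized, annotation, target_gene, tf_universe,
                      cluster = NULL, condition = NULL,
                      config = screen_config()) {
  stopifnot(inherits(normalized, "NormalizedMatrix"))
  validate_annotation(normalized, annotation)
  keep <- rep(TRUE, length(normalized$cells))
  idx <- match(normalized$cells, annotation$barcode)
  if (!is.null(cluster)) keep <- keep & annotation$cluster[idx] == cluster
  if (!is.null(condition)) keep <- keep & annotation$condition[idx] == condition
  if (sum(keep) < config$min_cells) {
    stop(sprintf("insufficient cells in slice (%d < min_cells %d)",
                 sum(keep), config$min_cells), call. = FALSE)
  }
  sub <- subset_norm_cells(normalized, which(keep))
  if (!target_gene %in% sub$genes) {
    stop(sprintf("target gene '%s' not in matrix", target_gene), call. = FALSE)
  }
  y <- as.numeric(sub$values[match(target_gene, sub$genes), ])
  if (stats::sd(y) == 0) {
    stop(sprintf("target gene '%s' has zero variance in this slice", target_gene),
         call. = FALSE)
  }
  tfs <- setdiff(intersect(tf_universe, sub$genes),
                 c(config$tf_exclusions, target_gene))
  if (!length(tfs)) stop("no eligible TFs in matrix", call. = FALSE)
  expr <- as.matrix(sub$values[match(tfs, sub$genes), , drop = FALSE])
  mean_expr <- rowMeans(expr)
  eligible <- mean_expr >= config$min_tf_mean_expr
  tfs <- tfs[eligible]; expr <- expr[eligible, , drop = FALSE]
  mean_expr <- mean_expr[eligible]
  if (!length(tfs)) {
    warning("no TF passes the mean-expression filter", call. = FALSE)
    empty <- data.frame(target = character(), tf = character(), r = numeric(),
                        p = numeric(), mean_expr = numeric(),
                        direction = character(), rank = integer())
    return(list(positive = empty, negative = empty))
  }
  res <- lapply(seq_along(tfs), function(i) pearson_cor(expr[i, ], y))
  tab <- data.frame(target = target_gene, tf = tfs,
                    r = vapply(res, `[[`, 0, "r"),
                    p = vapply(res, `[[`, 0, "p"),
                    mean_expr = mean_expr,
                    stringsAsFactors = FALSE)
  tab <- tab[!is.na(tab$r), , drop = FALSE]
  rank_side <- function(t, dir) {
    t <- if (dir == "positive") t[t$r > 0, , drop = FALSE] else t[t$r < 0, , drop = FALSE]
    o <- if (dir == "positive") order(-t$r, t$tf) else order(t$r, t$tf)
    t <- t[o, , drop = FALSE]
    if (nrow(t) < config$top_k) {
      warning(sprintf("%s list: only %d TF(s) available (top_k = %d)",
                      dir, nrow(t), config$top_k), call. = FALSE)
    }
    t <- utils::head(t, config$top_k)
    if (nrow(t)) { t$direction <- dir; t$rank <- seq_len(nrow(t)) }
    rownames(t) <- NULL
    t
  }
  list(positive = rank_side(tab, "positive"),
       negative = rank_side(tab, "negative"))
}

#' Cross-condition correlation shift
#'
#' Joins two screen outputs on (target, candidate), reports
#' `delta_r = r_B - r_A`, and flags a sign flip when `r_A * r_B < 0` and
#' both magnitudes exceed a reportable floor (default 0.1). Pairs missing
#' in either condition are skipped with a warning.
#'
#' @param records_a,records_b outputs of [correlation_screen()] run with
#'   bounds open (or any record tables with `target`, `candidate`, `r`).
#' @param floor minimum |r| on both sides for a reportable flip.
#' @return data frame `target`, `candidate`, `r_a`, `r_b`, `delta_r`,
#'   `sign_flip`.
#' @export
correlation_shift <- function(records_a, records_b, floor = 0.1) {
  key_a <- paste(records_a$target, records_a$candidate, sep = "\r")
  key_b <- paste(records_b$target, records_b$candidate, sep = "\r")
  common <- intersect(key_a, key_b)
  dropped <- length(union(key_a, key_b)) - length(common)
  if (dropped > 0) {
    warning(sprintf("%d pair(s) present in only one condition, skipped", dropped),
            call. = FALSE)
  }
  if (!length(common)) {
    return(data.frame(target = character(), candidate = character(),
                      r_a = numeric(), r_b = numeric(), delta_r = numeric(),
                      sign_flip = logical()))
  }
  ia <- match(common, key_a); ib <- match(common, key_b)
  r_a <- records_a$r[ia]; r_b <- records_b$r[ib]
  data.frame(target = records_a$target[ia],
             candidate = records_a$candidate[ia],
             r_a = r_a, r_b = r_b, delta_r = r_b - r_a,
             sign_flip = (r_a * r_b < 0) & (abs(r_a) > floor) & (abs(r_b) > floor),
             stringsAsFactors = FALSE)
}
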