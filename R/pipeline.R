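#' Validate a pipeline run configuration
#'
#' The run config is a JSON file (or equivalent list) with a global
#' `seed`, an `out_dir`, and one block per stage under `stages`. Every
#' block is validated against its module's parameter contract *before* any
#' stage runs, by constructing the corresponding config objects.
#'
#' @param config list (parsed JSON) or path to a JSON file.
#' @return normalized config list, invisibly classed `RunConfig`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  if (is.null(config$seed)) stop("run config needs a global seed", call. = FALSE)
  if (is.null(config$out_dir)) stop("run config needs out_dir", call. = FALSE)
  st <- config$stages %||% list()

  if (!is.null(st$simulate)) {
    s <- st$simulate
    mods <- lapply(s$modules %||% list(), function(m) do.call(module_spec, m))
    config$.sim_config <- synthetic_config(
      n_genes = s$n_genes %||% 1000,
      n_cells_per_cluster = unlist(s$n_cells_per_cluster %||% c(Lc = 500)),
      conditions = s$conditions %||% "Nt",
      baseline_mean = s$baseline_mean %||% 0.5,
      dispersion = s$dispersion %||% 2,
      libsize_sigma = s$libsize_sigma %||% 0.35,
      mito_genes = s$mito_genes %||% 10,
      mito_fraction = s$mito_fraction %||% 0.05,
      cluster_sigma = s$cluster_sigma %||% 0.25,
      modules = mods,
      seed = derive_seed(config$seed, "simulate"))
  }
  q <- st$qc %||% list()
  config$.qc_thresholds <- qc_thresholds(
    min_features = q$min_features %||% 200,
    max_features = q$max_features %||% 7000,
    max_percent_mt = q$max_percent_mt %||% 20,
    min_cells_per_gene = q$min_cells_per_gene %||% 3)
  for (blk_name in intersect(names(st), c("screen", "shift"))) {
    blk <- st[[blk_name]]
    sc <- screen_config(r_min_pos = blk$r_min_pos, r_max_neg = blk$r_max_neg,
                        top_k = blk$top_k %||% 20,
                        min_cells = blk$min_cells %||% 10)
    config[[paste0(".", blk_name, "_config")]] <- sc
  }
  structure(config, class = c("RunConfig", "list"))
}

.file_checksums <- function(dir) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  sums <- tools::md5sum(files)
  names(sums) <- list.files(dir, recursive = TRUE)
  as.list(sums)
}

#' Run the full pipeline from one configuration
#'
#' Executes the configured stages in dependency order
#' (simulate -> qc -> score -> screen -> shift -> de), writing each
#' stage's TSV outputs under `out_dir` and a JSON run manifest recording
#' parameters, derived seeds, output checksums and per-stage row counts.
#' Reruns with an identical config reproduce identical outputs.
#'
#' @param config list or JSON path (see [validate_run_config()]).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  st <- cfg$stages %||% list()
  manifest <- list(seed = cfg$seed, stages = list())
  mark <- function(name, params, rows) {
    manifest$stages[[name]] <<- list(params = params, rows = rows)
    sigcorr_log("stage %s done (%d rows)", name, rows)
  }

  # -- simulate ---------------------------------------------------------
  if (!is.null(cfg$.sim_config)) {
    sim <- generate_counts(cfg$.sim_config)
    sim_dir <- file.path(out_dir, "sim")
    write_synthetic(sim, sim_dir)
    mat <- sim$matrix; ann <- sim$annotation
    mark("simulate", list(seed = cfg$.sim_config$seed,
                          n_genes = cfg$.sim_config$n_genes),
         length(mat$cells))
  } else {
    in_dir <- st$input$dir %||% stop("no simulate stage and no input dir",
                                     call. = FALSE)
    mat <- read_mtx(in_dir)
    ann <- read_annotation(file.path(in_dir, "annotation.tsv"))
    mark("input", list(dir = in_dir), length(mat$cells))
  }

  # -- qc ---------------------------------------------------------------
  qc <- run_qc(mat, cfg$.qc_thresholds)
  mat <- qc$matrix
  ann <- ann[ann$barcode %in% mat$cells, , drop = FALSE]
  write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
  mark("qc", unclass(cfg$.qc_thresholds), nrow(qc$report))
  norm <- normalize_counts(mat)

  # -- score ------------------------------------------------------------
  scores <- NULL
  if (!is.null(st$score)) {
    sigs <- read_signatures(st$score$signatures)
    scores <- score_table(mat, sigs, ann)
    write_tsv(scores, file.path(out_dir, "scores.tsv"))
    mark("score", list(signatures = st$score$signatures), nrow(scores))
  }

  # -- screen -----------------------------------------------------------
  screen_out <- NULL
  if (!is.null(st$screen)) {
    if (is.null(scores)) stop("screen stage requires a score stage", call. = FALSE)
    b <- st$screen
    screen_out <- correlation_screen(scores, target = b$target,
                                     cluster = b$cluster, condition = b$condition,
                                     config = cfg$.screen_config)
    write_tsv(screen_out, file.path(out_dir, "screen.tsv"))
    mark("screen", b[setdiff(names(b), "candidates")], nrow(screen_out))
  }

  # -- shift ------------------------------------------------------------
  if (!is.null(st$shift)) {
    if (is.null(scores)) stop("shift stage requires a score stage", call. = FALSE)
    b <- st$shift
    open_cfg <- screen_config(min_cells = cfg$.shift_config$min_cells %||% 10)
    ra <- correlation_screen(scores, target = b$target, cluster = b$cluster,
                             condition = b$condition_a, config = open_cfg)
    rb <- correlation_screen(scores, target = b$target, cluster = b$cluster,
                             condition = b$condition_b, config = open_cfg)
    sh <- correlation_shift(ra, rb, floor = b$floor %||% 0.1)
    write_tsv(sh, file.path(out_dir, "shift.tsv"))
    mark("shift", b, nrow(sh))
  }

  # -- de ---------------------------------------------------------------
  if (!is.null(st$de)) {
    b <- st$de
    de <- wilcoxon_de(norm, ann, cluster = b$cluster,
                      condition_a = b$condition_a, condition_b = b$condition_b,
                      logfc_threshold = b$logfc_threshold %||% 0.25,
                      min_pct = b$min_pct %||% 0.2,
                      p_cutoff = b$p_cutoff %||% 0.05)
    write_tsv(de, file.path(out_dir, "de.tsv"))
    mark("de", b, nrow(de))
  }

  manifest$checksums <- .file_checksums(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
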