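#' Run the full replication-distance analysis
#'
#' End-to-end orchestration: read inputs, filter and normalize the spot
#' table, attach per-gene expression, call and label core genes,
#' annotate origin distances, compute sliding-window tracks and the
#' non-overlapping-window correlation table, gene-level correlations
#' (full set, transcription/translation excluded, core-only and
#' non-core-only), the expression-binned confound analysis, the core
#' versus non-core expression comparison, and the gene-dosage curve.
#' All results are written as TSV/bedGraph under `config$out_dir`
#' together with a run log; the same bundle is returned invisibly.
#'
#' @param config A [run_config()] (or path handled by
#'   [read_run_config()]).
#' @return Invisibly, a list with `genes`, `expression`, `tracks`,
#'   `window_correlations`, `gene_correlations`, `bin_report`,
#'   `core_expression_test` and `dosage`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat("", file = logf)
  stage <- function(name, expr) {
    logline("[%s] start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  genome <- circular_genome(config$length_bp, config$origins)
  logline("replorg %s; config: %d origins, L=%g; seed=%s",
          as.character(utils::packageVersion("replorg")),
          length(config$origins), config$length_bp,
          as.character(config$seed))

  genes <- stage("read_genes", {
    if (is.null(config$genes)) stop("config$genes is required")
    if (grepl("\\.gff3?$", config$genes))
      read_genes_gff3(config$genes, genome)
    else read_gene_tsv(config$genes, genome)
  })

  expression <- NULL
  if (!is.null(config$spots)) {
    expression <- stage("normalize", {
      spots <- read_spot_tsv(config$spots)
      logline("spots read: %d; surviving filter: %d", nrow(spots),
              nrow(filter_spots(spots)))
      normalize_expression(spots)
    })
    genes <- join_expression(genes, expression)
    write_expression_tsv(expression, file.path(out, "expression.tsv"))
    logline("genes with expression: %d of %d",
            sum(!is.na(genes$expression)), nrow(genes))
  }

  if (!is.null(config$cog_matrix)) {
    genes <- stage("core_call", {
      core <- call_core_cogs(read_cog_matrix_tsv(config$cog_matrix),
                             config$excluded_genomes)
      logline("core COGs called: %d", length(core))
      label_core_genes(genes, core)
    })
  }

  genes <- stage("distance", add_origin_distance(genes, genome))
  write_gene_tsv(genes, file.path(out, "genes_annotated.tsv"))

  tracks <- stage("tracks", {
    w <- make_windows(genome, config$window_size_bp,
                      config$window_step_bp, config$window_mode)
    window_features(genes, genome, w)
  })
  utils::write.table(tracks, file.path(out, "tracks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (f in setdiff(names(tracks), c("start", "end", "midpoint"))) {
    tr <- tracks[c("start", "end", "midpoint")]
    tr$value <- tracks[[f]]
    attr(tr, "feature") <- f
    write_bedgraph(tr, genome, file.path(out, paste0(f, ".bedgraph")))
  }

  window_correlations <- stage("correlate_windows", {
    w <- make_windows(genome, config$window_size_bp,
                      size_or_step(config), config$correlation_window_mode)
    feature_correlations(window_features(genes, genome, w))
  })
  utils::write.table(window_correlations,
                     file.path(out, "correlations_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gene_correlations <- stage("correlate_genes", {
    subsets <- list(
      all = NULL,
      excl_txn_translation =
        exclude_categories(config$exclude_txn_translation),
      core_only = only_category("core"),
      noncore_only = not_category("core"))
    rows <- lapply(names(subsets), function(nm) {
      st <- tryCatch(correlate_subset(genes, "expression",
                                      "origin_distance", subsets[[nm]]),
                     error = function(e) NULL)
      if (is.null(st)) return(NULL)
      data.frame(subset = nm, rho = st$statistic, p = st$p_two_sided,
                 n = st$n, method = st$method, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.table(gene_correlations,
                     file.path(out, "correlations_gene_level.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  core_expression_test <- bin_report <- NULL
  if (any(has_category(genes, "core")) &&
      any(!has_category(genes, "core")) &&
      sum(!is.na(genes$expression)) >= config$n_bins) {
    core_expression_test <- stage("core_expression", {
      ok <- !is.na(genes$expression)
      mann_whitney_test(genes$expression[ok & has_category(genes, "core")],
                        genes$expression[ok & !has_category(genes, "core")])
    })
    bin_report <- stage("bins",
      bin_confound_analysis(genes, config$n_bins, config$alpha))
    utils::write.table(bin_report$bins, file.path(out, "bin_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logline(paste0("bin analysis: %d usable bins, %d significant for ",
                   "distance (%d core-shorter)"),
            bin_report$n_usable, bin_report$n_significant_distance,
            bin_report$n_significant_core_shorter)
  }

  dosage <- stage("dosage", {
    model <- cell_cycle_model(config$s_start, config$s_duration)
    curve <- dosage_curve(genome, model, config$window_step_bp)
    list(model = model, ratio = dosage_ratio(model), curve = curve)
  })
  utils::write.table(dosage$curve, file.path(out, "dosage_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logline("dosage ratio (earliest/latest): %.4f", dosage$ratio)
  logline("done")

  invisible(list(genes = genes, expression = expression, tracks = tracks,
                 window_correlations = window_correlations,
                 gene_correlations = gene_correlations,
                 bin_report = bin_report,
                 core_expression_test = core_expression_test,
                 dosage = dosage, out_dir = out))
}

# correlation windows: non-overlapping windows step by their own size
size_or_step <- function(config) {
  if (config$correlation_window_mode == "nonoverlapping")
    config$window_size_bp else config$window_step_bp
}
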