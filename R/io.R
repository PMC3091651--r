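#' Read and write the gene-table TSV interchange format
#'
#' Columns: `gene_id`, `start`, `end` (0-based half-open, `end < start`
#' encodes wrap-around), `strand`, `categories` (comma-separated),
#' `cog_id`, `expression`. Empty strings read as `NA` for `cog_id`,
#' as `""` for `categories`.
#'
#' @param path File path.
#' @param genome Optional [circular_genome()] for validation on read.
#' @param genes Gene table to write.
#' @return `read_gene_tsv`: a gene table; `write_gene_tsv`: `path`,
#'   invisibly.
#' @export
read_gene_tsv <- function(path, genome = NULL) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA",
                           colClasses = c(gene_id = "character",
                                          categories = "character",
                                          cog_id = "character"))
  raw$categories[is.na(raw$categories)] <- ""
  g <- gene_table(raw$gene_id, raw$start, raw$end, raw$strand,
                  categories = raw$categories, cog_id = raw$cog_id,
                  expression = if ("expression" %in% names(raw))
                    raw$expression else NA_real_,
                  genome = genome)
  if ("origin_distance" %in% names(raw))
    g$origin_distance <- raw$origin_distance
  g
}

#' @rdname read_gene_tsv
#' @export
write_gene_tsv <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Imports a GFF3 file (1-based inclusive coordinates) through
#' `rtracklayer` and converts to the internal 0-based half-open gene
#' table. Category labels are taken from the attribute key named by
#' `category_attribute` (comma-separated), the COG id from
#' `cog_attribute`. Wrap-around genes cannot be expressed in GFF3; use
#' the TSV interchange format for those.
#'
#' @param path GFF3 file path.
#' @param genome Optional [circular_genome()] for validation.
#' @param feature_type GFF3 `type` to keep (default `"gene"`).
#' @param category_attribute,cog_attribute Attribute keys.
#' @return A gene table.
#' @export
read_genes_gff3 <- function(path, genome = NULL, feature_type = "gene",
                            category_attribute = "categories",
                            cog_attribute = "cog_id") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  meta <- S4Vectors::mcols(gr)
  getattr <- function(key, default) {
    if (key %in% names(meta)) {
      v <- as.character(meta[[key]])
      ifelse(is.na(v), default, v)
    } else rep(default, length(gr))
  }
  ids <- getattr("ID", NA_character_)
  if (anyNA(ids)) ids <- getattr("Name", sprintf("g%05d", seq_along(gr)))
  expr <- suppressWarnings(as.numeric(getattr("expression", NA_character_)))
  gene_table(gene_id = ids,
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             categories = getattr(category_attribute, ""),
             cog_id = getattr(cog_attribute, NA_character_),
             expression = expr, genome = genome)
}

#' Write gene annotation to GFF3
#'
#' Inverse of [read_genes_gff3()]; internal 0-based half-open
#' coordinates become 1-based inclusive. Wrap-around genes are rejected.
#'
#' @param genes A gene table.
#' @param path Output path.
#' @param seqname Chromosome name used in column 1.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path, seqname = "chr") {
  if (any(genes$end <= genes$start))
    stop("GFF3 cannot represent wrap-around genes; use write_gene_tsv")
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "replorg"
  gr$ID <- genes$gene_id
  gr$categories <- genes$categories
  gr$cog_id <- genes$cog_id
  if (!all(is.na(genes$expression))) gr$expression <- genes$expression
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read and write spot-table TSVs (GenePix-like dialect)
#'
#' Column names are configurable so exported scanner tables can be
#' consumed directly; defaults match the writer.
#'
#' @param path File path.
#' @param columns Named character vector mapping internal names
#'   (`array_id`, `gene_id`, `replicate`, `fg_cdna`, `bg_cdna`,
#'   `fg_gdna`, `bg_gdna`, `quality_ok`) to file column names.
#' @param spots Spot table to write.
#' @return `read_spot_tsv`: a validated spot table; `write_spot_tsv`:
#'   `path`, invisibly.
#' @export
read_spot_tsv <- function(path, columns = NULL) {
  defaults <- c(array_id = "array_id", gene_id = "gene_id",
                replicate = "replicate", fg_cdna = "fg_cdna",
                bg_cdna = "bg_cdna", fg_gdna = "fg_gdna",
                bg_gdna = "bg_gdna", quality_ok = "quality_ok")
  if (!is.null(columns)) defaults[names(columns)] <- columns
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(defaults), names(raw))
  if (length(missing_cols))
    stop("spot file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  spot_table(array_id = raw[[defaults["array_id"]]],
             gene_id = raw[[defaults["gene_id"]]],
             replicate = raw[[defaults["replicate"]]],
             fg_cdna = raw[[defaults["fg_cdna"]]],
             bg_cdna = raw[[defaults["bg_cdna"]]],
             fg_gdna = raw[[defaults["fg_gdna"]]],
             bg_gdna = raw[[defaults["bg_gdna"]]],
             quality_ok = raw[[defaults["quality_ok"]]])
}

#' @rdname read_spot_tsv
#' @export
write_spot_tsv <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a COG copy-count matrix from TSV
#'
#' Rows = COGs (first column `cog_id`), remaining columns = genomes,
#' integer cells.
#'
#' @param path File path.
#' @return A [cog_matrix()].
#' @export
read_cog_matrix_tsv <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- raw[[1L]]
  cog_matrix(m)
}

#' Write a per-gene expression table
#'
#' @param expression Table from [normalize_expression()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a window track as bedGraph
#'
#' 0-based half-open intervals; windows wrapping across position 0 are
#' split into two lines; windows with missing values are omitted (the
#' format has no NA representation).
#'
#' @param track A track from [window_track()] (columns `start`, `value`).
#' @param genome The [circular_genome()] the windows live on.
#' @param path Output path.
#' @param seqname Chromosome name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, genome, path, seqname = "chr") {
  L <- genome$length_bp
  size <- window_size(track, genome)
  keep <- !is.na(track$value)
  s <- track$start[keep]; v <- track$value[keep]
  e <- s + size
  wraps <- e > L
  lines <- character(0)
  fmt <- function(s, e, v) sprintf("%s\t%d\t%d\t%g", seqname,
                                   as.integer(s), as.integer(e), v)
  lines <- c(fmt(s[!wraps], e[!wraps], v[!wraps]),
             if (any(wraps)) c(fmt(s[wraps], rep(L, sum(wraps)), v[wraps]),
                               fmt(rep(0, sum(wraps)), e[wraps] - L,
                                   v[wraps])))
  writeLines(c(sprintf("track type=bedGraph name=%s",
                       attr(track, "feature") %||% "track"), lines), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML
#'
#' Single declarative YAML file holding the genome geometry, input
#' paths, window specification, statistical settings and (optionally) a
#' simulation block. Unknown keys are rejected to catch typos.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config` (see [run_config()]).
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Build a run configuration
#'
#' @param length_bp Chromosome length.
#' @param origins Replication-origin positions (0-based).
#' @param genes Path to a gene TSV or GFF3 (extension decides).
#' @param spots Path to a spot TSV, or `NULL` if `genes` already carries
#'   expression.
#' @param cog_matrix Path to a COG matrix TSV, or `NULL` if core labels
#'   are already in the gene table.
#' @param excluded_genomes Genomes excluded from the core call.
#' @param window_size_bp,window_step_bp,window_mode Window settings for
#'   the Figure-style sliding tracks.
#' @param correlation_window_mode Window mode for the window-level
#'   correlation table (default non-overlapping, statistically
#'   independent windows).
#' @param n_bins,alpha Confound-analysis settings.
#' @param exclude_txn_translation Category labels treated as
#'   transcription/translation genes in the exclusion correlation.
#' @param condition Condition label (`exponential` or `stationary`).
#' @param s_start,s_duration Cell-cycle model parameters.
#' @param out_dir Output directory.
#' @param seed Seed recorded in the run log.
#' @return A list of class `run_config`.
#' @export
run_config <- function(length_bp, origins, genes = NULL, spots = NULL,
                       cog_matrix = NULL,
                       excluded_genomes = character(0),
                       window_size_bp = 1e5, window_step_bp = 1e3,
                       window_mode = "sliding",
                       correlation_window_mode = "nonoverlapping",
                       n_bins = 12L, alpha = 0.05,
                       exclude_txn_translation = "txn_translation",
                       condition = "exponential",
                       s_start = 0.05, s_duration = 1 / 3,
                       out_dir = "replorg_out", seed = 1L) {
  cfg <- as.list(environment())
  circular_genome(length_bp, origins)
  structure(cfg, class = "run_config")
}
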