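#' Assemble and validate a spot table
#'
#' One row per printed spot: a gene probed on one array, one replicate
#' spot, with foreground and background intensities for the cDNA (Cy5)
#' and genomic-DNA (Cy3) channels and a scanner quality flag. The gDNA
#' channel comes from stationary-phase cells (all loci at equal copy
#' number), so the cDNA/gDNA ratio estimates relative transcript
#' abundance.
#'
#' @param array_id,gene_id Character identifiers.
#' @param replicate Replicate spot index within (array, gene).
#' @param fg_cdna,bg_cdna,fg_gdna,bg_gdna Non-negative intensities.
#' @param quality_ok Logical scanner quality flag.
#' @return A validated `data.frame` with the columns above.
#' @export
spot_table <- function(array_id, gene_id, replicate,
                       fg_cdna, bg_cdna, fg_gdna, bg_gdna,
                       quality_ok = TRUE) {
  spots <- data.frame(array_id = as.character(array_id),
                      gene_id = as.character(gene_id),
                      replicate = as.integer(replicate),
                      fg_cdna = as.numeric(fg_cdna),
                      bg_cdna = as.numeric(bg_cdna),
                      fg_gdna = as.numeric(fg_gdna),
                      bg_gdna = as.numeric(bg_gdna),
                      quality_ok = as.logical(quality_ok),
                      stringsAsFactors = FALSE)
  validate_spots(spots)
  spots
}

validate_spots <- function(spots) {
  need <- c("array_id", "gene_id", "replicate", "fg_cdna", "bg_cdna",
            "fg_gdna", "bg_gdna", "quality_ok")
  if (!all(need %in% names(spots)))
    stop("spot table must have columns: ", paste(need, collapse = ", "))
  ints <- c("fg_cdna", "bg_cdna", "fg_gdna", "bg_gdna")
  if (any(vapply(spots[ints], function(v) any(v < 0), logical(1L))))
    stop("intensities must be non-negative")
  if (anyDuplicated(spots[c("array_id", "gene_id", "replicate")]))
    stop("(array_id, gene_id, replicate) must be unique")
  invisible(spots)
}

#' Remove low-quality and background-dominated spots
#'
#' Retains spots that pass the scanner quality flag and have foreground
#' strictly above background in both channels (so the log ratio of
#' background-subtracted intensities is defined). Genes losing all spots
#' simply disappear from downstream tables.
#'
#' @param spots A spot table (see [spot_table()]).
#' @return The filtered spot table.
#' @export
filter_spots <- function(spots) {
  validate_spots(spots)
  keep <- spots$quality_ok &
    spots$fg_cdna > spots$bg_cdna & spots$fg_gdna > spots$bg_gdna
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-spot log2 cDNA/gDNA ratio of background-subtracted intensities
#'
#' `log2((fg_cdna - bg_cdna) / (fg_gdna - bg_gdna))`. Multiplicative
#' probe effects shared by the two channels cancel exactly.
#'
#' @param spots A filtered spot table (fg > bg in both channels).
#' @return Numeric vector of log2 ratios, one per spot.
#' @export
spot_log_ratio <- function(spots) {
  num <- spots$fg_cdna - spots$bg_cdna
  den <- spots$fg_gdna - spots$bg_gdna
  if (any(num <= 0) || any(den <= 0))
    stop("spots must be filtered first: foreground <= background found")
  log2(num / den)
}

#' Centre each array's log ratios at mean zero
#'
#' Normalizes every array so that its mean log ratio equals zero,
#' removing array-wide labelling and scanning gain differences.
#'
#' @param spots A filtered spot table.
#' @param ratio Per-spot log ratios; defaults to [spot_log_ratio()].
#' @return The spot table with a `log_ratio` column of centred ratios.
#' @export
normalize_arrays <- function(spots, ratio = spot_log_ratio(spots)) {
  if (!nrow(spots)) stop("no spots to normalize")
  centred <- ratio - stats::ave(ratio, spots$array_id)
  spots$log_ratio <- centred
  spots
}

#' Summarize normalized spot ratios into per-gene expression
#'
#' Two-stage averaging: within each array the replicate spots of a gene
#' are averaged first, then the per-array values are averaged with equal
#' weight regardless of how many replicates survived on each array.
#'
#' @param spots A spot table with a `log_ratio` column (from
#'   [normalize_arrays()]).
#' @return A `data.frame` with one row per retained gene: `gene_id`,
#'   `expression`, `n_arrays`, `n_spots`.
#' @export
summarize_genes <- function(spots) {
  if (!"log_ratio" %in% names(spots))
    stop("spots must carry normalized log_ratio (see normalize_arrays)")
  if (!nrow(spots))
    return(data.frame(gene_id = character(0), expression = numeric(0),
                      n_arrays = integer(0), n_spots = integer(0),
                      stringsAsFactors = FALSE))
  per_array <- stats::aggregate(log_ratio ~ gene_id + array_id,
                                data = spots, FUN = mean)
  per_gene <- stats::aggregate(log_ratio ~ gene_id, data = per_array,
                               FUN = mean)
  n_arrays <- stats::aggregate(array_id ~ gene_id, data = per_array,
                               FUN = length)
  n_spots <- stats::aggregate(array_id ~ gene_id, data = spots,
                              FUN = length)
  out <- data.frame(gene_id = per_gene$gene_id,
                    expression = per_gene$log_ratio,
                    n_arrays = n_arrays$array_id[
                      match(per_gene$gene_id, n_arrays$gene_id)],
                    n_spots = n_spots$array_id[
                      match(per_gene$gene_id, n_spots$gene_id)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full spot-to-expression pipeline
#'
#' Filter, ratio, per-array mean-zero normalization, two-stage averaging.
#'
#' @param spots A raw spot table.
#' @return Per-gene expression table (see [summarize_genes()]); zero rows
#'   if no spot survives filtering.
#' @export
normalize_expression <- function(spots) {
  kept <- filter_spots(spots)
  if (!nrow(kept))
    return(summarize_genes(cbind(kept, log_ratio = numeric(0))))
  summarize_genes(normalize_arrays(kept))
}

#' Attach measured expression to a gene table
#'
#' @param genes A gene table.
#' @param expression Per-gene expression table from
#'   [normalize_expression()].
#' @return The gene table with its `expression` column filled from the
#'   measurements (`NA` where a gene was filtered out).
#' @export
join_expression <- function(genes, expression) {
  genes$expression <-
    expression$expression[match(genes$gene_id, expression$gene_id)]
  genes
}
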