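#' COG copy-count matrix
#'
#' Integer matrix of per-genome gene copy counts, rows = COGs (clusters
#' of orthologous groups), columns = genomes. Built from precomputed
#' ortholog assignments; this package never infers orthology itself.
#'
#' @param counts Numeric matrix with rownames (COG ids) and colnames
#'   (genome ids); non-negative integers, zero meaning absent.
#' @return The validated matrix (class `cog_matrix`).
#' @export
cog_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry COG rownames and genome colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("copy counts must be non-negative integers")
  class(counts) <- c("cog_matrix", class(counts))
  counts
}

#' Call the archaeal core COG set
#'
#' A COG is core when it is present in exactly one copy in every genome
#' considered. Any genome with zero copies removes the COG (not
#' universal); any genome with two or more copies removes it too
#' (multi-copy families are unlikely to be essential in every member, the
#' classic example being the acetyl-CoA acetyltransferase COG with 11
#' copies in one Sulfolobus genome). Obligate symbionts with reduced
#' genomes are excluded from the universality requirement via
#' `excluded_genomes`.
#'
#' @param counts A [cog_matrix()] or plain matrix with dimnames.
#' @param excluded_genomes Genome ids ignored when requiring universal
#'   single-copy presence; must all be columns of `counts`.
#' @return Character vector of core COG ids.
#' @export
call_core_cogs <- function(counts, excluded_genomes = character(0)) {
  counts <- cog_matrix(unclass(counts))
  unknown <- setdiff(excluded_genomes, colnames(counts))
  if (length(unknown))
    stop("unknown excluded genome id(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(counts), excluded_genomes)
  if (!length(keep)) stop("no genomes left after exclusion")
  sub <- counts[, keep, drop = FALSE]
  rownames(counts)[rowSums(sub == 1) == length(keep)]
}

#' Label genes as archaeal core genes
#'
#' A gene gains the `core` category iff its `cog_id` belongs to the core
#' set; genes without a COG assignment stay non-core.
#'
#' @param genes A gene table with a `cog_id` column.
#' @param core_cogs Character vector of core COG ids (from
#'   [call_core_cogs()]).
#' @return The gene table with the `core` category set on matching genes.
#' @export
label_core_genes <- function(genes, core_cogs) {
  is_core <- !is.na(genes$cog_id) & genes$cog_id %in% core_cogs
  add_category(genes, "core", is_core)
}
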