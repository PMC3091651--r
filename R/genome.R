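#' Circular chromosome with replication origins
#'
#' Constructs the coordinate system every other computation runs on: a
#' circular chromosome of `length_bp` base pairs carrying one or more
#' replication origins. All positions are 0-based and interpreted modulo
#' `length_bp`; distances are shortest-arc distances.
#'
#' @param length_bp Chromosome length in base pairs (positive integer).
#' @param origins Numeric vector of origin positions in `[0, length_bp)`,
#'   strictly increasing, at least one. Sulfolobus chromosomes carry three
#'   unevenly spaced origins.
#' @return An object of class `circular_genome` with elements `length_bp`
#'   and `origins`.
#' @examples
#' g <- circular_genome(2.2e6, c(1e5, 9.5e5, 1.7e6))
#' circular_distance(c(0, 5e5, 2.1e6), g)
#' @export
circular_genome <- function(length_bp, origins) {
  if (!is.numeric(length_bp) || length(length_bp) != 1L || length_bp < 1)
    stop("length_bp must be a single positive number")
  if (!is.numeric(origins) || length(origins) < 1L)
    stop("at least one origin position is required")
  if (any(origins < 0) || any(origins >= length_bp))
    stop("origin positions must lie in [0, length_bp)")
  if (anyDuplicated(origins) || is.unsorted(origins, strictly = TRUE))
    stop("origins must be strictly increasing and duplicate-free")
  structure(list(length_bp = as.numeric(length_bp),
                 origins = as.numeric(origins)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("Circular genome: %s bp, %d replication origin(s) at %s\n",
              format(x$length_bp, big.mark = ","), length(x$origins),
              paste(format(x$origins, trim = TRUE, scientific = FALSE),
                    collapse = ", ")))
  invisible(x)
}

#' Distance to the nearest replication origin
#'
#' Shortest arc length along the circle from each position to any origin.
#' Under synchronous origin firing and constant fork speed this distance is
#' proportional to replication time, which is why it serves as the ordering
#' variable for all gradient analyses.
#'
#' @param pos Numeric vector of positions in `[0, length_bp)`.
#' @param genome A [circular_genome()].
#' @return Numeric vector of distances in `[0, length_bp/2]`.
#' @export
circular_distance <- function(pos, genome) {
  stopifnot(inherits(genome, "circular_genome"))
  L <- genome$length_bp
  if (any(!is.finite(pos)) || any(pos < 0) || any(pos >= L))
    stop("position out of range [0, length_bp)")
  ad <- abs(outer(pos, genome$origins, "-"))
  apply(pmin(ad, L - ad), 1L, min)
}

#' Assemble and validate a gene table
#'
#' The gene table is a plain `data.frame`, one row per annotated gene, with
#' 0-based half-open coordinates. A gene wrapping across position 0 is
#' encoded with `end < start`. `categories` is a comma-separated label set
#' drawn from `core`, `transposon`, `rrna_trna`, `txn_translation`,
#' `protein_coding`.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param start,end 0-based start (inclusive) and end (exclusive) in bp.
#' @param strand `"+"` or `"-"` per gene.
#' @param categories Comma-separated category labels (may be `""`).
#' @param cog_id COG identifier or `NA`.
#' @param expression Normalized log2 cDNA/gDNA ratio or `NA`.
#' @param genome Optional [circular_genome()]; when supplied, coordinates
#'   are validated against the chromosome length.
#' @return A `data.frame` with the columns above.
#' @export
gene_table <- function(gene_id, start, end, strand,
                       categories = "", cog_id = NA_character_,
                       expression = NA_real_, genome = NULL) {
  genes <- data.frame(gene_id = as.character(gene_id),
                      start = as.numeric(start), end = as.numeric(end),
                      strand = as.character(strand),
                      categories = as.character(categories),
                      cog_id = as.character(cog_id),
                      expression = as.numeric(expression),
                      stringsAsFactors = FALSE)
  if (!is.null(genome)) validate_genes(genes, genome)
  genes
}

#' Validate gene coordinates against a genome
#'
#' @param genes A gene table (see [gene_table()]).
#' @param genome A [circular_genome()].
#' @return The gene table, invisibly; errors on violation.
#' @export
validate_genes <- function(genes, genome) {
  stopifnot(inherits(genome, "circular_genome"))
  need <- c("gene_id", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  L <- genome$length_bp
  if (any(genes$start < 0) || any(genes$start >= L))
    stop("gene start out of range [0, length_bp)")
  if (any(genes$end < 0) || any(genes$end > L))
    stop("gene end out of range [0, length_bp]")
  len <- gene_length(genes, genome)
  if (any(len < 1) || any(len >= L))
    stop("modular gene length must be >= 1 and < length_bp")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  invisible(genes)
}

#' Modular gene length and midpoint
#'
#' `gene_length` is the modular span of `[start, end)`; `gene_midpoint` is
#' the modular midpoint, the reference point used for origin distances and
#' window membership (unbiased for long genes, unlike the start).
#'
#' @inheritParams validate_genes
#' @return Numeric vector, one value per gene.
#' @export
gene_length <- function(genes, genome) {
  L <- genome$length_bp
  len <- (genes$end - genes$start) %% L
  # end == start would be a full-circle gene; treated as length L (invalid)
  ifelse(len == 0, L, len)
}

#' @rdname gene_length
#' @export
gene_midpoint <- function(genes, genome) {
  (genes$start + gene_length(genes, genome) / 2) %% genome$length_bp
}

#' Gene-level distance to the nearest origin
#'
#' [circular_distance()] of each gene's modular midpoint.
#'
#' @inheritParams validate_genes
#' @return Numeric vector of distances in bp.
#' @export
gene_origin_distance <- function(genes, genome) {
  validate_genes(genes, genome)
  circular_distance(gene_midpoint(genes, genome), genome)
}

#' Annotate a gene table with origin distances
#'
#' @inheritParams validate_genes
#' @return The gene table with an added `origin_distance` column.
#' @export
add_origin_distance <- function(genes, genome) {
  genes$origin_distance <- gene_origin_distance(genes, genome)
  genes
}

#' Test genes for a category label
#'
#' @param genes A gene table.
#' @param category Single category label.
#' @return Logical vector.
#' @export
has_category <- function(genes, category) {
  vapply(strsplit(genes$categories, ",", fixed = TRUE),
         function(x) category %in% trimws(x), logical(1L))
}

#' Add a category label to selected genes
#'
#' @param genes A gene table.
#' @param category Label to add.
#' @param which Logical or integer index of genes receiving the label.
#' @return The modified gene table.
#' @export
add_category <- function(genes, category, which = TRUE) {
  idx <- seq_len(nrow(genes))[which]
  cur <- genes$categories[idx]
  hasit <- has_category(genes[idx, , drop = FALSE], category)
  genes$categories[idx] <- ifelse(hasit, cur,
                                  ifelse(cur == "" | is.na(cur), category,
                                         paste0(cur, ",", category)))
  genes
}

#' Intergenic gaps of divergently transcribed gene pairs
#'
#' Scans immediately adjacent gene pairs around the circle (including the
#' wrap pair last-to-first) and, for every pair whose upstream gene lies on
#' the minus strand and downstream gene on the plus strand (5' ends facing,
#' sharing an upstream intergenic region), reports the intergenic gap.
#' Overlapping divergent genes get gap 0.
#'
#' @param genes Gene table sorted by `start`; an error is raised otherwise.
#' @param genome A [circular_genome()].
#' @return A `data.frame` with columns `upstream`, `downstream` (gene ids),
#'   `gap` (bp) and `midpoint` (modular midpoint of the intergenic gap,
#'   used for window assignment).
#' @export
divergent_pair_gaps <- function(genes, genome) {
  validate_genes(genes, genome)
  if (is.unsorted(genes$start))
    stop("genes must be sorted by start position")
  n <- nrow(genes)
  empty <- data.frame(upstream = character(0), downstream = character(0),
                      gap = numeric(0), midpoint = numeric(0),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  L <- genome$length_bp
  up <- seq_len(n)
  dn <- c(seq_len(n)[-1L], 1L)
  sel <- genes$strand[up] == "-" & genes$strand[dn] == "+"
  up <- up[sel]; dn <- dn[sel]
  if (!length(up)) return(empty)
  len_up <- gene_length(genes, genome)[up]
  d_start <- (genes$start[dn] - genes$start[up]) %% L
  d_start[d_start == 0 & up != dn] <- L  # distinct genes, full turn apart
  gap <- pmax(0, d_start - len_up)
  mid <- (genes$start[up] + len_up + gap / 2) %% L
  data.frame(upstream = genes$gene_id[up], downstream = genes$gene_id[dn],
             gap = gap, midpoint = mid, stringsAsFactors = FALSE)
}

#' Protein-coding density of a circular interval
#'
#' Fraction of the interval `[a, b)` covered by the union of
#' `protein_coding` gene spans. An interval with `b <= a` wraps across
#' position 0; its length is the modular length.
#'
#' @param genes A gene table.
#' @param interval Numeric length-2 vector `c(a, b)`, 0-based half-open.
#' @param genome A [circular_genome()].
#' @return Covered fraction in `[0, 1]`.
#' @export
coding_density <- function(genes, interval, genome) {
  stopifnot(inherits(genome, "circular_genome"), length(interval) == 2L)
  L <- genome$length_bp
  a <- interval[1L] %% L
  ilen <- (interval[2L] - interval[1L]) %% L
  if (ilen == 0) {
    if (interval[2L] != interval[1L]) ilen <- L
    else stop("zero-length interval")
  }
  cg <- genes[has_category(genes, "protein_coding"), , drop = FALSE]
  if (!nrow(cg)) return(0)
  # shift so the interval becomes [0, ilen); each gene occupies
  # [s, s + len) mod L, i.e. up to two linear segments after clipping
  s <- (cg$start - a) %% L
  len <- gene_length(cg, genome)
  seg_s <- c(s, rep(0, nrow(cg)))
  seg_e <- c(pmin(s + len, L), pmax(s + len - L, 0))
  keep <- seg_e > seg_s & seg_s < ilen
  seg_s <- seg_s[keep]; seg_e <- pmin(seg_e[keep], ilen)
  if (!length(seg_s)) return(0)
  covered <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = floor(seg_s) + 1L, end = ceiling(seg_e)))))
  min(1, covered / ilen)
}

#' Rotate a coordinate system
#'
#' Shifts all gene coordinates and origins by a constant modular offset.
#' Distance- and gap-based quantities are invariant under this rotation,
#' which the test suite exploits.
#'
#' @param genes A gene table.
#' @param genome A [circular_genome()].
#' @param shift Offset in bp.
#' @return List with rotated `genes` (re-sorted by start) and `genome`.
#' @export
rotate_coordinates <- function(genes, genome, shift) {
  L <- genome$length_bp
  g2 <- genes
  g2$start <- (genes$start + shift) %% L
  g2$end <- (genes$end + shift) %% L
  g2 <- g2[order(g2$start), , drop = FALSE]
  rownames(g2) <- NULL
  genome2 <- circular_genome(L, sort((genome$origins + shift) %% L))
  list(genes = g2, genome = genome2)
}
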