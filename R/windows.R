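#' Build sliding or non-overlapping windows on the circle
#'
#' Sliding mode emulates chromosome-scale track plots: `ceiling(L/step)`
#' windows of `size_bp` starting every `step_bp`, wrapping across
#' position 0. Non-overlapping mode yields `floor(L/size)` abutting
#' windows starting at 0, the statistically independent window set used
#' for window-level correlation tables.
#'
#' @param genome A [circular_genome()].
#' @param size_bp Window size in bp (default 100 kb).
#' @param step_bp Step between sliding window starts (default 1 kb).
#' @param mode `"sliding"` or `"nonoverlapping"`.
#' @return A `data.frame` with one row per window: `start`, `end`
#'   (modular, half-open; `end < start` marks wrap-around) and
#'   `midpoint`.
#' @export
make_windows <- function(genome, size_bp = 1e5, step_bp = 1e3,
                         mode = c("sliding", "nonoverlapping")) {
  mode <- match.arg(mode)
  L <- genome$length_bp
  if (size_bp < 1 || step_bp < 1) stop("window size and step must be >= 1")
  if (step_bp > size_bp) stop("step_bp must not exceed size_bp")
  if (size_bp > L) stop("window size exceeds chromosome length")
  starts <- if (mode == "sliding") {
    seq(0, L - 1e-9, by = step_bp)[seq_len(ceiling(L / step_bp))]
  } else {
    seq(0, by = size_bp, length.out = floor(L / size_bp))
  }
  data.frame(start = starts,
             end = (starts + size_bp) %% L,
             midpoint = (starts + size_bp / 2) %% L)
}

# is position p inside circular window [s, s + size) ?
in_window <- function(p, s, size, L) ((p - s) %% L) < size

window_size <- function(windows, genome) {
  ((windows$end[1L] - windows$start[1L] - 1) %% genome$length_bp) + 1
}

#' Compute one feature track over a window set
#'
#' Gene membership is by modular gene midpoint. Supported features:
#' \describe{
#'   \item{mean_expression}{Mean expression of member genes with
#'     non-missing expression.}
#'   \item{core_proportion}{Core members / protein-coding members.}
#'   \item{coding_density}{Fraction of the window covered by
#'     protein-coding spans ([coding_density()]).}
#'   \item{transposon_proportion}{Transposon members / all members.}
#'   \item{mean_divergent_gap}{Mean intergenic gap of divergent pairs
#'     whose gap midpoint lies in the window ([divergent_pair_gaps()]).}
#'   \item{origin_distance}{[circular_distance()] of the window
#'     midpoint.}
#' }
#' Windows with no qualifying member get `NA`.
#'
#' @param genes A gene table (sorted or not; sorted internally where
#'   needed).
#' @param genome A [circular_genome()].
#' @param windows Window set from [make_windows()].
#' @param feature Feature name, one of the six above.
#' @return The `windows` data frame with a `value` column and a
#'   `"feature"` attribute.
#' @export
window_track <- function(genes, genome, windows, feature) {
  L <- genome$length_bp
  size <- window_size(windows, genome)
  value <- switch(
    feature,
    origin_distance = circular_distance(windows$midpoint, genome),
    coding_density = vapply(seq_len(nrow(windows)), function(i)
      coding_density(genes, c(windows$start[i],
                              (windows$start[i] + size) %% L), genome),
      numeric(1L)),
    mean_expression = ,
    core_proportion = ,
    transposon_proportion = {
      mid <- gene_midpoint(genes, genome)
      vapply(windows$start, function(s) {
        m <- in_window(mid, s, size, L)
        switch(feature,
               mean_expression = {
                 e <- genes$expression[m]
                 e <- e[!is.na(e)]
                 if (length(e)) mean(e) else NA_real_
               },
               core_proportion = {
                 pc <- m & has_category(genes, "protein_coding")
                 if (!any(pc)) NA_real_
                 else sum(pc & has_category(genes, "core")) / sum(pc)
               },
               transposon_proportion = {
                 if (!any(m)) NA_real_
                 else sum(m & has_category(genes, "transposon")) / sum(m)
               })
      }, numeric(1L))
    },
    mean_divergent_gap = {
      sorted <- genes[order(genes$start), , drop = FALSE]
      pairs <- divergent_pair_gaps(sorted, genome)
      vapply(windows$start, function(s) {
        m <- in_window(pairs$midpoint, s, size, L)
        if (any(m)) mean(pairs$gap[m]) else NA_real_
      }, numeric(1L))
    },
    stop("unknown feature: ", feature)
  )
  out <- windows
  out$value <- value
  attr(out, "feature") <- feature
  out
}

#' Compute several feature tracks on one window set
#'
#' @inheritParams window_track
#' @param features Character vector of feature names (see
#'   [window_track()]).
#' @return `windows` with one value column per feature, ready for
#'   [feature_correlations()].
#' @export
window_features <- function(genes, genome, windows,
                            features = c("origin_distance",
                                         "mean_expression",
                                         "core_proportion",
                                         "coding_density",
                                         "mean_divergent_gap",
                                         "transposon_proportion")) {
  out <- windows
  for (f in features) out[[f]] <- window_track(genes, genome, windows, f)$value
  out
}
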