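#' @useDynLib replorg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# memoised exact Spearman null distributions, keyed by sample size
.spearman_null_env <- new.env(parent = emptyenv())

spearman_null <- function(n) {
  key <- as.character(n)
  if (is.null(.spearman_null_env[[key]])) {
    counts <- spearman_null_counts(n)
    s <- which(counts > 0) - 1L
    .spearman_null_env[[key]] <- list(s = s, prob = counts[s + 1L] / sum(counts))
  }
  .spearman_null_env[[key]]
}

new_stat_result <- function(statistic, p, n, method,
                            estimate_name = "statistic") {
  structure(list(statistic = statistic, p_two_sided = p, n = n,
                 method = method, estimate_name = estimate_name),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  nlab <- paste(x$n, collapse = " vs ")
  cat(sprintf("%s: %s = %.4g, two-sided P = %.4g, n = %s\n",
              x$method, x$estimate_name, x$statistic, x$p_two_sided, nlab))
  invisible(x)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks
#' (average ranks on ties). The two-sided p-value comes from exhaustive
#' permutation enumeration when `n <= 10` and the data are tie-free
#' (method `spearman_exact`), and otherwise from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (method `spearman_t_approx`).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, finite values.
#' @return A `stat_result` with fields `statistic` (rho), `p_two_sided`,
#'   `n` and `method`.
#' @examples
#' spearman_test(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("undefined correlation: zero rank variance")
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  if (n <= 10L && !ties) {
    null <- spearman_null(n)
    mS <- n * (n + 1)^2 / 4
    vS <- n * (n^2 - 1) / 12
    rho_null <- (null$s - mS) / vS
    p <- sum(null$prob[abs(rho_null) >= abs(rho) - 1e-12])
    method <- "spearman_exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "spearman_t_approx"
  }
  new_stat_result(rho, max(min(p, 1), .Machine$double.xmin), n, method,
                  estimate_name = "rho")
}

#' Mann-Whitney U test (rank-sum) with exact small-sample p-value
#'
#' U counts, over all cross-pairs, how often a value of `a` exceeds a
#' value of `b`, with 0.5 credit for ties. The two-sided p-value is exact
#' (null distribution of U over all group assignments) when
#' `min(n1, n2) <= 8` and there are no ties (method `mw_exact`), and
#' otherwise uses the normal approximation with tie correction and
#' continuity correction (method `mw_normal`).
#'
#' @param a,b Non-empty numeric vectors.
#' @return A `stat_result` with `statistic` (U for group `a`),
#'   `p_two_sided`, `n = c(n1, n2)` and `method`.
#' @examples
#' mann_whitney_test(c(1, 2), c(3, 4))
#' @export
mann_whitney_test <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("values must be finite")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (min(n1, n2) <= 8L && !ties) {
    p_le <- stats::pwilcox(U, n1, n2)
    p_ge <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "mw_exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) stop("degenerate data: all values tied")
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "mw_normal"
  }
  new_stat_result(U, max(p, .Machine$double.xmin), c(n1, n2), method,
                  estimate_name = "U")
}

#' Split genes into equally sized expression bins
#'
#' Genes with non-missing expression are sorted ascending by expression
#' (ties keep input order) and split into `n_bins` contiguous bins whose
#' sizes differ by at most one, earlier bins taking the remainder.
#'
#' @param genes Gene table with an `expression` column.
#' @param n_bins Number of bins (default 12).
#' @return Integer vector over all rows of `genes`: bin index 1..n_bins,
#'   `NA` for genes without expression.
#' @export
expression_bins <- function(genes, n_bins = 12L) {
  expr <- genes$expression
  usable <- which(!is.na(expr))
  n <- length(usable)
  if (n < n_bins) stop("fewer genes with expression than bins")
  ord <- usable[order(expr[usable])]  # radix order: stable on ties
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + (seq_len(n_bins) <= extra)
  bins <- rep(NA_integer_, nrow(genes))
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Expression-binned core versus non-core confound analysis
#'
#' Tests whether core genes sit closer to replication origins than
#' non-core genes of the same expression level. Genes are binned by
#' expression ([expression_bins()]); within every bin containing both
#' categories a Mann-Whitney test compares the two groups on expression
#' (confound check: binning should have removed any difference) and on
#' origin distance, with the direction of the distance difference
#' recorded from group medians.
#'
#' @param genes Gene table with `expression`, `origin_distance` and a
#'   `core` category label.
#' @param n_bins Number of expression bins (default 12).
#' @param alpha Significance threshold for counting bins (default 0.05,
#'   raw, uncorrected).
#' @return A `bin_report`: per-bin data frame plus summary counts
#'   `n_usable` and `n_significant_distance`.
#' @export
bin_confound_analysis <- function(genes, n_bins = 12L, alpha = 0.05) {
  if (!"origin_distance" %in% names(genes))
    stop("genes need an origin_distance column (see add_origin_distance)")
  bins <- expression_bins(genes, n_bins)
  core <- has_category(genes, "core")
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- which(bins == b)
    is_core <- core[sel]
    n_core <- sum(is_core); n_non <- sum(!is_core)
    usable <- n_core >= 1L && n_non >= 1L
    p_expr <- p_dist <- NA_real_; direction <- NA_character_
    if (usable) {
      p_expr <- mann_whitney_test(genes$expression[sel][is_core],
                                  genes$expression[sel][!is_core])$p_two_sided
      p_dist <- mann_whitney_test(genes$origin_distance[sel][is_core],
                                  genes$origin_distance[sel][!is_core])$p_two_sided
      md_c <- stats::median(genes$origin_distance[sel][is_core])
      md_n <- stats::median(genes$origin_distance[sel][!is_core])
      direction <- if (md_c < md_n) "core_shorter"
                   else if (md_c > md_n) "core_longer" else "equal"
    }
    data.frame(bin = b, n_core = n_core, n_noncore = n_non,
               usable = usable, p_expression = p_expr,
               p_distance = p_dist, direction = direction,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sig <- tab$usable & !is.na(tab$p_distance) & tab$p_distance < alpha
  structure(list(bins = tab, n_bins = n_bins, alpha = alpha,
                 n_usable = sum(tab$usable),
                 n_significant_distance = sum(sig),
                 n_significant_core_shorter =
                   sum(sig & tab$direction == "core_shorter")),
            class = "bin_report")
}

#' @export
print.bin_report <- function(x, ...) {
  cat(sprintf(paste0("Expression-binned confound analysis: %d bins, ",
                     "%d usable (both categories present)\n"),
              x$n_bins, x$n_usable))
  cat(sprintf(paste0("Origin distance differs (P < %g) in %d of %d usable ",
                     "bins (%d with core genes closer to origins)\n"),
              x$alpha, x$n_significant_distance, x$n_usable,
              x$n_significant_core_shorter))
  invisible(x)
}

#' Rank correlation on a gene subset
#'
#' [spearman_test()] restricted to genes passing a predicate, typically a
#' category filter: e.g. excluding transcription/translation genes, or
#' restricting to core or non-core genes, to test whether a distance
#' gradient survives the restriction.
#'
#' @param genes Gene table.
#' @param value_a,value_b Column names of the two variables.
#' @param include Either a predicate `function(genes) -> logical` or
#'   `NULL` for all genes. The helpers [exclude_categories()] and
#'   [only_category()] build common predicates.
#' @return A `stat_result` from [spearman_test()] on the filtered rows
#'   with both values non-missing.
#' @export
correlate_subset <- function(genes, value_a, value_b, include = NULL) {
  keep <- if (is.null(include)) rep(TRUE, nrow(genes)) else include(genes)
  if (length(keep) != nrow(genes) || !is.logical(keep))
    stop("include must return one logical per gene")
  sub <- genes[keep & !is.na(genes[[value_a]]) & !is.na(genes[[value_b]]), ]
  if (nrow(sub) < 3L) stop("fewer than 3 genes pass the filter")
  spearman_test(sub[[value_a]], sub[[value_b]])
}

#' Category predicates for [correlate_subset()]
#'
#' `exclude_categories(labels)` keeps genes carrying none of the labels;
#' `only_category(label)` keeps genes carrying it; `not_category(label)`
#' keeps genes lacking it.
#'
#' @param labels,label Category label(s).
#' @return A predicate function over a gene table.
#' @export
exclude_categories <- function(labels) {
  function(genes) {
    drop <- Reduce(`|`, lapply(labels, function(l) has_category(genes, l)),
                   accumulate = FALSE, init = rep(FALSE, nrow(genes)))
    !drop
  }
}

#' @rdname exclude_categories
#' @export
only_category <- function(label) function(genes) has_category(genes, label)

#' @rdname exclude_categories
#' @export
not_category <- function(label) function(genes) !has_category(genes, label)

#' Pairwise rank correlations between window feature tracks
#'
#' All pairwise Spearman correlations among feature tracks sharing one
#' window set, the window-level analogue of a feature correlation table.
#' For each pair, windows missing either value are dropped.
#'
#' @param tracks A `data.frame` of one column per feature (plus optional
#'   `start`/`midpoint` columns, ignored), rows = windows; typically from
#'   [window_features()].
#' @return A tidy `data.frame` with columns `feature_a`, `feature_b`,
#'   `rho`, `p`, `n`, `method`, one row per unordered feature pair.
#' @export
feature_correlations <- function(tracks) {
  feats <- setdiff(names(tracks), c("start", "midpoint", "end"))
  if (length(feats) < 2L) stop("need at least two feature columns")
  pairs <- utils::combn(feats, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    x <- tracks[[pr[1L]]]; y <- tracks[[pr[2L]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) stop("fewer than 3 complete window pairs for ",
                           pr[1L], " vs ", pr[2L])
    st <- spearman_test(x[ok], y[ok])
    data.frame(feature_a = pr[1L], feature_b = pr[2L], rho = st$statistic,
               p = st$p_two_sided, n = st$n, method = st$method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
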