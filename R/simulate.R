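#' Parameters for the synthetic-data generator
#'
#' Defines a synthetic circular genome with known, injected
#' replication-distance structure: a log2 expression gradient declining
#' with origin distance, core genes enriched near origins, transposons
#' enriched far from them, intergenic gaps widening with distance, and a
#' two-channel spot-table model with dosage-scaled cDNA in exponential
#' phase. Defaults describe the scaled-down test genome (200 kb, three
#' unevenly spaced origins, ~200 genes); [sim_params_paper_scale()] gives
#' the 2.2 Mb configuration.
#'
#' @param length_bp Chromosome length.
#' @param origins Origin positions (three, unevenly spaced, by default).
#' @param beta0 Expression intercept (log2 units at distance 0).
#' @param beta1 Expression slope in log2 units per bp of origin distance
#'   (negative = declining away from origins).
#' @param sigma Biological expression noise sd (log2 units).
#' @param core_b0,core_b1 Logistic intercept and per-bp distance
#'   coefficient for the core-gene label (negative coefficient = core
#'   genes concentrate near origins).
#' @param tn_b0,tn_b1 Same for the transposon label (positive
#'   coefficient = transposons accumulate far from origins). Core and
#'   transposon labels are mutually exclusive (core wins).
#' @param frac_txn_translation Probability of the
#'   transcription/translation functional label, independent of
#'   distance.
#' @param gap_mean0 Mean intergenic gap at distance 0 (bp).
#' @param gap_mean_slope Increase of the mean gap per bp of origin
#'   distance.
#' @param len_meanlog,len_sdlog,len_min Lognormal gene-length parameters
#'   and minimum length (bp).
#' @param n_arrays Number of arrays (hybridisations; default 3).
#' @param n_replicate_spots Replicate spots per gene and array
#'   (default 2, duplicate printing).
#' @param low_quality_frac Fraction of spots flagged low-quality.
#' @param probe_sdlog Lognormal sd of the per-spot probe efficiency
#'   (identical in both channels, so it cancels in the ratio).
#' @param meas_sdlog Lognormal sd of per-channel measurement noise.
#' @param bg Additive background intensity (recorded in the background
#'   columns).
#' @param scale_cdna,scale_gdna Channel intensity scales.
#' @param condition `"exponential"` (cDNA dosage-scaled by the
#'   cell-cycle model) or `"stationary"` (copy number 1 everywhere).
#' @param cell_cycle A [cell_cycle_model()].
#' @param seed Mandatory integer seed; identical parameters give
#'   byte-identical output.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(length_bp = 2e5,
                       origins = c(10e3, 90e3, 160e3),
                       beta0 = 1, beta1 = -4e-5, sigma = 1,
                       core_b0 = -0.5, core_b1 = -2e-5,
                       tn_b0 = -3, tn_b1 = 3e-5,
                       frac_txn_translation = 0.08,
                       gap_mean0 = 120, gap_mean_slope = 1e-3,
                       len_meanlog = log(800), len_sdlog = 0.45,
                       len_min = 60,
                       n_arrays = 3L, n_replicate_spots = 2L,
                       low_quality_frac = 0.05,
                       probe_sdlog = 0.3, meas_sdlog = 0.1,
                       bg = 100, scale_cdna = 2000, scale_gdna = 1000,
                       condition = c("exponential", "stationary"),
                       cell_cycle = cell_cycle_model(),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  condition <- match.arg(condition)
  p <- as.list(environment())
  if (p$sigma < 0 || p$low_quality_frac < 0 || p$low_quality_frac > 1)
    stop("sigma must be >= 0 and low_quality_frac in [0, 1]")
  circular_genome(length_bp, origins)  # validates geometry
  structure(p, class = "sim_params")
}

#' Paper-scale simulation preset
#'
#' A 2.2 Mb circular chromosome with three unevenly spaced origins and
#' roughly 2,100 genes — the scale of a Sulfolobus chromosome. The
#' expression slope is calibrated with [calibrate_expression_slope()] so
#' the population gene-level Spearman correlation between measured
#' expression and origin distance is `rho_target` (default -0.41, a
#' typical observed exponential-phase gradient), accounting for the
#' gene-dosage contribution in exponential phase.
#'
#' @param seed Mandatory integer seed.
#' @param rho_target Target population Spearman correlation.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_params_paper_scale <- function(seed, rho_target = -0.41, ...) {
  length_bp <- 2.2e6
  origins <- c(1e5, 9.5e5, 1.7e6)
  genome <- circular_genome(length_bp, origins)
  model <- cell_cycle_model()
  beta1 <- calibrate_expression_slope(genome, rho_target = rho_target,
                                      sigma = 1, model = model,
                                      condition = "exponential")
  sim_params(length_bp = length_bp, origins = origins,
             beta1 = beta1, sigma = 1,
             core_b0 = -0.5, core_b1 = -3.5e-6,
             tn_b0 = -3, tn_b1 = 3.5e-6,
             gap_mean_slope = 2e-4,
             cell_cycle = model, seed = seed, ...)
}

#' Calibrate the expression slope to a target rank correlation
#'
#' For a bivariate normal pair, the population Spearman correlation
#' `rho_s` relates to the Pearson correlation by
#' `rho_p = 2 sin(pi * rho_s / 6)`. Given expression
#' `beta1 * d + noise(sigma)` and the distance distribution of the
#' genome (evaluated on a fine position grid, genes being approximately
#' uniform), the slope achieving the target is
#' `beta1 = rho_p * sigma / (sd(d) * sqrt(1 - rho_p^2))` with the sign
#' of the target. In exponential phase the log2 dosage term
#' `-s_duration * d / d_max` adds to the measured gradient and is
#' subtracted from the biological slope so the total matches the target.
#'
#' @param genome A [circular_genome()].
#' @param rho_target Target population Spearman correlation.
#' @param sigma Expression noise sd.
#' @param model A [cell_cycle_model()] (used when `condition` is
#'   exponential).
#' @param condition `"exponential"` or `"stationary"`.
#' @return The biological slope `beta1` in log2 units per bp.
#' @export
calibrate_expression_slope <- function(genome, rho_target = -0.41,
                                       sigma = 1, model = NULL,
                                       condition = "exponential") {
  grid <- seq(0, genome$length_bp - 1, by = max(1, genome$length_bp / 4096))
  sd_d <- stats::sd(circular_distance(grid, genome))
  r_p <- 2 * sin(pi * abs(rho_target) / 6)
  beta_total <- sign(rho_target) * r_p * sigma / (sd_d * sqrt(1 - r_p^2))
  if (identical(condition, "exponential") && !is.null(model)) {
    slope_dosage <- -model$s_duration / max_origin_distance(genome)
    beta_total - slope_dosage
  } else beta_total
}

# deterministic per-stage seed so e.g. adding arrays never perturbs the
# genome draw; kept below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483629)
}

#' Simulate a circular genome with injected distance structure
#'
#' Genes are placed around the circle by drawing exponential intergenic
#' gaps whose mean grows linearly with origin distance and lognormal
#' gene lengths; strands are fair coins. True log2 expression is
#' `beta0 + beta1 * d + Normal(0, sigma)` of the gene midpoint distance
#' `d`; core and transposon labels are Bernoulli draws from logistic
#' functions of `d` (mutually exclusive, core drawn first); all genes
#' are protein-coding; a distance-independent fraction carries the
#' transcription/translation label. Core genes get unique single-copy
#' COG ids, half of the non-core genes get non-core COG ids.
#'
#' @param params A [sim_params()].
#' @return A list with `genome` (a [circular_genome()]) and `genes` (a
#'   gene table whose `expression` column holds the true generative
#'   values).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  genome <- circular_genome(params$length_bp, params$origins)
  set.seed(stage_seed(params$seed, "genome"))
  L <- params$length_bp
  starts <- ends <- numeric(0)
  cur <- 0
  repeat {
    d_here <- circular_distance(cur %% L, genome)
    gap <- stats::rexp(1L, 1 / (params$gap_mean0 +
                                  params$gap_mean_slope * d_here))
    len <- max(params$len_min,
               round(stats::rlnorm(1L, params$len_meanlog,
                                   params$len_sdlog)))
    if (cur + gap + len > L) break
    starts <- c(starts, round(cur + gap))
    ends <- c(ends, round(cur + gap) + len)
    cur <- cur + gap + len
  }
  n <- length(starts)
  if (n < 2L) stop("parameters leave no room for genes")
  genes <- gene_table(gene_id = sprintf("gene%04d", seq_len(n)),
                      start = starts, end = ends %% L,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      categories = "protein_coding")
  d <- gene_origin_distance(genes, genome)
  genes$expression <- params$beta0 + params$beta1 * d +
    stats::rnorm(n, 0, params$sigma)
  is_core <- stats::runif(n) <
    stats::plogis(params$core_b0 + params$core_b1 * d)
  is_tn <- !is_core & stats::runif(n) <
    stats::plogis(params$tn_b0 + params$tn_b1 * d)
  is_txn <- stats::runif(n) < params$frac_txn_translation
  genes <- add_category(genes, "core", is_core)
  genes <- add_category(genes, "transposon", is_tn)
  genes <- add_category(genes, "txn_translation", is_txn)
  cogs <- rep(NA_character_, n)
  cogs[is_core] <- sprintf("COG%04d", seq_len(sum(is_core)))
  noncore_with_cog <- which(!is_core & stats::runif(n) < 0.5)
  cogs[noncore_with_cog] <-
    sprintf("NCOG%04d", seq_along(noncore_with_cog))
  genes$cog_id <- cogs
  validate_genes(genes, genome)
  list(genome = genome, genes = genes)
}

#' Simulate a COG copy-count matrix consistent with the core labels
#'
#' Builds a genomes-by-COGs copy matrix in which the simulated genome's
#' core COGs are single-copy in every genome while each non-core COG
#' violates the core rule somewhere (a zero-copy genome or a multi-copy
#' genome), so [call_core_cogs()] recovers exactly the simulated core
#' set. An excluded symbiont-like genome with many absences is included
#' to exercise genome exclusion.
#'
#' @param sim Output of [simulate_genome()].
#' @param n_genomes Number of non-excluded genomes (default 5).
#' @param seed Integer seed.
#' @return A list with `counts` (a [cog_matrix()]) and
#'   `excluded_genomes` (character).
#' @export
simulate_cog_matrix <- function(sim, n_genomes = 5L, seed) {
  set.seed(stage_seed(seed, "cogs"))
  cogs <- sort(unique(stats::na.omit(sim$genes$cog_id)))
  core <- grepl("^COG", cogs)
  gids <- c(sprintf("genome%02d", seq_len(n_genomes)), "symbiont")
  counts <- matrix(1L, nrow = length(cogs), ncol = length(gids),
                   dimnames = list(cogs, gids))
  # each non-core COG fails the single-copy rule in one random genome
  for (i in which(!core)) {
    j <- sample.int(n_genomes, 1L)
    counts[i, j] <- sample(c(0L, sample(2:11, 1L)), 1L)
  }
  # the excluded symbiont lacks most COGs; must not affect the core call
  counts[stats::runif(length(cogs)) < 0.7, "symbiont"] <- 0L
  list(counts = cog_matrix(counts), excluded_genomes = "symbiont")
}

#' Simulate a two-channel spot table
#'
#' For every gene, array and replicate spot: a lognormal probe
#' efficiency identical in both channels; cDNA foreground proportional
#' to `2^expression` times the locus copy number (the cell-cycle model's
#' mean copy number in exponential condition, 1 in stationary); gDNA
#' foreground proportional to 1; per-channel lognormal measurement
#' noise; constant additive background recorded in the background
#' columns; a random fraction of spots flagged low-quality.
#'
#' @param sim Output of [simulate_genome()].
#' @param params The same [sim_params()].
#' @return A spot table (see [spot_table()]).
#' @export
simulate_spot_table <- function(sim, params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params$seed, "spots"))
  genes <- sim$genes
  n <- nrow(genes)
  copy <- if (params$condition == "exponential") {
    mean_copy_number(replication_age(gene_midpoint(genes, sim$genome),
                                     sim$genome, params$cell_cycle))
  } else rep(1, n)
  idx <- expand.grid(gene = seq_len(n),
                     replicate = seq_len(params$n_replicate_spots),
                     array = seq_len(params$n_arrays))
  m <- nrow(idx)
  eff <- stats::rlnorm(m, 0, params$probe_sdlog)
  noise_c <- stats::rlnorm(m, 0, params$meas_sdlog)
  noise_g <- stats::rlnorm(m, 0, params$meas_sdlog)
  spot_table(array_id = sprintf("array%d", idx$array),
             gene_id = genes$gene_id[idx$gene],
             replicate = idx$replicate,
             fg_cdna = params$scale_cdna * eff *
               2^genes$expression[idx$gene] * copy[idx$gene] * noise_c +
               params$bg,
             bg_cdna = params$bg,
             fg_gdna = params$scale_gdna * eff * noise_g + params$bg,
             bg_gdna = params$bg,
             quality_ok = stats::runif(m) >= params$low_quality_frac)
}

#' Simulate genome and spot table in one call
#'
#' @param params A [sim_params()].
#' @return List with `genome`, `genes` (true expression) and `spots`.
#' @export
simulate_dataset <- function(params) {
  sim <- simulate_genome(params)
  sim$spots <- simulate_spot_table(sim, params)
  sim
}

#' Gradient recovery experiment over many simulation seeds
#'
#' For each seed: simulate a genome and spot table, run the full
#' spot-to-expression pipeline, annotate origin distances and record the
#' gene-level Spearman correlation between recovered expression and
#' distance. Summarises how well the injected gradient is recovered.
#'
#' @param params A [sim_params()]; its `seed` is the base, seed `+ i - 1`
#'   is used for replicate `i`.
#' @param n_seeds Number of replicates.
#' @return A `data.frame` with one row per seed: `seed`, `rho`, `p`,
#'   `n_genes`; the generative slope is attached as attribute
#'   `"beta1"`.
#' @export
recovery_experiment <- function(params, n_seeds = 20L) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    p <- params
    p$seed <- params$seed + i - 1L
    sim <- simulate_dataset(p)
    genes <- join_expression(sim$genes, normalize_expression(sim$spots))
    genes <- add_origin_distance(genes, sim$genome)
    st <- correlate_subset(genes, "expression", "origin_distance")
    data.frame(seed = p$seed, rho = st$statistic, p = st$p_two_sided,
               n_genes = st$n)
  })
  out <- do.call(rbind, rows)
  attr(out, "beta1") <- params$beta1
  out
}
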