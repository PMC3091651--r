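# Independent brute-force oracles used by the property tests. These are
# deliberately naive (per-bp loops, full enumeration) and share no code
# with the package internals.

oracle_circular_distance <- function(pos, L, origins) {
  min(vapply(origins, function(o)
    min((pos - o) %% L, (o - pos) %% L), numeric(1L)))
}

# per-bp boolean coverage of protein-coding genes over [a, a + ilen)
oracle_coding_density <- function(genes, a, ilen, L) {
  len <- (genes$end - genes$start) %% L
  len[len == 0] <- L
  pc <- has_category(genes, "protein_coding")
  covered <- vapply(seq_len(ilen) - 1L, function(off) {
    bp <- (a + off) %% L
    any(pc & ((bp - genes$start) %% L) < len)
  }, logical(1L))
  mean(covered)
}

# all permutations of v as a matrix, one per row (n <= 7 in tests)
all_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], all_perms(v[-i]))))
}

oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  pm <- all_perms(ry)
  rhos <- apply(pm, 1L, function(p) cor(rx, p))
  mean(abs(rhos) >= obs - 1e-12)
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values into groups of sizes n1, n2
oracle_mw_p <- function(a, b) {
  n1 <- length(a); pooled <- c(a, b); N <- length(pooled)
  u_of <- function(idx) sum(outer(pooled[idx], pooled[-idx], ">")) +
    0.5 * sum(outer(pooled[idx], pooled[-idx], "=="))
  u_all <- combn(N, n1, u_of)
  u_obs <- u_of(seq_len(n1))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# small random gene table on a circle, optionally wrap-around genes
random_gene_table <- function(L, n, wrap_ok = TRUE) {
  starts <- sort(sample.int(L, n) - 1L)
  lens <- sample(1:max(2L, L %/% (2L * n)), n, replace = TRUE)
  ends <- if (wrap_ok) (starts + lens) %% L else pmin(starts + lens, L)
  gene_table(sprintf("g%03d", seq_len(n)), starts, ends,
             sample(c("+", "-"), n, replace = TRUE),
             categories = ifelse(runif(n) < 0.7, "protein_coding", ""))
}

# tiny deterministic spot table used across expression tests
toy_spots <- function() {
  spot_table(
    array_id = rep(c("a1", "a2"), each = 4),
    gene_id = rep(c("g1", "g1", "g2", "g2"), 2),
    replicate = rep(1:2, 4),
    fg_cdna = c(500, 900, 300, 300, 500, 500, 700, 700),
    bg_cdna = 100,
    fg_gdna = c(300, 300, 300, 300, 300, 300, 300, 300),
    bg_gdna = 100,
    quality_ok = TRUE)
}
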