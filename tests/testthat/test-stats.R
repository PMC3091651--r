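test_that("spearman handles monotone, degenerate and invalid input", {
  expect_equal(spearman_test(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_test(1:8, -(1:8)^3)$statistic, -1)
  expect_error(spearman_test(1:2, 1:2), "at least 3")
  expect_error(spearman_test(1:4, 1:3), "equal length")
  expect_error(spearman_test(1:5, rep(1, 5)), "zero rank variance")
  # invariant under strictly monotone transforms
  set.seed(91)
  x <- rnorm(30); y <- rnorm(30)
  a <- spearman_test(x, y)
  b <- spearman_test(exp(x), rank(y)^3)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_two_sided, b$p_two_sided)
})

test_that("exact spearman p equals the permutation fraction", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:7, 1)
    x <- sample(100, n); y <- sample(100, n)   # tie-free
    got <- spearman_test(x, y)
    expect_equal(got$method, "spearman_exact")
    expect_equal(got$p_two_sided, oracle_spearman_p(x, y))
  }
})

test_that("exact spearman agrees with cor.test at n = 9 and 10", {
  set.seed(103)
  for (n in 9:10) {
    x <- sample(1000, n); y <- sample(1000, n)
    got <- spearman_test(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$statistic, unname(ref$estimate))
    # cor.test enumerates exactly only for n <= 9; at n = 10 it falls
    # back to the AS 89 series approximation, hence the loose tolerance
    tol <- if (n <= 9) 1e-12 else 5e-4
    expect_equal(got$p_two_sided, ref$p.value, tolerance = tol)
  }
})

test_that("t-approximate spearman p tracks exact enumeration at n = 10", {
  set.seed(107)
  for (i in 1:100) {
    x <- sample(1000, 10); y <- sample(1000, 10)
    st <- spearman_test(x, y)
    exact <- st$p_two_sided
    rho <- st$statistic
    tt <- rho * sqrt(8 / (1 - rho^2))
    approx <- 2 * pt(-abs(tt), df = 8)
    expect_lt(abs(approx - exact), 0.02)
  }
})

test_that("spearman p is uniform under the null", {
  set.seed(109)
  rej <- replicate(1000, {
    spearman_test(rnorm(50), rnorm(50))$p_two_sided < 0.05
  })
  halfwidth <- 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), halfwidth)
})

test_that("mann-whitney matches hand enumeration and wilcox.test", {
  a <- mann_whitney_test(c(1, 2), c(3, 4))
  expect_equal(a$statistic, 0)
  expect_equal(a$p_two_sided, 2 / 6)
  b <- mann_whitney_test(1, c(2, 3, 4))
  expect_equal(b$p_two_sided, 0.5)
  ident <- mann_whitney_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 4.5)               # n1 n2 / 2 with ties
  expect_error(mann_whitney_test(numeric(0), 1), "non-empty")
  set.seed(113)
  x <- rnorm(6); y <- rnorm(9)
  expect_equal(mann_whitney_test(x, y)$p_two_sided,
               wilcox.test(x, y, exact = TRUE)$p.value)
  x2 <- rnorm(20); y2 <- rnorm(25)
  expect_equal(mann_whitney_test(x2, y2)$p_two_sided,
               wilcox.test(x2, y2, exact = FALSE,
                           correct = TRUE)$p.value)
})

test_that("exact mann-whitney p equals assignment enumeration, 2v2-4v4", {
  set.seed(127)
  for (n1 in 2:4) for (n2 in 2:4) for (rep in 1:10) {
    a <- runif(n1); b <- runif(n2)
    got <- mann_whitney_test(a, b)
    expect_equal(got$method, "mw_exact")
    expect_equal(got$p_two_sided, oracle_mw_p(a, b))
  }
})

test_that("expression bins are contiguous, stable and near-equal sized", {
  genes <- gene_table(sprintf("g%02d", 1:24), (0:23) * 10,
                      (0:23) * 10 + 5, "+", "protein_coding",
                      expression = rev(seq(0.1, 2.4, by = 0.1)))
  bins <- expression_bins(genes, 12)
  expect_true(all(table(bins) == 2))
  expect_equal(bins[24], 1L)   # lowest expression lands in bin 1
  genes25 <- rbind(genes, gene_table("g25", 240, 245, "+",
                                     "protein_coding",
                                     expression = 0.05))
  sizes <- table(expression_bins(genes25, 12))
  expect_equal(as.integer(sizes), c(3L, rep(2L, 11)))  # remainder first
  expect_equal(unname(table(expression_bins(genes, 1))[1]), 24L)
  expect_error(expression_bins(genes[1:5, ], 12), "fewer genes")
  # NA expression stays unbinned
  genes$expression[3] <- NA
  expect_true(is.na(expression_bins(genes, 4)[3]))
})

test_that("bin confound analysis detects an injected distance offset", {
  set.seed(131)
  n <- 240
  core <- rep(c(TRUE, FALSE), n / 2)
  genes <- gene_table(sprintf("g%03d", 1:n), (0:(n - 1)) * 10,
                      (0:(n - 1)) * 10 + 5, "+",
                      ifelse(core, "protein_coding,core",
                             "protein_coding"),
                      expression = rnorm(n))
  genes$origin_distance <- runif(n, 100, 200) - ifelse(core, 90, 0)
  rep12 <- bin_confound_analysis(genes, 12)
  expect_equal(rep12$n_usable, 12L)
  expect_equal(rep12$n_significant_distance, 12L)
  expect_true(all(rep12$bins$direction[rep12$bins$usable] ==
                    "core_shorter"))
  all_core <- genes
  all_core$categories <- "protein_coding,core"
  expect_equal(bin_confound_analysis(all_core, 12)$n_usable, 0L)
})

test_that("subset correlations equal direct recomputation", {
  set.seed(137)
  n <- 20
  genes <- gene_table(sprintf("g%02d", 1:n), (0:(n - 1)) * 50,
                      (0:(n - 1)) * 50 + 25, "+",
                      ifelse(seq_len(n) <= 10, "protein_coding",
                             "protein_coding,transposon"),
                      expression = rnorm(n))
  genes$origin_distance <- runif(n, 0, 1000)
  full <- correlate_subset(genes, "expression", "origin_distance")
  expect_equal(full$statistic,
               spearman_test(genes$expression,
                             genes$origin_distance)$statistic)
  # excluding an absent category changes nothing
  same <- correlate_subset(genes, "expression", "origin_distance",
                           exclude_categories("rrna_trna"))
  expect_equal(same$p_two_sided, full$p_two_sided)
  sub <- correlate_subset(genes, "expression", "origin_distance",
                          not_category("transposon"))
  byhand <- spearman_test(genes$expression[1:10],
                          genes$origin_distance[1:10])
  expect_equal(sub$statistic, byhand$statistic)
  expect_equal(sub$p_two_sided, byhand$p_two_sided)
})

test_that("window-track correlation table matches pairwise recomputation", {
  set.seed(139)
  n <- 22
  tracks <- data.frame(start = (0:(n - 1)) * 1e5,
                       midpoint = (0:(n - 1)) * 1e5 + 5e4,
                       f1 = sort(rnorm(n)),
                       f2 = sort(rnorm(n)) + rnorm(n, 0, 0.3),
                       f3 = rnorm(n))
  tab <- feature_correlations(tracks)
  expect_equal(nrow(tab), 3L)
  row12 <- tab[tab$feature_a == "f1" & tab$feature_b == "f2", ]
  byhand <- spearman_test(tracks$f1, tracks$f2)
  expect_equal(row12$rho, byhand$statistic)
  expect_equal(row12$p, byhand$p_two_sided)
  # monotone transform leaves rank correlation at 1
  tracks2 <- data.frame(f1 = 1:10, f2 = exp(1:10 / 3))
  expect_equal(feature_correlations(tracks2)$rho, 1)
  # missing windows dropped pairwise
  tracks$f3[1:3] <- NA
  tab2 <- feature_correlations(tracks)
  expect_equal(tab2$n[tab2$feature_a == "f1" & tab2$feature_b == "f3"],
               19)
  expect_equal(tab2$n[tab2$feature_a == "f1" & tab2$feature_b == "f2"],
               22)
})
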