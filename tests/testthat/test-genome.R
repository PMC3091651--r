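test_that("circular genome construction enforces its invariants", {
  expect_error(circular_genome(100, numeric(0)), "at least one")
  expect_error(circular_genome(100, c(10, 10)), "strictly increasing")
  expect_error(circular_genome(100, 100), "\\[0, length_bp\\)")
  g <- circular_genome(100, c(0, 40))
  expect_s3_class(g, "circular_genome")
})

test_that("origin distance handles identity, antipode and two-origin cases", {
  g <- circular_genome(100, c(0, 40))
  expect_equal(circular_distance(0, g), 0)
  expect_equal(circular_distance(40, g), 0)
  expect_equal(circular_distance(90, g), 10)   # wrap arc to origin 0
  expect_equal(circular_distance(5, circular_genome(10, 0)), 5)
  expect_error(circular_distance(100, g), "out of range")
  expect_error(circular_distance(-1, g), "out of range")
})

test_that("origin distance matches brute force and is bounded by L/2", {
  set.seed(11)
  for (i in 1:300) {
    L <- sample(10:5000, 1)
    origins <- sort(sample.int(L, sample(1:5, 1)) - 1L)
    pos <- sample.int(L, 1) - 1L
    d <- circular_distance(pos, circular_genome(L, origins))
    expect_equal(d, oracle_circular_distance(pos, L, origins))
    expect_lte(d, L / 2)
    expect_identical(d == 0, pos %in% origins)
  }
})

test_that("gene midpoint distance uses the modular midpoint", {
  g <- circular_genome(100, 0)
  expect_equal(gene_origin_distance(
    gene_table("a", 10, 20, "+"), g), 15)
  expect_equal(gene_origin_distance(
    gene_table("a", 95, 5, "+"), g), 0)      # wrap-around gene
  expect_equal(gene_origin_distance(
    gene_table("a", 95, 5, "+"), circular_genome(100, 50)), 50)
})

test_that("gene coordinate validation rejects bad input", {
  g <- circular_genome(100, 0)
  expect_error(validate_genes(gene_table("a", 100, 5, "+"), g),
               "out of range")
  expect_error(validate_genes(gene_table("a", 5, 5, "+"), g),
               "gene length")
  expect_error(validate_genes(gene_table("a", 5, 10, "*"), g), "strand")
})

test_that("divergent pairs: orientation filter, gaps, overlap clamping", {
  g <- circular_genome(1000, 0)
  same <- gene_table(c("a", "b"), c(0, 150), c(100, 200), "+",
                     "protein_coding")
  expect_equal(nrow(divergent_pair_gaps(same, g)), 0L)
  # convergent orientation excluded (the wrap pair b->a around the
  # circle is genuinely divergent, so only check the a->b pair)
  conv <- gene_table(c("a", "b"), c(0, 150), c(100, 200), c("+", "-"),
                     "protein_coding")
  expect_false(any(divergent_pair_gaps(conv, g)$upstream == "a"))
  div <- gene_table(c("a", "b"), c(0, 150), c(100, 200), c("-", "+"),
                    "protein_coding")
  got <- divergent_pair_gaps(div, g)
  expect_equal(got$gap, 50)
  expect_equal(got$midpoint, 125)
  over <- gene_table(c("a", "b"), c(0, 80), c(100, 200), c("-", "+"),
                     "protein_coding")
  expect_equal(divergent_pair_gaps(over, g)$gap, 0)
  expect_error(divergent_pair_gaps(div[2:1, ], g), "sorted")
})

test_that("divergent pairs include the wrap pair across position 0", {
  g <- circular_genome(1000, 0)
  genes <- gene_table(c("a", "b"), c(100, 900), c(200, 950),
                      c("+", "-"), "protein_coding")
  got <- divergent_pair_gaps(genes, g)   # b (-) upstream wraps to a (+)
  expect_equal(got$upstream, "b")
  expect_equal(got$gap, 150)             # 950 -> 1000 -> 100
})

test_that("divergent gaps are invariant under coordinate rotation", {
  set.seed(21)
  for (i in 1:40) {
    L <- sample(200:2000, 1)
    genes <- random_gene_table(L, sample(4:12, 1), wrap_ok = FALSE)
    genome <- circular_genome(L, sort(sample.int(L, 2) - 1L))
    genes <- genes[order(genes$start), ]
    base <- sort(divergent_pair_gaps(genes, genome)$gap)
    rot <- rotate_coordinates(genes, genome, sample.int(L, 1))
    expect_equal(sort(divergent_pair_gaps(rot$genes, rot$genome)$gap),
                 base)
  }
})

test_that("coding density: trivial cases and union (not sum) coverage", {
  g <- circular_genome(100, 0)
  none <- gene_table("a", 10, 20, "+", categories = "")
  expect_equal(coding_density(none, c(0, 100), g), 0)
  full <- gene_table("a", 0, 100, "+", "protein_coding")
  expect_equal(coding_density(full, c(0, 100), g), 1)
  two <- gene_table(c("a", "b"), c(0, 30), c(40, 60), "+",
                    "protein_coding")
  expect_equal(coding_density(two, c(0, 100), g), 0.6)
  expect_error(coding_density(two, c(5, 5), g), "zero-length")
})

test_that("coding density equals per-bp coverage on random instances", {
  set.seed(31)
  for (i in 1:120) {
    L <- sample(50:1000, 1)
    genes <- random_gene_table(L, sample(2:8, 1))
    genome <- circular_genome(L, 0)
    a <- sample.int(L, 1) - 1L
    ilen <- sample.int(L - 1L, 1)
    got <- coding_density(genes, c(a, (a + ilen) %% L), genome)
    expect_equal(got, oracle_coding_density(genes, a, ilen, L))
  }
})
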