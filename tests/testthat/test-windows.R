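test_that("window construction covers the circle as specified", {
  g <- circular_genome(10, 0)
  w <- make_windows(g, 4, 2, "sliding")
  expect_equal(w$start, c(0, 2, 4, 6, 8))
  expect_equal(w$end, c(4, 6, 8, 0, 2))   # modular ends
  g1 <- circular_genome(100, 0)
  expect_equal(nrow(make_windows(g1, 100, 100, "nonoverlapping")), 1L)
  g2 <- circular_genome(2.2e6, 0)
  expect_equal(nrow(make_windows(g2, 1e5, 1e5, "nonoverlapping")), 22L)
  expect_equal(nrow(make_windows(g2, 1e5, 1e3, "sliding")), 2200L)
  expect_error(make_windows(g1, 10, 20), "step_bp")
  expect_error(make_windows(g1, 200, 10), "exceeds")
})

test_that("each midpoint falls in exactly size/step sliding windows", {
  set.seed(61)
  for (i in 1:25) {
    step <- sample(c(5, 10, 20), 1)
    size <- step * sample(2:5, 1)
    L <- step * sample(30:80, 1)
    genome <- circular_genome(L, 0)
    w <- make_windows(genome, size, step, "sliding")
    mids <- runif(20, 0, L - 1e-6)
    hits <- vapply(mids, function(m)
      sum(((m - w$start) %% L) < size), numeric(1L))
    expect_true(all(hits == size / step))
  }
})

test_that("window features follow their definitions on a toy genome", {
  g <- circular_genome(200, 0)
  genes <- gene_table(sprintf("g%d", 1:6),
                      start = c(10, 40, 60, 110, 140, 170),
                      end = c(30, 55, 80, 130, 160, 190),
                      strand = c("-", "+", "+", "+", "+", "+"),
                      categories = c("protein_coding,core",
                                     "protein_coding",
                                     "protein_coding,core",
                                     "protein_coding,transposon",
                                     "protein_coding", ""),
                      expression = c(1, 3, NA, 2, 4, 0))
  w <- make_windows(g, 100, 100, "nonoverlapping")
  tr <- window_features(genes, g, w)
  expect_equal(tr$mean_expression, c(2, 2))       # NA ignored
  expect_equal(tr$core_proportion, c(2 / 3, 0))   # coding members only
  expect_equal(tr$transposon_proportion, c(0, 1 / 3))
  expect_equal(tr$coding_density, c(55 / 100, 40 / 100))
  expect_equal(tr$origin_distance, c(50, 50))     # window midpoints
  # one divergent pair: g1(-) then g2(+), gap 10, midpoint 35
  expect_equal(tr$mean_divergent_gap, c(10, NA))
})

test_that("empty windows yield missing values", {
  g <- circular_genome(1000, 0)
  genes <- gene_table("g1", 10, 60, "+", "protein_coding",
                      expression = 1)
  w <- make_windows(g, 100, 100, "nonoverlapping")
  tr <- window_track(genes, g, w, "mean_expression")
  expect_equal(tr$value[1], 1)
  expect_true(all(is.na(tr$value[-1])))
})

test_that("non-overlapping window means match brute-force recomputation", {
  set.seed(71)
  for (i in 1:20) {
    L <- 1000
    genes <- random_gene_table(L, sample(10:30, 1))
    genes$expression <- rnorm(nrow(genes))
    genome <- circular_genome(L, sort(sample.int(L, 2) - 1L))
    w <- make_windows(genome, 100, 100, "nonoverlapping")
    tr <- window_track(genes, genome, w, "mean_expression")
    mid <- gene_midpoint(genes, genome)
    for (k in seq_len(nrow(w))) {
      inw <- mid >= w$start[k] & mid < w$start[k] + 100
      want <- if (any(inw)) mean(genes$expression[inw]) else NA_real_
      expect_equal(tr$value[k], want)
    }
  }
})

test_that("tracks are equivariant under coordinate rotation", {
  set.seed(81)
  L <- 1000
  genes <- random_gene_table(L, 25, wrap_ok = FALSE)
  genes$expression <- rnorm(25)
  genome <- circular_genome(L, c(100, 600))
  w <- make_windows(genome, 100, 50, "sliding")
  base <- window_features(genes, genome, w)
  shift <- 250   # multiple of the step so window starts map onto starts
  rot <- rotate_coordinates(genes, genome, shift)
  rot$genes$expression <- genes$expression[match(rot$genes$gene_id,
                                                 genes$gene_id)]
  rotated <- window_features(rot$genes, rot$genome, w)
  perm <- match((w$start - shift) %% L, w$start)
  for (f in c("origin_distance", "mean_expression", "coding_density",
              "core_proportion"))
    expect_equal(rotated[[f]], base[[f]][perm])
})
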