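test_that("rarefaction is an exact subsample with the right expectation", {
  x <- c(A = 80, B = 20)
  # identity at full depth
  expect_equal(rarefyCounts(x, 100), x)
  # short rows are excluded, not an error
  expect_null(rarefyCounts(x, 200))
  # hypergeometric expectation over many seeds
  draws <- vapply(1:4000, function(s) rarefyCounts(x, 50, seed = s),
                  numeric(2))
  expect_true(all(colSums(draws) == 50))
  expect_true(all(draws <= c(80, 20)))
  expect_equal(mean(draws["A", ]), 40, tolerance = 0.02)
  # seed-reproducible
  expect_identical(rarefyCounts(x, 50, seed = 1),
                   rarefyCounts(x, 50, seed = 1))
})

test_that("corrected depth divides counts by copy numbers", {
  expect_equal(correctedDepth(c(10, 10), c(1, 1)), 20)
  expect_equal(correctedDepth(c(A = 10, B = 9), c(A = 2, B = 3)), 8)
  # uniform copy number 3.88: 1940 raw reads represent 500 cells
  x <- rep(97, 20)  # total 1940
  expect_equal(correctedDepth(x, rep(3.88, 20)), 500)
})

test_that("the QMP depth optimiser matches the worked examples", {
  # three samples, loads and corrected depths chosen so the smallest d_s
  # retains everyone
  counts <- rbind(s1 = c(g1 = 20000L, g2 = 0L),
                  s2 = c(g1 = 4000L, g2 = 0L),
                  s3 = c(g1 = 30000L, g2 = 0L))
  co <- MicrobiomeCohort(counts, participant = c("p1", "p2", "p3"),
                         day = c(0L, 0L, 0L), unit = "reads",
                         sample_id = rownames(counts),
                         load = c(1e10, 1e10, 2e10),
                         copy_numbers = c(g1 = 1, g2 = 1))
  qb <- buildQMP(co, min_reads = 500, seed = 1)
  expect_equal(qb@target_depth, 4e-7)
  expect_setequal(qb@retained, c("s1", "s2", "s3"))
  expect_equal(unname(qb@rarefied_reads[c("s1", "s2", "s3")]),
               c(4000, 4000, 8000))

  # sample 2 drops below the minimum-read floor: optimum moves up
  counts2 <- counts; counts2["s2", "g1"] <- 400L
  co2 <- MicrobiomeCohort(counts2, participant = c("p1", "p2", "p3"),
                          day = c(0L, 0L, 0L), unit = "reads",
                          sample_id = rownames(counts2),
                          load = c(1e10, 1e10, 2e10),
                          copy_numbers = c(g1 = 1, g2 = 1))
  qb2 <- buildQMP(co2, min_reads = 500, seed = 1)
  expect_equal(qb2@target_depth, 1.5e-6)
  expect_setequal(qb2@retained, c("s1", "s3"))
  expect_equal(unname(qb2@excluded_reason["s2"]), "low_reads")
})

test_that("QMP retention equals the brute-force maximum over candidate depths", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    loads <- 10^runif(n, 10, 11.3)
    depths <- round(10^runif(n, 2.3, 4.5))
    counts <- matrix(0L, n, 2,
                     dimnames = list(sprintf("s%02d", 1:n), c("g1", "g2")))
    counts[, 1] <- as.integer(depths)
    co <- MicrobiomeCohort(counts, participant = sprintf("p%02d", 1:n),
                           day = rep(0L, n), unit = "reads",
                           sample_id = rownames(counts), load = loads,
                           copy_numbers = c(g1 = 1, g2 = 1))
    d_s <- depths / loads
    brute <- max(vapply(d_s, function(D)
      sum(d_s >= D & round(D * loads) >= 500 & depths >= 500), numeric(1)))
    if (brute == 0) next
    qb <- buildQMP(co, min_reads = 500, seed = rep)
    expect_equal(length(qb@retained), brute)
    expect_true(all(qb@rarefied_reads >= 500))
  }
})

test_that("QMP with equal loads preserves RMP ordering and inverts the
           copy-number distortion at depth", {
  # two genera with very different copy numbers, equal loads
  set.seed(7)
  cells <- matrix(rmultinom(1, 1e6, c(0.6, 0.3, 0.1)), 1)
  cn <- c(g1 = 8, g2 = 2, g3 = 1)
  reads <- as.integer(round(cells * cn / 2))
  counts <- matrix(reads, 1, dimnames = list("s1", names(cn)))
  co <- MicrobiomeCohort(counts, "p1", 0L, unit = "reads",
                         sample_id = "s1", load = 1e11, copy_numbers = cn)
  qb <- buildQMP(co, min_reads = 500, seed = 3)
  got <- abundances(qb@qmp)[, 1] / 1e11
  expect_equal(unname(got), c(0.6, 0.3, 0.1), tolerance = 0.02)
})

test_that("alpha diversity follows the standard formulas", {
  r <- alphaDiversity(c(5, 5))
  expect_equal(r$richness, 2)
  expect_equal(r$shannon, log(2))
  expect_equal(r$pielou, 1)
  r1 <- alphaDiversity(c(7, 0, 0))
  expect_equal(r1$richness, 1)
  expect_equal(r1$shannon, 0)
  expect_true(is.na(r1$pielou))
  r2 <- alphaDiversity(c(3, 1))
  expect_equal(r2$shannon, -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(r2$pielou, r2$shannon / log(2), tolerance = 1e-12)
  r3 <- alphaDiversity(c(0, 0))
  expect_true(all(is.na(r3)))
})

test_that("the abundance filter keeps and drops genera as stated", {
  counts <- rbind(s1 = c(big = 900L, small = 4L, mid = 96L),
                  s2 = c(big = 950L, small = 3L, mid = 47L))
  co <- MicrobiomeCohort(counts, c("p1", "p2"), c(0L, 0L), unit = "reads",
                         sample_id = rownames(counts))
  # 'small' peaks at 0.4% -> dropped at the default 0.5% threshold
  expect_setequal(filterGenera(co), c("big", "mid"))
  expect_setequal(filterGenera(co, min_rel_abundance = 0),
                  c("big", "small", "mid"))
})
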