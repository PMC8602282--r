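test_that("Bray-Curtis matches hand arithmetic and a naive double loop", {
  m <- rbind(x = c(2, 0, 1), y = c(1, 1, 0))
  expect_equal(as.numeric(brayCurtis(m)), 0.6)
  expect_equal(as.numeric(brayCurtis(rbind(a = c(1, 2), b = c(1, 2)))), 0)
  expect_equal(as.numeric(brayCurtis(rbind(a = c(1, 0), b = c(0, 3)))), 1)
  set.seed(5)
  r <- matrix(rexp(6 * 9), 6)
  expect_equal(as.matrix(brayCurtis(r)), unname(bruteBC(r)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PCoA reproduces planar configurations and keeps negative
           eigenvalues", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  r3 <- pcoaOrdination(d3)
  pos <- r3$eigenvalues[r3$eigenvalues > 1e-8]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  set.seed(8)
  pts <- matrix(rnorm(14), 7, 2)
  d <- as.matrix(dist(pts))
  r <- pcoaOrdination(d, k = 2)
  # Procrustes-align the recovered coordinates onto the originals
  a <- scale(r$coordinates, scale = FALSE)
  b <- scale(pts, scale = FALSE)
  sv <- svd(t(b) %*% a)
  rot <- sv$v %*% t(sv$u)
  expect_lt(max(abs(a %*% rot - b)), 1e-9)
  # eigenvalue sum equals the trace of the centred Gower matrix: for
  # Euclidean input all eigenvalues are >= 0
  expect_true(all(r$eigenvalues > -1e-9))
  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("dispersion testing is calibrated and detects scale differences", {
  set.seed(31)
  # translated identical clouds: equal dispersion, high p
  base <- matrix(rnorm(40), 20, 2)
  pts <- rbind(base, base + 5)
  d <- dist(pts)
  r <- dispersionTest(d, rep(c("a", "b"), each = 20))
  expect_equal(unname(r$dispersion["a"]), unname(r$dispersion["b"]),
               tolerance = 1e-9)
  expect_gt(r$p, 0.9)
  # one cloud scaled x3: significant in most replicates
  hits <- mean(vapply(1:60, function(i) {
    a <- matrix(rnorm(24), 12, 2)
    b <- matrix(rnorm(24, sd = 3), 12, 2) + 5
    dispersionTest(dist(rbind(a, b)), rep(c("a", "b"), each = 12))$p < 0.05
  }, logical(1)))
  expect_gte(hits, 0.9)
  # type-I error under exchangeable groups
  set.seed(77)
  fp <- mean(vapply(1:400, function(i) {
    pts <- matrix(rnorm(48), 24, 2)
    dispersionTest(dist(pts), rep(c("a", "b"), each = 12))$p < 0.05
  }, logical(1)))
  expect_lt(abs(fp - 0.05), 0.03)
  expect_warning(dispersionTest(dist(matrix(rnorm(14), 7)),
                                c("a", "a", "a", "b", "b", "b", "c")),
                 "singleton")
})

test_that("within- vs between-subject dispersion separates tight series", {
  sim <- simulateCohort(cohortSpec(n_participants = 6, n_days = 15,
                                   n_genera = 40, seed = 12))
  qb <- buildQMP(sim$cohort, seed = 1)
  r <- withinBetweenDispersion(qb@qmp)
  expect_equal(nrow(r), 6)
  expect_true(all(r$within < r$between))
  expect_true(all(r$q <= 1 & r$q >= r$p - 1e-12))
})

test_that("similarity decay is flat for exchangeable series and negative
           under drift", {
  set.seed(9)
  G <- 25
  mkseries <- function(drift = 0) {
    base <- rexp(G, 1 / 100)
    t(vapply(0:29, function(d)
      base * exp(drift * d) + rexp(G, 1 / 20), numeric(G)))
  }
  mkco <- function(m) {
    rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
    colnames(m) <- paste0("g", seq_len(ncol(m)))
    MicrobiomeCohort(m, rep("p1", nrow(m)), seq_len(nrow(m)) - 1L,
                     unit = "cells_per_gram", sample_id = rownames(m))
  }
  # exchangeable: slope within 2 SE of zero in most replicates
  ok <- mean(vapply(1:40, function(i) {
    f <- similarityDecay(mkco(mkseries()), max_days = 15, seed = i)$fit
    abs(f$slope) < 2 * f$slope_se
  }, logical(1)))
  expect_gte(ok, 0.85)
  # drifting series: decay detected
  f <- similarityDecay(mkco(mkseries(drift = 0.15)), max_days = 15,
                       seed = 3)$fit
  expect_lt(f$slope, 0)
  expect_lt(f$p, 0.05)
  # balanced design bookkeeping
  expect_equal(f$n_pairs, f$pairs_per_day * f$max_days)
  expect_error(similarityDecay(mkco(mkseries()), max_days = 99),
               "span")
})

test_that("interpolation only bridges short gaps", {
  m <- matrix(c(10, 20, 40, 80), 1)
  r <- mbtemporal:::.interpDaily(m, days = c(0, 1, 2, 3), max_gap = 3)
  expect_equal(as.numeric(r$mat), c(10, 20, 40, 80))
  # a 5-day hole with max_gap 3 stays missing
  r2 <- mbtemporal:::.interpDaily(matrix(c(10, 80), 1), days = c(0, 5),
                                  max_gap = 3)
  expect_true(all(!r2$complete[2:5]))
  expect_true(r2$complete[1] && r2$complete[6])
  # a 2-day hole is interpolated linearly
  r3 <- mbtemporal:::.interpDaily(matrix(c(10, 40), 1), days = c(0, 2),
                                  max_gap = 3)
  expect_equal(as.numeric(r3$mat), c(10, 25, 40))
  expect_true(all(r3$complete))
})
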