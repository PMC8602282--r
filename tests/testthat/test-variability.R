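test_that("ICC matches the hand-computed ANOVA example", {
  r <- iccAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$var_among, (13.5 - 1) / 3, tolerance = 1e-12)
  expect_equal(r$var_within, 1, tolerance = 1e-12)
  expect_equal(r$icc, 4.1666667 / 5.1666667, tolerance = 1e-6)
  # constant-within, differing means: all variance among groups
  r2 <- iccAnova(rep(c(1, 5, 9), each = 4), rep(c("a", "b", "c"), each = 4))
  expect_equal(r2$var_within, 0)
  expect_equal(r2$icc, 1)
  # zero total variance is undefined
  expect_true(is.na(iccAnova(rep(2, 6), rep(c("a", "b"), each = 3))$icc))
})

test_that("ICC equals a brute-force variance-components oracle on random
           instances", {
  set.seed(10)
  for (k in 2:6) for (n in 2:6) {
    v <- rnorm(k * n)
    g <- rep(seq_len(k), each = n)
    expect_equal(iccAnova(v, g)$icc, bruteICC(v, g), tolerance = 1e-10)
  }
  # unbalanced designs too
  for (rep in 1:20) {
    sizes <- sample(2:6, sample(2:5, 1), replace = TRUE)
    g <- rep(seq_along(sizes), sizes)
    v <- rnorm(length(g)) + g
    expect_equal(iccAnova(v, g)$icc, bruteICC(v, g), tolerance = 1e-10)
  }
})

test_that("coefficients of variation follow sd/mean on detected values", {
  counts <- rbind(s1 = c(g = 1L), s2 = c(g = 2L), s3 = c(g = 3L))
  co <- MicrobiomeCohort(counts, rep("p1", 3), 0:2, unit = "reads",
                         sample_id = rownames(counts))
  cv <- genusCV(co, min_detect = 3)
  expect_equal(cv$per_series$cv, 0.5)
  # constant series: CV 0
  counts2 <- matrix(5L, 4, 1, dimnames = list(paste0("s", 1:4), "g"))
  co2 <- MicrobiomeCohort(counts2, rep("p1", 4), 0:3, unit = "reads",
                          sample_id = rownames(counts2))
  expect_equal(genusCV(co2, min_detect = 3)$per_series$cv, 0)
})

test_that("fold changes agree with exhaustive pair enumeration", {
  mkco <- function(v) {
    counts <- matrix(as.integer(v), length(v), 1,
                     dimnames = list(sprintf("s%02d", seq_along(v)), "g"))
    MicrobiomeCohort(counts, rep("p1", length(v)),
                     seq_along(v) - 1L, unit = "reads",
                     sample_id = rownames(counts))
  }
  fc <- foldChanges(mkco(c(10, 1000, 50)))
  expect_equal(fc$max_overall, 100)
  expect_equal(fc$max_consecutive, 100)
  fc2 <- foldChanges(mkco(rep(7, 5)))
  expect_equal(fc2$max_overall, 1)
  expect_equal(fc2$max_consecutive, 1)
  # property: equals brute force on random series with zeros
  set.seed(3)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    v <- rpois(n, 20) * rbinom(n, 1, 0.8)
    if (sum(v > 0) < 2) next
    fcr <- foldChanges(mkco(v))
    pos <- v[v > 0]
    brute_all <- max(outer(pos, pos, "/"))
    adj <- which(v[-length(v)] > 0 & v[-1] > 0)
    brute_adj <- if (length(adj))
      max(pmax(v[adj + 1] / v[adj], v[adj] / v[adj + 1])) else NA_real_
    expect_equal(fcr$max_overall, brute_all)
    expect_equal(fcr$max_consecutive, brute_adj)
    if (!is.na(fcr$max_consecutive))
      expect_lte(fcr$max_consecutive, fcr$max_overall * (1 + 1e-12))
  }
})

test_that("rank spans use dense within-sample ranks", {
  counts <- rbind(s1 = c(a = 30L, b = 20L, c = 10L),
                  s2 = c(a = 10L, b = 30L, c = 20L),
                  s3 = c(a = 5L, b = 40L, c = 30L))
  co <- MicrobiomeCohort(counts, rep("p1", 3), 0:2, unit = "reads",
                         sample_id = rownames(counts))
  fc <- foldChanges(co)
  # genus a is ranked 1, 3, 3 -> span 3; b: 2, 1, 1 -> 2; c: 3, 2, 2 -> 2
  expect_equal(fc$rank_span[match(c("a", "b", "c"), fc$genus_id)],
               c(3L, 2L, 2L))
})

test_that("the ADF test separates stationary series from random walks", {
  set.seed(21)
  rej_ar <- mean(vapply(1:300, function(i) {
    y <- as.numeric(arima.sim(list(ar = 0.2), 40))
    adfTest(y)$p < 0.05
  }, logical(1)))
  rej_rw <- mean(vapply(1:300, function(i) {
    y <- cumsum(rnorm(40))
    adfTest(y)$p < 0.05
  }, logical(1)))
  expect_gte(rej_ar, 0.8)
  expect_lte(rej_rw, 0.1)
})

test_that("Taylor fits recover exact power laws and hand least squares", {
  # constant CV: slope exactly 2
  mk <- function(msd) {
    # participants with prescribed (mean, sd): construct 4-point positive
    # series with exact sample moments via an affine transform of a
    # right-skewed standardized pattern (min z ~ -0.78, so values stay
    # positive up to CV ~ 1.27)
    sapply(seq_len(nrow(msd)), function(i) {
      z <- c(-0.9, -0.9, 0.3, 1.5)
      z <- (z - mean(z)) / sd(z)
      msd[i, 1] + msd[i, 2] * z
    })
  }
  msd <- cbind(c(10, 100, 1000), sqrt(c(100, 10000, 1e6)))
  series <- mk(msd)  # 4 x 3 (samples x participants)
  counts <- matrix(as.numeric(series), ncol = 1,
                   dimnames = list(sprintf("s%02d", 1:12), "g"))
  co <- MicrobiomeCohort(counts, rep(c("p1", "p2", "p3"), each = 4),
                         rep(0:3, 3), unit = "cells_per_gram",
                         sample_id = rownames(counts))
  tf <- suppressWarnings(taylorFit(co, min_points = 3))  # exact fit
  expect_equal(tf$slope, 2, tolerance = 1e-9)
  expect_equal(tf$adj_r2, 1, tolerance = 1e-9)
  # hand least squares on (0,0), (1,1.5), (2,3.4): slope = cov/var = 1.7
  msd2 <- cbind(10^c(0, 1, 2), sqrt(10^c(0, 1.5, 3.4)))
  series2 <- mk(msd2)
  counts2 <- matrix(as.numeric(series2), ncol = 1,
                    dimnames = list(sprintf("s%02d", 1:12), "g"))
  co2 <- MicrobiomeCohort(counts2, rep(c("p1", "p2", "p3"), each = 4),
                          rep(0:3, 3), unit = "cells_per_gram",
                          sample_id = rownames(counts2))
  tf2 <- taylorFit(co2, min_points = 3)
  expect_equal(tf2$slope, 1.7, tolerance = 1e-6)
})

test_that("Taylor slopes are invariant to global rescaling", {
  sim <- simulateCohort(cohortSpec(n_participants = 8, n_days = 14,
                                   n_genera = 25, n_states = 1, seed = 6))
  lat <- sim$truth$cells
  co <- MicrobiomeCohort(lat, participants(sim$cohort),
                         sampleDays(sim$cohort), unit = "cells_per_gram",
                         sample_id = colData(sim$cohort)$sample_id)
  co2 <- MicrobiomeCohort(lat * 1e-9, participants(sim$cohort),
                          sampleDays(sim$cohort), unit = "cells_per_gram",
                          sample_id = colData(sim$cohort)$sample_id)
  t1 <- taylorFit(co); t2 <- taylorFit(co2)
  expect_equal(t1$slope, t2$slope, tolerance = 1e-8)
})

test_that("rank contrasts reduce to the Welch t-test", {
  fits <- data.frame(genus_id = letters[1:6],
                     slope = c(2, 2.1, 1.9, 1.5, 1.4, 1.6))
  ranks <- setNames(1:6, letters[1:6])
  r <- taylorRankContrast(fits, ranks, top_n = 3)
  tt <- t.test(c(2, 2.1, 1.9), c(1.5, 1.4, 1.6))
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r$p, tt$p.value, tolerance = 1e-12)
  # identical slopes: t = 0, p = 1
  fits2 <- data.frame(genus_id = letters[1:6], slope = rep(2, 6))
  r2 <- taylorRankContrast(fits2, ranks, top_n = 3)
  expect_equal(r2$t, 0)
  expect_equal(r2$p, 1)
  expect_error(taylorRankContrast(fits, ranks, top_n = 6), "top_n")
})

test_that("median-error curves vanish for constant series and full draws", {
  counts <- matrix(rep(c(5, 9, 13), each = 8), nrow = 8)
  colnames(counts) <- c("g1", "g2", "g3")
  rownames(counts) <- sprintf("s%d", 1:8)
  co <- MicrobiomeCohort(counts, rep("p1", 8), 0:7,
                         unit = "cells_per_gram",
                         sample_id = rownames(counts))
  r <- medianErrorCurve(co, n_points = c(1, 3, 8), reps = 50, seed = 1)
  expect_equal(r$curve$error, c(0, 0, 0))
  # full-length draws always reproduce the full median
  set.seed(2)
  counts2 <- matrix(rpois(24, 50), 8)
  colnames(counts2) <- c("g1", "g2", "g3")
  rownames(counts2) <- sprintf("s%d", 1:8)
  co2 <- MicrobiomeCohort(counts2, rep("p1", 8), 0:7,
                          unit = "cells_per_gram",
                          sample_id = rownames(counts2))
  r2 <- medianErrorCurve(co2, n_points = 8, reps = 30, seed = 3)
  expect_equal(r2$curve$error, 0)
})

test_that("median-error curves decrease with sampling effort", {
  sim <- simulateCohort(cohortSpec(n_participants = 4, n_days = 24,
                                   n_genera = 20, drop_prob = 0, seed = 8))
  r <- medianErrorCurve(sim$cohort, n_points = c(2, 5, 10, 20),
                        reps = 400, top_genera = 15, seed = 4)
  expect_true(all(diff(r$curve$error) < 0))
  expect_true(r$elbow %in% r$curve$n)
})
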