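# helper to build a one-participant cohort from a presence mask
maskCohort <- function(masks) {
  # masks: list of participant -> genus x sample logical matrix
  all_counts <- list()
  part <- c(); day <- c()
  for (p in names(masks)) {
    m <- masks[[p]]
    counts <- t(m) * 100L  # samples x genera
    rownames(counts) <- sprintf("%s_s%02d", p, seq_len(nrow(counts)))
    all_counts[[p]] <- counts
    part <- c(part, rep(p, nrow(counts)))
    day <- c(day, seq_len(nrow(counts)) - 1L)
  }
  counts <- do.call(rbind, all_counts)
  MicrobiomeCohort(counts, part, day, unit = "reads",
                   sample_id = rownames(counts))
}

test_that("membership classes follow the presence-fraction rules", {
  # 10 samples, genus A present everywhere; B with pattern 1110000000;
  # C with presence 7/10 scattered (transient); D absent
  mask <- rbind(A = rep(TRUE, 10),
                B = c(rep(TRUE, 3), rep(FALSE, 7)),
                C = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE,
                      TRUE, TRUE, TRUE),
                D = rep(FALSE, 10))
  r <- classifyMembership(maskCohort(list(p1 = mask, p2 = mask)),
                          min_rel_abundance = 0)
  p1 <- r$per_participant[r$per_participant$participant_id == "p1", ]
  a <- p1[p1$genus_id == "A", ]
  expect_true(a$temporal_core)
  b <- p1[p1$genus_id == "B", ]
  expect_equal(b$presence_fraction, 0.3)
  expect_equal(b$consecutive_fraction, 1)
  expect_true(b$persistent)
  expect_false(b$transient)
  cc <- p1[p1$genus_id == "C", ]
  expect_equal(cc$presence_fraction, 0.7)
  expect_lt(cc$consecutive_fraction, 0.75)
  expect_true(cc$transient)
  # both participants identical: A..C are cross-sectional core, D dropped
  expect_true(all(r$cohort$cross_sectional_core[r$cohort$genus_id
                                                %in% c("A", "B", "C")]))
})

test_that("person-specific calls respect negative controls", {
  maskP1 <- rbind(shared = rep(TRUE, 6), own = c(TRUE, TRUE, rep(FALSE, 4)),
                  contam = c(TRUE, rep(FALSE, 5)))
  maskP2 <- rbind(shared = rep(TRUE, 6), own = rep(FALSE, 6),
                  contam = rep(FALSE, 6))
  r <- classifyMembership(maskCohort(list(p1 = maskP1, p2 = maskP2)),
                          negative_control_genera = "contam",
                          min_rel_abundance = 0)
  coh <- r$cohort
  expect_true(coh$person_specific[coh$genus_id == "own"])
  expect_false(coh$person_specific[coh$genus_id == "contam"])
  expect_false(coh$person_specific[coh$genus_id == "shared"])
})

test_that("membership equals brute-force rule evaluation on random masks", {
  set.seed(14)
  for (rep in 1:300) {
    n <- sample(5:20, 1)
    pres <- runif(n) < runif(1)
    if (!any(pres)) pres[sample(n, 1)] <- TRUE
    mask <- rbind(g = pres, filler = rep(TRUE, n))
    r <- classifyMembership(maskCohort(list(p1 = mask)),
                            min_rel_abundance = 0)
    g <- r$per_participant[r$per_participant$genus_id == "g", ]
    f <- mean(pres)
    neighbour <- c(FALSE, pres[-n]) | c(pres[-1], FALSE)
    cons <- sum(pres & neighbour) / sum(pres)
    expect_equal(g$presence_fraction, f)
    expect_equal(g$consecutive_fraction, cons)
    expect_equal(g$temporal_core, f > 0.95)
    expect_equal(g$persistent, f > 0.20 && cons >= 0.90)
    expect_equal(g$transient, f > 0.60 && cons < 0.75)
  }
})

test_that("core-size accumulation hits the endpoints and shrinks with n", {
  set.seed(4)
  mask <- matrix(runif(12 * 20) < 0.85, 12, 20)
  mask[1:3, ] <- TRUE
  rownames(mask) <- paste0("g", 1:12)
  co <- maskCohort(list(p1 = mask))
  r <- coreSizeAccumulation(co, n_samples = c(1, 5, 20), reps = 100,
                            min_rel_abundance = 0, seed = 2)
  # n = full length reproduces the full-series core exactly
  expect_equal(r$curve$mean_core_size[r$curve$n == 20],
               r$full_size$core_size)
  # n = 1: every genus present in the drawn sample is "core"
  expect_equal(r$curve$mean_core_size[r$curve$n == 1],
               mean(colSums(mask)), tolerance = 0.05)
  # expectation decreases with effort
  expect_true(all(diff(r$curve$mean_core_size) <= 1e-9))
})
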