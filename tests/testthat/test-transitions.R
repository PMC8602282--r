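test_that("expected transition probabilities match the worked example", {
  r <- transitionNull(c("A", "A", "B"), rep("p1", 3), day = 1:3)
  tab <- r$table
  expect_equal(tab$expected_prob[tab$pair == "A-A"], 1 / 3)
  expect_equal(tab$expected_prob[tab$pair == "A-B"], 2 / 3)
  expect_equal(tab$observed[tab$pair == "A-A"], 1)
  expect_equal(tab$observed[tab$pair == "A-B"], 1)
  expect_equal(tab$expected[tab$pair == "A-A"], 2 / 3)
  expect_equal(tab$expected[tab$pair == "A-B"], 4 / 3)
  expect_equal(sum(tab$expected_prob), 1, tolerance = 1e-12)
})

test_that("a single-state series gives chi-square 0 and p = 1", {
  r <- transitionNull(rep("A", 6), rep(c("p1", "p2"), each = 3),
                      day = rep(1:3, 2))
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(sum(r$table$expected_prob), 1)
})

test_that("expected probabilities match exhaustive pair enumeration", {
  set.seed(17)
  states <- c("B1", "B2", "R", "P")
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    lab <- sample(states, n, replace = TRUE)
    npart <- sample(1:3, 1)
    part <- sort(rep_len(paste0("p", seq_len(npart)), n))
    day <- stats::ave(seq_len(n), part, FUN = seq_along)
    r <- transitionNull(lab, part, day = day, states = states)
    # enumeration over all unordered sample pairs
    combs <- combn(n, 2)
    pair_lab <- apply(combs, 2, function(ij) {
      k <- sort(match(lab[ij], states))
      paste(states[k], collapse = "-")
    })
    brute <- table(factor(pair_lab, levels = r$table$pair)) / ncol(combs)
    expect_equal(r$table$expected_prob, as.numeric(brute),
                 tolerance = 1e-12)
    expect_equal(sum(r$table$expected_prob), 1, tolerance = 1e-12)
    expect_equal(sum(r$table$observed), r$n_transitions)
  }
})

test_that("same-state excess is detected in a sticky chain", {
  set.seed(30)
  d <- simulateCTMC(12, 30, matrix(c(-0.05, 0.05, 0.05, -0.05), 2,
                                   byrow = TRUE), seed = 8)
  r <- transitionNull(as.character(d$state), d$id, d$day)
  expect_lt(r$p, 1e-6)
  same <- r$table$state_a == r$table$state_b
  expect_true(all(r$table$residual[same & r$table$expected > 0] > 0))
})

test_that("constellation medians agree with direct enumeration", {
  dm <- matrix(c(0, .1, .5, .6,
                 .1, 0, .7, .8,
                 .5, .7, 0, .2,
                 .6, .8, .2, 0), 4, byrow = TRUE)
  rownames(dm) <- colnames(dm) <- paste0("s", 1:4)
  lab <- c("X", "X", "Y", "Y")
  r <- constellationDissimilarity(dm, lab,
                                  participant = c("p1", "p1", "p2", "p2"))
  bs <- r$between_states
  expect_equal(bs$median_bc[bs$pair == "X-X"], 0.1)
  expect_equal(bs$median_bc[bs$pair == "Y-Y"], 0.2)
  expect_equal(bs$median_bc[bs$pair == "X-Y"], median(c(.5, .6, .7, .8)))
  ws <- r$within_subject
  expect_equal(ws$median_bc[ws$participant_id == "p1"], 0.1)
  expect_equal(ws$majority_state[ws$participant_id == "p2"], "Y")
})

test_that("the consecutive-shift test is calibrated and powered", {
  set.seed(42)
  mkdist <- function(shift) {
    n <- 40
    lab <- sample(c("A", "B"), n, replace = TRUE)
    lab[1:2] <- c("A", "A"); lab[3:4] <- c("A", "B")  # both kinds present
    # consecutive BC values: same-state pairs ~ U(0.2, 0.6), different
    # shifted up
    day <- seq_len(n)
    dm <- matrix(runif(n * n, 0.2, 0.6), n)
    dm[cbind(seq_len(n - 1), 2:n)] <-
      dm[cbind(2:n, seq_len(n - 1))] <-
      runif(n - 1, 0.2, 0.6) + ifelse(lab[-n] != lab[-1], shift, 0)
    dm <- (dm + t(dm)) / 2; diag(dm) <- 0
    rownames(dm) <- colnames(dm) <- paste0("s", seq_len(n))
    list(d = dm, lab = lab, part = rep("p1", n), day = day)
  }
  null_rej <- mean(vapply(1:200, function(i) {
    x <- mkdist(0)
    consecutiveShiftTest(x$d, x$lab, x$part, x$day, seed = i)$p < 0.05
  }, logical(1)))
  expect_lt(abs(null_rej - 0.05), 0.04)
  power <- mean(vapply(1:60, function(i) {
    x <- mkdist(0.2)
    consecutiveShiftTest(x$d, x$lab, x$part, x$day, seed = i)$p < 0.05
  }, logical(1)))
  expect_gte(power, 0.9)
})

test_that("CTMC bookkeeping: generator rows, probability rows, null risk
           ratios, identical-model LR", {
  set.seed(3)
  Q <- matrix(c(-0.15, 0.15, 0.3, -0.3), 2, byrow = TRUE)
  d <- simulateCTMC(40, 15, Q, seed = 5)
  m0 <- ctmcFit(d$state, d$id, d$day)
  expect_equal(rowSums(m0@Q), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- ctmcTransitionProbs(m0, t = 2.5)
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(P >= 0))
  # no-covariate model has no risk ratios; a zero-covariate fit has RR ~ 1
  expect_equal(nrow(riskRatios(m0)), 0)
  lr <- ctmcLRTest(m0, m0)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p, 1)
})

test_that("CTMC recovers intensities and covariate effects", {
  Q <- matrix(c(-0.1, 0.1, 0.2, -0.2), 2, byrow = TRUE)
  beta <- matrix(c(0.5, 0.5), 2, 1)
  d <- simulateCTMC(120, 25, Q, beta, seed = 19)
  m1 <- ctmcFit(d$state, d$id, d$day, covariates = cbind(z = d$z1))
  expect_equal(m1@Q[1, 2], 0.1, tolerance = 0.35)
  expect_equal(m1@Q[2, 1], 0.2, tolerance = 0.35)
  rr <- riskRatios(m1)
  expect_true(all(rr$lo < exp(0.5) & exp(0.5) < rr$hi))
  m0 <- ctmcFit(d$state, d$id, d$day)
  lr <- ctmcLRTest(m1, m0)
  expect_lt(lr$p, 0.01)
  # likelihood at the fit beats the perturbed parameters
  gr <- mbtemporal:::.ctmcGroups(
    mbtemporal:::.ctmcIntervals(d$state, d$id, d$day,
                                as.matrix(d[, "z1", drop = FALSE])))
  nll_hat <- mbtemporal:::.ctmcNll(m1@par, gr, 2, m1@trans_idx)
  nll_pert <- mbtemporal:::.ctmcNll(m1@par + 0.3, gr, 2, m1@trans_idx)
  expect_lt(nll_hat, nll_pert)
})
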