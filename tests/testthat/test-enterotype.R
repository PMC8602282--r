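test_that("a K = 1 fit is the single Dirichlet-multinomial MLE", {
  set.seed(2)
  alpha_true <- c(8, 4, 2, 1)
  X <- t(vapply(1:200, function(i) {
    p <- rgamma(4, alpha_true); p <- p / sum(p)
    as.numeric(rmultinom(1, 500, p))
  }, numeric(4)))
  fit <- dmmFit(X, K = 1, seed = 1)
  expect_equal(fit@weights, 1)
  expect_true(all(fit@responsibilities == 1))
  # at the fixed point, the alpha gradient condition holds: the update map
  # leaves alpha unchanged
  upd <- mbtemporal:::.dmAlphaUpdate(X, rep(1, nrow(X)), fit@alpha[1, ],
                                     rowSums(X))
  expect_equal(upd, fit@alpha[1, ], tolerance = 1e-3)
  # and the recovered alpha is close to the generating one
  expect_equal(unname(fit@alpha[1, ]), alpha_true, tolerance = 0.15 * 8)
})

test_that("alpha recovery from a known Dirichlet-multinomial is within 10%", {
  set.seed(6)
  alpha_true <- rexp(12, 1 / 5) + 0.5
  X <- t(vapply(1:1000, function(i) {
    p <- rgamma(12, alpha_true); p <- p / sum(p)
    as.numeric(rmultinom(1, 10000, p))
  }, numeric(12)))
  fit <- dmmFit(X, K = 1, seed = 1, max_iter = 400)
  expect_lt(max(abs(fit@alpha[1, ] - alpha_true) / alpha_true), 0.1)
})

test_that("EM separates two well-separated templates", {
  tpl <- enterotypeTemplates(30)
  bg <- simulateBackground(150, tpl$alpha[c(3, 4), ], weights = c(0.5, 0.5),
                           seed = 4)
  X <- t(abundances(bg$cohort))
  fit <- dmmFit(X, K = 2, seed = 2)
  expect_gt(adjRand(fit@assignment, bg$truth$state), 0.9)
  expect_true(all(abs(rowSums(fit@responsibilities) - 1) < 1e-9))
  expect_true(all(fit@alpha > 0))
})

test_that("model selection finds a single template and posteriors align", {
  tpl <- enterotypeTemplates(25)
  bg <- simulateBackground(120, tpl$alpha[1, , drop = FALSE],
                           weights = 1, seed = 9)
  X <- t(abundances(bg$cohort))
  sel <- dmmSelectK(X, 1:3, seed = 5)
  expect_equal(sel$best_k, 1L)
  # posterior assignment of the training samples matches the fit
  fit <- sel$models[[1]]
  po <- dmmPosterior(fit, X[1:10, ])
  expect_equal(po$assignment, rep(1L, 10))
})

test_that("enterotype naming follows the driver taxa", {
  tpl <- enterotypeTemplates(40)
  bg <- simulateBackground(400, tpl$alpha, seed = 3)
  fit <- dmmFit(t(abundances(bg$cohort)), K = 4, seed = 1)
  fit <- nameEnterotypes(fit)
  expect_setequal(fit@state_names, c("Bact1", "Bact2", "Rum", "Prev"))
  # the named components recover the generating templates
  map <- fit@state_names[fit@assignment]
  truth <- rownames(tpl$alpha)[bg$truth$state]
  expect_gt(mean(map == truth), 0.9)
})

test_that("iterative enterotyping recovers generating states per sample", {
  tpl <- enterotypeTemplates(40)
  bg <- simulateBackground(200, tpl$alpha, seed = 2)
  ts <- simulateTemplateSeries(8, 8, tpl$alpha, switch_prob = 0.05,
                               seed = 5)
  for (mode in c("assign", "refit")) {
    et <- iterativeEnterotyping(ts$cohort, bg$cohort, K = 4, seed = 7,
                                mode = mode)
    truth <- rownames(tpl$alpha)[ts$truth$state[et$labels$sample_id]]
    expect_gte(mean(et$labels$state_name == truth), 0.9)
    expect_true(all(et$labels$posterior >= 0 & et$labels$posterior <= 1))
  }
  # reproducible from seed
  e1 <- iterativeEnterotyping(ts$cohort, bg$cohort, seed = 3,
                              mode = "assign")
  e2 <- iterativeEnterotyping(ts$cohort, bg$cohort, seed = 3,
                              mode = "assign")
  expect_identical(e1$labels, e2$labels)
})

test_that("the mislabel screen recovers injected swaps without false
           reciprocal pairs", {
  # well-separated participants: the regime the screen assumes
  sim <- simulateCohort(cohortSpec(n_participants = 8, n_days = 30,
                                   n_genera = 80, icc_target = 0.7,
                                   seed = 21))
  co <- sim$cohort
  ids <- split(colData(co)$sample_id, participants(co))
  pair1 <- c(ids[[1]][4], ids[[3]][9])
  pair2 <- c(ids[[5]][2], ids[[8]][11])
  sw <- injectSwaps(co, list(pair1, pair2))
  scr <- mislabelScreen(brayCurtis(relativeAbundances(sw)),
                        participants(sw))
  got <- apply(scr$swap_candidates[, c("sample_a", "sample_b")], 1,
               function(r) paste(sort(r), collapse = "+"))
  expect_true(paste(sort(pair1), collapse = "+") %in% got)
  expect_true(paste(sort(pair2), collapse = "+") %in% got)
  expect_equal(nrow(scr$swap_candidates), 2)
  # clean cohort: no reciprocal candidates
  scr0 <- mislabelScreen(brayCurtis(relativeAbundances(co)),
                         participants(co))
  expect_equal(nrow(scr0$swap_candidates), 0)
})

test_that("the DMM cluster evidence points at swapped samples", {
  tpl <- enterotypeTemplates(30)
  ts <- simulateTemplateSeries(4, 10, tpl$alpha, switch_prob = 0,
                               seed = 3)
  co <- ts$cohort
  ids <- split(colData(co)$sample_id, participants(co))
  # swap across the two most distinct community types (Rum <-> Prev)
  sw <- injectSwaps(co, list(c(ids[[3]][2], ids[[4]][7])))
  scr <- mislabelScreen(brayCurtis(relativeAbundances(sw)),
                        participants(sw),
                        counts = t(abundances(sw)), n_clusters = 4,
                        seed = 11)
  ev <- scr$dmm_evidence
  expect_true(all(ev$mismatch[ev$sample_id %in% c(ids[[3]][2],
                                                  ids[[4]][7])]))
})
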