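#' Dirichlet community templates for four enterotype-like states
#'
#' Builds K = 4 Dirichlet parameter vectors over \code{n_genera} genera with
#' the driver structure of the canonical gut community states: two
#' Bacteroides-dominant templates split by Faecalibacterium level (Bact1
#' high, Bact2 depleted and less concentrated, i.e. more dispersed), a
#' Ruminococcaceae-dominant template (Rum) and a Prevotella-dominant template
#' (Prev). The first four genera are named after the drivers; the remainder
#' follow a log-normal rank-abundance profile shared across templates.
#'
#' @param n_genera number of genera (>= 8).
#' @param concentration per-template total Dirichlet concentration; the
#'   default makes Bact2 the most dispersed state.
#' @param seed integer seed for the shared background profile.
#' @return A list with \code{alpha} (4 x n_genera matrix, rows named
#'   Bact1/Bact2/Rum/Prev) and \code{drivers} (named driver genera).
#' @export
enterotypeTemplates <- function(n_genera = 100L,
                                concentration = c(Bact1 = 60, Bact2 = 22,
                                                  Rum = 60, Prev = 55),
                                seed = 7L) {
  stopifnot(n_genera >= 8)
  drivers <- c(Bacteroides = "g__Bacteroides", Prevotella = "g__Prevotella",
               Faecalibacterium = "g__Faecalibacterium",
               Ruminococcaceae = "uc_f_Ruminococcaceae")
  genus_id <- .genusNames(n_genera)
  base <- .withSeed(seed, {
    b <- sort(stats::rlnorm(n_genera, meanlog = 0, sdlog = 1.4),
              decreasing = TRUE)
    b / sum(b)
  })
  names(base) <- genus_id
  boost <- function(rel, up, dn = character()) {
    r <- rel
    r[up] <- r[up] * 25
    r[dn] <- r[dn] * 0.05
    r / sum(r)
  }
  rel <- rbind(
    Bact1 = boost(base, c(drivers[["Bacteroides"]],
                          drivers[["Faecalibacterium"]])),
    Bact2 = boost(base, drivers[["Bacteroides"]],
                  drivers[["Faecalibacterium"]]),
    Rum   = boost(base, drivers[["Ruminococcaceae"]]),
    Prev  = boost(base, drivers[["Prevotella"]])
  )
  list(alpha = rel * concentration[rownames(rel)], drivers = drivers)
}

.genusNames <- function(n_genera) {
  drivers <- c("g__Bacteroides", "g__Prevotella", "g__Faecalibacterium",
               "uc_f_Ruminococcaceae")
  rest <- sprintf("g__genus%03d", seq_len(max(0, n_genera - 4L)))
  # a minority of unclassified bins, as genus-level 16S tables have
  uc <- seq_along(rest) %% 6 == 0
  rest[uc] <- sub("^g__genus", "uc_f_fam", rest[uc])
  c(drivers, rest)[seq_len(n_genera)]
}

#' Simulate a dense longitudinal quantitative microbiome cohort
#'
#' Generates read counts, sample metadata (load, moisture, Bristol score,
#' sampling time), daily diet records, a genus copy-number map and the full
#' ground truth, following the generative model the downstream analyses
#' assume:
#' \itemize{
#'   \item latent per-genus log10 cell abundance follows an AR(1) process
#'     around a per-participant equilibrium, with stationary SD set from a
#'     per-genus coefficient of variation and a Taylor exponent \code{b}
#'     (\code{var = c * mean^b} across participants);
#'   \item a continuous-time Markov chain over \code{n_states} community
#'     templates boosts state-specific driver genera;
#'   \item microbial load is the sum of genus cell abundances; moisture
#'     correlates negatively with load and responds to the
#'     protein/carbohydrate energy ratio at \code{diet_lag_days};
#'   \item reads are multinomial draws from copy-number-distorted relative
#'     cell abundances (reads proportional to cells x copy number — the
#'     forward model \code{\link{buildQMP}} inverts), after truncating
#'     relative abundances below \code{detection_limit} to zero;
#'   \item candidate days are randomly dropped to mimic missed collections.
#' }
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return A list with \code{cohort} (a \linkS4class{MicrobiomeCohort}, unit
#'   reads, with loads, moisture, diet and copy numbers attached) and
#'   \code{truth}: per-participant equilibria (\code{mu}, log10 cells/g,
#'   participants x genera), per-genus between/within log10 SDs and implied
#'   ICC, per-(participant, genus) CV, per-sample latent cell abundances and
#'   state labels, the state intensity matrix \code{Q}, template effects,
#'   the diet lag, and the drop manifest.
#' @export
simulateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  s <- spec
  .withSeed(s$seed, {
    P <- s$n_participants; Dd <- s$n_days; G <- s$n_genera; K <- s$n_states
    pid <- sprintf("p%03d", 800 + seq_len(P))
    genus_id <- .genusNames(G)
    drivers <- genus_id[1:4]

    # cohort-level mean log10 cells/g per genus; drivers abundant
    M <- stats::rnorm(G, mean = 8.0, sd = 1.1)
    M[1:4] <- stats::rnorm(4, mean = 9.6, sd = 0.15)
    M <- M + log10(mean(s$load_range)) - log10(sum(10^M) * 1.35)

    # per-genus temporal CV (log-uniform in range) and log10 SDs
    cvr <- pmax(s$genus_cv_range, 1e-8)
    cv_g <- exp(stats::runif(G, log(cvr[1]), log(cvr[2])))
    if (diff(s$genus_cv_range) == 0) cv_g[] <- s$genus_cv_range[1]
    # abundant genera fluctuate less (noisy inverse coupling of CV rank to
    # abundance rank); also keeps the total load realistically narrow
    cv_g <- sort(cv_g)[rank(-(M + stats::rnorm(G, 0, 0.8)),
                            ties.method = "first")]
    sd_w_g <- sqrt(log(1 + cv_g^2)) / log(10)          # within, log10
    icc <- min(max(s$icc_target, 0), 0.999)
    sd_b_g <- sd_w_g * sqrt(icc / max(1 - icc, 1e-9))  # between, log10

    mu <- matrix(M, P, G, byrow = TRUE) +
      matrix(stats::rnorm(P * G, 0, rep(sd_b_g, each = P)), P, G)
    dimnames(mu) <- list(pid, genus_id)
    # anchor each participant's expected total load inside load_range
    # (log-uniform targets, slightly shrunk so day-to-day fluctuation stays
    # within the stated range); lift = E[10^z]/10^mu for lognormal z
    lr <- log10(s$load_range * c(1.15, 1 / 1.15))
    target_p <- pmin(pmax(stats::rnorm(P, mean(lr), 0.08), min(lr)),
                     max(lr))
    lift_g <- sqrt(1 + cv_g^2)
    mu <- mu + (target_p - log10(10^mu %*% lift_g)[, 1])

    # Taylor control: CV_pg = CV_g * (equilibrium ratio)^((b-2)/2), with the
    # realized per-genus mean equilibrium as reference
    dev <- sweep(mu, 2, colMeans(mu))
    cv_pg <- matrix(cv_g, P, G, byrow = TRUE) *
      10^(dev * (s$taylor_slope - 2) / 2)
    sd_w_pg <- sqrt(log(1 + cv_pg^2)) / log(10)

    # community states: CTMC over K templates, observed daily
    lam <- if (s$state_switch_prob >= 1) 5 else -log(1 - s$state_switch_prob)
    Q <- matrix(lam / max(K - 1, 1), K, K); diag(Q) <- -lam
    if (K == 1) Q <- matrix(0, 1, 1)
    Pday <- .matExpR(Q)
    E <- matrix(0, K, G, dimnames = list(NULL, genus_id))
    if (K > 1 && s$state_effect > 0) {
      eff <- s$state_effect
      E[1, drivers[1]] <- eff; E[1, drivers[3]] <- eff / 2        # Bact1
      if (K >= 2) { E[2, drivers[1]] <- eff; E[2, drivers[3]] <- -eff } # Bact2
      if (K >= 3) E[3, drivers[4]] <- eff                         # Rum
      if (K >= 4) E[4, drivers[2]] <- 1.8 * eff                   # Prev
      rownames(E) <- c("Bact1", "Bact2", "Rum", "Prev")[seq_len(K)]
    }
    home <- rep_len(seq_len(K), P)

    # diet: daily macronutrients, P/C energy ratio drives moisture at lag
    diet <- do.call(rbind, lapply(seq_len(P), function(p) {
      data.frame(
        participant_id = pid[p], day = seq_len(Dd) - 1L,
        carb_g = stats::rlnorm(Dd, log(220), 0.25),
        protein_g = stats::rlnorm(Dd, log(80), 0.25),
        fat_g = stats::rlnorm(Dd, log(70), 0.3),
        fiber_g = stats::rlnorm(Dd, log(20), 0.3),
        sodium_g = stats::rlnorm(Dd, log(3), 0.3),
        cycle_day = ((seq_len(Dd) - 1L) %% 29L) + 1L,
        cycle_length = 29L
      )
    }))

    cohort_rows <- list(); truth_rows <- list()
    cells_list <- list(); depth_mu <- log(s$depth)
    for (p in seq_len(P)) {
      z <- matrix(0, Dd, G)
      z[1, ] <- stats::rnorm(G, mu[p, ], sd_w_pg[p, ])
      phi <- s$ar_coef
      innov_sd <- sd_w_pg[p, ] * sqrt(1 - phi^2)
      for (t in 2:Dd)
        z[t, ] <- mu[p, ] + phi * (z[t - 1, ] - mu[p, ]) +
          stats::rnorm(G, 0, innov_sd)
      st <- rep(home[p], Dd)
      if (K > 1) for (t in 2:Dd)
        st[t] <- sample.int(K, 1, prob = Pday[st[t - 1], ])
      # shared day factor: total-biomass swings scaling every genus
      f <- numeric(Dd)
      f[1] <- stats::rnorm(1, 0, s$daily_load_sd)
      for (t in 2:Dd)
        f[t] <- phi * f[t - 1] +
          stats::rnorm(1, 0, s$daily_load_sd * sqrt(1 - phi^2))
      zs <- z + E[st, , drop = FALSE] + f
      cells <- 10^zs
      load <- rowSums(cells)

      dsub <- diet[diet$participant_id == pid[p], ]
      ei <- energyIntake(dsub)
      pc <- ei$pc_ratio
      lag <- s$diet_lag_days
      pc_lag <- c(rep(NA, lag), pc)[seq_len(Dd)]
      mc_mid <- mean(s$moisture_range); mc_half <- diff(s$moisture_range) / 2
      zl <- as.numeric(scale(log10(load)))
      zp <- as.numeric(scale(ifelse(is.na(pc_lag), 0, pc_lag)))
      mc <- mc_mid + mc_half * (-0.45 * zl + 0.4 * zp +
                                  0.45 * stats::rnorm(Dd)) / 1.6
      mc <- pmin(pmax(mc, s$moisture_range[1]), s$moisture_range[2])

      keep <- c(TRUE, stats::runif(Dd - 1) >= s$drop_prob)
      cohort_rows[[p]] <- data.frame(
        sample_id = sprintf("%s_d%d", pid[p], which(keep) - 1L),
        participant_id = pid[p], day = which(keep) - 1L,
        load = load[keep], moisture = mc[keep],
        bss = pmin(7, pmax(1, round(1 + 6 * (mc[keep] - s$moisture_range[1]) /
                                      max(diff(s$moisture_range), 1e-9)))),
        sampling_time = sample(c("morning", "noon", "afternoon_evening",
                                 "night"), sum(keep), replace = TRUE,
                               prob = c(0.5, 0.2, 0.25, 0.05)),
        state = st[keep]
      )
      cells_list[[p]] <- cells[keep, , drop = FALSE]
    }
    meta <- do.call(rbind, cohort_rows)
    cells <- do.call(rbind, cells_list)
    rownames(cells) <- meta$sample_id
    colnames(cells) <- genus_id

    # copy numbers and read sampling (reads ~ cells * copy number)
    cn <- pmin(pmax(stats::rlnorm(G, log(3.3), 0.45), 1), 15)
    names(cn) <- genus_id
    rel <- sweep(cells, 1, rowSums(cells), "/")
    rel[rel < s$detection_limit] <- 0
    pr <- sweep(rel, 2, cn, "*")
    depth_s <- pmax(1000, round(stats::rlnorm(nrow(pr), depth_mu, 0.2)))
    reads <- t(vapply(seq_len(nrow(pr)), function(i)
      as.numeric(stats::rmultinom(1, depth_s[i], pr[i, ])), numeric(G)))
    dimnames(reads) <- dimnames(cells)

    cohort <- MicrobiomeCohort(
      reads, participant = meta$participant_id, day = meta$day,
      unit = "reads", sample_id = meta$sample_id, load = meta$load,
      moisture = meta$moisture, bss = meta$bss,
      sampling_time = meta$sampling_time, copy_numbers = cn, diet = diet
    )
    ord <- match(colData(cohort)$sample_id, meta$sample_id)
    vb_g <- apply(mu, 2, stats::var)
    vw_g <- colMeans(sd_w_pg^2) + s$daily_load_sd^2
    truth <- list(
      mu = mu, cohort_mean_log10 = M, cv = cv_pg,
      sd_between = sd_b_g, sd_within = sd_w_g,
      icc = vb_g / (vb_g + vw_g),
      cells = cells[ord, , drop = FALSE],
      state = stats::setNames(meta$state[ord], meta$sample_id[ord]),
      state_names = if (!is.null(rownames(E))) rownames(E) else NULL,
      Q = Q, template_effects = E, diet_lag = s$diet_lag_days,
      copy_numbers = cn, depth = stats::setNames(depth_s[ord],
                                                 meta$sample_id[ord])
    )
    list(cohort = cohort, truth = truth)
  })
}

# dense matrix exponential (scaling and squaring on a Taylor base); small
# matrices only — used for the daily state chain and by the CTMC tests.
.matExpR <- function(A, order = 12L) {
  n <- nrow(A)
  if (n == 1) return(matrix(exp(A[1, 1]), 1, 1))
  nrm <- max(rowSums(abs(A)))
  k <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 1L)
  As <- A / 2^k
  S <- diag(n); term <- diag(n)
  for (j in seq_len(order)) {
    term <- term %*% As / j
    S <- S + term
  }
  for (j in seq_len(k)) S <- S %*% S
  S
}

#' Simulate a cross-sectional background population
#'
#' One sample per pseudo-participant, drawn from Dirichlet community
#' templates: a stand-in for a large cross-sectional reference cohort used to
#' anchor enterotype space. State labels are returned as ground truth.
#'
#' @param n_samples number of samples; must be >= number of templates.
#' @param templates a K x G matrix of Dirichlet parameters (rows = states),
#'   e.g. \code{enterotypeTemplates(G)$alpha}.
#' @param weights state prevalences (default mirrors a Western cross-sectional
#'   cohort: Bact1 most common, Bact2 and Prev least).
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return A list with \code{cohort} (unit reads, one sample per
#'   pseudo-participant) and \code{truth} (state index and name per sample).
#' @export
simulateBackground <- function(n_samples, templates,
                               weights = NULL, depth = 1e4, seed = 1L) {
  templates <- as.matrix(templates)
  K <- nrow(templates)
  if (n_samples < K)
    stop("n_samples must be at least the number of templates")
  if (is.null(weights))
    weights <- if (K == 4) c(0.36, 0.17, 0.30, 0.17) else rep(1 / K, K)
  .withSeed(seed, {
    st <- sample.int(K, n_samples, replace = TRUE, prob = weights)
    # guarantee every template appears
    st[seq_len(K)] <- seq_len(K)
    rel <- matrix(0, n_samples, ncol(templates))
    for (k in seq_len(K)) {
      i <- which(st == k)
      if (length(i))
        rel[i, ] <- .rdirichlet(length(i), templates[k, ])
    }
    reads <- t(apply(rel, 1, function(p) stats::rmultinom(1, depth, p)))
    colnames(reads) <- colnames(templates)
    pid <- sprintf("bg%04d", seq_len(n_samples))
    cohort <- MicrobiomeCohort(reads, participant = pid,
                               day = rep(0L, n_samples), unit = "reads",
                               sample_id = pid)
    labels <- stats::setNames(st[match(colData(cohort)$sample_id, pid)],
                              colData(cohort)$sample_id)
    list(cohort = cohort,
         truth = list(state = labels,
                      state_names = rownames(templates)))
  })
}

#' Simulate longitudinal series drawn from community templates
#'
#' Each participant starts in a home state and follows a daily Markov chain
#' with a small switching probability over the same Dirichlet templates a
#' cross-sectional background is built from; every sample is an independent
#' Dirichlet-multinomial draw from its day's template. This is the matched
#' longitudinal companion of \code{\link{simulateBackground}} for
#' label-recovery experiments.
#'
#' @param n_participants,n_days cohort dimensions.
#' @param templates K x G Dirichlet parameter matrix.
#' @param switch_prob daily probability of leaving the current state.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return list with \code{cohort} (unit reads) and \code{truth} (state per
#'   sample, state names).
#' @export
simulateTemplateSeries <- function(n_participants, n_days, templates,
                                   switch_prob = 0.05, depth = 1e4,
                                   seed = 1L) {
  templates <- as.matrix(templates)
  K <- nrow(templates)
  .withSeed(seed, {
    pid <- sprintf("p%03d", 800 + seq_len(n_participants))
    home <- rep_len(seq_len(K), n_participants)
    rows <- list(); states <- list()
    for (p in seq_len(n_participants)) {
      st <- integer(n_days); st[1] <- home[p]
      for (t in 2:n_days)
        st[t] <- if (stats::runif(1) < switch_prob)
          sample(setdiff(seq_len(K), st[t - 1]), 1) else st[t - 1]
      rel <- t(vapply(st, function(k)
        .rdirichlet(1, templates[k, ])[1, ], numeric(ncol(templates))))
      reads <- t(apply(rel, 1, function(pr) stats::rmultinom(1, depth, pr)))
      colnames(reads) <- colnames(templates)
      rownames(reads) <- sprintf("%s_d%d", pid[p], seq_len(n_days) - 1L)
      rows[[p]] <- reads
      states[[p]] <- stats::setNames(st, rownames(reads))
    }
    reads <- do.call(rbind, rows)
    cohort <- MicrobiomeCohort(reads,
                               participant = rep(pid, each = n_days),
                               day = rep(seq_len(n_days) - 1L,
                                         n_participants),
                               unit = "reads", sample_id = rownames(reads))
    st <- unlist(states)[colData(cohort)$sample_id]
    list(cohort = cohort,
         truth = list(state = st, state_names = rownames(templates)))
  })
}

#' Exchange the abundance rows of sample pairs (mislabelling fixture)
#'
#' Swaps the abundance profiles of each pair while leaving all metadata
#' labels in place — exactly what a sample swap during processing produces.
#' The manifest is recorded in \code{metadata(x)$swap_manifest}.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param swap_pairs list of length-2 character vectors of sample ids (or a
#'   2-column matrix).
#' @return The cohort with profiles exchanged.
#' @export
injectSwaps <- function(x, swap_pairs) {
  if (is.matrix(swap_pairs))
    swap_pairs <- split(swap_pairs, seq_len(nrow(swap_pairs)))
  if (!length(swap_pairs)) return(x)
  a <- abundances(x)
  ids <- colData(x)$sample_id
  for (pr in swap_pairs) {
    i <- match(pr[1], ids); j <- match(pr[2], ids)
    if (is.na(i) || is.na(j))
      stop("unknown sample_id in swap pair: ", paste(pr, collapse = ", "))
    tmp <- a[, i]; a[, i] <- a[, j]; a[, j] <- tmp
  }
  assay(x, "abundance") <- a
  metadata(x)$swap_manifest <- do.call(rbind, lapply(swap_pairs, function(pr)
    data.frame(sample_a = pr[1], sample_b = pr[2])))
  x
}

#' Simulate paired diet-ratio and moisture series with a known lag
#'
#' Generates a protein/carbohydrate energy-ratio series and a stool-moisture
#' series responding to it at a fixed lag with a chosen correlation — the
#' construction used to validate \code{\link{dietaryLag}} recovery.
#'
#' @param n_days series length.
#' @param lag lag in days (diet leading moisture).
#' @param r target correlation between the lagged ratio and moisture.
#' @param seed integer seed.
#' @return data.frame with \code{day}, \code{pc_ratio}, \code{moisture}.
#' @export
simulateDietMoisture <- function(n_days = 35L, lag = 1L, r = 0.5, seed = 1L) {
  stopifnot(lag >= 0, abs(r) <= 1)
  .withSeed(seed, {
    pc <- stats::rlnorm(n_days + lag, log(0.3), 0.3)
    zp <- as.numeric(scale(pc))
    mc_z <- r * zp[seq_len(n_days)] + sqrt(1 - r^2) * stats::rnorm(n_days)
    data.frame(day = seq_len(n_days) - 1L,
               pc_ratio = pc[seq_len(n_days) + lag],
               moisture = 72 + 8 * mc_z)
  })
}
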