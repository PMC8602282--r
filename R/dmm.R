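# Dirichlet multinomial mixture machinery.
#
# The mixture is fit by EM: responsibilities from component
# Dirichlet-multinomial likelihoods in the E-step, weights by mean
# responsibility and alphas by a weighted fixed-point iteration in the
# M-step. Model evidence is approximated by Laplace's method with a
# Sherman-Morrison determinant for the per-component Hessian.

# log DM(x | alpha) for all rows of X, including the multinomial
# normalising constant.
.dmLogLik <- function(X, alpha, nvec = rowSums(X), lconst = NULL) {
  A <- sum(alpha)
  if (is.null(lconst))
    lconst <- lgamma(nvec + 1) - rowSums(lgamma(X + 1))
  lconst + lgamma(A) - lgamma(A + nvec) +
    rowSums(lgamma(sweep(X, 2, alpha, "+"))) - sum(lgamma(alpha))
}

# one weighted fixed-point update of alpha (Minka); monotone in the
# weighted DM likelihood.
.dmAlphaUpdate <- function(X, w, alpha, nvec) {
  A <- sum(alpha)
  den <- sum(w * (digamma(nvec + A) - digamma(A)))
  num <- colSums(w * (digamma(sweep(X, 2, alpha, "+")) -
                        rep(digamma(alpha), each = nrow(X))))
  pmax(alpha * num / max(den, 1e-300), 1e-8)
}

# method-of-moments Dirichlet estimate from relative abundances
.dirichletMoM <- function(P) {
  m <- colMeans(P)
  v <- apply(P, 2, stats::var)
  ok <- m > 1e-8 & m < 1 - 1e-8 & v > 1e-12
  A <- if (any(ok)) stats::median(m[ok] * (1 - m[ok]) / v[ok] - 1) else 10
  A <- min(max(A, 1), 1e4)
  pmax(m * A, 1e-4)
}

#' Fit a Dirichlet multinomial mixture
#'
#' EM over K Dirichlet-multinomial components on an integer count matrix
#' (one row per sample, typically rarefied relative-profile counts).
#' Initialisation is k-means on relative abundances followed by
#' method-of-moments Dirichlet estimates per cluster. The log-likelihood is
#' checked to be non-decreasing every iteration.
#'
#' @param counts integer matrix, samples x genera. Empty samples are
#'   excluded.
#' @param K number of components (>= 1).
#' @param seed integer seed (k-means initialisation).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance; non-convergence returns the best model with a
#'   warning.
#' @param evidence \code{"laplace"} (half log-determinant of the observed
#'   information at the MLE) or \code{"bic"}; Laplace falls back to BIC for
#'   components whose Hessian is not positive definite.
#' @return A \linkS4class{DMMModel}.
#' @export
dmmFit <- function(counts, K, seed = NULL, max_iter = 200L, tol = 1e-6,
                   evidence = c("laplace", "bic")) {
  evidence <- match.arg(evidence)
  X <- as.matrix(counts)
  stopifnot(K >= 1, all(X >= 0), max(abs(X - round(X))) < 1e-8)
  X <- X[rowSums(X) > 0, , drop = FALSE]
  n <- nrow(X); G <- ncol(X)
  nvec <- rowSums(X)
  lconst <- lgamma(nvec + 1) - rowSums(lgamma(X + 1))
  P <- X / nvec

  alpha <- .withSeed(seed, {
    if (K == 1) {
      matrix(.dirichletMoM(P), 1)
    } else {
      cl <- tryCatch(stats::kmeans(P, centers = K, nstart = 5,
                                   iter.max = 50)$cluster,
                     error = function(e) sample.int(K, n, replace = TRUE))
      t(vapply(seq_len(K), function(k) {
        i <- which(cl == k)
        if (length(i) < 2) i <- sample.int(n, max(2, n %/% K))
        .dirichletMoM(P[i, , drop = FALSE])
      }, numeric(G)))
    }
  })
  w <- rep(1 / K, K)

  ll_old <- -Inf; r <- NULL; converged <- FALSE
  for (it in seq_len(max_iter)) {
    lph <- vapply(seq_len(K), function(k)
      log(w[k]) + .dmLogLik(X, alpha[k, ], nvec, lconst), numeric(n))
    mx <- apply(lph, 1, max)
    r <- exp(lph - mx)
    rs <- rowSums(r)
    r <- r / rs
    ll <- sum(mx + log(rs))
    if (ll < ll_old - 1e-6 * max(1, abs(ll_old)))
      warning("EM log-likelihood decreased at iteration ", it)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    w <- pmax(colMeans(r), 1e-10); w <- w / sum(w)
    for (k in seq_len(K)) {
      for (inner in 1:2)
        alpha[k, ] <- .dmAlphaUpdate(X, r[, k], alpha[k, ], nvec)
    }
  }
  if (!converged) warning("EM did not converge in ", max_iter,
                          " iterations; returning the best model")
  colnames(alpha) <- colnames(X)

  # negative log model evidence
  pn <- K * G
  nle <- if (evidence == "bic") {
    -ll_old + 0.5 * pn * log(n)
  } else {
    # per-component Hessian of the negative log-likelihood at the MLE has
    # the form diag(d) + c * 11', so its determinant follows from the
    # matrix determinant lemma in O(G).
    half_logdet <- vapply(seq_len(K), function(k) {
      A <- sum(alpha[k, ])
      cc <- sum(r[, k] * (trigamma(A + nvec) - trigamma(A)))
      dmat <- sweep(trigamma(sweep(X, 2, alpha[k, ], "+")), 2,
                    trigamma(alpha[k, ]), "-")
      dd <- -colSums(r[, k] * dmat)
      if (any(dd <= 0)) return(NA_real_)
      lem <- 1 + cc * sum(1 / dd)
      if (lem <= 0) return(NA_real_)
      0.5 * (sum(log(dd)) + log(lem))
    }, numeric(1))
    if (anyNA(half_logdet)) -ll_old + 0.5 * pn * log(n)
    else -ll_old - 0.5 * pn * log(2 * pi) + sum(half_logdet)
  }

  new("DMMModel", K = as.integer(K), weights = w, alpha = alpha,
      responsibilities = r,
      assignment = as.integer(apply(r, 1, which.max)),
      logLik = ll_old, fit_metric = nle, state_names = character(),
      converged = converged)
}

#' Posterior component membership of new samples under a fitted DMM
#'
#' @param model a \linkS4class{DMMModel}.
#' @param counts integer matrix, samples x genera (columns aligned with the
#'   model's alpha).
#' @return list with \code{responsibilities} and \code{assignment}.
#' @export
dmmPosterior <- function(model, counts) {
  X <- as.matrix(counts)
  nvec <- rowSums(X)
  lph <- vapply(seq_len(model@K), function(k)
    log(model@weights[k]) + .dmLogLik(X, model@alpha[k, ], nvec),
    numeric(nrow(X)))
  if (nrow(X) == 1) lph <- matrix(lph, 1)
  mx <- apply(lph, 1, max)
  r <- exp(lph - mx); r <- r / rowSums(r)
  list(responsibilities = r, assignment = as.integer(apply(r, 1, which.max)))
}

#' Select the number of DMM components by model evidence
#'
#' Fits each K and returns the one minimising the Laplace-approximated
#' negative log model evidence.
#'
#' @inheritParams dmmFit
#' @param K_range candidate component counts (within 1..10).
#' @return list with \code{best_k}, \code{fit_curve} (data.frame K, metric)
#'   and \code{models}.
#' @export
dmmSelectK <- function(counts, K_range = 1:6, seed = NULL, max_iter = 200L,
                       tol = 1e-6, evidence = c("laplace", "bic")) {
  evidence <- match.arg(evidence)
  stopifnot(all(K_range >= 1), all(K_range <= 10))
  seeds <- .subSeeds(seed, length(K_range))
  models <- lapply(seq_along(K_range), function(i)
    dmmFit(counts, K_range[i], seed = seeds[[i]], max_iter = max_iter,
           tol = tol, evidence = evidence))
  metric <- vapply(models, slot, numeric(1), "fit_metric")
  list(best_k = K_range[which.min(metric)],
       fit_curve = data.frame(K = K_range, neg_log_evidence = metric),
       models = models)
}

#' Map DMM components to enterotype names by driver taxa
#'
#' Assigns Prev to the component with the highest expected Prevotella
#' fraction, Rum to the (remaining) component highest in the unclassified
#' Ruminococcaceae bin, and splits the remaining Bacteroides-dominant
#' components by Faecalibacterium level: higher becomes Bact1, lower Bact2
#' (the dysbiosis-associated, Faecalibacterium-depleted state). With K != 4
#' components are named after their top driver.
#'
#' @param model a \linkS4class{DMMModel}.
#' @param drivers named character vector with entries Bacteroides,
#'   Prevotella, Faecalibacterium, Ruminococcaceae giving the genus ids to
#'   use (defaults match the synthetic generator's naming).
#' @return The model with \code{state_names} filled.
#' @export
nameEnterotypes <- function(model,
                            drivers = c(Bacteroides = "g__Bacteroides",
                                        Prevotella = "g__Prevotella",
                                        Faecalibacterium = "g__Faecalibacterium",
                                        Ruminococcaceae = "uc_f_Ruminococcaceae")) {
  rel <- model@alpha / rowSums(model@alpha)
  have <- drivers[drivers %in% colnames(rel)]
  if (length(have) < length(drivers) || model@K != 4) {
    top <- colnames(rel)[apply(rel, 1, which.max)]
    model@state_names <- make.unique(top)
    return(model)
  }
  nm <- character(model@K)
  prev <- which.max(rel[, drivers[["Prevotella"]]])
  nm[prev] <- "Prev"
  restr <- setdiff(seq_len(model@K), prev)
  rum <- restr[which.max(rel[restr, drivers[["Ruminococcaceae"]]])]
  nm[rum] <- "Rum"
  bact <- setdiff(restr, rum)
  b1 <- bact[which.max(rel[bact, drivers[["Faecalibacterium"]]])]
  nm[b1] <- "Bact1"
  nm[setdiff(bact, b1)] <- "Bact2"
  model@state_names <- nm
  model
}

#' Iterative enterotyping of a longitudinal cohort on a background
#'
#' Avoids clustering two samples of the same individual at once: the
#' within-participant sample indices are visited in random order, and each
#' iteration clusters the background plus a single time point per
#' participant. In \code{"refit"} mode every iteration refits the mixture
#' and component identities are resolved against a reference fit by
#' majority overlap of background-sample assignments (ties by cosine
#' similarity of alpha vectors); \code{"assign"} mode fits once on the
#' background and only computes posteriors, which is much cheaper.
#'
#' @param study a \linkS4class{MicrobiomeCohort} of read counts (rarefied to
#'   the background's depth).
#' @param background a \linkS4class{MicrobiomeCohort} of read counts (one
#'   sample per pseudo-participant).
#' @param K number of components (default 4).
#' @param seed integer seed (iteration order and fits).
#' @param mode \code{"refit"} or \code{"assign"}.
#' @param name_states run \code{\link{nameEnterotypes}} on the reference
#'   model and label samples accordingly.
#' @return list with \code{labels} (data.frame: sample_id, participant_id,
#'   state, state_name, posterior) and \code{model} (the reference
#'   \linkS4class{DMMModel}).
#' @export
iterativeEnterotyping <- function(study, background, K = 4L, seed = NULL,
                                  mode = c("refit", "assign"),
                                  name_states = TRUE) {
  mode <- match.arg(mode)
  common <- intersect(rownames(abundances(study)),
                      rownames(abundances(background)))
  stopifnot(length(common) >= 2)
  Xs <- t(abundances(study))[, common, drop = FALSE]
  Xb <- t(abundances(background))[, common, drop = FALSE]
  nb <- nrow(Xb)
  seeds <- .subSeeds(seed, 3)

  ref <- dmmFit(Xb, K, seed = seeds[[1]])
  if (name_states) ref <- nameEnterotypes(ref)
  snames <- if (length(ref@state_names)) ref@state_names
            else as.character(seq_len(K))

  idx <- .seriesIndex(study)
  ord <- .withSeed(seeds[[2]], lapply(idx, sample))
  n_iter <- max(vapply(ord, length, 1L))
  out_state <- integer(ncol(abundances(study)))
  out_post <- numeric(ncol(abundances(study)))

  it_seeds <- .subSeeds(seeds[[3]], n_iter)
  for (i in seq_len(n_iter)) {
    take <- unlist(lapply(ord, function(o) if (length(o) >= i) o[i]))
    Xi <- Xs[take, , drop = FALSE]
    if (mode == "assign") {
      po <- dmmPosterior(ref, Xi)
      lab <- po$assignment
      post <- po$responsibilities[cbind(seq_along(lab), lab)]
    } else {
      fit <- dmmFit(rbind(Xb, Xi), K, seed = it_seeds[[i]])
      # map this fit's components onto the reference by background overlap
      map <- .matchComponents(fit@assignment[seq_len(nb)],
                              ref@assignment, K, fit@alpha, ref@alpha)
      lab <- map[fit@assignment[nb + seq_len(nrow(Xi))]]
      post <- fit@responsibilities[nb + seq_len(nrow(Xi)), , drop = FALSE]
      post <- vapply(seq_along(lab), function(j)
        sum(post[j, map == lab[j]]), numeric(1))
    }
    out_state[take] <- lab
    out_post[take] <- post
  }
  labels <- data.frame(sample_id = colData(study)$sample_id,
                       participant_id = participants(study),
                       state = out_state,
                       state_name = snames[out_state],
                       posterior = out_post)
  list(labels = labels, model = ref)
}

# map components of `fit` (labels a) onto reference components (labels b)
# by majority overlap on shared samples; ties broken by cosine similarity
# of alpha vectors.
.matchComponents <- function(a, b, K, alpha_a, alpha_b) {
  overlap <- matrix(0, K, K)
  for (k in seq_len(K))
    for (l in seq_len(K))
      overlap[k, l] <- sum(a == k & b == l)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  map <- integer(K)
  used <- logical(K)
  for (k in order(-apply(overlap, 1, max))) {
    cand <- which(!used)
    best <- cand[overlap[k, cand] == max(overlap[k, cand])]
    if (length(best) > 1) {
      sims <- vapply(best, function(l)
        cosine(alpha_a[k, ], alpha_b[l, ]), numeric(1))
      message("component-matching tie resolved by alpha cosine similarity")
      best <- best[which.max(sims)]
    }
    map[k] <- best
    used[best] <- TRUE
  }
  map
}

#' Screen for mislabelled or swapped samples
#'
#' For every sample, one-sided Wilcoxon tests ask whether its Bray-Curtis
#' dissimilarities to each other participant's samples are stochastically
#' smaller than to its own participant's remaining samples; p-values are
#' Benjamini-Hochberg adjusted across all (sample, foreign participant)
#' tests and a sample is flagged where any foreign distribution wins at
#' \code{alpha}. Reciprocal flags — a sample of p matching q while a sample
#' of q matches p — are reported as swap candidates, one per participant
#' pair (the samples with the strongest evidence on each side, since a
#' physical swap exchanges exactly one pair). Optionally the whole
#' dataset is also clustered into as many DMM components as participants
#' and each sample's cluster is compared to its participant's modal
#' cluster as supporting evidence.
#'
#' @param d a \code{dist} or matrix of Bray-Curtis dissimilarities.
#' @param participant participant label per sample of \code{d}.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param counts optional integer count matrix (samples x genera) enabling
#'   the DMM-cluster evidence.
#' @param n_clusters DMM cluster count (default: number of participants).
#' @param seed integer seed (DMM evidence only).
#' @return list with \code{flags} (all significant sample-vs-participant
#'   tests), \code{flagged_samples}, \code{swap_candidates} (reciprocal
#'   pairs) and optionally \code{dmm_evidence}.
#' @export
mislabelScreen <- function(d, participant, alpha = 0.05, counts = NULL,
                           n_clusters = NULL, seed = NULL) {
  dm <- as.matrix(d)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dm)))
  participant <- as.character(participant)
  parts <- unique(participant)
  res <- list(); k <- 0L
  for (i in seq_along(ids)) {
    own <- dm[i, participant == participant[i]]
    own <- own[-which(names(own) == ids[i])[1]]
    if (length(own) < 2) next
    for (q in parts[parts != participant[i]]) {
      foreign <- dm[i, participant == q]
      p <- suppressWarnings(
        stats::wilcox.test(foreign, own, alternative = "less",
                           exact = FALSE)$p.value)
      k <- k + 1L
      res[[k]] <- data.frame(sample_id = ids[i],
                             participant_id = participant[i],
                             foreign_participant = q, p = p)
    }
  }
  res <- do.call(rbind, res)
  res$q <- .bh(res$p)
  flags <- res[res$q < alpha, , drop = FALSE]
  flagged <- unique(flags$sample_id)

  swaps <- list(); k <- 0L
  if (nrow(flags)) {
    key <- unique(flags[, c("participant_id", "foreign_participant")])
    for (r in seq_len(nrow(key))) {
      p1 <- key$participant_id[r]; p2 <- key$foreign_participant[r]
      if (p1 >= p2) next
      back <- flags$participant_id == p2 & flags$foreign_participant == p1
      if (!any(back)) next
      fwd <- flags[flags$participant_id == p1 &
                     flags$foreign_participant == p2, ]
      bwd <- flags[back, ]
      # one swap event maps to one sample pair: keep the strongest
      # reciprocal match for this participant pair
      a <- fwd$sample_id[which.min(fwd$p)]
      b <- bwd$sample_id[which.min(bwd$p)]
      k <- k + 1L
      swaps[[k]] <- data.frame(sample_a = a, participant_a = p1,
                               sample_b = b, participant_b = p2)
    }
  }
  out <- list(flags = flags, flagged_samples = flagged,
              swap_candidates = if (k) do.call(rbind, swaps) else
                data.frame(sample_a = character(), participant_a = character(),
                           sample_b = character(), participant_b = character()),
              tests = res)
  if (!is.null(counts)) {
    if (is.null(n_clusters)) n_clusters <- length(parts)
    fit <- dmmFit(counts, n_clusters, seed = seed)
    cl <- fit@assignment
    modal <- vapply(split(cl, participant), function(v)
      as.integer(names(which.max(table(v)))), integer(1))
    out$dmm_evidence <- data.frame(
      sample_id = ids, participant_id = participant, cluster = cl,
      modal_cluster = modal[participant],
      mismatch = cl != modal[participant])
  }
  out
}
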