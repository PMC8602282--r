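#' Observed versus expected enterotype transitions
#'
#' Counts state transitions between consecutive collected samples of each
#' participant, collapsed to unordered state pairs, and compares them with
#' the expectation under random pairing given state prevalences: with n_A
#' samples labelled A out of N in total, the expected probability of an
#' unordered pair is C(n_A, 2)/C(N, 2) for A = A and n_A n_B / C(N, 2) for
#' A != B. A chi-square goodness-of-fit over the pair categories tests
#' whether same-state transitions are over-represented (enterotype
#' stability); standardized residuals (O - E)/sqrt(E (1 - p_i)) localise the
#' discrepancies.
#'
#' @param labels state label per sample (character or factor).
#' @param participant participant id per sample.
#' @param day collection day per sample (orders the series).
#' @param states optional state universe (defaults to observed labels).
#' @param residuals \code{"standardized"} (default) or \code{"pearson"}.
#' @return list with \code{table} (one row per unordered pair: observed,
#'   expected_prob, expected, residual), \code{chi2}, \code{df}, \code{p},
#'   \code{n_transitions}.
#' @export
transitionNull <- function(labels, participant, day = NULL, states = NULL,
                           residuals = c("standardized", "pearson")) {
  residuals <- match.arg(residuals)
  labels <- as.character(labels)
  if (is.null(states)) states <- sort(unique(labels))
  if (is.null(day)) day <- stats::ave(seq_along(labels), participant,
                                      FUN = seq_along)
  K <- length(states)
  pairs <- cbind(rep(seq_len(K), times = K), rep(seq_len(K), each = K))
  pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
  pname <- paste(states[pairs[, 1]], states[pairs[, 2]], sep = "-")

  nA <- as.numeric(table(factor(labels, levels = states)))
  N <- length(labels)
  expected_prob <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i == j) choose(nA[i], 2) / choose(N, 2)
    else nA[i] * nA[j] / choose(N, 2)
  }, numeric(1))

  obs <- stats::setNames(numeric(nrow(pairs)), pname)
  for (p in unique(participant)) {
    i <- which(participant == p)
    i <- i[order(day[i])]
    if (length(i) < 2) next
    a <- match(labels[i[-length(i)]], states)
    b <- match(labels[i[-1]], states)
    lo <- pmin(a, b); hi <- pmax(a, b)
    nm <- paste(states[lo], states[hi], sep = "-")
    tb <- table(nm)
    obs[names(tb)] <- obs[names(tb)] + tb
  }
  Tn <- sum(obs)
  E <- expected_prob * Tn
  if (any(E == 0 & obs > 0))
    stop("observed transitions in a category with zero expected count")
  use <- E > 0
  chi2 <- sum((obs[use] - E[use])^2 / E[use])
  df <- sum(use) - 1
  resid <- ifelse(E > 0,
                  if (residuals == "standardized")
                    (obs - E) / sqrt(E * (1 - expected_prob))
                  else (obs - E) / sqrt(E),
                  NA_real_)
  list(table = data.frame(pair = pname,
                          state_a = states[pairs[, 1]],
                          state_b = states[pairs[, 2]],
                          observed = as.numeric(obs),
                          expected_prob = expected_prob,
                          expected = E, residual = resid),
       chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       n_transitions = Tn)
}

#' Compositional dissimilarity of enterotype constellations
#'
#' Median Bray-Curtis dissimilarity between samples of each unordered state
#' pair (over all samples), plus per-participant within-subject median
#' dissimilarities grouped by the participant's majority enterotype, and —
#' when a background distance and labels are supplied — the between-subject
#' per-enterotype dispersion via \code{\link{dispersionTest}}.
#'
#' @param d \code{dist}/matrix of dissimilarities for the cohort samples.
#' @param labels state label per sample of \code{d}.
#' @param participant optional participant id per sample (enables the
#'   within-subject component).
#' @param background_d,background_labels optional cross-sectional background
#'   for the between-subject dispersion component.
#' @param exclude participants to drop from the within-subject component.
#' @return list with \code{between_states} (median BC per state pair),
#'   \code{within_subject} (per participant: majority state, median BC) and
#'   optionally \code{background_dispersion}.
#' @export
constellationDissimilarity <- function(d, labels, participant = NULL,
                                       background_d = NULL,
                                       background_labels = NULL,
                                       exclude = character()) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  states <- sort(unique(labels))
  K <- length(states)
  out <- list()
  rows <- list(); k <- 0L
  for (i in seq_len(K)) for (j in i:K) {
    ii <- which(labels == states[i]); jj <- which(labels == states[j])
    if (i == j) {
      if (length(ii) < 2) { v <- NA_real_; n <- 0L }
      else { m <- dm[ii, ii]; v <- stats::median(m[upper.tri(m)])
             n <- choose(length(ii), 2) }
    } else {
      if (!length(ii) || !length(jj)) { v <- NA_real_; n <- 0L }
      else { v <- stats::median(dm[ii, jj]); n <- length(ii) * length(jj) }
    }
    k <- k + 1L
    rows[[k]] <- data.frame(pair = paste(states[i], states[j], sep = "-"),
                            state_a = states[i], state_b = states[j],
                            median_bc = v, n_pairs = n)
  }
  out$between_states <- do.call(rbind, rows)
  if (!is.null(participant)) {
    participant <- as.character(participant)
    keep <- !participant %in% exclude
    ws <- do.call(rbind, lapply(unique(participant[keep]), function(p) {
      i <- which(participant == p)
      maj <- names(which.max(table(labels[i])))
      m <- dm[i, i]
      data.frame(participant_id = p, majority_state = maj,
                 median_bc = stats::median(m[upper.tri(m)]))
    }))
    out$within_subject <- ws
  }
  if (!is.null(background_d))
    out$background_dispersion <- dispersionTest(background_d,
                                                background_labels)
  out
}

#' Consecutive-sample shifts: same- versus different-enterotype
#' dissimilarity
#'
#' Collects the Bray-Curtis dissimilarities of consecutive sample pairs,
#' split by whether the enterotype label changed, subsamples the larger
#' group to the smaller's size, and runs a two-sided Wilcoxon test.
#'
#' @param d \code{dist}/matrix of dissimilarities.
#' @param labels state label per sample.
#' @param participant participant id per sample.
#' @param day collection day per sample.
#' @param seed integer seed for the subsample.
#' @return list with \code{p}, \code{n_per_group}, group medians, and the
#'   consecutive-pair table. NULL p when either group is empty.
#' @export
consecutiveShiftTest <- function(d, labels, participant, day = NULL,
                                 seed = NULL) {
  dm <- as.matrix(d)
  labels <- as.character(labels)
  if (is.null(day)) day <- stats::ave(seq_along(labels), participant,
                                      FUN = seq_along)
  rows <- list(); k <- 0L
  for (p in unique(participant)) {
    i <- which(participant == p)
    i <- i[order(day[i])]
    if (length(i) < 2) next
    for (j in seq_len(length(i) - 1)) {
      k <- k + 1L
      rows[[k]] <- data.frame(bc = dm[i[j], i[j + 1]],
                              same = labels[i[j]] == labels[i[j + 1]])
    }
  }
  tab <- do.call(rbind, rows)
  same <- tab$bc[tab$same]; diff_ <- tab$bc[!tab$same]
  if (!length(same) || !length(diff_))
    return(list(p = NULL, n_per_group = 0L, pairs = tab))
  n <- min(length(same), length(diff_))
  .withSeed(seed, {
    if (length(same) > n) same <- sample(same, n)
    if (length(diff_) > n) diff_ <- sample(diff_, n)
  })
  w <- suppressWarnings(stats::wilcox.test(same, diff_, exact = FALSE))
  list(p = w$p.value, n_per_group = n,
       median_same = stats::median(same),
       median_different = stats::median(diff_), pairs = tab)
}
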