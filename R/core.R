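#' Classify genera as temporal core, persistent, transient, cross-sectional
#' core or person-specific
#'
#' Presence is defined on the post-filter abundance matrix (genera whose
#' maximum relative abundance never exceeds the 0.5\% threshold are treated
#' as absent throughout). Per participant, with presence fraction f over the
#' collection-ordered samples and consecutive fraction c (the fraction of
#' presence observations whose previous or next collected sample is also a
#' presence):
#' \itemize{
#'   \item temporal core: f > 0.95;
#'   \item persistent: f > 0.20 and c >= 0.90;
#'   \item transient: f > 0.60 and c < 0.75.
#' }
#' Cohort-level classes: cross-sectional core = present in at least one
#' sample of every participant; person-specific = present in at least one
#' sample of exactly one participant, excluding genera detected in negative
#' controls. A genus may satisfy several per-participant predicates; all
#' satisfied classes are reported and overlaps flagged rather than forced
#' exclusive.
#'
#' @param x a \linkS4class{MicrobiomeCohort} (QMP recommended).
#' @param negative_control_genera genus ids seen in negative controls
#'   (excluded from person-specific calls).
#' @param min_rel_abundance the abundance filter threshold (see
#'   \code{\link{filterGenera}}); set to 0 to classify on raw presence.
#' @return list with \code{per_participant} (genus x participant records:
#'   presence/consecutive fractions and logical class columns),
#'   \code{cohort} (per-genus cross-sectional core / person-specific flags)
#'   and \code{temporal_core_size} (per participant).
#' @export
classifyMembership <- function(x, negative_control_genera = character(),
                               min_rel_abundance = 0.005) {
  keep <- filterGenera(x, min_rel_abundance = min_rel_abundance)
  a <- abundances(x)[keep, , drop = FALSE]
  idx <- .seriesIndex(x)
  per <- do.call(rbind, lapply(names(idx), function(p) {
    m <- a[, idx[[p]], drop = FALSE] > 0
    df <- do.call(rbind, lapply(rownames(m), function(g)
      .membershipRecord(m[g, ])))
    cbind(data.frame(participant_id = p, genus_id = rownames(m)), df)
  }))
  rownames(per) <- NULL
  per$overlap <- per$persistent & per$transient

  pres_by_part <- vapply(idx, function(i)
    rowSums(a[, i, drop = FALSE] > 0) > 0, logical(nrow(a)))
  if (is.null(dim(pres_by_part)))
    pres_by_part <- matrix(pres_by_part, nrow = nrow(a))
  n_part_present <- rowSums(pres_by_part)
  cohort <- data.frame(
    genus_id = rownames(a),
    n_participants_present = n_part_present,
    cross_sectional_core = n_part_present == length(idx),
    person_specific = n_part_present == 1 &
      !(rownames(a) %in% negative_control_genera),
    row.names = NULL
  )
  core_size <- tapply(per$temporal_core, per$participant_id, sum)
  list(per_participant = per, cohort = cohort,
       temporal_core_size = data.frame(
         participant_id = names(core_size),
         core_size = as.integer(core_size), row.names = NULL))
}

# classify one presence mask (collection-ordered logical vector)
.membershipRecord <- function(pres) {
  n <- length(pres)
  f <- mean(pres)
  cons <- NA_real_
  if (any(pres)) {
    nb <- c(FALSE, pres[-n]) | c(pres[-1], FALSE)
    cons <- sum(pres & nb) / sum(pres)
  }
  data.frame(
    presence_fraction = f,
    consecutive_fraction = cons,
    temporal_core = f > 0.95,
    persistent = f > 0.20 & !is.na(cons) & cons >= 0.90,
    transient = f > 0.60 & !is.na(cons) & cons < 0.75
  )
}

#' Temporal core size as a function of sampling effort
#'
#' For each n, repeatedly draws n samples (without replacement) from every
#' participant's series, recomputes the temporal-core size (>95\% presence
#' over the subsample) and averages over repetitions. Also reports, per
#' participant, the smallest n whose mean estimate falls within
#' \code{band} (default 90\%) of the full-series core size.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param n_samples subsample sizes; default 1 up to the shortest series.
#' @param reps repetitions per n.
#' @param band closeness band as a fraction of the full-series core size.
#' @param min_rel_abundance abundance filter threshold.
#' @param seed integer seed.
#' @return list with \code{curve} (participant, n, mean core size),
#'   \code{full_size} and \code{n_within_band} per participant.
#' @export
coreSizeAccumulation <- function(x, n_samples = NULL, reps = 200L,
                                 band = 0.9, min_rel_abundance = 0.005,
                                 seed = NULL) {
  keep <- filterGenera(x, min_rel_abundance = min_rel_abundance)
  a <- abundances(x)[keep, , drop = FALSE] > 0
  idx <- .seriesIndex(x)
  if (is.null(n_samples))
    n_samples <- seq_len(min(vapply(idx, length, 1L)))
  seeds <- .subSeeds(seed, length(idx))
  curve <- list(); full <- integer(length(idx)); nb <- integer(length(idx))
  for (pi in seq_along(idx)) {
    m <- a[, idx[[pi]], drop = FALSE]
    Tn <- ncol(m)
    full[pi] <- sum(rowMeans(m) > 0.95)
    ns <- n_samples[n_samples <= Tn]
    mean_size <- .withSeed(seeds[[pi]], vapply(ns, function(n) {
      mean(vapply(seq_len(reps), function(r) {
        j <- sample.int(Tn, n)
        sum(rowMeans(m[, j, drop = FALSE]) > 0.95)
      }, numeric(1)))
    }, numeric(1)))
    within <- abs(mean_size - full[pi]) <= (1 - band) * full[pi]
    # smallest n from which the estimate stays within the band
    stays <- rev(cumprod(rev(within))) == 1
    nb[pi] <- if (any(stays)) ns[which(stays)[1]] else NA_integer_
    curve[[pi]] <- data.frame(participant_id = names(idx)[pi], n = ns,
                              mean_core_size = mean_size)
  }
  list(curve = do.call(rbind, curve),
       full_size = data.frame(participant_id = names(idx),
                              core_size = full, row.names = NULL),
       n_within_band = data.frame(participant_id = names(idx),
                                  n = nb, row.names = NULL))
}
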