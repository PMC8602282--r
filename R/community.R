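#' Bray-Curtis dissimilarity between all samples
#'
#' BC(x, y) = sum|x - y| / sum(x + y), computed on whichever profile the
#' cohort holds (QMP or RMP). Pairs of all-zero samples are undefined (NaN).
#'
#' @param x a \linkS4class{MicrobiomeCohort} or a samples-by-features
#'   matrix.
#' @return A \code{dist} with sample labels.
#' @export
brayCurtis <- function(x) {
  m <- if (is(x, "MicrobiomeCohort")) t(abundances(x)) else as.matrix(x)
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower double-centering and eigendecomposition of a dissimilarity matrix.
#' Coordinates are returned for positive eigenvalues (ordered decreasing);
#' negative eigenvalues — which Bray-Curtis matrices routinely produce —
#' are retained and reported, not silently dropped.
#'
#' @param d a \code{dist} or symmetric matrix.
#' @param k number of coordinate axes to return (default: all positive).
#' @return list with \code{coordinates} (samples x axes),
#'   \code{eigenvalues} (all, including negative) and
#'   \code{rel_eig} (positive eigenvalues over the positive total).
#' @export
pcoaOrdination <- function(d, k = NULL) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d), tol = 1e-8))
      stop("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (is.null(k)) k <- n - 1
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- fit$points[, seq_len(min(k, npos)), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       rel_eig = pmax(eig, 0) / sum(pmax(eig, 0)))
}

#' ANOVA on multivariate homogeneity of group dispersions
#'
#' Embeds the samples by principal coordinates, measures each sample's
#' distance to its group centroid combining real and imaginary axes as
#' sqrt(max(0, d_real^2 - d_imag^2)), and runs a one-way ANOVA on those
#' distances (the \code{vegan::betadisper} construction with centroids).
#' Singleton groups are dropped with a warning.
#'
#' @param d a \code{dist} or symmetric dissimilarity matrix.
#' @param groups grouping vector aligned with the samples of \code{d}.
#' @return list with \code{dispersion} (per-group mean distance to
#'   centroid), \code{F}, \code{p}, and the underlying per-sample distances.
#' @export
dispersionTest <- function(d, groups) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  groups <- as.character(groups)
  tb <- table(groups)
  if (any(tb < 2)) {
    warning("dropping singleton group(s): ",
            paste(names(tb)[tb < 2], collapse = ", "))
    keep <- groups %in% names(tb)[tb >= 2]
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least two non-singleton groups")
  bd <- vegan::betadisper(d, factor(groups), type = "centroid")
  an <- stats::anova(bd)
  list(dispersion = tapply(bd$distances, groups, mean),
       F = an$`F value`[1], p = an$`Pr(>F)`[1],
       distances = bd$distances, groups = groups)
}

#' Within- versus between-subject dispersion, per participant
#'
#' For each participant, contrasts the dispersion of their full time series
#' against the between-individual dispersion of a one-sample-per-participant
#' reference set (by default each participant's first sample; supply
#' \code{reference_samples} to use e.g. the sample closest to the first day
#' of menses). P-values are Benjamini-Hochberg adjusted across participants.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param d optional precomputed \code{\link{brayCurtis}} distance.
#' @param reference_samples named character: one sample id per participant.
#' @return data.frame per participant: within and between dispersion, F, p,
#'   q.
#' @export
withinBetweenDispersion <- function(x, d = NULL, reference_samples = NULL) {
  if (is.null(d)) d <- brayCurtis(x)
  dm <- as.matrix(d)
  ids <- colData(x)$sample_id
  idx <- .seriesIndex(x)
  if (is.null(reference_samples))
    reference_samples <- vapply(idx, function(i) ids[i[1]], character(1))
  out <- do.call(rbind, lapply(names(idx), function(p) {
    own <- ids[idx[[p]]]
    ref <- reference_samples[setdiff(names(idx), p)]
    sel <- c(own, ref)
    grp <- c(rep("within", length(own)), rep("between", length(ref)))
    r <- dispersionTest(dm[sel, sel], grp)
    data.frame(participant_id = p,
               within = unname(r$dispersion["within"]),
               between = unname(r$dispersion["between"]),
               F = r$F, p = r$p)
  }))
  out$q <- .bh(out$p)
  rownames(out) <- NULL
  out
}

#' Similarity decay over elapsed time
#'
#' Interpolates each participant's series to daily resolution (linear per
#' genus, only across gaps of at most \code{max_gap} days; longer gaps stay
#' missing), computes Bray-Curtis dissimilarities between all within-person
#' day pairs separated by 1..\code{max_days} days, balances the design by
#' subsampling every elapsed-day stratum to the size of the smallest, and
#' fits the log-linear model log(1 - BC) ~ elapsed days. A flat slope means
#' community composition drifts no further from baseline with longer
#' sampling intervals.
#'
#' @param x a \linkS4class{MicrobiomeCohort} (QMP recommended).
#' @param max_days longest elapsed interval analysed (default 36).
#' @param max_gap longest missing-day run to interpolate across (default 3).
#' @param seed integer seed for the balanced subsample.
#' @param exclude participants to drop (e.g. perturbed series).
#' @return list with \code{fit} (slope per day, r2, adj_r2, p, n_pairs,
#'   pairs_per_day, max_days) and \code{pairs} (the balanced table).
#' @export
similarityDecay <- function(x, max_days = 36L, max_gap = 3L, seed = NULL,
                            exclude = character()) {
  idx <- .seriesIndex(x)
  idx <- idx[!names(idx) %in% exclude]
  a <- abundances(x)
  days_all <- sampleDays(x)
  span <- vapply(idx, function(i) diff(range(days_all[i])), numeric(1))
  if (all(span < max_days))
    stop("max_days exceeds every participant's day span")
  pairs <- list()
  for (p in names(idx)) {
    i <- idx[[p]]
    m <- .interpDaily(a[, i, drop = FALSE], days_all[i], max_gap)
    if (ncol(m$mat) < 2) next
    ok <- which(m$complete)
    if (length(ok) < 2) next
    bc <- as.matrix(vegan::vegdist(t(m$mat[, ok, drop = FALSE]),
                                   method = "bray"))
    dd <- abs(outer(m$days[ok], m$days[ok], "-"))
    ut <- upper.tri(dd)
    sel <- ut & dd >= 1 & dd <= max_days
    if (!any(sel)) next
    pairs[[p]] <- data.frame(participant_id = p, elapsed = dd[sel],
                             bc = bc[sel])
  }
  pairs <- do.call(rbind, pairs)
  cnt <- table(factor(pairs$elapsed, levels = seq_len(max_days)))
  if (any(cnt == 0))
    stop("no pairs at elapsed day(s) ",
         paste(names(cnt)[cnt == 0], collapse = ", "),
         "; lower max_days")
  n_per <- min(cnt)
  seeds <- .subSeeds(seed, 1)
  bal <- .withSeed(seeds[[1]], do.call(rbind, lapply(seq_len(max_days),
    function(dday) {
      sub <- pairs[pairs$elapsed == dday, ]
      sub[sample.int(nrow(sub), n_per), ]
    })))
  sim <- 1 - bal$bc
  keep <- sim > 0
  fit <- stats::lm(log(sim[keep]) ~ bal$elapsed[keep])
  sm <- summary(fit)
  list(fit = data.frame(slope = unname(stats::coef(fit)[2]),
                        slope_se = sm$coefficients[2, 2],
                        r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                        p = sm$coefficients[2, 4],
                        n_pairs = sum(keep),
                        pairs_per_day = as.integer(n_per),
                        max_days = max_days),
       pairs = bal)
}

# linear interpolation to a daily grid, per genus, across gaps <= max_gap
.interpDaily <- function(m, days, max_gap) {
  o <- order(days); days <- days[o]; m <- m[, o, drop = FALSE]
  grid <- seq(min(days), max(days))
  prev_obs <- vapply(grid, function(d) max(days[days <= d]), numeric(1))
  next_obs <- vapply(grid, function(d) min(days[days >= d]), numeric(1))
  complete <- (next_obs - prev_obs) <= max_gap
  out <- matrix(NA_real_, nrow(m), length(grid),
                dimnames = list(rownames(m), paste0("d", grid)))
  if (length(days) >= 2) {
    for (g in seq_len(nrow(m)))
      out[g, ] <- stats::approx(days, m[g, ], xout = grid)$y
  } else out[, 1] <- m[, 1]
  list(mat = out, days = grid, complete = complete)
}
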