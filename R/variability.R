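#' Intraclass correlation from one-way ANOVA variance components
#'
#' Fixed-effects one-way ANOVA estimator: var_within = MSW and
#' var_among = (MSB - MSW) / k0, with the unbalanced-design average group
#' size k0 = (N - sum(n_i^2)/N) / (k - 1); ICC =
#' var_among / (var_among + var_within). Slightly negative estimates (when
#' MSB < MSW) are reported as-is, not truncated.
#'
#' @param values numeric observations (one per sample).
#' @param groups grouping factor (e.g. participant per sample).
#' @return data.frame with \code{var_among}, \code{var_within}, \code{icc},
#'   \code{n_groups}, \code{n_obs}. Zero total variance yields \code{NA} icc.
#' @export
iccAnova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  tab <- table(groups)
  tab <- tab[tab >= 1]
  k <- length(tab); N <- sum(tab)
  stopifnot(k >= 2, all(tab >= 1))
  gm <- mean(values)
  mi <- tapply(values, groups, mean)
  ssb <- sum(tab * (mi - gm)^2)
  ssw <- sum((values - mi[groups])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  k0 <- (N - sum(tab^2) / N) / (k - 1)
  va <- (msb - msw) / k0
  vw <- msw
  icc <- if (va + vw <= 0) NA_real_ else va / (va + vw)
  data.frame(var_among = va, var_within = vw, icc = icc,
             n_groups = k, n_obs = N)
}

#' Per-genus intraclass correlation across a cohort
#'
#' Applies \code{\link{iccAnova}} genus-by-genus with participant as the
#' grouping factor, optionally after log10 transform of positive abundances
#' (zeros kept as zeros on the raw scale are excluded under \code{log10}).
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param genera genus ids to use (default: all).
#' @param transform \code{"identity"} or \code{"log10"} (positive values
#'   only).
#' @return data.frame, one row per genus.
#' @export
genusICC <- function(x, genera = NULL, transform = c("identity", "log10")) {
  transform <- match.arg(transform)
  a <- abundances(x)
  if (!is.null(genera)) a <- a[genera, , drop = FALSE]
  grp <- participants(x)
  out <- lapply(rownames(a), function(g) {
    v <- a[g, ]
    if (transform == "log10") {
      keep <- v > 0
      v <- log10(v[keep]); gg <- grp[keep]
    } else gg <- grp
    if (length(unique(gg)) < 2 || length(v) < 4)
      return(data.frame(genus_id = g, var_among = NA, var_within = NA,
                        icc = NA, n_groups = length(unique(gg)),
                        n_obs = length(v)))
    cbind(genus_id = g, iccAnova(v, gg))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Temporal coefficients of variation per genus and participant
#'
#' CV = sd/mean of a genus over a participant's detected (positive) samples;
#' participants with fewer than \code{min_detect} detections yield NA. The
#' cohort summary reduces each genus to its median CV across participants
#' and reports their mean, sd and range.
#'
#' @param x a \linkS4class{MicrobiomeCohort} (QMP or RMP).
#' @param genera genus subset (default all; pass the variability filter's
#'   output for the headline summary).
#' @param min_detect minimum detections per series.
#' @return list with \code{per_series} (participant x genus long table),
#'   \code{per_genus} (median CV per genus) and \code{summary}
#'   (\code{mean}, \code{sd}, \code{min}, \code{max} of the per-genus
#'   medians).
#' @export
genusCV <- function(x, genera = NULL, min_detect = 3L) {
  a <- abundances(x)
  if (!is.null(genera)) a <- a[genera, , drop = FALSE]
  if (!nrow(a))
    return(list(per_series = data.frame(), per_genus = data.frame(),
                summary = data.frame(mean = NA_real_, sd = NA_real_,
                                     min = NA_real_, max = NA_real_)))
  idx <- .seriesIndex(x)
  per <- do.call(rbind, lapply(names(idx), function(p) {
    m <- a[, idx[[p]], drop = FALSE]
    cv <- apply(m, 1, function(v) {
      v <- v[v > 0]
      if (length(v) < min_detect || mean(v) == 0) return(NA_real_)
      stats::sd(v) / mean(v)
    })
    data.frame(participant_id = p, genus_id = rownames(m), cv = cv,
               row.names = NULL)
  }))
  med <- tapply(per$cv, per$genus_id, stats::median, na.rm = TRUE)
  med <- med[!is.na(med)]
  list(per_series = per,
       per_genus = data.frame(genus_id = names(med), median_cv = as.numeric(med),
                              row.names = NULL),
       summary = data.frame(mean = mean(med), sd = stats::sd(med),
                            min = min(med), max = max(med)))
}

#' Maximum fold changes and rank coverage per genus and participant
#'
#' For each participant's series of a genus: the maximum ratio
#' (larger/smaller) over all pairs of positive observations
#' (\code{max_overall}), over adjacent collected samples only
#' (\code{max_consecutive}), and the span of dense abundance ranks the genus
#' covers across the participant's samples (genera ranked within each sample
#' by descending abundance; span = max rank - min rank + 1). Zeros are
#' ignored rather than pseudocounted unless \code{pseudocount = TRUE}, which
#' substitutes half the minimum positive value of the matrix.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param genera genus subset defining both the series analysed and the rank
#'   universe.
#' @param pseudocount replace zeros by half the minimum positive abundance.
#' @param rank_measure \code{"span"} (max - min + 1) or \code{"distinct"}
#'   (number of distinct ranks attained).
#' @return data.frame, one row per (participant, genus); series with fewer
#'   than two positive observations yield NA fold changes.
#' @export
foldChanges <- function(x, genera = NULL, pseudocount = FALSE,
                        rank_measure = c("span", "distinct")) {
  rank_measure <- match.arg(rank_measure)
  a <- abundances(x)
  if (!is.null(genera)) a <- a[genera, , drop = FALSE]
  if (pseudocount) {
    pc <- min(a[a > 0]) / 2
    a[a == 0] <- pc
  }
  idx <- .seriesIndex(x)
  do.call(rbind, lapply(names(idx), function(p) {
    m <- a[, idx[[p]], drop = FALSE]
    ranks <- matrix(apply(m, 2, .denseRankDesc), nrow = nrow(m))
    do.call(rbind, lapply(seq_len(nrow(m)), function(g) {
      v <- m[g, ]
      pos <- v > 0
      fo <- fc <- NA_real_
      if (sum(pos) >= 2) {
        vp <- v[pos]
        fo <- max(vp) / min(vp)
        adj <- which(pos[-length(pos)] & pos[-1])
        if (length(adj)) {
          r <- v[adj + 1] / v[adj]
          fc <- max(pmax(r, 1 / r))
        }
      }
      rk <- ranks[g, pos]
      span <- if (!length(rk)) NA_integer_
              else if (rank_measure == "span") diff(range(rk)) + 1L
              else length(unique(rk))
      data.frame(participant_id = p, genus_id = rownames(m)[g],
                 max_overall = fo, max_consecutive = fc, rank_span = span,
                 n_positive = sum(pos), row.names = NULL)
    }))
  }))
}

#' Taylor's law fit per genus
#'
#' Regresses log10 temporal variance on log10 temporal mean across
#' participants (ordinary least squares with intercept). Each participant
#' contributes one (mean, variance) point per genus, computed over the
#' participant's positive observations; series with fewer than
#' \code{min_detect} detections are dropped, and genera with fewer than
#' \code{min_points} remaining points are skipped. A slope of 2 corresponds
#' to a constant coefficient of variation across participants.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param genera genus subset.
#' @param min_detect minimum detections per participant series (default 3,
#'   so the variance is defined on at least two-degree data).
#' @param min_points minimum participants contributing points (default 5).
#' @return data.frame with \code{genus_id}, \code{slope}, \code{intercept},
#'   \code{adj_r2}, \code{p}, \code{n_points}.
#' @export
taylorFit <- function(x, genera = NULL, min_detect = 3L, min_points = 5L) {
  a <- abundances(x)
  if (!is.null(genera)) a <- a[genera, , drop = FALSE]
  idx <- .seriesIndex(x)
  out <- lapply(rownames(a), function(g) {
    pts <- vapply(idx, function(i) {
      v <- a[g, i]; v <- v[v > 0]
      if (length(v) < min_detect) return(c(NA_real_, NA_real_))
      c(mean(v), stats::var(v))
    }, numeric(2))
    m <- pts[1, ]; v <- pts[2, ]
    ok <- !is.na(m) & m > 0 & v > 0
    if (sum(ok) < min_points || stats::var(log10(m[ok])) == 0)
      return(data.frame(genus_id = g, slope = NA_real_,
                        intercept = NA_real_, adj_r2 = NA_real_,
                        p = NA_real_, n_points = sum(ok)))
    fit <- stats::lm(log10(v[ok]) ~ log10(m[ok]))
    sm <- summary(fit)
    data.frame(genus_id = g, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               adj_r2 = sm$adj.r.squared,
               p = unname(sm$coefficients[2, 4]), n_points = sum(ok))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Contrast Taylor slopes of high- versus low-ranked genera
#'
#' Two-sided Welch t-test of the Taylor slopes of the \code{top_n} genera by
#' cohort-wide mean abundance rank against all remaining genera.
#'
#' @param fits output of \code{\link{taylorFit}}.
#' @param mean_ranks named numeric: cohort-wide mean abundance rank per
#'   genus (1 = most abundant).
#' @param top_n size of the high-ranked group.
#' @return data.frame with \code{top_n}, \code{t}, \code{p}, group means.
#' @export
taylorRankContrast <- function(fits, mean_ranks, top_n) {
  fits <- fits[!is.na(fits$slope), ]
  rk <- mean_ranks[fits$genus_id]
  if (top_n >= nrow(fits)) stop("top_n must be below the number of genera")
  top <- fits$slope[rank(rk, ties.method = "first") <= top_n]
  rest <- fits$slope[rank(rk, ties.method = "first") > top_n]
  if (stats::sd(top) == 0 && stats::sd(rest) == 0 &&
      mean(top) == mean(rest))
    return(data.frame(top_n = top_n, t = 0, p = 1,
                      mean_top = mean(top), mean_rest = mean(rest)))
  tt <- stats::t.test(top, rest)
  data.frame(top_n = top_n, t = unname(tt$statistic), p = tt$p.value,
             mean_top = mean(top), mean_rest = mean(rest))
}

#' Error on median genus abundance with increasing sampling effort
#'
#' For each number of timepoints n, repeatedly draws n distinct samples from
#' each participant's series, takes per-genus medians over the subsample and
#' measures the standard deviation of those medians across repetitions —
#' averaged over the \code{top_genera} most abundant genera of each
#' participant and over participants. Also reports the curve's elbow (the n
#' at maximum perpendicular distance from the chord between the curve's
#' endpoints).
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param n_points vector of subsample sizes (default 1..21).
#' @param reps repetitions per n (default 10000).
#' @param top_genera number of most-abundant genera per participant.
#' @param seed integer seed.
#' @param relative express each genus error relative to its mean abundance
#'   before averaging, so abundant genera do not dominate the curve.
#' @return list with \code{curve} (data.frame n, error) and \code{elbow}.
#' @export
medianErrorCurve <- function(x, n_points = 1:21, reps = 1e4,
                             top_genera = 100L, seed = NULL,
                             relative = TRUE) {
  a <- abundances(x)
  idx <- .seriesIndex(x)
  short <- vapply(idx, length, 1L) < max(n_points)
  if (any(short)) idx <- idx[!short]
  stopifnot(length(idx) >= 1)
  seeds <- .subSeeds(seed, length(idx))
  errs <- matrix(0, length(n_points), length(idx))
  for (pi in seq_along(idx)) {
    m <- a[, idx[[pi]], drop = FALSE]
    g <- utils::head(order(rowMeans(m), decreasing = TRUE),
                     min(top_genera, nrow(m)))
    m <- m[g, , drop = FALSE]
    Tn <- ncol(m)
    gm <- rowMeans(m)
    sc <- if (relative) ifelse(gm > 0, gm, 1) else rep(1, nrow(m))
    .withSeed(seeds[[pi]], {
      for (ni in seq_along(n_points)) {
        n <- n_points[ni]
        draw <- vapply(seq_len(reps), function(r)
          sample.int(Tn, n), integer(n))
        sds <- cpp_median_sd(m, matrix(draw, nrow = n))
        errs[ni, pi] <- mean(sds / sc)
      }
    })
  }
  curve <- data.frame(n = n_points, error = rowMeans(errs))
  list(curve = curve, elbow = .elbow(curve$n, curve$error))
}

# point of maximum perpendicular distance from the chord
.elbow <- function(x, y) {
  if (length(x) < 3) return(x[1])
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  x[which.max(d)]
}
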