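# Dickey-Fuller critical values, drift (constant, no trend) specification,
# for sample sizes 25, 50, 100, 250, 500, Inf at tail probabilities
# 0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99 (Fuller's tau_mu table).
.DF_TAU_MU <- list(
  n = c(25, 50, 100, 250, 500, Inf),
  p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
  crit = rbind(
    c(-3.75, -3.33, -3.00, -2.63, -0.37, 0.00, 0.34, 0.72),
    c(-3.58, -3.22, -2.93, -2.60, -0.40, -0.03, 0.29, 0.66),
    c(-3.51, -3.17, -2.89, -2.58, -0.42, -0.05, 0.26, 0.63),
    c(-3.46, -3.14, -2.88, -2.57, -0.42, -0.06, 0.24, 0.62),
    c(-3.44, -3.13, -2.87, -2.57, -0.43, -0.07, 0.24, 0.61),
    c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
  )
)

#' Augmented Dickey-Fuller unit-root test (drift, no trend)
#'
#' Fits the regression
#' \deqn{\Delta y_t = \alpha + \rho y_{t-1} + \sum_{i=1}^{p} \phi_i
#'   \Delta y_{t-i} + \epsilon_t}
#' and tests \eqn{\rho = 0} (unit root) against \eqn{\rho < 0} using the
#' Dickey-Fuller t-distribution; the p-value is interpolated from the
#' drift-case critical-value table over both sample size and significance
#' level, clamped to [0.01, 0.99]. Rejection (small p) indicates
#' stationarity: fluctuation around an equilibrium level rather than a
#' random walk. The drift-only specification matches that hypothesis (no
#' deterministic trend under the alternative).
#'
#' @param y numeric series (length >= 10).
#' @param n_lags number of lagged differences p. The default selects p in
#'   0..floor((n-1)^(1/3)) by AIC of the ADF regression (superfluous lags
#'   cost the test most of its power at these series lengths); pass a fixed
#'   value to pin the order.
#' @param alpha significance level for the \code{stationary} flag.
#' @return data.frame with \code{statistic}, \code{p}, \code{n_lags},
#'   \code{stationary}.
#' @export
adfTest <- function(y, n_lags = NULL, alpha = 0.05) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("series too short for the ADF regression (need >= 10)")
  if (stats::sd(y) == 0)
    return(data.frame(statistic = NA_real_, p = NA_real_,
                      n_lags = NA_integer_, stationary = NA))
  if (is.null(n_lags)) {
    pmax_ <- max(0L, floor((n - 1)^(1 / 3)))
    # compare AIC on the common estimation window (rows lost to pmax_)
    aics <- vapply(0:pmax_, function(p)
      .adfRegression(y, p, align = pmax_)$aic, numeric(1))
    n_lags <- (0:pmax_)[which.min(aics)]
  }
  r <- .adfRegression(y, n_lags)
  p <- .dfPValue(r$stat, r$n_used)
  data.frame(statistic = r$stat, p = p, n_lags = n_lags,
             stationary = p < alpha)
}

.adfRegression <- function(y, k, align = k) {
  n <- length(y)
  dy <- diff(y)
  t_idx <- (align + 1):(n - 1)
  X <- cbind(ylag = y[t_idx])
  if (k > 0)
    for (i in seq_len(k)) X <- cbind(X, dy[t_idx - i])
  fit <- stats::lm(dy[t_idx] ~ X)
  list(stat = summary(fit)$coefficients[2, "t value"],  # the y_{t-1} term
       aic = stats::AIC(fit), n_used = length(t_idx))
}

.dfPValue <- function(stat, n) {
  tb <- .DF_TAU_MU
  crit <- vapply(seq_along(tb$p), function(j)
    stats::approx(tb$n, tb$crit[, j], xout = n, rule = 2)$y, numeric(1))
  stats::approx(crit, tb$p, xout = stat, rule = 2)$y
}

#' Stationarity screen over a cohort's genus series
#'
#' Applies \code{\link{adfTest}} to each participant's series of each genus
#' present in more than \code{min_presence} of that participant's samples
#' (series below the threshold are skipped and recorded). Returns the
#' per-series results and the per-participant fraction classified
#' stationary.
#'
#' @param x a \linkS4class{MicrobiomeCohort} (QMP recommended).
#' @param genera genus subset.
#' @param min_presence minimum presence fraction (default 0.6).
#' @param alpha significance level.
#' @return list with \code{per_series} and \code{per_participant}
#'   data.frames.
#' @export
adfStationarity <- function(x, genera = NULL, min_presence = 0.6,
                            alpha = 0.05) {
  a <- abundances(x)
  if (!is.null(genera)) a <- a[genera, , drop = FALSE]
  idx <- .seriesIndex(x)
  per <- do.call(rbind, lapply(names(idx), function(p) {
    m <- a[, idx[[p]], drop = FALSE]
    do.call(rbind, lapply(rownames(m), function(g) {
      v <- m[g, ]
      pres <- mean(v > 0)
      if (pres <= min_presence || length(v) < 10)
        return(data.frame(participant_id = p, genus_id = g,
                          presence = pres, statistic = NA_real_,
                          p = NA_real_, stationary = NA,
                          skipped = TRUE))
      r <- adfTest(v, alpha = alpha)
      data.frame(participant_id = p, genus_id = g, presence = pres,
                 statistic = r$statistic, p = r$p,
                 stationary = r$stationary, skipped = FALSE)
    }))
  }))
  tested <- per[!per$skipped & !is.na(per$stationary), ]
  frac <- tapply(tested$stationary, tested$participant_id, mean)
  list(per_series = per,
       per_participant = data.frame(participant_id = names(frac),
                                    frac_stationary = as.numeric(frac),
                                    row.names = NULL))
}
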