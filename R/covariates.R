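#' Daily energy intake and macronutrient energy fractions
#'
#' EI = 9 kcal/g x fat + 4 kcal/g x protein + 4 kcal/g x carbohydrate;
#' percent energy intake per macronutrient and the protein/carbohydrate
#' energy ratio P/C (defined only when carbohydrate energy is positive).
#' Zero total energy yields NA fractions.
#'
#' @param diet data.frame with \code{carb_g}, \code{protein_g},
#'   \code{fat_g} (other columns are carried through).
#' @return The input with \code{ei_kcal}, \code{carb_pct}, \code{protein_pct},
#'   \code{fat_pct}, \code{pc_ratio} appended.
#' @export
energyIntake <- function(diet) {
  stopifnot(all(c("carb_g", "protein_g", "fat_g") %in% colnames(diet)))
  mass <- as.matrix(diet[, c("carb_g", "protein_g", "fat_g")])
  if (any(mass < 0, na.rm = TRUE)) stop("negative dietary mass")
  ei <- 4 * diet$carb_g + 4 * diet$protein_g + 9 * diet$fat_g
  carb <- ifelse(ei > 0, 100 * 4 * diet$carb_g / ei, NA_real_)
  prot <- ifelse(ei > 0, 100 * 4 * diet$protein_g / ei, NA_real_)
  fat <- ifelse(ei > 0, 100 * 9 * diet$fat_g / ei, NA_real_)
  diet$ei_kcal <- ei
  diet$carb_pct <- carb
  diet$protein_pct <- prot
  diet$fat_pct <- fat
  diet$pc_ratio <- ifelse(!is.na(carb) & carb > 0, prot / carb, NA_real_)
  diet
}

#' Personal dietary lag from diet-moisture cross-correlation
#'
#' Starts from a standard one-day lag (average gut transit time) and
#' adjusts it per participant from the cross-correlation between the
#' protein/carbohydrate energy ratio and stool moisture: if a significant
#' correlation (|r| > 1.96/sqrt(n)) at some lag in \code{search_lags}
#' (diet leading, days 2..5) is stronger than the lag-1 correlation, the
#' lag moves there; if the strongest significant correlation sits at lag 0
#' (same day), the lag becomes 0 only when the majority of the
#' participant's samples were collected in the late afternoon or evening
#' (otherwise digestion cannot plausibly be same-day and the default
#' stands).
#'
#' @param pc_ratio named-by-day or plain numeric P/C series (index = day).
#' @param moisture numeric moisture series on the same day grid (NA for
#'   missing days).
#' @param sampling_time optional character vector of the participant's
#'   sampling-time categories (used for the same-day rule; the category
#'   \code{"afternoon_evening"} counts as late).
#' @param search_lags candidate lags in days (default 1..5; lag 0 is always
#'   examined for the evening rule).
#' @param min_overlap minimum pairwise-complete observations per lag.
#' @return data.frame with \code{lag_days}, \code{best_ccf_lag},
#'   per-lag correlations (\code{ccf_0} .. ), \code{significant},
#'   \code{rationale} (one of default / ccf_adjusted / evening_sampling).
#' @export
dietaryLag <- function(pc_ratio, moisture, sampling_time = NULL,
                       search_lags = 1:5, min_overlap = 10L) {
  stopifnot(length(pc_ratio) == length(moisture))
  lags <- sort(unique(c(0L, search_lags)))
  n_days <- length(pc_ratio)
  cc <- vapply(lags, function(k) {
    if (k >= n_days) return(NA_real_)
    x <- pc_ratio[seq_len(n_days - k)]
    y <- moisture[seq_len(n_days - k) + k]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_overlap) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  names(cc) <- paste0("ccf_", lags)
  nn <- vapply(lags, function(k) {
    if (k >= n_days) return(0L)
    sum(!is.na(pc_ratio[seq_len(n_days - k)]) &
          !is.na(moisture[seq_len(n_days - k) + k]))
  }, integer(1))
  sig <- abs(cc) > 1.96 / sqrt(pmax(nn, 1))
  res <- data.frame(lag_days = 1L, best_ccf_lag = NA_integer_,
                    significant = FALSE, rationale = "default")
  if (all(is.na(cc))) {
    out <- cbind(res, as.data.frame(as.list(cc)))
    return(out)
  }
  best <- lags[which.max(abs(cc))]
  res$best_ccf_lag <- best
  r1 <- cc[match(1L, lags)]
  if (!is.na(cc[which.max(abs(cc))]) && sig[which.max(abs(cc))]) {
    res$significant <- TRUE
    if (best >= 2 && (is.na(r1) || abs(cc[which.max(abs(cc))]) > abs(r1))) {
      res$lag_days <- best
      res$rationale <- "ccf_adjusted"
    } else if (best == 0) {
      evening <- !is.null(sampling_time) &&
        mean(sampling_time %in% c("afternoon_evening", "evening",
                                  "late_afternoon"), na.rm = TRUE) > 0.5
      if (evening) {
        res$lag_days <- 0L
        res$rationale <- "evening_sampling"
      }
    }
  }
  cbind(res, as.data.frame(as.list(cc)))
}

#' Synthetic standard menstrual-cycle hormone curves
#'
#' A parameterised 28-day reference profile for estrogen and progesterone:
#' estrogen with a pre-ovulatory peak just before the day-14 LH reference
#' and a broad luteal plateau; progesterone low in the follicular phase and
#' peaking mid-luteal (~day 21). The shapes are log-normal-like bumps —
#' a synthetic stand-in with the canonical qualitative form, not measured
#' population data; supply your own 28-row curve for quantitative work.
#'
#' @return data.frame with \code{day} (1..28), \code{estrogen},
#'   \code{progesterone} (arbitrary units).
#' @export
standardHormoneCurve <- function() {
  day <- 1:28
  bump <- function(center, width, height)
    height * exp(-0.5 * ((day - center) / width)^2)
  estrogen <- 40 + bump(13, 1.8, 220) + bump(21, 3.5, 90)
  progesterone <- 1 + bump(21, 3.0, 14)
  data.frame(day = day, estrogen = estrogen, progesterone = progesterone)
}

#' Personal hormone profile for an arbitrary cycle length
#'
#' The luteal phase (final 14 days of the standard 28-day curve) varies
#' little between cycles, so length adjustment only touches the beginning:
#' cycles shorter than 28 days drop days from the start of the curve;
#' longer cycles insert extrapolated early days, where the day beyond the
#' standard 28 at distance x carries
#' \code{level(day1) + (level(day1) - level(day28)) * exp(-x)} — converging
#' to the day-1 level as x grows. For \code{cycle_length = 28} the personal
#' profile is the standard curve exactly.
#'
#' @param cycle_length cycle length in days; values outside [21, 45] are
#'   clamped with a warning.
#' @param curve 28-value numeric vector (or the data.frame from
#'   \code{\link{standardHormoneCurve}}, in which case every hormone column
#'   is adjusted).
#' @param cycle_day optional day (1..cycle_length) to evaluate at; default
#'   returns the whole profile.
#' @return numeric vector of length \code{cycle_length} (or a data.frame
#'   when \code{curve} is one), or the single level at \code{cycle_day}.
#' @export
inferHormones <- function(cycle_length, curve = standardHormoneCurve(),
                          cycle_day = NULL) {
  if (is.data.frame(curve)) {
    hcols <- setdiff(colnames(curve), "day")
    out <- data.frame(day = seq_len(.clampCycle(cycle_length)))
    for (h in hcols)
      out[[h]] <- inferHormones(cycle_length, curve[[h]])
    if (!is.null(cycle_day)) return(out[out$day == cycle_day, ])
    return(out)
  }
  stopifnot(length(curve) == 28)
  L <- .clampCycle(cycle_length)
  if (L == 28) prof <- curve
  else if (L < 28) prof <- curve[(28 - L + 1):28]
  else {
    x <- seq_len(L - 28)
    extra <- curve[1] + (curve[1] - curve[28]) * exp(-x)
    prof <- c(extra, curve)
  }
  if (!is.null(cycle_day)) return(prof[cycle_day])
  prof
}

.clampCycle <- function(cycle_length) {
  L <- as.integer(round(cycle_length))
  if (L < 21 || L > 45) {
    warning("cycle length ", L, " outside [21, 45]; clamped")
    L <- min(max(L, 21L), 45L)
  }
  L
}
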