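#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

.COHORT_UNITS <- c("reads", "relative", "cells_per_gram")

#' MicrobiomeCohort: a longitudinal genus-abundance table with sample metadata
#'
#' An extension of \linkS4class{SummarizedExperiment} holding one abundance
#' assay (genera in rows, samples in columns) together with the per-sample
#' annotations a longitudinal quantitative-profiling analysis needs:
#' participant identifier, study day (0-based, relative to each participant's
#' first sample), microbial load (cells per gram of faecal material, from flow
#' cytometry), stool moisture (percent), Bristol Stool Score, sampling time
#' and medication flags. Per-genus 16S rRNA gene copy numbers live in
#' \code{rowData}; per-participant daily diet records and the abundance unit
#' live in \code{metadata}.
#'
#' The abundance unit is one of \code{"reads"} (non-negative integers),
#' \code{"relative"} (rows with positive totals sum to one) or
#' \code{"cells_per_gram"} (a quantitative profile).
#'
#' @slot unit character(1), the abundance unit.
#' @export
setClass("MicrobiomeCohort",
  contains = "SummarizedExperiment",
  slots = c(unit = "character")
)

setValidity("MicrobiomeCohort", function(object) {
  msg <- character()
  if (length(object@unit) != 1L || !object@unit %in% .COHORT_UNITS)
    msg <- c(msg, sprintf("unit must be one of %s",
                          paste(.COHORT_UNITS, collapse = ", ")))
  a <- assay(object, "abundance")
  if (any(!is.finite(a)))
    msg <- c(msg, "abundance matrix contains non-finite values")
  else if (any(a < 0))
    msg <- c(msg, "abundance matrix contains negative values")
  cd <- colData(object)
  need <- c("sample_id", "participant_id", "day")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(cd$sample_id))
      msg <- c(msg, "duplicate sample_id")
    if (anyDuplicated(paste(cd$participant_id, cd$day)))
      msg <- c(msg, "duplicate (participant_id, day) pair")
    if (identical(object@unit, "reads") && any(abs(a - round(a)) > 1e-8))
      msg <- c(msg, "unit 'reads' requires integer counts")
    if (identical(object@unit, "relative")) {
      tot <- colSums(a)
      bad <- tot > 0 & abs(tot - 1) > 1e-9
      if (any(bad))
        msg <- c(msg, "unit 'relative' requires nonzero columns to sum to 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MicrobiomeCohort
#'
#' @param abundance numeric matrix, samples in rows and genera in columns
#'   (the orientation tabular inputs come in; it is transposed to the
#'   genera-by-samples SummarizedExperiment layout internally).
#' @param participant character vector of participant identifiers, one per
#'   sample.
#' @param day integer vector of study days (0-based within participant).
#' @param unit abundance unit, one of \code{"reads"}, \code{"relative"},
#'   \code{"cells_per_gram"}.
#' @param sample_id optional sample identifiers; default
#'   \code{<participant>_d<day>}.
#' @param load,moisture,bss numeric per-sample microbial load (cells/g),
#'   stool moisture (percent) and Bristol Stool Score; \code{NA} where not
#'   measured.
#' @param sampling_time factor/character per-sample collection time category.
#' @param medication logical per-sample medication flag (or a data.frame of
#'   several flags).
#' @param copy_numbers named numeric vector of per-genus 16S copy numbers.
#' @param diet data.frame of per-participant daily diet records (see
#'   \code{\link{energyIntake}}).
#' @return A \linkS4class{MicrobiomeCohort}. Samples are ordered by
#'   participant then day.
#' @export
MicrobiomeCohort <- function(abundance, participant, day,
                             unit = c("reads", "relative", "cells_per_gram"),
                             sample_id = NULL, load = NULL, moisture = NULL,
                             bss = NULL, sampling_time = NULL,
                             medication = NULL, copy_numbers = NULL,
                             diet = NULL) {
  unit <- match.arg(unit)
  abundance <- as.matrix(abundance)
  if (any(abundance < 0, na.rm = TRUE)) stop("negative abundance")
  n <- nrow(abundance)
  participant <- as.character(participant)
  day <- as.integer(day)
  stopifnot(length(participant) == n, length(day) == n)
  if (is.null(sample_id)) sample_id <- sprintf("%s_d%d", participant, day)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id")
  if (is.null(colnames(abundance)))
    colnames(abundance) <- sprintf("g%03d", seq_len(ncol(abundance)))
  fill <- function(x) if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
  cd <- DataFrame(
    sample_id = as.character(sample_id),
    participant_id = participant,
    day = day,
    load = fill(load),
    moisture = fill(moisture),
    bss = fill(bss),
    sampling_time = if (is.null(sampling_time)) rep(NA_character_, n)
                    else as.character(sampling_time),
    row.names = as.character(sample_id)
  )
  if (!is.null(medication)) {
    if (is.data.frame(medication)) {
      for (cn in colnames(medication)) cd[[cn]] <- medication[[cn]]
    } else cd$medication <- as.logical(medication)
  }
  rd <- DataFrame(genus_id = colnames(abundance),
                  row.names = colnames(abundance))
  if (!is.null(copy_numbers)) {
    cnv <- copy_numbers[colnames(abundance)]
    if (anyNA(cnv)) {
      mcn <- mean(copy_numbers, na.rm = TRUE)
      message(sum(is.na(cnv)), " genera absent from the copy-number map; ",
              "assigned the map mean (", signif(mcn, 4), ")")
      cnv[is.na(cnv)] <- mcn
    }
    rd$copy_number <- as.numeric(cnv)
  }
  o <- order(cd$participant_id, cd$day)
  se <- SummarizedExperiment(
    assays = SimpleList(abundance = t(abundance)[, o, drop = FALSE]),
    colData = cd[o, , drop = FALSE], rowData = rd
  )
  obj <- new("MicrobiomeCohort", se, unit = unit)
  if (!is.null(diet)) metadata(obj)$diet <- diet
  validObject(obj)
  obj
}

#' Parameters of the synthetic longitudinal cohort generator
#'
#' Bundles the knobs of \code{\link{simulateCohort}}. Defaults reproduce the
#' structure of a dense 20-person near-daily 16S time series: ~36 candidate
#' days per participant with occasional missed collections (~96\% sample
#' completeness), microbial loads in the 6e10--22e10 cells/g range, stool
#' moisture between 52 and 93 percent correlating negatively with load and
#' responding to the protein/carbohydrate dietary ratio at a one-day lag,
#' per-genus log-normal fluctuation around per-participant equilibria with
#' mean--variance scaling controlled by a Taylor exponent, and four Dirichlet
#' community templates visited by a slowly switching continuous-time Markov
#' chain.
#'
#' @param n_participants,n_days,n_genera cohort dimensions.
#' @param taylor_slope target Taylor-law exponent b in var = c * mean^b across
#'   participants (2 gives a constant coefficient of variation).
#' @param genus_cv_range range the per-genus temporal coefficients of
#'   variation are drawn from (log-uniform).
#' @param icc_target average intraclass correlation of log10 genus abundance
#'   (between-participant spread of equilibria relative to total variance).
#' @param ar_coef AR(1) coefficient of the latent log10 abundance process.
#' @param load_range target microbial load range, cells/g.
#' @param daily_load_sd log10 SD of a shared AR(1) day factor scaling all
#'   genera of a sample together (day-to-day total-biomass swings; cancels
#'   out of relative profiles but not quantitative ones).
#' @param moisture_range stool moisture range, percent.
#' @param n_states number of community templates (enterotype-like states).
#' @param state_switch_prob daily probability of leaving the current state.
#' @param state_effect log10 fold boost the state applies to its driver genera
#'   (0 disables community states).
#' @param diet_lag_days lag (days) at which diet drives moisture.
#' @param depth mean sequencing depth (reads/sample).
#' @param detection_limit relative cell abundances below this fraction are
#'   truncated to zero before read sampling (sparse absences).
#' @param drop_prob probability a candidate day is a missed collection.
#' @param seed integer seed; every draw is reproducible from it.
#' @return A list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(n_participants = 20L, n_days = 36L, n_genera = 150L,
                       taylor_slope = 2, genus_cv_range = c(0.4, 2.5),
                       icc_target = 0.35, ar_coef = 0.3,
                       load_range = c(6e10, 22e10), daily_load_sd = 0.15,
                       moisture_range = c(52, 93),
                       n_states = 4L, state_switch_prob = 0.05,
                       state_effect = 0.6, diet_lag_days = 1L,
                       depth = 3e4, detection_limit = 1e-4,
                       drop_prob = 0.036, seed = 1L) {
  stopifnot(n_participants >= 2, n_days >= 3, n_genera >= 5,
            diff(genus_cv_range) >= 0, diff(load_range) >= 0,
            diff(moisture_range) >= 0,
            state_switch_prob >= 0, state_switch_prob <= 1)
  if (taylor_slope <= 0) stop("infeasible Taylor target: slope must be > 0")
  spec <- as.list(environment())
  class(spec) <- "CohortSpec"
  spec
}

#' A depth-optimised quantitative microbiome profile build
#'
#' Result of \code{\link{buildQMP}}: the chosen even sampling depth (corrected
#' reads per cell), per-sample corrected depths, the retained/excluded sample
#' partition and the cells-per-gram profile.
#'
#' @slot qmp a \linkS4class{MicrobiomeCohort} with unit \code{cells_per_gram}.
#' @slot target_depth numeric(1), the chosen sampling depth D.
#' @slot sampling_depth named numeric, per-sample d_s = corrected depth / load.
#' @slot corrected_depth named numeric, per-sample copy-number-corrected read
#'   totals.
#' @slot rarefied_reads named numeric, reads each retained sample was rarefied
#'   to (round(D * load)).
#' @slot retained,excluded character sample ids; \code{excluded_reason} gives
#'   \code{"low_reads"} (corrected depth below the minimum upfront) or
#'   \code{"below_min_after_rarefaction"}.
#' @export
setClass("QMPBuild", slots = c(
  qmp = "MicrobiomeCohort", target_depth = "numeric",
  sampling_depth = "numeric", corrected_depth = "numeric",
  rarefied_reads = "numeric", retained = "character",
  excluded = "character", excluded_reason = "character",
  min_reads = "numeric"
))

#' A fitted Dirichlet multinomial mixture
#'
#' @slot K integer, number of components.
#' @slot weights numeric simplex of mixture weights.
#' @slot alpha K x G matrix of positive Dirichlet parameters.
#' @slot responsibilities n x K posterior membership matrix.
#' @slot assignment integer hard labels (max responsibility).
#' @slot logLik numeric(1) final log-likelihood.
#' @slot fit_metric numeric(1) negative log model evidence (Laplace; BIC
#'   fallback where the Hessian is not positive definite).
#' @slot state_names character component labels (e.g. Bact1/Bact2/Rum/Prev).
#' @slot converged logical(1).
#' @export
setClass("DMMModel", slots = c(
  K = "integer", weights = "numeric", alpha = "matrix",
  responsibilities = "matrix", assignment = "integer",
  logLik = "numeric", fit_metric = "numeric", state_names = "character",
  converged = "logical"
))

#' A continuous-time Markov multi-state model with covariates
#'
#' Transition intensities follow \code{q_rs(z) = q_rs0 * exp(beta_rs . z)};
#' the likelihood is a product of matrix-exponential transition probabilities
#' between successive observations (snapshot observation scheme).
#'
#' @slot states character state labels.
#' @slot Q baseline intensity matrix (rows sum to zero).
#' @slot beta array n_trans x n_covariates of log risk ratios.
#' @slot par,se packed parameter vector (log q, then beta) and standard errors.
#' @slot logLik numeric(1) maximised log-likelihood.
#' @slot covariates character covariate names.
#' @slot trans_idx two-column matrix of allowed (from, to) state indices.
#' @slot convergence integer optim convergence code.
#' @export
setClass("CTMCModel", slots = c(
  states = "character", Q = "matrix", beta = "matrix",
  par = "numeric", se = "numeric", logLik = "numeric",
  covariates = "character", trans_idx = "matrix", convergence = "integer",
  n_obs = "integer"
))
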