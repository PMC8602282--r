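#' @include AllClasses.R
NULL

#' Accessors for MicrobiomeCohort
#'
#' \code{abundances} returns the genera-by-samples matrix;
#' \code{abundanceUnit} the unit; \code{participants} and \code{sampleDays}
#' the per-sample annotations; \code{microbialLoads}, \code{stoolMoisture}
#' the per-sample measurements; \code{copyNumbers} the per-genus 16S copy
#' numbers (NULL when none were attached); \code{dietRecords} the diet table.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @return See description.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
abundances <- function(x) assay(x, "abundance")

#' @rdname cohort-accessors
#' @export
abundanceUnit <- function(x) x@unit

#' @rdname cohort-accessors
#' @export
participants <- function(x) colData(x)$participant_id

#' @rdname cohort-accessors
#' @export
sampleDays <- function(x) colData(x)$day

#' @rdname cohort-accessors
#' @export
microbialLoads <- function(x) {
  stats::setNames(colData(x)$load, colData(x)$sample_id)
}

#' @rdname cohort-accessors
#' @export
stoolMoisture <- function(x) {
  stats::setNames(colData(x)$moisture, colData(x)$sample_id)
}

#' @rdname cohort-accessors
#' @export
copyNumbers <- function(x) {
  rd <- rowData(x)
  if (!"copy_number" %in% colnames(rd)) return(NULL)
  stats::setNames(rd$copy_number, rd$genus_id)
}

#' @rdname cohort-accessors
#' @export
dietRecords <- function(x) metadata(x)$diet

setMethod("show", "MicrobiomeCohort", function(object) {
  cat("MicrobiomeCohort (", object@unit, ")\n", sep = "")
  cat("  ", nrow(object), " genera x ", ncol(object), " samples, ",
      length(unique(participants(object))), " participants\n", sep = "")
  if (!all(is.na(colData(object)$load)))
    cat("  microbial load: ",
        sum(!is.na(colData(object)$load)), "/", ncol(object),
        " samples measured\n", sep = "")
  invisible(NULL)
})

setMethod("show", "QMPBuild", function(object) {
  cat("QMPBuild: target depth D =", format(object@target_depth, digits = 6),
      "corrected reads/cell\n")
  cat("  retained ", length(object@retained), " samples, excluded ",
      length(object@excluded), sep = "")
  if (length(object@excluded)) {
    tb <- table(object@excluded_reason)
    cat(" (", paste(names(tb), tb, sep = ": ", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(NULL)
})

setMethod("show", "DMMModel", function(object) {
  cat("DMMModel: K =", object@K, "components over",
      ncol(object@alpha), "genera\n")
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n")
  cat("  logLik:", format(object@logLik, digits = 8),
      " negative log-evidence:", format(object@fit_metric, digits = 8), "\n")
  if (length(object@state_names))
    cat("  states:", paste(object@state_names, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "CTMCModel", function(object) {
  cat("CTMCModel over states:", paste(object@states, collapse = ", "), "\n")
  cat("  logLik:", format(object@logLik, digits = 8),
      " covariates:", if (length(object@covariates))
        paste(object@covariates, collapse = ", ") else "(none)", "\n")
  cat("  baseline intensities (per day):\n")
  print(round(object@Q, 5))
  invisible(NULL)
})

#' Subset a cohort to a set of samples or genera
#'
#' Thin wrappers over SummarizedExperiment subsetting that keep the unit.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param samples character sample ids or logical/integer index.
#' @param genera character genus ids or logical/integer index.
#' @return A \linkS4class{MicrobiomeCohort}.
#' @export
subsetCohort <- function(x, samples = NULL, genera = NULL) {
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, colData(x)$sample_id)
    x <- x[, samples]
  }
  if (!is.null(genera)) {
    if (is.character(genera)) genera <- match(genera, rowData(x)$genus_id)
    x <- x[genera, ]
  }
  x
}

#' Convert a cohort to relative abundances
#'
#' Divides every sample by its total; all-zero samples stay zero.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @return A \linkS4class{MicrobiomeCohort} with unit \code{"relative"}.
#' @export
relativeAbundances <- function(x) {
  a <- abundances(x)
  tot <- colSums(a)
  tot[tot == 0] <- 1
  a <- sweep(a, 2, tot, "/")
  assay(x, "abundance") <- a
  x@unit <- "relative"
  validObject(x)
  x
}

# split sample indices by participant, each ordered by day
.seriesIndex <- function(x) {
  cd <- colData(x)
  idx <- split(seq_len(ncol(x)), cd$participant_id)
  lapply(idx, function(i) i[order(cd$day[i])])
}
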