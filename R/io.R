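#' Read a longitudinal cohort from tabular files
#'
#' Assembles a validated \linkS4class{MicrobiomeCohort} from four plain-text
#' tables: a count table (samples in rows, genera in columns, first column
#' the sample id), a sample metadata table, an optional per-participant daily
#' diet table and an optional two-column genus copy-number table. Samples
#' missing a microbial load are retained but flagged (and excluded later by
#' \code{\link{buildQMP}}); genera absent from the copy-number map are
#' assigned the map mean with a message. Row order of the inputs is
#' irrelevant: samples are sorted by participant and day on load.
#'
#' @param counts_path TSV of counts; integer entries unless
#'   \code{unit != "reads"}.
#' @param meta_path TSV with columns (after \code{col_map} renaming)
#'   \code{sample_id}, \code{participant_id}, \code{day}, and optionally
#'   \code{load}, \code{moisture}, \code{bss}, \code{sampling_time},
#'   \code{medication}.
#' @param diet_path optional TSV with \code{participant_id}, \code{day},
#'   \code{carb_g}, \code{protein_g}, \code{fat_g}, \code{fiber_g},
#'   \code{sodium_g} and optionally \code{cycle_day}, \code{cycle_length}.
#' @param cn_path optional TSV with \code{genus_id}, \code{copy_number}.
#' @param unit abundance unit of the count table.
#' @param col_map named character vector mapping the documented column names
#'   to the names actually present, e.g. \code{c(load = "cells_per_g")};
#'   supplied because deposited tables rarely agree on a schema.
#' @return A \linkS4class{MicrobiomeCohort}.
#' @export
readCohort <- function(counts_path, meta_path, diet_path = NULL,
                       cn_path = NULL, unit = "reads", col_map = character()) {
  counts <- utils::read.delim(counts_path, check.names = FALSE)
  rownames(counts) <- as.character(counts[[1]])
  counts <- as.matrix(counts[, -1, drop = FALSE])
  if (any(counts < 0)) stop("negative abundance in ", counts_path)
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  for (std in names(col_map)) {
    j <- match(col_map[[std]], colnames(meta))
    if (!is.na(j)) colnames(meta)[j] <- std
  }
  need <- c("sample_id", "participant_id", "day")
  if (!all(need %in% colnames(meta)))
    stop("metadata must provide columns ", paste(need, collapse = ", "),
         " (use col_map to rename)")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  miss <- setdiff(rownames(counts), meta$sample_id)
  if (length(miss))
    stop("samples in counts without metadata: ",
         paste(utils::head(miss, 5), collapse = ", "))
  meta <- meta[match(rownames(counts), meta$sample_id), ]
  cn <- NULL
  if (!is.null(cn_path)) {
    cnt <- utils::read.delim(cn_path, stringsAsFactors = FALSE)
    if (any(cnt[[2]] < 1 | !is.finite(cnt[[2]])))
      stop("copy numbers must be finite and >= 1")
    cn <- stats::setNames(as.numeric(cnt[[2]]), as.character(cnt[[1]]))
  }
  diet <- NULL
  if (!is.null(diet_path)) {
    diet <- utils::read.delim(diet_path, stringsAsFactors = FALSE)
    mass <- intersect(c("carb_g", "protein_g", "fat_g", "fiber_g", "sodium_g"),
                      colnames(diet))
    if (any(as.matrix(diet[mass]) < 0, na.rm = TRUE))
      stop("negative dietary mass")
  }
  pick <- function(col) if (col %in% colnames(meta)) meta[[col]] else NULL
  MicrobiomeCohort(
    counts, participant = meta$participant_id, day = meta$day, unit = unit,
    sample_id = meta$sample_id, load = pick("load"),
    moisture = pick("moisture"), bss = pick("bss"),
    sampling_time = pick("sampling_time"),
    medication = if ("medication" %in% colnames(meta))
      as.logical(meta$medication) else NULL,
    copy_numbers = cn, diet = diet
  )
}

#' Read a count table from a BIOM file
#'
#' Reads a (JSON, v1) BIOM-format table into the samples-by-genera count
#' matrix \code{\link{readCohort}} and \code{\link{MicrobiomeCohort}} expect.
#'
#' @param path a BIOM file.
#' @return numeric matrix, samples in rows, genera in columns.
#' @export
readCountsBiom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("readCountsBiom requires the biomformat package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
  t(m)
}

#' Write a cohort back to tabular files
#'
#' Emits the counts / metadata / diet / copy-number files
#' \code{\link{readCohort}} reads, with deterministic column order. Floats
#' are written at 12 significant digits, so integer count tables round-trip
#' exactly and quantitative tables to ~1e-12 relative error.
#'
#' @param x a \linkS4class{MicrobiomeCohort}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the named vector of files written.
#' @export
writeCohort <- function(x, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, paste0(prefix, "_", name, ".tsv"))
  out <- c(counts = f("counts"), meta = f("meta"))
  a <- t(abundances(x))
  df <- data.frame(sample_id = rownames(a), signif(a, 12),
                   check.names = FALSE)
  if (abundanceUnit(x) == "reads")
    df[-1] <- lapply(df[-1], function(v) as.integer(round(v)))
  utils::write.table(df, out["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(colData(x))
  utils::write.table(cd, out["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(copyNumbers(x))) {
    out["copy_numbers"] <- f("copy_numbers")
    utils::write.table(
      data.frame(genus_id = names(copyNumbers(x)),
                 copy_number = signif(copyNumbers(x), 12)),
      out["copy_numbers"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(dietRecords(x))) {
    out["diet"] <- f("diet")
    utils::write.table(dietRecords(x), out["diet"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(out)
}

#' Write a pipeline result to disk
#'
#' Tabular results (data.frames) go to TSV with deterministic column order
#' and 12-significant-digit floats; nested results (lists,
#' \linkS4class{DMMModel}, \linkS4class{CTMCModel}, \linkS4class{QMPBuild})
#' go to JSON.
#'
#' @param object a result object.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"json"}; default picks by type.
#' @return Invisibly, \code{path}.
#' @export
writeResults <- function(object, path, format = NULL) {
  if (is.null(format))
    format <- if (is.data.frame(object)) "tsv" else "json"
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (format == "tsv") {
    if (!is.data.frame(object)) object <- as.data.frame(object)
    num <- vapply(object, is.double, logical(1))
    object[num] <- lapply(object[num], signif, digits = 12)
    utils::write.table(object, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(.asSerializable(object), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

.asSerializable <- function(object) {
  if (isVirtualClass(class(object)) || !isS4(object)) {
    if (is.data.frame(object)) return(object)
    if (is.list(object)) return(lapply(object, .asSerializable))
    return(object)
  }
  out <- lapply(slotNames(object), function(s) {
    v <- slot(object, s)
    if (isS4(v)) class(v) else v
  })
  names(out) <- slotNames(object)
  out
}
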