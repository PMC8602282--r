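#' Rarefy a count vector or cohort to an even read depth
#'
#' Subsampling is without replacement (multivariate hypergeometric): the
#' rarefied entries never exceed the originals and sum exactly to
#' \code{depth}. Samples with fewer reads than \code{depth} are not an error
#' — they are dropped and reported, matching the exclusion contract of
#' relative profiling at a fixed depth.
#'
#' @param x a \linkS4class{MicrobiomeCohort} with unit \code{"reads"}, or a
#'   single non-negative integer vector of counts.
#' @param depth target read depth (default 10000, the standard depth for
#'   relative profiles).
#' @param seed integer seed.
#' @return For a vector: the rarefied vector (or \code{NULL} when the total
#'   is below \code{depth}). For a cohort: a list with \code{cohort} (the
#'   retained, rarefied samples, unit reads) and \code{excluded} (sample ids
#'   dropped for insufficient reads).
#' @export
rarefyCounts <- function(x, depth = 1e4, seed = NULL) {
  stopifnot(depth > 0)
  if (is.numeric(x) && is.null(dim(x))) {
    if (sum(x) < depth) return(NULL)
    if (sum(x) == depth) return(x)
    return(.withSeed(seed, .rmvhyper(x, depth)))
  }
  stopifnot(is(x, "MicrobiomeCohort"), abundanceUnit(x) == "reads")
  a <- abundances(x)
  keep <- colSums(a) >= depth
  .withSeed(seed, {
    for (j in which(keep)) {
      if (sum(a[, j]) > depth) a[, j] <- .rmvhyper(a[, j], depth)
    }
  })
  out <- x[, keep]
  assay(out, "abundance") <- a[, keep, drop = FALSE]
  list(cohort = out, excluded = colData(x)$sample_id[!keep])
}

#' Build relative microbiome profiles (RMP)
#'
#' Rarefies every sample to a fixed depth and converts to proportions.
#'
#' @inheritParams rarefyCounts
#' @return list with \code{rmp} (unit \code{"relative"}) and \code{excluded}.
#' @export
buildRMP <- function(x, depth = 1e4, seed = NULL) {
  r <- rarefyCounts(x, depth = depth, seed = seed)
  list(rmp = relativeAbundances(r$cohort), excluded = r$excluded)
}

#' Copy-number-corrected sequencing depth
#'
#' The total of genus read counts divided by their 16S rRNA gene copy
#' numbers, sum(count_g / cn_g): an estimate of the number of cells actually
#' sequenced rather than amplicons.
#'
#' @param counts non-negative count vector (or matrix, genera in rows).
#' @param cn copy numbers aligned to \code{counts} (names matched when
#'   present).
#' @return numeric corrected depth (one per sample for matrix input).
#' @export
correctedDepth <- function(counts, cn) {
  if (is.matrix(counts)) {
    cn <- .alignCn(cn, rownames(counts), nrow(counts))
    return(colSums(counts / cn))
  }
  cn <- .alignCn(cn, names(counts), length(counts))
  sum(counts / cn)
}

.alignCn <- function(cn, ids, n) {
  if (!is.null(names(cn)) && !is.null(ids)) cn <- cn[ids]
  if (length(cn) == 1) cn <- rep(cn, n)
  if (anyNA(cn)) stop("unmapped genera in copy-number vector")
  if (any(cn < 1)) stop("copy numbers must be >= 1")
  cn
}

#' Build quantitative microbiome profiles (QMP) at an optimised even depth
#'
#' Converts read counts to cells per gram by rarefying each sample's
#' copy-number-corrected reads to an even \emph{sampling depth} — corrected
#' reads per cell, d_s = corrected_depth_s / load_s — and scaling the
#' resulting composition by the flow-cytometric load. The target depth D is
#' chosen among the observed d_s values to retain as many samples as
#' possible subject to every retained sample keeping at least
#' \code{min_reads} corrected reads after rarefaction (round(D x load_s));
#' ties favour the larger D (more reads per sample). Samples whose corrected
#' depth is below \code{min_reads} can never be retained and are excluded
#' upfront (\code{"low_reads"}); the rest of the non-retained samples carry
#' reason \code{"below_min_after_rarefaction"}. Samples without a load
#' measurement are excluded upfront as well.
#'
#' Rarefaction on the corrected scale draws round(D x load_s) reads from a
#' multinomial with probabilities proportional to count_g / cn_g (corrected
#' "reads" are fractional, so an exact without-replacement subsample is not
#' defined; the multinomial is the matching probability model).
#'
#' @param x a \linkS4class{MicrobiomeCohort} with unit \code{"reads"}, loads
#'   and copy numbers attached (or supplied via \code{loads} / \code{cn}).
#' @param min_reads minimum corrected reads per retained sample (default
#'   500).
#' @param loads optional named per-sample loads overriding the cohort's.
#' @param cn optional named per-genus copy numbers overriding the cohort's.
#' @param seed integer seed for the rarefaction draws.
#' @return A \linkS4class{QMPBuild}.
#' @export
buildQMP <- function(x, min_reads = 500, loads = NULL, cn = NULL,
                     seed = NULL) {
  stopifnot(is(x, "MicrobiomeCohort"), abundanceUnit(x) == "reads")
  a <- abundances(x)
  ids <- colData(x)$sample_id
  if (is.null(loads)) loads <- microbialLoads(x) else loads <- loads[ids]
  if (is.null(cn)) cn <- copyNumbers(x)
  if (is.null(cn)) stop("no copy numbers available")
  cn <- .alignCn(cn, rownames(a), nrow(a))

  cdepth <- colSums(a / cn)
  usable <- !is.na(loads) & loads > 0
  d_s <- ifelse(usable, cdepth / loads, NA_real_)
  names(d_s) <- names(cdepth) <- ids
  upfront <- usable & cdepth < min_reads
  eligible <- usable & !upfront

  cand <- sort(unique(d_s[usable]))
  if (!length(cand)) stop("no sample has a usable load")
  best <- NULL
  for (D in cand) {
    ret <- eligible & d_s >= D & round(D * loads) >= min_reads
    if (is.null(best) || sum(ret) > best$n ||
        (sum(ret) == best$n && D > best$D))
      best <- list(D = D, n = sum(ret), ret = ret)
  }
  if (best$n < 1) stop("no candidate depth retains any sample")
  retained <- ids[which(best$ret)]
  excluded <- setdiff(ids, retained)
  reason <- ifelse(!usable, "no_load",
                   ifelse(upfront, "low_reads",
                          "below_min_after_rarefaction"))[match(excluded, ids)]
  names(reason) <- excluded

  target_reads <- round(best$D * loads[retained])
  probs <- sweep(a[, retained, drop = FALSE], 1, cn, "/")
  qa <- matrix(0, nrow(a), length(retained),
               dimnames = list(rownames(a), retained))
  .withSeed(seed, {
    for (j in seq_along(retained)) {
      draw <- stats::rmultinom(1, target_reads[j], probs[, j])
      qa[, j] <- draw / sum(draw) * loads[retained[j]]
    }
  })
  keep <- match(retained, ids)
  qmp <- x[, keep]
  assay(qmp, "abundance") <- qa
  qmp@unit <- "cells_per_gram"
  validObject(qmp)
  new("QMPBuild", qmp = qmp, target_depth = best$D,
      sampling_depth = d_s, corrected_depth = cdepth,
      rarefied_reads = target_reads, retained = retained,
      excluded = excluded, excluded_reason = reason,
      min_reads = min_reads)
}

#' Alpha diversity of one sample or every sample of a cohort
#'
#' Observed richness S (taxa with positive abundance), Shannon index
#' H = -sum p_i ln p_i (natural log) and Pielou evenness J = H / ln S.
#' J is undefined (NA) for S <= 1; an all-zero sample yields all-NA.
#'
#' @param x a non-negative abundance vector, or a
#'   \linkS4class{MicrobiomeCohort}.
#' @return A one-row (or per-sample) data.frame with \code{richness},
#'   \code{shannon}, \code{pielou}.
#' @export
alphaDiversity <- function(x) {
  if (is(x, "MicrobiomeCohort")) {
    a <- abundances(x)
    out <- do.call(rbind, lapply(seq_len(ncol(a)), function(j)
      alphaDiversity(a[, j])))
    out <- cbind(data.frame(sample_id = colData(x)$sample_id,
                            participant_id = participants(x)), out)
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(all(x >= 0))
  if (sum(x) == 0)
    return(data.frame(richness = NA_integer_, shannon = NA_real_,
                      pielou = NA_real_))
  p <- x[x > 0] / sum(x)
  S <- length(p)
  H <- -sum(p * log(p))
  data.frame(richness = S, shannon = H,
             pielou = if (S >= 2) H / log(S) else NA_real_)
}

#' Filter genera by maximum relative abundance and prevalence
#'
#' Keeps genera whose maximum within-cohort relative abundance exceeds
#' \code{min_rel_abundance} (default 0.5\%, the detection-noise threshold
#' for genus-level 16S profiles) and — when \code{min_participants} /
#' \code{min_samples} are given — genera present in more than
#' \code{min_participants} participants with more than \code{min_samples}
#' positive samples each (the variability filter: >5 individuals, >3
#' samples).
#'
#' @param x a \linkS4class{MicrobiomeCohort} (any unit; converted to
#'   relative internally for the abundance criterion).
#' @param min_rel_abundance maximum relative abundance a genus must exceed
#'   somewhere in the cohort.
#' @param min_participants,min_samples optional prevalence criterion
#'   (strict: present in \emph{more than} this many).
#' @return Character vector of retained genus ids.
#' @export
filterGenera <- function(x, min_rel_abundance = 0.005,
                         min_participants = NULL, min_samples = NULL) {
  rel <- abundances(relativeAbundances(x))
  keep <- apply(rel, 1, max) > min_rel_abundance
  if (!is.null(min_participants)) {
    if (is.null(min_samples)) min_samples <- 0
    pos <- abundances(x) > 0
    npos <- t(rowsum(t(pos) * 1, participants(x)))  # genus x participant
    keep <- keep & rowSums(npos > min_samples) > min_participants
  }
  rownames(rel)[keep]
}
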