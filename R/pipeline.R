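#' Run the full longitudinal analysis on a cohort
#'
#' Chains the pipeline stages — profiling (QMP and/or RMP), alpha diversity
#' and ICC, temporal variability (CV, fold changes, stationarity, Taylor's
#' law), core membership, community structure (dispersion, similarity
#' decay), optional enterotyping against a background with transition
#' statistics and a moisture CTMC, and host covariates (energy intake,
#' dietary lag) — writing deterministic TSV/JSON results plus a
#' reproducibility manifest. Any stage failure preserves the results
#' written so far and re-raises the error.
#'
#' @param cohort a \linkS4class{MicrobiomeCohort} of read counts with loads
#'   and copy numbers (e.g. \code{simulateCohort()$cohort}).
#' @param out_dir output directory.
#' @param seed master seed; every random stage receives a derived sub-seed.
#' @param profile \code{"qmp"}, \code{"rmp"} or \code{"both"}.
#' @param background optional background \linkS4class{MicrobiomeCohort}
#'   (read counts) enabling the enterotyping and transition stages.
#' @param rmp_depth,min_reads,min_rel_abundance pipeline thresholds
#'   (defaults: 10000 reads, 500 corrected reads, 0.5\%).
#' @param decay_max_days similarity-decay horizon (days).
#' @param enterotype_mode passed to \code{\link{iterativeEnterotyping}}.
#' @return Invisibly, a named list of the stage results.
#' @export
runCohortAnalysis <- function(cohort, out_dir, seed = 1L,
                              profile = c("qmp", "rmp", "both"),
                              background = NULL, rmp_depth = 1e4,
                              min_reads = 500, min_rel_abundance = 0.005,
                              decay_max_days = 21L,
                              enterotype_mode = "assign") {
  profile <- match.arg(profile)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .subSeeds(seed, 10)
  results <- list()
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  on.exit({
    writeLines(log_lines, file.path(out_dir, "run.log"))
    manifest <- list(
      package_version = as.character(utils::packageVersion("mbtemporal")),
      r_version = R.version.string, seed = seed, profile = profile,
      thresholds = list(rmp_depth = rmp_depth, min_reads = min_reads,
                        min_rel_abundance = min_rel_abundance,
                        decay_max_days = decay_max_days),
      n_samples = ncol(cohort),
      n_participants = length(unique(participants(cohort))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }, add = TRUE)

  profiles <- list()
  if (profile %in% c("qmp", "both")) {
    say("building QMP")
    qb <- buildQMP(cohort, min_reads = min_reads, seed = seeds[[1]])
    results$qmp_build <- qb
    writeResults(data.frame(sample_id = qb@excluded,
                            reason = qb@excluded_reason),
                 file.path(out_dir, "qmp_exclusions.tsv"))
    writeCohort(qb@qmp, out_dir, "qmp")
    profiles$qmp <- qb@qmp
  }
  if (profile %in% c("rmp", "both")) {
    say("building RMP at depth ", rmp_depth)
    rb <- buildRMP(cohort, depth = rmp_depth, seed = seeds[[2]])
    results$rmp <- rb
    writeCohort(rb$rmp, out_dir, "rmp")
    profiles$rmp <- rb$rmp
  }

  for (pname in names(profiles)) {
    prof <- profiles[[pname]]
    tag <- function(f) file.path(out_dir, paste0(pname, "_", f))
    say("analysing ", pname, " profile")
    genera <- filterGenera(prof, min_rel_abundance = min_rel_abundance)
    var_genera <- filterGenera(prof, min_rel_abundance = min_rel_abundance,
                               min_participants = 5, min_samples = 3)
    alpha <- alphaDiversity(prof)
    writeResults(alpha, tag("alpha.tsv"))
    icc_alpha <- do.call(rbind, lapply(
      c("richness", "shannon", "pielou"), function(mm)
        cbind(metric = mm, iccAnova(alpha[[mm]], alpha$participant_id))))
    writeResults(icc_alpha, tag("icc_alpha.tsv"))
    results[[paste0(pname, "_icc_alpha")]] <- icc_alpha
    icc_gen <- genusICC(prof, genera = genera, transform = "log10")
    writeResults(icc_gen, tag("icc_genus.tsv"))
    results[[paste0(pname, "_icc_genus")]] <- icc_gen

    cv <- genusCV(prof, genera = var_genera)
    writeResults(cv$per_genus, tag("cv.tsv"))
    results[[paste0(pname, "_cv")]] <- cv
    fc <- foldChanges(prof, genera = genera)
    writeResults(fc, tag("fold_changes.tsv"))
    results[[paste0(pname, "_fold_changes")]] <- fc
    adf <- adfStationarity(prof, genera = genera)
    writeResults(adf$per_participant, tag("adf.tsv"))
    results[[paste0(pname, "_adf")]] <- adf
    tl <- taylorFit(prof, genera = var_genera)
    writeResults(tl, tag("taylor.tsv"))
    results[[paste0(pname, "_taylor")]] <- tl

    core <- classifyMembership(prof, min_rel_abundance = min_rel_abundance)
    writeResults(core$per_participant, tag("membership.tsv"))
    results[[paste0(pname, "_core")]] <- core

    d <- brayCurtis(prof)
    disp <- withinBetweenDispersion(prof, d = d)
    writeResults(disp, tag("dispersion.tsv"))
    results[[paste0(pname, "_dispersion")]] <- disp
    decay <- tryCatch(
      similarityDecay(prof, max_days = decay_max_days, seed = seeds[[3]]),
      error = function(e) { say("similarity decay skipped: ",
                                conditionMessage(e)); NULL })
    if (!is.null(decay)) {
      writeResults(decay$fit, tag("decay.tsv"))
      results[[paste0(pname, "_decay")]] <- decay
    }
  }

  if (!is.null(background)) {
    say("enterotyping against background")
    rmp_study <- if ("rmp" %in% names(profiles))
      results$rmp$rmp else buildRMP(cohort, depth = rmp_depth,
                                    seed = seeds[[2]])$rmp
    study_counts <- rarefyCounts(cohort, depth = rmp_depth,
                                 seed = seeds[[4]])$cohort
    et <- iterativeEnterotyping(study_counts, background,
                                seed = seeds[[5]], mode = enterotype_mode)
    writeResults(et$labels, file.path(out_dir, "enterotypes.tsv"))
    writeResults(et$model, file.path(out_dir, "dmm_model.json"))
    results$enterotypes <- et

    lab <- et$labels
    tn <- transitionNull(lab$state_name, lab$participant_id,
                         day = sampleDays(study_counts))
    writeResults(tn$table, file.path(out_dir, "transition_null.tsv"))
    results$transition_null <- tn

    say("fitting moisture CTMC")
    mc <- stoolMoisture(study_counts)
    ok <- !is.na(mc)
    ct <- tryCatch(
      ctmcFit(lab$state[ok], lab$participant_id[ok],
              sampleDays(study_counts)[ok],
              covariates = cbind(moisture = as.numeric(scale(mc[ok]))),
              states = et$model@state_names),
      error = function(e) { say("CTMC skipped: ", conditionMessage(e)); NULL })
    if (!is.null(ct)) {
      writeResults(riskRatios(ct), file.path(out_dir, "ctmc_risk_ratios.tsv"))
      results$ctmc <- ct
    }
  }

  diet <- dietRecords(cohort)
  if (!is.null(diet)) {
    say("host covariates")
    ei <- energyIntake(diet)
    writeResults(ei, file.path(out_dir, "energy_intake.tsv"))
    results$energy <- ei
    lags <- do.call(rbind, lapply(split(ei, ei$participant_id), function(dd) {
      dd <- dd[order(dd$day), ]
      days <- dd$day
      pc <- rep(NA_real_, max(days) + 1); pc[days + 1] <- dd$pc_ratio
      cd <- colData(cohort)
      sel <- cd$participant_id == dd$participant_id[1]
      mc <- rep(NA_real_, max(days) + 1)
      sd_ok <- cd$day[sel] <= max(days)
      mc[cd$day[sel][sd_ok] + 1] <- cd$moisture[sel][sd_ok]
      cbind(participant_id = dd$participant_id[1],
            dietaryLag(pc, mc, sampling_time = cd$sampling_time[sel]))
    }))
    writeResults(lags, file.path(out_dir, "dietary_lags.tsv"))
    results$dietary_lags <- lags
  }
  say("done")
  invisible(results)
}
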