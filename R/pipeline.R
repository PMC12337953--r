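#' @include AllClasses.R classify.R chcdf.R llps.R stats.R synthetic.R
NULL

.writeTsv <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.logLines <- function(path, lines) {
  if (length(lines)) cat(lines, file = path, sep = "\n", append = TRUE)
}

.asProteomeList <- function(proteomes) {
  if (is(proteomes, "Proteome")) proteomes <- list(proteomes)
  proteomes <- lapply(proteomes, function(p) {
    if (is.character(p)) readProteome(p) else p
  })
  stopifnot(all(vapply(proteomes, is, logical(1), "Proteome")))
  names(proteomes) <- vapply(proteomes, proteomeName, character(1))
  proteomes
}

#' Profile one or more proteomes
#'
#' Runs the full per-proteome pipeline: per-residue disorder profiles,
#' ADS/PPDR summaries and tier counts, CH-CDF points under a calibrated
#' boundary, and PS-IDR profiles with the cumulative-length curve. Writes
#' one TSV per output per proteome into \code{out_dir}
#' (\code{<name>_disorder.tsv}, \code{<name>_tiers.tsv},
#' \code{<name>_chcdf.tsv}, \code{<name>_ps.tsv}, \code{<name>_curve.tsv})
#' plus a \code{run_log.txt} with one line per skipped record. Outputs are
#' deterministic given inputs and configuration.
#'
#' @param proteomes a [Proteome-class], a list of them, or FASTA paths.
#' @param out_dir output directory (created if absent); \code{NULL} skips
#'   writing and only returns results.
#' @param predictor,window passed to [disorderProfiles()].
#' @param boundary a [CDFBoundary-class]; by default calibrated once from
#'   the packaged synthetic reference sets.
#' @param llps_config see [llpsConfig()].
#' @param thresholds see [classificationThresholds()].
#' @return (invisibly when writing) a named list per proteome with elements
#'   \code{summary}, \code{tiers}, \code{chcdf}, \code{ps}, \code{curve}.
#' @export
runProfile <- function(proteomes, out_dir = NULL, predictor = "foldindex",
                       window = 21, boundary = NULL,
                       llps_config = llpsConfig(),
                       thresholds = classificationThresholds()) {
  proteomes <- .asProteomeList(proteomes)
  if (is.null(boundary)) {
    refs <- generateReferenceSets()
    boundary <- calibrateCdfBoundary(refs$ordered, refs$disordered,
                                     predictor, window)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log_path <- if (!is.null(out_dir)) file.path(out_dir, "run_log.txt")
  results <- list()
  for (nm in names(proteomes)) {
    p <- proteomes[[nm]]
    profiles <- disorderProfiles(p, predictor, window)
    summ <- disorderSummary(p, profiles, thresholds)
    psum <- proteomeSummary(summ)
    tiers <- data.frame(tier = names(psum$counts),
                        count = unname(psum$counts),
                        percent = unname(psum$percentages))
    points <- chcdfPoints(p, boundary, predictor, window)
    ps <- psProfiles(p, llps_config)
    curve <- cumulativePsCurve(ps)
    if (!is.null(out_dir)) {
      .writeTsv(summ, file.path(out_dir, paste0(nm, "_disorder.tsv")))
      .writeTsv(tiers, file.path(out_dir, paste0(nm, "_tiers.tsv")))
      .writeTsv(points, file.path(out_dir, paste0(nm, "_chcdf.tsv")))
      .writeTsv(ps, file.path(out_dir, paste0(nm, "_ps.tsv")))
      .writeTsv(curve, file.path(out_dir, paste0(nm, "_curve.tsv")))
      sk <- skippedRecords(p)
      .logLines(log_path, sprintf("[%s] skipped on import: %s (%s)", nm,
                                  sk$id, sk$reason))
      dropped <- ps[!is.na(ps$skipped), , drop = FALSE]
      .logLines(log_path, sprintf("[%s] skipped in PS analysis: %s (%s)",
                                  nm, dropped$id, dropped$skipped))
    }
    results[[nm]] <- list(summary = summ, tiers = tiers, chcdf = points,
                          ps = ps, curve = curve)
  }
  if (is.null(out_dir)) results else invisible(results)
}

#' Compare proteomes: ANOVA, Tukey, pairwise t, quadrant chi-squared,
#' recall AUC
#'
#' Cross-proteome inference over the profiling results: one-way ANOVA with
#' Tukey HSD and pairwise Welch t for ADS, PPDR and PS score; the
#' proteome-by-quadrant contingency table with its Pearson chi-squared; and
#' recall AUCs of every proteome against the named reference.
#'
#' @param proteomes as in [runProfile()] (>= 2 proteomes).
#' @param reference name of the reference proteome for recall AUC.
#' @param out_dir optional output directory for TSV reports.
#' @param ... passed to [runProfile()].
#' @return list with \code{anova} (per metric), \code{tukey},
#'   \code{pairwise}, \code{contingency}, \code{chi2}, \code{recall_auc},
#'   and the underlying \code{profiles}.
#' @export
runCompare <- function(proteomes, reference = NULL, out_dir = NULL, ...) {
  proteomes <- .asProteomeList(proteomes)
  if (length(proteomes) < 2L) stop("need >= 2 proteomes to compare")
  if (!is.null(reference) && !reference %in% names(proteomes))
    stop("reference '", reference, "' is not among the proteomes")
  prof <- runProfile(proteomes, out_dir = NULL, ...)
  groups <- list(
    ads = lapply(prof, function(r) r$summary$ads),
    ppdr = lapply(prof, function(r) r$summary$ppdr),
    ps_score = lapply(prof, function(r)
      r$ps$ps_score[!is.na(r$ps$ps_score)])
  )
  anova <- lapply(groups, oneWayAnova)
  tukey <- lapply(groups, tukeyHsd)
  pairwise <- lapply(groups, pairwiseT)
  tab <- quadrantContingency(lapply(prof, function(r) r$chcdf))
  # quadrants unoccupied across every proteome carry no information and
  # would zero a column; they are excluded from the test, not the table
  occupied <- colSums(tab) > 0
  chi2 <- chiSquaredTest(tab[, occupied, drop = FALSE])
  recall <- NULL
  if (!is.null(reference)) {
    ref_scores <- groups$ps_score[[reference]]
    recall <- data.frame(
      proteome = names(prof),
      auc = vapply(names(prof), function(nm)
        recallAuc(groups$ps_score[[nm]], ref_scores), numeric(1))
    )
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    av <- data.frame(metric = names(anova),
                     f = vapply(anova, `[[`, numeric(1), "f_stat"),
                     p = vapply(anova, `[[`, numeric(1), "p_value"))
    .writeTsv(av, file.path(out_dir, "anova.tsv"))
    for (m in names(tukey))
      .writeTsv(tukey[[m]], file.path(out_dir, paste0("tukey_", m, ".tsv")))
    for (m in names(pairwise))
      .writeTsv(pairwise[[m]],
                file.path(out_dir, paste0("pairwise_", m, ".tsv")))
    .writeTsv(cbind(proteome = rownames(tab), as.data.frame(tab)),
              file.path(out_dir, "quadrant_counts.tsv"))
    chi_report <- data.frame(chi2 = chi2$chi2, dof = chi2$dof,
                             p_value = chi2$p_value)
    .writeTsv(chi_report, file.path(out_dir, "chi2.tsv"))
    if (!is.null(recall)) .writeTsv(recall, file.path(out_dir, "recall_auc.tsv"))
  }
  list(anova = anova, tukey = tukey, pairwise = pairwise,
       contingency = tab, chi2 = chi2, recall_auc = recall,
       profiles = prof)
}

#' Overlap analysis of a test proteome against a reference
#'
#' Splits the test proteome into proteins shared with the reference and
#' proteins unique to it, then compares ADS, PPDR and PS score between the
#' two groups (ANOVA over the two groups plus Welch t). When either group
#' is empty the statistics are skipped with a logged notice.
#'
#' @param test,reference [Proteome-class] objects or FASTA paths.
#' @param out_dir optional output directory.
#' @param ... passed to [runProfile()].
#' @return list with \code{split} (from [overlapSplit()]),
#'   \code{membership} (\code{DataFrame} id/group), \code{stats} (per
#'   metric, or \code{NULL} when a group is empty) and \code{notice}.
#' @export
runOverlap <- function(test, reference, out_dir = NULL, ...) {
  pl <- .asProteomeList(list(test, reference))
  test <- pl[[1]]; reference <- pl[[2]]
  sp <- overlapSplit(test, reference)
  membership <- S4Vectors::DataFrame(
    id = c(sp$overlap_ids, sp$unique_ids),
    group = rep(c("overlap", "unique"),
                c(length(sp$overlap_ids), length(sp$unique_ids))))
  notice <- NULL
  stats_out <- NULL
  if (length(sp$overlap_ids) < 2L || length(sp$unique_ids) < 2L) {
    notice <- "overlap or unique group too small; statistics skipped"
  } else {
    prof <- runProfile(test, out_dir = NULL, ...)[[1]]
    byGroup <- function(values, ids) {
      names(values) <- ids
      list(overlap = unname(values[sp$overlap_ids]),
           unique = unname(values[sp$unique_ids]))
    }
    mk <- list(
      ads = byGroup(prof$summary$ads, prof$summary$id),
      ppdr = byGroup(prof$summary$ppdr, prof$summary$id),
      ps_score = lapply(byGroup(prof$ps$ps_score, prof$ps$id),
                        function(v) v[!is.na(v)])
    )
    stats_out <- lapply(mk, function(g) {
      list(anova = oneWayAnova(g), t = pairwiseT(g))
    })
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .writeTsv(membership, file.path(out_dir, "overlap_membership.tsv"))
    if (!is.null(notice))
      .logLines(file.path(out_dir, "run_log.txt"), notice)
  }
  list(split = sp, membership = membership, stats = stats_out,
       notice = notice)
}

#' Simulate a synthetic proteome to disk
#'
#' Thin wrapper over [generateProteome()] that writes FASTA plus the
#' ground-truth label TSV.
#'
#' @inheritParams generateProteome
#' @param out_dir output directory.
#' @return invisibly, the written paths.
#' @export
runSimulate <- function(n, mixture, seed, out_dir, name = "synthetic",
                        length_range = c(100, 500)) {
  g <- generateProteome(n, mixture, seed, name, length_range)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  writeSyntheticProteome(g,
    file.path(out_dir, paste0(name, ".fasta")),
    file.path(out_dir, paste0(name, "_labels.tsv")))
}
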