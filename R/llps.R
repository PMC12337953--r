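#' @include AllClasses.R disorder.R
NULL

# pi-contact / sticker-prone residue set used by the contact feature
.STICKER <- c("R", "G", "F", "Y", "W", "Q", "S")

#' Configuration for PS-IDR detection
#'
#' @param window sliding-window length in residues (default 25).
#' @param min_region minimum PS-IDR length in residues (default 20).
#' @param min_seq,max_seq sequence-length bounds; proteins outside
#'   [min_seq, max_seq] are skipped and logged (defaults 25 and 10,000).
#' @param contact_threshold minimum sticker-residue fraction for a window to
#'   be phase-separation prone (default 0.4).
#' @return a validated named list.
#' @export
llpsConfig <- function(window = 25, min_region = 20, min_seq = 25,
                       max_seq = 10000, contact_threshold = 0.4) {
  stopifnot(window >= 3, min_region >= 1, min_seq <= max_seq,
            contact_threshold >= 0, contact_threshold <= 1)
  list(window = as.integer(window), min_region = as.integer(min_region),
       min_seq = as.integer(min_seq), max_seq = as.integer(max_seq),
       contact_threshold = contact_threshold)
}

#' Window features for phase-separation classification
#'
#' For one window: \code{disorder_proxy} is the charge-hydropathy score of
#' the window (positive = disordered side, see [chScore()]);
#' \code{contact_proxy} is the fraction of residues in the sticker-prone set
#' \{R, G, F, Y, W, Q, S\}.
#'
#' @param window_sequence amino-acid string of exactly the configured window
#'   length.
#' @param config see [llpsConfig()].
#' @return named numeric vector (disorder_proxy, contact_proxy).
#' @export
windowFeatures <- function(window_sequence, config = llpsConfig()) {
  chars <- .seqChars(window_sequence)
  if (length(chars) != config$window)
    stop("window sequence must have length ", config$window)
  c(disorder_proxy = chScore(window_sequence),
    contact_proxy = mean(chars %in% .STICKER))
}

# vectorised window features over all windows of a sequence
.allWindowFeatures <- function(chars, window) {
  n <- length(chars)
  nw <- n - window + 1L
  q <- .CHARGE[chars]; q[is.na(q)] <- 0
  h <- .residueValues(chars, .KD_NORM, "hydropathy")
  s <- as.numeric(chars %in% .STICKER)
  wsum <- function(x) {
    cs <- cumsum(c(0, x))
    cs[(window + 1L):(n + 1L)] - cs[1:nw]
  }
  list(disorder = abs(wsum(unname(q)) / window) -
         2.785 * wsum(h) / window + 1.151,
       contact = wsum(s) / window)
}

#' Classify sliding windows as P, D or F
#'
#' Labels every window of the sequence: \code{P} (phase-separation-prone
#' disordered) when the disorder proxy is positive and the contact proxy
#' reaches the threshold; \code{D} (disordered, non-PS) when only the
#' disorder proxy is positive; \code{F} (folded-prone) otherwise.
#' Sequences outside the configured length bounds are not classified: the
#' function returns an empty vector with attribute \code{"skipped"} giving
#' the reason (the caller logs it).
#'
#' @param sequence amino-acid string or \code{AAString}.
#' @param config see [llpsConfig()].
#' @return character vector with one label per window (position i labels
#'   the window starting at residue i); length zero with a \code{"skipped"}
#'   attribute if the sequence was excluded.
#' @export
classifyWindows <- function(sequence, config = llpsConfig()) {
  chars <- .seqChars(sequence)
  n <- length(chars)
  if (n < config$min_seq || n > config$max_seq) {
    return(structure(character(0), skipped = sprintf(
      "sequence length %d outside [%d, %d]", n, config$min_seq,
      config$max_seq)))
  }
  f <- .allWindowFeatures(chars, config$window)
  ifelse(f$disorder > 0,
         ifelse(f$contact >= config$contact_threshold, "P", "D"),
         "F")
}

#' Extract PS-IDRs from window labels
#'
#' Residues covered by any P-labelled window are P-residues; maximal runs of
#' consecutive P-residues at least \code{min_region} long become regions.
#'
#' @param window_labels labels from [classifyWindows()].
#' @param config see [llpsConfig()].
#' @return an \code{IRanges} of PS-IDRs (1-based, inclusive).
#' @export
findPsIdrs <- function(window_labels, config = llpsConfig()) {
  w <- config$window
  nw <- length(window_labels)
  n <- nw + w - 1L
  covered <- logical(n)
  p <- which(window_labels == "P")
  for (i in p) covered[i:(i + w - 1L)] <- TRUE
  r <- IRanges::reduce(IRanges::IRanges(covered))
  r[IRanges::width(r) >= config$min_region]
}

#' PS profile of one protein
#'
#' @param sequence amino-acid string.
#' @param config see [llpsConfig()].
#' @return list with \code{regions} (\code{IRanges}),
#'   \code{max_region_length}, \code{ps_score} (fraction of residues covered
#'   by PS-IDRs), and \code{skipped} (reason string or \code{NA}).
#' @export
psProfile <- function(sequence, config = llpsConfig()) {
  labels <- classifyWindows(sequence, config)
  if (length(labels) == 0L) {
    return(list(regions = IRanges::IRanges(), max_region_length = 0L,
                ps_score = NA_real_, skipped = attr(labels, "skipped")))
  }
  regions <- findPsIdrs(labels, config)
  n <- nchar(as.character(sequence))
  list(regions = regions,
       max_region_length = if (length(regions)) max(IRanges::width(regions))
                           else 0L,
       ps_score = sum(IRanges::width(regions)) / n,
       skipped = NA_character_)
}

#' PS profiles for a whole proteome
#'
#' Applies [psProfile()] to every protein; proteins outside the length
#' bounds get \code{NA} scores and a reason in the \code{skipped} column.
#'
#' @param proteome a [Proteome-class].
#' @param config see [llpsConfig()].
#' @return \code{DataFrame} with columns id, n_regions, max_region_length,
#'   ps_score, skipped.
#' @export
psProfiles <- function(proteome, config = llpsConfig()) {
  seqs <- as.character(sequences(proteome))
  profs <- lapply(seqs, psProfile, config = config)
  S4Vectors::DataFrame(
    id = proteinIds(proteome),
    n_regions = vapply(profs, function(p) length(p$regions), integer(1)),
    max_region_length = vapply(profs, function(p)
      as.integer(p$max_region_length), integer(1)),
    ps_score = vapply(profs, function(p) p$ps_score, numeric(1)),
    skipped = vapply(profs, function(p) p$skipped, character(1))
  )
}

#' Cumulative PS-IDR length curve
#'
#' For each length L, the percentage of analyzed proteins whose longest
#' PS-IDR is at least L residues long. A point (50, 15) means 15% of the
#' proteome carries a PS-IDR of 50+ residues. y(0) = 100 by construction
#' and the curve is non-increasing in L.
#'
#' @param ps \code{DataFrame} from [psProfiles()] (skipped proteins are
#'   excluded from the denominator).
#' @param lengths x-axis lengths; default 0 to the longest observed region.
#' @return \code{data.frame} with columns \code{length} and \code{percent}.
#' @export
cumulativePsCurve <- function(ps, lengths = NULL) {
  keep <- is.na(ps$skipped)
  ml <- ps$max_region_length[keep]
  if (length(ml) == 0L) stop("no analyzed proteins")
  if (is.null(lengths)) lengths <- 0:max(c(ml, 1L))
  data.frame(length = lengths,
             percent = vapply(lengths, function(L) 100 * mean(ml >= L),
                              numeric(1)))
}

#' Recall AUC of a test proteome against a reference
#'
#' Sweeps a score threshold from high to low; at each threshold x is the
#' fraction of the reference recalled and y the fraction of the test
#' proteome recalled. The area under this curve (trapezoidal, ties split
#' evenly) equals the Mann-Whitney probability that a random test score
#' exceeds a random reference score; 0.5 is the null of identically
#' distributed scores, AUC > 0.5 indicates enrichment in phase-separation
#' potential relative to the reference.
#'
#' @param test_scores,reference_scores non-empty numeric score vectors
#'   (\code{NA}s dropped).
#' @return AUC in [0, 1].
#' @export
recallAuc <- function(test_scores, reference_scores) {
  t <- test_scores[!is.na(test_scores)]
  r <- reference_scores[!is.na(reference_scores)]
  if (length(t) == 0L || length(r) == 0L) stop("empty score collection")
  ranks <- rank(c(t, r))  # midranks: ties split evenly
  (sum(ranks[seq_along(t)]) - length(t) * (length(t) + 1) / 2) /
    (length(t) * length(r))
}

#' Cumulative PS-IDR curve plot
#'
#' @param curves named list of \code{data.frame}s from
#'   [cumulativePsCurve()], one per proteome.
#' @return invisibly, \code{curves}.
#' @export
plotPsCurves <- function(curves) {
  xmax <- max(vapply(curves, function(c) max(c$length), numeric(1)))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 100),
                 xlab = "PS-IDR length (residues)",
                 ylab = "% proteins with PS-IDR >= length")
  for (k in seq_along(curves))
    graphics::lines(curves[[k]]$length, curves[[k]]$percent, col = k, lwd = 2)
  graphics::legend("topright", legend = names(curves), col = seq_along(curves),
                   lwd = 2, bty = "n")
  invisible(curves)
}
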