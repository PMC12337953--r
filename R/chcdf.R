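#' @include AllClasses.R disorder.R
NULL

#' Whole-sequence charge-hydropathy (CH) score
#'
#' The CH-plot discriminant evaluated on the whole protein:
#' \eqn{CH = |\langle R \rangle| - 2.785 \langle H \rangle + 1.151}, where
#' \eqn{|\langle R \rangle|} is the absolute mean net charge (K/R = +1,
#' D/E = -1, pH 7) and \eqn{\langle H \rangle} the mean min-max-normalized
#' Kyte-Doolittle hydropathy. CH > 0 places the protein on the
#' extended-disordered side of the boundary line.
#'
#' @param sequence amino-acid string or \code{AAString}.
#' @return signed scalar CH score.
#' @examples
#' chScore(strrep("E", 50))  # charged, low hydropathy: positive
#' chScore(strrep("I", 50))  # hydrophobic: negative
#' @export
chScore <- function(sequence) {
  chars <- .seqChars(sequence)
  q <- .CHARGE[chars]
  q[is.na(q)] <- 0
  h <- mean(.residueValues(chars, .KD_NORM, "hydropathy"))
  abs(mean(q)) - 2.785 * h + 1.151
}

#' Cumulative distribution function (CDF) curve of a disorder profile
#'
#' At each threshold \eqn{t}, the fraction of residues whose disorder score
#' is \eqn{\le t}. Ordered proteins accumulate low scores early, so their
#' curves run high.
#'
#' @param profile numeric per-residue disorder scores in [0, 1].
#' @param thresholds evaluation points in (0, 1); default 0.1 to 0.7 by 0.1.
#' @return numeric vector of cumulative fractions, named by threshold.
#' @export
cdfCurve <- function(profile, thresholds = seq(0.1, 0.7, by = 0.1)) {
  if (length(profile) == 0L) stop("empty profile")
  stopifnot(all(thresholds > 0), all(thresholds < 1))
  vapply(thresholds, function(t) mean(profile <= t), numeric(1)) |>
    stats::setNames(thresholds)
}

#' Calibrate a CDF decision boundary from reference sets
#'
#' Computes the mean CDF curve of an ordered and of a disordered reference
#' proteome under a given predictor and places the boundary at the midpoint
#' of the two means at every threshold. Calibration is deterministic given
#' the reference sets; identical mean curves at all thresholds are a
#' degenerate calibration and an error.
#'
#' @param ordered_set,disordered_set [Proteome-class] calibration sets (see
#'   [generateReferenceSets()] for the packaged synthetic references).
#' @param predictor,window passed to [disorderProfiles()].
#' @param thresholds CDF evaluation points.
#' @return a [CDFBoundary-class].
#' @export
calibrateCdfBoundary <- function(ordered_set, disordered_set,
                                 predictor = "foldindex", window = 21,
                                 thresholds = seq(0.1, 0.7, by = 0.1)) {
  meanCurve <- function(p) {
    prof <- disorderProfiles(p, predictor, window)
    rowMeans(vapply(as.list(prof), cdfCurve, numeric(length(thresholds)),
                    thresholds = thresholds))
  }
  mo <- meanCurve(ordered_set)
  md <- meanCurve(disordered_set)
  if (all(abs(mo - md) < .Machine$double.eps^0.5))
    stop("degenerate calibration: ordered and disordered reference sets ",
         "have identical mean CDF curves")
  CDFBoundary(thresholds, (mo + md) / 2)
}

#' Signed CDF score against a boundary
#'
#' Mean over the thresholds of (curve value - boundary value). Positive
#' scores mean the curve runs above the boundary, i.e. the ordered side;
#' negative scores the disordered side.
#'
#' @param curve cumulative fractions from [cdfCurve()].
#' @param boundary a [CDFBoundary-class] with the same thresholds.
#' @return signed scalar CDF score.
#' @export
cdfScore <- function(curve, boundary) {
  stopifnot(is(boundary, "CDFBoundary"))
  if (length(curve) != length(cdfValues(boundary)))
    stop("curve and boundary evaluate different numbers of thresholds")
  if (!is.null(names(curve)) &&
      !isTRUE(all.equal(as.numeric(names(curve)), cdfThresholds(boundary))))
    stop("curve and boundary thresholds differ")
  mean(curve - cdfValues(boundary))
}

#' Assign a CH-CDF quadrant
#'
#' Joint classification of the two per-protein scores:
#' \describe{
#'   \item{Q1}{CH <= 0, CDF >= 0 — structured;}
#'   \item{Q2}{CH <= 0, CDF < 0 — molten-globule / hybrid;}
#'   \item{Q3}{CH > 0, CDF < 0 — highly disordered;}
#'   \item{Q4}{CH > 0, CDF >= 0 — CH-disordered but CDF-ordered (mixed).}
#' }
#' Zeros fall on the ordered side of each axis (documented tie-break), so
#' (0, 0) is Q1.
#'
#' @param ch,cdf finite numeric vectors of equal length.
#' @return character vector of quadrant labels.
#' @export
assignQuadrant <- function(ch, cdf) {
  stopifnot(length(ch) == length(cdf), all(is.finite(ch)),
            all(is.finite(cdf)))
  ifelse(ch <= 0,
         ifelse(cdf >= 0, "Q1", "Q2"),
         ifelse(cdf < 0, "Q3", "Q4"))
}

#' CH-CDF points for a whole proteome
#'
#' @param proteome a [Proteome-class].
#' @param boundary a calibrated [CDFBoundary-class].
#' @param predictor,window passed to [disorderProfiles()] for the CDF axis.
#' @return \code{DataFrame} with columns id, ch, cdf, quadrant.
#' @export
chcdfPoints <- function(proteome, boundary, predictor = "foldindex",
                        window = 21) {
  profiles <- disorderProfiles(proteome, predictor, window)
  ch <- vapply(as.character(sequences(proteome)), chScore, numeric(1),
               USE.NAMES = FALSE)
  cdf <- vapply(as.list(profiles), function(p)
    cdfScore(cdfCurve(p, cdfThresholds(boundary)), boundary), numeric(1))
  S4Vectors::DataFrame(id = proteinIds(proteome), ch = ch,
                       cdf = unname(cdf),
                       quadrant = assignQuadrant(ch, unname(cdf)))
}

#' Proteome-by-quadrant contingency table
#'
#' @param assignments a named list: one character vector of quadrant labels
#'   (or a \code{DataFrame} from [chcdfPoints()]) per proteome.
#' @return integer matrix, proteomes as rows, columns Q1-Q4; row sums equal
#'   the numbers of assigned proteins.
#' @export
quadrantContingency <- function(assignments) {
  quads <- c("Q1", "Q2", "Q3", "Q4")
  rows <- lapply(assignments, function(a) {
    if (is(a, "DataFrame") || is.data.frame(a)) a <- a$quadrant
    stopifnot(all(a %in% quads))
    vapply(quads, function(q) sum(a == q), integer(1))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(assignments)
  out
}

#' CH-CDF scatter plot
#'
#' Quadrant scatter of per-protein CH and CDF scores (base graphics), one
#' panel per call.
#'
#' @param points \code{DataFrame} from [chcdfPoints()].
#' @param main plot title.
#' @return invisibly, \code{points}.
#' @export
plotChCdf <- function(points, main = "CH-CDF plot") {
  cols <- c(Q1 = "#1b9e77", Q2 = "#7570b3", Q3 = "#d95f02", Q4 = "#e7298a")
  graphics::plot(points$cdf, points$ch, col = cols[points$quadrant],
                 pch = 16, cex = 0.6, xlab = "CDF score", ylab = "CH score",
                 main = main)
  graphics::abline(h = 0, v = 0, lty = 2, col = "grey40")
  invisible(points)
}
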