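#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges NumericList
NULL

.AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Proteome: a named collection of protein sequences
#'
#' The unit of comparison throughout the package. Wraps a
#' \linkS4class{AAStringSet} restricted to the canonical 20-letter amino-acid
#' alphabet, together with a proteome label and a log of records skipped
#' during import (non-canonical residues, length filters).
#'
#' @slot name single character label for the proteome.
#' @slot sequences an \code{AAStringSet}; element names are protein ids,
#'   unique and non-empty.
#' @slot skipped a \code{DataFrame} with columns \code{id} and \code{reason}
#'   recording records dropped on import.
#'
#' @seealso [Proteome()] for construction, [readProteome()] for FASTA import.
#' @exportClass Proteome
setClass("Proteome",
  slots = c(
    name = "character",
    sequences = "AAStringSet",
    skipped = "DataFrame"
  )
)

setValidity("Proteome", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@sequences) == 0L)
    msg <- c(msg, "a Proteome must contain at least one sequence")
  ids <- names(object@sequences)
  if (is.null(ids) || any(!nzchar(ids)))
    msg <- c(msg, "all sequences must be named with non-empty ids")
  else if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    msg <- c(msg, sprintf("duplicate protein id(s): %s",
                          paste(head(dup, 5L), collapse = ", ")))
  }
  if (length(object@sequences) > 0L) {
    if (any(Biostrings::width(object@sequences) == 0L))
      msg <- c(msg, "sequences must be non-empty")
    freq <- Biostrings::alphabetFrequency(object@sequences)
    bad <- colnames(freq)[!(colnames(freq) %in% .AA_CANONICAL)]
    if (sum(freq[, bad, drop = FALSE]) > 0)
      msg <- c(msg, "sequences contain non-canonical residues; use validateSequence()/readProteome() to clean input")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Proteome
#'
#' @param name proteome label.
#' @param sequences a named \code{AAStringSet} or named character vector of
#'   amino-acid sequences (canonical 20-letter alphabet, upper case).
#' @param skipped optional \code{DataFrame} (columns \code{id},
#'   \code{reason}) of records dropped during import.
#' @return a [Proteome-class] object.
#' @examples
#' p <- Proteome("toy", c(P1 = "MKVLAE", P2 = "EEKKRR"))
#' proteinIds(p)
#' @export
Proteome <- function(name, sequences, skipped = S4Vectors::DataFrame(
                       id = character(), reason = character())) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  new("Proteome", name = name, sequences = sequences, skipped = skipped)
}

#' CDF boundary curve
#'
#' A calibrated decision boundary for cumulative-distribution-function (CDF)
#' analysis of per-residue disorder scores: at each disorder-score threshold
#' it stores the cumulative-fraction value separating ordered-like from
#' disordered-like proteins.
#'
#' @slot thresholds strictly increasing evaluation points on the
#'   disorder-score axis, each in (0, 1).
#' @slot values boundary cumulative fractions in [0, 1], one per threshold.
#'
#' @seealso [calibrateCdfBoundary()], [cdfScore()]
#' @exportClass CDFBoundary
setClass("CDFBoundary",
  slots = c(thresholds = "numeric", values = "numeric")
)

setValidity("CDFBoundary", function(object) {
  msg <- character()
  t <- object@thresholds
  v <- object@values
  if (length(t) < 1L || any(!is.finite(t)) || any(t <= 0) || any(t >= 1))
    msg <- c(msg, "thresholds must be finite and in (0, 1)")
  if (is.unsorted(t, strictly = TRUE))
    msg <- c(msg, "thresholds must be strictly increasing")
  if (length(v) != length(t))
    msg <- c(msg, "one boundary value per threshold required")
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    msg <- c(msg, "boundary values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn CDFBoundary-class constructor.
#' @param thresholds,values see slot descriptions.
#' @export
CDFBoundary <- function(thresholds, values) {
  new("CDFBoundary", thresholds = as.numeric(thresholds),
      values = as.numeric(values))
}
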