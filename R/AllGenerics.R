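#' @include AllClasses.R
NULL

#' @rdname Proteome-class
#' @param object,x a \code{Proteome}.
#' @export
setGeneric("proteomeName", function(x) standardGeneric("proteomeName"))

#' @rdname Proteome-class
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname Proteome-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname Proteome-class
#' @export
setGeneric("skippedRecords", function(x) standardGeneric("skippedRecords"))

#' @rdname Proteome-class
#' @export
setMethod("proteomeName", "Proteome", function(x) x@name)

#' @rdname Proteome-class
#' @export
setMethod("proteinIds", "Proteome", function(x) names(x@sequences))

#' @rdname Proteome-class
#' @export
setMethod("sequences", "Proteome", function(x) x@sequences)

#' @rdname Proteome-class
#' @export
setMethod("skippedRecords", "Proteome", function(x) x@skipped)

#' @rdname Proteome-class
#' @export
setMethod("length", "Proteome", function(x) length(x@sequences))

#' @rdname Proteome-class
#' @param i index (id or position) of proteins to keep.
#' @export
setMethod("[", "Proteome", function(x, i) {
  initialize(x, sequences = x@sequences[i])
})

#' @rdname Proteome-class
#' @export
setMethod("show", "Proteome", function(object) {
  w <- Biostrings::width(object@sequences)
  cat(sprintf("Proteome '%s': %d proteins (length %d-%d aa", object@name,
              length(object@sequences), min(w), max(w)),
      sprintf(", median %.0f)\n", stats::median(w)), sep = "")
  if (nrow(object@skipped) > 0L)
    cat(sprintf("  %d record(s) skipped on import\n", nrow(object@skipped)))
})

#' @rdname CDFBoundary-class
#' @param object a \code{CDFBoundary}.
#' @export
setMethod("show", "CDFBoundary", function(object) {
  cat("CDFBoundary over", length(object@thresholds), "thresholds\n")
  print(stats::setNames(round(object@values, 4), object@thresholds))
})

#' @rdname CDFBoundary-class
#' @param x a \code{CDFBoundary}.
#' @export
setGeneric("cdfThresholds", function(x) standardGeneric("cdfThresholds"))

#' @rdname CDFBoundary-class
#' @export
setGeneric("cdfValues", function(x) standardGeneric("cdfValues"))

#' @rdname CDFBoundary-class
#' @export
setMethod("cdfThresholds", "CDFBoundary", function(x) x@thresholds)

#' @rdname CDFBoundary-class
#' @export
setMethod("cdfValues", "CDFBoundary", function(x) x@values)
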