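#' Published retinal-proteome count tables
#'
#' Count tables transcribed from a published comparative study of six
#' retinal proteomes (a healthy-control retinal proteome, an inherited
#' retinal disease gene set, and AMD, glaucoma and diabetic-retinopathy
#' proteomes with and without gliosis). These printed counts are inputs to
#' the package's contingency and percentage arithmetic — the study's
#' per-protein scores came from external trained predictors and are not
#' reproduced here.
#'
#' @param table which table to load: \describe{
#'   \item{quadrants}{proteome-by-CH-CDF-quadrant counts (6 x 4);}
#'   \item{tiers}{proteome-by-disorder-tier counts (6 x 4);}
#'   \item{sizes}{number of proteins per proteome;}
#'   \item{overlap}{overlap/unique counts of each disease proteome against
#'     the control.}}
#' @return a \code{data.frame}; for \code{quadrants} and \code{tiers} the
#'   proteome column is moved to row names.
#' @examples
#' chiSquaredTest(retinaReferenceCounts("quadrants"))
#' @export
retinaReferenceCounts <- function(table = c("quadrants", "tiers", "sizes",
                                            "overlap")) {
  table <- match.arg(table)
  file <- switch(table,
    quadrants = "retina_quadrant_counts.tsv",
    tiers = "retina_tier_counts.tsv",
    sizes = "retina_proteome_sizes.tsv",
    overlap = "retina_overlap_counts.tsv")
  path <- system.file("extdata", file, package = "ProteoDisorder",
                      mustWork = TRUE)
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE)
  if (table %in% c("quadrants", "tiers")) {
    rownames(d) <- d$proteome
    d$proteome <- NULL
  }
  d
}
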