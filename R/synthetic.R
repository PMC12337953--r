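#' @include AllClasses.R proteome-io.R
NULL

# archetype residue compositions (probabilities sum to 1).
# ORDERED is hydrophobic-rich (globular-like), DISORDERED is enriched in
# the classic disorder-promoting residues P/E/S/K/Q/G.
.COMP_ORDERED <- c(I = 0.13, L = 0.14, V = 0.12, F = 0.09, A = 0.12,
                   W = 0.03, M = 0.05, G = 0.07, T = 0.06, S = 0.06,
                   C = 0.03, Y = 0.04, N = 0.02, D = 0.01, E = 0.01,
                   K = 0.01, R = 0.01)
.COMP_DISORDERED <- c(P = 0.13, E = 0.15, S = 0.13, K = 0.12, Q = 0.09,
                      G = 0.11, A = 0.06, R = 0.05, D = 0.07, T = 0.05,
                      N = 0.04)
# sticker motifs and spacer alphabet for the PS-prone archetype
.PS_MOTIFS <- c("RG", "RG", "RG", "SY", "FG", "QG", "GS")
.PS_SPACER <- c("G", "S", "Q", "N", "P", "E", "K")

.ARCHETYPES <- c("ORDERED", "DISORDERED", "PS_PRONE", "MIXED")

#' Archetype specification for synthetic sequences
#'
#' @param archetype one of \code{"ORDERED"}, \code{"DISORDERED"},
#'   \code{"PS_PRONE"}, \code{"MIXED"}.
#' @param length_range (min, max) sequence length in residues; lengths are
#'   drawn uniformly. Minimum allowed is 30.
#' @param composition optional named residue-probability vector overriding
#'   the archetype default (ignored for \code{PS_PRONE}, which is built
#'   from sticker blocks and spacers).
#' @return a validated named list.
#' @export
archetypeSpec <- function(archetype = c("ORDERED", "DISORDERED", "PS_PRONE",
                                        "MIXED"),
                          length_range = c(100, 500),
                          composition = NULL) {
  archetype <- match.arg(archetype)
  stopifnot(length(length_range) == 2L, length_range[1] >= 30,
            length_range[1] <= length_range[2])
  if (is.null(composition)) {
    composition <- switch(archetype,
      ORDERED = .COMP_ORDERED,
      DISORDERED = .COMP_DISORDERED,
      PS_PRONE = NULL,
      MIXED = NULL)
  } else {
    if (is.null(names(composition)) ||
        !all(names(composition) %in% .AA_CANONICAL))
      stop("composition must be named by canonical residues")
    if (abs(sum(composition) - 1) > 1e-9)
      stop("composition probabilities must sum to 1")
  }
  list(archetype = archetype, length_range = as.integer(length_range),
       composition = composition)
}

.sampleComposition <- function(n, composition) {
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

.samplePsProne <- function(n) {
  parts <- character(0)
  total <- 0L
  while (total < n) {
    block <- paste(sample(.PS_MOTIFS, sample(3:5, 1L), replace = TRUE),
                   collapse = "")
    spacer <- paste(sample(.PS_SPACER, sample(4:8, 1L), replace = TRUE),
                    collapse = "")
    parts <- c(parts, block, spacer)
    total <- total + nchar(block) + nchar(spacer)
  }
  substr(paste(parts, collapse = ""), 1L, n)
}

#' Generate one synthetic amino-acid sequence
#'
#' Draws the length uniformly from the spec's range and builds the sequence
#' according to the archetype: i.i.d. sampling from the composition
#' (ORDERED / DISORDERED), interleaved sticker blocks (RG/SY/FG-style
#' motifs) and disordered spacers (PS_PRONE), or an ordered segment
#' concatenated with a disordered one (MIXED). Uses the current RNG state;
#' seed externally (or via [generateProteome()]) for reproducibility.
#'
#' @param spec see [archetypeSpec()].
#' @return a single amino-acid string.
#' @export
generateSequence <- function(spec) {
  n <- sample(spec$length_range[1]:spec$length_range[2], 1L)
  switch(spec$archetype,
    ORDERED = ,
    DISORDERED = .sampleComposition(n, spec$composition),
    PS_PRONE = .samplePsProne(n),
    MIXED = {
      h <- n %/% 2L
      paste0(.sampleComposition(h, .COMP_ORDERED),
             .sampleComposition(n - h, .COMP_DISORDERED))
    })
}

.largestRemainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties broken by position in the mixture (first listed wins)
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic proteome with known composition
#'
#' Builds \code{n} proteins as a mixture of archetypes. Archetype counts
#' follow the mixture fractions exactly after deterministic
#' largest-remainder rounding. One global seed drives a per-protein seed
#' stream (seed + 10007 * index, mod 2^31 - 1) so any subset regenerates
#' identically; record order is shuffled so ids carry no label information,
#' and the ground-truth labels are returned separately.
#'
#' @param n number of proteins (>= 1).
#' @param mixture named numeric vector of archetype fractions summing to 1,
#'   names drawn from ORDERED, DISORDERED, PS_PRONE, MIXED.
#' @param seed integer seed.
#' @param name proteome label.
#' @param length_range passed to [archetypeSpec()].
#' @return list with \code{proteome} (a [Proteome-class]) and \code{labels}
#'   (\code{DataFrame} with id, archetype).
#' @examples
#' g <- generateProteome(10, c(DISORDERED = 0.6, ORDERED = 0.4), seed = 1)
#' table(g$labels$archetype)
#' @export
generateProteome <- function(n, mixture, seed, name = "synthetic",
                             length_range = c(100, 500)) {
  stopifnot(n >= 1)
  if (is.null(names(mixture)) || !all(names(mixture) %in% .ARCHETYPES))
    stop("mixture must be named by archetypes: ",
         paste(.ARCHETYPES, collapse = ", "))
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture fractions must sum to 1 (got ", sum(mixture), ")")
  counts <- .largestRemainder(n, mixture)
  archetype <- rep(names(mixture), counts)
  seqs <- character(n)
  for (i in seq_len(n)) {
    set.seed((as.integer(seed) + 10007L * i) %% 2147483647L)
    seqs[i] <- generateSequence(archetypeSpec(archetype[i],
                                              length_range = length_range))
  }
  set.seed(as.integer(seed) %% 2147483647L)
  ord <- sample.int(n)
  ids <- sprintf("SYN%05d", seq_len(n))
  list(
    proteome = Proteome(name, stats::setNames(seqs[ord], ids)),
    labels = S4Vectors::DataFrame(id = ids, archetype = archetype[ord])
  )
}

#' Fixed calibration reference sets
#'
#' Reproducible ordered and disordered archetype proteomes (200 + 200
#' proteins at a fixed seed by default) used to calibrate the CDF boundary
#' via [calibrateCdfBoundary()].
#'
#' @param n proteins per set.
#' @param seed integer seed.
#' @return list with \code{ordered} and \code{disordered}
#'   [Proteome-class] objects.
#' @export
generateReferenceSets <- function(n = 200, seed = 20240515) {
  ord <- generateProteome(n, c(ORDERED = 1), seed = seed,
                          name = "reference_ordered")
  dis <- generateProteome(n, c(DISORDERED = 1), seed = seed + 1,
                          name = "reference_disordered")
  list(ordered = ord$proteome, disordered = dis$proteome)
}

#' Write a synthetic proteome and its labels
#'
#' Emits standard FASTA plus a two-column ground-truth TSV (id, archetype).
#'
#' @param generated a list from [generateProteome()].
#' @param fasta_path,labels_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
writeSyntheticProteome <- function(generated, fasta_path, labels_path) {
  writeProteome(generated$proteome, fasta_path)
  utils::write.table(as.data.frame(generated$labels), labels_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_path, labels = labels_path))
}
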