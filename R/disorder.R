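#' @include AllClasses.R
NULL

# Kyte-Doolittle hydropathy, raw scale (range -4.5 .. 4.5)
.KD_RAW <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
             E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
             M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
             Y = -1.3, V = 4.2)
.KD_NORM <- (.KD_RAW - min(.KD_RAW)) / (max(.KD_RAW) - min(.KD_RAW))

# TOP-IDP per-residue disorder propensity (Campen et al.-style one-value
# scale; larger = more disorder-prone, P max, W min)
.TOPIDP_RAW <- c(W = -0.884, F = -0.697, Y = -0.510, I = -0.486, M = -0.397,
                 L = -0.326, V = -0.121, N = 0.007, C = 0.020, T = 0.059,
                 A = 0.060, G = 0.166, R = 0.180, D = 0.192, H = 0.303,
                 Q = 0.318, S = 0.341, K = 0.586, E = 0.736, P = 0.987)
.TOPIDP_NORM <- (.TOPIDP_RAW - min(.TOPIDP_RAW)) /
  (max(.TOPIDP_RAW) - min(.TOPIDP_RAW))

# charge at pH 7, standard CH-plot convention: H and termini ignored
.CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

.seqChars <- function(sequence) {
  if (is(sequence, "AAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  strsplit(sequence, "")[[1]]
}

.residueValues <- function(chars, scale, what) {
  v <- scale[chars]
  if (anyNA(v))
    stop("unknown residue(s) under the ", what, " scale: ",
         paste(unique(chars[is.na(v)]), collapse = ""))
  unname(v)
}

# centred running mean with truncated (not padded) windows at the termini
.windowMean <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.checkWindow <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || window < 3 ||
      window %% 2 != 1)
    stop("'window' must be an odd integer >= 3")
  as.integer(window)
}

#' Per-residue normalized hydropathy
#'
#' Windowed mean of min-max-normalized Kyte-Doolittle hydropathy values
#' (0 = Arg, 1 = Ile). Windows are centred and truncated at the termini.
#'
#' @param sequence amino-acid string (canonical alphabet) or \code{AAString}.
#' @param window odd window size, default 21.
#' @return numeric vector in [0, 1], one value per residue.
#' @export
normalizedHydropathy <- function(sequence, window = 21) {
  window <- .checkWindow(window)
  chars <- .seqChars(sequence)
  .windowMean(.residueValues(chars, .KD_NORM, "hydropathy"), window)
}

#' Per-residue windowed absolute net charge
#'
#' Absolute mean net charge over a centred window, with K/R = +1 and
#' D/E = -1 (H uncharged; pH 7 convention).
#'
#' @inheritParams normalizedHydropathy
#' @return numeric vector in [0, 1].
#' @export
windowNetCharge <- function(sequence, window = 21) {
  window <- .checkWindow(window)
  chars <- .seqChars(sequence)
  q <- .CHARGE[chars]
  q[is.na(q)] <- 0
  abs(.windowMean(unname(q), window))
}

#' FoldIndex-style windowed charge-hydropathy disorder profile
#'
#' Applies the charge-hydropathy discriminant in a sliding window: the raw
#' window score is \eqn{FI = 2.785 \langle H \rangle - |\langle R \rangle| -
#' 1.151}, negative on the disordered side, and is mapped to a disorder
#' score \eqn{s = clamp(0.5 - FI/2, 0, 1)} so that \eqn{FI < 0
#' \Rightarrow s > 0.5}.
#'
#' @inheritParams normalizedHydropathy
#' @return numeric disorder scores in [0, 1], one per residue.
#' @export
foldIndexProfile <- function(sequence, window = 21) {
  h <- normalizedHydropathy(sequence, window)
  r <- windowNetCharge(sequence, window)
  fi <- 2.785 * h - r - 1.151
  pmin(pmax(0.5 - fi / 2, 0), 1)
}

#' Disorder-propensity profile from a one-value-per-residue scale
#'
#' Windowed mean of a per-residue disorder propensity, min-max normalized
#' over the scale so the most disorder-promoting homopolymer scores 1 and
#' the least scores 0. The default scale is a TOP-IDP-style propensity
#' ranking (Pro most disorder-promoting, Trp least).
#'
#' @inheritParams normalizedHydropathy
#' @param scale named numeric vector mapping residues to propensities, or
#'   the name \code{"topidp"}.
#' @return numeric disorder scores in [0, 1], one per residue.
#' @export
propensityProfile <- function(sequence, scale = "topidp", window = 21) {
  window <- .checkWindow(window)
  if (is.character(scale)) {
    scale <- match.arg(scale, "topidp")
    sc <- .TOPIDP_NORM
  } else {
    rng <- range(scale)
    if (diff(rng) <= 0) stop("degenerate propensity scale")
    sc <- (scale - rng[1]) / diff(rng)
  }
  chars <- .seqChars(sequence)
  .windowMean(.residueValues(chars, sc, "propensity"), window)
}

#' Consensus of several disorder profiles
#'
#' Per-residue weighted mean of profiles for the same protein, the package's
#' analogue of multi-predictor consensus scoring. With a single profile it
#' is the identity; it is invariant to the order of its inputs.
#'
#' @param profiles list of numeric score vectors of equal length, each in
#'   [0, 1].
#' @param weights non-negative weights, one per profile, summing > 0.
#'   Default: equal weights.
#' @return numeric vector in [0, 1].
#' @examples
#' consensusProfile(list(c(0.2, 0.8), c(0.6, 0.4)), weights = c(1, 3))
#' @export
consensusProfile <- function(profiles, weights = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  len <- lengths(profiles)
  if (length(unique(len)) != 1L)
    stop("profiles have mismatched lengths: ",
         paste(unique(len), collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(profiles))
  if (length(weights) != length(profiles) || any(weights < 0) ||
      sum(weights) <= 0)
    stop("weights must be non-negative, one per profile, with positive sum")
  w <- weights / sum(weights)
  out <- numeric(len[1])
  for (k in seq_along(profiles)) out <- out + w[k] * profiles[[k]]
  out
}

# ---- predictor registry ----------------------------------------------------

.predictorRegistry <- new.env(parent = emptyenv())

#' Predictor registry
#'
#' Per-residue disorder predictors are looked up by name, so externally
#' computed per-residue score tables (see [readScoreTable()]) can substitute
#' for any built-in predictor. A predictor is a function
#' \code{f(sequence, window)} returning one disorder score in [0, 1] per
#' residue. Built-ins: \code{"foldindex"} and \code{"topidp"}.
#'
#' @param name predictor name.
#' @param fun a function \code{(sequence, window) -> numeric}.
#' @return \code{registerPredictor} returns \code{name} invisibly;
#'   \code{getPredictor} the registered function; \code{listPredictors} the
#'   registered names.
#' @export
registerPredictor <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .predictorRegistry)
  invisible(name)
}

#' @rdname registerPredictor
#' @export
getPredictor <- function(name) {
  if (!exists(name, envir = .predictorRegistry, inherits = FALSE))
    stop("unknown predictor '", name, "'; see listPredictors()")
  get(name, envir = .predictorRegistry, inherits = FALSE)
}

#' @rdname registerPredictor
#' @export
listPredictors <- function() sort(ls(.predictorRegistry))

registerPredictor("foldindex", function(sequence, window = 21)
  foldIndexProfile(sequence, window))
registerPredictor("topidp", function(sequence, window = 21)
  propensityProfile(sequence, "topidp", window))

#' Per-residue disorder profiles for a whole proteome
#'
#' Runs a registered predictor over every protein, or accepts a named list
#' of externally computed per-residue scores (e.g. from
#' \code{readScoreTable(kind = "per_residue")}) as a drop-in predictor, in
#' which case scores are checked against sequence lengths.
#'
#' @param proteome a [Proteome-class].
#' @param predictor predictor name (see [listPredictors()]), a function
#'   \code{(sequence, window)}, or a named list of per-residue score
#'   vectors covering every protein.
#' @param window odd window size passed to sequence-based predictors.
#' @return a \code{NumericList} of per-residue scores, one element per
#'   protein, with \code{metadata()$predictor} recording the source.
#' @export
disorderProfiles <- function(proteome, predictor = "foldindex", window = 21) {
  stopifnot(is(proteome, "Proteome"))
  ids <- proteinIds(proteome)
  label <- "external"
  if (is.list(predictor)) {
    missing <- setdiff(ids, names(predictor))
    if (length(missing))
      stop("external scores missing for protein(s): ",
           paste(head(missing, 5L), collapse = ", "))
    scores <- predictor[ids]
    lens <- Biostrings::width(sequences(proteome))
    bad <- which(lengths(scores) != lens)
    if (length(bad))
      stop("external score length mismatch for: ",
           paste(ids[head(bad, 5L)], collapse = ", "))
    if (any(unlist(scores, use.names = FALSE) < 0) ||
        any(unlist(scores, use.names = FALSE) > 1))
      stop("disorder scores must lie in [0, 1]")
  } else {
    if (is.character(predictor)) {
      label <- predictor
      predictor <- getPredictor(predictor)
    } else label <- "custom"
    seqs <- as.character(sequences(proteome))
    scores <- lapply(seqs, predictor, window = window)
    names(scores) <- ids
  }
  out <- IRanges::NumericList(scores)
  S4Vectors::metadata(out) <- list(predictor = label)
  out
}

#' Export per-residue profiles as a TSV score table
#'
#' Writes the \code{per_residue} dialect read by [readScoreTable()]:
#' columns (id, position, score), tab-separated, no header.
#'
#' @param profiles named list / \code{NumericList} of per-residue scores.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoreTable <- function(profiles, path) {
  profiles <- as.list(profiles)
  df <- data.frame(
    id = rep(names(profiles), lengths(profiles)),
    position = unlist(lapply(profiles, seq_along), use.names = FALSE),
    score = unlist(profiles, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
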