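#' @include AllClasses.R
NULL

#' Validate and normalise a raw amino-acid sequence
#'
#' Uppercases the input and checks it against the canonical 20-letter
#' alphabet. Non-canonical letters (B, Z, U, O, X, gap and any other symbol)
#' are rejected: under the default policy the caller is expected to skip the
#' record (a \code{NA} is returned with the offending letters in
#' \code{attr(, "reason")}); in strict mode an error is thrown.
#'
#' @param raw a single character string (non-empty).
#' @param strict error instead of returning \code{NA} for non-canonical input.
#' @return the cleaned upper-case sequence, or \code{NA_character_} with a
#'   \code{"reason"} attribute when rejected under the default policy.
#' @examples
#' validateSequence("mkv")
#' validateSequence("MKX")   # NA, reason records the 'X'
#' @export
validateSequence <- function(raw, strict = FALSE) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop("sequence is empty")
  seq <- toupper(raw)
  letters <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(letters), .AA_CANONICAL)
  if (length(bad)) {
    reason <- sprintf("non-canonical residue(s): %s",
                      paste(bad, collapse = ""))
    if (strict) stop(reason)
    return(structure(NA_character_, reason = reason))
  }
  seq
}

.headerToId <- function(header) {
  tok <- sub("\\s.*$", "", header)
  # UniProt-style "sp|ACC|NAME" / "tr|ACC|NAME" headers: keep the accession
  if (grepl("^(sp|tr)\\|[^|]+\\|", tok))
    tok <- strsplit(tok, "|", fixed = TRUE)[[1]][2]
  tok
}

#' Read a proteome from FASTA
#'
#' Parses a FASTA file into a [Proteome-class]. Protein ids are the first
#' whitespace-delimited token of each header; UniProt \code{sp|ACC|NAME}
#' headers are reduced to the accession. Sequences are uppercased and
#' validated against the canonical alphabet; records failing validation are
#' skipped and logged in \code{skippedRecords()} (or abort the read when
#' \code{strict = TRUE}). Duplicate ids are a hard error.
#'
#' @param path FASTA file path.
#' @param name proteome label; defaults to the file base name.
#' @param strict error on non-canonical residues instead of skipping.
#' @return a [Proteome-class].
#' @seealso [writeProteome()], [validateSequence()]
#' @export
readProteome <- function(path, name = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name))
    name <- sub("\\.(fa|fasta|faa)(\\.gz)?$", "", basename(path),
                ignore.case = TRUE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("not FASTA-formatted: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(names(set), .headerToId, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate protein id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.character(set)
  cleaned <- character(length(raw))
  skip_id <- character()
  skip_reason <- character()
  for (k in seq_along(raw)) {
    v <- validateSequence(raw[[k]], strict = strict)
    if (is.na(v)) {
      skip_id <- c(skip_id, ids[k])
      skip_reason <- c(skip_reason, attr(v, "reason"))
      cleaned[k] <- NA_character_
    } else cleaned[k] <- v
  }
  keep <- !is.na(cleaned)
  if (!any(keep))
    stop("no valid records in ", path, " after sequence validation")
  Proteome(name,
           stats::setNames(cleaned[keep], ids[keep]),
           skipped = S4Vectors::DataFrame(id = skip_id,
                                          reason = skip_reason))
}

#' Write a proteome to FASTA
#'
#' @param proteome a [Proteome-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProteome <- function(proteome, path) {
  stopifnot(is(proteome, "Proteome"))
  Biostrings::writeXStringSet(sequences(proteome), path)
  invisible(path)
}

#' Read an external score table
#'
#' Ingests tab-separated score tables produced by external predictors so
#' their outputs can stand in for any built-in predictor. Two dialects:
#' \code{per_protein} has columns (id, score) and yields a named numeric
#' vector; \code{per_residue} has columns (id, position, score) with 1-based
#' contiguous positions per protein and yields a named list of per-residue
#' score vectors.
#'
#' @param path TSV file path (no header).
#' @param kind \code{"per_protein"} or \code{"per_residue"}.
#' @param disorder when \code{TRUE}, scores are required to lie in [0, 1]
#'   (the convention for disorder scores).
#' @return named numeric vector or named list of numeric vectors.
#' @export
readScoreTable <- function(path, kind = c("per_protein", "per_residue"),
                           disorder = TRUE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  ncols <- if (kind == "per_protein") 2L else 3L
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) != ncols)
    stop("malformed score table: expected ", ncols, " columns, found ",
         ncol(tab))
  score_col <- ncols
  scores <- suppressWarnings(as.numeric(tab[[score_col]]))
  if (any(is.na(scores) | !is.finite(scores)))
    stop("malformed score table: non-numeric or non-finite score values")
  if (disorder && (any(scores < 0) || any(scores > 1)))
    stop("disorder scores must lie in [0, 1]")
  if (kind == "per_protein") {
    if (anyDuplicated(tab[[1]]))
      stop("duplicate protein id(s) in per-protein table")
    return(stats::setNames(scores, tab[[1]]))
  }
  pos <- suppressWarnings(as.integer(tab[[2]]))
  if (any(is.na(pos))) stop("malformed positions in per-residue table")
  out <- split(data.frame(pos = pos, score = scores), tab[[1]])
  lapply(out, function(d) {
    d <- d[order(d$pos), , drop = FALSE]
    if (!identical(d$pos, seq_len(nrow(d))))
      stop("per-residue positions must be 1-based and contiguous (gap near ",
           "position ", d$pos[which(d$pos != seq_len(nrow(d)))[1]], ")")
    d$score
  })
}

#' Split a proteome into overlap and unique sets against a reference
#'
#' Partitions the ids of \code{test} into those also present in
#' \code{reference} (overlap) and the remainder (unique). Used to compare
#' disease proteomes against a control proteome.
#'
#' @param test,reference [Proteome-class] objects, or character vectors of
#'   protein ids.
#' @return list with elements \code{overlap_ids} and \code{unique_ids};
#'   disjoint, and their union is the id set of \code{test}.
#' @examples
#' overlapSplit(c("A", "B", "C"), c("B", "C", "D"))
#' @export
overlapSplit <- function(test, reference) {
  tid <- if (is(test, "Proteome")) proteinIds(test) else as.character(test)
  rid <- if (is(reference, "Proteome")) proteinIds(reference)
         else as.character(reference)
  if (anyDuplicated(tid)) stop("duplicate ids in test proteome")
  inref <- tid %in% rid
  list(overlap_ids = tid[inref], unique_ids = tid[!inref])
}
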