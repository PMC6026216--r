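#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## The 20 standard one-letter amino-acid codes, alphabetical.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Characters accepted in a subject protein sequence: the 20 standard
## residues plus unknown (X), selenocysteine (U), pyrrolysine (O),
## translation stop (*) and alignment gap (-).
SEQ_ALLOWED <- c(AA_ALPHABET20, "X", "U", "O", "*", "-")

## Sequence characters a wildcard element consumes: everything a protein
## sequence may legitimately contain at a residue position.  Stops and
## gaps are never residues, so a wildcard rejects them.
WILDCARD_MATCHES <- c(AA_ALPHABET20, "X", "U", "O")

#' Motif: a degenerate amino-acid search pattern
#'
#' A \code{Motif} is an ordered sequence of pattern elements, each either a
#' literal residue (\code{"G"}), a residue class (\code{"[RKS]"}) or a
#' wildcard spacer (\code{"X"}), optionally carrying a repeat bound written
#' \code{\{n\}} or \code{\{n,m\}}.  This is the pattern language in which
#' functional-center search motifs such as the 14-residue guanylate-cyclase
#' catalytic-center motif are expressed.
#'
#' @slot name single character string naming the motif.
#' @slot elements list of elements; each element is a list with entries
#'   \code{kind} (\code{"literal"}, \code{"class"} or \code{"wildcard"}),
#'   \code{residues} (character vector of one-letter codes, in curated
#'   order), \code{min} and \code{max} (integer repeat bounds).
#' @slot annotations named list mapping residue positions (1-based along a
#'   minimal-length match, as character names) to free-text functional
#'   notes, e.g. the substrate-specificity position of a cyclase motif.
#' @slot provenance character string recording where the motif came from
#'   (curation, derivation, induction).
#'
#' @seealso [parseMotif()], [renderMotif()], [findMatches()]
#' @export
setClass("Motif",
    representation(name = "character", elements = "list",
                   annotations = "list", provenance = "character"))

setValidity("Motif", function(object) {
    msgs <- character()
    if (length(object@name) != 1L || is.na(object@name))
        msgs <- c(msgs, "'name' must be a single string")
    if (length(object@elements) < 1L)
        msgs <- c(msgs, "a motif must have at least one element")
    for (i in seq_along(object@elements)) {
        e <- object@elements[[i]]
        if (!all(c("kind", "residues", "min", "max") %in% names(e))) {
            msgs <- c(msgs, sprintf("element %d is malformed", i))
            next
        }
        if (!e$kind %in% c("literal", "class", "wildcard"))
            msgs <- c(msgs, sprintf("element %d has unknown kind '%s'", i, e$kind))
        if (length(e$residues) == 0L)
            msgs <- c(msgs, sprintf("element %d has an empty residue set", i))
        if (anyDuplicated(e$residues))
            msgs <- c(msgs, sprintf("element %d has duplicate residues", i))
        if (!all(e$residues %in% AA_ALPHABET20))
            msgs <- c(msgs, sprintf("element %d contains letters outside the 20-residue alphabet", i))
        if (e$kind == "literal" && length(e$residues) != 1L)
            msgs <- c(msgs, sprintf("literal element %d must hold exactly one residue", i))
        if (e$kind == "wildcard" && !setequal(e$residues, AA_ALPHABET20))
            msgs <- c(msgs, sprintf("wildcard element %d must span the full alphabet", i))
        if (e$min < 0L || e$max < 1L || e$min > e$max)
            msgs <- c(msgs, sprintf("element %d violates 0 <= min <= max, max >= 1 repeat bounds", i))
    }
    if (length(object@elements) &&
        sum(vapply(object@elements, function(e) e$min, 1L)) < 1L)
        msgs <- c(msgs, "motif minimum length must be at least 1 residue")
    if (length(object@annotations)) {
        pos <- suppressWarnings(as.integer(names(object@annotations)))
        if (anyNA(pos) || any(pos < 1L))
            msgs <- c(msgs, "annotation names must be positive residue positions")
        else if (length(object@elements) &&
                 any(pos > sum(vapply(object@elements, function(e) e$max, 1L))))
            msgs <- c(msgs, "annotation position exceeds the motif's maximum length")
    }
    if (length(msgs)) msgs else TRUE
})

#' HitTable: motif occurrences from a proteome scan
#'
#' Records every occurrence (span) of a motif found in a set of protein
#' sequences, plus scan provenance.  Coordinates are 1-based and inclusive
#' at both ends, following the convention in which an occurrence is
#' reported as, e.g., spanning positions S5 to K18 of a protein.
#'
#' @slot spans a [S4Vectors::DataFrame] with columns \code{sequence_id},
#'   \code{start}, \code{end}, \code{matched_seq} and \code{motif};
#'   sorted by (sequence_id, start, end), no duplicates.
#' @slot motifName name of the motif scanned.
#' @slot proteomePath path of the scanned FASTA file, or \code{NA} for
#'   in-memory input.
#' @slot proteomeDigest content digest of the scanned sequences, so counts
#'   can be tied to a pinned proteome release.
#' @slot parameters named list snapshot of scan parameters.
#' @slot timestamp creation time, as a character string.
#'
#' @seealso [scanProteome()], [collapseToLoci()], [writeHitsTsv()]
#' @export
setClass("HitTable",
    representation(spans = "DataFrame", motifName = "character",
                   proteomePath = "character", proteomeDigest = "character",
                   parameters = "list", timestamp = "character"))

setValidity("HitTable", function(object) {
    sp <- object@spans
    need <- c("sequence_id", "start", "end", "matched_seq", "motif")
    if (!all(need %in% colnames(sp)))
        return(sprintf("spans must have columns %s", paste(need, collapse = ", ")))
    if (nrow(sp)) {
        if (any(sp$start < 1L) || any(sp$end < sp$start))
            return("spans must satisfy 1 <= start <= end")
        key <- paste(sp$sequence_id, sp$start, sp$end, sp$motif)
        if (anyDuplicated(key))
            return("duplicate (sequence_id, start, end, motif) spans")
        o <- order(sp$sequence_id, sp$start, sp$end)
        if (!identical(o, seq_len(nrow(sp))))
            return("spans must be sorted by (sequence_id, start, end)")
    }
    TRUE
})

#' BackgroundModel: i.i.d. residue frequencies
#'
#' A residue frequency vector over (a subset of) the 20-letter amino-acid
#' alphabet, used to compute how often a motif is expected to occur by
#' chance in unrelated sequence — the statistical layer that helps
#' discriminate true functional centers from false positives.
#'
#' @slot frequency named numeric vector of residue probabilities; names are
#'   one-letter codes, values are non-negative and sum to 1.
#'
#' @seealso [uniformBackground()], [expectedHits()], [monteCarloHits()]
#' @export
setClass("BackgroundModel", representation(frequency = "numeric"))

setValidity("BackgroundModel", function(object) {
    f <- object@frequency
    if (is.null(names(f)) || !all(names(f) %in% AA_ALPHABET20))
        return("frequencies must be named by letters of the 20-residue alphabet")
    if (anyDuplicated(names(f)))
        return("duplicate residue names")
    if (any(f < 0))
        return("frequencies must be non-negative")
    if (abs(sum(f) - 1) > 1e-9)
        return(sprintf("frequencies must sum to 1 (got %.12f)", sum(f)))
    TRUE
})
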