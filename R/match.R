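## Exact occurrence enumeration for degenerate motifs.
##
## Strategy: a PCRE regex with a zero-width lookahead locates every
## position where at least one occurrence can begin (the regex engine
## handles the bounded-repeat backtracking), then a recursive
## element-consumption walk at each candidate start enumerates every
## distinct end position, so flexible spacers report all realizable
## (start, end) spans, not just one per start.

## Regex character class for one element.  A wildcard consumes any residue
## character (including unknown X, selenocysteine U and pyrrolysine O);
## classes and literals assert residue identity, which an unknown residue
## cannot confirm, so they match only their listed letters.  Stops '*' and
## gaps '-' never match anything.
elementRegex <- function(e) {
    core <- switch(e$kind,
        literal  = e$residues,
        class    = paste0("[", paste(e$residues, collapse = ""), "]"),
        wildcard = paste0("[", paste(WILDCARD_MATCHES, collapse = ""), "]"))
    rep <- if (e$min == 1L && e$max == 1L) ""
           else if (e$min == e$max) sprintf("{%d}", e$min)
           else sprintf("{%d,%d}", e$min, e$max)
    paste0(core, rep)
}

motifRegex <- function(m) {
    paste(vapply(m@elements, elementRegex, ""), collapse = "")
}

## Letters an element can consume, as a character vector.
elementMatchSet <- function(e) {
    if (e$kind == "wildcard") WILDCARD_MATCHES else e$residues
}

checkSequenceChars <- function(chars, sequence_id) {
    bad <- which(!chars %in% SEQ_ALLOWED)
    if (length(bad))
        stop(sprintf(
            "sequence '%s' contains invalid character '%s' at position %d",
            sequence_id, chars[bad[1]], bad[1]), call. = FALSE)
    invisible(NULL)
}

## All end positions (1-based inclusive) of occurrences beginning at
## 'start', given per-element logical match vectors over the sequence.
enumerateEnds <- function(matchv, elements, start, L) {
    nE <- length(elements)
    ends <- logical(L)
    recurse <- function(ei, pos) {
        if (ei > nE) {
            if (pos > start) ends[pos - 1L] <<- TRUE
            return(invisible(NULL))
        }
        e <- elements[[ei]]
        mv <- matchv[[ei]]
        ## consume the mandatory e$min residues, then optionally up to e$max
        p <- pos
        cnt <- 0L
        while (cnt < e$min) {
            if (p > L || !mv[p]) return(invisible(NULL))
            p <- p + 1L
            cnt <- cnt + 1L
        }
        recurse(ei + 1L, p)
        while (cnt < e$max) {
            if (p > L || !mv[p]) return(invisible(NULL))
            p <- p + 1L
            cnt <- cnt + 1L
            recurse(ei + 1L, p)
        }
        invisible(NULL)
    }
    recurse(1L, start)
    which(ends)
}

#' Find all occurrences of a motif in one protein sequence
#'
#' Enumerates every distinct (start, end) span such that some assignment of
#' repeat counts to the motif's elements consumes exactly the subsequence
#' \code{seq[start..end]}, each consumed residue belonging to its element's
#' residue set.  All spans are reported, including overlapping ones and
#' multiple ends per start arising from flexible spacers; coordinates are
#' 1-based and inclusive at both ends.
#'
#' Lowercase input is uppercased.  An unknown residue \code{X} in the
#' sequence matches only wildcard elements, never classes or literals
#' (a class asserts identity that the data cannot confirm); \code{*} and
#' \code{-} never match; \code{U} and \code{O} match only wildcards.
#'
#' @param m a [Motif-class].
#' @param seq single protein sequence (character string or
#'   [Biostrings::AAString]).
#' @param sequence_id identifier reported in the result.
#'
#' @return a [S4Vectors::DataFrame] with columns \code{sequence_id},
#'   \code{start}, \code{end}, \code{matched_seq}, \code{motif}, sorted by
#'   (start, end).  Zero rows when there is no occurrence (an empty
#'   sequence is not an error).
#'
#' @examples
#' gc <- getCuratedMotif("GC14")
#' findMatches(gc, "KYCIFGDAVAAAAK")           # one span, 1-14
#' findMatches(parseMotif("HX{1,2}R", "m"), "HARR")  # spans (1,3) and (1,4)
#'
#' @export
findMatches <- function(m, seq, sequence_id = "seq") {
    stopifnot(is(m, "Motif"))
    seq <- toupper(as.character(seq))
    if (length(seq) != 1L || is.na(seq))
        stop("'seq' must be a single sequence", call. = FALSE)
    if (!is.character(sequence_id) || length(sequence_id) != 1L ||
        !nzchar(sequence_id))
        stop("'sequence_id' must be a non-empty string", call. = FALSE)
    empty <- DataFrame(sequence_id = character(), start = integer(),
                       end = integer(), matched_seq = character(),
                       motif = character())
    if (!nzchar(seq)) return(empty)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    checkSequenceChars(chars, sequence_id)
    L <- length(chars)

    ## candidate starts via zero-width lookahead (finds every position
    ## where at least one occurrence begins)
    starts <- gregexpr(paste0("(?=", motifRegex(m), ")"), seq,
                       perl = TRUE)[[1]]
    if (starts[1] == -1L) return(empty)
    starts <- as.integer(starts)

    elements <- m@elements
    matchv <- lapply(elements, function(e) chars %in% elementMatchSet(e))
    out_start <- integer()
    out_end <- integer()
    for (s in starts) {
        ends <- enumerateEnds(matchv, elements, s, L)
        if (length(ends)) {
            out_start <- c(out_start, rep.int(s, length(ends)))
            out_end <- c(out_end, ends)
        }
    }
    if (!length(out_start)) return(empty)
    o <- order(out_start, out_end)
    out_start <- out_start[o]; out_end <- out_end[o]
    DataFrame(sequence_id = rep.int(sequence_id, length(out_start)),
              start = out_start, end = out_end,
              matched_seq = substring(seq, out_start, out_end),
              motif = rep.int(m@name, length(out_start)))
}

#' @describeIn findMatches \code{TRUE} when the motif occurs at least once
#'   in the sequence.
#' @export
motifOccurs <- function(m, seq, sequence_id = "seq") {
    nrow(findMatches(m, seq, sequence_id)) > 0L
}
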