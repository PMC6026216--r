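## Pattern-language front end: parse and render motif strings, length
## bounds, accessors and structural comparison.

newElement <- function(kind, residues, min = 1L, max = 1L) {
    list(kind = kind, residues = residues,
         min = as.integer(min), max = as.integer(max))
}

newMotif <- function(name, elements, annotations = list(), provenance = "") {
    new("Motif", name = name, elements = elements,
        annotations = annotations, provenance = provenance)
}

parseStop <- function(token, offset, why) {
    stop(sprintf("motif parse error at offset %d near '%s': %s",
                 offset, token, why), call. = FALSE)
}

#' Parse a motif string into a Motif object
#'
#' Parses the degenerate-pattern syntax used for functional-center search
#' motifs: uppercase literals (\code{"G"}), bracketed residue classes
#' (\code{"[RKS]"}), the wildcard \code{"X"}, and repeat bounds written
#' either \code{"\{n\}"}/\code{"\{n,m\}"} or, in the dialect some
#' supplementary tables use, \code{"(n)"}/\code{"(n,m)"}.  A repeat suffix
#' attaches to the immediately preceding element; an element with no suffix
#' occurs exactly once.
#'
#' @param text motif string, e.g.
#'   \code{"[RKS][YFW][CTGH][VIL][FV]G[DNA]X[VIL]X\{4\}[KR]"}.
#' @param name name to give the motif.
#' @param annotations optional named list of per-residue-position
#'   functional notes (names are 1-based positions along a minimal-length
#'   match).
#' @param provenance optional character string recording the motif's origin.
#'
#' @return a [Motif-class] object.
#'
#' @examples
#' m <- parseMotif("HX{12}PX{14,16}YXSXR", "HNOX")
#' motifLengthBounds(m)   # 33 35
#'
#' @seealso [renderMotif()], [motifLengthBounds()], [findMatches()]
#' @export
parseMotif <- function(text, name = "motif", annotations = list(),
                       provenance = "") {
    if (!is.character(text) || length(text) != 1L || is.na(text) ||
        !nzchar(text))
        stop("'text' must be a single non-empty string", call. = FALSE)
    chars <- strsplit(text, "", fixed = TRUE)[[1]]
    n <- length(chars)
    elements <- list()
    i <- 1L
    while (i <= n) {
        ch <- chars[i]
        if (ch == "[") {
            j <- i + 1L
            members <- character()
            while (j <= n && chars[j] != "]") {
                if (!chars[j] %in% AA_ALPHABET20)
                    parseStop(chars[j], j,
                              "unknown residue letter inside a class")
                members <- c(members, chars[j])
                j <- j + 1L
            }
            if (j > n)
                parseStop("[", i, "dangling '[' with no closing ']'")
            if (length(members) == 0L)
                parseStop("[]", i, "empty residue class")
            if (anyDuplicated(members))
                parseStop(paste0("[", paste(members, collapse = ""), "]"), i,
                          "duplicate residue in class")
            elements[[length(elements) + 1L]] <-
                newElement("class", members)
            i <- j + 1L
        } else if (ch == "X") {
            elements[[length(elements) + 1L]] <-
                newElement("wildcard", AA_ALPHABET20)
            i <- i + 1L
        } else if (ch %in% AA_ALPHABET20) {
            elements[[length(elements) + 1L]] <- newElement("literal", ch)
            i <- i + 1L
        } else if (ch == "{" || ch == "(") {
            close <- if (ch == "{") "}" else ")"
            if (length(elements) == 0L)
                parseStop(ch, i, "repeat bound with no preceding element")
            j <- i + 1L
            body <- character()
            while (j <= n && chars[j] != close) {
                body <- c(body, chars[j])
                j <- j + 1L
            }
            if (j > n)
                parseStop(ch, i, sprintf("dangling '%s' with no closing '%s'",
                                         ch, close))
            spec <- paste(body, collapse = "")
            tok <- paste0(ch, spec, close)
            if (!grepl("^[0-9]+(,[0-9]+)?$", spec))
                parseStop(tok, i, "malformed repeat bound (expected n or n,m)")
            parts <- as.integer(strsplit(spec, ",", fixed = TRUE)[[1]])
            lo <- parts[1]
            hi <- if (length(parts) == 2L) parts[2] else parts[1]
            if (hi == 0L)
                parseStop(tok, i, "repeat maximum must be at least 1")
            if (lo > hi)
                parseStop(tok, i, "repeat minimum exceeds maximum")
            k <- length(elements)
            if (elements[[k]]$min != 1L || elements[[k]]$max != 1L)
                parseStop(tok, i, "element already carries a repeat bound")
            elements[[k]]$min <- lo
            elements[[k]]$max <- hi
            i <- j + 1L
        } else {
            parseStop(ch, i, "unexpected character")
        }
    }
    if (length(elements) == 0L)
        stop("motif parse error: no elements in pattern", call. = FALSE)
    newMotif(name, elements, annotations, provenance)
}

#' Render a Motif to its canonical string form
#'
#' Emits the canonical syntax: classes in bracket notation with residues in
#' their stored (curated) order, repeats in brace notation, with
#' \code{\{n,n\}} collapsed to \code{\{n\}} and \code{\{1\}} omitted.
#' \code{parseMotif(renderMotif(m))} reproduces an identical element
#' sequence.
#'
#' @param m a [Motif-class].
#' @return single character string.
#'
#' @examples
#' renderMotif(parseMotif("[DE]X(7,8)RX(3,4)[DE]X(5)YX(6)H", "ABA"))
#' ## "[DE]X{7,8}RX{3,4}[DE]X{5}YX{6}H"
#'
#' @export
renderMotif <- function(m) {
    stopifnot(is(m, "Motif"))
    paste(vapply(m@elements, function(e) {
        core <- switch(e$kind,
            literal  = e$residues,
            wildcard = "X",
            class    = paste0("[", paste(e$residues, collapse = ""), "]"))
        rep <- if (e$min == 1L && e$max == 1L) ""
               else if (e$min == e$max) sprintf("{%d}", e$min)
               else sprintf("{%d,%d}", e$min, e$max)
        paste0(core, rep)
    }, ""), collapse = "")
}

#' Minimum and maximum match length of a motif
#'
#' @param m a [Motif-class].
#' @return integer vector \code{c(min, max)}: the sums of the elements'
#'   minimum and maximum repeat counts.
#'
#' @examples
#' gc <- parseMotif("[RKS][YFW][CTGH][VIL][FV]G[DNA]X[VIL]X{4}[KR]", "GC14")
#' motifLengthBounds(gc)   # 14 14
#'
#' @export
motifLengthBounds <- function(m) {
    stopifnot(is(m, "Motif"))
    c(min = sum(vapply(m@elements, function(e) e$min, 1L)),
      max = sum(vapply(m@elements, function(e) e$max, 1L)))
}

#' @describeIn parseMotif number of pattern elements in a motif.
#' @export
motifSize <- function(m) {
    stopifnot(is(m, "Motif"))
    length(m@elements)
}

#' Accessors for Motif slots
#'
#' @param m a [Motif-class].
#' @return \code{motifName}: the motif's name; \code{motifElements}: the
#'   list of pattern elements; \code{motifAnnotations}: the named list of
#'   per-position functional notes; \code{motifProvenance}: the provenance
#'   string.
#' @name motif-accessors
NULL

#' @rdname motif-accessors
#' @export
motifName <- function(m) { stopifnot(is(m, "Motif")); m@name }

#' @rdname motif-accessors
#' @export
motifElements <- function(m) { stopifnot(is(m, "Motif")); m@elements }

#' @rdname motif-accessors
#' @export
motifAnnotations <- function(m) { stopifnot(is(m, "Motif")); m@annotations }

#' @rdname motif-accessors
#' @export
motifProvenance <- function(m) { stopifnot(is(m, "Motif")); m@provenance }

#' Structural equality of two motifs
#'
#' Two motifs are structurally equal when their element sequences agree in
#' kind, residue membership (as sets) and repeat bounds.  Names,
#' annotations, provenance and the presentational order of residues inside
#' a class are ignored, so the brace and parenthesis repeat dialects of the
#' same printed motif compare equal.
#'
#' @param a,b [Motif-class] objects.
#' @return logical scalar.
#' @export
motifIdentical <- function(a, b) {
    stopifnot(is(a, "Motif"), is(b, "Motif"))
    ea <- a@elements; eb <- b@elements
    if (length(ea) != length(eb)) return(FALSE)
    ## a literal and a singleton class constrain matching identically;
    ## a wildcard does not (it also consumes X/U/O), so it stays distinct
    canonKind <- function(k) if (k == "wildcard") "wildcard" else "set"
    for (i in seq_along(ea)) {
        if (canonKind(ea[[i]]$kind) != canonKind(eb[[i]]$kind)) return(FALSE)
        if (!setequal(ea[[i]]$residues, eb[[i]]$residues)) return(FALSE)
        if (ea[[i]]$min != eb[[i]]$min || ea[[i]]$max != eb[[i]]$max)
            return(FALSE)
    }
    TRUE
}

setMethod("show", "Motif", function(object) {
    b <- motifLengthBounds(object)
    cat(sprintf("Motif '%s': %s\n", object@name, renderMotif(object)))
    cat(sprintf("  %d elements, match length %d", length(object@elements),
                b[["min"]]))
    if (b[["max"]] != b[["min"]]) cat(sprintf("-%d", b[["max"]]))
    cat(" residues\n")
    if (length(object@annotations)) {
        for (p in names(object@annotations))
            cat(sprintf("  position %s: %s\n", p, object@annotations[[p]]))
    }
    if (nzchar(object@provenance))
        cat(sprintf("  provenance: %s\n", object@provenance))
    invisible(NULL)
})
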