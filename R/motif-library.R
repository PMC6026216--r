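## Curated functional-center motifs and rational derivation operations:
## position substitution, similarity-based relaxation, restriction.

#' Default amino-acid similarity groups
#'
#' A coarse partition of the 20-letter alphabet into size/charge groups,
#' used to relax a motif position to residues that could conceivably
#' perform the same function: positive \{K,R,H\}, negative \{D,E\}, amide
#' \{N,Q\}, small \{G,A,S,T,C\}, aliphatic \{V,I,L,M\}, aromatic \{F,Y,W\}
#' and proline alone.  The grouping is a configuration value, not a
#' constant; supply your own partition to
#' [expandPositionBySimilarity()] to change it.
#'
#' @return named list of character vectors partitioning the alphabet.
#' @export
defaultSimilarityGroups <- function() {
    list(positive  = c("K", "R", "H"),
         negative  = c("D", "E"),
         amide     = c("N", "Q"),
         small     = c("G", "A", "S", "T", "C"),
         aliphatic = c("V", "I", "L", "M"),
         aromatic  = c("F", "Y", "W"),
         proline   = "P")
}

validateSimilarityGroups <- function(groups) {
    all_res <- unlist(groups, use.names = FALSE)
    if (anyDuplicated(all_res))
        stop("similarity groups must be disjoint", call. = FALSE)
    if (!setequal(all_res, AA_ALPHABET20))
        stop("similarity groups must cover the full 20-residue alphabet",
             call. = FALSE)
    invisible(groups)
}

## Map a residue position (counted along a minimal-length match, the
## convention in which a cyclase motif's substrate-specificity residue is
## "position 3" and its phosphate-binding residue "position 14") to the
## index of the element occupying it.  Only positions held by a
## single-residue element (min = max = 1) are addressable.
positionToElement <- function(m, residue_position) {
    stopifnot(is(m, "Motif"))
    pos <- as.integer(residue_position)
    if (length(pos) != 1L || is.na(pos) || pos < 1L)
        stop("'residue_position' must be a single positive integer",
             call. = FALSE)
    at <- 1L
    for (i in seq_along(m@elements)) {
        e <- m@elements[[i]]
        if (pos < at + e$min) {
            if (e$min == 1L && e$max == 1L) return(i)
            stop(sprintf(paste0(
                "position %d falls inside a spacer/repeated element ",
                "(element %d, %s): only single-residue positions are ",
                "substitutable"), pos, i, elementRegex(e)), call. = FALSE)
        }
        at <- at + e$min
    }
    stop(sprintf(
        "position %d exceeds the motif's length: only single-residue positions are substitutable",
        pos), call. = FALSE)
}

checkResidueSet <- function(residues) {
    residues <- unique(toupper(as.character(residues)))
    if (!length(residues) || !all(residues %in% AA_ALPHABET20))
        stop("residue set must be a non-empty subset of the 20-letter alphabet",
             call. = FALSE)
    residues
}

#' Rational motif derivation: substitute, relax or restrict one position
#'
#' These operations implement the rational modification step of
#' motif-based functional-center discovery: a curated motif is made more or
#' less stringent at a single residue position.  \code{substitutePosition}
#' replaces the residue class outright (e.g. swapping the
#' substrate-specificity class of a guanylate-cyclase motif from
#' \code{[CTGH]} to \code{[DE]} turns it into an adenylate-cyclase motif).
#' \code{expandPositionBySimilarity} enlarges the class to the union of the
#' similarity groups of its current members (never removing a residue).
#' \code{restrictPosition} narrows the class to a subset, increasing
#' specificity.
#'
#' Positions count residues along a minimal-length match; positions falling
#' inside a wildcard spacer are not addressable and raise an error rather
#' than being guessed at.
#'
#' @param m a [Motif-class].
#' @param residue_position 1-based residue position along a minimal-length
#'   match.
#' @param new_residues,residues character vector of one-letter codes.
#' @param groups similarity partition, as from [defaultSimilarityGroups()].
#' @param name optional name for the derived motif (default: keep
#'   \code{m}'s name).
#'
#' @return a new [Motif-class]; the input motif is unchanged and the
#'   result's provenance records the edit.
#'
#' @examples
#' gc <- getCuratedMotif("GC14")
#' ac <- substitutePosition(gc, 3, c("D", "E"), name = "AC14")
#' renderMotif(ac)
#' ## relaxed motif admitting serine at the substrate position:
#' renderMotif(expandPositionBySimilarity(gc, 3))
#'
#' @export
substitutePosition <- function(m, residue_position, new_residues,
                               name = motifName(m)) {
    i <- positionToElement(m, residue_position)
    new_residues <- checkResidueSet(new_residues)
    old <- m@elements[[i]]
    elements <- m@elements
    kind <- if (length(new_residues) == 1L) "literal" else "class"
    elements[[i]] <- newElement(kind, new_residues, old$min, old$max)
    note <- sprintf("substituted position %d: %s -> [%s]",
                    as.integer(residue_position), elementRegex(old),
                    paste(new_residues, collapse = ""))
    newMotif(name, elements, m@annotations,
             provenance = paste(c(
                 if (nzchar(m@provenance)) m@provenance,
                 sprintf("derived from '%s': %s", m@name, note)),
                 collapse = "; "))
}

#' @rdname substitutePosition
#' @export
expandPositionBySimilarity <- function(m, residue_position,
                                       groups = defaultSimilarityGroups(),
                                       name = motifName(m)) {
    validateSimilarityGroups(groups)
    i <- positionToElement(m, residue_position)
    old <- m@elements[[i]]
    if (old$kind == "wildcard")
        stop("a wildcard cannot be expanded further", call. = FALSE)
    in_groups <- vapply(groups, function(g) any(old$residues %in% g), NA)
    expanded <- unlist(groups[in_groups], use.names = FALSE)
    added <- sort(setdiff(expanded, old$residues))
    result <- c(old$residues, added)      # curated order first, additions after
    elements <- m@elements
    kind <- if (length(result) == 1L) old$kind else "class"
    elements[[i]] <- newElement(kind, result, old$min, old$max)
    if (!length(added)) return(m)         # fixed point: already the full union
    note <- sprintf("expanded position %d by similarity: %s -> [%s]",
                    as.integer(residue_position), elementRegex(old),
                    paste(result, collapse = ""))
    newMotif(name, elements, m@annotations,
             provenance = paste(c(
                 if (nzchar(m@provenance)) m@provenance,
                 sprintf("derived from '%s': %s", m@name, note)),
                 collapse = "; "))
}

#' @rdname substitutePosition
#' @export
restrictPosition <- function(m, residue_position, residues,
                             name = motifName(m)) {
    i <- positionToElement(m, residue_position)
    residues <- checkResidueSet(residues)
    old <- m@elements[[i]]
    current <- elementMatchSet(old)
    if (!all(residues %in% old$residues) && old$kind != "wildcard")
        stop(sprintf(
            "restriction cannot introduce residues: {%s} is not a subset of {%s}",
            paste(setdiff(residues, old$residues), collapse = ","),
            paste(old$residues, collapse = ",")), call. = FALSE)
    kept <- if (old$kind == "wildcard") residues
            else old$residues[old$residues %in% residues]
    if (old$kind != "wildcard" && setequal(kept, old$residues))
        return(m)                         # restriction to the full set
    elements <- m@elements
    kind <- if (length(kept) == 1L) "literal" else "class"
    elements[[i]] <- newElement(kind, kept, old$min, old$max)
    note <- sprintf("restricted position %d: %s -> [%s]",
                    as.integer(residue_position), elementRegex(old),
                    paste(kept, collapse = ""))
    newMotif(name, elements, m@annotations,
             provenance = paste(c(
                 if (nzchar(m@provenance)) m@provenance,
                 sprintf("derived from '%s': %s", m@name, note)),
                 collapse = "; "))
}

## ---- curated registry -----------------------------------------------------

.registry <- new.env(parent = emptyenv())

buildRegistry <- function() {
    reg <- list()

    reg$GC14 <- parseMotif(
        "[RKS][YFW][CTGH][VIL][FV]G[DNA]X[VIL]X{4}[KR]", name = "GC14",
        annotations = list(
            `1`  = "forms hydrogen bonds with the guanine of the substrate GTP",
            `3`  = "confers substrate specificity for GTP over ATP",
            `14` = "binds the phosphate acyl group and stabilizes the GTP-to-cGMP transition"),
        provenance = paste("curated 14-residue guanylate-cyclase catalytic-center",
                           "search motif, deduced from aligned catalytic regions",
                           "of prokaryotic and eukaryotic GCs"))

    reg$GC_CORE <- parseMotif(
        "[KS]X[CGS]X{10}[KR]", name = "GC_CORE",
        annotations = list(
            `1`  = "guanine hydrogen-bonding residue of the catalytic core",
            `3`  = "substrate-specificity residue of the catalytic core",
            `14` = "phosphate-binding residue of the catalytic core"),
        provenance = paste("relaxed guanylate-cyclase core motif retaining only",
                           "the conserved functional residues of the GC center"))

    ## AC14 is materialized by applying the substitution rule to GC14, so
    ## the derivation itself is exercised whenever the registry is built:
    ## swapping the substrate-specificity class [CTGH] -> [DE] changes
    ## specificity from GTP to ATP.
    reg$AC14 <- substitutePosition(reg$GC14, 3, c("D", "E"), name = "AC14")

    reg$HNOX <- parseMotif(
        "HX{12}PX{14,16}YXSXR", name = "HNOX",
        annotations = list(
            `1`  = "histidine coordinating the heme iron as axial ligand (reversible NO binding)",
            `14` = "proximal proline inducing steric strain at the bound heme cofactor",
            `29` = "start of the YXSXR signature hydrogen-bonding the heme-b carboxylates"),
        provenance = paste("curated H-NOX nitric-oxide-sensing motif from aligned",
                           "heme centers of gas-responsive H-NOX family proteins"))

    reg$ABA <- parseMotif(
        "[DE]X{7,8}RX{3,4}[DE]X{5}YX{6}H", name = "ABA",
        annotations = list(
            `1` = "first conserved latch-region acidic residue of canonical ABA receptors"),
        provenance = paste("curated abscisic-acid modulatory-site motif from the",
                           "conserved latch-like region of PYR/PYL/RCAR receptors",
                           "and the ABA-interacting GORK channel"))

    reg
}

getRegistry <- function() {
    if (is.null(.registry$entries))
        .registry$entries <- buildRegistry()
    .registry$entries
}

#' Curated functional-center motifs
#'
#' The registry of curated search motifs: \code{GC14} (14-residue
#' guanylate-cyclase catalytic center), \code{GC_CORE} (relaxed GC core
#' retaining only the conserved functional residues), \code{AC14}
#' (adenylate-cyclase motif, derived from GC14 by substituting the
#' substrate-specificity position \code{[CTGH] -> [DE]}), \code{HNOX}
#' (heme-nitric-oxide/oxygen sensing center) and \code{ABA} (abscisic-acid
#' modulatory site).  Each motif carries per-position functional
#' annotations and a provenance note.
#'
#' @param key one of \code{curatedMotifKeys()}.
#' @return \code{getCuratedMotif}: the [Motif-class];
#'   \code{curatedMotifKeys}: character vector of registry keys.
#'
#' @examples
#' curatedMotifKeys()
#' getCuratedMotif("HNOX")
#'
#' @export
getCuratedMotif <- function(key) {
    reg <- getRegistry()
    if (!is.character(key) || length(key) != 1L || !key %in% names(reg))
        stop(sprintf("unknown curated motif '%s'; valid keys: %s",
                     as.character(key)[1],
                     paste(names(reg), collapse = ", ")), call. = FALSE)
    reg[[key]]
}

#' @rdname getCuratedMotif
#' @export
curatedMotifKeys <- function() names(getRegistry())

#' Export or import a motif registry as JSON
#'
#' Serializes motifs (key, canonical motif string, per-position
#' annotations, provenance) to a JSON document and reads such a document
#' back into a named list of [Motif-class] objects.
#'
#' @param motifs named list of [Motif-class] objects (default: the curated
#'   registry).
#' @param path file path.
#' @return \code{exportMotifRegistry}: \code{path}, invisibly;
#'   \code{importMotifRegistry}: named list of motifs.
#'
#' @export
exportMotifRegistry <- function(path, motifs = getRegistry()) {
    doc <- lapply(names(motifs), function(k) {
        m <- motifs[[k]]
        list(key = k, motif = renderMotif(m),
             annotations = m@annotations, citation = m@provenance)
    })
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' @rdname exportMotifRegistry
#' @export
importMotifRegistry <- function(path) {
    doc <- jsonlite::read_json(path)
    out <- lapply(doc, function(rec)
        parseMotif(rec$motif, name = rec$key,
                   annotations = lapply(rec$annotations, as.character),
                   provenance = if (is.null(rec$citation)) "" else rec$citation))
    names(out) <- vapply(doc, function(rec) rec$key, "")
    out
}
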