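## Proteome scanning: multi-FASTA input, motif search over all records,
## splice-isoform collapsing, exclusion lists, TSV/GFF3 output.
## Coordinates in all outputs are 1-based and inclusive at both ends.

#' Read a protein multi-FASTA file
#'
#' Reads a (possibly gzip-compressed) protein FASTA file.  The record
#' identifier is the first whitespace-delimited token of the header; the
#' remainder is kept as the description.  Sequences are uppercased.
#' Duplicate identifiers are an error; records with empty sequences are
#' skipped with a warning.
#'
#' @param path FASTA file path (optionally \code{.gz}).
#' @return a [Biostrings::AAStringSet] named by identifier, with the
#'   description in \code{mcols(x)$description}.
#' @export
readProteinFasta <- function(path) {
    if (!file.exists(path))
        stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
    recs <- tryCatch(Biostrings::readAAStringSet(path),
                     error = function(e)
                         stop(sprintf("not a valid FASTA file (%s): %s",
                                      path, conditionMessage(e)),
                              call. = FALSE))
    headers <- names(recs)
    ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
    desc <- sub("^\\S+\\s*", "", headers)
    if (anyNA(ids) || any(!nzchar(ids)))
        stop(sprintf("record %d has an empty identifier",
                     which(is.na(ids) | !nzchar(ids))[1]), call. = FALSE)
    if (anyDuplicated(ids))
        stop(sprintf("duplicate sequence identifier '%s'",
                     ids[duplicated(ids)][1]), call. = FALSE)
    empty <- Biostrings::width(recs) == 0L
    if (any(empty)) {
        warning(sprintf("skipping %d record(s) with empty sequence: %s",
                        sum(empty), paste(ids[empty], collapse = ", ")),
                call. = FALSE)
        recs <- recs[!empty]; ids <- ids[!empty]; desc <- desc[!empty]
    }
    recs <- Biostrings::AAStringSet(toupper(as.character(recs)))
    names(recs) <- ids
    S4Vectors::mcols(recs) <- DataFrame(description = desc)
    recs
}

## Content digest tying a scan to a pinned proteome: md5 of "id\tseq"
## lines (via a temporary file and tools::md5sum), independent of the
## on-disk representation.
proteomeDigest <- function(records) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(paste(names(records), as.character(records), sep = "\t"), tf)
    unname(tools::md5sum(tf))
}

emptySpans <- function() {
    DataFrame(sequence_id = character(), start = integer(),
              end = integer(), matched_seq = character(),
              motif = character())
}

#' Scan a proteome with a motif
#'
#' Runs [findMatches()] over every record and collects all spans into a
#' [HitTable-class] with scan provenance (proteome path, content digest,
#' parameter snapshot, timestamp), so candidate counts can be reproduced
#' against a pinned proteome file.
#'
#' @param m a [Motif-class].
#' @param records a [Biostrings::AAStringSet] (as from
#'   [readProteinFasta()]) or named character vector of protein sequences,
#'   or a FASTA file path.
#' @return a [HitTable-class].
#'
#' @examples
#' ht <- scanProteome(getCuratedMotif("GC14"),
#'                    c(p1 = "MKYCIFGDAVAAAAKL", p2 = "MAAAA"))
#' hits(ht)
#'
#' @export
scanProteome <- function(m, records) {
    stopifnot(is(m, "Motif"))
    path <- NA_character_
    if (is.character(records) && length(records) == 1L &&
        is.null(names(records)) && file.exists(records)) {
        path <- records
        records <- readProteinFasta(records)
    }
    if (is.character(records)) {
        if (is.null(names(records)) || any(!nzchar(names(records))))
            stop("'records' must be named sequences", call. = FALSE)
        ## validate before XString construction so errors name the record
        for (i in seq_along(records))
            checkSequenceChars(strsplit(toupper(records[[i]]), "",
                                        fixed = TRUE)[[1]],
                               names(records)[i])
        records <- Biostrings::AAStringSet(toupper(records))
    }
    stopifnot(is(records, "AAStringSet"))
    if (anyDuplicated(names(records)))
        stop("duplicate sequence identifiers in 'records'", call. = FALSE)
    seqs <- as.character(records)
    spans <- emptySpans()
    if (length(seqs)) {
        per <- lapply(seq_along(seqs), function(i)
            findMatches(m, seqs[[i]], names(seqs)[i]))
        spans <- do.call(rbind, per)
    }
    o <- order(spans$sequence_id, spans$start, spans$end)
    new("HitTable", spans = spans[o, , drop = FALSE], motifName = m@name,
        proteomePath = path, proteomeDigest = proteomeDigest(records),
        parameters = list(motif = renderMotif(m),
                          n_sequences = length(records)),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' HitTable accessors
#'
#' @param x a [HitTable-class].
#' @return \code{hits}: the span [S4Vectors::DataFrame]; \code{hitCount}:
#'   number of spans; \code{scanProvenance}: list with the motif name,
#'   proteome path, content digest, parameters and timestamp.
#' @name hittable-accessors
NULL

#' @rdname hittable-accessors
#' @export
hits <- function(x) { stopifnot(is(x, "HitTable")); x@spans }

#' @rdname hittable-accessors
#' @export
hitCount <- function(x) { stopifnot(is(x, "HitTable")); nrow(x@spans) }

#' @rdname hittable-accessors
#' @export
scanProvenance <- function(x) {
    stopifnot(is(x, "HitTable"))
    list(motif = x@motifName, proteome_path = x@proteomePath,
         proteome_digest = x@proteomeDigest, parameters = x@parameters,
         timestamp = x@timestamp)
}

setMethod("show", "HitTable", function(object) {
    cat(sprintf("HitTable: %d span(s) of motif '%s' on %d sequence(s)\n",
                nrow(object@spans), object@motifName,
                length(unique(object@spans$sequence_id))))
    if (!is.na(object@proteomePath))
        cat(sprintf("  proteome: %s\n", object@proteomePath))
    cat(sprintf("  digest: %s\n", object@proteomeDigest))
    if (nrow(object@spans)) show(utils::head(object@spans, 5L))
    invisible(NULL)
})

#' Default splice-isoform rule for AGI-style identifiers
#'
#' Maps a protein identifier to its gene locus by stripping a trailing
#' \code{.<digits>} isoform suffix (\code{"AT1G54130.2"} ->
#' \code{"AT1G54130"}); identifiers without the suffix map to themselves.
#' Case is preserved.
#'
#' @param id character vector of identifiers.
#' @return character vector of locus identifiers.
#' @export
agiIsoformRule <- function(id) sub("\\.[0-9]+$", "", id)

#' Collapse hits to gene loci
#'
#' Groups the spans of a [HitTable-class] by gene locus so that splice
#' isoforms of one gene count as a single candidate — the "excluding their
#' spliced variants" convention of candidate screens.
#'
#' @param h a [HitTable-class].
#' @param isoformRule function mapping an identifier to its locus
#'   (default: [agiIsoformRule()]).
#' @return list with \code{loci} (named list of span
#'   [S4Vectors::DataFrame]s, one per locus) and \code{count} (number of
#'   distinct loci with at least one span).
#'
#' @examples
#' ## two isoforms of one gene collapse to one candidate locus
#' ht <- scanProteome(getCuratedMotif("GC14"),
#'                    c(AT1G54130.1 = "KYCIFGDAVAAAAK",
#'                      AT1G54130.2 = "KYCIFGDAVAAAAK"))
#' collapseToLoci(ht)$count   # 1
#'
#' @export
collapseToLoci <- function(h, isoformRule = agiIsoformRule) {
    stopifnot(is(h, "HitTable"), is.function(isoformRule))
    sp <- h@spans
    if (!nrow(sp)) return(list(loci = structure(list(), names = character()),
                               count = 0L))
    locus <- isoformRule(sp$sequence_id)
    loci <- lapply(split(seq_len(nrow(sp)), locus),
                   function(i) sp[i, , drop = FALSE])
    list(loci = loci, count = length(loci))
}

#' Remove excluded loci from a collapsed hit list
#'
#' Drops loci named on an exclusion list — e.g. the already-known bait
#' proteins and canonical receptors a candidate screen sets aside.  AGI
#' identifiers appear in the wild in mixed case (\code{"At1g54130"} and
#' \code{"AT1G54130"}), so comparison is case-insensitive by default.
#'
#' @param loci result of [collapseToLoci()].
#' @param exclusions character vector of locus identifiers to remove, or
#'   a file path (one identifier per line, \code{#} comments allowed).
#' @param caseInsensitive compare identifiers case-insensitively
#'   (default \code{TRUE}).
#' @return list with \code{loci} (retained), \code{count},
#'   \code{removed} (excluded loci that were present) and \code{unused}
#'   (exclusion identifiers that matched nothing; reported, not an error).
#' @export
applyExclusions <- function(loci, exclusions, caseInsensitive = TRUE) {
    stopifnot(is.list(loci), !is.null(loci$loci))
    if (is.character(exclusions) && length(exclusions) == 1L &&
        file.exists(exclusions))
        exclusions <- readExclusionFile(exclusions)
    exclusions <- as.character(exclusions)
    ids <- names(loci$loci)
    fold <- if (caseInsensitive) toupper else identity
    drop <- fold(ids) %in% fold(exclusions)
    unused <- exclusions[!fold(exclusions) %in% fold(ids)]
    kept <- loci$loci[!drop]
    list(loci = kept, count = length(kept), removed = ids[drop],
         unused = unused)
}

#' @rdname applyExclusions
#' @param path exclusion file path.
#' @export
readExclusionFile <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines[nzchar(lines)]
}

#' Write / read motif hits as TSV, write GFF3
#'
#' \code{writeHitsTsv} writes a tab-delimited table with header columns
#' \code{motif, sequence_id, locus, start, end, length, matched_seq}
#' (1-based inclusive coordinates).  \code{readHitsTsv} reads such a file
#' back into a [HitTable-class], round-tripping the span set.
#' \code{writeGff3} writes the spans as GFF3 \code{polypeptide_motif}
#' features (source \code{centerscan}, 1-based inclusive coordinates,
#' attributes carrying the motif name and matched text).
#'
#' @param h a [HitTable-class].
#' @param path output file path.
#' @param isoformRule locus rule used for the TSV \code{locus} column.
#' @return the path, invisibly (\code{readHitsTsv}: a
#'   [HitTable-class]).
#' @export
writeHitsTsv <- function(h, path, isoformRule = agiIsoformRule) {
    stopifnot(is(h, "HitTable"))
    sp <- h@spans
    df <- data.frame(motif = sp$motif, sequence_id = sp$sequence_id,
                     locus = isoformRule(sp$sequence_id),
                     start = sp$start, end = sp$end,
                     length = sp$end - sp$start + 1L,
                     matched_seq = sp$matched_seq)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeHitsTsv
#' @export
readHitsTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("motif", "sequence_id", "start", "end", "matched_seq")
    if (!all(need %in% colnames(df)))
        stop(sprintf("hits TSV must have columns %s",
                     paste(need, collapse = ", ")), call. = FALSE)
    sp <- DataFrame(sequence_id = as.character(df$sequence_id),
                    start = as.integer(df$start), end = as.integer(df$end),
                    matched_seq = as.character(df$matched_seq),
                    motif = as.character(df$motif))
    o <- order(sp$sequence_id, sp$start, sp$end)
    new("HitTable", spans = sp[o, , drop = FALSE],
        motifName = if (nrow(sp)) sp$motif[1] else NA_character_,
        proteomePath = path, proteomeDigest = NA_character_,
        parameters = list(source = "tsv"),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' @rdname writeHitsTsv
#' @export
writeGff3 <- function(h, path) {
    stopifnot(is(h, "HitTable"))
    sp <- h@spans
    if (!nrow(sp)) {             # no features: version pragma only
        writeLines("##gff-version 3", path)
        return(invisible(path))
    }
    gr <- GenomicRanges::GRanges(
        seqnames = if (nrow(sp)) sp$sequence_id else character(),
        ranges = IRanges::IRanges(start = sp$start, end = sp$end))
    S4Vectors::mcols(gr)$source <- rep("centerscan", nrow(sp))
    S4Vectors::mcols(gr)$type <- rep("polypeptide_motif", nrow(sp))
    S4Vectors::mcols(gr)$Name <- sp$motif
    S4Vectors::mcols(gr)$matched_seq <- sp$matched_seq
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}
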