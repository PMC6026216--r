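## Consensus motif induction from a multiple sequence alignment of
## annotated functional centers: conserved columns become residue-class
## anchors, runs of variable columns become bounded wildcard spacers.

#' Read a multiple sequence alignment
#'
#' Reads an aligned FASTA or Clustal file of functional-center sequences.
#' All rows must have equal length once gaps (\code{-}) are included; gaps
#' are preserved.
#'
#' @param path file path.
#' @param format \code{"auto"} (detect from content), \code{"fasta"} or
#'   \code{"clustal"}.
#' @return a [Biostrings::AAStringSet] of aligned rows, named by
#'   identifier.
#' @export
readAlignmentFile <- function(path, format = c("auto", "fasta", "clustal")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop(sprintf("alignment file not found: %s", path), call. = FALSE)
    if (format == "auto") {
        head_lines <- readLines(path, n = 5L, warn = FALSE)
        head_lines <- head_lines[nzchar(trimws(head_lines))]
        if (!length(head_lines))
            stop(sprintf("empty alignment file: %s", path), call. = FALSE)
        format <- if (startsWith(head_lines[1], ">")) "fasta" else "clustal"
    }
    aln <- if (format == "fasta") {
        Biostrings::readAAStringSet(path)
    } else {
        methods::as(Biostrings::readAAMultipleAlignment(path,
                                                        format = "clustal"),
                    "AAStringSet")
    }
    if (length(aln) == 0L)
        stop(sprintf("no sequences in alignment file: %s", path),
             call. = FALSE)
    w <- Biostrings::width(aln)
    if (length(unique(w)) != 1L) {
        off <- names(aln)[which(w != w[1])[1]]
        stop(sprintf(
            "ragged alignment: row '%s' has length %d, expected %d",
            off, w[w != w[1]][1], w[1]), call. = FALSE)
    }
    names(aln) <- vapply(strsplit(names(aln), "\\s+"), `[`, "", 1)
    aln
}

alignmentMatrix <- function(alignment) {
    if (is.matrix(alignment)) return(alignment)
    if (is.character(alignment))
        alignment <- Biostrings::AAStringSet(alignment)
    stopifnot(is(alignment, "AAStringSet"), length(alignment) > 0L)
    w <- Biostrings::width(alignment)
    if (length(unique(w)) != 1L)
        stop("alignment rows have unequal lengths", call. = FALSE)
    mat <- do.call(rbind,
                   strsplit(toupper(as.character(alignment)), "", fixed = TRUE))
    rownames(mat) <- names(alignment)
    mat
}

#' Per-column residue profiles of an alignment
#'
#' @param alignment a [Biostrings::AAStringSet] of equal-width rows, or a
#'   character vector of aligned sequences.
#' @return list with one entry per column: \code{column} (1-based index),
#'   \code{counts} (named integer vector of residue counts, uppercase,
#'   gaps excluded) and \code{gaps} (gap count).  Counts plus gaps sum to
#'   the number of aligned sequences.
#' @export
profileColumns <- function(alignment) {
    mat <- alignmentMatrix(alignment)
    lapply(seq_len(ncol(mat)), function(j) {
        col <- mat[, j]
        gaps <- sum(col == "-")
        res <- col[col != "-"]
        counts <- if (length(res)) table(res) else integer()
        counts <- stats::setNames(as.integer(counts), names(counts))
        list(column = j, counts = counts, gaps = as.integer(gaps))
    })
}

#' Induce a consensus search motif from an alignment
#'
#' Builds a degenerate search motif from a multiple sequence alignment of
#' functional centers, the first two steps of motif-based center
#' discovery: highly conserved columns ("anchors") become residue-class
#' elements of their observed residues, and each maximal run of
#' non-conserved columns between two anchors becomes one bounded wildcard
#' spacer whose repeat bounds are the minimum and maximum number of
#' residues (non-gap characters) any aligned sequence places in that run —
#' so gapped alignments yield \code{X\{n,m\}} spacers.  Columns before the
#' first and after the last anchor are trimmed, keeping the motif anchored
#' at functional residues.
#'
#' A column is an anchor when it is listed in \code{anchorOverrides}
#' (forcing columns with annotated molecular function to anchor status
#' regardless of conservation arithmetic), or when it shows at most
#' \code{maxDistinctResidues} distinct residues and at most
#' \code{maxGapFraction} gaps.
#'
#' @param alignment a [Biostrings::AAStringSet] (or character vector) of
#'   equal-width aligned sequences.
#' @param maxDistinctResidues maximum number of distinct residues a column
#'   may show and still anchor (default 3, matching the 1-4 residue class
#'   sizes of the curated motifs).
#' @param maxGapFraction maximum gap fraction of an anchor column
#'   (default 0.1).
#' @param anchorOverrides integer vector of column indices forced to
#'   anchor status.
#' @param similarityExpansion when \code{TRUE}, each anchor class is
#'   expanded to the union of its members' similarity groups.
#' @param groups similarity partition used when expanding.
#' @param name name for the induced motif.
#' @param details when \code{TRUE}, return
#'   \code{list(motif =, report =)} where the report is a per-column
#'   data.frame (column, distinct, gap_fraction, role).
#'
#' @return a [Motif-class] (or a list, with \code{details = TRUE}).  Every
#'   input row, with gaps removed, matches the induced motif.
#' @export
induceMotif <- function(alignment, maxDistinctResidues = 3L,
                        maxGapFraction = 0.1, anchorOverrides = integer(),
                        similarityExpansion = FALSE,
                        groups = defaultSimilarityGroups(),
                        name = "induced", details = FALSE) {
    stopifnot(maxDistinctResidues >= 1L,
              maxGapFraction >= 0, maxGapFraction <= 1)
    mat <- alignmentMatrix(alignment)
    bad <- which(!(mat %in% c(AA_ALPHABET20, "-")))
    if (length(bad)) {
        j <- (bad[1] - 1L) %/% nrow(mat) + 1L
        stop(sprintf("alignment contains invalid character '%s' in column %d",
                     mat[bad[1]], j), call. = FALSE)
    }
    nseq <- nrow(mat); width <- ncol(mat)
    anchorOverrides <- as.integer(anchorOverrides)
    if (length(anchorOverrides) &&
        (any(anchorOverrides < 1L) || any(anchorOverrides > width)))
        stop("anchorOverrides outside alignment columns", call. = FALSE)

    profs <- profileColumns(mat)
    distinct <- vapply(profs, function(p) length(p$counts), 1L)
    gap_frac <- vapply(profs, function(p) p$gaps / nseq, 1)
    anchor <- (distinct >= 1L & distinct <= maxDistinctResidues &
               gap_frac <= maxGapFraction)
    anchor[anchorOverrides] <- TRUE
    if (any(anchorOverrides %in% which(distinct == 0L)))
        stop("an all-gap column cannot be forced to anchor status",
             call. = FALSE)
    if (!any(anchor))
        stop(paste("no anchor column under the current thresholds;",
                   "consider raising maxDistinctResidues or maxGapFraction"),
             call. = FALSE)

    first <- min(which(anchor)); last <- max(which(anchor))
    role <- rep("trimmed", width)
    role[first:last] <- ifelse(anchor[first:last], "anchor", "spacer")

    if (similarityExpansion) validateSimilarityGroups(groups)
    elements <- list()
    j <- first
    while (j <= last) {
        if (anchor[j]) {
            residues <- sort(names(profs[[j]]$counts))
            if (similarityExpansion) {
                in_g <- vapply(groups, function(g) any(residues %in% g), NA)
                residues <- sort(unique(c(residues,
                                          unlist(groups[in_g],
                                                 use.names = FALSE))))
            }
            kind <- if (length(residues) == 1L) "literal" else "class"
            elements[[length(elements) + 1L]] <- newElement(kind, residues)
            j <- j + 1L
        } else {
            run <- j
            while (!anchor[run + 1L]) run <- run + 1L   # next anchor exists
            runcols <- j:run
            ## per-sequence residue counts in the run, not column counts:
            per_seq <- rowSums(mat[, runcols, drop = FALSE] != "-")
            lo <- min(per_seq); hi <- max(per_seq)
            if (hi > 0L)
                elements[[length(elements) + 1L]] <-
                    newElement("wildcard", AA_ALPHABET20, min = lo, max = hi)
            j <- run + 1L
        }
    }
    m <- newMotif(name, elements, provenance = sprintf(
        "induced from %d aligned sequences (width %d, maxDistinct=%d, maxGapFraction=%g%s)",
        nseq, width, as.integer(maxDistinctResidues), maxGapFraction,
        if (length(anchorOverrides))
            paste0(", overrides=", paste(anchorOverrides, collapse = ","))
        else ""))
    if (!details) return(m)
    list(motif = m,
         report = data.frame(column = seq_len(width), distinct = distinct,
                             gap_fraction = gap_frac, role = role))
}
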