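## Synthetic proteomes with planted motif instances and a ground-truth
## table, so scanning, collapsing and statistics are testable without any
## external database download.

#' Sample one realization of a motif
#'
#' Realizes a motif as concrete sequence text: each element's repeat count
#' is drawn uniformly from its bounds and each consumed position is drawn
#' uniformly from the element's residue set.  The result is always matched
#' by the motif with a span covering the full sampled text.
#'
#' @param m a [Motif-class].
#' @param seed optional integer seed; when \code{NULL}, the current RNG
#'   stream is used (so callers can manage one seeded stream).
#' @return a character string.
#'
#' @examples
#' sampleMotifInstance(getCuratedMotif("GC14"), seed = 1)  # 14 residues
#'
#' @export
sampleMotifInstance <- function(m, seed = NULL) {
    stopifnot(is(m, "Motif"))
    withSeed(seed, {
        pieces <- vapply(m@elements, function(e) {
            cnt <- if (e$min == e$max) e$min
                   else sample(seq.int(e$min, e$max), 1L)
            if (cnt == 0L) return("")
            paste(sample(e$residues, cnt, replace = TRUE), collapse = "")
        }, "")
        paste(pieces, collapse = "")
    })
}

## Resolve a plants specification (named counts, names being curated keys,
## or a list of Motif objects with a 'count' attribute via list(list(motif,
## count))) into a list of list(motif=, count=).
resolvePlants <- function(plants, motifs = NULL) {
    if (is.null(plants) || length(plants) == 0L) return(list())
    if (is.numeric(plants)) {
        if (is.null(names(plants)))
            stop("'plants' counts must be named by motif", call. = FALSE)
        return(lapply(names(plants), function(k) {
            m <- if (!is.null(motifs) && k %in% names(motifs)) motifs[[k]]
                 else getCuratedMotif(k)
            list(motif = m, count = as.integer(plants[[k]]))
        }))
    }
    stopifnot(is.list(plants))
    lapply(plants, function(p) {
        stopifnot(is(p$motif, "Motif"), p$count >= 0)
        list(motif = p$motif, count = as.integer(p$count))
    })
}

## Uniformly choose a placement of 'len' consecutive positions inside
## 1..L avoiding the already-occupied intervals; NULL when impossible.
chooseOffset <- function(L, len, occupied) {
    if (len > L) return(NULL)
    free <- rep(TRUE, L - len + 1L)
    for (iv in occupied) {
        lo <- max(1L, iv[1] - len + 1L)
        hi <- min(L - len + 1L, iv[2])
        if (lo <= hi) free[lo:hi] <- FALSE
    }
    starts <- which(free)
    if (!length(starts)) return(NULL)
    starts[sample.int(length(starts), 1L)]
}

#' Generate a synthetic proteome with planted motif instances
#'
#' Emits \code{n_seqs} protein sequences of i.i.d. background residues,
#' with motif instances planted at known coordinates, plus a ground-truth
#' table.  Planted instances overwrite background residues (keeping each
#' declared sequence length exact) at uniformly chosen offsets, and never
#' overlap another plant in the same record.  Sequence lengths are drawn
#' as \code{floor + Geometric(mean - floor)}, where the floor is at least
#' the longest planted motif's maximum length plus 2, guaranteeing
#' feasibility.  Identifiers are \code{SYN000001}, \code{SYN000002}, ...
#'
#' The same seed always reproduces byte-identical FASTA and truth files.
#'
#' @param n_seqs number of sequences.
#' @param mean_length target mean sequence length in residues.
#' @param min_length optional explicit length floor (raised automatically
#'   to fit the plants).
#' @param background a [BackgroundModel-class].
#' @param plants named integer vector of instance counts, named by curated
#'   motif key (e.g. \code{c(GC14 = 20, ABA = 10)}), or a list of
#'   \code{list(motif =, count =)} entries for arbitrary motifs.
#' @param motifs optional named list of [Motif-class] objects overriding
#'   the curated registry for plant lookup.
#' @param seed integer seed (required).
#' @param fasta_path,truth_path optional output paths; when given, the
#'   FASTA and the truth TSV are written there.
#'
#' @return list with \code{records} (a [Biostrings::AAStringSet]),
#'   \code{truth} (data.frame: sequence_id, motif_name, start, end,
#'   planted_text) and the generation parameters.
#'
#' @examples
#' fx <- generateFixtureProteome(10, mean_length = 120,
#'                               plants = c(GC14 = 3), seed = 42)
#' nrow(fx$truth)   # 3
#'
#' @export
generateFixtureProteome <- function(n_seqs, mean_length = 400,
                                    min_length = NULL,
                                    background = uniformBackground(),
                                    plants = integer(), motifs = NULL,
                                    seed, fasta_path = NULL,
                                    truth_path = NULL) {
    stopifnot(n_seqs >= 1L, is(background, "BackgroundModel"))
    if (missing(seed) || is.null(seed))
        stop("an explicit 'seed' is required for reproducibility",
             call. = FALSE)
    plant_list <- resolvePlants(plants, motifs)
    max_plant <- if (length(plant_list))
        max(vapply(plant_list, function(p)
            motifLengthBounds(p$motif)[["max"]], 1L)) else 0L
    floor_len <- max(if (is.null(min_length)) 0L else as.integer(min_length),
                     max_plant + 2L, 10L)
    if (mean_length < floor_len)
        mean_length <- floor_len
    result <- withSeed(seed, {
        lengths <- floor_len + stats::rgeom(
            n_seqs, prob = 1 / (mean_length - floor_len + 1))
        seqs <- lapply(lengths, function(L)
            sampleBackgroundChars(L, background))
        ids <- sprintf("SYN%06d", seq_len(n_seqs))
        occupied <- rep(list(list()), n_seqs)
        truth <- list()
        for (p in plant_list) {
            for (k in seq_len(p$count)) {
                inst <- sampleMotifInstance(p$motif)
                len <- nchar(inst)
                placed <- FALSE
                ## uniformly chosen record, re-drawn when the record has no
                ## remaining room for this instance
                for (try in seq_len(50L * n_seqs)) {
                    ri <- sample.int(n_seqs, 1L)
                    off <- chooseOffset(lengths[ri], len, occupied[[ri]])
                    if (!is.null(off)) {
                        seqs[[ri]][off:(off + len - 1L)] <-
                            strsplit(inst, "", fixed = TRUE)[[1]]
                        occupied[[ri]] <- c(occupied[[ri]],
                                            list(c(off, off + len - 1L)))
                        truth[[length(truth) + 1L]] <- data.frame(
                            sequence_id = ids[ri],
                            motif_name = motifName(p$motif),
                            start = off, end = off + len - 1L,
                            planted_text = inst)
                        placed <- TRUE
                        break
                    }
                }
                if (!placed)
                    stop(sprintf(
                        "infeasible planting: no room left for an instance of '%s'",
                        motifName(p$motif)), call. = FALSE)
            }
        }
        truth <- if (length(truth)) do.call(rbind, truth)
                 else data.frame(sequence_id = character(),
                                 motif_name = character(),
                                 start = integer(), end = integer(),
                                 planted_text = character())
        truth <- truth[order(truth$sequence_id, truth$start, truth$end), ,
                       drop = FALSE]
        rownames(truth) <- NULL
        records <- Biostrings::AAStringSet(
            vapply(seqs, paste, "", collapse = ""))
        names(records) <- ids
        list(records = records, truth = truth)
    })
    result$parameters <- list(seed = as.integer(seed), n_seqs = n_seqs,
                              mean_length = mean_length,
                              floor_length = floor_len,
                              background = background@frequency,
                              plants = vapply(plant_list, function(p)
                                  p$count, 1L))
    if (!is.null(fasta_path)) {
        Biostrings::writeXStringSet(result$records, fasta_path)
        result$fasta_path <- fasta_path
    }
    if (!is.null(truth_path)) {
        utils::write.table(result$truth, truth_path, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        result$truth_path <- truth_path
    }
    result
}

#' Splice-isoform fixture for locus collapsing
#'
#' Emits \code{n_isoforms} records named \code{<base_locus>.1} ...
#' \code{<base_locus>.<n>}, each carrying one planted instance of the
#' motif, so [collapseToLoci()] on a scan of these records must report
#' exactly one locus.
#'
#' @param base_locus locus identifier (e.g. \code{"AT1G54130"}).
#' @param n_isoforms number of isoform records (>= 1).
#' @param m a [Motif-class].
#' @param seed integer seed.
#' @param flank number of background residues on either side of the
#'   planted instance.
#' @param background a [BackgroundModel-class].
#' @return list with \code{records} and \code{truth}, as for
#'   [generateFixtureProteome()].
#' @export
makeIsoformFixture <- function(base_locus, n_isoforms, m, seed,
                               flank = 15L,
                               background = uniformBackground()) {
    stopifnot(n_isoforms >= 1L, is(m, "Motif"))
    withSeed(seed, {
        ids <- paste0(base_locus, ".", seq_len(n_isoforms))
        rows <- list()
        seqs <- vapply(seq_len(n_isoforms), function(i) {
            inst <- sampleMotifInstance(m)
            left <- paste(sampleBackgroundChars(flank, background),
                          collapse = "")
            right <- paste(sampleBackgroundChars(flank, background),
                           collapse = "")
            rows[[i]] <<- data.frame(sequence_id = ids[i],
                                     motif_name = motifName(m),
                                     start = flank + 1L,
                                     end = flank + nchar(inst),
                                     planted_text = inst)
            paste0(left, inst, right)
        }, "")
        records <- Biostrings::AAStringSet(seqs)
        names(records) <- ids
        list(records = records, truth = do.call(rbind, rows))
    })
}
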