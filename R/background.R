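## Expected motif occurrences under an i.i.d. residue background — the
## statistical layer for judging whether proteome hits exceed chance,
## i.e. for discriminating true functional centers from false positives.

#' Construct background residue-frequency models
#'
#' \code{uniformBackground} gives every standard residue probability 1/20.
#' \code{backgroundModel} builds a model from a named probability vector.
#' \code{backgroundFromSequences} estimates frequencies from observed
#' protein sequences (non-standard characters ignored).
#' \code{readBackgroundTsv}/\code{writeBackgroundTsv} exchange the model as
#' a two-column TSV (\code{residue}, \code{frequency}).
#'
#' @param frequency named numeric vector of residue probabilities (names
#'   are one-letter codes; must sum to 1).
#' @param records a [Biostrings::AAStringSet] or character vector of
#'   protein sequences.
#' @param b a [BackgroundModel-class].
#' @param path TSV file path.
#'
#' @return a [BackgroundModel-class] (writers: the path, invisibly).
#'
#' @examples
#' b <- uniformBackground()
#' setProbability(c("K", "R"), b)   # 0.1
#'
#' @export
uniformBackground <- function() {
    backgroundModel(stats::setNames(rep(1 / 20, 20), AA_ALPHABET20))
}

#' @rdname uniformBackground
#' @export
backgroundModel <- function(frequency) {
    new("BackgroundModel", frequency = frequency)
}

#' @rdname uniformBackground
#' @export
backgroundFromSequences <- function(records) {
    chars <- strsplit(toupper(paste(as.character(records), collapse = "")),
                      "", fixed = TRUE)[[1]]
    chars <- chars[chars %in% AA_ALPHABET20]
    if (!length(chars))
        stop("no standard residues in input", call. = FALSE)
    counts <- table(factor(chars, levels = AA_ALPHABET20))
    backgroundModel(stats::setNames(as.numeric(counts) / sum(counts),
                                    AA_ALPHABET20))
}

#' @rdname uniformBackground
#' @export
backgroundFrequencies <- function(b) {
    stopifnot(is(b, "BackgroundModel"))
    b@frequency
}

#' @rdname uniformBackground
#' @export
readBackgroundTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("residue", "frequency") %in% colnames(df)))
        stop("background TSV must have columns 'residue' and 'frequency'",
             call. = FALSE)
    backgroundModel(stats::setNames(as.numeric(df$frequency),
                                    toupper(df$residue)))
}

#' @rdname uniformBackground
#' @export
writeBackgroundTsv <- function(b, path) {
    stopifnot(is(b, "BackgroundModel"))
    utils::write.table(
        data.frame(residue = names(b@frequency), frequency = b@frequency),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

setMethod("show", "BackgroundModel", function(object) {
    f <- object@frequency
    cat(sprintf("BackgroundModel over %d residues", length(f)))
    if (length(unique(round(f, 12))) == 1L) cat(" (uniform)")
    cat("\n")
    print(round(f, 4))
    invisible(NULL)
})

#' Probability that a background residue falls in a residue set
#'
#' @param s character vector of one-letter codes (or a motif element).
#' @param b a [BackgroundModel-class].
#' @return the summed frequency of the set's members.
#' @export
setProbability <- function(s, b) {
    stopifnot(is(b, "BackgroundModel"))
    if (is.list(s)) s <- s$residues
    s <- unique(toupper(as.character(s)))
    sum(b@frequency[names(b@frequency) %in% s])
}

## One row per repeat-count assignment (composition): total length and
## the product of per-position set probabilities.
compositionTable <- function(m, b) {
    stopifnot(is(m, "Motif"), is(b, "BackgroundModel"))
    probs <- vapply(m@elements, function(e) setProbability(e$residues, b), 1)
    ranges <- lapply(m@elements, function(e) seq.int(e$min, e$max))
    grid <- do.call(expand.grid, c(ranges, KEEP.OUT.ATTRS = FALSE))
    len <- as.integer(rowSums(grid))
    prod <- apply(grid, 1L, function(cnt) prod(probs ^ cnt))
    data.frame(length = len, probability = prod)
}

#' Expected motif occurrences under an i.i.d. background
#'
#' \code{compositionExpectation} is the expected number of
#' composition-level matches beginning at one position: the sum over all
#' repeat-count assignments (compositions) of the product, over consumed
#' positions, of the governing element's set probability.  For a
#' fixed-length motif this equals the probability that a match starts at
#' the position; for motifs with flexible spacers it upper-bounds the
#' probability that at least one span begins there (overlapping
#' compositions are counted separately, by linearity).
#'
#' \code{expectedHits} extends this over a sequence of given length,
#' weighting each composition by its number of valid start positions.
#'
#' \code{monteCarloHits} estimates the mean number of distinct
#' (start, end) spans per sequence by simulation, the quantity the exact
#' composition-level formula upper-bounds for flexible motifs.
#'
#' @param m a [Motif-class].
#' @param b a [BackgroundModel-class].
#' @param seq_length sequence length in residues.
#' @param replicates number of simulated sequences.
#' @param seed integer seed (required; all randomness flows through it).
#'
#' @return \code{compositionExpectation}, \code{expectedHits}: a single
#'   number.  \code{monteCarloHits}: list with \code{mean}, \code{se}
#'   (standard error of the mean), \code{replicates}, \code{seed}.
#'
#' @examples
#' b <- uniformBackground()
#' compositionExpectation(getCuratedMotif("GC14"), b)  # 3888 / 20^9
#' expectedHits(parseMotif("[KR]", "kr"), b, 100)      # 10
#'
#' @export
compositionExpectation <- function(m, b) {
    sum(compositionTable(m, b)$probability)
}

#' @rdname compositionExpectation
#' @export
expectedHits <- function(m, b, seq_length) {
    stopifnot(length(seq_length) == 1L, seq_length >= 0)
    ct <- compositionTable(m, b)
    starts <- pmax(seq_length - ct$length + 1, 0)
    sum(starts * ct$probability)
}

## Evaluate 'code' under a temporary RNG state seeded with 'seed',
## restoring the caller's RNG state afterwards.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        } else {
            on.exit(suppressWarnings(rm(".Random.seed",
                                        envir = globalenv())))
        }
        set.seed(as.integer(seed))
    }
    force(code)
}

sampleBackgroundChars <- function(n, b) {
    f <- b@frequency
    sample(names(f), n, replace = TRUE, prob = f)
}

#' @rdname compositionExpectation
#' @export
monteCarloHits <- function(m, b, seq_length, replicates = 1000L, seed) {
    stopifnot(is(m, "Motif"), is(b, "BackgroundModel"), replicates >= 1L)
    if (missing(seed) || is.null(seed))
        stop("an explicit 'seed' is required for reproducibility",
             call. = FALSE)
    counts <- withSeed(seed, {
        vapply(seq_len(replicates), function(i) {
            s <- paste(sampleBackgroundChars(seq_length, b), collapse = "")
            nrow(findMatches(m, s, "mc"))
        }, 1L)
    })
    mu <- mean(counts)
    se <- if (replicates > 1L) stats::sd(counts) / sqrt(replicates) else 0
    list(mean = mu, se = se, replicates = as.integer(replicates),
         seed = as.integer(seed))
}
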