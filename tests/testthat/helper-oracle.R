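## Independent brute-force oracle for motif matching: tests every
## (start, end) window of the sequence by naive recursive element
## consumption.  Shares no code with the package's matcher (which uses a
## regex prefilter + end enumeration).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracleAllowed <- function(e) {
    if (e$kind == "wildcard") c(AA20, "X", "U", "O") else e$residues
}

## can elements[ei..] consume exactly chars[pos..end]?
oracleConsumes <- function(elements, chars, ei, pos, end) {
    if (ei > length(elements)) return(pos == end + 1L)
    e <- elements[[ei]]
    allowed <- oracleAllowed(e)
    for (cnt in e$min:e$max) {
        last <- pos + cnt - 1L
        if (last > end) break                       # overruns the window
        if (cnt > 0L && !all(chars[pos:last] %in% allowed))
            break                                   # longer counts fail too
        if (oracleConsumes(elements, chars, ei + 1L, pos + cnt, end))
            return(TRUE)
    }
    FALSE
}

## all (start, end) spans of m in seq, by exhaustive window testing
oracleSpans <- function(m, seq) {
    chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
    L <- length(chars)
    bounds <- motifLengthBounds(m)
    elements <- motifElements(m)
    out <- list()
    for (s in seq_len(L)) {
        for (e in seq(from = min(s + bounds[["min"]] - 1L, L),
                      to = min(s + bounds[["max"]] - 1L, L))) {
            if (e < s + bounds[["min"]] - 1L) next
            if (oracleConsumes(elements, chars, 1L, s, e))
                out[[length(out) + 1L]] <- c(s, e)
        }
    }
    if (!length(out))
        return(data.frame(start = integer(), end = integer()))
    df <- unique(do.call(rbind, out))
    df <- df[order(df[, 1], df[, 2]), , drop = FALSE]
    data.frame(start = df[, 1], end = df[, 2])
}

spansOf <- function(mdf) data.frame(start = as.integer(mdf$start),
                                    end = as.integer(mdf$end))

## random test-case generators (callers fix the RNG seed)

randomSequence <- function(len, p_unknown = 0.02) {
    pool <- c(AA20, "X")
    probs <- c(rep((1 - p_unknown) / 20, 20), p_unknown)
    paste(sample(pool, len, replace = TRUE, prob = probs), collapse = "")
}

randomSmallMotif <- function(max_elements = 6L, max_repeat = 4L) {
    n <- sample.int(max_elements, 1L)
    elems <- character(n)
    for (i in seq_len(n)) {
        kind <- sample(c("literal", "class", "wildcard"), 1L,
                       prob = c(0.3, 0.4, 0.3))
        core <- switch(kind,
            literal = sample(AA20, 1L),
            class = paste0("[", paste(sample(AA20,
                                             sample(2:4, 1L)),
                                      collapse = ""), "]"),
            wildcard = "X")
        rep_suffix <- ""
        if (stats::runif(1) < 0.4) {
            lo <- sample.int(max_repeat, 1L)
            hi <- if (lo == max_repeat) lo
                  else sample(lo:max_repeat, 1L)
            rep_suffix <- if (lo == hi) sprintf("{%d}", lo)
                          else sprintf("{%d,%d}", lo, hi)
        }
        elems[i] <- paste0(core, rep_suffix)
    }
    parseMotif(paste(elems, collapse = ""), name = "rand")
}

## alignment of sampled motif instances, aligned by construction: each
## element occupies max_repeat columns, short realizations padded with
## gaps on the right of the element block
alignSampledInstances <- function(m, n) {
    elements <- motifElements(m)
    rows <- vapply(seq_len(n), function(i) {
        paste(vapply(elements, function(e) {
            cnt <- if (e$min == e$max) e$min
                   else sample(seq.int(e$min, e$max), 1L)
            txt <- if (cnt == 0L) "" else
                paste(sample(e$residues, cnt, replace = TRUE),
                      collapse = "")
            paste0(txt, strrep("-", e$max - cnt))
        }, ""), collapse = "")
    }, "")
    names(rows) <- sprintf("inst%02d", seq_len(n))
    rows
}
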