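test_that("parsing tokenizes classes, literals, wildcards and repeats", {
    m <- parseMotif("[KR]", "m")
    expect_equal(motifSize(m), 1L)
    expect_setequal(motifElements(m)[[1]]$residues, c("K", "R"))
    expect_equal(motifElements(m)[[1]][c("min", "max")],
                 list(min = 1L, max = 1L))

    gc <- parseMotif("[RKS][YFW][CTGH][VIL][FV]G[DNA]X[VIL]X{4}[KR]", "GC14")
    expect_equal(motifSize(gc), 11L)
    expect_equal(unname(motifLengthBounds(gc)), c(14L, 14L))

    hnox <- parseMotif("HX{12}PX{14,16}YXSXR", "HNOX")
    expect_equal(motifSize(hnox), 9L)
    ## independent arithmetic: 1+12+1+14+1+1+1+1+1 = 33, max swaps 14 -> 16
    expect_equal(unname(motifLengthBounds(hnox)), c(33L, 35L))

    ## both repeat dialects parse to the same structure
    expect_true(motifIdentical(
        parseMotif("[DE]X(7,8)RX(3,4)[DE]X(5)YX(6)H", "aba_paren"),
        parseMotif("[DE]X{7,8}RX{3,4}[DE]X{5}YX{6}H", "aba_brace")))
})

test_that("malformed patterns raise parse errors naming the token", {
    expect_error(parseMotif("[DE]X{4,3}", "m"), "minimum exceeds maximum")
    expect_error(parseMotif("[]", "m"), "empty residue class")
    expect_error(parseMotif("[KB]", "m"), "unknown residue letter")
    expect_error(parseMotif("X{0}", "m"), "at least 1")
    expect_error(parseMotif("X{a}", "m"), "malformed repeat")
    expect_error(parseMotif("[KR", "m"), "dangling")
    expect_error(parseMotif("{2}K", "m"), "no preceding element")
    expect_error(parseMotif("X{2}{3}", "m"), "already carries")
    expect_error(parseMotif("K.R", "m"), "offset 2")
    expect_error(parseMotif("", "m"), "non-empty")
})

test_that("rendering is canonical and round-trips through parsing", {
    expect_equal(renderMotif(parseMotif("[DE]X(7,8)RX(3,4)[DE]X(5)YX(6)H", "m")),
                 "[DE]X{7,8}RX{3,4}[DE]X{5}YX{6}H")
    expect_equal(renderMotif(parseMotif("G", "m")), "G")
    expect_equal(renderMotif(parseMotif("X{1}", "m")), "X")
    expect_equal(renderMotif(parseMotif("X{2,2}", "m")), "X{2}")
    ## class residue order is preserved as curated
    expect_equal(renderMotif(parseMotif("[RKS]", "m")), "[RKS]")

    set.seed(101)
    for (i in 1:40) {
        m <- randomSmallMotif()
        again <- parseMotif(renderMotif(m), "m")
        expect_true(motifIdentical(m, again))
        expect_equal(renderMotif(again), renderMotif(m))  # idempotent
    }
})

test_that("findMatches enumerates exactly the realizable spans", {
    gc <- getCuratedMotif("GC14")
    df <- findMatches(gc, "KYCIFGDAVAAAAK", "p1")
    expect_equal(spansOf(df), data.frame(start = 1L, end = 14L))
    expect_equal(df$matched_seq, "KYCIFGDAVAAAAK")
    expect_equal(df$sequence_id, "p1")

    ## flexible spacer: both gap lengths realize a span from one start
    df <- findMatches(parseMotif("HX{1,2}R", "m"), "HARR")
    expect_equal(spansOf(df),
                 data.frame(start = c(1L, 1L), end = c(3L, 4L)))

    aba <- getCuratedMotif("ABA")
    df <- findMatches(aba, "DAAAAAAARAAADAAAAAYAAAAAAH")
    expect_equal(spansOf(df), data.frame(start = 1L, end = 26L))

    ## first element unsatisfiable
    hnox <- getCuratedMotif("HNOX")
    noH <- strrep("ACDEFGIKLMNPQRSTVWY", 3)
    expect_equal(nrow(findMatches(hnox, noH)), 0L)

    expect_equal(nrow(findMatches(gc, "")), 0L)
})

test_that("sequence character rules are conservative", {
    kr <- parseMotif("[KR]", "m")
    x1 <- parseMotif("X", "m")
    ## unknown residue X matches wildcards only, never classes/literals
    expect_equal(nrow(findMatches(kr, "AXA")), 0L)
    expect_equal(nrow(findMatches(x1, "X")), 1L)
    expect_equal(nrow(findMatches(parseMotif("K", "m"), "X")), 0L)
    ## selenocysteine/pyrrolysine likewise wildcard-only
    expect_equal(nrow(findMatches(kr, "UO")), 0L)
    expect_equal(nrow(findMatches(x1, "U")), 1L)
    ## stops and gaps match nothing, not even wildcards
    expect_equal(nrow(findMatches(x1, "*-")), 0L)
    ## lowercase input is uppercased
    expect_equal(spansOf(findMatches(kr, "akra")),
                 data.frame(start = c(2L, 3L), end = c(2L, 3L)))
    ## out-of-alphabet characters are an input error naming the position
    expect_error(findMatches(kr, "AK1R", "s7"),
                 "'s7'.*'1' at position 3")
})

test_that("matcher agrees with the brute-force oracle on random cases", {
    set.seed(202)
    curated <- lapply(curatedMotifKeys(), getCuratedMotif)
    for (i in 1:30) {
        s <- randomSequence(sample(10:60, 1L))
        for (m in curated)
            expect_equal(spansOf(findMatches(m, s)), oracleSpans(m, s))
    }
    for (i in 1:25) {
        m <- randomSmallMotif()
        for (j in 1:6) {
            s <- randomSequence(sample(5:60, 1L))
            expect_equal(spansOf(findMatches(m, s)), oracleSpans(m, s),
                         info = paste(renderMotif(m), s))
        }
    }
})

test_that("span lengths always lie within the motif's length bounds", {
    set.seed(303)
    for (i in 1:20) {
        m <- randomSmallMotif()
        b <- motifLengthBounds(m)
        df <- findMatches(m, randomSequence(60))
        if (nrow(df)) {
            len <- df$end - df$start + 1L
            expect_true(all(len >= b[["min"]] & len <= b[["max"]]))
        }
    }
})

test_that("enlarging a class never removes spans; shrinking never adds", {
    set.seed(404)
    base <- parseMotif("[KR]X{1,2}[DE]", "m")
    wider <- parseMotif("[KRH]X{1,2}[DEQ]", "m")
    narrower <- parseMotif("KX{1,2}[DE]", "m")
    for (i in 1:25) {
        s <- randomSequence(50)
        sp0 <- spansOf(findMatches(base, s))
        spW <- spansOf(findMatches(wider, s))
        spN <- spansOf(findMatches(narrower, s))
        key <- function(d) paste(d$start, d$end)
        expect_true(all(key(sp0) %in% key(spW)))
        expect_true(all(key(spN) %in% key(sp0)))
    }
})

test_that("a sampled motif instance is matched with a full-cover span", {
    set.seed(505)
    motifs <- c(lapply(curatedMotifKeys(), getCuratedMotif),
                lapply(1:10, function(i) randomSmallMotif()))
    for (m in motifs) {
        inst <- sampleMotifInstance(m)
        df <- findMatches(m, inst)
        expect_true(any(df$start == 1L & df$end == nchar(inst)),
                    info = paste(renderMotif(m), inst))
    }
})
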