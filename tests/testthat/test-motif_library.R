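GC14_STRING <- "[RKS][YFW][CTGH][VIL][FV]G[DNA]X[VIL]X{4}[KR]"

test_that("the curated registry holds the five motifs verbatim", {
    expect_setequal(curatedMotifKeys(),
                    c("GC14", "GC_CORE", "AC14", "HNOX", "ABA"))
    expect_equal(renderMotif(getCuratedMotif("GC14")), GC14_STRING)
    expect_equal(renderMotif(getCuratedMotif("GC_CORE")),
                 "[KS]X[CGS]X{10}[KR]")
    expect_equal(renderMotif(getCuratedMotif("AC14")),
                 "[RKS][YFW][DE][VIL][FV]G[DNA]X[VIL]X{4}[KR]")
    expect_equal(renderMotif(getCuratedMotif("HNOX")),
                 "HX{12}PX{14,16}YXSXR")
    expect_equal(renderMotif(getCuratedMotif("ABA")),
                 "[DE]X{7,8}RX{3,4}[DE]X{5}YX{6}H")
    expect_equal(unname(motifLengthBounds(getCuratedMotif("GC14"))),
                 c(14L, 14L))
    expect_error(getCuratedMotif("NOPE"), "valid keys.*GC14")
})

test_that("curated annotations sit at the documented functional positions", {
    gc <- getCuratedMotif("GC14")
    expect_setequal(names(motifAnnotations(gc)), c("1", "3", "14"))
    expect_match(motifAnnotations(gc)[["1"]], "guanine")
    expect_match(motifAnnotations(gc)[["3"]], "specificity")
    expect_match(motifAnnotations(gc)[["14"]], "phosphate")
    hnox <- motifAnnotations(getCuratedMotif("HNOX"))
    expect_match(hnox[["1"]], "iron")
    expect_match(hnox[["14"]], "steric")
    expect_match(hnox[["29"]], "heme")
    ## AC14 records its derivation from GC14
    expect_match(motifProvenance(getCuratedMotif("AC14")),
                 "derived from 'GC14'")
    ## all five round-trip unchanged through render/parse
    for (k in curatedMotifKeys()) {
        m <- getCuratedMotif(k)
        expect_true(motifIdentical(m, parseMotif(renderMotif(m), k)))
    }
})

test_that("substitutePosition edits exactly the addressed residue position", {
    gc <- getCuratedMotif("GC14")
    ac <- substitutePosition(gc, 3, c("D", "E"), name = "AC14")
    expect_true(motifIdentical(ac, getCuratedMotif("AC14")))
    ## identity substitution preserves structure; source is unchanged
    expect_true(motifIdentical(substitutePosition(gc, 3, c("C", "T", "G", "H")),
                               gc))
    expect_equal(renderMotif(gc), GC14_STRING)
    ## positions 10-13 fall inside the X{4} spacer
    expect_error(substitutePosition(gc, 10, "A"),
                 "single-residue positions are substitutable")
    expect_error(substitutePosition(gc, 15, "A"), "exceeds")
    expect_error(substitutePosition(gc, 3, character()), "non-empty")
    ## position 14 addresses the final class, past the spacer
    m14 <- substitutePosition(gc, 14, "K")
    expect_equal(renderMotif(m14),
                 "[RKS][YFW][CTGH][VIL][FV]G[DNA]X[VIL]X{4}K")
})

test_that("similarity expansion relaxes a position to its groups' union", {
    core <- getCuratedMotif("GC_CORE")
    ## C, G, S all sit in the 'small' group {G,A,S,T,C}
    relaxed <- expandPositionBySimilarity(core, 3)
    expect_setequal(motifElements(relaxed)[[3]]$residues,
                    c("C", "G", "S", "A", "T"))
    ## original members keep curated order; additions are appended
    expect_equal(renderMotif(relaxed), "[KS]X[CGSAT]X{10}[KR]")
    ## a class already equal to its union is a fixed point
    expect_true(motifIdentical(expandPositionBySimilarity(relaxed, 3),
                               relaxed))
    ## result is always a superset: matching is never reduced
    set.seed(77)
    for (i in 1:10) {
        s <- randomSequence(60)
        k0 <- paste(findMatches(core, s)$start, findMatches(core, s)$end)
        k1 <- paste(findMatches(relaxed, s)$start,
                    findMatches(relaxed, s)$end)
        expect_true(all(k0 %in% k1))
    }
})

test_that("the relaxed NO-regulated GC recipe admits serine at position 3", {
    gc <- getCuratedMotif("GC14")
    ## as an explicit substitution of the printed class plus serine
    relaxed <- substitutePosition(gc, 3, c("C", "T", "G", "H", "S"),
                                  name = "GC14_relaxed")
    expect_equal(renderMotif(relaxed),
                 "[RKS][YFW][CTGHS][VIL][FV]G[DNA]X[VIL]X{4}[KR]")
    ## or via similarity groups that place serine with the thiol/small set
    groups <- list(g1 = c("C", "T", "G", "H", "S"),
                   rest = setdiff(AA20, c("C", "T", "G", "H", "S")))
    expanded <- expandPositionBySimilarity(gc, 3, groups = groups)
    expect_setequal(motifElements(expanded)[[3]]$residues,
                    c("C", "T", "G", "H", "S"))
    expect_true(motifOccurs(relaxed, "KYSIFGDAVAAAAK"))
    expect_false(motifOccurs(gc, "KYSIFGDAVAAAAK"))
})

test_that("restrictPosition narrows a class and rejects new residues", {
    gc <- getCuratedMotif("GC14")
    r <- restrictPosition(gc, 1, "K")
    expect_equal(renderMotif(r), sub("\\[RKS\\]", "K", GC14_STRING))
    expect_true(motifOccurs(r, "KYCIFGDAVAAAAK"))
    expect_false(motifOccurs(r, "RYCIFGDAVAAAAK"))
    expect_true(motifOccurs(gc, "RYCIFGDAVAAAAK"))
    ## restriction to the current full set is the identity
    expect_true(motifIdentical(restrictPosition(gc, 1, c("R", "K", "S")), gc))
    ## cannot introduce residues: {C} is not a subset of {D,E}
    expect_error(restrictPosition(getCuratedMotif("AC14"), 3, "C"),
                 "cannot introduce residues")
})

test_that("GC and AC motifs are disjoint at the substrate position", {
    gc <- getCuratedMotif("GC14")
    ac <- getCuratedMotif("AC14")
    expect_true(motifOccurs(gc, "KYCIFGDAVAAAAK"))
    expect_false(motifOccurs(ac, "KYCIFGDAVAAAAK"))
    expect_true(motifOccurs(ac, "KYDIFGDAVAAAAK"))
    expect_false(motifOccurs(gc, "KYDIFGDAVAAAAK"))
})

test_that("similarity groups must partition the alphabet", {
    bad <- defaultSimilarityGroups()
    bad$positive <- c(bad$positive, "D")         # overlap with 'negative'
    expect_error(expandPositionBySimilarity(getCuratedMotif("GC14"), 1,
                                            groups = bad), "disjoint")
    short <- defaultSimilarityGroups()
    short$proline <- NULL
    expect_error(expandPositionBySimilarity(getCuratedMotif("GC14"), 1,
                                            groups = short), "cover")
    expect_silent(validObject(getCuratedMotif("GC14")))
})

test_that("the registry exports to JSON and imports back unchanged", {
    path <- withr::local_tempfile(fileext = ".json")
    exportMotifRegistry(path)
    back <- importMotifRegistry(path)
    expect_setequal(names(back), curatedMotifKeys())
    for (k in names(back)) {
        expect_true(motifIdentical(back[[k]], getCuratedMotif(k)))
        expect_equal(motifAnnotations(back[[k]]),
                     motifAnnotations(getCuratedMotif(k)))
    }
})
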