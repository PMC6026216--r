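# centerscan

Motif-based discovery of hidden functional centers in multi-domain plant
proteins.

## The problem

Plant genomes encode few orthologues of the guanylate cyclases (GCs),
adenylate cyclases (ACs), gaseous-signal sensors and hormone receptors known
from animals, fungi and bacteria — yet cGMP, cAMP, NO responses and
ABA-modulated activities are all well documented in plants. A resolution is
that the responsible *functional centers* — short catalytic or
ligand-binding regions, smaller than a regular domain — sit embedded inside
large multi-domain proteins (kinases, receptors, ion channels) where
homology searches cannot see them.

centerscan implements the motif-based search strategy for such centers:

1. **Express the center as a degenerate amino-acid motif** built only from
   the residues that perform the molecular function. The pattern language
   has literals (`G`), residue classes (`[RKS]`) and bounded wildcard
   spacers (`X`, `X{4}`, `X{14,16}`) — PatMatch-style syntax. Both
   `{n,m}` and `(n,m)` repeat delimiters are accepted.
2. **Rationally tighten or relax the motif** — substitute a position
   (e.g. the substrate-specificity class `[CTGH] → [DE]` converts the GC
   motif into an AC motif), expand a class by size/charge similarity
   groups, or restrict it to fewer residues.
3. **Induce a motif from an alignment** of annotated functional centers:
   conserved columns become residue classes, variable runs become bounded
   spacers.
4. **Scan a proteome**, enumerate *all* occurrences (including overlapping
   spans and multiple spacer lengths per start), collapse splice isoforms
   to gene loci, and apply exclusion lists — the bookkeeping behind
   candidate screens such as "25 new candidates excluding their spliced
   variants".
5. **Judge hit counts against chance** with exact expected-occurrence
   statistics under an i.i.d. residue background, plus Monte Carlo
   estimates of distinct-span counts.

A synthetic-proteome generator with planted motif instances provides ground
truth, so the entire workflow is testable without downloading any external
database.

## Curated motifs

| key | motif | center |
|-----|-------|--------|
| `GC14` | `[RKS][YFW][CTGH][VIL][FV]G[DNA]X[VIL]X{4}[KR]` | guanylate-cyclase catalytic center (14 aa) |
| `GC_CORE` | `[KS]X[CGS]X{10}[KR]` | relaxed GC core (conserved functional residues only) |
| `AC14` | `[RKS][YFW][DE][VIL][FV]G[DNA]X[VIL]X{4}[KR]` | adenylate-cyclase center, derived from GC14 by the position-3 substitution |
| `HNOX` | `HX{12}PX{14,16}YXSXR` | H-NOX heme-based NO sensing center |
| `ABA` | `[DE]X{7,8}RX{3,4}[DE]X{5}YX{6}H` | abscisic-acid modulatory site (receptor latch region) |

Each motif carries per-position functional annotations (e.g. GC14 position
1 hydrogen-bonds the guanine of GTP, position 3 confers GTP-vs-ATP
specificity, position 14 binds the phosphate acyl group).

## Worked example

```r
library(centerscan)

gc <- getCuratedMotif("GC14")
gc
#> Motif 'GC14': [RKS][YFW][CTGH][VIL][FV]G[DNA]X[VIL]X{4}[KR]
#>   11 elements, match length 14 residues
#>   position 1: forms hydrogen bonds with the guanine of the substrate GTP
#>   position 3: confers substrate specificity for GTP over ATP
#>   position 14: binds the phosphate acyl group and stabilizes the GTP-to-cGMP transition

findMatches(gc, "MTSKYCIFGDAVAAAAKLWQ", "AtGC1_fragment")
#> DataFrame with 1 row and 5 columns
#>      sequence_id     start       end    matched_seq       motif
#> 1 AtGC1_fragment         4        17 KYCIFGDAVAAAAK        GC14
```

The span runs from residue 4 to 17, 1-based and inclusive at both ends —
the same convention in which a center is reported as sitting at, say,
positions S5–K18 of a protein.

How often would this motif occur by chance? Under a uniform residue
background the per-start match probability is the product of the class
sizes over 20 per constrained position (wildcards contribute factor 1):

```r
b <- uniformBackground()
compositionExpectation(gc, b)
#> [1] 7.59375e-09         # = 3888 / 20^9
expectedHits(gc, b, 500)
#> [1] 3.698156e-06        # expected spans in one 500-residue protein
```

So even one GC14 hit in a proteome-sized search is far above background —
the statistical basis for treating hits as candidates rather than noise.

A full synthetic screen, end to end:

```r
fx <- generateFixtureProteome(100, mean_length = 400,
                              plants = c(GC14 = 10, ABA = 5), seed = 42)
ht <- scanProteome(getCuratedMotif("ABA"), fx$records)
hitCount(ht)                 #> 5   (all 5 planted ABA sites recovered)
collapseToLoci(ht)$count     #> 5   distinct candidate loci
```

A thin command-line front end wraps the same functions
(`inst/scripts/centerscan.R`): subcommands `list-motifs`, `derive`,
`induce`, `scan`, `stats`, `simulate`.

## Screening a pinned proteome

Candidate counts from proteome screens depend on the exact proteome
release scanned (databases grow and gene models change), so counts such as
"25 new ABA-site candidates" or "four H-NOX candidates" are reproducible
only against a pinned file. The procedure is:

```r
recs <- readProteinFasta("Athaliana_pinned_release.fasta.gz")
ht   <- scanProteome(getCuratedMotif("ABA"), recs)
col  <- collapseToLoci(ht)                     # splice isoforms -> loci
res  <- applyExclusions(col, "known_baits.txt")  # e.g. GORK, PYL8, PYL10
res$count
```

`scanProvenance(ht)` records the proteome path and an md5 content digest so
a reported count is tied to the exact file scanned.

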