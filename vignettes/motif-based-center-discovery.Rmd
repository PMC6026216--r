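---
title: "Motif-based discovery of functional centers: methods and design"
author: "centerscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based discovery of functional centers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centerscan)
```

# The method and its assumptions

Functional centers — catalytic sites, ligand-binding pockets, interaction
surfaces smaller than a regular domain — can hide inside large multi-domain
proteins where whole-sequence homology search does not reach them. The
motif-based strategy implemented here rests on one biological assumption:
residues that directly perform a molecular function are conserved across
species, while intermediary and flanking residues are free to drift,
because many residue combinations fold equivalently. A search motif
therefore encodes *only* the functional residues, as residue classes, and
abstracts everything between them into bounded wildcard spacers.

The workflow is: align known centers, read off conserved columns as
classes and variable runs as spacers (`induceMotif`), optionally tighten
or relax positions rationally (`substitutePosition`,
`expandPositionBySimilarity`, `restrictPosition`), scan a proteome
(`scanProteome`), collapse splice isoforms and apply exclusion lists
(`collapseToLoci`, `applyExclusions`), and compare observed counts with
what an i.i.d. background would produce (`expectedHits`,
`monteCarloHits`).

# The pattern language and matching semantics

A motif is an ordered list of elements: literals (`G`), classes (`[RKS]`)
and wildcards (`X`), each with repeat bounds written `{n}` or `{n,m}`.
Because published motif strings occur in two dialects, the parser accepts
both brace and parenthesis repeat delimiters; canonical output always uses
braces. Coordinates everywhere are 1-based and inclusive at both ends,
matching the convention in which a center is reported as spanning, say,
positions S5–K18 of a protein.

Matching choices that the motif notation itself does not pin down were
resolved as follows, always in the conservative direction:

* **All spans are reported.** A flexible spacer can realize several ends
  from one start, and spans may overlap; candidate discovery must not
  silently drop occurrences, so `findMatches` enumerates every distinct
  `(start, end)` pair and de-duplicates spans realizable by more than one
  repeat assignment.
* **Unknown residues never satisfy a class.** A sequence `X` (and the rare
  letters `U`, `O`) matches only wildcard elements: a class asserts residue
  identity that an undetermined position cannot confirm. Stops (`*`) and
  gaps (`-`) match nothing. Lowercase input is uppercased.
* **No mismatch tolerance, no negated classes.** The curated motifs use
  neither, and adding them would change the statistics silently.
* **Repeat bounds are allowed on any element kind** (not only `X`), and a
  spacer minimum of 0 is representable (`X{0,2}`) so that induction from
  gapped alignments is closed under its own rule; the motif as a whole
  must still consume at least one residue.

The matcher locates candidate starts with a zero-width-lookahead PCRE
regex (the regex engine handles the bounded-repeat backtracking), then
enumerates all end positions at each start by recursive element
consumption. The test suite checks this two-stage implementation against
an independent single-stage brute-force oracle that tests every window by
recursion, on the curated motifs and on randomly generated small motifs.

# The curated registry

Five motifs ship with per-position functional annotations: the 14-residue
guanylate-cyclase catalytic-center motif `GC14`, its relaxed core
`GC_CORE`, the adenylate-cyclase motif `AC14`, the H-NOX NO-sensing motif
`HNOX` and the abscisic-acid modulatory-site motif `ABA`. `AC14` is not
stored as a string: it is materialized at registry build time by applying
`substitutePosition(GC14, 3, c("D","E"))`, so the derivation rule itself
is exercised whenever the registry loads. The class at GC14 position 3 is
stored as `{C,T,G,H}` in that order; orderings of the same set in
different printed contexts are treated as presentational.

"Position *k*" counts residue positions along a minimal-length match
(GC14 positions 1–9 map to elements 1–9, 10–13 fall inside the `X{4}`
spacer, 14 is the final class). Substitution inside a spacer is rejected
rather than guessed: there is no principled way to address one residue of
a variable-length run.

The relaxed NO-regulated GC motif is described in the literature only as
"a serine added at position 3"; since no full string is printed, it is
provided as a derivation recipe
(`substitutePosition(gc, 3, c("C","T","G","H","S"))`) rather than as a
sixth registry entry.

## Similarity groups

Relaxation "by residues of similar size and charge" needs a concrete
partition, which no source quantifies. The default —
positive `{K,R,H}`, negative `{D,E}`, amide `{N,Q}`, small `{G,A,S,T,C}`,
aliphatic `{V,I,L,M}`, aromatic `{F,Y,W}`, proline `{P}` — is a coarse
standard physicochemical grouping; it is a configuration value, validated
to be a disjoint cover of the alphabet, and any alternative partition can
be supplied.

# Motif induction

`induceMotif` operationalizes "highly conserved" — which no source
quantifies — as: a column anchors when it shows at most
`maxDistinctResidues` distinct residues (default 3, matching the 1–4
residue class sizes of the curated motifs) and at most `maxGapFraction`
gaps (default 0.1). `anchorOverrides` forces columns with annotated
molecular function to anchor regardless of the arithmetic, reflecting that
functional annotation, not conservation alone, is the primary criterion.

Spacer bounds come from *per-sequence* residue counts across a non-anchor
run, not from column counts, so gapped alignments yield `X{n,m}` ranges
exactly like the published flexible spacers. Runs whose maximum is 0
vanish; columns before the first and after the last anchor are trimmed, so
induced motifs begin and end on functional residues like every curated
motif. Note that the induction operation consumes the alignment itself
rather than column profiles alone, precisely because per-sequence run
lengths are not recoverable from column marginals.

With `maxGapFraction = 0`, every ungapped input row provably matches the
induced motif (anchors are then gap-free, so each row's residue at each
anchor is in the observed class, and each row's run length is within the
observed bounds). The default 0.1 deliberately trades this closure
guarantee for robustness: a single gapped row in an otherwise conserved
column should not demote it to spacer status. Induction is deterministic:
identical input and configuration always give identical motifs.

# Occurrence statistics

Expected counts are defined at *composition* level: a composition is one
assignment of repeat counts to the motif's elements. The per-start
expectation is the sum over compositions of the product of per-position
class probabilities; for a sequence of length $L$, each composition of
length $\ell$ contributes $(L-\ell+1)^+$ starts. For a fixed-length motif
this is exact. For flexible motifs, overlapping compositions are counted
separately, so the linear formula upper-bounds the expected number of
*distinct* spans; the distinct-span quantity is provided honestly by Monte
Carlo (`monteCarloHits`) instead of by an intractable inclusion–exclusion.
The test suite verifies exactness by exhaustively enumerating all
sequences over a two-letter reduced alphabet up to length 12 and comparing
the average match count with the formula.

The default background is uniform (1/20 per residue); a model estimated
from any proteome (`backgroundFromSequences`) or read from a TSV can be
substituted. No scoring function beyond occurrence statistics is
provided: proposals to score candidates by topological or physicochemical
parameters remain undefined in the source literature, and inventing one
here would be presented as fact.

# Synthetic data

`generateFixtureProteome` emulates the null situation the statistics
describe: sequences of i.i.d. background residues, with motif instances
planted at known coordinates. Instances *overwrite* background residues
rather than inserting, so declared lengths stay exact; plants never
overlap within a record; offsets are uniform over feasible positions, and
infeasible requests fail before any file is written. Sequence lengths are
drawn as `floor + Geometric(mean − floor)` with the floor at least the
longest planted motif plus 2 — a skewed, long-tailed law loosely shaped
like real protein-length distributions, and fully documented so a seed
reproduces files byte for byte.

What the generator does *not* emulate: residue autocorrelation, domain
architecture, low-complexity regions, paralog families and evolutionary
divergence of planted instances (every instance is sampled fresh from the
motif, not mutated from an ancestor). Passing recall/precision tests on
synthetic proteomes therefore demonstrates correctness of the matcher and
bookkeeping, not biological sensitivity on real proteomes.

`makeIsoformFixture` produces `locus.1 … locus.n` records each carrying
one planted instance, giving locus-collapsing a known truth
(`count == 1`).

# Reproducibility of published candidate counts

Counts such as "25 new ABA-site candidates" or "four H-NOX candidates"
were obtained against specific (unstated) proteome releases and cannot be
reproduced without the pinned file. The package therefore asserts only
the in-package behaviours — AGI-style identifier collapsing
(`AT1G54130.1/.2` → one locus), case-insensitive exclusion matching
(`At1g54130` vs `AT1G54130`) — and records a content digest in every
`HitTable` so that counts against a pinned file are attributable. Both
screening modes (all isoforms, or representative gene models only) are
supported since the original choice is not stated.

# Problem sizes and tolerances

The shipped checks use sizes chosen to exercise every code path while
staying quick on a laptop: oracle equivalence on 200 random sequences
(length ≤ 60) against the 5 curated plus 50 random motifs; planted-motif
recall on a 500-sequence proteome with 20 instances per curated motif;
Monte Carlo calibration with 2000 replicates checked within four standard
errors of the closed form; exact-arithmetic assertions at relative
tolerance 1e-12. Larger simulations change none of the logic and can be
run through the same functions.

# Known limitations

* Matching is exact-membership only; degenerate biological reality
  (conservative substitutions at functional positions) must be expressed
  in the motif, not absorbed by a mismatch tolerance.
* The background model is i.i.d.; real proteomes have compositional
  autocorrelation, so expected counts are a guide, not a test statistic.
* Induction requires a trustworthy alignment; it does not compute one,
  and does not weight sequences phylogenetically, so redundant taxon
  sampling biases anchor classes.
* The pattern language deliberately excludes PROSITE extensions
  (anchors `<`/`>`, negated classes) and nucleotide alphabets.
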