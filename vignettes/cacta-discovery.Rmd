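---
title: "TIR-anchored discovery of CACTA transposons: methods and design"
author: "CactaScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TIR-anchored discovery of CACTA transposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CactaScan)
```

## The problem and the model

CACTA (En/Spm) transposons are plant DNA transposons bounded by terminal
inverted repeats (TIRs) whose extreme termini begin with the conserved
CACTA pentanucleotide, and whose insertion duplicates a 3-nt host
trinucleotide on both flanks (the target-site duplication, TSD). Most
family members are nonautonomous — they carry no transposase and their
internal sequence is largely captured host DNA — so homology search against
the element body finds almost nothing. What is conserved is the *geometry*:
two inward-facing TIRs at a plausible distance, bracketed by identical
trinucleotides. CactaScan implements discovery from that geometry alone:

1. **Seed scan** (`scanSeeds()`): every position on both strands of every
   contig where a short degenerate motif — by default the 12-nt TIR
   terminus `CACTACTNGAAA` — matches within a substitution budget. The
   degenerate position 8 lets a single query find both TIR variants of a
   family; the base observed there tags each occurrence as A-type or
   B-type.
2. **Extension** (`extendToTir()`): each seed hit is extended inward to a
   uniform 28-nt TIR occurrence (the 12-nt terminus plus 16 nt into the
   element), and the trinucleotide immediately *outside* the TIR is read
   as the putative TSD. Hits too close to a contig edge, or whose TIR or
   TSD contains an N, are set aside with an explicit reason.
3. **Pair calling** (`callElements()`): a left-orientation occurrence
   upstream of a right-orientation occurrence on the same contig becomes a
   candidate element when the TIR-inclusive span lies within
   [`minSpan`, `maxSpan`] (default 1,000–30,000 nt) and the two flanking
   trinucleotides are identical. Cross-contig pairing never happens.

Downstream, `tirAbundance()` profiles TIR-sequence redundancy (all genomic
copies vs copies confirmed as a terminus of a call), `tsdFrequency()`
tallies the TSD spectrum over all 64 trinucleotides, and
`annotationOverlap()` compares call sets against prior repeat annotations.

## Matching semantics and numerical choices

* **Substitution-only matching.** Seed matching is IUPAC-aware and
  ungapped. A BLAST-style search with permissive word size admits gapped
  hits too; we deliberately exclude indels because the fixed-length
  extension to 28 nt presumes an ungapped register, and because exact
  semantics make the scanner testable against a sliding-window oracle.
  `maxMismatches` (default 0) recovers degenerate family members.
* **N handling.** An N in the genome never matches any motif code — not
  even motif N — and a TIR or TSD containing N is excluded from calling:
  TSD identity is an exact test and cannot be verified on ambiguous bases.
* **Coordinates.** Internally everything is a `GRanges` (1-based
  inclusive). GFF3 output is 1-based inclusive, BED 0-based half-open;
  a printed coordinate pair such as 18,848,559–18,852,487 therefore has
  length `end − start + 1` = 3,929 (`intervalLength1Based()`).
* **Span convention.** The element span is TIR-inclusive — first base of
  the left TIR through last base of the right TIR — and the 1–30 kb
  window applies to that span.
* **Pairing conflicts.** Real genomes produce left/right occurrence sets
  with ambiguous pairings (solo TIRs, truncated derivatives, nested
  insertions). No single resolution rule is canonical, so three policies
  are provided: `all` (every valid pair; the enumeration oracle used in
  tests), `nearest` (default: lefts processed left-to-right, each takes
  the closest valid right, every occurrence used at most once — the
  deterministic non-nested common case), and `innermost` (shortest span
  first; favors nested inner elements). `nearest` and `innermost` outputs
  are always subsets of `all`.
* **Ties and determinism.** Family tables sort by total count descending
  with lexicographic tie-break; calls sort by coordinate; every output is
  a total order so files are reproducible byte-for-byte.

## The synthetic genome generator

`generateGenome()` plants known features in i.i.d. random background so
that every discovery claim can be scored against ground truth
(`evaluateRecovery()`):

* **complete** elements: `TSD + [TIR-B + filler + revcomp(TIR-A)] + TSD`,
  the detectable two-TIR geometry;
* **truncated** derivatives: a partial TSD (default: the last 2 of 3
  bases), the 3′ portion of an element including only the right TIR, and a
  full TSD — the one-TIR geometry of a derivative formed by incomplete
  excision, which pair-calling *cannot* detect (these score as
  unmatchable);
* **solo TIRs**: a single TIR with one TSD copy.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `gcContent` | 0.40 | typical composite nuclear GC for Asteraceae-scale plant genomes |
| `spanDistribution` | lognormal, median 5,600 nt, sigma 0.62, truncated to [1,000, 30,000] | reproduces the right-skewed span spectrum of a natural CACTA family in which the mean (~6,800 nt) exceeds the median (~5,600 nt) |
| `tsdWeights` | per-base A = T = 0.3, C = G = 0.2 | AT-rich trinucleotides most frequent, all 64 present — the qualitative TSD spectrum of plant CACTA insertion sites |
| `tirA`, `tirB` | 28-mers differing at seed position 8 and two downstream bases | an imperfect TIR pair distinguished at the degenerate seed position, without asserting any real family's full 28-mers |
| `tirMutationRate` | 0 | mutation-free baseline; raising it degrades recall monotonically at `maxMismatches = 0` |
| `truncatedTsdKeep` | 2 | the partial-TSD geometry observed in a natural one-TIR derivative |

Two generator behaviors deserve emphasis. First, generation is fully
deterministic given the configuration (including its seed) and restores
the caller's RNG state. Second, by default the generator *scrubs*
accidental seed-motif matches that arise by chance in random background or
filler (about one expected exact hit per few hundred kb): any exact hit
whose footprint is not a planted TIR terminus has one base outside
protected regions re-drawn. This makes the ground truth complete — every
exact seed hit in the emitted genome is a planted TIR — so recovery
scores measure the caller, not background luck. Set
`scrubBackground = FALSE` to keep raw background.

What the simulator does *not* emulate: repeat-rich backgrounds, nested
insertions (a stress flag plants none by default), sequence evolution,
captured host-gene fragments with real homology, or assembly artifacts.
Perfect recovery on these genomes therefore demonstrates correctness of
the detector logic, not expected performance on a real 2.4-Gb assembly,
where degenerate TIRs, truncated derivatives, and nesting make pairing
genuinely ambiguous.

```{r pipeline}
cfg <- simulationConfig(
    genomeLength = 100000L, nComplete = 20L, nTruncated = 2L,
    nSoloTir = 3L,
    spanDistribution = list(type = "uniform", min = 1200, max = 3500),
    seed = 42L)
sim <- generateGenome(cfg)
occ <- findTirOccurrences(simGenome(sim))
calls <- callElements(occ)
summarizeElements(calls)
unlist(evaluateRecovery(calls, simTruth(sim)))
```

Decoy features can defeat the default pairing: a solo left TIR upstream of
a complete element steals its right TIR under `nearest` whenever the two
TSD trinucleotides coincide (probability roughly 1/64 per decoy), costing
one true positive and one false positive at once. That failure mode is
inherent to geometry-only discovery, not to this implementation.

## Insertion-locus arithmetic

An insertion allele is summarized by two numbers: the element length and
the length of the extra TSD copy its insertion created
(`insertionAllele()`). The *observed* insertion — what a spanning PCR or
alignment sees relative to the insertion-free allele — is their sum
(`insertionObservedLength()`): a 3,913-nt element with a 3-nt TSD appears
as 3,916 nt; a 1,094-nt truncated derivative with a 2-nt partial TSD as
1,096 nt. A spanning genotyping assay's amplicon is its insertion-free
baseline plus the observed insertion (`ampliconLength()`): baseline 280 nt
gives 4,196 nt and 1,376 nt for those two alleles. `truncationLoss()`
differences observed lengths (3,916 − 1,096 = 2,820 nt); note the
element-only difference is 2,819 nt — the two reconcile only because one
TSD base is part of the observed loss, which is why the function works on
observed lengths and the element-only figure is available separately.
Assays with a primer *inside* the element (presence/absence assays) are
represented as data (`spansInsertionSite = FALSE`) and have no derivable
arithmetic.

`excise()` models somatic excision footprint-free: the element plus
exactly one TSD copy is removed, so `plantElement()` followed by
`excise()` is the identity. Real CACTA excision frequently leaves
footprints; the reversible model is the simplest one consistent with
phenotypic reversion and is flagged as such. A one-TIR derivative with a
partial 5′ TSD has non-identical flanks and is refused as not excisable —
the molecular reason such derivatives are immobile.

## Phenotype statistics

`relativeToReference()` normalizes per-plant measurements to the pooled
mean of all reference plants (multiple reference subgroups are thereby
weighted by size) and reports ratios both unrounded and rounded to 2
decimals. With two reference groups of five plants at means 0.69 and 0.56,
a query group at 1.10 gives 1.76, and the 0.69 group itself 1.10.
Ratios computed from *rounded* published group means can disagree with
published ratios in the second decimal (pooled arithmetic on such inputs
gives 2.35 where 2.34 was printed, 31.06 where 31.01 was printed); the
package documents this reconstruction limit rather than targeting those
values. `pearsonCorrelation()` is the standard product-moment coefficient
with the two-sided t-test on n − 2 degrees of freedom;
`segregationTest()` is Pearson's goodness-of-fit chi-square against
expected class proportions, default 1:1:2 — the ratio expected among
self-progeny of a heterozygote whose both homozygote classes are
distinguishable.

## Problem sizes and verification

The test suite verifies the scanner against a brute-force sliding-window
oracle (10–50 kb sequences, 0–2 mismatches, degenerate motifs), the caller
against exhaustive pair enumeration, conservation laws (confirmed TIR
termini = 2 × calls; TSD counts = calls; 64 TSD categories always),
strand symmetry under reverse complement, perfect recovery on mutation-free
complete-element genomes across 20 seeds, zero calls on truncated-only
genomes, monotone recall degradation with TIR mutation load, and
byte-identical regeneration under a fixed seed. Simulated genomes in the
suite are 30–400 kb with 3–30 planted features; a full
simulate–scan–call–profile–evaluate round on a 100-kb genome with 20
elements runs in a few seconds on one CPU, and the whole suite in well
under a minute. These sizes exercise every code path; scaling to
chromosome-scale FASTA is linear in genome length and bounded by the seed
scan.

## Known limitations

* Indel-containing seed matches are not found; heavily diverged TIRs
  require raising `maxMismatches`, which increases decoy pairings.
* No subterminal-repeat modeling, no autonomous/nonautonomous
  classification, no deconvolution of nested insertions beyond the
  pairing policies.
* One-TIR derivatives are structurally invisible to pair-calling; they
  can only be scored as unmatchable truth.
* The simulator's i.i.d. background understates false-positive rates on
  repeat-rich real genomes.
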