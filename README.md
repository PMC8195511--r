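# CactaScan

Structure-based discovery of CACTA (En/Spm) transposons in genome
assemblies, for researchers annotating plant repeats or tracing individual
mobile-element insertions to phenotypes.

Most CACTA family members are nonautonomous: their internal sequence is
captured host DNA, so homology search against an element body finds almost
nothing. What is conserved is the geometry — two ~28-nt terminal inverted
repeats (TIRs) whose termini begin with the CACTA motif, facing inward at a
plausible distance, bracketed by an identical 3-nt target-site duplication
(TSD). CactaScan turns that geometry into a tested pipeline:

1. `scanSeeds()` — find every match of a degenerate 12-nt seed
   (`CACTACTNGAAA`; position 8 distinguishes the two TIR variants of a
   family) on both strands, IUPAC-aware, substitution-only, with a
   configurable mismatch budget. A genome `N` never matches.
2. `extendToTir()` — extend each hit 16 nt inward to a uniform 28-nt TIR
   occurrence and read the flanking trinucleotide as the putative TSD.
3. `callElements()` — pair a left-orientation TIR with a downstream
   right-orientation TIR on the same contig when the TIR-inclusive span is
   within 1,000–30,000 nt and the two flanking trinucleotides are
   identical; conflicts are resolved by a `nearest` (default), `innermost`,
   or `all` policy.

Around the caller: TIR-family redundancy profiling (`tirAbundance()`:
total vs confirmed copies), the 64-category TSD spectrum
(`tsdFrequency()`), annotation overlap (`annotationOverlap()`), a
deterministic synthetic-genome simulator with planted complete elements,
one-TIR truncated derivatives and solo TIRs plus recovery scoring
(`generateGenome()`, `evaluateRecovery()`), insertion-locus arithmetic
(`insertionObservedLength()`, `ampliconLength()`, `excise()`), and
genotype–phenotype statistics (`relativeToReference()`,
`pearsonCorrelation()`, `segregationTest()`).

GFF3/BED/TSV output follows each format's convention (GFF3 1-based
inclusive, BED 0-based half-open). A thin command-line front end with
`simulate` / `scan` / `call` / `profile` / `evaluate` / `genotype`
subcommands ships in `inst/scripts/cactascan`.

## Worked example

```r
library(CactaScan)

cfg <- simulationConfig(
    genomeLength = 100000L, nComplete = 20L, nTruncated = 2L,
    nSoloTir = 3L,
    spanDistribution = list(type = "uniform", min = 1200, max = 3500),
    seed = 42L)
sim   <- generateGenome(cfg)                 # 100-kb genome, 25 planted features
occ   <- findTirOccurrences(simGenome(sim))  # scan + extend: 45 TIR occurrences
calls <- callElements(occ)                   # pair under the default filters

summarizeElements(calls)
#>   n_elements total_length mean_length median_length
#> 1         20        52204      2610.2        2693.5

unlist(evaluateRecovery(calls, simTruth(sim)))[1:5]
#>    true_positives   false_positives   false_negatives  precision  recall
#>                20                 0                 0          1       1

head(tirAbundance(occ, calls), 2)
#>                   tir_sequence total_count confirmed_count
#> 1 CACTACTAGAAACGGTTGCAAGTCGTAC          24              20
#> 2 CACTACTCGAAACGGTTGCAAGTCGACT          21              20
```

All 20 complete elements are recovered exactly (precision = recall = 1).
The 2 truncated derivatives and 3 solo TIRs are *not* called — a one-TIR
feature is structurally invisible to pair-calling — which is why 24 + 21
TIR occurrences yield only 2 × 20 confirmed copies. The locus arithmetic
works the same way on real alleles: a 3,913-nt element inserted with a
3-nt TSD is observed as a 3,916-nt insertion, and a spanning assay with a
280-nt baseline amplicon predicts 280, 4,196, and 1,376 nt for the
insertion-free, full-length, and truncated (1,094 nt + 2-nt partial TSD)
alleles respectively:

```r
ans1 <- primerAssay("ANS1", 280)
ampliconLength(ans1, insertionAllele(3913, 3))   # 4196
ampliconLength(ans1, insertionAllele(1094, 2))   # 1376
```

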