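---
title: "Pooled mixture sequencing of spontaneous suppressor screens"
author: "poolrevert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled mixture sequencing of spontaneous suppressor screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolrevert)
```

## The experimental design this package models

A temperature-sensitive (ts) mutant of a haploid yeast grows at the
permissive temperature but not at the restrictive one. Plating a large
number of cells at the restrictive temperature selects rare colonies —
revertants — that acquired a spontaneous second-site *suppressor* mutation
compensating the ts defect. Sequencing each revertant individually is
wasteful; instead, genomic DNA of N = 10 revertants of the *same* ts mutant
is mixed in equal amounts and sequenced as one library. Three frequency
strata then separate the signal:

* the original ts mutation is present in every revertant, so its allele
  frequency (af) in the pooled reads is ~100% — a built-in positive
  control (the *anchor*);
* parental-strain background variants are likewise shared by all
  revertants and also sit at ~100%;
* each private suppressor is carried by one genome out of N, so it appears
  at af ~ 1/N = 10%.

Candidate suppressors are the mid-frequency calls; genes (or protein
complexes) hit by at least two independent events across mixtures are the
reported suppressor genes. Ten barcoded mixtures in one sequencing lane
cover 100 revertant genomes while handling only ten libraries.

`poolrevert` implements this whole pipeline at desk scale: a synthetic-data
generator standing in for the wet-lab steps, a read aligner and pooled
variant caller standing in for the production mapping/calling tools, the
frequency classifier and recurrence filter, and the screen-design
calculators that decide whether a screen is worth running at all.

## The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| genome length | 100 kb | toy stand-in for a ~12.5 Mb yeast genome |
| GC fraction | 0.36 | approximate fission-yeast GC content |
| genes | 20, 300–1500 bp | non-overlapping CDSs, random strand |
| N (pool size) | 10 | revertants mixed per library |
| suppressors per revertant | exactly 1 | the protocol's design assumption |
| background variants | 30 | parental polymorphisms, af = 1 |
| reads | paired-end 2×150 bp | insert 400 ± 40 bp |
| coverage | 30× per genome | pooled depth ~300× |
| error rate | 0.002/base | uniform substitution errors, constant Q37 |

Genomes are haploid throughout (the screening protocol works in haploid
derivatives), so there is no heterozygosity anywhere. Because the toy
genome is an i.i.d. base sequence, open reading frames essentially never
occur by chance; `make_annotation()` therefore *writes* a clean ORF (ATG,
sense codons, one terminal stop) into each chosen interval and returns the
patched genome alongside the gene table. All downstream coordinates refer
to that patched reference.

The coverage phrase "30-fold per genome" is read as per pooled genome, so
the pooled depth is N × 30 ≈ 300×; the parameter is exposed so the other
reading (30× total) is equally testable. Each revertant receives its
suppressor at a position distinct from every other planted variant of the
same mixture — each colony is an independent mutational event — while the
same substitution may recur across mixtures, which is exactly the
recurrence the gene-level filter rewards. Insertions can be planted (they
appear in the truth table and lengthen the revertant genome), but the
default effect mix is substitutions only, because the built-in aligner is
ungapped; indel-bearing screens are meant to enter through external SAM
files.

Read names encode the true origin of each fragment (revertant, chromosome,
fragment start). This is metadata for test oracles only; no pipeline stage
reads it.

What the generator does *not* emulate: PCR duplicates, GC bias, quality
decay along the read, indel sequencing errors, repetitive sequence, and
real strain-to-strain structural variation. Passing tests on simulated
screens therefore demonstrate the statistical machinery — frequency
recovery, error control, recurrence logic — not robustness to every
artefact of real libraries.

## Alignment

`map_reads()` is a deliberately minimal seed-and-extend aligner for the
repeat-free toy genome: non-overlapping k-mers (k = 15) of the read and of
its reverse complement are looked up in an exact index; every hit implies
one ungapped candidate placement, scored by Hamming distance over the full
read. A read is placed only if its best placement is unique and has at
most 10% mismatches — ties are dropped rather than randomly placed, so a
repeated region cannot fabricate allele counts. On ≤10 kb instances the
aligner is tested to agree exactly with an exhaustive all-offset Hamming
scan, and on simulator output at the default error rate the mapping rate
exceeds 99%.

Real aligners handle gaps, quality scores and ambiguity; those differences
are acknowledged rather than imitated. Gapped external alignments enter
through plain-text SAM: `read_sam()` consumes primary mapped records and
walks the CIGAR string per operation (M/=/X contribute bases, I/S consume
query, D/N consume reference), so externally aligned indel data still
produce a correct pileup. `pileup()` tallies every aligned base with no
base- or mapping-quality weighting — the simulator emits constant
qualities, and quality-aware calling is out of scope.

## The pooled caller

At each site and for each of the three possible alternative bases the
caller computes the exact binomial upper tail
`P(X >= alt_count), X ~ Binomial(depth, e/3)` — the probability that
uniform sequencing error alone (aggregate rate `e`, spread evenly over the
three wrong bases) produced the observed count. Family-wise error is
controlled by Bonferroni over `3 × genome length` tests; Bonferroni rather
than FDR because it matches the published behaviour of the pooled caller
whose role this module fills, and because it yields a clean, testable
guarantee (expected false calls per null mixture ≤ α). A call is emitted
when the corrected p-value passes α = 0.05 **and** af ≥ 2% **and**
depth ≥ 10. The 2% floor is the protocol's reported selection cutoff; both
filters are required, so an overwhelmingly significant site at af = 1.9%
is still suppressed. `estimate_error_rate()` recovers `e` empirically from
the pileup (non-reference fraction over ≥1000 sites, with called/planted
sites maskable) for data whose error rate is not known a priori.

At the default conditions the arithmetic is comfortable: a private
suppressor at af 0.1 and pooled depth ~300 yields ~30 alternative reads
against an error expectation of 0.2, so detection power exceeds 0.999
(`detection_power()` computes this exactly, marginalising the decision rule
over the Poisson depth distribution, and is tested against Monte-Carlo).

## Classification and recurrence filtering

`classify_calls()` assigns each call to exactly one category. The known ts
locus at af ≥ 0.9 is `anchor_ts`; its absence raises a mixture-integrity
warning (sample mix-up, or a revertant that lost the ts allele). Calls
matching the parental variant list, or any call at af ≥ 0.8, are
`background_common` — 0.8/0.9 rather than 1.0 because binomial sampling at
depth ~300 and sequencing error pull fixed sites slightly below 100%.
Remaining calls at af ≥ 2% are `suppressor_candidate`; there is
deliberately no upper af cap below the background threshold, because k
revertants sharing one suppressor legitimately show af ≈ k/N.

`annotate_effect()` recomputes the affected codon on the coding strand and
names effects the way geneticists write them (`G338D`, `Q64Stop`,
`silent`, `ins(frameshift)`); it is property-tested against an independent
full-CDS translation oracle.

`recurrence_filter()` counts one independent event per (mixture, variant):
identical substitutions in different mixtures are separate colonies and
count separately, while duplicated rows within a mixture collapse (pooled
af alone cannot resolve two revertants of one mixture sharing a variant —
that situation is visible instead as af ≈ k/N, which is why af is carried
into the report). Genes with ≥ 2 events are reported; sub-threshold genes
sharing a protein complex aggregate to a complex-level report only when at
least two distinct genes contribute, since single-gene evidence should not
masquerade as complex-level evidence. The threshold default is 2 — the
two-event gene evidence standard — and is configurable. Units containing
the ts gene are flagged intragenic. Mid-frequency variants recurring at
the same position across mixtures are *not* auto-subtracted as artefacts
(genuinely recurrent suppressors are expected); they carry a
cross-mixture recurrence count for the manual-review step the protocol
prescribes.

## Screen-design calculators

`revertant_frequency()` implements the usable screening window: revertant
frequencies between 1e-8 and 1e-6 (inclusive at both ends) are
`suitable`; below, suppressors tend to be intragenic; above, suppression
tends to be weak. Window endpoints are inclusive because the protocol's
own flagship screen sits at 9.4e-7, just inside. Two of the three
published screens fall slightly above 1e-6 yet were described as ~1e-6;
the verdict is strict, but the report also prints the nearest power of
ten so both readings are visible. `expected_af()`, `lane_multiplex()` and
`detection_power()` complete the feasibility arithmetic.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (VCF/GFF convention); SAM
  POS is consumed as 1-based.
* All randomness flows through explicit integer seeds; the same seed
  reproduces FASTQ output byte-identically. Seeds are restored after each
  generator call, so library code never perturbs the caller's RNG state.
* The binomial tail is computed by `pbinom(lower.tail = FALSE)` and is
  tested to 12 significant digits against values frozen from an exact
  rational-arithmetic summation.
* The Poisson sum in `detection_power()` is truncated at six standard
  deviations of the depth distribution.
* Ambiguous alignments and sub-floor calls are dropped deterministically;
  no tie-breaking randomness exists downstream of read simulation.
* `run_screen()` serialises its config into the run directory and logs
  UTC timestamps; anchor-integrity warnings are non-fatal but surfaced in
  the return value (and as a distinct exit code in the command-line
  wrapper under `inst/cli`).

## Problem sizes used in the tests

The simulated-screen tests run on a 100 kb genome (one mixture of ten
revertants at pooled depth ~300×) — large enough that the Bonferroni
family (3 × 10^5 tests) and the depth distribution behave like the real
screen's, small enough to run comfortably on a laptop. Supporting
property suites use 4–50 kb genomes, 100 null-mixture replicates for the
type-I bound, 2 × 10^4 Monte-Carlo sites per power-grid cell, and ~1300
random substitutions against the translation oracle.

## Limitations

The package is a method model, not a production caller: no BAM/CRAM, no
gapped built-in alignment, no quality recalibration, no diploid
genotyping, no strand-bias tests, and no modelling of the mutagenesis
biology upstream of the screen (fluctuation analysis, mutation spectra).
The recurrence filter reproduces the published selection rule; the final
step of the real protocol — Sanger confirmation and biological follow-up —
is outside any simulation's reach.
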