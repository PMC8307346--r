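---
title: "Comparative mitogenomics with mitocomp: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope

`mitocomp` implements the statistics used to characterize and compare
annotated insect mitochondrial genomes: partition composition and AT/GC
strand skews, codon usage and RSCU under the invertebrate mitochondrial
code, gene overlap/spacer geometry, control-region tandem repeats, per-gene
and sliding-window nucleotide diversity, Kimura 2-parameter (K2P) pairwise
distances, Nei–Gojobori (1986) Ka/Ks, and Bowker matched-pairs symmetry
tests. Annotation itself (tRNA prediction, assembly) and phylogenetic tree
inference are out of scope: the package consumes annotated GenBank records
and per-gene codon-aware alignments and ends at the statistics tables.

A first-class synthetic-data module generates annotated mitogenomes and
evolved alignment sets with known ground truth, so every estimator in the
package is validated by recovery tests that need no external downloads.

## Statistics and their definitions

**Strand skews.** For one strand of a region,
AT skew = (A − T)/(A + T) and GC skew = (G − C)/(G + C). Percentages are
reported to 1 decimal and skews to 2, the conventional display precision
for mitogenome composition tables; a zero denominator yields `NA` rather
than an error. Ambiguity codes are excluded from every denominator.

**Genome partitions.** Composition rows are computed for the full genome;
the concatenated protein-coding genes (PCGs) in coding sense with terminal
stop codons — complete `TAA`/`TAG` or truncated `T`/`TA` remnants — excluded;
the 1st/2nd/3rd codon positions of that concatenation (three rows of equal
size, PCG length / 3); the concatenated tRNAs; the rRNAs; and the control
region. Overlapping genes are counted once per containing feature, matching
the per-gene concatenation convention of the standard tools.

**RSCU.** For codon *c* with count *X~c~* in a synonymous family of size
*k*, RSCU(*c*) = *X~c~* / ((1/*k*) Σ *X*). Families come from NCBI
translation table 5 (invertebrate mitochondrial: AGA/AGG = Ser, AUA = Met,
UGA = Trp), so Ser has 6 codons and Met 2; stop codons are excluded, as is
standard. Counts are pooled over all 13 PCGs, giving one genome-wide
ranking.

**Nucleotide diversity (Pi)** is the mean over all unordered sequence pairs
of (pairwise differences / pairwise usable sites), with pairwise deletion
of gaps and ambiguities. The sliding-window profile uses a 200 bp window
and 20 bp step by default; windows start at position 0 and only full
windows are evaluated.

**K2P distance.** With transition fraction *P* and transversion fraction
*Q* over the usable sites of a pair,
*d* = −½·ln(1 − 2*P* − *Q*) − ¼·ln(1 − 2*Q*). A non-positive logarithm
argument means saturation; the pair is flagged undefined and excluded from
gene means (with the exclusion count reported) rather than silently
clamped.

**NG86 Ka/Ks.** Synonymous site counts per codon come from the single-base
mutational neighborhood, with mutations creating stops excluded from the
denominator; sites are averaged over the two sequences so S + N = 3 ×
codons. Codons differing at 2–3 positions are averaged over all minimal
mutational pathways, discarding pathways through stop codons (if every
pathway hits a stop, all are retained — a rare corner kept explicit so the
brute-force oracle and the implementation agree). The proportions ps =
Sd/S and pn = Nd/N receive the Jukes–Cantor correction −¾·ln(1 − 4p/3),
undefined at p ≥ 0.75. Gene-level ω is the mean of the defined pairwise
ratios (not the ratio of mean Ka to mean Ks); the choice matters for
skewed pair distributions and is stated here because either convention is
defensible.

**Bowker's test.** For a taxon pair, the 4×4 site-pattern count matrix
*n~ij~* over ungapped, unambiguous sites gives
χ² = Σ~i<j~ (n~ij~ − n~ji~)² / (n~ij~ + n~ji~), with degrees of freedom
counting only the unordered base pairs with n~ij~ + n~ji~ > 0 (the SymTest
convention — zero-count pairs are common in short genes); df = 0 yields
p = 1. Rejection indicates violation of stationarity, reversibility or
homogeneity between the two sequences. The comparative pipeline reports the
matrix for the all-positions dataset and for codon positions 1+2, the
contrast that isolates third-position heterogeneity.

## The synthetic-data generator

`synthetic_genome_spec()` defaults describe a typical firefly mitogenome:
A 42.5 / C 13.9 / G 9.4 / T 34.2 (A+T = 76.7%), the canonical 37-gene
insect gene order with 9 PCGs + 14 tRNAs on the majority strand and 4 PCGs
+ 8 tRNAs + 2 rRNAs on the minority strand, seven overlaps of 1–4 bp with
the longest (4 bp) at atp8/atp6 and nad4/nad4l, thirteen spacers totalling
211 bp with the longest (72 bp) between trnW and trnC, and a 1776 bp
control region carrying a 136 bp × 2 repeat and a 171 bp × 2 + 9 bp
repeat. These values are the published characterization of a real firefly
mitogenome, used as the reference condition for all recovery tests.

Design points a user should know:

* **Exact-count pools.** Non-coding partitions draw bases by
  largest-remainder allocation, and PCG bodies draw stop-free codons whose
  sampling probabilities are fixed-point-adjusted so the average positional
  marginal equals the target; a repair pass then swaps single-base codon
  variants to cancel the residual rounding bias. The realized genome-strand
  composition is typically within 0.1 percentage point of target (the
  guaranteed envelope used in tests is 0.5).
* **The composition target applies to the genome strand.** Minority-strand
  genes are built in coding sense against the complement-swapped target, so
  their coding-sense composition mirrors the genome target. Real
  mitogenomes show genuine strand asymmetry in every partition; the
  synthetic genome does not emulate that, and no test should read
  per-partition skews of synthetic data as biology.
* **PCG–PCG overlaps use a shared `ATAA` motif** (one gene's `...A|TAA`
  stop is the other's `ATA|A...` start, reverse-complemented for
  minority-strand pairs), so both reading frames stay valid. Only the
  canonical 4 bp length is supported for PCG–PCG junctions; overlaps
  involving an unconstrained gene (tRNA/rRNA/CR) may take any feasible
  length.
* **Planted repeats are exactly maximal.** A window of ⌊u/10⌋ + 2 bases on
  each flank of a planted repeat block is forced to mismatch the would-be
  consensus continuation (with a composition-preserving swap into the
  unplaced background), so the planted unit length, copy number and span
  are recovered bit-exactly by the scanner rather than extended by chance
  flank matches.
* **Star-tree evolution only.** `evolve_k2p()` mutates every taxon
  independently from the root with the K2P transition-probability matrix at
  branch length *d* (expected pairwise distance 2*d*); `evolve_codons()`
  uses a mutation–acceptance scheme (synonymous always accepted,
  non-synonymous with probability ω, stops rejected). Neither simulates
  tree structure, indels, or among-site rate variation, so passing recovery
  tests demonstrates estimator correctness, not robustness to real-data
  misspecification.

## Numerical choices and degenerate inputs

* Tandem-repeat scan: exhaustive over unit lengths 5–400 bp (control
  regions are ≤ ~2.4 kb, so the exact O(L·u~max~) scan is fast and fully
  deterministic). The consensus is the first copy; successive full blocks
  must match it at ≥ 0.9 identity; the fractional trailing copy counts only
  the exactly matching consensus prefix; hits are canonicalized by trimming
  leading lag-u mismatches; overlapping hits are resolved by longer span,
  then higher identity, then smaller unit. A region shorter than two units
  warns and returns an empty table. Random AT-rich backgrounds do contain
  genuine short tandem repeats; detecting them is correct behavior, which
  is why planted-truth tests match hits by position and unit rather than
  asserting a unique hit.
* Pairwise deletion everywhere (per-site for K2P/Pi/Bowker, per-codon for
  Ka/Ks): complete deletion would shrink short genes like atp8 excessively.
* `evolve_codons()` with ω = 0 keeps the protein literally invariant, yet
  NG86 can attribute a small non-synonymous count to codons hit at two
  sites in different lineages, because pathway averaging splits such
  differences over orders. The recovery tests therefore allow
  max(3·SE, 0.01) around the planted ω — an estimator artifact bound, not a
  loosened target.
* Bowker type-I calibration is checked against a symmetric K2P simulation
  at 8,000 sites and pairwise divergence 0.3, where every off-diagonal
  pattern count is large enough for the chi-square null to be accurate; at
  low divergence the transversion cells hold only a handful of counts and
  the uniformity check would measure the chi-square approximation rather
  than the implementation.
* K2P recovery is asserted within 2 standard errors of the replicate mean
  at 10,000 sites for planted distances 0.05/0.2/0.4.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen as the smallest sizes at which the asymptotic checks are
meaningful: 10,000 sites × 25 replicates for distance recovery, 300 codons
× 4 taxa × 10 replicates per ω for selection recovery, 600 replicates ×
8,000 sites for Bowker calibration, 20 planted-repeat constructions over
units 9–303 bp, and 500 random 30-codon pairs for the NG86
pathway-enumeration oracle.

## Reproducing a published characterization

The package ships the published composition table of the *Cyphonocerus
sanguineus klapperichi* mitogenome (GenBank MW365445) as a regression
fixture: `csk_composition()`. The skew operations reproduce all printed
skew pairs from the printed percentages at 2 decimals:

```{r}
tab <- csk_composition()
all(round(mapply(at_skew, tab$pctA, tab$pctT), 2) == tab$at_skew)
all(round(mapply(gc_skew, tab$pctG, tab$pctC), 2) == tab$gc_skew)
```

Running the full single-genome characterization against the deposited
record itself (genome length 16,443 bp; PCG partition 11,008 bp; UUA-Leu
count 352; control-region repeats 136 bp × 2 and 171 bp × 2 + 9 bp)
requires downloading accession MW365445 and placing it at
`inst/paper-data/MW365445.gb`; the corresponding acceptance test documents
the expected values and runs whenever the record is present. The published
PCG row (11,008 bp) is, incidentally, not divisible by 3 while the three
codon-position rows are each 3,669 bp; the package always derives
codon-position partitions from actual codons, so its own tables are
internally consistent.

## Known limitations

* Ka/Ks is NG86 + Jukes–Cantor only; the software used for published
  firefly values is named but not parameterized in the literature, so
  numeric agreement on real data carries a method-choice tolerance
  (maximum-likelihood dN/dS is a non-goal).
* The Bowker module implements the matched-pairs symmetry test only, not
  the Stuart marginal-symmetry or internal-symmetry extensions.
* The GenBank reader trusts the deposited feature table; it does not
  re-annotate, and multi-segment `join` locations other than the
  origin-wrapping form are rejected.
* Tandem-repeat scores are not comparable to Tandem Repeat Finder's
  alignment scores; only the repeat structure (unit, copies, identity) is
  reported.
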