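---
title: "Methods: variant-resolved bisulfite methylation analysis of 35S rDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant-resolved bisulfite methylation analysis of 35S rDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnamethyl)
```

## The problem

Plant 35S rRNA genes occur as thousands of nearly identical tandem copies,
and only a subset is transcribed. When a genome carries several rDNA
sequence variants, some variant families can be epigenetically silenced
while others stay active (nucleolar dominance), and the silencing correlates
with cytosine methylation in a context-specific way: CG and CWG (CAG/CTG)
methylation tracks transcriptional state, while CCG and asymmetric CHH
methylation is largely a property of the individual cytosine's position.

`rdnamethyl` implements the full desk-scale analysis of this system:

1. a synthetic generator for L- and S-type rDNA units, per-molecule
   methylomes and bisulfite/transcriptome reads with a hidden truth table;
2. cytosine context classification (CG / CWG / CCG / CHH with AT-rich
   subtypes) and a conversion-safety calculus for diagnostic SNPs;
3. bisulfite-aware read assignment to ~120 nt ETS2 regions with a strict
   identity filter and variant calling from conversion-safe SNPs only;
4. per-cytosine and whole-read methylation metrics;
5. the D_s-a statistic (silent minus active methylation medians) with
   Mann-Whitney U and Student's t support, and positional-variability
   analysis across biological samples;
6. genome vs transcriptome variant proportions, specific-transcription
   ratios, and in-silico CAPS (MboI/NlaIII) genotyping.

Everything runs on synthetic data, so every stage is testable without
downloads, and estimates can be reconciled against the generating truth.

## The synthetic rDNA unit

A unit is an ordered tiling of elements (coordinates 0-based, half-open; the
plus strand is the G-rich strand of ETS2): the rRNA genes and internal
spacers, ETS1, then an intergenic spacer of seven ~80 bp promoter elements
P1-P7 (each containing exactly one copy of the PolI TIS-core motif
`TATATATRGGG`), five blocks of exact 103 bp R103 repeats, an `(AT)20`
microsatellite (R2), `(CCTTGGG)7` (R7), the R156 satellite (four 156 bp
units, each non-first copy degenerated by 4 substitutions, i.e. ~2.6%
per-copy divergence, within the 5% tolerance of the approximate tandem
annotator), and a 720 bp ETS2 carrying the diagnostic SNPs. Backbone filler
is seeded uniform 50% GC sequence.

Two determinism properties matter and are enforced:

* **Shared backbone.** Every element's filler is generated from a seed
  derived from the element name and the run's reference seed, so all
  haplotypes built under one seed share an identical backbone and differ
  exactly at SNP positions plus the R103b/R103d copy numbers (L: 7 and 4
  copies; S: 3 and 2 — the L/S length polymorphism).
* **Scrubbing.** Accidental occurrences of the TIS motif (and its reverse
  complement), and of GATC/CATG inside ETS2, the R103 monomer and the
  promoter elements, are deterministically mutated away — treating tandem
  monomers as circular so no pattern can arise across head-to-tail
  junctions, and considering every possible SNP allele so the scrub is
  haplotype-independent. A generated unit therefore always contains exactly
  7 TIS motifs, and the designed restriction targets are the only ones in
  the CAPS amplicons, for any seed.

### Diagnostic SNPs

ETS2 carries nine diagnostic positions, all chosen so that no plus-strand
allele is a cytosine — every SNP is fully informative on the G-rich strand
after bisulfite conversion:

| SNP | alleles (plus strand) | separates | safe on minus? |
|-----|----------------------|-----------|----------------|
| snp2, snp4, snp7, snp8 | L: G, S: T | all L from all S | yes (reads C vs A) |
| snp1, snp3, snp5, snp6 | L: A; one S-subvariant: G; other S: T | L from S **and** one S-subvariant each | no (G/A pair reads C/T) |
| nla | La: A; Ls and S: G | La from everything else | no (reads C vs T) |

snp7's L allele completes one of the two GATC (MboI) targets of the 605 bp
ETS2 amplicon; the `nla` G>A transition destroys the single CATG (NlaIII)
target of the 88 bp amplicon in La. The triallelic design of snp1/3/5/6
makes the four S-specific substitutions double as the four subvariant
markers, matching how a small set of homogenized SNVs can both separate the
arrays and resolve subvariants. One additional L/S SNV (snp8) is placed in
region VI so that *every* 120 nt region carries at least one safe L/S
discriminator; without it, reads from that region could never be attributed
to an array.

ETS2 is tiled into six 120 nt regions I-VI. These boundaries are
config-level defaults, not biological claims; the generator emits bisulfite
reads as exact region-aligned windows, i.e. it emulates the mapped,
reference-identical read population that per-cytosine analysis operates on,
not a shotgun library. Transcriptome and genomic amplicon reads are 605 bp
Sanger-clone-like sequences covering all SNPs, so a single read resolves
every subvariant.

## The methylation model

Per molecule and site, methylation is Bernoulli with an effective rate

```
rate = base(context | site) + silent_offset(context) * [variant silent]
       + tissue_offset(context, tissue),  clamped to [0, 1]
```

* **Base rates** (proportions): CG 0.973, CWG 0.880, CCG 0.35, CHH 0.07 —
  the reported ETS2 averages used as generating values.
* **Positional lattices.** CG and CWG are uniform across sites. CCG and
  AT-rich CHH (CAA/CTA/CAT) rates are per-site: each site draws its rate
  from a fixed quantile lattice of a target distribution, assigned to
  positions in a seeded random order. Quantile assignment makes the
  across-site mean equal the target mean by construction (seed-stable),
  while sites differ strongly — the positional effect. The lattice is keyed
  by (strand, position) on a canonical reference defined only by the spec
  and the reference seed, so the same cytosine keeps one generating rate in
  every variant, tissue, lineage and sample.
  * CCG: Beta(1.4, 2.6) rescaled to mean 0.35 (wide spread, mean preserved).
  * AT-rich CHH: a three-component mixture — 3% of sites uniform on
    (0.55, 0.65); 30% uniform on (2e-4, 0.0055); the remainder log-uniform
    on (0.012, 0.24) rescaled so the overall mean is exactly 0.07. The
    component bounds are background-aware: with 99.9% conversion the low
    component *observes* at most ~0.65% methylation and stays below the 1%
    bin edge, and the high component stays safely above 50% at the depths
    used. Non-AT-rich CHH sites use the flat 0.07.
* **Silent offsets** (defaults +0.15 CWG, +0.01 CG, 0 for CCG/CHH) encode
  the finding that silencing raises CWG methylation strongly, CG slightly,
  and leaves CCG/CHH untouched. The CWG offset saturates at the clamp, so
  silent CWG sits near-fully methylated.
* **Tissue offsets** (defaults: root tips -0.04 CWG, seedlings -0.05 CWG)
  encode CWG hypomethylation in rapidly dividing tissues.
* **Chemistry**: conversion efficiency 0.999, inappropriate conversion
  (methylated C read as T) 0.001, substitution sequencing error 0.001 per
  base, read length 120 nt, strand fraction 0.5. The kit-grade conversion
  values keep the unconverted background (~0.1%) an order of magnitude
  below the 1% bin edge of the site-rate histogram; a 1% background would
  make a "<1% methylated" site class unobservable in principle.

### Lineage presets

* `por1`: S1-S5 only (weights 0.40/0.10/0.20/0.18/0.12). S1-S3 active with
  specific-transcription multipliers 1.0/2.2/1.3 (S2 under-represented in
  the genome but most efficiently transcribed); S4/S5 silent (multiplier 0).
* `por2`: La/Ls/S1-S5 with weights 0.45/0.10/0.15/0.08/0.10/0.07/0.05 — the
  L array more abundant than S and dominated by La. Only La is transcribed;
  Ls and all S-subvariants are silent.

Weights and multipliers are design defaults consistent with the qualitative
record (L more abundant than S in por2; La the single abundant transcribed
variant; S silenced in por2 but active in por1); the exact proportions are
not printed anywhere and are configurable.

## Assignment and profiling

Matching is ungapped (the regions are short and repeat-free; reads with
indels fail), in both orientations, with bisulfite-aware equivalence: a read
T is accepted where the oriented reference has C, because conversion acts on
the read's own strand. The best window by mismatch count wins; ties and
reads worse than 25% mismatches are `fail-no-region`. The identity filter
then demands zero mismatches, where declared SNP positions accept any
tabulated allele — the strict reading of "only reads identical to the
reference".

Variant calling intersects, over the SNPs that are conversion-safe on the
read's strand (all SNPs for unconverted reads; safety requires every allele
pair's observable letter sets to be disjoint), the haplotypes consistent
with the observed letters, and reports the most specific label: a variant
id, `S-group`/`L-group` when the consistent set is one array, else
`ambiguous`. Minus-strand reads can therefore resolve the array but never
La vs Ls (the G>A SNP reads C>T there) — an assignment-level consequence of
chemistry, asserted by mutation tests.

Per-site methylation is `100 * C / (C + T)` over pass-filter reads at each
cytosine on the read strand, with other letters ignored. Sites whose
trinucleotide context overlaps a SNP are excluded so every profiled
cytosine has an identical context in all variants; cytosines with a
truncated downstream window are `indeterminate` and excluded. Summaries use
a minimum depth of 10 reads per site. Whole-read metrics follow the two
classic modes: fraction of reads with *every* overlapped CWG (or CCG, CAA,
CAT) reading T, and for the saturated CGs the fraction of reads with at
least one CG reading T.

## Statistics

* **D_s-a** is the difference of per-site percentage medians (mean version
  also reported), silent minus active, per context. In the por2-like
  lineage the operational contrast is the S array (uniformly silent) versus
  the L array (dominated by active La, with a minor silent Ls fraction);
  this is the array-level comparison the CAPS/NlaIII design supports, and
  it slightly *understates* the pure silent-vs-active difference.
* **Support**: two-tailed Mann-Whitney U (`wilcox.test`: exact for small
  tie-free samples, normal approximation with tie correction otherwise) and
  Student's t (`t.test`, equal variances), with tiers ns (p2 > 0.05),
  moderate (0.01 < p2 < 0.05), significant (p2 < 0.01), and |D_s-a| tiers
  <5 / 5-10 / >10 points. Degenerate comparisons (both groups constant and
  equal) report p2 = 1; fewer than 3 sites per group reports ns with a
  warning. No multiple-testing correction is applied by default (raw p2
  values are reported, as is conventional for this analysis); p.adjust can
  be applied downstream.
* **Positional variability** treats per-sample site percentages as the
  sampling unit: for every unordered pair of sites of one context, a U test
  across the samples, reporting the fraction of pairs with p2 < 0.01. With
  the default model this is high for AT-rich CHH and CCG (each site has its
  own rate) and near the test's size for CG/CWG (shared rates; sample-level
  effects are common to both sites of a pair and cancel).
* **Specific transcription** is the ratio of a variant's cDNA proportion to
  its gDNA proportion, with a seeded 1,000-resample percentile bootstrap CI
  and a two-proportion test; ratio 0 with p_D > 0 marks silencing, and
  p_D = 0 is flagged `not_in_genome` rather than divided.

## Problem sizes and numerical choices

The packaged analyses use 5,000-15,000 reads per sample (per-site depth
roughly 400-1,100 after the ~10% identity-filter attrition from the 0.001
error rate), eight biological samples for positional variability, and
1,000 bootstrap resamples — sizes chosen so each stage completes in seconds
to tens of seconds while keeping binomial noise well inside the tolerances
asserted in the tests. Strict bin edges are used throughout (a site at
exactly 50% or 1% falls in the middle bin); region-match ties fail rather
than break arbitrarily; MboI cuts before its GATC site (offset 0) and
NlaIII after its CATG (offset 4), the standard conventions; the tandem
annotator's approximate mode tolerates a per-copy Hamming distance of 5% of
the unit length and requires equal-length copies.

## What passing tests do and do not show

The generator emulates: variant-structured tandem units on a shared
backbone, context- and position-structured methylation with activity and
tissue effects, incomplete/inappropriate conversion, substitution errors,
and copy-number-weighted sampling of molecules. It does not emulate: indels
or PCR/sequencing chimeras, quality-score structure, paired-end chemistry,
PCR duplicates, hemimethylation, within-array heterogeneity of a variant's
methylation (beyond Bernoulli sampling), or the real GenBank backbone
sequences. Consequently, passing tests demonstrate that the analysis
recovers known generating structure under a faithful but idealized read
model — not that it would be robust to alignment artifacts or library
chemistry effects in real data, where the identity filter is the main
guard.

Other limitations: absolute per-variant methylation levels are anchored to
reported *averages* and *differences*, not to per-variant ground truth
(which is not printed anywhere); minus-strand reads cannot resolve La/Ls,
so La-specific minus-strand methylation is only available pooled at the
array level; and the deletion polymorphisms of real spacers (P5-R103c
deletions, truncated spacers) are not simulated by default.
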