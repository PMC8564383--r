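---
title: "Sex-identification markers for fig: models, simulation design and limits"
author: "figsex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-identification markers for fig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(figsex)
```

## The biological model

Fig is gynodioecious. Sex behaves as a single Mendelian locus: caprifigs
("males") are heterozygous GA/ga, females are the recessive homozygote
ga/ga, so a female x male cross yields a 1:1 sex ratio among seedlings.
Two physical signatures of the male-determining haplotype support PCR
assays:

1. **AG presence/absence.** Male genomes carry two extra *AGAMOUS* alleles
   (AG2/AG3, 759-bp CDS, 7 coding exons) that retain a 15-bp stretch in
   exon 7; the conserved allele found in both sexes (744-bp CDS, gene
   length 5230 bp) lacks it. A forward primer equal to the 15-bp sequence
   (`CAGGAGGAGGAAGCT`) and a reverse primer complementary to the last 20
   coding bases yield a 146-bp product only where a male allele is present.
   Because absence of a band is the female signal, the caller requires a
   positive amplification control (Actin, 250 bp) before calling female;
   the original assay leaves this implicit, so the requirement is an
   assumption here and can be disabled (`controlEnabled = FALSE`).
2. **RAN1 zygosity.** The sex-linked *RAN1* gene (3015-bp CDS, 9 coding
   exons) carries 15 catalogued SNP sites. At a *sex-discriminating* site
   every male is heterozygous (the male-specific haplotype carries the
   alternative base, giving a double-base peak, written as an IUPAC
   ambiguity code in the consensus) and every female homozygous. Twelve of
   the fifteen sites discriminate; sites seq000259_9823, _9855 and _10377
   do not. Six discriminating sites fall inside a 608-bp exon-2 amplicon
   (the RAN1-Marker), which therefore works on genomic DNA and cDNA alike:
   all-het means male, all-hom means female, a mixture is reported
   `ambiguous` rather than majority-voted, and an uninformative profile is
   `failed`.

## What the generator emulates

`buildLocusModels()` constructs, from a seed, gene models and panels that
carry exactly these features, so that the discovery stages have something
real to find:

* exon/intron layouts are fixed by design (AG: coding exons
  181/67/62/100/42/45/247 bp with introns summing to 4486 bp; RAN1: coding
  exons 150/700/100/420/90/500/180/800/75 bp with short introns), chosen so
  that every published amplicon lies inside a single exon and all printed
  lengths (744/759/3015-bp CDS, 5230-bp gene, 146/608/371/444/766/156/250-bp
  products) are reproduced exactly;
* all primer footprints are embedded verbatim at in-frame positions; the
  degenerate AG primers are embedded as one concrete expansion and matched
  with intersection semantics;
* the random background is uniform over A/C/G/T, introns are canonical
  (GT..AG, minimum 60 bp), and the whole construction is *verified* after
  each draw: clean translations, exact splice-map round trip, and an
  exhaustive both-strand scan proving no primer of the table matches
  anywhere unintended. A violating draw is regenerated, never silently
  accepted; the retry loop is deterministic given the seed.

Two placement decisions deserve a note:

* **The reverse-marker footprint includes the stop codon.** The published
  primer sequences settle what "20 bp before the termination site" means:
  the reverse complement of the full-CDS reverse primer *ends* the CDS and
  its final TAA is the stop; the marker reverse primer is its 20-bp suffix.
  Placing the footprint entirely *before* the stop codon would force an
  in-frame TAA inside the CDS — impossible in a clean gene model. The
  15-bp insertion therefore starts at male CDS position 614, and the
  146-bp product runs from the insertion start through the CDS 3' end.
  `designPresenceMarker()` re-derives the published reverse primer
  byte-for-byte from the synthetic template, which is a strong consistency
  check of this reading.
* **SNP labels are identifiers, not coordinates.** The published scaffold
  offsets cannot be reconciled with a 608-bp exon-2 window (the labelled
  sites span far more than 608 bp), so the generator keeps the labels
  verbatim but chooses its own CDS positions: the exon-2 window holds six
  discriminating sites (8998, 9166, 9876, 9900, 10431, 11760), the 1-SNP
  amplicon holds 12314, the 2-SNP amplicon 12388 and 12646, and the 6SNP-2
  amplicon the three invalid sites plus 12722 (twice) and 12743 — matching
  the published per-amplicon coverage counts of 6/1/2/6.

**The seq000259_12722 duplicate.** The site list names 12722 under both the
missense and the synonymous mutations, yet fifteen sites are counted and
the SNP1..SNP15 numbering (SNP15-8998 ... SNP6-12314) only closes if 12722
occupies two slots. The generator therefore models two distinct sites under
that label by default (SNP2 missense, SNP3 synonymous);
`buildRan1Model(site12722 = "missense")` gives the one-site reading (14
sites) for users who prefer the typo interpretation. Effect flags are not
taken on faith anywhere: the test suite re-verifies each one by translating
the female CDS against the single-base male substitution.

**Panels.** The cultivar panel is 27 males + 24 females. Males carry the
conserved AG allele plus AG2/AG3 and the het consensus at all 15 RAN1
sites; females carry only female-type sequences. At each invalid site one
seed-chosen male is made homozygous and one female heterozygous, so the
strict screen fails those sites in both directions — mirroring how they
fail on real cultivars. F1 populations are generated either with fixed
counts ((110, 132) and (49, 36) reproduce the observed segregations) or as
fair Bernoulli(0.5) draws of the male haplotype. F1 seedlings carry the
clean sex pattern at all 15 sites: the invalid-site exceptions are a
cultivar-panel phenomenon and the markers never read outside the exon-2
window, so modelling their F1 behaviour would not change any call.

## Algorithms and numerical choices

* **Alignment** is global Needleman–Wunsch with affine gaps (Gotoh, in
  C++). Defaults: match +2, mismatch −3, gap open −5, gap extend −2; a gap
  of length L costs `open + L*extend`. These keep one contiguous 15-bp gap
  (−35) cheaper than any fragmented alternative, so the biological indel
  surfaces as a single event. Tie-breaking is fixed (substitution over gap,
  gap in the second sequence over gap in the first) so alignments are
  byte-reproducible. IUPAC codes score as matches when the base sets
  intersect. The implementation is checked against an independent dynamic
  program on thousands of small pairs and against
  `Biostrings::pairwiseAlignment` scores.
* **Primer matching** uses intersection semantics on both sides
  (`Biostrings::matchPattern(fixed = FALSE)`): degenerate primer bases
  match compatible template bases, and a concrete primer base matches a
  heterozygous template code — required for the RAN1-Marker to amplify male
  consensus sequences. Default 0 mismatches; a mismatch budget and a
  3'-anchor rule exist but are off, since the assays are clean
  presence/absence. Amplicon enumeration is exhaustive under `maxLen`
  (default 5000), not shortest-product-only; the fixtures guarantee
  uniqueness rather than the engine assuming it.
* **Splice mapping** (`spliceMap`) finds coding-exon chains whose
  concatenation equals the CDS exactly, with GT..AG introns of at least
  60 bp, by greedy longest-exon-first search with backtracking and
  failed-state memoisation. Exact matching only: an inconsistent CDS (the
  assembly-error situation) raises an error instead of guessing.
* **Coordinates** are 1-based inclusive everywhere, the R/Bioconductor
  idiom.
* **Statistics.** The sex-ratio string uses 2 significant figures with
  trailing zeros stripped — the only rounding rule that reproduces both
  published ratios (1:1.2 and 1:0.73). The 1:1 test is the plain
  chi-square with df = 1 and no continuity correction (Yates optional);
  its p-value comes from `pchisq`. The published tallies give
  chi-square = 2.0 (n = 242) and 1.99 (n = 85), so neither population
  rejects the Mendelian expectation at the 5% level — an inference this
  package draws, not a published claim. Relative expression uses the
  standard 2^−ΔΔCt transform with a mandatory reference gene and
  calibrator sample.

## Problem sizes

The shipped study conditions are the published ones: 51 cultivars, F1
populations of 242 and 85, 15 SNP sites, and genes of 5.2 kb (AG) and
3.8 kb (RAN1 genomic). The oracle-equivalence suite uses 1000 random pairs
of up to 12 bp; the type-I-error recovery check uses 2000 simulated
populations of n = 242. The full test suite runs in about a minute on one
CPU.

## Limitations

The simulation is a fixture for the *logic* of the assays, not a model of
wet-lab data. It does not emulate chromatogram traces or base-calling
quality, sequencing or PCR error, recombination inside the sex-linked
region (marker concordance is exactly 1 by construction, so recombination
distance is unidentifiable), indel heterozygotes in Sanger consensus
(frame-shifted double peaks), or realistic base composition and repeat
structure. Passing tests therefore demonstrate that the discovery rules,
callers and statistics implement the published procedure faithfully on
clean data — not that the assays are robust to noisy templates. True
scaffold coordinates of the SNP sites, and the exact exon-2 positions of
the six marker SNPs, are synthetic by construction.
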