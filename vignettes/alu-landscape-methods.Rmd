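---
title: "Methods: the Alu repeat landscape of a candidate-gene set"
author: "alulandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Alu repeat landscape of a candidate-gene set}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alulandscape)
```

## Scope and model

`alulandscape` analyses the landscape of Alu/SINE repeat elements inside a
set of candidate genes. Alu elements are ~300 nt primate SINE
retrotransposons (subfamilies AluJ, AluS, AluY, plus the free monomers
FLAM/FRAM/FAM); they cover roughly 11% of the human genome and cluster in
gene-rich, GC-rich regions. The package answers five questions about a
gene set:

1. **Inventory** — how many repeats and Alus does each region category
   (whole genes, CDS, introns, 5'UTRs, 3'UTRs) carry; what fraction of
   sequences harbour them; how many nt of sequence per Alu ("one Alu per
   N nt"); what fraction of bases is Alu-covered.
2. **Enrichment** — is Alu base coverage in the gene set higher than the
   genomic background (2×2 base-count chi-square), and are the
   Alu-carrying genes enriched for annotation terms (hypergeometric
   right-tail / EASE score, Bonferroni, group enrichment score).
3. **Orientation** — sense vs antisense counts of embedded Alus relative
   to transcript direction, per UTR class.
4. **IRAlus** — which transcripts carry at least one sense and one
   antisense Alu in their 3'UTR: such inverted pairs can base-pair into
   a double-stranded RNA duplex, the substrate for A-to-I editing,
   nuclear retention and Staufen-mediated decay.
5. **Duplex verification** — does the designated inverted pair actually
   fold into an intermolecular duplex, checked with a base-pair
   maximisation cofold.

Every stage runs on plain files (FASTA, GFF3, BED, RepeatMasker `.out`,
TSV) and every stage is exercisable on synthetic data with exact planted
truth, so the whole pipeline is testable without any external database.

## Coordinates and conventions

All internal coordinates are 0-based half-open; GFF3 and `.out` readers
and writers convert at the boundary (GFF3 and `.out` are 1-based
inclusive; `.out` uses `C` for the complement strand). "Sense" always
means transcript orientation: region sequences are spliced in transcript
order and reverse-complemented for minus-strand transcripts before
scanning, so a `+` hit on an extracted 3'UTR is a sense Alu.

Two display conventions coexist in published repeat tables and both are
explicit modes of `percent()`: table percentages are *truncated* at the
printed precision (112/217 = 51.61% prints as 51.6), while integer prose
percentages are *rounded* (554/941 = 58.87% prints as 59%). Densities
and average lengths are floored integers (20,074,601/11,335 = 1771.03
prints as 1771). These conventions were fixed once against the printed
cells they reproduce and are not configurable elsewhere.

## The repeat detector

Production repeat annotation uses RepeatMasker against a curated
consensus library; `read_repeatmasker_out()` ingests such annotations
directly. The built-in detector (`scan_repeats()`) is a desk-scale
seed-and-extend local aligner sufficient for consensus libraries of a
few dozen families:

* exact `seed_k = 12` k-mer seeds against each consensus, forward and
  reverse complement;
* seeds clustered by diagonal (half-width `band = 25`), each cluster
  realigned by full affine-gap Smith–Waterman inside the projected
  window, so a reported score **is** the local-alignment optimum of its
  interval — a property the tests verify against an independent
  implementation (`Biostrings::pairwiseAlignment`);
* scores: match +2, mismatch −3, gap of length L costs −5 − 2(L−1) (the
  BLAST-like parameterisation); hits below `min_score = 200` or shorter
  than `min_length = 50` nt are discarded. The 200 floor makes chance
  hits on random background vanishingly rare (a random 12-mer seed match
  cannot extend to score 200 without ~100 matching positions).
* overlapping calls are reduced greedily by descending score; a hit
  overlapping a kept hit by more than half the shorter hit's length is
  dropped, ties broken by earlier start then family name. Greedy
  selection matches how non-redundant repeat annotations are built; it
  is deliberately not a global optimiser.

Divergence is reported as mismatches / aligned columns × 100, gaps
excluded, close enough to RepeatMasker's %div for ranking and age
proxies. `min_length = 50` excludes sub-seed fragments; annotations
containing shorter fragments (e.g. a 49 nt `Alu`) should be imported
via the `.out` reader rather than re-detected.

## IRAlu definition

A transcript is IRAlu-positive iff its 3'UTR carries ≥1 sense and ≥1
antisense Alu element, *regardless of element length* — published IRAlu
inventories include rows whose only antisense element is a 75 nt
fragment, so a length filter on the flag would miss real carriers. The
length filter (`min_alu_length = 100`) applies only to *pair
designation*: the pairs enumerated for folding must both be reasonably
full-length, and the primary pair maximises the summed alignment score
(ties: smaller gap, then leftmost). No maximum gap is imposed by
default. Gene-level counts are reported twice: all biotypes, and
restricted to protein-coding transcripts (nonsense-mediated-decay
isoforms are real transcripts but not translated, so the protein-coding
count is the biologically conservative one).

## Folding model

The duplex check uses weighted base-pair maximisation (Nussinov dynamic
programming) rather than nearest-neighbour free energies: GC = 3, AU =
2, GU = 1, minimum hairpin loop 3 nt. This preserves the qualitative
stability ordering and is exactly testable — the DP optimum is compared
against exhaustive structure enumeration for short sequences. It does
**not** reproduce kcal/mol values; claims are therefore qualitative
("the inverted pair forms a duplex, the same-orientation control does
not"), which is the inference the analysis needs.

Cofolding concatenates the two sequences through a 10 nt sentinel
linker that can never pair; pairs spanning the cut are exempt from the
hairpin constraint (the standard cofold-by-concatenation trick). The
`duplex` verdict requires an intermolecular pairing fraction ≥ 0.5 and
a pair count ≥ 0.3 × the shorter element. In practice true inverted
pairs at ≤10% divergence reach fractions near 1.0 while
same-orientation controls stay far below 0.5 (typically 0.1–0.3,
because base-pair maximisation will happily fold random RNA
intramolecularly). The traceback is deterministic (position *i* pairs
the smallest admissible partner achieving the optimum), so outputs are
reproducible byte for byte.

One ambiguity is left to the caller: whether to fold the whole 3'UTR or
only the extracted pair. Both are exposed (`nussinov_fold()` on the UTR
vs `duplex_report()` on the pair); the pair-only mode is the default
pipeline behaviour because the intermolecular fraction is then directly
interpretable.

## Statistics

The 2×2 chi-square uses base counts (Alu bases vs non-Alu bases, gene
set vs genome), with Yates continuity correction on by default — the
correction is immaterial at these sample sizes, and a flag disables it.
The contingency construction from coverage percentages is a design
choice; the resulting p-value bound is robust to any genome length from
2.8 to 3.2 Gb, which the acceptance tests sweep. p-values are computed
in log space (`pchisq(log.p = TRUE)`, log-sum-exp hypergeometric
tails), so they stay meaningful below 1e−300; the conventional
"< 2.2e-16" floor is applied only at display time by `format_p()`.

The EASE score is the jackknifed Fisher exact probability: the
hypergeometric right tail at k−1 instead of k. It is conservative by
construction (always ≥ the Fisher p), which is why the null calibration
test checks the type-I rate is *at most* 0.05 plus sampling noise. The
group enrichment score is −mean(log10 EASE) over a cluster, so 0.05
everywhere ↦ 1.30103. Term clustering itself (kappa-statistic
co-membership) is out of scope; the group score operates on a given
cluster.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
study conditions used throughout the tests:

* background: i.i.d. bases at a target GC (0.41, the genomic average;
  0.48/0.55 for UTR-like and CDS-like segments);
* library: random consensi (detector behaviour is consensus-agnostic),
  or `alu_subfamily_library()` whose members descend from one ancestor
  at 5% divergence — mirroring the high sequence identity of real Alu
  subfamilies, and necessary for cross-family inverted pairs to duplex;
* planted copies: substitution-only point mutations (no indels), copies
  *substituted* into the background rather than inserted, so truth BED
  coordinates match the emitted FASTA exactly; strand randomised;
  placement by rejection sampling with non-overlap enforced;
* planted divergence 0–0.10, spanning the identity range of recently to
  moderately aged subfamily copies;
* the IRAlu constructor plants a sense AluSz-like (311 nt) and
  antisense AluSg-like (307 nt) pair — the canonical published layout —
  or a same-orientation negative control;
* the annotation-table generator plants one term whose membership
  probability is multiplied by `fold_effect` in a designated gene
  subset, against a uniform Bernoulli background.

What the generator does **not** emulate: the dimeric left/right-arm
structure of real Alus with the A-rich linker, indel evolution, CpG
hypermutability, tandem repeats and low-complexity sequence, and the
correlated placement of repeats in real genomes. Passing tests
therefore demonstrate algorithmic correctness on point-mutated planted
copies, not field performance against RepeatMasker on real genomes —
for real annotations, import the `.out` files.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale, chosen so the
full suite completes in well under a minute of compute per module:
backgrounds of 20–60 kb with 20–90 planted copies for detector
validation; 200 random sequences ≤ 14 nt for the fold-DP/enumeration
cross-check; 200 null terms over a 300-gene universe for the EASE
calibration; 100 replicates for planted-term recovery. Every random
draw goes through a seed argument, and seeded runs are byte-identical —
the pipeline writes a JSON manifest (config snapshot, input checksums,
row counts) with every run, and re-running an identical config
reproduces every analytic output exactly.

## Known limitations

* The detector is not a RepeatMasker replacement: no sensitivity modes,
  no CpG-adjusted matrices, no satellite/low-complexity masking.
* Published raw counts for a given gene set depend on the annotation
  release and library version; the package reproduces the *derivable*
  arithmetic of such tables and validates the machinery on synthetic
  truth instead of chasing version-pinned counts.
* Fold scores are dimensionless; no partition function, pseudoknots or
  base-pair probabilities.
* The greedy overlap resolver is order-deterministic but not globally
  optimal; pathological score configurations can keep a lower-total
  subset (documented behaviour, matching its specification).
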