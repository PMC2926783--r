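---
title: "Methods: conservation analysis of lincRNA loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation analysis of lincRNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincons)
```

lincons implements the comparative-genomics characterisation of long
intergenic noncoding RNA (lincRNA) loci: cohort selection against
protein-coding annotation, conserved-element overlap statistics, a
generic-locus ("metagene") conservation profile, evolutionarily conserved
region (ECR) detection from pairwise alignments, ortholog percent-identity
summaries, coding-potential screening (longest ORF and Nei–Gojobori dN/dS),
and poly(A)/splice-site motif annotation. This vignette documents the models,
the parameters that matter, the numerical conventions, and the design choices
that were genuinely open.

## Cohort selection

Two filters remove lincRNA candidates that may be unannotated fragments of
protein-coding genes:

* **Exonic overlap**: a transcript is removed when any of its exons shares at
  least one base with any coding exon. Overlap is tested at exon level (not
  locus level) because a lincRNA lying entirely inside a long coding intron is
  genuinely intergenic in the sense that matters here; locus-level overlap
  would discard it.
* **Proximity**: a transcript is removed when the gap between its locus
  interval and the nearest coding locus is *strictly* below `min_distance`
  (default 5000 bp): a gap of exactly 5 kb is kept. The gap is measured
  between loci (not TSSs) and ignores strand, since the contamination the
  filter guards against — untranslated regions and alternative transcripts of
  neighbouring genes — arises on both strands.

`overlap_fraction()` computes, per transcript, the fraction of exonic bases
and of all locus bases covered by discrete conserved elements. Elements are
unioned before counting, so duplicated or mutually overlapping element
annotations can never double-count a base; this makes the statistic invariant
under element duplication, which the test suite checks. A transcript counts
as "constrained" on any positive overlap — no minimum is imposed.

## Metagene conservation profile

Each multi-exon locus is partitioned, strand-aware, into six regions in
transcriptional order: a 200 bp upstream flank (the putative core promoter),
first exon, introns, middle exons, last exon, and a 200 bp downstream flank.
Each region is rescaled to `samples_per_region` slots (default 200):

* With `L >= k` concatenated bases and `k` slots, slot `i` (0-based) holds
  the score of base `round(i (L-1)/(k-1))` — scores are *sampled*, never
  interpolated, so every profile value is a real track value.
* With `L < k`, each base lands in slot `round(p (k-1)/(L-1))` and the
  remaining slots stay missing; short regions are used entirely.
* Rounding is half-up, so the slot map is deterministic and monotone.

Averaging is locus-weighted: each locus contributes at most once per slot, so
a locus with a 100 kb intron weighs the same as one with a 500 bp intron.
Within a locus, the pooled `introns` and `middle_exons` regions are rescaled
per feature and then averaged, so one long intron cannot dominate its locus'
intron profile. Positions absent from the score track are excluded from the
means rather than imputed as zero: conservation tracks legitimately omit
unalignable sequence, and imputing zeros would bias flanks downward. (For
element-derived tracks where absence genuinely means "not conserved", build
the track with explicit zero runs.)

`call_peak()` reports the argmax slot of a region, with ties resolved toward
the region's anchor — the TSS for the upstream flank (its 3' boundary),
the 5' boundary otherwise. For the fixed-length flanks the offset is
converted to bp (negative = upstream of the TSS); for locus-scaled regions
the natural unit is the slot, since their physical length varies per locus.

## ECR detection

An ECR is a reference-genome segment of at least `min_length` bases (default
100) aligning to a second species at `min_identity` (default 0.70) or more.
The scanner tests *every* window of exactly `min_length` consecutive
reference bases (step 1, rolling sum, verified against an exhaustive
enumeration), then merges overlapping or adjacent qualifying windows into
maximal intervals. Conventions:

* Windows are measured in reference (ungapped) bases, not alignment columns:
  segment sizes are genome distances.
* A column is a match only when both characters are non-gap, non-N, and equal
  case-insensitively; soft-masking (lower case) does not affect identity, and
  N counts as a mismatch — conservative for assembly gaps.
* The merged interval's identity is recomputed over the full interval and may
  fall below the window threshold; it is reported as-is together with
  `n_windows` for transparency. Merging (rather than per-window reporting)
  was chosen because the definition quantifies over segments, and merged
  intervals are what one draws on a locus figure.

A window detector necessarily extends a planted conserved segment into
background whose local identity sits near the qualifying margin — with a
100 bp window, up to roughly one window length in total. Recovery tests
therefore plant segments several hundred bp long (500 bp at 0.90 identity on
a 0.45 background by default), for which the detected interval's reciprocal
overlap with the truth exceeds 80%; segments near the 100–150 bp minimum
cannot meet that reciprocal bound with any window-based scanner.

## Ortholog percent identity

`overall_identity()` reproduces the summed-local-alignment convention:
percent identity = 100 × (identical aligned pairs over accepted,
non-overlapping hits) / query length. Choices a reader needs to interpret
the number:

* Scoring is the classic nucleotide default: match +2, mismatch −3, gap open
  5, gap extend 2; the affine-gap kernel is `Biostrings::pairwiseAlignment`
  (exact dynamic programming, adequate at cDNA scale), cross-checked in the
  tests against an independent pure-R Smith–Waterman oracle.
* Hits are accepted by greedy query masking: best alignment first, its query
  span masked, repeat until the best remaining score falls below `min_score`
  (default 30 ≈ 15 exact matches). Ties resolve to the smallest query start,
  then smallest subject start, so results are fully deterministic.
* Each optimal alignment is decomposed at X-drop boundaries (`xdrop = 50`):
  wherever the running alignment score falls 50 below its running maximum,
  the alignment is cut and only positive-scoring segments are kept. An exact
  DP otherwise bridges long low-identity stretches whenever the anchor beyond
  them outweighs the bridge cost, and the gap-shifted chance matches inside
  such bridges (~25% of bridged bases) would inflate the summed identities;
  seeded aligners never report them. With the decomposition, planted
  identical fractions of 0.3/0.5/0.9 are recovered as ~31/52/94%.
* The denominator is the *query* length (the reference-species transcript),
  so the measure is deliberately asymmetric; swapping arguments changes the
  percentage whenever lengths differ.

`windowed_identity_profile()` emits per-species identity in windows of
alignment columns (default 100, step 10), mapped back to reference
coordinates — the tabular equivalent of a percent-identity plot.

## Coding-potential screen

`find_longest_orf()` scans the forward strand only (inputs are oriented
cDNAs), all three frames, from each ATG to the first in-frame stop; the
longest ORF in amino acids wins, ties to the 5'-most start. ORFs containing
N are skipped; an ATG without a downstream stop yields an incomplete ORF
counted at its current length, since cDNA truncation is common. The
`long_orf` flag is a strict "> 100 aa" rule.

dN/dS uses Nei–Gojobori (1986) counting with Jukes–Cantor correction, chosen
over codon-model maximum likelihood because it is fully specified,
desk-verifiable codon by codon, and sufficient for the question asked of it —
whether an ORF shows protein-level constraint (dN/dS well below 1) or not
(≈ 1). Per codon, the nine single-nucleotide mutants partition sites into
synonymous and non-synonymous fractions, with stop mutants excluded and the
rest rescaled so n + s = 3 (so N + S = 3 × codons, an invariant the tests
assert to 1e−6). Differences between a codon pair are averaged over all
substitution orderings that avoid stop intermediates; pairs with no
stop-free pathway are dropped and counted in a QC field, as are gapped and
ambiguous codons. dX = −(3/4) ln(1 − 4pX/3) is undefined at pX ≥ 3/4 and the
ratio is undefined when dS is 0 or undefined; these are reported as flagged
missing values, never silently clamped.

## Motif annotation

`scan_iupac()` matches IUPAC patterns (overlaps allowed, case-insensitive);
`|` in a pattern is junction annotation only, as in the U2-type donor
consensus MAG|GTRAG. `polya_offset()` reports the poly(A) signal nearest the
3' end, scanning AATAAA before the ATAAA variant; `offset_3p` counts from
the motif's first base to the 3' terminus (a signal "30 bp upstream of the
3' end" has `offset_3p = 30`), and the convention is stated in output
headers since the alternative (motif end) is defensible. When the nearest
hit is contained inside a higher-priority pattern's hit (every AATAAA
contains an ATAAA), the canonical form is reported. A transcript with no
signal is a missing value, not an error — real ortholog sets include
transcripts without an identifiable signal. `splice_consensus_report()`
reports per intron, strand-aware, the terminal dinucleotides, the canonical
GT..AG flag, and whether the donor junction (last 3 exonic + first 5
intronic bases) matches MAG|GTRAG; every donor-consensus site is necessarily
also GT-AG, a containment the tests verify.

## Synthetic data: what it emulates, and what it does not

All tests run on seeded synthetic data; the generators plant known structure
and emit machine-readable ground truth, with the truth labels themselves
recomputed from the emitted coordinates by exhaustive scans rather than
trusted from the layout.

* **Annotation** (`sim_annotation`): units of one coding gene plus one
  multi-exon lincRNA with controlled gaps; configurable fractions violate
  the overlap and proximity filters. Defaults: 60 + 60 loci, 2–5 exons of
  100–250 bp, introns 200–600 bp.
* **Score track** (`sim_score_track`): uniform jitter (half-width 0.04)
  around a 0.05 background, a Gaussian promoter bump (σ = 10 bp — narrow
  enough for an unambiguous argmax) reaching an absolute height of 0.19 at
  43 bp upstream of each TSS, and splice-site bumps reaching 0.12 within
  ±20 bp of internal junctions. `promoter_peak_height` is the absolute peak
  score, so the planted peak is directly comparable to a reported peak
  height. Noise is independent per base: the analysis nowhere assumes
  autocorrelation, and uniform jitter keeps the signal-to-noise ratio
  interpretable. Elements are maximal runs above an exonic-quantile
  threshold chosen to hit the target exonic coverage (default 0.11).
* **Alignments** (`sim_alignment`): two-species blocks, ungapped reference,
  per-column match probability 0.45 outside planted segments (gapped at
  0.02), segment identity inside; default one 500 bp segment at 0.90.
* **Ortholog pairs** (`sim_ortholog_pair`): conserved blocks copied verbatim
  covering the configured fraction of the query, diverged segments with
  every base substituted plus short (1–10 bp) indels never inside conserved
  blocks — so the identical-aligned fraction equals the conserved coverage
  by construction. Partially substituted segments were rejected: their
  ~25% residual identity is recoverable by gapped alignment and would
  inflate measured identity above the planted value. The optional 3'
  conserved block carries an ATAAA starting exactly 30 bp from the 3' end,
  with chance signals 3' of it scrubbed.
* **Neutral codon pairs** (`sim_neutral_codon_pair`): both sequences descend
  from a stop-free ancestor with uniform per-site substitution (stops
  rejected); under no protein-level selection the NG86 ratio is ~1.

What the synthetic data does *not* emulate: realistic base composition,
repeat families, autocorrelated conservation, phylogenetically structured
multi-species evolution, or expression. Passing tests therefore demonstrate
correctness of the computations and recoverability of planted signal at
realistic signal-to-noise — not that any particular biological cohort will
show these signals.

## Problem sizes and determinism

The checked-in analyses use cohorts of 200 multi-exon loci (20 replicates)
for peak recovery, 100 replicate alignments of 2 kb for ECR recovery, 50
replicates of 300 codons for the neutral dN/dS regime, and 2 kb cDNA pairs
for identity calibration — sizes at which each planted quantity is
recovered well inside its tolerance while a full run stays in the minutes
range on one core. Every stochastic step is seeded; rerunning any generator
or the full pipeline with the same seed and configuration is byte-identical
(timestamps excluded), which the test suite asserts.

## Known limitations

* Genome-scale cohort statistics (percent of a real transcript catalogue
  overlapping conserved elements, etc.) depend on the exact external
  annotation and conservation build used; this package computes them for
  whatever inputs it is given but ships no reference data.
* NG86 is an estimator of dN/dS, not a substitute for codon-model ML when
  transition/transversion bias or branch structure matters.
* `local_align` is exact DP plus X-drop decomposition, not a seeded
  heuristic: identical results do not imply identical scores to any
  particular external aligner's E-value machinery.
* The upstream flank is fixed at 200 bp by default (the core promoter
  definition); peaks further upstream require a larger `flank_length`.
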