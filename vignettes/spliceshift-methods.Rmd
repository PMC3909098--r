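---
title: "spliceshift: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spliceshift: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshift)
```

## Scope and model

`spliceshift` analyses mutation-associated alternative splicing from
junction read counts. Its ingestion boundary is deliberately the junction
table, not the alignment: read mapping is upstream, and everything the
pipeline needs — event structure, usage quantification, splice-site
sequence context — can be derived from junction coordinates, an
annotation, and a genome.

Events are assembled by comparing junction structure against the
annotation. Two junctions sharing a donor with distinct acceptors form an
alternative 3′ splice-site (A3SS) event unless both acceptors belong to
distinct annotated terminal exons (then it is an alternative last exon,
ALE) or the pair is explained by a cassette exon (CE: two flanking
inclusion junctions plus an exon-bridging exclusion junction) or by a
mutually exclusive exon quadruple (MXE: both inner exons annotated, never
co-occurring in one transcript). The symmetric donor-side case is A5SS.
Intron retention (IR) pits an annotated intron's junction reads against
intron-body reads; because junction tables carry no body evidence, IR
events are only built when a body-count table is supplied.

Per event and sample, usage is percent-spliced-in,
`PSI = 100 * I / (I + E)`, undefined below a combined support threshold.
The proximal isoform (the acceptor nearer the shared donor in the
direction of transcription, i.e. the shorter intron) plays the inclusion
role, so ΔPSI < 0 — mutant minus control — reads as exon skipping or
distal 3′ splice-site gain. On the minus strand "distal" is the smaller
genomic coordinate; all coordinates are 1-based and inclusive of the
first and last intronic base, matching how single splice-site positions
are conventionally reported.

## Statistical procedure

Group comparisons run a two-sided Wilcoxon rank-sum test per event on the
PSI values, pairwise-complete (missing PSI values are dropped, never
imputed, and an event needs at least two defined values per group).
Events whose absolute median difference is under `delta_thresh` (5
percentage points) are not tested at all; among tested events p-values
are Benjamini–Hochberg adjusted, and a significant call additionally
requires an absolute median difference above `median_delta_filter` (10
points). The two thresholds are distinct on purpose: the first trims the
testing burden, the second enforces an effect size on survivors.

Two-library designs (one sequencing library per condition) cannot support
a rank test; there each event's inclusion/exclusion counts form a 2×2
table tested with Fisher's exact test, with a 25-read support floor per
library and a 5-point PSI difference required of significant calls. A
specificity filter retains events significant in the mutant comparison
and quiet in the control comparisons; an event that moved significantly
but in the *opposite* direction under the wild-type control is still
dropped as non-specific, yet flagged so it can be footnoted.

Splice-site switches are deliberately looser: any annotated two-choice
CE/A3SS event with at least 25 reads in both conditions whose proximal
PSI moves by more than 5 points counts as a switch toward the gaining
site, with no statistical cutoff. Each switch is labeled by the −3
trinucleotide classes (TAG/CAG/AAG/other, read from positions 18–20 of
the 23-nt site sequence: 20 intronic plus 3 exonic bases) of the losing
and gaining acceptor. Direction biases use an exact two-sided binomial
test against 0.5, and condition contrasts a two-sided Fisher test; the
sidedness is not dictated by the procedure itself, and two-sided is the
conservative choice.

Motif matrices report per-column base frequencies and information
content `2 − H − e(n)` bits with the standard small-sample logo
correction `e(n) = 3 / (2 ln(2) n)`; groups under 10 sequences return no
matrix. Rendering is out of scope — the matrices are the artifact.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_event_count` | 2 | reads | pooled support every member junction needs |
| `psi_min_total` | 10 (25 pairwise) | reads | support floor for a defined PSI |
| `delta_thresh` | 5 | % points | pre-test median ΔPSI filter |
| `median_delta_filter` | 10 | % points | post-FDR effect-size filter |
| `fdr_alpha` | 0.05 | fraction | BH cutoff |
| `jcn_seq_len` | 88 | nt | IR body-count normalisation (88 or 202 by read length) |
| `switch_dpsi` | 5 | % points | switch-calling threshold |

`jcn_seq_len` enters *only* the IR normalisation. Its value tracks read
length, consistent with a length-normalisation role; junction-vs-junction
events compare like with like and use raw counts.

## Numerical choices

- Cassette-exon inclusion support is the mean of the two flanking
  junctions, rounded half-up. Averaging avoids double-counting a fragment
  that spans both flanks; half-up keeps integer counts without a downward
  bias. MXE events apply the same rule to each exon's junction pair.
- The Wilcoxon test is exact when the combined sample count is at most 12
  and the data are tie-free, and otherwise uses the normal approximation
  with tie correction and (by default, switchable via
  `wilcoxon_correct`) continuity correction. Real cohorts (e.g. 8 mutant
  vs ~100 wild-type) force the approximation; the exact branch keeps small
  fixtures checkable against enumeration.
- Events with more than two isoform choices are decomposed into pairwise
  sub-events against the most-supported acceptor, mirroring the
  most-significant-isoform reporting convention; the original choice
  count is kept so the switch analysis can restrict to genuinely
  two-choice events.
- Unstranded junction records (STAR strand code 0) are dropped with a
  warning: the −3 classification is strand-dependent and an unstranded
  junction cannot be sequenced-typed.
- Planted simulation shifts are clipped to PSI ∈ [1, 99] (logged), never
  silently wrapped; degenerate all-or-none isoforms would make binomial
  sampling uninformative.
- "Expressed in both cohorts", the universe for the cross-cohort overlap
  test, means PSI defined in at least half the samples of each cohort;
  the restriction is standard, its threshold is this package's choice.
- Coordinate matches whose AS types disagree are reported flagged rather
  than auto-dropped — identical splice-site pairs can describe different
  event structures, and that judgement is left to review.
- Replicate libraries in switch comparisons are pooled by summing counts
  before PSI; pooling is appropriate for single-library induction designs
  and exposed rather than hard-wired.

## The simulator

The generator is the package's statement of study conditions, not a
tuning knob. Defaults: 200 two-choice events (120 CE, 80 A3SS) on one
toy chromosome per gene; 8 mutant vs 20 control samples; baseline PSI
uniform on [5, 95]; 25% of classed events planted with a 30-point shift
toward the distal acceptor; 80% of planted events oriented proximal-TAG /
distal-CAG (so the planted switch is TAG→CAG); total junction coverage
negative-binomial with mean 100 and size 10 — the standard overdispersed
count model for junction data, with inclusion reads binomial at the true
PSI. Every intron is canonical (GT…AG) with its −3 base drawn from
configurable class proportions (default TAG 0.4 / CAG 0.4 / AAG 0.2).
Genes land on a random strand; minus-strand genes are stored
reverse-complemented with mirrored coordinates, which exercises the
strand logic end to end.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: overlapping genes and shared junctions,
unannotated (novel) splice sites, alignment and multi-mapping artifacts,
library-size differences between samples, NMD-coupled degradation of
aberrant isoforms, and correlated effects across events in one gene.
Recovery numbers on simulated cohorts are statements about the
statistical machinery under its own assumptions, not about TCGA-scale
cancer cohorts.

With those defaults, testing at the package's problem sizes (20 count
replicates for power, 30–50 replicate null cohorts for calibration,
chosen to keep the suite comfortably within a coffee break), the
pipeline detects planted shifts with mean power above 0.9, calls no null
events significant under the 10-point median filter, keeps the raw
q < 0.05 fraction on pure-null cohorts under 1%, and recovers the planted
0.8 TAG→CAG orientation inside its binomial confidence interval. The
acceptance script recomputes all of these at run time.

## Known limitations

- ALE PSI uses the proximal-terminal-exon junction as the inclusion
  isoform; there is no community-standard denominator for ALE and this
  choice is ours, recorded here rather than inferred as anyone's intent.
- IR requires externally supplied intron-body counts; the package does
  not count body reads from alignments.
- The BH pre-filter (`delta_thresh`) conditions the tested set on an
  observed effect, which mildly biases the null p-value distribution of
  tested events; the effect-size filter on calls keeps realised false
  positives low (measured, not assumed, in the test suite).
- Junction counts are taken at face value; multi-mapper and non-canonical
  read filtering is an upstream concern.
- Gene assignment is by annotated-intron match with an overlap fallback;
  events in unannotated loci report `unknown`.
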