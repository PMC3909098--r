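# spliceshift

Differential alternative splicing from splice-junction read counts, with 3′
splice-site sequence preference analysis.

## The problem

Somatic mutations in 3′ splice-site recognition factors (the canonical case
being the S34F/Y hotspot of *U2AF1*) reshape how the spliceosome chooses
between competing acceptor sites. Detecting this from RNA-Seq requires a
chain of steps: assembling alternative-splicing events from junction
evidence, quantifying each event's usage per sample, testing for shifts
between mutant and wild-type sample groups, and then asking whether the
shifted events share a sequence signature at the intronic −3 position — the
base immediately before the terminal AG, which distinguishes TAG, CAG and
AAG acceptors. `spliceshift` implements that chain as a desk-scale,
fully-tested R pipeline that takes junction count tables (STAR
`SJ.out.tab`, BED12 junctions, or a plain TSV), a transcript annotation
(GTF or intron BED) and a genome FASTA.

## The model

For an event with inclusion-junction support $I$ and exclusion support $E$
in one sample, the percent-spliced-in value is

$$\mathrm{PSI} = 100 \cdot \frac{I}{I + E},$$

left undefined when $I + E$ is below a support threshold (default 10
reads; 25 for single-library designs). Cassette exons use the rounded mean
of their two flanking junctions as $I$; intron retention scales intron-body
counts by `jcn_seq_len / intron length`. Group comparisons use a two-sided
Wilcoxon rank-sum test on PSI (exact for small tie-free samples) with
Benjamini–Hochberg correction; a call is significant at q < 0.05 with a
median ΔPSI over 10 points. Two-library designs use a per-event Fisher's
exact test on the 2×2 inclusion/exclusion table. Splice-site switches —
PSI reallocations > 5 points between two competing acceptors, with no
statistical cutoff — are labeled by the −3 classes of the losing and
gaining site (e.g. TAG→CAG), and direction biases are tested with exact
binomial and Fisher tests.

## Worked example

Simulate a cohort of 8 mutant and 20 control samples with 200 two-choice
events, a quarter of them planted with a 30-point shift toward the distal
acceptor, then run the full chain:

```r
library(spliceshift)
co <- simulate_cohort(simulation_spec(seed = 7))
ev <- build_events(co$counts$junctions, co$sim$annotation,
                   min_event_count = 2)
pt <- compute_psi(ev, co$counts$junctions, psi_min_total = 10)
res <- wilcoxon_diff(pt, co$counts$sheet, "control", "mutant",
                     run_config())
head(annotate_results(res, ev)[order(res$q_value), ], 5)
```

```
               event_id as_type median_psi_group0 median_psi_group1 delta_psi
1  A3SS_g0121:151-390:+    A3SS              52.2              19.4     -32.8
11 A3SS_g0131:151-390:+    A3SS              55.2              27.4     -27.8
14 A3SS_g0134:151-390:+    A3SS              54.4              24.0     -30.4
16 A3SS_g0136:281-520:-    A3SS              47.1              18.5     -28.7
21 A3SS_g0141:281-520:-    A3SS              67.8              34.9     -32.9
    q_value significant
1  5.83e-05        TRUE
```

46 events come out significant, all with negative ΔPSI — the planted
shift toward distal acceptor usage. A negative ΔPSI (mutant minus control
on the proximal/inclusion isoform) means exon skipping or distal 3′
splice-site gain.

Comparing switch directions between two conditions (here the published
per-condition switch counts, 884/181 toward CAG/TAG under the mutant
versus 347/313 under wild-type):

```r
sw <- switch_direction_fisher(c(884, 181), c(347, 313))
# toward-CAG: 83% vs 53%, Fisher p = 2.47e-41
```

A command-line wrapper with `simulate`, `events`, `psi`, `diff` and
`overlap` subcommands lives at `inst/cli/spliceshift.R`.

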