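---
title: "Quantifying TE transcriptional contribution and calibrating gene expression with BUSCO orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TE transcriptional contribution and calibrating gene expression with BUSCO orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecontrib)
```

## The problem

Transposable elements (TEs) are mobile DNA sequences whose transcription
responds to physiological stress. In fish exposed to different salinity
conditions — freshwater (FW), brackish water (BW) and salt water (SW) — the
fraction of gill RNA-Seq reads originating from TE transcripts is a direct
readout of TE transcriptional activity, and the host's TE-silencing
machinery (Argonaute proteins, heterochromatin factors, the NuRD complex
and its recruiters) can be profiled alongside it.

Two methodological obstacles arise with de novo transcriptome assemblies:

1. **Repeat-annotation redundancy.** RepeatMasker reports every repeat hit
   on every transcript, including overlapping and non-TE hits, so reads
   cannot be attributed to a TE class until the annotation is reduced to
   one confident TE call per transcript.
2. **Cross-sample and cross-species comparability.** Raw mapped-read counts
   depend on library depth and assembly composition. Comparing
   silencing-gene expression between conditions and species requires a
   common yardstick; a fixed set of universal single-copy orthologs
   (BUSCOs) provides one.

`tecontrib` implements both stages as a tested, deterministic pipeline, and
ships a synthetic-data generator with closed-form ground truth so every
stage can be validated end to end.

## TE contribution model

Let $c_{t,s}$ be the mapped-read count of transcript $t$ in sample $s$ and
$M_s$ the sample's total mapped reads. After annotation each TE transcript
carries one class $k(t) \in \{$SINE, Retro, LTR, LINE, DNA, Unclear$\}$.
The contribution of class $k$ in sample $s$ is

$$P_{k,s} = 100 \times \frac{\sum_{t : k(t) = k} c_{t,s}}{M_s},$$

and the total TE contribution is $P_s = \sum_k P_{k,s}$. The denominator is
*total* mapped reads, including reads on non-TE transcripts: this is what
makes the unit ("percent of mapped reads") comparable between libraries of
different depth and between species. Percentages are conserved by
construction ($\sum_k P_{k,s} = P_s$ to machine precision) and invariant to
a uniform rescaling of all counts.

Between two samples $a$ (baseline) and $b$, the signed percentage
variation of any contribution value is

$$V(a, b) = 100 \times \frac{P_b - P_a}{P_a}.$$

Because published comparisons rarely state which condition is the baseline,
`contrast_conditions()` reports **both orderings** of every pair by default
and labels each row with its pair, so any quoted number is auditable in
either direction. $V(a,a) = 0$ always; a zero baseline with a non-zero
comparison value is reported as `NA` (undefined), never as infinity.

### Redundancy resolution

`resolve_redundancy()` first discards hits whose repeat category is not a
transposable element (simple repeats, low-complexity, satellites,
structural RNAs), then keeps per transcript the hit maximizing
(Smith–Waterman score, match length) lexicographically. Remaining exact
ties are broken by repeat name (ascending) then query start (ascending) —
an arbitrary but deterministic rule, chosen so that reruns and platforms
agree bitwise.

Two genuinely open readings of "best hit" exist: per-transcript selection
(one class per transcript) and per-interval merging (a transcript split
among several repeats). We implement per-transcript selection because
expression is counted at transcript level — a mapped read is attributed to
a transcript, not to a sub-interval — so a single class per transcript is
the only attribution consistent with read counting. Interval merging is
deliberately not implemented.

The class vocabulary is loaded from a versioned mapping table
(`inst/extdata/te_class_map.tsv`), matched by prefix on the part of the
class/family string before the first `/`. Two mapping decisions deserve
note: rolling-circle elements (`RC/Helitron`) count as DNA transposons,
and `Retroposon` — the only remaining retroelement category once LINEs,
SINEs and LTR elements are named — is what the "Retro" class denotes.
Unrecognized strings map to "Unclear" with a warning rather than being
dropped, so the TE total never silently loses mass.

## BUSCO-anchored calibration

For each sample the calibration set assigns every BUSCO ortholog an
expression value from the sample's count table:

* **Complete** (single copy) and **Fragmented**: the mapped-read count of
  the referenced transcript, as is;
* **Duplicated** (typically assembly isoforms): the sum over *all* copies,
  however many rows the ortholog occupies;
* **Missing**: 0.

The cumulative calibration expression $C_s = \sum_{\text{BUSCO}} e_{b,s}$
measures the sample's effective depth over a fixed gene set. The scaling
factor of sample $s$ relative to a reference $r$ is $f_s = C_r / C_s$
(so $f_r = 1$ and $C_s f_s$ is constant across samples), and calibrated
gene expression is $\tilde{g}_s = g_s \times f_s$. This
ratio-of-cumulatives construction is the simplest scaling scheme consistent
with using a calibration set; per-gene median-ratio alternatives exist, but
with thousands of orthologs summed the cumulative ratio is robust to
individual outliers and keeps the factor interpretable as a depth ratio.
The reference sample is user-selectable (default: first sample
lexicographically); changing it rescales every calibrated value by one
global constant and changes nothing else.

### Numerical detail: exact library-size invariance

Calibration must undo a uniform rescaling of a count table exactly: if
sample $B$'s counts are $k$ times sample $A$'s, the calibrated values must
be identical. We therefore evaluate
$\tilde{g}_s = (g_s \times C_r) / C_s$ — products of exact integers
followed by a single IEEE division — rather than
$g_s \times (C_r / C_s)$. With the fused ordering, numerator and
denominator of the scaled run are exactly $k$ times those of the unscaled
run, and correctly-rounded division makes the results bit-identical for
any $k$; with the pre-divided factor they can differ in the last ulp. The
two orderings agree to $\sim 10^{-16}$ relative error, so the reported
`scaling_factor` column remains the interpretable quantity. One
consequence: "calibrated = raw × factor" holds to floating-point
round-off, not bitwise; the invariance property was given priority because
it is the one with analytical meaning. Note that rescaling the *reference*
sample's table rescales every calibrated value by construction — the
invariance concerns non-reference samples.

A BUSCO transcript absent from a count table counts as 0 with a warning
(assemblies and mappings can disagree); an ortholog with zero cumulative
expression in *every* sample would make the factor undefined, and the
pipeline stops with an error naming the sample whose cumulative is zero.

### The gene panel

The bundled panel (`inst/extdata/silencing_gene_panel.tsv`) lists the 26
genes whose calibrated expression the pipeline reports: the four
*Argonaute*-subfamily genes (AGO1–4), six heterochromatin-formation genes
(HP1a, HP1ba, HP1bb, HP1g, DNMT1, DNMT3aa), fourteen NuRD-complex genes
(CHD3, CHD4a, CHD4b, HDAC1, HDAC2, MBD2, MBD3b, MTA1, MTA2, MTA3,
GATAD2ab, GATAD2b, RBBP4, RBBP7) and the two proposed NuRD recruiters in
ray-finned fish, TRIM33 and KRAB-like. `bundled_gene_panel()` asserts
these category counts at load time, so the shipped configuration cannot
drift silently. Users map panel genes to their own transcript ids via a
two-column TSV (`gene`, `transcript_id`).

## What the synthetic generator emulates

`generate_dataset()` produces every input the pipeline consumes — assembly
FASTA, RepeatMasker `.out`, per-sample count TSVs with a totals file,
BUSCO `full_table.tsv`, gene-panel TSV — plus a JSON manifest holding the
ground truth. Its statistical model matches exactly the assumptions the
pipeline's statistics rely on:

* Each transcript has one true label (a TE class or non-TE), allocated by
  largest-remainder rounding of `class_fractions`.
* Reads in sample $s$ are one multinomial draw of the library size over
  transcripts, with weight `expression_shift[s][class(t)]` per transcript.
  Expected class read fractions are therefore available in closed form and
  recorded in the manifest next to the realized (drawn) counts. Counts are
  multinomial rather than negative-binomial on purpose: every statistic
  the pipeline computes is a deterministic function of the counts, so
  overdispersion would only inflate the Monte-Carlo error of recovery
  tests without exercising any additional code path.
* TE transcripts get one RepeatMasker hit of their true class; a fraction
  `overlap_rate` get competing hits that always lose the (score, length)
  contest (`force_score_ties = TRUE` makes them tie the score exactly, to
  exercise the length tie-break), and some non-TE transcripts get
  simple-repeat hits, exercising the TE filter.
* BUSCO status counts follow `busco_status_mix` by largest-remainder
  rounding (statuses then shuffled across ids), so status proportions are
  exact rather than sampled — e.g. a 50% Duplicated mix over 10 orthologs
  yields exactly 5 Duplicated ids with 2 copies each.
* Gene-panel transcripts are sampled from non-TE transcripts, disjoint
  from BUSCO-referenced ones by default (`panel_overlaps_busco = TRUE`
  allows overlap; whether a real transcript can be both is
  assembly-dependent, and disjointness is the conservative default that
  keeps calibration and panel expression independent).

All randomness derives from `seed`; identical configurations produce
byte-identical files.

The defaults describe a three-condition FW/BW/SW design: 600 transcripts
of which 12% are TE transcripts (DNA transposons the largest class, LINEs
second — the composition typical of teleost transcriptomes), library sizes
of 100, 120 and 80 thousand mapped reads, BW up-weighting all TE classes
by 1.1, and SW down-weighting them to 0.8 except SINEs at 1.3 — a
salinity-responsive TE load with a class moving against the total, which
gives the variation statistics something non-trivial to find.

What the generator does **not** emulate: read-level errors and mapping
ambiguity (counts are drawn, not aligned), assembly fragmentation and
chimerism, overdispersion between biological replicates (conditions are
single pooled libraries, as is common in de novo designs), and TE
annotation errors beyond decoy competing hits. Passing recovery tests
therefore shows that the pipeline's arithmetic and bookkeeping are
correct under the stated sampling model — not that RepeatMasker
annotations or read mapping on real data are accurate.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle or a
closed form: redundancy resolution against an exhaustive pairwise-
comparison search on randomized hit sets (200 sets of 50 transcripts with
up to 10 hits each, with frequent exact score ties); variation maxima
against a brute-force scan over all pairs and classes; percent
conservation and scale invariance as exact identities; ground-truth
recovery over 20 seeds at library size $10^5$, requiring each class
percent to fall within 3 binomial standard errors
($\mathrm{SE} = \sqrt{p(1-p)/M}$) of its closed-form expectation in at
least 95% of seed-by-class cells; and calibration invariance bit-for-bit
under count rescaling by 2, 10 and 1000. These sizes keep the full suite
under a minute while leaving each Monte-Carlo check enough resolution to
fail loudly if an off-by-one or a denominator swap were introduced.

## Known limitations

* One TE class per transcript: a chimeric transcript carrying two genuine
  TEs contributes all its reads to the winning class.
* The percent-of-mapped-reads denominator includes non-TE reads by
  definition; pipelines that report percent of TE-mapped reads will print
  larger numbers for the same data.
* The scaling factor is a single global depth ratio; it corrects library
  size, not gene-specific composition effects.
* No significance testing is attached to variation statistics: with one
  pooled library per condition there is no replicate variance to test
  against, so the numbers are descriptive.
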