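---
title: "Motif enrichment in quiescent and active NSPC enhancers: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif enrichment in quiescent and active NSPC enhancers: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhmotif)
```

## Scientific setting

Adult neural stem and progenitor cells (NSPCs) alternate between a
quiescent and an actively proliferating state, and the two states use
different sets of enhancers (distal regulatory regions marked empirically
by p300 binding and H3K27ac). Labelling each enhancer as
quiescence-specific (`Q`), active-specific (`A`) or shared (`PAN`) raises
a concrete sequence-analysis question: which transcription-factor binding
motifs are over-represented in these enhancers relative to neighbouring
DNA, do any motifs prefer one cell state's enhancers, and does motif
presence near a gene predict how that gene's expression changes between
states? The Wnt effector LEF1 (which binds the Wnt response element
`CTTTGWW`, core `CTTTGT`) and the quiescence-associated factor NFIX
(consensus core `TTGGCA`) are the motivating pair: LEF1 sites are expected
in enhancers of all groups, while NFIX-like words cluster next to LEF1
sites specifically in quiescence enhancers. Alongside the genomics, the
package implements the small closed-form quantifications used at the
bench in the same projects: percent exon retention from gel densitometry
(the *Lef1* exon-6 splice isoforms), 2^-ddCt qPCR fold changes,
dual-reporter normalisation, and protein half-life from cycloheximide
chases.

This vignette explains the models and procedures, the tunable parameters
and their defaults, the synthetic data generator the test-suite runs on,
and the numerical choices and limitations a user should know about.

## PWM scoring model

A position count matrix (4 rows A, C, G, T; one column per motif
position) is converted to a log-odds position weight matrix by

\[
\mathrm{lo}_{b,j} = \log_2 \frac{(c_{b,j} + s\,\pi_b) / (\sum_{b'} c_{b',j} + s)}
                                {\pi_b},
\]

where \(s > 0\) is the pseudocount (default 1, distributed across bases in
proportion to the background) and \(\pi\) the background composition
(default uniform, configurable to the observed composition). Base 2 makes
scores read in bits and makes an uninformative column score exactly 0.

Each sequence is scored by its **single best placement** over all offsets
and, by default, both strands; this "only the maximally scoring motif"
rule makes the per-sequence statistic a simple presence/absence call
downstream. A placement that touches any masked base (lowercase
soft-masking or `N`) is invalid rather than scored with a neutral
contribution, mirroring scanning of masked genome assemblies. Ties are
broken by smallest offset, then the plus strand, so scans are
deterministic. The best score is rescaled to

\[
\mathrm{rel} = \frac{\mathrm{score} - \min}{\max - \min} \in [0, 1],
\]

where max/min are the column-wise attainable extremes; a sequence is
called **motif-positive when rel ≥ 0.8**, mirroring the
80-percent-of-maximum convention of common PWM scanners. The same single
cut-off is reused everywhere (enrichment, group comparison, gene
profiles) so that results are comparable across stages. Note that on this
min-max scale a 0.8 cut admits single-mismatch words for motifs of six or
more informative columns — the per-column cost of one mismatch is about
\(1/w\) of the total range — so background sequence has a non-trivial
positive rate; all tests below are therefore *differences* of presence
fractions, never raw fractions.

## Bootstrap enrichment tests

**Enhancers versus flanks.** For each enhancer the two immediately
adjacent regions of the same length are taken as controls (dropped if they
run off the contig or overlap another enhancer of the set). The observed
statistic is the difference of motif-positive fractions, enhancers minus
controls. The null distribution draws, `B` times, one enhancer-sized and
one control-sized resample (both with replacement from the control pool)
and recomputes the same difference; the p-value is the +1-smoothed upper
tail \((1 + \#\{t^\ast \ge t\}) / (B + 1)\), so it can never be smaller
than \(1/(B+1)\). Comparing two resampled fractions — rather than one
resample against the fixed control fraction — matters: the observed
statistic carries sampling noise from *both* sets, and a null built from
only one resample is variance-deficient and rejects far too often (about
twice the nominal rate in our checks). The two-resample null reproduces
the nominal 5% type-I rate in the suite's 500-dataset calibration test.
Resampling is order-sensitive but seed-deterministic; sort inputs by id
before a run if bit-reproducibility across differently ordered files is
needed.

**Between groups.** For each ordered pair of enhancer groups the same
difference statistic is used, with a null that pools the two groups'
presence calls and draws group-sized resamples from the pool — a
bootstrap analogue of a permutation test.

**Positional bias.** To ask whether hits concentrate centrally (as they
would if the motif defined the enhancers), the share of hit midpoints in
the central window (default half of the sequence) is compared to the
uniform expectation with an exact binomial upper tail. This is a
deliberately simple stand-in for likelihood-ratio local-enrichment tools;
it tests central concentration only, not arbitrary positional profiles.

Raw p-values are reported and interpreted per motif at 0.05; no
multiplicity correction is applied across motifs (a Bonferroni column is
trivial to add given the handful of motifs in a library).

## Word discovery in anchor flanks

Co-occurring motifs are sought in the 15 bp windows immediately left and
right of each plus-strand `CTTTGT` anchor match (the anchor itself is
excluded; windows truncate at sequence ends). The 15 bp width is read as
15 bp **per side**; anchors are matched on the plus strand only. Each
exact word of length 4–8 occurring in the positive windows (word and
reverse complement collapsed to one class) is scored by a one-sided
Fisher exact test of per-window presence, positives versus negatives,
and an E-value \(= p \times\) (number of distinct candidate words). The
best word is reported, positive windows containing it are removed, and
the search repeats — a desk-scale, fully deterministic analogue of
discriminative regular-expression discovery. When no negative set is
supplied, seeded dinucleotide-preserving shuffles (random Eulerian walks
on the transition multigraph) of the positive windows are used, so the
negatives keep first-order composition exactly.

Exact-word counting has one characteristic failure mode: a planted motif
is counted by the word *and all of its subwords*, whose p-values differ
only through background noise, so the raw ranking occasionally surfaces
a fragment (e.g. a 5-mer inside a planted 6-mer). The selection step
therefore promotes the chosen word to the most specific significant
candidate that contains it (up to reverse complement) and still covers at
least 90% of its positive windows. Because any window containing the
longer word necessarily contains the shorter, coverage near 1 identifies
the short word as a fragment, while genuine independent short-word signal
keeps coverage low and blocks promotion. This mirrors the generalization
step of RE-based tools in a deterministic form.

Discovered words are mapped to a motif library by converting each word to
a degenerate count matrix (matched bases weight 1, `N` uniform) and
maximising the mean per-column Pearson correlation of column frequencies
over all alignments and both orientations, with at least 4 overlapping
columns; a zero-variance column contributes correlation 0, so an
uninformative target scores 0. This column-correlation matcher is a
simplified stand-in for full motif-comparison machinery: it reports the
best alignment and similarity but no E-value.

## Linking motif presence to expression

Genes are classed `up` / `down` / `ns` by sign and p-value (threshold
0.01, matching the expression analysis the enhancer atlas came with),
linked to enhancers either through a supplied association table or by the
nearest enhancer (distance 0 inside an interval, otherwise the gap to the
nearer edge; exact ties go to the upstream enhancer, then the smaller
start). A 3×2 table of DE class by motif presence is tested with the
plain Pearson chi-squared statistic \(\sum (O - E)^2 / E\) on 2 degrees
of freedom — no continuity correction, which is undefined for 3×2 — with
a flag when any expected count falls below 5. Genes without a linked
enhancer count as motif-absent (configurable by filtering beforehand), so
the table always partitions the gene list. Exclusive-Q gene sets collect
genes whose motif presence is confined to Q enhancers, optionally
requiring one Q enhancer to carry both the anchor and the second motif
(the dual-motif criterion).

## Assay formulas

* Percent exon retention: \(100 \cdot I_{FL} / (I_{FL} + I_{\Delta E6})\).
  Molar correction (dividing band intensities by amplicon length, so the
  ratio counts molecules rather than stained mass) is available but off
  by default; the uncorrected intensity ratio is the documented default,
  not asserted to be any particular published variant.
* qPCR: \(2^{-\Delta\Delta C_t}\) with amplification efficiency fixed at
  2 (the Livak assumption); efficiency-corrected variants are out of
  scope.
* Dual reporter: \((\mathrm{eGFP}/\mathrm{mCherry})\) normalised to the
  calibrator's ratio.
* Half-life: ordinary least squares of \(\log\) intensity on time;
  \(k = -\text{slope}\), \(t_{1/2} = \ln 2 / k\). The log-linear fit is
  the standard closed-form estimator for first-order decay after a
  translation block; a non-positive \(k\) (no measurable decay) returns a
  flagged fit with \(t_{1/2} = \infty\) rather than an error. Timepoints
  are in hours and must start at 0 (the normalisation anchor).

## The synthetic data generator

Every stage is exercised on generated data with machine-readable ground
truth, because the real enhancer atlas, genome assembly and microarray
are external resources. The generator emulates the *statistical
structure* the analysis assumes:

* per group, `n` enhancers of fixed length embedded mid-contig in an
  order-1 Markov background (default uniform transitions), so
  length-matched flanks always exist;
* one contiguous soft-masked run per contig (default 2% of its length);
* with a per-group probability, one anchor-motif consensus planted at a
  uniform offset on the plus strand; with a conditional probability, a
  co-motif word planted within 15 bp of the planted anchor (Q only, by
  default);
* a DE gene table whose motif-presence indicator has a configured odds
  ratio between up-regulated and unchanged genes, plus independent
  per-group presence profiles with known exclusive-Q and dual-motif gene
  lists;
* assay tables with multiplicative lognormal (gel, decay) or additive
  Gaussian (Ct) noise around known truths.

All randomness derives from one master seed through named substreams, so
changing, say, the assay noise level cannot perturb the sequence draws.
Defaults are desk-scale: 300 enhancers per group, 300 bp each, anchor
planting probability 0.4 in all groups, a second motif at 0.3 in Q versus
0.05 elsewhere, co-motif probability 0.6 given an anchor, 600 genes with
presence odds ratio 3 for up-regulated genes, retention truth 61%,
fold-change truth 8, half-life truth 3.3 h. The 300 bp length keeps the
background presence rate at the 0.8 relative-score cut low enough that
planted-versus-background contrasts remain detectable at these sample
sizes; at substantially longer lengths the presence call saturates and
count-based statistics would be preferable. The bundled motif library
(`default_motif_library()`) consists of *synthetic* width-8 matrices
whose consensi contain the field's consensus words (`CTTTGT` within
`ACTTTGTT`, `TTGGCA` within `TTGGCACA`, a SOX2-like `CCATTGTT` with a
degenerate third column, and the ASCL E-box cores); they are constructed
stand-ins, not database downloads.

What the generator does **not** emulate: real genomic repeat structure
and composition (the background is first-order Markov), overlapping or
variable-length enhancers, distance-dependent gene–enhancer assignment
(profiles are drawn directly), or correlated biological replicates in the
assay tables. Passing tests therefore demonstrate correctness and
calibration of the statistical machinery under its own assumptions, not
performance on a real genome.

## Numerical choices and edge cases

* Pseudocount 1 distributed by background; any positive value is
  accepted, and a zero-total column is rejected at construction.
* Scan tie-breaks: smallest offset, then plus strand. Motif-comparison
  tie-breaks: smaller absolute offset, then the `same` orientation.
  Word ranking: E-value, then lexicographic.
* A fully masked sequence yields a "no valid placement" sentinel
  (`valid = FALSE`), not an error; a sequence shorter than the motif is
  an error.
* Bootstrap p-values are floored at \(1/(B+1)\); `B` below 100 is
  rejected.
* The chi-squared test refuses zero margins (the statistic is undefined)
  and flags expected counts below 5 instead of switching tests.
* Palindromic IUPAC patterns are reported once per window (plus strand),
  not double-counted on the minus strand.
* `R`'s RNG state is saved and restored around every seeded generator
  call, so package functions never perturb a user's random stream.

## Problem sizes in the test-suite

The suite runs entirely on generated data: 500 null datasets of 100 + 100
sequences for the type-I calibration of the bootstrap, 20 seeded runs for
each power and recovery check (40% versus 5% planting at 200 sequences;
60% co-motif planting in 300 windows), 500 replicates for the chi-squared
null calibration at 600 genes, 100 decay series for half-life recovery,
and one full pipeline run at the default 3 × 300 enhancers with B = 500.
These sizes were chosen so that each check has conventional statistical
resolution (binomial standard errors near one percentage point) while the
whole suite stays desk-scale.

## Limitations

The enrichment machinery calls presence from the single best hit; motifs
occurring many times per sequence are better served by the hits-per-kb
statistic, which is not the default. The word discovery searches exact
words (with reverse-complement collapsing and maximality promotion), not
degenerate expressions, and models no positional preference within the
flank window. The motif matcher reports correlation similarity without a
calibrated E-value. None of the genomic headline numbers of the
motivating study (enhancer counts, specific gene lists) can be reproduced
without its external atlas; the package reproduces the *pattern* on
synthetic data with known truth instead.
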