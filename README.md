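# enhmotif

Transcription-factor motif enrichment in state-specific enhancers of
neural stem and progenitor cells (NSPCs), plus the closed-form bench
quantifications that accompany such studies.

Adult NSPCs switch between quiescent and actively proliferating states,
and each state uses its own enhancer repertoire (p300/H3K27ac-defined,
labelled `Q` = quiescence-specific, `A` = active-specific, `PAN` =
shared). `enhmotif` answers three questions about such an atlas:

1. **Is a motif over-represented in enhancers?** Sequences are scored
   with log-odds position weight matrices built from JASPAR-style count
   matrices, `lo[b,j] = log2(((c[b,j] + s·π_b)/(Σc[·,j] + s))/π_b)`, each
   sequence contributing only its maximally scoring placement; a sequence
   is motif-positive when the best hit's min–max relative score reaches
   0.8. Enrichment is the difference in positive fractions between
   enhancers and length-matched flanking controls, tested against a
   seeded bootstrap null (B resamples from the control pool, +1-smoothed
   upper-tail p), and analogously between enhancer groups. A binomial
   test checks for central positional bias of hits.
2. **What co-occurs next to an anchor motif?** The 15 bp windows flanking
   each plus-strand `CTTTGT` (LEF1/TCF core) match are searched for exact
   words of length 4–8 enriched over a negative set (one-sided Fisher per
   window, E-value-corrected, greedy with maximality promotion), and
   discovered words are matched to a motif library by mean per-column
   correlation over the best alignment.
3. **Does motif presence track differential expression?** A 3×2 table of
   DE class (`up`/`down`/`ns`, p < 0.01) by motif presence is tested with
   the plain Pearson chi-squared statistic on 2 df, and exclusive-Q /
   dual-motif (anchor + second motif on one Q enhancer) gene sets are
   extracted.

Assay-side, the package computes percent exon retention
`100·I_FL/(I_FL+I_ΔE6)`, qPCR fold changes `2^−ΔΔCt`, dual-reporter
ratios `(eGFP/mCherry)/(eGFP_cal/mCherry_cal)`, and protein half-lives
`t½ = ln2/k` from log-linear fits of cycloheximide-chase series.

A fully seeded synthetic-data generator (`gen_enhancer_dataset()`,
`gen_de_table()`, `gen_assay_data()`) produces every input with
machine-readable ground truth, so the whole pipeline is testable without
genome downloads. `default_motif_library()` ships small *synthetic*
matrices whose consensi contain the field's consensus words (`CTTTGT`,
`TTGGCA`, the ASCL E-box cores); they are constructed stand-ins, not
database matrices.

## Worked example

```r
library(enhmotif)

lib <- default_motif_library()
pwm <- counts_to_pwm(lib$LEF1_LIKE)
pwm
#> pwm LEF1_LIKE (width 8, bits), consensus ACTTTGTT
#>   score range [-34.690, 15.563]

scan_best_hit(pwm, "TTGACTTTGTTACGATCGCTAAGCTAGGC")
#>   enhancer_id  motif_id offset strand width    score relative_score valid
#> 1         seq LEF1_LIKE      3      +     8 15.56332              1  TRUE

percent_exon_retention(3, 1)        # full-length band three times the skipped band
#> [1] 75

fit_half_life(c(0, 1, 2, 4, 6),
              exp(-log(2)/3.3 * c(0, 1, 2, 4, 6)) * c(1, 1.04, 0.97, 1.02, 0.95))
#> half-life fit: k = 0.2183 /h, t1/2 = 3.18 h, R2 = 0.997 (n=5)
```

The end-to-end synthetic demonstration (three groups of 300 enhancers,
anchor motif planted in all groups, NFIX-like motif and co-word planted
in Q):

```r
rep <- run_pipeline(synth_config(seed = 1), B = 500, verbose = FALSE)
rep
#> enhmotif pipeline report (seed 1)
#>
#> Enhancers vs flanks (bootstrap p by motif x group):
#>    motif_id group    statistic bootstrap_p
#>   LEF1_LIKE     Q  0.293333333 0.001996008
#>   LEF1_LIKE     A  0.308333333 0.001996008
#>   LEF1_LIKE   PAN  0.298333333 0.001996008
#>   ...
#>
#> Group-differential (top rows):
#>    motif_id group1 group2     frac1     frac2  statistic bootstrap_p   B
#>   NFIX_LIKE      Q      A 0.5133333 0.2833333 0.23000000 0.001996008 500
#>   ...
#>
#> Discovered flank words:
#>    word width pos_count pos_total neg_count neg_total            p      e_value
#>  TGCCAA     6        61       274         3       274 7.719164e-17 4.424625e-13
#>
#> Best library matches:
#>    word target_id offset orientation similarity overlap
#>  TGCCAA NFIX_LIKE     -2     revcomp          1       6
#>
#> 3x2 chi-squared: X2 = 27.1493, df = 2, p = 1.272e-06
#> ...
#> Gene sets: 123 exclusive-Q, 99 exclusive-Q dual-motif
#> Assays: mean retention 60.5%, mean fold 7.72, mean t1/2 3.34 h
```

Reading the report: the anchor motif is enriched in all three groups over
their flanks (positive statistic, bootstrap p at the floor `1/(B+1)`);
the NFIX-like motif is enriched in `Q` versus `A`; the top word found
next to anchors in `Q` flanks is `TGCCAA` — the reverse complement of the
planted `TTGGCA` — and maps to the NFIX-like library matrix with
similarity 1; motif presence associates with up-regulation in the 3×2
chi-squared test; and the noisy assay tables recover their ground truths
(retention 61%, 8-fold, t½ = 3.3 h) to within noise. See the methods
vignette (`vignettes/motif-enrichment-workflow.Rmd`) for the models,
defaults and limitations.

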