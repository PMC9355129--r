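Package: enhmotif
Title: Motif Enrichment in Quiescent and Active Neural Stem Cell Enhancers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Position weight matrix scanning of enhancer sequences and
    bootstrap tests of transcription-factor motif enrichment in enhancers
    versus length-matched flanking controls and between enhancer groups
    (quiescent-specific, active-specific, pan-active), together with
    de-novo word discovery in sequences flanking an anchor motif,
    motif-to-library matching by column correlation, contingency tests
    linking motif presence to differential-expression classes, and the
    bench-side quantification formulas used alongside such analyses
    (percent exon retention from gel densitometry, 2^-ddCt qPCR fold
    changes, dual-reporter normalisation, and cycloheximide-chase
    protein half-life fitting). A seeded synthetic-data generator with
    machine-readable ground truth makes every stage testable without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
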