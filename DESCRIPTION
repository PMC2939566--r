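Package: regenprofiler
Title: Regeneration Time-Course Transcriptome Profiling for Fragmented Imaginal Discs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the staged transcriptome analysis of regenerating
    Drosophila wing imaginal discs: a simplified two-colour microarray
    differential-expression caller (two-fold / FDR < 0.05 rule with
    dye-swap correction), four-class temporal gene classification across
    the early (0-24 h) and late (24-72 h) regeneration contrasts,
    fold-enrichment and running-sum (GSEA-style) gene-set enrichment,
    promoter extraction with IUPAC/PWM motif scanning, phylogenetic
    conservation filtering across a Drosophila species panel, and a
    resampling Z-test for conserved binding-site enrichment. Includes a
    fully ground-truthed synthetic data generator so every stage is
    testable without external array data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
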