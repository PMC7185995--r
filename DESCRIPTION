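Package: ontosleep
Title: Sleep Ontogeny Analysis for Drosophila Activity Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the maturation of sleep in Drosophila from
    Trikinetics Drosophila Activity Monitor (DAM) recordings. Reads and
    writes DAM monitor files, scores sleep as runs of at least five
    consecutive inactive minutes, summarises sleep architecture (day/night
    totals, bout number and bout length), computes per-genotype ontogeny
    ratios (young over mature daytime sleep) and calls screen hits at a
    ratio cutoff, runs the screen's statistics (Holm-Sidak corrected t
    tests, Welch t tests, one-way ANOVA with Tukey HSD), quantifies
    free-running rhythmicity with an FFT periodogram, implements confocal
    quantifications (innervation density, 3D puncta counting, corrected
    total cell fluorescence, normalised ROI signal, binary innervation
    scoring), and performs gene-set selection and intersection for
    RNA-Seq/ChIP-Seq integration. A synthetic-data generator built on an
    alternating-renewal sleep-wake model provides DAM files, image stacks
    and omics tables with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
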