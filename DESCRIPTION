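Package: tecontrib
Title: Transposable-Element Transcriptional Contribution and
    BUSCO-Anchored Expression Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the transcriptional contribution of transposable
    elements (TEs) in de novo transcriptome assemblies from RepeatMasker
    annotations and per-sample mapped-read counts, expressed as percent of
    mapped reads per TE class (SINE, Retro, LTR, LINE, DNA, Unclear), with
    between-condition percentage-variation statistics. Also builds a
    BUSCO-ortholog calibration set (Complete/Fragmented kept as mapped
    reads, Duplicated summed over copies, Missing set to 0), derives
    per-sample scaling factors from cumulative calibration expression, and
    applies them to a bundled TE-silencing gene panel so expression is
    comparable across samples and species. Includes a seeded synthetic-data
    generator that emits all pipeline inputs with a machine-readable
    ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
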