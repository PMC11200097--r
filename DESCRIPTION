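Package: ssrexp
Title: Transcriptome Microsatellite Mining and Expression-Modulating Motif Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines perfect and compound simple sequence repeats (SSRs) from
    transcript sequences under MISA-style criteria, canonicalizes repeat
    motifs under rotation and reverse-complement equivalence, assigns SSRs
    to transcribed regions (5'-UTR, CDS, 3'-UTR, lncRNA), derives expression
    capacity (maximum TPM) and tissue specificity (TPM coefficient of
    variation) from an organ-level expression matrix, and detects
    expression-modulating motifs (expMotifs) by a cascade of nonparametric
    tests and polynomial/bivariate regression with BIC model selection and
    VIF screening. Includes a synthetic-transcriptome generator with planted
    repeats and planted expression effects so the whole pipeline can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
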