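Package: blastodyn
Title: Transcriptome Dynamics of the Colonial Ascidian Blastogenetic Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression and gene-ontology dynamics analysis for
    phase-resolved RNA-seq of the Botryllus schlosseri blastogenetic cycle.
    Implements pairwise per-colony differential-expression calling on read
    counts (Fisher's exact test combined with a likelihood-ratio G-test),
    replicate-consensus filtering (minimum-clues rule), per-GO-category
    up/down tallies with the gene regulation variation (GRV) and gene number
    variation (GNV) change statistics, transcript recovery (ORF completeness
    classification and best-hit taxonomy inheritance), a 2^-ddCt qPCR
    validation helper, and a seeded synthetic-data generator emulating the
    five-colony, three-phase study design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
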