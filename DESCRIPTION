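Package: seedscreen
Title: Seed-Match Enrichment Analysis for RNAi Screen Off-Target Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate off-targeted transcripts in large-scale RNAi
    screen data by miRNA-like seed-region analysis. Guide-strand seeds
    (nucleotides 2-8 by default) are extracted from active and inactive
    siRNA/shRNA reagents, transcript sequences are scanned for perfect
    seed-complement sites, and per-transcript 2x2 enrichment of matches among
    active versus inactive reagents is tested with the two-sided Fisher exact
    test or the Yates continuity-corrected chi-square test, with Bonferroni,
    Holm and Benjamini-Hochberg corrections. Includes a theoretical-inactive
    construction for actives-only screens, a scrambled-seed control, a
    deterministic synthetic screen generator with planted off-target
    structure, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
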