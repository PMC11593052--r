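Package: domainfirst
Title: Domain-First Annotation of De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates de novo assembled transcriptomes domain-first: every
    transcript is conceptually translated in all six reading frames, a target
    conserved protein domain (such as SH2) is detected anywhere in the
    resulting proteome, hits are mapped back to open reading frames and
    transcript coordinates, homology matches are filtered by explicit
    coverage/identity/e-value criteria, and each domain-bearing transcript is
    classified as matched to a known protein, an assembly error or truncated
    RNA (including proteins split across two transcripts or across reading
    frames of one transcript), or novel. Ships a seeded synthetic-transcriptome
    generator with planted ground truth so the whole pipeline is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
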