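Package: cenpcscan
Title: Degenerate Motif and Cupin-Domain Architecture Screening for
    CENP-C Ortholog Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens protein sequences for the domain architecture of the
    inner-kinetochore protein CENP-C. Provides degenerate-pattern parsing
    and mismatch-tolerant motif scanning with IUPAC ambiguity codes,
    consensus-motif derivation from protein multiple alignments,
    Smith-Waterman local alignment with affine gaps for cupin-domain
    localization, rule-based per-protein architecture classification
    (canonical CENP-C, putative fish-type CENP-C, M18BP1-like motif-only
    evidence), and a seeded synthetic-proteome generator with
    machine-readable truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
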