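Package: coiref
Title: Curated COI DNA Barcode Reference Collections from ENA and BOLD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds curated reference collections of animal mitochondrial
    cytochrome c oxidase subunit I (COI) DNA barcode sequences. Ingests
    EMBL flat files and BOLD-style TSV specimen dumps, screens sequences
    by scoring six-frame mitochondrial translations against a profile
    hidden Markov model at its trusted cutoff, validates ENA
    coding-sequence annotations against the profile footprint, applies
    length, ambiguity and stop-codon quality gates plus an optional
    BLAST-based contamination screen, merges and dereplicates the two
    sources, harmonizes taxonomy to the seven-rank NCBI backbone, and
    writes FASTA plus taxonomy/metadata TSV outputs with collection-level
    summary statistics. Includes a deterministic synthetic-corpus
    generator with ground-truth verdicts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
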