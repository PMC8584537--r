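Package: mitofold
Title: Mitochondrial Heteroplasmy Calling on Duplicated-Reference Amplicon Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking low-level heteroplasmy detection on
    amplicon-based mitochondrial DNA whole-genome panels that align reads to
    an extended circular reference (the canonical 16,569-bp rCRS with its
    first 80 bases duplicated at the end). Provides coordinate folding of
    variant calls back to canonical rCRS positions with duplicate-record
    merging, a transparent pileup-based SNV caller with heteroplasmy
    threshold sweeps, cross-run variant reliability grading (A/B/C/novel),
    two-haplotype mixture truth sets with expected variant levels, confusion
    matrix metrics with F1-driven threshold optimization, and a false
    positive annotation battery (normalized coverage, strand bias, NUMT
    counts, low-complexity regions, amplicon edge distance). A seeded
    synthetic-data generator emulates haplotypes, mixtures, per-amplicon
    depth and strand-split base counts for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    vcfR,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
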