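Package: spliceshift
Title: Differential Alternative Splicing from Junction Counts with 3' Splice-Site
    Sequence Preference Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for mutation-associated alternative splicing
    analysis from splice-junction read counts. Builds and classifies splicing
    events (cassette exons, alternative 3'/5' splice sites, alternative last
    exons, intron retention, mutually exclusive exons) from junction tables and
    a transcript annotation, quantifies percent-spliced-in (PSI) per sample,
    calls differential splicing between sample groups (Wilcoxon rank-sum with
    Benjamini-Hochberg correction and delta-PSI filters) or between two single
    libraries (per-event Fisher's exact test), characterises 3' splice-site
    sequence preferences at the intronic -3 position (TAG vs CAG/AAG),
    enumerates splice-site switches between conditions, tests cross-cohort
    event overlap, and simulates cohorts with planted splicing shifts for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
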