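Package: famvar
Title: Family-Based Prioritization of Germline Variants in Cancer Pedigrees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Staged prioritization of rare germline variants from family
    exome studies. Provides call-quality and allele-frequency pre-filters,
    a pedigree segregation filter, and a threshold-and-voting cascade over
    precomputed annotation scores (CADD, conservation, gene intolerance and
    an ensemble of deleteriousness predictors) with full funnel accounting.
    A regulatory arm intersects non-coding variants with regulatory-element
    tracks and compares predicted transcription-factor binding sites between
    wild-type and mutant promoter sequence using JASPAR-style position
    frequency matrices with a relative-score threshold. Also includes
    ortholog-alignment conservation summaries around a mutation site and a
    deterministic synthetic-data generator so that every stage of the
    pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
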