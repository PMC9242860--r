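Package: regscreen
Title: Pooled CRISPR Dropout-Screen Scoring and Regulatory-Element Analysis
Version: 0.1.0
Authors@R:
    person("regscreen", "developers", email = "regscreen@example.org",
           role = c("aut", "cre"))
Description: Scoring and inference for pooled CRISPR/CRISPRi dropout screens
    at the gene and enhancer-region level: control-centred guide fold
    changes, top-k depleted sensitivity scores, region-level depletion
    statistics with permutation empirical p-values, peak-to-TSS window
    enrichment, Fisher interval-overlap tests, PWM motif scanning with
    allele-aware scoring and motif-pair geometry, allele-specific
    ChIP/RT-qPCR ratio normalisation, time-course target-gene filtering,
    and seed-deterministic synthetic-data generators (plasmid skew, guide
    efficacy, engraftment bottlenecks, overdispersed counts) so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    jsonlite,
    optparse,
    yaml,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
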