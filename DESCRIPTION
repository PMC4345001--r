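Package: genemerge
Title: Strategy-Aware Merging of Ab Initio and Evidence-Based Gene Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines gene predictions from ab initio gene finders (HMM-based
    models applied to genomic sequence alone) with evidence-based predictions
    (derived from RNA-seq, ESTs or protein homology) into a single consensus
    annotation. Ab initio loci are tested for support by evidence-based
    predictions using exonic-overlap thresholds in prokaryotic mode and
    order-preserving exon-chain matching in eukaryotic mode; accepted
    transcripts are classified by reliability (perfect, supported, partially
    accepted), conflicting predictions are resolved in favour of concordant
    evidence, and genes absent from the ab initio output but concordantly
    predicted by two or more evidence-based methods can be reported as novel.
    Includes Cufflinks-dialect GTF input/output, converters for AUGUSTUS GFF
    and Glimmer3 predict files, Cuffcompare-style exon- and transcript-level
    accuracy evaluation, and a seeded simulator of ground-truth annotations
    with method-specific error profiles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
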