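Package: circprofiler
Title: Backsplice Junction Detection and Expression Profiling for rRNA-Depleted RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale pipeline for profiling circular RNA
    alongside mRNA and lncRNA from single-end, rRNA-depleted RNA-seq reads.
    Provides a deterministic synthetic-data generator (toy genome, GTF
    annotation, FASTQ reads with backsplice-junction reads and controlled
    overhangs), read quality filtering, a k-mer seed-and-extend linear
    aligner with SAM ingestion, backsplice (head-to-tail) junction discovery
    from segment matches of unmapped reads with position-weight-matrix
    splice-site scoring, pseudo-circular junction quantification with an
    overhang rule, DESeq-style negative-binomial differential expression
    (median-of-ratios size factors, moment dispersion with a conservative
    trend maximum, exact test), Fisher-exact GO and pathway enrichment with
    Benjamini-Hochberg correction, GO-tree and pathway networks, and
    condition-specific Pearson co-expression networks with degree, W-core
    and differential-hub analysis. All user-facing functions take and return
    tibbles so stages compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    generics,
    data.table,
    jsonlite,
    ggplot2,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    DESeq2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
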