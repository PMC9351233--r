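Package: dmlscreen
Title: SNP-Aware Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for calling differentially methylated CpG loci (DML)
    from strand-resolved whole-genome bisulfite sequencing counts. Screens
    out C->T SNPs that masquerade as unmethylated cytosines using
    opposite-strand base identity, builds a filtered, normalized, destranded
    and united methylation matrix, tests each locus with a binomial logistic
    regression (treatment plus an ordinal maturation covariate) corrected for
    overdispersion before a chi-squared test, converts p-values to q-values
    with a sliding-linear-model estimate of the true-null proportion, and
    characterizes the resulting DML against genome feature tracks (introns,
    UTRs, flanks, intergenic regions, transposable elements) with
    contingency tests and gene ontology enrichment. Includes a synthetic
    data generator with planted DML and planted C->T SNPs for calibration
    and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
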