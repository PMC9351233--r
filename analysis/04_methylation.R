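#!/usr/bin/env Rscript
# Stage 4 — build the methylation matrix and characterize the landscape.
#
# Canonical order: destrand -> filter (5x, 99.9th percentile) -> normalize
# -> unite (5x in all samples) -> C->T SNP exclusion. Then classify loci
# into low (<=10%), moderate and high (>=50%) methylation, and check that
# treatments do not separate globally (pairwise Pearson correlations, PCA).

suppressMessages(library(dmlscreen))

run_dir <- "results/run"
genome <- read_genome_fasta(file.path(run_dir, "genome.fa"))
samples <- data.table::fread(file.path(run_dir, "samples.tsv"))
cov_files <- stats::setNames(
  file.path(run_dir, "coverage", paste0(samples$sample_id, ".cov")),
  samples$sample_id)
coverage <- read_bismark_cov(cov_files)
snps <- data.table::fread(file.path(run_dir, "snps.bed"),
                          col.names = c("chrom", "start", "pos", "name"))

destranded <- lapply(coverage, destrand, cg_sites = genome)
filtered <- lapply(destranded, filter_coverage, lo = 5, high_percentile = 99.9)
normalized <- normalize_coverage(filtered)
mm <- unite_samples(normalized, samples, min_cov = 5)
excl <- apply_snp_exclusion(mm, snps)

classes <- classify_loci(excl$matrix)
cors <- sample_correlations(excl$matrix)
pca <- sample_pca(excl$matrix)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write_methyl_matrix(mm, file.path(run_dir, "united_matrix.tsv"))
write_cpg_bedgraph(excl$matrix, file.path(run_dir, "cpg_5x.bedgraph"))
data.table::fwrite(classes$summary, "results/tables/methylation_classes.tsv",
                   sep = "\t")
data.table::fwrite(data.table::as.data.table(cors, keep.rownames = "sample"),
                   "results/tables/sample_correlations.tsv", sep = "\t")
data.table::fwrite(
  data.table::data.table(sample = rownames(pca$scores),
                         PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                         treatment = samples$treatment),
  "results/tables/sample_pca.tsv", sep = "\t")

message(sprintf("united %d loci; %d removed by SNP exclusion (%d kept)",
                nrow(mm$loci), excl$n_removed, nrow(excl$matrix$loci)))
message(sprintf("classes: %s",
                paste(sprintf("%s %.1f%%", classes$summary$class,
                              classes$summary$percent), collapse = ", ")))
message(sprintf("median between-sample correlation %.3f; PC1 explains %.1f%%",
                stats::median(cors[lower.tri(cors)]), 100 * pca$explained[1]))
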