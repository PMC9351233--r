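#!/usr/bin/env Rscript
# Stage 5 — differential methylation testing and DML calling.
#
# Per united locus: binomial logistic regression of methylation on
# treatment with the maturation stage as ordinal covariate, likelihood-
# ratio chi-squared test with the MN overdispersion correction, SLIM
# q-values, then calling at q < 0.01 and |difference| >= 50 points with
# C->T SNP overlaps removed. Recovery is scored against the planted truth.

suppressMessages(library(dmlscreen))

run_dir <- "results/run"
genome <- read_genome_fasta(file.path(run_dir, "genome.fa"))
samples <- data.table::fread(file.path(run_dir, "samples.tsv"))
coverage <- read_bismark_cov(stats::setNames(
  file.path(run_dir, "coverage", paste0(samples$sample_id, ".cov")),
  samples$sample_id))
snps <- data.table::fread(file.path(run_dir, "snps.bed"),
                          col.names = c("chrom", "start", "pos", "name"))

destranded <- lapply(coverage, destrand, cg_sites = genome)
filtered <- lapply(destranded, filter_coverage)
normalized <- normalize_coverage(filtered)
mm <- unite_samples(normalized, samples)

results <- suppressWarnings(dml_test(mm, correct = TRUE, use_covariate = TRUE))
called <- call_dml(results, snps, diff_cutoff = 50, q_cutoff = 0.01)
acc <- called$accounting

write_dml(called$dml, file.path(run_dir, "dml.bed"), file.path(run_dir, "dml.tsv"))
acc_dt <- data.table::data.table(metric = names(acc),
                                 value = unlist(acc))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(acc_dt, "results/tables/dml_accounting.tsv", sep = "\t")

truth <- data.table::fread(file.path(run_dir, "truth_dml.tsv"))
snp_truth <- data.table::fread(file.path(run_dir, "truth_snp.tsv"))
truth_key <- paste(truth$chrom, truth$pos)
called_key <- paste(called$dml$chrom, called$dml$pos)
united_key <- paste(mm$loci$chrom, mm$loci$pos)
eligible <- setdiff(intersect(truth_key, united_key),
                    paste(snp_truth$chrom, snp_truth$pos))
sens <- mean(eligible %in% called_key)
fdr <- if (length(called_key) > 0) mean(!(called_key %in% truth_key)) else 0
data.table::fwrite(
  data.table::data.table(metric = c("sensitivity", "fdr", "pi0"),
                         value = c(sens, fdr, attr(results, "pi0"))),
  "results/tables/dml_recovery.tsv", sep = "\t")

message(sprintf("%d candidates, %d removed as SNP overlaps, %d DML retained (%d hyper / %d hypo)",
                acc$n_candidates, acc$n_snp_removed, acc$n_retained,
                acc$n_hyper, acc$n_hypo))
message(sprintf("recovery of planted DML: sensitivity %.2f, FDR %.3f", sens, fdr))
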