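#!/usr/bin/env Rscript
# Stage 3 — bisulfite-aware C->T SNP screen.
#
# Calls C->T SNPs from opposite-strand A/G evidence in the per-sample
# pileups, in merged-across-samples and per-sample modes, takes their
# union as the exclusion set, and scores the screen against the planted
# truth (error rate 0: hom sensitivity and specificity should be perfect).

suppressMessages(library(dmlscreen))

run_dir <- "results/run"
pileups <- read_pileups(list.files(file.path(run_dir, "pileups"),
                                   full.names = TRUE))

merged <- screen_genome(pileups, "merged")
per_sample <- screen_genome(pileups, "per_sample")
snps <- union_snp_sets(merged, per_sample)
write_snp_set(snps, file.path(run_dir, "snps.bed"), file.path(run_dir, "snps.vcf"))

truth <- data.table::fread(file.path(run_dir, "truth_snp.tsv"))
called_plus <- snps[strand == "+"]
hom_truth <- truth[genotype == "hom_CT"]
hom_sens <- mean(paste(hom_truth$chrom, hom_truth$pos) %in%
                   paste(called_plus$chrom, called_plus$pos))
false_pos <- sum(!(paste(called_plus$chrom, called_plus$pos) %in%
                     paste(truth$chrom, truth$pos)))

summary <- data.table::data.table(
  metric = c("n_merged_calls", "n_per_sample_calls", "n_union",
             "hom_sensitivity", "n_false_positive_plus_strand"),
  value = c(nrow(merged), nrow(per_sample), nrow(snps), hom_sens, false_pos))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(summary, "results/tables/snp_screen_summary.tsv", sep = "\t")

message(sprintf("%d exclusion positions (merged %d, per-sample %d); hom sensitivity %.2f, %d false positives",
                nrow(snps), nrow(merged), nrow(per_sample), hom_sens, false_pos))
message("summary -> results/tables/snp_screen_summary.tsv")
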