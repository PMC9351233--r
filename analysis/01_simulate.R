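#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic WGBS experiment.
#
# Generates a toy genome with a controlled CpG density, a nested
# gene/exon/CDS annotation, per-sample Bismark-style coverage tables for
# 2 pH treatments x 4 oysters with an ordinal maturation stage, strand-
# resolved pileups, and the truth tables (planted DML, planted C->T SNPs)
# used by later stages to measure recovery.

suppressMessages(library(dmlscreen))

run_dir <- "results/run"
seed <- 1L

cfg <- sim_config(genome_length_per_chrom = 100000, n_chroms = 2,
                  gc_cpg_density = 10, dml_fraction = 0.05, dml_effect = 60,
                  snp_fraction = 0.05, het_fraction = 0.3, mean_coverage = 30,
                  dispersion_rho = 0.05, error_rate = 0, seed = seed)

genome <- simulate_genome(cfg)
annotation <- simulate_annotation(genome, cfg)
counts <- simulate_counts(genome, annotation, cfg)
pileups <- simulate_pileups(genome, cfg, counts$truth)

dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
write_genome_fasta(genome, file.path(run_dir, "genome.fa"))
write_chrom_sizes(genome$sizes, file.path(run_dir, "chrom.sizes"))
write_annotation_gff3(annotation, file.path(run_dir, "annotation.gff3"))
write_track_bed(annotation$te, file.path(run_dir, "te.bed"))
write_bismark_cov(counts, file.path(run_dir, "coverage"))
write_pileups(pileups, file.path(run_dir, "pileups"))
write_truth_set(counts$truth, run_dir)
data.table::fwrite(counts$samples, file.path(run_dir, "samples.tsv"), sep = "\t")
g2g <- simulate_gene2go(unique(annotation$genes$gene_id), seed = seed)
data.table::fwrite(g2g, file.path(run_dir, "gene2go.tsv"), sep = "\t",
                   col.names = FALSE)

message(sprintf("simulated %d CpGs on %d chromosomes; %d planted DML, %d planted C->T SNPs",
                nrow(genome$cg), cfg$n_chroms,
                nrow(counts$truth$dml_truth), nrow(counts$truth$snp_truth)))
message("outputs under ", run_dir)
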