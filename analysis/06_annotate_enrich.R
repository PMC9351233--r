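#!/usr/bin/env Rscript
# Stage 6 — DML characterization and GO enrichment.
#
# Overlaps the retained DML with every feature track (one-base rule),
# tests the feature distribution of DML against the 5x CpG background
# with a chi-squared contingency test on the exclusive partition, tabulates
# DML per chromosome and per gene, and runs gene-level Fisher enrichment
# of GO terms (universe: genes with 5x CpGs; interest: genes with DML).

suppressMessages(library(dmlscreen))

run_dir <- "results/run"
genome <- read_genome_fasta(file.path(run_dir, "genome.fa"))
sizes <- read_chrom_sizes(file.path(run_dir, "chrom.sizes"))
ann <- read_annotation_gff3(file.path(run_dir, "annotation.gff3"),
                            stats::setNames(sizes$length, sizes$chrom))
te <- read_track_bed(file.path(run_dir, "te.bed"), sizes)
tracks <- build_feature_tracks(ann$genes, ann$exons, ann$cds, sizes, te = te)
dml <- data.table::fread(file.path(run_dir, "dml.tsv"))
background <- data.table::fread(file.path(run_dir, "united_matrix.tsv"))[
  , .(chrom, pos)]

dml_ov <- overlap_features(dml, tracks)
bg_ov <- overlap_features(background, tracks)
conting <- contingency_test(bg_ov$partition_counts, dml_ov$partition_counts)

cpg_chrom <- table(genome$cg$chrom)
gene_chrom <- table(as.character(GenomicRanges::seqnames(ann$genes)))
chrom_tab <- chromosome_density(dml, cpg_chrom, gene_chrom)
per_gene <- dml_per_gene(dml, ann$genes, sizes)

universe <- dml_interest_genes(background, ann$genes, sizes)
interest <- dml_interest_genes(dml, ann$genes, sizes)
enrich <- go_enrichment(interest, universe,
                        file.path(run_dir, "gene2go.tsv"), p_cutoff = 0.01)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(dml_ov$table, "results/tables/dml_feature_overlap.tsv", sep = "\t")
data.table::fwrite(bg_ov$table, "results/tables/background_feature_overlap.tsv", sep = "\t")
data.table::fwrite(chrom_tab, "results/tables/dml_per_chromosome.tsv", sep = "\t")
data.table::fwrite(per_gene, "results/tables/dml_per_gene.tsv", sep = "\t")
data.table::fwrite(enrich, "results/tables/go_enrichment.tsv", sep = "\t")

genic <- dml_ov$table[dml_ov$table$feature == "genic"]
message(sprintf("%d DML: %d genic (%.1f%%); feature-distribution chi2 = %.1f (df %d, p = %.3g)",
                dml_ov$n_loci, genic$n, genic$percent,
                conting$statistic, conting$df, conting$p_value))
message(sprintf("%d genes with DML (max %d DML in one gene); %d/%d GO terms at p < 0.01",
                nrow(per_gene), if (nrow(per_gene)) max(per_gene$n_dml) else 0L,
                sum(enrich$significant), nrow(enrich)))
message("tables under results/tables/")
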