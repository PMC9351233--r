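#!/usr/bin/env Rscript
# Stage 2 — derive genome feature tracks and count CpGs per feature.
#
# Reads the genome FASTA and GFF3 annotation written by stage 1, derives
# introns, exon UTRs, 1-kb flanks and intergenic regions by interval
# algebra, and counts CG motifs overlapping each class (one-base-overlap
# rule, so a class total can exceed the disjoint partition).

suppressMessages(library(dmlscreen))

run_dir <- "results/run"
genome <- read_genome_fasta(file.path(run_dir, "genome.fa"))
sizes <- read_chrom_sizes(file.path(run_dir, "chrom.sizes"))
ann <- read_annotation_gff3(file.path(run_dir, "annotation.gff3"),
                            stats::setNames(sizes$length, sizes$chrom))
te <- read_track_bed(file.path(run_dir, "te.bed"), sizes)

tracks <- build_feature_tracks(ann$genes, ann$exons, ann$cds, sizes, te = te)
cg <- find_cg_motifs(genome)

tab <- data.table::data.table(
  feature = names(tracks),
  n_cpg = vapply(tracks, function(tr) count_cpgs_in_track(cg, tr), integer(1)))
tab <- rbind(tab, data.table::data.table(feature = "genome", n_cpg = length(cg)))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
data.table::fwrite(tab, "results/tables/feature_cpg_counts.tsv", sep = "\t")
for (cls in c("intron", "exon_UTR", "flank_up", "flank_down", "intergenic")) {
  write_track_bed(tracks[[cls]], file.path(run_dir, paste0(cls, ".bed")))
}

message(sprintf("%d CG motifs; %d in genes (%.1f%%), %d in introns, %d intergenic",
                length(cg),
                tab[feature == "gene"]$n_cpg,
                100 * tab[feature == "gene"]$n_cpg / length(cg),
                tab[feature == "intron"]$n_cpg,
                tab[feature == "intergenic"]$n_cpg))
message("feature CpG counts -> results/tables/feature_cpg_counts.tsv")
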