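# End-to-end orchestration: simulate -> tracks -> snps -> methylation ->
# dml -> annotate -> enrich, with a machine-readable run report.

#' Pipeline configuration
#'
#' Collects the analysis thresholds (all defaulting to the pipeline's
#' canonical settings) together with the synthetic-experiment config used
#' when no external inputs are supplied.
#'
#' @param sim A [sim_config()] for the simulate stage.
#' @param lo_count Minimum per-sample CpG coverage (5).
#' @param high_perc Upper coverage percentile filter (99.9).
#' @param diff_cutoff DML methylation-difference threshold in points (50).
#' @param q_cutoff DML q-value threshold (0.01).
#' @param enrich_p GO enrichment significance threshold (0.01,
#'   uncorrected).
#' @param flank_width Gene flank width in bp (1000).
#' @param snp_min_cov,snp_het_min,snp_hom_min SNP-call thresholds.
#' @param seed Seed for the run (propagated into `sim`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), lo_count = 5,
                            high_perc = 99.9, diff_cutoff = 50,
                            q_cutoff = 0.01, enrich_p = 0.01,
                            flank_width = 1000, snp_min_cov = 5,
                            snp_het_min = 0.1, snp_hom_min = 0.85,
                            seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  assert_that(lo_count >= 1, "lo_count must be >= 1")
  assert_that(high_perc > 0 && high_perc <= 100, "high_perc must be in (0, 100]")
  assert_that(diff_cutoff > 0 && diff_cutoff <= 100, "diff_cutoff in (0, 100]")
  assert_that(q_cutoff > 0 && q_cutoff < 1, "q_cutoff in (0, 1)")
  structure(list(sim = sim, lo_count = lo_count, high_perc = high_perc,
                 diff_cutoff = diff_cutoff, q_cutoff = q_cutoff,
                 enrich_p = enrich_p, flank_width = flank_width,
                 snp_min_cov = snp_min_cov, snp_het_min = snp_het_min,
                 snp_hom_min = snp_hom_min),
            class = "pipeline_config")
}

#' Run the full pipeline on a synthetic experiment
#'
#' Executes every stage in canonical order on data generated from
#' `config$sim`, and assembles a run report whose accounting identities
#' (retained = candidates - SNP-removed; hyper + hypo = retained;
#' methylation-class counts summing to the united locus count) always
#' hold. Identical configs give identical reports.
#'
#' @param config A [pipeline_config()].
#' @param gene2go Optional gene-to-GO mapping for the enrichment stage;
#'   `NULL` simulates one from the annotation.
#' @param outdir Optional directory: when given, stage outputs (FASTA,
#'   GFF3, coverage files, SNP BED/VCF, united matrix, DML BED/TSV, report
#'   JSON) are written there.
#' @return A `pipeline_result` list: `report`, plus the stage objects
#'   (`genome`, `annotation`, `tracks`, `snps`, `matrix`, `dml`,
#'   `features`, `enrichment`, `truth`).
#' @export
run_pipeline <- function(config = pipeline_config(), gene2go = NULL,
                         outdir = NULL) {
  log_stage <- function(...) message(sprintf(...))

  # simulate
  log_stage("stage simulate: genome + annotation + counts + pileups")
  genome <- simulate_genome(config$sim)
  annotation <- simulate_annotation(genome, config$sim)
  counts <- simulate_counts(genome, annotation, config$sim)
  pileups <- simulate_pileups(genome, config$sim, counts$truth)
  log_stage("  %d CpGs, %d samples", nrow(genome$cg), nrow(counts$samples))

  # tracks
  log_stage("stage tracks: feature derivation")
  tracks <- build_feature_tracks(annotation$genes, annotation$exons,
                                 annotation$cds, genome$sizes,
                                 te = annotation$te, lncrna = annotation$lncrna,
                                 flank_width = config$flank_width)
  cg_gr <- find_cg_motifs(genome)

  # snps
  log_stage("stage snps: merged + per-sample screens")
  snps_merged <- screen_genome(pileups, "merged", config$snp_min_cov,
                               config$snp_het_min, config$snp_hom_min)
  snps_per <- screen_genome(pileups, "per_sample", config$snp_min_cov,
                            config$snp_het_min, config$snp_hom_min)
  snps <- union_snp_sets(snps_merged, snps_per)
  log_stage("  %d C->T exclusion positions", nrow(snps))

  # methylation
  log_stage("stage methylation: destrand -> filter -> normalize -> unite")
  destranded <- lapply(counts$coverage, destrand, cg_sites = genome)
  filtered <- lapply(destranded, filter_coverage, lo = config$lo_count,
                     high_percentile = config$high_perc)
  normalized <- normalize_coverage(filtered)
  mm <- unite_samples(normalized, counts$samples, min_cov = config$lo_count)
  excl <- apply_snp_exclusion(mm, snps)
  classes <- classify_loci(excl$matrix)
  log_stage("  %d united loci, %d SNP-excluded", nrow(mm$loci), excl$n_removed)

  # dml
  log_stage("stage dml: logistic LRT + SLIM q-values")
  results <- dml_test(mm, correct = TRUE, use_covariate = TRUE)
  called <- call_dml(results, snps, config$diff_cutoff, config$q_cutoff)
  acc <- called$accounting
  log_stage("  %d candidates, %d SNP-removed, %d retained",
            acc$n_candidates, acc$n_snp_removed, acc$n_retained)

  # annotate
  log_stage("stage annotate: feature overlap + contingency + densities")
  bg_overlap <- overlap_features(excl$matrix$loci, tracks)
  dml_overlap <- overlap_features(called$dml, tracks)
  conting <- if (acc$n_retained > 0) {
    contingency_test(bg_overlap$partition_counts, dml_overlap$partition_counts)
  } else NULL
  cpg_chrom <- table(genome$cg$chrom)
  gene_chrom <- table(as.character(GenomicRanges::seqnames(annotation$genes)))
  chrom_tab <- chromosome_density(called$dml, cpg_chrom, gene_chrom)
  per_gene <- dml_per_gene(called$dml, annotation$genes, genome$sizes)

  # enrich
  log_stage("stage enrich: GO Fisher tests")
  if (is.null(gene2go)) {
    gene2go <- simulate_gene2go(unique(annotation$genes$gene_id),
                                seed = config$sim$seed + 6L)
  }
  universe <- dml_interest_genes(excl$matrix$loci, annotation$genes,
                                 genome$sizes)
  interest <- dml_interest_genes(called$dml, annotation$genes, genome$sizes)
  enrichment <- if (length(interest) > 0 && length(universe) > 0) {
    go_enrichment(interest, universe, gene2go, p_cutoff = config$enrich_p)
  } else NULL

  report <- list(
    config = list(lo_count = config$lo_count, high_perc = config$high_perc,
                  diff_cutoff = config$diff_cutoff, q_cutoff = config$q_cutoff,
                  enrich_p = config$enrich_p, flank_width = config$flank_width,
                  snp_min_cov = config$snp_min_cov,
                  snp_het_min = config$snp_het_min,
                  snp_hom_min = config$snp_hom_min,
                  sim = unclass(config$sim)),
    n_cpg = nrow(genome$cg),
    n_samples = nrow(counts$samples),
    n_snp_exclusion = nrow(snps),
    n_united = nrow(mm$loci),
    n_united_after_snp = nrow(excl$matrix$loci),
    n_class_excluded = excl$n_removed,
    class_summary = classes$summary,
    accounting = acc,
    pi0 = attr(results, "pi0"),
    background_features = bg_overlap$table,
    dml_features = dml_overlap$table,
    contingency = if (is.null(conting)) NULL else
      conting[c("statistic", "df", "p_value")],
    chromosome_density = chrom_tab,
    n_interest_genes = length(interest),
    n_universe_genes = length(universe),
    n_enriched_terms = if (is.null(enrichment)) 0L else
      sum(enrichment$significant)
  )

  out <- list(report = report, genome = genome, annotation = annotation,
              tracks = tracks, snps = snps, matrix = mm,
              matrix_snp_excluded = excl$matrix, classes = classes,
              results = results, dml = called$dml,
              candidates = called$candidates, features = dml_overlap,
              background_features = bg_overlap, chromosome_density = chrom_tab,
              dml_per_gene = per_gene, enrichment = enrichment,
              truth = counts$truth, samples = counts$samples)
  class(out) <- "pipeline_result"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(genome, file.path(outdir, "genome.fa"))
    write_annotation_gff3(annotation, file.path(outdir, "annotation.gff3"))
    write_chrom_sizes(genome$sizes, file.path(outdir, "chrom.sizes"))
    write_bismark_cov(counts, file.path(outdir, "coverage"))
    write_pileups(pileups, file.path(outdir, "pileups"))
    write_truth_set(counts$truth, outdir)
    write_snp_set(snps, file.path(outdir, "snps.bed"),
                  file.path(outdir, "snps.vcf"))
    write_methyl_matrix(mm, file.path(outdir, "united_matrix.tsv"))
    write_cpg_bedgraph(excl$matrix, file.path(outdir, "cpg_5x.bedgraph"))
    write_dml(called$dml, file.path(outdir, "dml.bed"),
              file.path(outdir, "dml.tsv"))
    write_run_report(report, file.path(outdir, "report.json"))
  }
  out
}

#' Write a run report as JSON
#' @param report Report list from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, null = "null")
  invisible(path)
}
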