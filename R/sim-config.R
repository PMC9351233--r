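#' Configuration for the synthetic WGBS experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the pipeline targets: two pH treatments (low pH vs
#' ambient) with four female oysters each, an ordinal gonad maturation stage
#' (0 = indeterminate to 3 = spawn-ready mature female) as covariate,
#' beta-binomially overdispersed CpG methylation counts at roughly 30x
#' coverage, a minority of loci carrying a planted treatment effect of at
#' least 50 percentage points (the callable threshold), and a small fraction
#' of CpG cytosines carrying a planted C->T SNP.
#'
#' @param genome_length_per_chrom Bases per chromosome.
#' @param n_chroms Number of chromosomes.
#' @param gc_cpg_density Planted CpG dinucleotides per kilobase.
#' @param n_samples_per_group Samples per treatment group.
#' @param covariate_levels Ordinal maturation stages sampled per animal.
#' @param baseline_meth_mixture Named weights (`low`, `mid`, `high`) for the
#'   baseline methylation strata; defaults mirror the heavily low-methylated
#'   landscape of an invertebrate genome.
#' @param dml_fraction Proportion of CpG loci with a planted treatment effect.
#' @param dml_effect Planted methylation difference in percentage points;
#'   must lie in (0, 100].
#' @param stage_effect Covariate effect on the logit scale per maturation
#'   stage unit.
#' @param snp_fraction Proportion of CpG cytosines with a planted C->T SNP.
#' @param het_fraction Proportion of planted SNPs that are heterozygous.
#' @param mean_coverage Mean read coverage per strand-site (negative
#'   binomial).
#' @param nb_size Negative-binomial size (dispersion) of coverage.
#' @param dispersion_rho Beta-binomial intra-site correlation in [0, 1);
#'   0 gives pure binomial counts.
#' @param error_rate Per-base sequencing error probability.
#' @param snp_both_strands Plant homozygous SNPs on both CpG strand
#'   positions of the pileup (default plants on the plus-strand C only).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length_per_chrom = 50000,
                       n_chroms = 2,
                       gc_cpg_density = 10,
                       n_samples_per_group = 4,
                       covariate_levels = 0:3,
                       baseline_meth_mixture = c(low = 0.82, mid = 0.09, high = 0.09),
                       dml_fraction = 0.02,
                       dml_effect = 60,
                       stage_effect = 0.3,
                       snp_fraction = 0.05,
                       het_fraction = 0.3,
                       mean_coverage = 30,
                       nb_size = 10,
                       dispersion_rho = 0.05,
                       error_rate = 0,
                       snp_both_strands = FALSE,
                       seed = 1L) {
  cfg <- list(
    genome_length_per_chrom = as.integer(genome_length_per_chrom),
    n_chroms = as.integer(n_chroms),
    gc_cpg_density = gc_cpg_density,
    n_samples_per_group = as.integer(n_samples_per_group),
    covariate_levels = as.integer(covariate_levels),
    baseline_meth_mixture = baseline_meth_mixture,
    dml_fraction = dml_fraction,
    dml_effect = dml_effect,
    stage_effect = stage_effect,
    snp_fraction = snp_fraction,
    het_fraction = het_fraction,
    mean_coverage = mean_coverage,
    nb_size = nb_size,
    dispersion_rho = dispersion_rho,
    error_rate = error_rate,
    snp_both_strands = isTRUE(snp_both_strands),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  assert_that(cfg$genome_length_per_chrom > 0L, "genome_length_per_chrom must be positive")
  assert_that(cfg$n_chroms > 0L, "n_chroms must be positive")
  assert_that(cfg$gc_cpg_density > 0, "gc_cpg_density must be positive")
  assert_that(cfg$n_samples_per_group >= 1L, "need at least one sample per group")
  for (f in c("dml_fraction", "snp_fraction", "het_fraction", "error_rate")) {
    assert_that(cfg[[f]] >= 0 && cfg[[f]] <= 1, "%s must be in [0, 1]", f)
  }
  assert_that(cfg$dml_effect > 0 && cfg$dml_effect <= 100,
              "dml_effect must be in (0, 100]")
  assert_that(cfg$mean_coverage >= 1, "mean_coverage must be >= 1")
  assert_that(cfg$dispersion_rho >= 0 && cfg$dispersion_rho < 1,
              "dispersion_rho must be in [0, 1)")
  mix <- cfg$baseline_meth_mixture
  assert_that(length(mix) == 3 && all(c("low", "mid", "high") %in% names(mix)),
              "baseline_meth_mixture needs named weights low/mid/high")
  assert_that(all(mix >= 0) && sum(mix) > 0, "mixture weights must be non-negative")
  invisible(cfg)
}
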