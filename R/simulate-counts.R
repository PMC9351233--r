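# Synthetic methylation counts and strand-resolved pileups.
#
# The generator works at the post-alignment abstraction: it emits per-sample
# Bismark-coverage-style count records and per-cytosine pileups directly,
# with planted differential methylation, an ordinal maturation covariate,
# beta-binomial overdispersion, and planted C->T SNPs.

# Draw per-locus baseline methylation, planted DML effects and planted SNPs.
# Shared by simulate_counts() and simulate_pileups() so that, under one
# config, both views describe the same underlying experiment.
#' @keywords internal
sim_locus_params <- function(genome, config) {
  set.seed(config$seed + 2L)
  cg <- data.table::copy(genome$cg)
  n <- nrow(cg)
  mix <- config$baseline_meth_mixture / sum(config$baseline_meth_mixture)
  stratum <- sample(c("low", "mid", "high"), n, replace = TRUE, prob = mix[c("low", "mid", "high")])
  base_p <- numeric(n)
  base_p[stratum == "low"] <- stats::runif(sum(stratum == "low"), 0.01, 0.08)
  base_p[stratum == "mid"] <- stats::runif(sum(stratum == "mid"), 0.15, 0.45)
  base_p[stratum == "high"] <- stats::runif(sum(stratum == "high"), 0.70, 0.95)
  cg[, `:=`(stratum = stratum, p_ctl = base_p, p_trt = base_p,
            is_dml = FALSE, effect = 0)]

  n_dml <- round(n * config$dml_fraction)
  if (n_dml > 0) {
    e <- config$dml_effect / 100
    idx <- sample.int(n, n_dml)
    dir <- sample(c(1, -1), n_dml, replace = TRUE)
    lo <- 0.02
    hi <- 0.98
    pc <- ifelse(dir > 0, stats::runif(n_dml, lo, hi - e), stats::runif(n_dml, lo + e, hi))
    pt <- pc + dir * e
    cg[idx, `:=`(p_ctl = pc, p_trt = pt, is_dml = TRUE,
                 effect = dir * config$dml_effect)]
  }

  cg[, genotype := "ref"]
  n_snp <- round(n * config$snp_fraction)
  if (n_snp > 0) {
    idx <- sample.int(n, n_snp)  # may overlap planted DML, deliberately
    het <- stats::runif(n_snp) < config$het_fraction
    cg[idx, genotype := ifelse(het, "het_CT", "hom_CT")]
  }
  cg[]
}

#' @keywords internal
sim_samples <- function(config) {
  set.seed(config$seed + 3L)
  n <- config$n_samples_per_group
  data.table::data.table(
    sample_id = c(sprintf("lowpH_%d", seq_len(n)), sprintf("ambient_%d", seq_len(n))),
    treatment = rep(c("low_pH", "ambient"), each = n),
    stage = sample(config$covariate_levels, 2L * n, replace = TRUE)
  )
}

# Sample-and-locus-level methylation probability: group baseline shifted on
# the logit scale by the (centered) maturation stage, then modified by any
# planted SNP (hom: reads all appear unmethylated; het: apparent methylation
# halved) and by the symmetric read error rate.
#' @keywords internal
apparent_p <- function(p_group, stage, config) {
  p <- pmin(pmax(p_group, 1e-4), 1 - 1e-4)
  shift <- config$stage_effect * (stage - mean(config$covariate_levels))
  stats::plogis(stats::qlogis(p) + shift)
}

#' Simulate per-sample CpG methylation count tables with a truth set
#'
#' For every CpG the plus-strand C (position p) and minus-strand C
#' (position p + 1) each receive an independent negative-binomial coverage
#' draw; methylated counts are beta-binomial around a shared per-locus,
#' per-sample methylation probability so that destranded counts keep the
#' configured intra-site correlation. Planted homozygous C->T SNPs force all
#' reads at the locus to appear unmethylated; heterozygous SNPs halve the
#' apparent methylation in expectation. Strand-positions whose coverage draw
#' is zero are absent from the output, matching Bismark coverage-file
#' semantics.
#'
#' @param genome A `sim_genome`.
#' @param annotation Optional annotation list (used only to attach feature
#'   membership to the truth set).
#' @param config A [sim_config()].
#' @return A `sim_counts` list: `samples` (metadata), `coverage` (named list
#'   of per-sample data.tables: `chrom`, `pos`, `strand`, `count_meth`,
#'   `count_unmeth`), and `truth` (a `truth_set`: `dml_truth`, `snp_truth`,
#'   `locus_params`, optional `feature_membership`).
#' @export
simulate_counts <- function(genome, annotation = NULL, config = sim_config()) {
  params <- sim_locus_params(genome, config)
  samples <- sim_samples(config)
  set.seed(config$seed + 4L)
  n_loci <- nrow(params)
  rho <- config$dispersion_rho
  err <- config$error_rate

  coverage <- vector("list", nrow(samples))
  names(coverage) <- samples$sample_id
  for (s in seq_len(nrow(samples))) {
    p_group <- if (samples$treatment[s] == "low_pH") params$p_trt else params$p_ctl
    p <- apparent_p(p_group, samples$stage[s], config)
    p[params$genotype == "hom_CT"] <- 0
    het <- params$genotype == "het_CT"
    p[het] <- p[het] / 2
    # one beta draw per locus-sample, shared by both strands
    if (rho > 0) {
      a <- p * (1 - rho) / rho
      b <- (1 - p) * (1 - rho) / rho
      p_site <- ifelse(p <= 0, 0, ifelse(p >= 1, 1, stats::rbeta(n_loci, a, b)))
    } else {
      p_site <- p
    }
    p_obs <- p_site * (1 - err) + (1 - p_site) * err
    strand_rows <- lapply(c("+", "-"), function(st) {
      cov <- stats::rnbinom(n_loci, mu = config$mean_coverage, size = config$nb_size)
      m <- stats::rbinom(n_loci, cov, p_obs)
      keep <- cov > 0
      data.table::data.table(
        chrom = params$chrom[keep],
        pos = params$start[keep] + (st == "-"),
        strand = st,
        count_meth = m[keep],
        count_unmeth = cov[keep] - m[keep])
    })
    dt <- data.table::rbindlist(strand_rows)
    data.table::setorder(dt, chrom, pos)
    coverage[[s]] <- dt
  }

  truth <- list(
    dml_truth = params[params$is_dml == TRUE,
                       .(chrom, pos = start, effect, p_ctl, p_trt)],
    snp_truth = params[params$genotype != "ref",
                       .(chrom, pos = start, genotype)],
    locus_params = params
  )
  if (!is.null(annotation)) {
    tracks <- build_feature_tracks(annotation$genes, annotation$exons,
                                   annotation$cds, genome$sizes,
                                   te = annotation$te, lncrna = annotation$lncrna)
    loci <- cpg_granges(params$chrom, params$start, genome$sizes)
    truth$feature_membership <- data.table::data.table(
      chrom = params$chrom, pos = params$start,
      feature = locus_partition(loci, tracks))
  }
  class(truth) <- "truth_set"
  structure(list(samples = samples, coverage = coverage, truth = truth),
            class = "sim_counts")
}

#' Simulate strand-resolved base pileups at CpG cytosines
#'
#' Emits, per sample and per CpG strand-position, the read base counts on
#' the strand carrying the reference cytosine and on the opposite strand.
#' At a non-SNP site the opposite strand reads G (pairing the reference C or
#' its bisulfite-converted T); at a planted homozygous C->T SNP it reads A;
#' at a heterozygote roughly half A, half G. Sequencing error moves each
#' read to one of the three other bases uniformly.
#'
#' @param genome A `sim_genome`.
#' @param config A [sim_config()].
#' @param truth Optional `truth_set` from [simulate_counts()]; when absent
#'   the same per-locus parameters are regenerated from the config seed, so
#'   pileups and counts describe the same experiment.
#' @return A `sim_pileups` list: `samples` and `pileups` (named list of
#'   per-sample data.tables with columns `chrom`, `pos`, `strand`,
#'   `this_A/C/G/T`, `opp_A/C/G/T`).
#' @export
simulate_pileups <- function(genome, config = sim_config(), truth = NULL) {
  params <- if (is.null(truth)) sim_locus_params(genome, config) else truth$locus_params
  samples <- sim_samples(config)
  set.seed(config$seed + 5L)
  n <- nrow(params)
  err <- config$error_rate

  # distribute reads of one true base across reported bases under uniform error
  spread_error <- function(counts_true, base) {
    out <- matrix(0L, nrow = length(counts_true), ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    if (err <= 0) { out[, base] <- counts_true; return(out) }
    probs <- stats::setNames(rep(err / 3, 4), c("A", "C", "G", "T"))
    probs[base] <- 1 - err
    for (i in seq_along(counts_true)) {
      out[i, ] <- stats::rmultinom(1, counts_true[i], probs)
    }
    out
  }

  pileups <- vector("list", nrow(samples))
  names(pileups) <- samples$sample_id
  for (s in seq_len(nrow(samples))) {
    p_group <- if (samples$treatment[s] == "low_pH") params$p_trt else params$p_ctl
    p <- apparent_p(p_group, samples$stage[s], config)
    per_strand <- lapply(c("+", "-"), function(st) {
      hom_here <- params$genotype == "hom_CT" & (st == "+" | config$snp_both_strands)
      # a hom SNP on the plus C destroys the CpG: the minus-strand C is left in
      # non-CpG context and reads unmethylated even when only one strand is planted
      p_here <- ifelse(params$genotype == "hom_CT", 0,
                       ifelse(params$genotype == "het_CT", p / 2, p))
      cov_this <- stats::rnbinom(n, mu = config$mean_coverage, size = config$nb_size)
      cov_opp <- stats::rnbinom(n, mu = config$mean_coverage, size = config$nb_size)
      n_C <- stats::rbinom(n, cov_this, ifelse(hom_here, 0, p_here))
      n_T <- cov_this - n_C
      het_here <- params$genotype == "het_CT" & (st == "+" | config$snp_both_strands)
      opp_A_frac <- ifelse(hom_here, 1, ifelse(het_here, 0.5, 0))
      n_A <- stats::rbinom(n, cov_opp, opp_A_frac)
      n_G <- cov_opp - n_A
      this_counts <- spread_error(n_C, "C") + spread_error(n_T, "T")
      opp_counts <- spread_error(n_A, "A") + spread_error(n_G, "G")
      data.table::data.table(
        chrom = params$chrom, pos = params$start + (st == "-"), strand = st,
        this_A = this_counts[, "A"], this_C = this_counts[, "C"],
        this_G = this_counts[, "G"], this_T = this_counts[, "T"],
        opp_A = opp_counts[, "A"], opp_C = opp_counts[, "C"],
        opp_G = opp_counts[, "G"], opp_T = opp_counts[, "T"])
    })
    dt <- data.table::rbindlist(per_strand)
    data.table::setorder(dt, chrom, pos)
    pileups[[s]] <- dt
  }
  structure(list(samples = samples, pileups = pileups), class = "sim_pileups")
}

#' Simulate a gene-to-GO-term mapping
#'
#' Assigns each gene a Poisson number of GO identifiers drawn from a shared
#' term pool, for exercising the enrichment stage.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param n_terms Size of the GO term pool.
#' @param terms_per_gene Mean number of terms per gene.
#' @param seed Integer seed.
#' @return data.table with columns `gene_id`, `go_ids` (comma-separated).
#' @export
simulate_gene2go <- function(gene_ids, n_terms = 50, terms_per_gene = 3, seed = 1L) {
  set.seed(seed)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  go <- vapply(gene_ids, function(g) {
    k <- min(n_terms, stats::rpois(1, terms_per_gene))
    if (k == 0) "" else paste(sample(terms, k), collapse = ",")
  }, character(1))
  data.table::data.table(gene_id = gene_ids, go_ids = unname(go))[go != ""]
}

#' Write per-sample methylation counts as Bismark-style coverage files
#'
#' Columns: chromosome, 1-based position, 1-based position, percent
#' methylation, count methylated, count unmethylated.
#'
#' @param sim A `sim_counts` object (or a named list of coverage tables).
#' @param dir Output directory; one `<sample>.cov` file per sample.
#' @return Named character vector of file paths, invisibly.
#' @export
write_bismark_cov <- function(sim, dir) {
  tabs <- if (inherits(sim, "sim_counts")) sim$coverage else sim
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(file.path(dir, paste0(names(tabs), ".cov")), names(tabs))
  for (nm in names(tabs)) {
    dt <- tabs[[nm]]
    out <- data.table::data.table(
      chrom = dt$chrom, start = dt$pos, end = dt$pos,
      pct = round(100 * dt$count_meth / (dt$count_meth + dt$count_unmeth), 6),
      count_meth = dt$count_meth, count_unmeth = dt$count_unmeth)
    data.table::fwrite(out, paths[[nm]], sep = "\t", col.names = FALSE)
  }
  invisible(paths)
}

#' Read Bismark coverage files
#' @param paths Named character vector of coverage files (names become
#'   sample ids; unnamed paths use the file base name).
#' @return Named list of data.tables: `chrom`, `pos`, `count_meth`,
#'   `count_unmeth`.
#' @export
read_bismark_cov <- function(paths) {
  if (is.null(names(paths))) names(paths) <- sub("\\.cov(\\.gz)?$", "", basename(paths))
  lapply(paths, function(p) {
    dt <- data.table::fread(p, header = FALSE,
                            col.names = c("chrom", "pos", "end", "pct",
                                          "count_meth", "count_unmeth"))
    dt[, .(chrom, pos, count_meth, count_unmeth)]
  })
}

#' Write per-sample pileup tables
#' @param sim A `sim_pileups` object.
#' @param dir Output directory; one `<sample>.pileup.tsv` per sample.
#' @return Named character vector of paths, invisibly.
#' @export
write_pileups <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(file.path(dir, paste0(names(sim$pileups), ".pileup.tsv")),
                           names(sim$pileups))
  for (nm in names(sim$pileups)) {
    data.table::fwrite(sim$pileups[[nm]], paths[[nm]], sep = "\t")
  }
  invisible(paths)
}

#' Read pileup tables written by [write_pileups()]
#' @param paths Named character vector of pileup files.
#' @return Named list of data.tables.
#' @export
read_pileups <- function(paths) {
  if (is.null(names(paths))) names(paths) <- sub("\\.pileup\\.tsv$", "", basename(paths))
  lapply(paths, data.table::fread)
}

#' Write the simulation truth tables
#' @param truth A `truth_set`.
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_truth_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dml = file.path(dir, "truth_dml.tsv"),
             snp = file.path(dir, "truth_snp.tsv"))
  data.table::fwrite(truth$dml_truth, paths[["dml"]], sep = "\t")
  data.table::fwrite(truth$snp_truth, paths[["snp"]], sep = "\t")
  if (!is.null(truth$feature_membership)) {
    paths <- c(paths, features = file.path(dir, "truth_features.tsv"))
    data.table::fwrite(truth$feature_membership, paths[["features"]], sep = "\t")
  }
  invisible(paths)
}
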