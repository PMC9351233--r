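# From per-sample coverage records to a united methylation matrix.
#
# Canonical order: destrand -> filter -> normalize -> unite -> SNP-exclude.

#' Consolidate CpG counts between strands
#'
#' The plus-strand C at position p and the minus-strand C at position p + 1
#' of the same CpG are summed and reported at 1-based position p. A
#' minus-strand record with no plus partner is kept and reported at its
#' CpG's start. Records at positions that are not CpG cytosines are
#' dropped.
#'
#' @param records data.table with `chrom`, `pos`, `count_meth`,
#'   `count_unmeth` (a `strand` column, if present, is ignored: position
#'   within the CpG identifies the strand).
#' @param cg_sites CpG positions: a data.table with `chrom`, `start`
#'   (1-based plus-strand C), a GRanges of CG motifs, or a `sim_genome`.
#' @return data.table `chrom`, `pos` (destranded), `count_meth`,
#'   `count_unmeth`.
#' @export
destrand <- function(records, cg_sites) {
  cg <- cg_lookup(cg_sites)
  lookup <- data.table::rbindlist(list(
    data.table::data.table(chrom = cg$chrom, pos = cg$start, cpg = cg$start),
    data.table::data.table(chrom = cg$chrom, pos = cg$start + 1L, cpg = cg$start)))
  dt <- data.table::as.data.table(records)
  dt <- merge(dt, lookup, by = c("chrom", "pos"))
  out <- dt[, .(count_meth = sum(count_meth), count_unmeth = sum(count_unmeth)),
            by = .(chrom, pos = cpg)]
  data.table::setorder(out, chrom, pos)
  out[]
}

#' @keywords internal
cg_lookup <- function(cg_sites) {
  if (inherits(cg_sites, "sim_genome")) return(cg_sites$cg)
  if (inherits(cg_sites, "GRanges")) {
    return(data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(cg_sites)),
      start = GenomicRanges::start(cg_sites)))
  }
  data.table::as.data.table(cg_sites)
}

#' Coverage filtering per sample
#'
#' Drops loci below `lo` coverage and loci above the sample's
#' `high_percentile`-th coverage percentile (a PCR-duplicate guard). The
#' percentile uses linear interpolation between order statistics
#' (`quantile` type 7).
#'
#' @param records Destranded data.table for one sample.
#' @param lo Minimum coverage (default 5).
#' @param high_percentile Upper percentile cut, default 99.9.
#' @return Filtered data.table.
#' @export
filter_coverage <- function(records, lo = 5, high_percentile = 99.9) {
  dt <- data.table::as.data.table(records)
  cov <- dt$count_meth + dt$count_unmeth
  hi <- stats::quantile(cov, high_percentile / 100, type = 7, names = FALSE)
  out <- dt[cov >= lo & cov <= hi]
  if (nrow(out) == 0) warning("no loci survive coverage filtering")
  out
}

#' Normalize coverage across samples
#'
#' Scales each sample's counts by (median of all samples' median coverages)
#' / (sample's median coverage), so no sample dominates downstream tests by
#' read depth. Counts are rounded half away from zero; a locus whose
#' scaled coverage would reach zero is floored at coverage 1.
#'
#' @param records_list Named list of per-sample destranded+filtered
#'   data.tables.
#' @return Named list of scaled data.tables, with scaling factors attached
#'   as attribute `factors`.
#' @export
normalize_coverage <- function(records_list) {
  med <- vapply(records_list, function(dt) {
    stats::median(dt$count_meth + dt$count_unmeth)
  }, numeric(1))
  assert_that(all(med > 0), "zero median coverage in at least one sample")
  ref <- stats::median(med)
  factors <- ref / med
  out <- Map(function(dt, f) {
    dt <- data.table::copy(dt)
    m_raw <- dt$count_meth * f
    u_raw <- dt$count_unmeth * f
    m <- round_half_away(m_raw)
    u <- round_half_away(u_raw)
    zero <- m + u == 0
    if (any(zero)) {
      bump_meth <- m_raw[zero] >= u_raw[zero]
      m[zero][bump_meth] <- 1
      u[zero][!bump_meth] <- 1
    }
    dt[, `:=`(count_meth = as.integer(m), count_unmeth = as.integer(u))]
    dt
  }, records_list, factors)
  attr(out, "factors") <- factors
  out
}

#' Unite samples into a methylation matrix
#'
#' Retains only loci covered at `min_cov` or more in every sample: the CpG
#' background for differential testing and for the enrichment gene
#' universe.
#'
#' @param records_list Named list of per-sample destranded data.tables.
#' @param samples data.frame with `sample_id`, `treatment` (`low_pH` /
#'   `ambient`) and `stage` (ordinal 0-3); row order fixes column order.
#' @param min_cov Minimum per-sample coverage at a retained locus.
#' @return A `methyl_matrix`: list with `loci` (data.table `chrom`, `pos`),
#'   `M` and `U` (loci x samples integer matrices) and `samples`.
#' @export
unite_samples <- function(records_list, samples, min_cov = 5) {
  samples <- data.table::as.data.table(samples)
  assert_that(all(samples$sample_id %in% names(records_list)),
              "records missing for some samples")
  tabs <- lapply(samples$sample_id, function(id) {
    dt <- records_list[[id]]
    dt[dt$count_meth + dt$count_unmeth >= min_cov,
       .(chrom, pos, count_meth, count_unmeth)]
  })
  common <- tabs[[1]][, .(chrom, pos)]
  for (i in seq_along(tabs)[-1]) {
    common <- merge(common, tabs[[i]][, .(chrom, pos)], by = c("chrom", "pos"))
  }
  data.table::setorder(common, chrom, pos)
  if (nrow(common) == 0) warning("no loci covered in all samples")
  M <- U <- matrix(0L, nrow = nrow(common), ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  for (i in seq_along(tabs)) {
    dt <- merge(common, tabs[[i]], by = c("chrom", "pos"), sort = FALSE)
    data.table::setorder(dt, chrom, pos)
    M[, i] <- dt$count_meth
    U[, i] <- dt$count_unmeth
  }
  structure(list(loci = common, M = M, U = U, samples = samples),
            class = "methyl_matrix")
}

#' Remove loci overlapping a C->T SNP exclusion set
#'
#' A destranded CpG locus at position p is removed when the SNP set
#' contains either of its strand positions (p or p + 1).
#'
#' @param mm A `methyl_matrix`.
#' @param snps A `snp_set` (or data.table with `chrom`, `pos`).
#' @return List: `matrix` (filtered `methyl_matrix`) and `n_removed`.
#' @export
apply_snp_exclusion <- function(mm, snps) {
  if (is.null(snps) || nrow(snps) == 0) {
    return(list(matrix = mm, n_removed = 0L))
  }
  hit <- snp_overlap_flag(mm$loci, snps)
  out <- mm
  out$loci <- mm$loci[!hit]
  out$M <- mm$M[!hit, , drop = FALSE]
  out$U <- mm$U[!hit, , drop = FALSE]
  list(matrix = out, n_removed = sum(hit))
}

#' @keywords internal
snp_overlap_flag <- function(loci, snps) {
  snp_key <- unique(data.table::data.table(chrom = snps$chrom, pos = snps$pos))
  plus <- paste(loci$chrom, loci$pos)
  minus <- paste(loci$chrom, loci$pos + 1L)
  keys <- paste(snp_key$chrom, snp_key$pos)
  plus %in% keys | minus %in% keys
}

#' Percent methylation per locus and sample
#' @param mm A `methyl_matrix`.
#' @return Numeric matrix (loci x samples) of percentages.
#' @export
percent_methylation <- function(mm) {
  100 * mm$M / (mm$M + mm$U)
}

#' Classify loci into high / moderate / low methylation
#'
#' Per-locus percent methylation is the coverage-weighted pooled mean
#' across samples (total methylated reads over total reads); set
#' `weighted = FALSE` for the unweighted mean of per-sample percentages.
#' Classes: high when percent >= 50, low when percent <= 10, moderate in
#' between (boundaries inclusive on the high/low side).
#'
#' @param mm A `methyl_matrix`.
#' @param weighted Use pooled (coverage-weighted) percent, default `TRUE`.
#' @return List: `loci` (data.table with `percent` and `class`) and
#'   `summary` (counts and percentages per class).
#' @export
classify_loci <- function(mm, weighted = TRUE) {
  pct <- if (weighted) {
    100 * rowSums(mm$M) / rowSums(mm$M + mm$U)
  } else {
    rowMeans(percent_methylation(mm))
  }
  cls <- ifelse(pct >= 50, "high", ifelse(pct <= 10, "low", "moderate"))
  loci <- data.table::copy(mm$loci)[, `:=`(percent = pct, class = cls)]
  counts <- table(factor(cls, levels = c("low", "moderate", "high")))
  summary <- data.table::data.table(
    class = names(counts),
    n = as.integer(counts),
    percent = round(100 * as.integer(counts) / max(1L, length(cls)), 1))
  list(loci = loci[], summary = summary)
}

#' Pairwise Pearson correlations between sample methylation profiles
#'
#' @param mm A `methyl_matrix`.
#' @return Symmetric correlation matrix with unit diagonal; a constant
#'   sample column yields `NA` entries with a warning.
#' @export
sample_correlations <- function(mm) {
  pct <- percent_methylation(mm)
  const <- apply(pct, 2, function(x) stats::sd(x) == 0 || is.na(stats::sd(x)))
  if (any(const)) {
    warning("constant percent-methylation column(s): ",
            paste(colnames(pct)[const], collapse = ", "))
  }
  suppressWarnings(stats::cor(pct, use = "pairwise.complete.obs"))
}

#' PCA of sample methylation profiles
#'
#' Principal components of the centered percent-methylation matrix, samples
#' as observations.
#'
#' @param mm A `methyl_matrix`.
#' @return List: `scores` (samples x PCs), `explained` (variance
#'   fractions), and the `prcomp` fit.
#' @export
sample_pca <- function(mm) {
  pct <- percent_methylation(mm)
  fit <- stats::prcomp(t(pct), center = TRUE, scale. = FALSE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, explained = explained, fit = fit)
}

#' Write a united matrix as TSV
#' @param mm A `methyl_matrix`.
#' @param path Output file: chrom, pos, then per-sample M/U columns.
#' @return `path`, invisibly.
#' @export
write_methyl_matrix <- function(mm, path) {
  dt <- data.table::copy(mm$loci)
  for (id in colnames(mm$M)) {
    dt[, (paste0(id, "_M")) := mm$M[, id]]
    dt[, (paste0(id, "_U")) := mm$U[, id]]
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write covered-CpG positions as a BEDgraph track
#' @param mm A `methyl_matrix`.
#' @param path Output file; score is the pooled percent methylation.
#' @return `path`, invisibly.
#' @export
write_cpg_bedgraph <- function(mm, path) {
  pct <- 100 * rowSums(mm$M) / rowSums(mm$M + mm$U)
  dt <- data.table::data.table(chrom = mm$loci$chrom, start = mm$loci$pos - 1L,
                               end = mm$loci$pos + 1L, score = round(pct, 2))
  con <- file(path, "w")
  writeLines('track type=bedGraph name="CpG_5x"', con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}
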