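# Bisulfite-aware C->T SNP screening.
#
# Bisulfite conversion makes a C->T SNP indistinguishable from an
# unmethylated cytosine on the read strand: both appear as T. The opposite
# strand disambiguates: a T paired with an adenine is a genuine C->T SNP,
# while a T paired with a guanine is a bisulfite-converted unmethylated C.
# Calls therefore use only opposite-strand A/G evidence.

#' Call the SNP genotype of reference-C positions from pileup counts
#'
#' Vectorized over rows of a pileup table. With f = A / (A + G) on the
#' opposite strand and coverage = A + G: coverage below `min_cov` gives no
#' call (`ref`); f at or above `hom_min` a homozygous C->T call; f between
#' `het_min` and `hom_min` a heterozygous call; anything else `ref`.
#' This-strand T counts never contribute evidence.
#'
#' @param pileup data.table with at least `opp_A` and `opp_G` (typically
#'   also `chrom`, `pos`, `strand`, carried through).
#' @param min_cov Minimum informative (opposite-strand A+G) coverage.
#' @param het_min,hom_min Allele-fraction thresholds for het/hom calls.
#' @return data.table: input positions plus `genotype` (`hom_CT`, `het_CT`,
#'   `ref`) and `alt_allele_fraction`.
#' @export
call_site <- function(pileup, min_cov = 5, het_min = 0.1, hom_min = 0.85) {
  assert_that(all(pileup$opp_A >= 0) && all(pileup$opp_G >= 0),
              "negative pileup counts")
  cov <- pileup$opp_A + pileup$opp_G
  f <- ifelse(cov > 0, pileup$opp_A / cov, NA_real_)
  genotype <- rep("ref", nrow(pileup))
  callable <- cov >= min_cov
  genotype[callable & !is.na(f) & f >= hom_min] <- "hom_CT"
  genotype[callable & !is.na(f) & f >= het_min & f < hom_min] <- "het_CT"
  out <- data.table::as.data.table(pileup)[, intersect(c("chrom", "pos", "strand"),
                                                       names(pileup)), with = FALSE]
  out[, `:=`(genotype = genotype, alt_allele_fraction = f)]
  out[]
}

#' Screen a genome for C->T SNPs across samples
#'
#' `merged` mode sums base counts across samples before calling (high
#' power for shared variants); `per_sample` mode calls each sample
#' independently and keeps any position called in at least one sample
#' (catches variants private to one animal that dilute out of a merged
#' call). The returned set records its provenance.
#'
#' @param pileups Named list of per-sample pileup data.tables (or a
#'   `sim_pileups` object).
#' @param mode `"merged"` or `"per_sample"`.
#' @param min_cov,het_min,hom_min Passed to [call_site()].
#' @return A `snp_set` data.table: `chrom`, `pos`, `strand`, `genotype`,
#'   `alt_allele_fraction`, `mode`; non-ref calls only.
#' @export
screen_genome <- function(pileups, mode = c("merged", "per_sample"),
                          min_cov = 5, het_min = 0.1, hom_min = 0.85) {
  mode <- match.arg(mode)
  if (inherits(pileups, "sim_pileups")) pileups <- pileups$pileups
  key <- c("chrom", "pos", "strand")
  if (mode == "merged") {
    all_dt <- data.table::rbindlist(pileups)
    merged <- all_dt[, lapply(.SD, sum), by = key,
                     .SDcols = grep("^(this|opp)_", names(all_dt), value = TRUE)]
    calls <- call_site(merged, min_cov, het_min, hom_min)
    calls <- calls[genotype != "ref"]
  } else {
    per <- lapply(pileups, function(dt) {
      cc <- call_site(dt, min_cov, het_min, hom_min)
      cc[genotype != "ref"]
    })
    calls <- data.table::rbindlist(per)
    # one row per position: prefer hom over het, keep max allele fraction
    if (nrow(calls) > 0) {
      calls <- calls[order(chrom, pos, genotype != "hom_CT", -alt_allele_fraction)]
      calls <- calls[, .SD[1], by = key]
    }
  }
  data.table::set(calls, j = "mode", value = mode)
  data.table::setorder(calls, chrom, pos)
  structure(calls, class = c("snp_set", class(calls)))
}

#' Union of SNP call sets
#'
#' Position-wise union of any number of `snp_set`s, deduplicated; only C->T
#' genotypes are retained, since only they corrupt methylation calls. Where
#' the same position carries different genotypes across sets, the hom call
#' is kept — the exclusion downstream only needs the position.
#'
#' @param ... `snp_set` data.tables.
#' @return A single `snp_set` with `mode = "union"` on rows present in more
#'   than one input.
#' @export
union_snp_sets <- function(...) {
  sets <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(sets) == 0) {
    empty <- data.table::data.table(chrom = character(), pos = integer(),
                                    strand = character(), genotype = character(),
                                    alt_allele_fraction = numeric(), mode = character())
    return(structure(empty, class = c("snp_set", class(empty))))
  }
  all_dt <- data.table::rbindlist(sets, use.names = TRUE)
  all_dt <- all_dt[genotype %in% c("hom_CT", "het_CT")]
  all_dt[, n_modes := data.table::uniqueN(mode), by = .(chrom, pos)]
  all_dt <- all_dt[order(chrom, pos, genotype != "hom_CT")]
  out <- all_dt[, .SD[1], by = .(chrom, pos)]
  out[n_modes > 1, mode := "union"]
  out[, n_modes := NULL]
  data.table::setorder(out, chrom, pos)
  structure(out, class = c("snp_set", class(out)))
}

#' Write a SNP set as BED (0-based) and minimal VCF (1-based)
#' @param snps A `snp_set`.
#' @param bed_path,vcf_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_snp_set <- function(snps, bed_path = NULL, vcf_path = NULL) {
  written <- character()
  if (!is.null(bed_path)) {
    bed <- data.table::data.table(chrom = snps$chrom, start = snps$pos - 1L,
                                  end = snps$pos, name = snps$genotype)
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
    written <- c(written, bed_path)
  }
  if (!is.null(vcf_path)) {
    con <- file(vcf_path, "w")
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(snps) > 0) {
      gt <- ifelse(snps$genotype == "hom_CT", "1/1", "0/1")
      writeLines(sprintf("%s\t%d\t.\tC\tT\t.\tPASS\tGT=%s", snps$chrom,
                         snps$pos, gt), con)
    }
    close(con)
    written <- c(written, vcf_path)
  }
  invisible(written)
}
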